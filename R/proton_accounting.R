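#' Pathway proton-production factor
#'
#' The proton factor of a pathway is the arithmetic mean of the net proton
#' stoichiometric coefficients of its reactions,
#' \eqn{h_i = |R_i|^{-1} \sum_{r \in R_i} h_r}. Positive means net proton
#' production per unit flux.
#'
#' @param reactions A reactions tibble (columns `proton_coefficient`), a
#'   numeric vector of per-reaction coefficients, or a [glc_network] (then
#'   one factor per sink pathway is returned, named).
#' @return A single mean coefficient, or a named per-pathway vector for a
#'   network.
#' @export
pathway_proton_factor <- function(reactions) {
  if (inherits(reactions, "glc_network")) {
    rxns <- reactions$reactions
    return(vapply(
      setNames(reactions$sink_pathways, reactions$sink_pathways),
      function(p) mean(rxns$proton_coefficient[rxns$pathway == p]),
      numeric(1)))
  }
  hr <- if (is.data.frame(reactions)) reactions$proton_coefficient else reactions
  if (length(hr) == 0) {
    abort("Cannot average proton coefficients of an empty reaction set.",
          class = "glucoflux_domain_error")
  }
  mean(hr)
}

#' Pathway proton fluxes
#'
#' \eqn{J_{H^+,i} = v_i \cdot h_i}: elementwise product of pathway fluxes
#' and proton factors (matched by name when both are named).
#'
#' @param v Per-pathway fluxes (named numeric).
#' @param h Per-pathway proton factors (named numeric).
#' @return Named per-pathway proton fluxes.
#' @export
proton_fluxes <- function(v, h) {
  if (!is.null(names(v)) && !is.null(names(h))) {
    if (!setequal(names(v), names(h))) {
      abort("Flux and proton-factor pathway sets differ.",
            class = "glucoflux_shape_error")
    }
    h <- h[names(v)]
  } else if (length(v) != length(h)) {
    abort("Flux and proton-factor vectors have different lengths.",
          class = "glucoflux_shape_error")
  }
  v * h
}

#' Proton production fractions
#'
#' Net proton-consuming pathways (negative J) contribute nothing to
#' production: negative fluxes are clipped to zero and the remainder is
#' normalized to fractions summing to 1.
#'
#' @param J Named per-pathway proton fluxes.
#' @return Named fractions in \[0, 1\] summing to 1.
#' @export
proton_fractions <- function(J) {
  clipped <- pmax(J, 0)
  if (sum(clipped) <= 0) {
    abort("No pathway produces protons; production fractions undefined.",
          class = "glucoflux_domain_error")
  }
  clipped / sum(clipped)
}

#' Per-sample proton ledger for an allocation
#'
#' Combines per-sample sink fluxes with the network's pathway proton factors
#' into proton fluxes and production fractions.
#'
#' @param allocation A `glc_allocation` tibble from [allocate_fluxes()].
#' @param network The [glc_network] the allocation was computed on.
#' @return A tibble: sample, pathway, flux, `h` (proton factor), `J`
#'   (proton flux), `production_fraction`.
#' @export
proton_ledger <- function(allocation, network) {
  h <- pathway_proton_factor(network)
  df <- allocation
  df$h <- unname(h[df$pathway])
  df$J <- df$flux * df$h
  parts <- split(df, df$sample)
  out <- bind_rows(lapply(parts, function(d) {
    d$production_fraction <- as.numeric(proton_fractions(setNames(d$J, d$pathway)))
    d
  }))
  out <- out[order(match(out$sample, unique(allocation$sample))), ]
  out[, c("sample", "pathway", "flux", "h", "J", "production_fraction")]
}
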