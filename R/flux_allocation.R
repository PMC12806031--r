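#' Capacity bounds for sink fluxes
#'
#' Each sink's flux upper bound is the product of its positive scaled
#' pathway activity score G (from [pathway_activity_score()]) and its
#' estimated catalytic efficiency: \eqn{B = G \times k_{cat}/K_m}.
#'
#' @param G Sink-by-sample matrix of positive pathway activity scores (or a
#'   named per-sink vector for a single sample).
#' @param eff Named numeric of sink efficiencies (names = sink pathway
#'   labels, matching the rows of `G`).
#' @return Same shape as `G`: per-sink (per-sample) bounds.
#' @export
compute_flux_bounds <- function(G, eff) {
  if (any(unlist(G) < 0) || any(eff < 0)) {
    abort("Activity scores and efficiencies must be nonnegative.",
          class = "glucoflux_domain_error")
  }
  if (is.matrix(G)) {
    missing <- setdiff(rownames(G), names(eff))
    if (length(missing) > 0) {
      abort(paste("No efficiency for sink(s):",
                  paste(missing, collapse = ", ")),
            class = "glucoflux_domain_error")
    }
    return(G * eff[rownames(G)])
  }
  missing <- setdiff(names(G), names(eff))
  if (length(missing) > 0) {
    abort(paste("No efficiency for sink(s):", paste(missing, collapse = ", ")),
          class = "glucoflux_domain_error")
  }
  G * eff[names(G)]
}

#' Sink weights from capacity bounds
#'
#' The default square-root normalization
#' \eqn{w_s = \sqrt{B_s} / \sum_{s'} \sqrt{B_{s'}}} tempers the dynamic
#' range of the expression-based bounds; the plain linear normalization
#' \eqn{B_s / \sum B_{s'}} is available as `method = "linear"`. All-zero
#' bounds fall back to uniform weights with a warning.
#'
#' @param B Named nonnegative numeric vector of bounds.
#' @param method `"sqrt"` (default) or `"linear"`.
#' @return Named weights summing to 1.
#' @export
compute_sink_weights <- function(B, method = c("sqrt", "linear")) {
  method <- match.arg(method)
  if (any(B < 0)) {
    abort("Bounds must be nonnegative.", class = "glucoflux_domain_error")
  }
  raw <- if (method == "sqrt") sqrt(B) else B
  if (sum(raw) == 0) {
    warn("All bounds are zero; using uniform sink weights.")
    return(setNames(rep(1 / length(B), length(B)), names(B)))
  }
  raw / sum(raw)
}

#' Solve the balanced flux-allocation quadratic program for one sample
#'
#' Maximizes \eqn{\sum_s (w_s v_s - \lambda v_s^2)} over all reaction fluxes
#' subject to mass balance at every internal metabolite, total sink flux
#' equal to the glucose influx, nonnegativity, and per-sink capacity bounds
#' \eqn{0 \le v_s \le B_s}. The quadratic penalty discourages
#' winner-take-all allocations. Internal reaction fluxes are free
#' nonnegative variables bounded only by the balance constraints; a
#' negligible ridge (1e-6 of the sink curvature) on them makes the program
#' strictly convex and deterministically tie-breaks degenerate internal
#' routings.
#'
#' @param network A [glc_network].
#' @param bounds Named per-sink capacity bounds (names = sink pathways).
#' @param weights Named per-sink weights (default: [compute_sink_weights()]
#'   of `bounds`).
#' @param vglc_in Total glucose influx (nonnegative).
#' @param lambda_qp Quadratic penalty; default `1 / (2 * mean(bounds))`, so
#'   the quadratic term is comparable to the linear term at typical flux
#'   scales.
#' @return An object of class `glc_flux` with elements `vglc_in`, `flux`
#'   (tibble: reaction, pathway, flux), `sinks` (tibble: pathway, flux,
#'   bound, weight, fraction), `residuals` (named per-internal-metabolite),
#'   `objective`, `lambda_qp`.
#' @export
solve_flux_qp <- function(network, bounds, weights = NULL, vglc_in,
                          lambda_qp = NULL) {
  vglc_in <- assert_scalar(vglc_in, "vglc_in", 0)
  sinks <- network$sink_pathways
  if (!all(sinks %in% names(bounds))) {
    abort("`bounds` must name every sink pathway of the network.",
          class = "glucoflux_domain_error")
  }
  B <- pmax(as.numeric(bounds[sinks]), 0)
  names(B) <- sinks
  if (sum(B) < vglc_in * (1 - 1e-9)) {
    abort(sprintf(
      "Infeasible allocation: total sink capacity %.6g < influx %.6g (gap %.6g).",
      sum(B), vglc_in, vglc_in - sum(B)),
      class = "glucoflux_infeasible")
  }
  weights <- weights %||% compute_sink_weights(B)
  w <- as.numeric(weights[sinks])
  lambda_qp <- lambda_qp %||% (if (mean(B) > 0) 1 / (2 * mean(B)) else 1)
  lambda_qp <- assert_scalar(lambda_qp, "lambda_qp", 0, open_lower = TRUE)

  rxns <- network$reactions
  S_int <- internal_stoich_matrix(network)
  src_met <- network$metabolites$id[network$metabolites$role == "source"]
  # the uptake reaction consumes the source metabolite; its flux is fixed
  # at vglc_in and enters the internal balance as a constant
  is_uptake <- map_lgl(rxns$stoichiometry,
                       function(st) isTRUE(st[src_met] < 0))
  if (sum(is_uptake) != 1) {
    abort("Network must have exactly one source uptake reaction.",
          class = "glucoflux_schema_error")
  }
  free <- which(!is_uptake)
  sink_cols <- which(rxns$pathway[free] != "internal")
  sink_order <- rxns$pathway[free][sink_cols]

  A_eq <- S_int[, free, drop = FALSE]
  b_eq <- -as.numeric(S_int[, is_uptake, drop = FALSE]) * vglc_in

  nv <- length(free)
  curv <- rep(2 * lambda_qp * 1e-6, nv) # ridge on internal routing
  lin <- rep(0, nv)
  curv[sink_cols] <- 2 * lambda_qp
  lin[sink_cols] <- -w[match(sink_order, sinks)]
  ub <- rep(vglc_in + sum(B), nv)
  ub[sink_cols] <- B[match(sink_order, sinks)]
  lb <- rep(0, nv)

  binding <- sum(B) * (1 - 1e-9) <= vglc_in
  if (vglc_in == 0) {
    v <- rep(0, nv)
  } else if (binding) {
    # capacity-limited sample: the feasible set collapses to the (scaled)
    # bound vector, which the active-set solver cannot be asked to find;
    # sink fluxes are set analytically and the internal routing solved as an
    # exact nonnegative least-squares system
    v <- rep(0, nv)
    v[sink_cols] <- B[match(sink_order, sinks)] * (vglc_in / sum(B))
    int_cols <- setdiff(seq_len(nv), sink_cols)
    if (length(int_cols) > 0) {
      rhs <- b_eq - A_eq[, sink_cols, drop = FALSE] %*% v[sink_cols]
      ls <- pracma::lsqnonneg(A_eq[, int_cols, drop = FALSE],
                              as.numeric(rhs))
      v[int_cols] <- ls$x
    }
  } else {
    qp <- tryCatch(
      pracma::quadprog(C = diag(curv, nv), d = lin, Aeq = A_eq, beq = b_eq,
                       lb = lb, ub = ub),
      error = function(e) {
        abort(paste("QP solver failed:", conditionMessage(e)),
              class = "glucoflux_solver_error")
      })
    v <- qp$xmin
  }

  flux_all <- numeric(nrow(rxns))
  flux_all[is_uptake] <- vglc_in
  flux_all[free] <- pmax(v, 0)
  resid <- as.numeric(stoich_matrix(network)[
    network$metabolites$role == "internal", , drop = FALSE] %*% flux_all)
  names(resid) <- network$metabolites$id[network$metabolites$role == "internal"]

  sink_flux <- setNames(
    vapply(sinks, function(p) sum(flux_all[rxns$pathway == p]), numeric(1)),
    sinks)
  fractions <- if (vglc_in > 0) sink_flux / vglc_in else rep(NA_real_, length(sinks))
  objective <- sum(w * sink_flux - lambda_qp * sink_flux^2)

  structure(list(
    vglc_in = vglc_in,
    flux = tibble(reaction = rxns$id, pathway = rxns$pathway,
                  flux = flux_all),
    sinks = tibble(pathway = sinks, flux = unname(sink_flux),
                   bound = unname(B), weight = w,
                   fraction = unname(fractions)),
    residuals = resid,
    objective = objective,
    lambda_qp = lambda_qp
  ), class = "glc_flux")
}

#' @export
print.glc_flux <- function(x, ...) {
  cat(sprintf("<glc_flux> influx %.4g, %d sinks, max |residual| %.3g\n",
              x$vglc_in, nrow(x$sinks), max(abs(x$residuals))))
  print(x$sinks)
  invisible(x)
}

#' Per-sample flux allocation across a cohort
#'
#' Runs [solve_flux_qp()] for every sample: bounds come per sample from the
#' pathway activity scores, the influx from the sample's glucose-transporter
#' expression. When a sample's total sink capacity falls short of its
#' nominal influx the influx is rescaled down to the capacity
#' (`on_infeasible = "rescale"`, the default, since the absolute flux units
#' are arbitrary and all reported outputs are fractions) or an error is
#' raised (`"error"`).
#'
#' @param network A [glc_network].
#' @param bounds Sink-by-sample matrix of capacity bounds
#'   ([compute_flux_bounds()]).
#' @param vglc_in Named per-sample influx values (see
#'   [glucose_influx()]).
#' @param lambda_qp Optional quadratic penalty; by default each sample uses
#'   `1 / (2 * mean(bounds[, sample]))`.
#' @param on_infeasible `"rescale"` or `"error"`.
#' @return A long tibble (class `glc_allocation`): sample, pathway, flux,
#'   bound, weight, fraction, vglc_in.
#' @export
allocate_fluxes <- function(network, bounds, vglc_in, lambda_qp = NULL,
                            on_infeasible = c("rescale", "error")) {
  on_infeasible <- match.arg(on_infeasible)
  samples <- colnames(bounds)
  if (is.null(samples) || is.null(names(vglc_in))) {
    abort("`bounds` needs sample colnames and `vglc_in` sample names.",
          class = "glucoflux_domain_error")
  }
  missing <- setdiff(samples, names(vglc_in))
  if (length(missing) > 0) {
    abort(paste("No influx for sample(s):",
                paste(head(missing, 5), collapse = ", ")),
          class = "glucoflux_domain_error")
  }
  n_rescaled <- 0L
  rows <- lapply(samples, function(s) {
    B <- bounds[, s]
    V <- unname(vglc_in[s])
    if (sum(B) < V) {
      if (on_infeasible == "error") {
        abort(sprintf(
          "Sample %s infeasible: capacity %.6g < influx %.6g.", s, sum(B), V),
          class = "glucoflux_infeasible")
      }
      V <- sum(B)
      n_rescaled <<- n_rescaled + 1L
    }
    sol <- solve_flux_qp(network, B, vglc_in = V, lambda_qp = lambda_qp)
    out <- sol$sinks
    out$sample <- s
    out$vglc_in <- V
    out
  })
  out <- bind_rows(rows)[, c("sample", "pathway", "flux", "bound", "weight",
                             "fraction", "vglc_in")]
  if (n_rescaled > 0) {
    message(sprintf(
      "Influx exceeded sink capacity in %d/%d samples; rescaled to capacity.",
      n_rescaled, length(samples)))
  }
  class(out) <- c("glc_allocation", class(out))
  out
}

#' Per-sample glucose influx from transporter expression
#'
#' The nominal glucose influx of a sample is the sum of the linear-scale TPM
#' of the glucose transporter genes (by default SLC2A1, SLC2A3, SLC5A1,
#' SLC5A2 and SLC2A10). The absolute units are arbitrary; all reported
#' allocation outputs are fractions of this influx.
#'
#' @param expr Gene-by-sample matrix of log2(TPM+1) expression.
#' @param transporters Character vector of transporter gene ids.
#' @return Named per-sample numeric influx.
#' @export
glucose_influx <- function(expr,
                           transporters = c("SLC2A1", "SLC2A3", "SLC5A1",
                                            "SLC5A2", "SLC2A10")) {
  expr <- as_expression_matrix(expr)
  present <- intersect(transporters, rownames(expr))
  if (length(present) == 0) {
    abort("None of the transporter genes are in the expression matrix.",
          class = "glucoflux_missing_gene")
  }
  colSums(log2_to_tpm(expr[present, , drop = FALSE]))
}

#' Mean allocation fractions by sample group
#'
#' Aggregates per-sample allocation fractions to mean percentages per
#' pathway, optionally within metadata groups (e.g. tumor stage).
#'
#' @param allocation A `glc_allocation` tibble from [allocate_fluxes()].
#' @param metadata Optional tibble with `sample_id` plus grouping columns.
#' @param by Character vector of metadata columns to group by.
#' @return A tibble: grouping columns, pathway, `mean_fraction`,
#'   `mean_percent`.
#' @export
allocation_fractions <- function(allocation, metadata = NULL, by = "stage") {
  if (any(allocation$vglc_in == 0)) {
    abort("Allocation fractions undefined for samples with zero influx.",
          class = "glucoflux_domain_error")
  }
  df <- allocation
  if (!is.null(metadata)) {
    df <- left_join(df, metadata, by = c(sample = "sample_id"))
    df <- group_by(df, across(all_of(c(by, "pathway"))))
  } else {
    df <- group_by(df, .data$pathway)
  }
  out <- summarise(df, mean_fraction = mean(.data$fraction),
                   n_samples = dplyr::n_distinct(.data$sample),
                   .groups = "drop")
  out$mean_percent <- 100 * out$mean_fraction
  out
}

#' @export
autoplot.glc_allocation <- function(object, ...) {
  means <- allocation_fractions(object)
  means$pathway <- stats::reorder(means$pathway, -means$mean_percent)
  ggplot2::ggplot(means,
                  ggplot2::aes(x = .data$pathway, y = .data$mean_percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "mean % of glucose influx",
                  title = "Glucose flux allocation across sink pathways") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 40, hjust = 1))
}

#' Lactate fate weights from export and lactylation activity scores
#'
#' Nonnegative ssGSEA-derived scores are log-compressed
#' (\eqn{z_i = \ln(1 + s_i)}), converted to a temperature-scaled softmax,
#' and blended with a uniform prior:
#' \eqn{w_i = \alpha/2 + (1-\alpha)\,\tilde w_i}. Higher temperature or a
#' stronger prior pulls the weights toward an even split.
#'
#' @param s_export,s_lactylation Nonnegative activity scores (vectors of
#'   equal length are allowed).
#' @param tau Softmax temperature (> 0, default 1).
#' @param alpha Uniform-prior blend in (0, 1), default 0.2.
#' @return A tibble with columns `s_export`, `s_lactylation`, `z_export`,
#'   `z_lactylation`, `w_export`, `w_lactylation` (weights sum to 1).
#' @export
lactate_fate_weights <- function(s_export, s_lactylation, tau = 1,
                                 alpha = 0.2) {
  tau <- assert_scalar(tau, "tau", 0, open_lower = TRUE)
  alpha <- assert_scalar(alpha, "alpha", 0, 1, open_lower = TRUE,
                         open_upper = TRUE)
  if (any(s_export < 0) || any(s_lactylation < 0)) {
    abort("Activity scores must be nonnegative (shift them upstream).",
          class = "glucoflux_domain_error")
  }
  s_export <- unname(s_export)
  s_lactylation <- unname(s_lactylation)
  z_e <- log1p(s_export)
  z_l <- log1p(s_lactylation)
  m <- pmax(z_e, z_l) / tau # stabilized softmax
  soft_e <- exp(z_e / tau - m) / (exp(z_e / tau - m) + exp(z_l / tau - m))
  w_e <- alpha * 0.5 + (1 - alpha) * soft_e
  tibble(s_export = s_export, s_lactylation = s_lactylation,
         z_export = z_e, z_lactylation = z_l,
         w_export = w_e, w_lactylation = 1 - w_e)
}

#' Partition lactate flux between export and lactylation
#'
#' Solves \eqn{\max\, w_1 v_1 + w_2 v_2 - \lambda(v_1^2 + v_2^2)} subject to
#' \eqn{v_1 + v_2 = v_{lactate}}, \eqn{v \ge 0}. The optimum has the closed
#' form \eqn{v_1 = \mathrm{clip}(L/2 + (w_1 - w_2)/(4\lambda),\, 0,\, L)},
#' which this function evaluates exactly.
#'
#' @param v_lactate Nonnegative lactate flux (vectorized).
#' @param weights Tibble from [lactate_fate_weights()] (recycled if one
#'   row), or a length-2 numeric `c(w_export, w_lactylation)`.
#' @param lambda_qp Quadratic penalty (> 0).
#' @return A tibble with columns `v_lactate`, `v_export`, `v_lactylation`
#'   (the two parts sum to `v_lactate` exactly).
#' @export
partition_lactate <- function(v_lactate, weights, lambda_qp = 0.5) {
  lambda_qp <- assert_scalar(lambda_qp, "lambda_qp", 0, open_lower = TRUE)
  if (any(v_lactate < 0)) {
    abort("`v_lactate` must be nonnegative.",
          class = "glucoflux_domain_error")
  }
  if (is.data.frame(weights)) {
    w1 <- weights$w_export
    w2 <- weights$w_lactylation
  } else {
    w1 <- unname(weights[1])
    w2 <- unname(weights[2])
  }
  v_lactate <- unname(v_lactate)
  v1 <- pmin(pmax(v_lactate / 2 + (w1 - w2) / (4 * lambda_qp), 0), v_lactate)
  tibble(v_lactate = v_lactate, v_export = v1, v_lactylation = v_lactate - v1)
}
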