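#' Analysis configuration
#'
#' Single home for every tunable scalar of the pipeline, each tagged with
#' its provenance: `"stated"` for values fixed by the published analysis,
#' `"decision"` for defaults this implementation had to choose. Print the
#' config to see the provenance table.
#'
#' @param gamma Fold-change tempering exponent of the gene weights (0.75).
#' @param eta Significance exponent of the gene weights (0.7).
#' @param r_threshold Co-expression edge threshold on |Pearson r| (0.8).
#' @param poly_degree Polynomial expansion degree (2).
#' @param r2_stop Forward-selection R-squared stop (0.95).
#' @param max_features Maximum selected polynomial terms; `NULL` means
#'   `floor(n_samples / 10)`.
#' @param ssgsea_exponent ssGSEA rank-weighting exponent (0.25).
#' @param lambda_qp Quadratic flux penalty; `NULL` means
#'   `1 / (2 * mean(bounds))` per sample.
#' @param lambda_nnls Named prior-adherence strengths for the efficiency
#'   NNLS (curated 1.0, predicted 0.5, fallback 0.1).
#' @param tau Softmax temperature of the lactate fate weights (1.0).
#' @param alpha Uniform-prior blend of the lactate fate weights (0.2).
#' @param n_perm Permutations for the ATE test (500).
#' @param pls_components Retained PLS components (1).
#' @param top_proliferation_genes Size of the proliferation signature (500).
#' @param p_adj_threshold Adjusted-p threshold of the upregulation filter
#'   (0.05).
#' @param weight_method Sink-weight normalization, `"sqrt"` or `"linear"`.
#' @param activity_scale Expression scale of the activity proxy,
#'   `"linear"` (TPM) or `"log2"`.
#' @param seed Master seed for all randomized stages.
#' @return A validated list of class `glc_config`.
#' @export
flux_config <- function(gamma = 0.75, eta = 0.7, r_threshold = 0.8,
                        poly_degree = 2, r2_stop = 0.95, max_features = NULL,
                        ssgsea_exponent = 0.25, lambda_qp = NULL,
                        lambda_nnls = c(curated = 1.0, predicted = 0.5,
                                        fallback = 0.1),
                        tau = 1.0, alpha = 0.2, n_perm = 500,
                        pls_components = 1, top_proliferation_genes = 500,
                        p_adj_threshold = 0.05,
                        weight_method = c("sqrt", "linear"),
                        activity_scale = c("linear", "log2"),
                        seed = 1) {
  cfg <- list(
    gamma = assert_scalar(gamma, "gamma", 0, open_lower = TRUE),
    eta = assert_scalar(eta, "eta", 0, open_lower = TRUE),
    r_threshold = assert_scalar(r_threshold, "r_threshold", 0),
    poly_degree = assert_count(poly_degree, "poly_degree", 1),
    r2_stop = assert_scalar(r2_stop, "r2_stop", 0, 1),
    max_features = if (is.null(max_features)) NULL else {
      assert_count(max_features, "max_features", 1)
    },
    ssgsea_exponent = assert_scalar(ssgsea_exponent, "ssgsea_exponent", 0),
    lambda_qp = if (is.null(lambda_qp)) NULL else {
      assert_scalar(lambda_qp, "lambda_qp", 0, open_lower = TRUE)
    },
    lambda_nnls = lambda_nnls,
    tau = assert_scalar(tau, "tau", 0, open_lower = TRUE),
    alpha = assert_scalar(alpha, "alpha", 0, 1, open_lower = TRUE,
                          open_upper = TRUE),
    n_perm = assert_count(n_perm, "n_perm", 1),
    pls_components = assert_count(pls_components, "pls_components", 1),
    top_proliferation_genes = assert_count(top_proliferation_genes,
                                           "top_proliferation_genes", 1),
    p_adj_threshold = assert_scalar(p_adj_threshold, "p_adj_threshold", 0, 1),
    weight_method = match.arg(weight_method),
    activity_scale = match.arg(activity_scale),
    seed = assert_count(seed, "seed", 0)
  )
  if (!all(c("curated", "predicted", "fallback") %in% names(cfg$lambda_nnls)) ||
      any(cfg$lambda_nnls < 0)) {
    abort("`lambda_nnls` needs nonnegative entries named curated, predicted, fallback.",
          class = "glucoflux_invalid_config")
  }
  structure(cfg, class = "glc_config")
}

config_provenance <- function() {
  tibble(
    parameter = c("gamma", "eta", "r_threshold", "poly_degree", "r2_stop",
                  "n_perm", "top_proliferation_genes", "p_adj_threshold",
                  "pls_components", "max_features", "ssgsea_exponent",
                  "lambda_qp", "lambda_nnls", "tau", "alpha",
                  "weight_method", "activity_scale"),
    provenance = c(rep("stated", 9), rep("decision", 8))
  )
}

#' @export
print.glc_config <- function(x, ...) {
  cat("<glc_config>\n")
  prov <- config_provenance()
  for (i in seq_len(nrow(prov))) {
    p <- prov$parameter[i]
    val <- x[[p]]
    val_str <- if (is.null(val)) "auto" else paste(format(val), collapse = "/")
    cat(sprintf("  %-24s %-12s [%s]\n", p, val_str, prov$provenance[i]))
  }
  cat(sprintf("  %-24s %-12s\n", "seed", x$seed))
  invisible(x)
}

#' Read / write an analysis configuration as YAML
#'
#' Unknown keys raise an error; missing keys take their defaults. The
#' round trip `read_flux_config(write_flux_config(cfg, path))` is the
#' identity.
#'
#' @param path File path.
#' @return `read_flux_config()` returns a `glc_config`.
#' @export
read_flux_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path),
          class = "glucoflux_io_error")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(flux_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste("Unknown config field(s):", paste(unknown, collapse = ", ")),
          class = "glucoflux_invalid_config")
  }
  if (!is.null(raw$lambda_nnls)) raw$lambda_nnls <- unlist(raw$lambda_nnls)
  do.call(flux_config, raw)
}

#' @param config A `glc_config`.
#' @rdname read_flux_config
#' @export
write_flux_config <- function(config, path) {
  out <- unclass(config)
  out$lambda_nnls <- as.list(out$lambda_nnls)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}
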