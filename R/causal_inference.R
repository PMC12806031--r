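#' Construct the treatment, outcome and confounder variables
#'
#' Builds the causal triple for the nucleotide-synthesis -> cell-cycle
#' analysis: the treatment T is the per-tumor-sample ssGSEA score of the
#' nucleotide-synthesis genes that are upregulated in tumors (fold change
#' >= 0, adjusted p < 0.05); the confounder W is the ssGSEA score of the
#' proliferation signature with nucleotide genes removed (so the two gene
#' sets are disjoint); the outcome Y is log2 MKI67 expression. All three are
#' z-scored across the included samples.
#'
#' @param expr Gene-by-sample matrix of log2 expression (tumor samples, or
#'   pass `samples` to subset).
#' @param de Differential-expression table from
#'   [differential_expression()].
#' @param nucleotide_genes Nucleotide-synthesis pathway gene set.
#' @param proliferation_genes General proliferation signature gene set.
#' @param mki67 Proliferation marker gene id (default `"MKI67"`).
#' @param samples Optional character vector of sample columns to use.
#' @param exponent ssGSEA rank-weighting exponent.
#' @return A tibble (class `glc_causal_triple`) with columns `sample`, `T`,
#'   `Y`, `W`; attributes `treatment_genes` and `confounder_genes` record
#'   the refined sets.
#' @export
construct_causal_variables <- function(expr, de, nucleotide_genes,
                                       proliferation_genes, mki67 = "MKI67",
                                       samples = NULL, exponent = 0.25) {
  expr <- as_expression_matrix(expr)
  if (!is.null(samples)) expr <- expr[, samples, drop = FALSE]
  if (!mki67 %in% rownames(expr)) {
    abort(sprintf("Proliferation marker '%s' not in the expression matrix.",
                  mki67),
          class = "glucoflux_missing_marker")
  }
  up <- de$gene[de$upregulated]
  t_set <- intersect(intersect(nucleotide_genes, up), rownames(expr))
  if (length(t_set) == 0) {
    abort("No nucleotide-synthesis gene passes the upregulation filter.",
          class = "glucoflux_empty_signature")
  }
  w_set <- intersect(setdiff(proliferation_genes, nucleotide_genes),
                     rownames(expr))
  if (length(w_set) == 0) {
    abort("Proliferation signature is empty after removing nucleotide genes.",
          class = "glucoflux_empty_signature")
  }
  zscore <- function(x) (x - mean(x)) / sd(x)
  T_ <- apply(expr, 2, ssgsea_score, gene_set = t_set, exponent = exponent)
  W <- apply(expr, 2, ssgsea_score, gene_set = w_set, exponent = exponent)
  Y <- expr[mki67, ]
  out <- tibble(sample = colnames(expr),
                T = zscore(T_), Y = zscore(Y), W = zscore(W))
  attr(out, "treatment_genes") <- t_set
  attr(out, "confounder_genes") <- w_set
  class(out) <- c("glc_causal_triple", class(out))
  out
}

#' Backdoor-adjusted average treatment effect
#'
#' With the proliferation confounder W blocking the only backdoor path from
#' treatment to outcome, the average treatment effect is identified by
#' adjusting for W; it is estimated as the coefficient on T in the
#' multivariable OLS regression \eqn{Y = \beta_0 + \beta_{ATE} T + \beta_W W}.
#'
#' @param triple A data frame with columns `T`, `Y`, `W` (e.g. from
#'   [construct_causal_variables()] or [simulate_causal_data()]).
#' @return An object of class `glc_ate`: `ate`, `beta_w`, `intercept`,
#'   `unadjusted` (simple Y ~ T slope), `model`, `n`. Extend it with
#'   [permutation_test()] and [refute_with_latent_confounder()].
#' @export
estimate_ate <- function(triple) {
  n <- nrow(triple)
  if (n < 10) {
    abort("Need at least 10 samples to estimate the ATE.",
          class = "glucoflux_insufficient_data")
  }
  if (abs(cor(triple$T, triple$W)) >= 0.999) {
    abort("Treatment and confounder are collinear; the ATE is not identifiable.",
          class = "glucoflux_non_identifiable")
  }
  model <- lm(Y ~ T + W, data = triple)
  est <- coef(model)
  unadj <- coef(lm(Y ~ T, data = triple))[["T"]]
  structure(list(ate = unname(est["T"]), beta_w = unname(est["W"]),
                 intercept = unname(est["(Intercept)"]),
                 unadjusted = unadj, model = model, n = n,
                 permutation_p = NULL, refutation_curve = NULL),
            class = "glc_ate")
}

#' @export
print.glc_ate <- function(x, ...) {
  cat(sprintf("<glc_ate> ATE = %.4f (unadjusted %.4f), beta_W = %.4f, n = %d\n",
              x$ate, x$unadjusted, x$beta_w, x$n))
  if (!is.null(x$permutation_p)) {
    cat(sprintf("permutation p = %.4g\n", x$permutation_p))
  }
  invisible(x)
}

#' @export
tidy.glc_ate <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble(term = c("(Intercept)", "T", "W"),
         estimate = c(x$intercept, x$ate, x$beta_w),
         std.error = sm[, "Std. Error"],
         p.value = sm[, "Pr(>|t|)"])
}

#' @export
glance.glc_ate <- function(x, ...) {
  tibble(ate = x$ate, unadjusted = x$unadjusted, beta_w = x$beta_w,
         nobs = x$n,
         permutation_p = x$permutation_p %||% NA_real_)
}

# ATE from precomputed cross-products; used by the permutation fast path.
ate_from_sums <- function(n, sT, sW, sY, sTT, sWW, sTW, sTY, sWY) {
  XtX <- matrix(c(n, sT, sW,
                  sT, sTT, sTW,
                  sW, sTW, sWW), 3, 3)
  Xty <- c(sY, sTY, sWY)
  solve(XtX, Xty)[2]
}

#' Permutation test for the adjusted treatment effect
#'
#' Shuffles the treatment variable `n_perm` times, re-estimating the
#' adjusted ATE each time, and reports the add-one permutation p-value
#' \eqn{p = (1 + \#\{|\beta^{perm}| \ge |\beta^{obs}|\}) / (n_{perm} + 1)},
#' never exactly zero by construction.
#'
#' @param triple A data frame with columns `T`, `Y`, `W`.
#' @param n_perm Number of permutations (default 500).
#' @param seed Integer seed.
#' @return The permutation p-value, with the null ATEs as attribute
#'   `null_ates`.
#' @export
permutation_test <- function(triple, n_perm = 500, seed = 1) {
  n_perm <- assert_count(n_perm, "n_perm", 1)
  T_ <- triple$T
  W <- triple$W
  Y <- triple$Y
  n <- length(T_)
  obs <- estimate_ate(triple)$ate
  sW <- sum(W); sY <- sum(Y); sWW <- sum(W * W); sWY <- sum(W * Y)
  sT <- sum(T_); sTT <- sum(T_ * T_)
  null_ates <- with_seed(child_seed(seed, 4), {
    vapply(seq_len(n_perm), function(i) {
      Tp <- T_[sample.int(n)]
      ate_from_sums(n, sT, sW, sY, sTT, sWW,
                    sum(Tp * W), sum(Tp * Y), sWY)
    }, numeric(1))
  })
  p <- (1 + sum(abs(null_ates) >= abs(obs))) / (n_perm + 1)
  attr(p, "null_ates") <- null_ates
  p
}

#' Latent-confounder refutation curve
#'
#' Probes sensitivity to unobserved confounding: for each strength c a
#' simulated standard-normal latent variable U is added to both the
#' (z-scored) treatment and outcome with coefficient c, and the adjusted ATE
#' is re-estimated. At c = 0 the curve equals the original estimate; the
#' drift with |c| measures how much hidden confounding would be needed to
#' overturn the conclusion.
#'
#' @param triple A data frame with columns `T`, `Y`, `W`.
#' @param strengths Numeric vector of confounder strengths.
#' @param seed Integer seed (one latent draw is shared across strengths so
#'   the curve is smooth in c).
#' @return A tibble (class `glc_refutation`): `strength`, `ate`.
#' @export
refute_with_latent_confounder <- function(triple,
                                          strengths = seq(0, 1, by = 0.25),
                                          seed = 1) {
  if (length(strengths) == 0) {
    abort("`strengths` must be non-empty.", class = "glucoflux_domain_error")
  }
  U <- with_seed(child_seed(seed, 5), rnorm(nrow(triple)))
  out <- tibble(
    strength = strengths,
    ate = vapply(strengths, function(cc) {
      tr <- triple
      tr$T <- tr$T + cc * U
      tr$Y <- tr$Y + cc * U
      estimate_ate(tr)$ate
    }, numeric(1)))
  class(out) <- c("glc_refutation", class(out))
  out
}

#' @export
autoplot.glc_refutation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$strength, y = .data$ate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$ate[object$strength == 0],
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "latent confounder strength",
                  y = "re-estimated ATE",
                  title = "Refutation: sensitivity to an unobserved confounder") +
    ggplot2::theme_minimal()
}

#' Partial-regression coordinates for the treatment-outcome relation
#'
#' Residualizes both Y and T on the confounder W; the slope of the returned
#' point cloud equals the adjusted ATE (Frisch-Waugh-Lovell).
#'
#' @param triple A data frame with columns `T`, `Y`, `W`.
#' @return A tibble: `sample` (if present), `t_resid`, `y_resid`.
#' @export
partial_regression <- function(triple) {
  t_res <- stats::residuals(lm(T ~ W, data = triple))
  y_res <- stats::residuals(lm(Y ~ W, data = triple))
  out <- tibble(t_resid = unname(t_res), y_resid = unname(y_res))
  if ("sample" %in% names(triple)) {
    out <- dplyr::bind_cols(tibble(sample = triple$sample), out)
  }
  out
}

#' Scatter plot of the partial-regression coordinates
#'
#' @param triple A data frame with columns `T`, `Y`, `W`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_partial_regression <- function(triple, ...) {
  pr <- partial_regression(triple)
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$t_resid, y = .data$y_resid)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "treatment | confounder", y = "outcome | confounder",
                  title = "Partial regression: nucleotide synthesis vs cell cycle") +
    ggplot2::theme_minimal()
}
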