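#' Partial least squares regression with a single response (PLS1)
#'
#' NIPALS extraction of k latent components maximizing covariance between
#' the centered predictor matrix X and the centered response y. For PLS1 the
#' first weight vector is proportional to \eqn{X^\top y} (after centering),
#' successive components are extracted from the deflated matrix, and the
#' X-scores of different components are mutually orthogonal.
#'
#' @param X Sample-by-gene numeric matrix.
#' @param y Per-sample response vector (non-constant).
#' @param k Number of components (default 1; must satisfy `k < n - 1`).
#' @return An object of class `glc_pls`: `scores` (n-by-k matrix T),
#'   `x_weights` (W), `x_loadings` (P), `y_loadings` (q), `x_center`,
#'   `y_center`, `k`.
#' @export
fit_pls <- function(X, y, k = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) {
    abort("`y` must have one value per row of `X`.",
          class = "glucoflux_shape_error")
  }
  if (n < k + 2) {
    abort(sprintf("Need at least k + 2 = %d samples for %d component(s).",
                  k + 2, k),
          class = "glucoflux_rank_error")
  }
  if (sd(y) == 0) {
    abort("Response is constant; PLS is degenerate.",
          class = "glucoflux_degenerate_response")
  }
  x_center <- colMeans(X)
  y_center <- mean(y)
  Xc <- sweep(X, 2, x_center)
  yc <- y - y_center

  p <- ncol(X)
  W <- matrix(0, p, k)
  P <- matrix(0, p, k)
  Tm <- matrix(0, n, k)
  q <- numeric(k)
  for (comp in seq_len(k)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      abort(sprintf("X carries no covariance with y at component %d.", comp),
            class = "glucoflux_rank_error")
    }
    w <- w / nw
    t_ <- drop(Xc %*% w)
    tt <- sum(t_^2)
    p_ <- drop(crossprod(Xc, t_)) / tt
    q[comp] <- sum(yc * t_) / tt
    Xc <- Xc - tcrossprod(t_, p_)
    yc <- yc - q[comp] * t_
    W[, comp] <- w
    P[, comp] <- p_
    Tm[, comp] <- t_
  }
  dimnames(W) <- list(colnames(X), paste0("comp", seq_len(k)))
  dimnames(P) <- dimnames(W)
  dimnames(Tm) <- list(rownames(X), paste0("comp", seq_len(k)))
  structure(list(scores = Tm, x_weights = W, x_loadings = P,
                 y_loadings = q, x_center = x_center, y_center = y_center,
                 k = k),
            class = "glc_pls")
}

#' @export
print.glc_pls <- function(x, ...) {
  cat(sprintf("<glc_pls> %d component(s), %d genes, %d samples\n",
              x$k, nrow(x$x_weights), nrow(x$scores)))
  invisible(x)
}

#' @export
tidy.glc_pls <- function(x, ...) {
  out <- as_tibble(x$x_weights, rownames = "gene")
  tidyr::pivot_longer(out, -"gene", names_to = "component",
                      values_to = "weight")
}

#' @export
glance.glc_pls <- function(x, ...) {
  tibble(k = x$k, n_genes = nrow(x$x_weights), nobs = nrow(x$scores))
}

#' OLS regression of an outcome on PLS signature scores
#'
#' Fits \eqn{Y_i = \beta_0 + \sum_j \beta_j T_{ij} + \epsilon_i} with
#' intercept and reports the coefficient of determination
#' \eqn{R^2 = 1 - \mathrm{SSE}/\mathrm{SST}} and the residual SD.
#'
#' @param scores Sample-by-component score matrix (or a `glc_pls` object).
#' @param outcome Per-sample outcome vector.
#' @return An object of class `glc_sigfit`: `coefficients`, `r2`, `sigma`,
#'   `model`, `n`.
#' @export
score_signature_regression <- function(scores, outcome) {
  if (inherits(scores, "glc_pls")) scores <- scores$scores
  scores <- as.matrix(scores)
  if (nrow(scores) != length(outcome)) {
    abort("Scores and outcome cover different numbers of samples.",
          class = "glucoflux_alignment_error")
  }
  if (nrow(scores) <= ncol(scores) + 1) {
    abort("Need n > k + 1 samples for the score regression.",
          class = "glucoflux_insufficient_data")
  }
  if (is.null(colnames(scores))) {
    colnames(scores) <- paste0("comp", seq_len(ncol(scores)))
  }
  df <- data.frame(scores, check.names = FALSE)
  df$.outcome <- outcome
  model <- lm(.outcome ~ ., data = df)
  sm <- summary(model)
  structure(list(coefficients = coef(model), r2 = sm$r.squared,
                 sigma = sm$sigma, model = model, n = nrow(scores)),
            class = "glc_sigfit")
}

#' @export
print.glc_sigfit <- function(x, ...) {
  cat(sprintf("<glc_sigfit> R^2 = %.4f, residual SD = %.4f, n = %d\n",
              x$r2, x$sigma, x$n))
  invisible(x)
}

#' @export
tidy.glc_sigfit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble(term = gsub("^`|`$", "", rownames(sm)),
         estimate = sm[, "Estimate"],
         std.error = sm[, "Std. Error"],
         p.value = sm[, "Pr(>|t|)"])
}

#' @export
glance.glc_sigfit <- function(x, ...) {
  tibble(r.squared = x$r2, sigma = x$sigma, nobs = x$n)
}

#' Fenton-reaction neutralization regression
#'
#' Scores the Fenton-reaction gene set and each of the glucose sink
#' pathways by one-component PLS (response: the per-sample mean expression
#' of the respective set), then regresses the Fenton score on the eight
#' pathway scores. The R-squared measures the fraction of Fenton-reaction
#' variability jointly explained by glucose-downstream metabolism.
#'
#' @param expr Gene-by-sample matrix of log2 expression (tumor samples).
#' @param fenton_genes Fenton-reaction gene set.
#' @param pathway_sets Named list of the sink-pathway gene sets.
#' @return A `glc_sigfit` whose coefficients follow the order of
#'   `pathway_sets`; the per-sample scores are attached as attribute
#'   `scores` (tibble with fenton plus one column per pathway).
#' @export
fenton_neutralization_fit <- function(expr, fenton_genes, pathway_sets) {
  expr <- as_expression_matrix(expr)
  pls1_score <- function(genes, label) {
    gs <- intersect(genes, rownames(expr))
    if (length(gs) == 0) {
      abort(sprintf("Gene set '%s' is empty in the expression matrix.", label),
            class = "glucoflux_empty_signature")
    }
    Xk <- t(expr[gs, , drop = FALSE])
    yk <- colMeans(expr[gs, , drop = FALSE])
    drop(fit_pls(Xk, yk, k = 1)$scores)
  }
  t_f <- pls1_score(fenton_genes, "fenton")
  t_k <- vapply(names(pathway_sets),
                function(p) pls1_score(pathway_sets[[p]], p),
                numeric(ncol(expr)))
  fit <- score_signature_regression(t_k, t_f)
  attr(fit, "scores") <- dplyr::bind_cols(
    tibble(sample = colnames(expr), fenton = t_f),
    as_tibble(t_k))
  fit
}

#' Mean log2 expression of a migration gene set
#'
#' @param expr Gene-by-sample matrix of log2 expression.
#' @param migration_genes Curated migration gene set.
#' @return Named per-sample mean expression.
#' @export
migration_outcome <- function(expr, migration_genes) {
  expr <- as_expression_matrix(expr)
  gs <- intersect(migration_genes, rownames(expr))
  if (length(gs) == 0) {
    abort("Migration gene set is empty in the expression matrix.",
          class = "glucoflux_empty_signature")
  }
  colMeans(expr[gs, , drop = FALSE])
}
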