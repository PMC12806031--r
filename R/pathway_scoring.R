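#' Single-sample gene-set enrichment score (ssGSEA)
#'
#' Barbie-style single-sample enrichment: genes are ranked by descending
#' expression; at each rank the difference between the weighted in-set
#' empirical CDF and the unweighted out-of-set CDF is accumulated, and the
#' score is the sum of those differences over all ranks. In-set weights are
#' \eqn{|x|^{\mathrm{exponent}}}; with exponent 0 the score reduces to a
#' hand-computable ECDF-difference sum.
#'
#' @param sample_expression Named numeric vector of one sample's expression.
#' @param gene_set Character vector of gene ids.
#' @param exponent Rank-weighting exponent (default 0.25).
#' @return A single numeric enrichment score.
#' @export
ssgsea_score <- function(sample_expression, gene_set, exponent = 0.25) {
  x <- sample_expression
  if (is.null(names(x))) {
    abort("`sample_expression` must be named by gene id.",
          class = "glucoflux_domain_error")
  }
  inset <- names(x) %in% gene_set
  if (!any(inset)) {
    abort("Gene set does not intersect the expressed genes.",
          class = "glucoflux_domain_error")
  }
  if (all(inset)) {
    abort("Gene-set complement is empty; the score is undefined.",
          class = "glucoflux_domain_error")
  }
  ord <- order(x, decreasing = TRUE)
  inset <- inset[ord]
  w <- abs(x[ord])^exponent
  w[!inset] <- 0
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!inset) / sum(!inset)
  sum(p_in - p_out)
}

#' ssGSEA scores for several gene sets across all samples
#'
#' @param expr Gene-by-sample matrix of log2 expression.
#' @param gene_sets Named list of gene-id vectors.
#' @param exponent Rank-weighting exponent (default 0.25).
#' @return A pathway-by-sample numeric matrix of enrichment scores.
#' @export
ssgsea_matrix <- function(expr, gene_sets, exponent = 0.25) {
  expr <- as_expression_matrix(expr)
  out <- matrix(NA_real_, nrow = length(gene_sets), ncol = ncol(expr),
                dimnames = list(names(gene_sets), colnames(expr)))
  for (i in seq_len(ncol(expr))) {
    x <- expr[, i]
    for (p in names(gene_sets)) {
      out[p, i] <- ssgsea_score(x, gene_sets[[p]], exponent)
    }
  }
  out
}

#' Positive scaled pathway activity score
#'
#' Transforms raw per-sample ssGSEA values of one pathway into strictly
#' positive capacity scores \eqn{G = e^z}, where z is the within-pathway
#' z-score across samples (population SD). The transform is strictly
#' monotone, so sample ordering is preserved; a pathway with zero variance
#' across samples yields G = 1 everywhere with a warning.
#'
#' @param scores Numeric vector of one pathway's ssGSEA values across
#'   samples (length >= 2), or a pathway-by-sample matrix (each row is
#'   transformed independently).
#' @return Same shape as the input, strictly positive.
#' @export
pathway_activity_score <- function(scores) {
  if (is.matrix(scores)) {
    out <- t(apply(scores, 1, pathway_activity_score))
    dimnames(out) <- dimnames(scores)
    return(out)
  }
  if (length(scores) < 2) {
    abort("Need >= 2 samples to standardize pathway scores.",
          class = "glucoflux_insufficient_data")
  }
  mu <- mean(scores)
  sdev <- sqrt(mean((scores - mu)^2))
  if (sdev == 0) {
    warn("Pathway scores have zero variance across samples; G = 1 for all.")
    return(rep(1, length(scores)))
  }
  exp((scores - mu) / sdev)
}

#' Co-expression hub feature for a pathway
#'
#' Builds a co-expression network over all expressed genes with edges where
#' \eqn{|r| >} `r_threshold` (Pearson, across samples), calls a pathway gene
#' a hub when its raw degree is at least the mean degree over all genes, and
#' returns the per-sample mean expression of the hub genes as the pathway's
#' representative feature. If no pathway gene qualifies, all pathway genes
#' are used with a warning.
#'
#' @param expr Gene-by-sample matrix of log2 expression (>= 3 samples).
#' @param pathway_genes Character vector of pathway gene ids (>= 2 present).
#' @param r_threshold Absolute-correlation edge threshold (default 0.8).
#' @return A list with `hubs` (character) and `feature` (named numeric, one
#'   value per sample).
#' @export
coexpression_hub_feature <- function(expr, pathway_genes, r_threshold = 0.8) {
  expr <- as_expression_matrix(expr)
  if (ncol(expr) < 3) {
    abort("Need >= 3 samples to estimate correlations.",
          class = "glucoflux_insufficient_data")
  }
  present <- intersect(pathway_genes, rownames(expr))
  if (length(present) < 2) {
    abort("Need >= 2 pathway genes present in the expression matrix.",
          class = "glucoflux_insufficient_data")
  }
  cm <- suppressWarnings(cor(t(expr)))
  cm[is.na(cm)] <- 0
  adj <- abs(cm) > r_threshold
  diag(adj) <- FALSE
  degree <- rowSums(adj)
  hubs <- present[degree[present] >= mean(degree)]
  if (length(hubs) == 0) {
    warn("No pathway gene reaches the mean degree; falling back to all pathway genes.")
    hubs <- present
  }
  feature <- colMeans(expr[hubs, , drop = FALSE])
  list(hubs = hubs, feature = feature)
}

#' Greedy forward selection over a degree-2 polynomial feature expansion
#'
#' Candidate terms are the raw features, their squares, and all pairwise
#' interactions (in that deterministic order, interactions lexicographic).
#' Starting from the empty model, the term whose addition maximizes R-squared
#' is added at each step; selection stops when R-squared reaches `r2_stop`
#' or `max_features` terms are in the model. Ties break toward the
#' lowest-index candidate.
#'
#' @param features Sample-by-feature data frame or matrix of pathway
#'   features.
#' @param response Per-sample response (glucose-import proxy).
#' @param degree Polynomial degree (currently 1 or 2; default 2).
#' @param r2_stop R-squared stopping threshold (default 0.95).
#' @param max_features Maximum number of selected terms; default
#'   `floor(n_samples / 10)` so the term count stays well below the sample
#'   count.
#' @return An object of class `glc_polyfit` with the selection trace,
#'   coefficients, R-squared and overall F-test p-value; see [tidy()] and
#'   [glance()] methods.
#' @export
forward_polynomial_fit <- function(features, response, degree = 2,
                                   r2_stop = 0.95, max_features = NULL) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  if (length(response) != n) {
    abort("`response` must have one value per sample row.",
          class = "glucoflux_domain_error")
  }
  max_features <- max_features %||% max(1L, floor(n / 10))

  # deterministic candidate enumeration: raw, squares, interactions
  cand <- as.list(colnames(X))
  names(cand) <- colnames(X)
  terms_mat <- X
  if (degree >= 2) {
    for (j in seq_len(ncol(X))) {
      nm <- paste0(colnames(X)[j], "^2")
      terms_mat <- cbind(terms_mat, X[, j]^2)
      colnames(terms_mat)[ncol(terms_mat)] <- nm
    }
    if (ncol(X) >= 2) {
      for (j in seq_len(ncol(X) - 1)) {
        for (l in seq((j + 1), ncol(X))) {
          nm <- paste0(colnames(X)[j], ":", colnames(X)[l])
          terms_mat <- cbind(terms_mat, X[, j] * X[, l])
          colnames(terms_mat)[ncol(terms_mat)] <- nm
        }
      }
    }
  }

  sst <- sum((response - mean(response))^2)
  if (sst == 0) {
    fit <- structure(list(selected_terms = character(0),
                          coefficients = c(`(Intercept)` = mean(response)),
                          r2 = 0, f_test_p = NA_real_,
                          trace = tibble(term = character(), r2 = numeric()),
                          model = NULL, n = n),
                     class = "glc_polyfit")
    return(fit)
  }

  selected <- integer(0)
  trace <- list()
  best_r2 <- 0
  repeat {
    if (length(selected) >= max_features || best_r2 >= r2_stop) break
    remaining <- setdiff(seq_len(ncol(terms_mat)), selected)
    if (length(remaining) == 0) break
    if (n <= length(selected) + 2) break # keep residual df positive
    r2s <- vapply(remaining, function(j) {
      m <- stats::lm.fit(cbind(1, terms_mat[, c(selected, j), drop = FALSE]),
                         response)
      1 - sum(m$residuals^2) / sst
    }, numeric(1))
    j_best <- remaining[which.max(r2s)] # which.max -> lowest index on ties
    r2_new <- max(r2s)
    if (r2_new <= best_r2 + 1e-12 && length(selected) > 0) break
    selected <- c(selected, j_best)
    best_r2 <- r2_new
    trace[[length(trace) + 1]] <- tibble(
      term = colnames(terms_mat)[j_best], r2 = r2_new)
  }

  if (length(selected) == 0) {
    fit <- structure(list(selected_terms = character(0),
                          coefficients = c(`(Intercept)` = mean(response)),
                          r2 = 0, f_test_p = NA_real_,
                          trace = tibble(term = character(), r2 = numeric()),
                          model = NULL, n = n),
                     class = "glc_polyfit")
    return(fit)
  }

  df_model <- data.frame(terms_mat[, selected, drop = FALSE],
                         check.names = FALSE)
  df_model$.response <- response
  model <- lm(.response ~ ., data = df_model)
  sm <- summary(model)
  fp <- if (is.null(sm$fstatistic)) NA_real_ else {
    unname(pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
              lower.tail = FALSE))
  }
  structure(list(
    selected_terms = colnames(terms_mat)[selected],
    coefficients = coef(model),
    r2 = sm$r.squared,
    f_test_p = fp,
    trace = bind_rows(trace),
    model = model,
    n = n
  ), class = "glc_polyfit")
}

#' @export
print.glc_polyfit <- function(x, ...) {
  cat(sprintf("<glc_polyfit> %d term(s), R^2 = %.4f, F-test p = %.3g\n",
              length(x$selected_terms), x$r2, x$f_test_p))
  if (length(x$selected_terms)) {
    cat("terms:", paste(x$selected_terms, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.glc_polyfit <- function(x, ...) {
  trace_r2 <- setNames(x$trace$r2, x$trace$term)
  nm <- gsub("^`|`$", "", names(x$coefficients))
  tibble(term = nm,
         estimate = unname(x$coefficients),
         cumulative_r2 = unname(trace_r2[nm]))
}

#' @export
glance.glc_polyfit <- function(x, ...) {
  tibble(r.squared = x$r2, p.value = x$f_test_p,
         n_terms = length(x$selected_terms), nobs = x$n)
}

#' @export
autoplot.glc_polyfit <- function(object, ...) {
  tr <- object$trace
  tr$step <- seq_len(nrow(tr))
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$step, y = .data$r2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$term), vjust = -0.6,
                       size = 3) +
    ggplot2::scale_x_continuous(breaks = tr$step) +
    ggplot2::labs(x = "selection step", y = expression(R^2),
                  title = "Forward polynomial selection trace") +
    ggplot2::theme_minimal()
}

#' Read / write gene sets in GMT format
#'
#' GMT is tab-separated: set name, description, then gene ids. Descriptions
#' are preserved on read as an attribute and written as `"na"` when absent.
#'
#' @param path File path.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("GMT file not found: %s", path),
          class = "glucoflux_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1)
  sets
}

#' @param gene_sets Named list of character vectors.
#' @rdname read_gmt
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, "na", gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
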