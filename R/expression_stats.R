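#' Differential expression between tumor and normal samples
#'
#' Per-gene Welch (unequal-variance) two-sample t-tests on log2-transformed
#' expression. The fold change is the difference of group means on the log2
#' scale (tumor minus normal); p-values are corrected by the
#' Benjamini-Hochberg procedure; a gene is called upregulated when its fold
#' change is >= 0 and its adjusted p-value is < `p_adj_threshold`.
#'
#' Degenerate genes (zero variance in both groups) get p = 1 when the group
#' means are equal and p = 0 when they differ, a deterministic
#' continuity-respecting convention.
#'
#' @param expr Gene-by-sample matrix of log2 expression (or a data frame
#'   whose first column is the gene id).
#' @param groups Character vector along the columns of `expr` with values
#'   `"tumor"` / `"normal"` (or a two-level factor; the first level in
#'   `tumor_level` is treated as tumor).
#' @param tumor_level,normal_level Labels identifying the two groups.
#' @param p_adj_threshold Significance threshold on the adjusted p-value
#'   (default 0.05).
#' @return A tibble with columns `gene`, `log2fc`, `p_value`, `p_adj`,
#'   `upregulated`.
#' @export
differential_expression <- function(expr, groups, tumor_level = "tumor",
                                    normal_level = "normal",
                                    p_adj_threshold = 0.05) {
  expr <- as_expression_matrix(expr)
  groups <- as.character(groups)
  if (length(groups) != ncol(expr)) {
    abort("`groups` must have one label per sample column.",
          class = "glucoflux_domain_error")
  }
  ti <- which(groups == tumor_level)
  ni <- which(groups == normal_level)
  if (length(ti) < 2 || length(ni) < 2) {
    abort("Each group needs at least 2 samples for a Welch t-test.",
          class = "glucoflux_insufficient_data")
  }
  xt <- expr[, ti, drop = FALSE]
  xn <- expr[, ni, drop = FALSE]
  n1 <- length(ti)
  n2 <- length(ni)
  m1 <- rowMeans(xt)
  m2 <- rowMeans(xn)
  v1 <- rowSums((xt - m1)^2) / (n1 - 1)
  v2 <- rowSums((xn - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  # zero variance in both groups: p = 1 on equal means, p = 0 otherwise
  degen <- se2 == 0
  if (any(degen)) {
    p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  }
  tibble(
    gene = rownames(expr),
    log2fc = unname(m1 - m2),
    p_value = unname(p),
    p_adj = bh_adjust(unname(p)),
    upregulated = unname(m1 - m2) >= 0 & bh_adjust(unname(p)) < p_adj_threshold
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up adjusted p-values, clipped at 1 and monotone in rank.
#' Values outside \[0, 1\] raise a domain error.
#'
#' @param p_values Numeric vector of raw p-values.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) ||
      any(is.na(p_values) | p_values < 0 | p_values > 1)) {
    abort("p-values must be numeric in [0, 1].",
          class = "glucoflux_domain_error")
  }
  p.adjust(p_values, method = "BH")
}

#' Composite gene weights from fold change and significance
#'
#' Each gene's weight is the product of a fold-change factor
#' \eqn{w_{FC} = 2^{\gamma \cdot \mathrm{log2FC}}} (with exponent
#' \eqn{\gamma} tempering extreme fold changes) and a significance factor
#' \eqn{w_{FDR} = (1 - p_{adj})^{\eta}} penalizing genes with weak
#' statistical support.
#'
#' @param de A differential-expression table from
#'   [differential_expression()] (columns `gene`, `log2fc`, `p_adj`).
#' @param gamma Fold-change tempering exponent (> 0, default 0.75).
#' @param eta Significance exponent (> 0, default 0.7).
#' @return A tibble with columns `gene`, `w_fc`, `w_fdr`, `w`.
#' @export
gene_weights <- function(de, gamma = 0.75, eta = 0.7) {
  gamma <- assert_scalar(gamma, "gamma", 0, open_lower = TRUE)
  eta <- assert_scalar(eta, "eta", 0, open_lower = TRUE)
  w_fc <- 2^(gamma * de$log2fc)
  w_fdr <- (1 - de$p_adj)^eta
  tibble(gene = de$gene, w_fc = w_fc, w_fdr = w_fdr, w = w_fc * w_fdr)
}

#' Enzyme-activity proxy matrix
#'
#' For reaction j and sample i the activity proxy is
#' \eqn{E_{ij} = \sum_{g \in R_j} w_g \cdot \mathrm{TPM}_{ig}} over the
#' reaction's GPR gene set, computed on the linear TPM scale (log2 input is
#' back-transformed as \eqn{2^x - 1}); the whole matrix is then divided by
#' its global median over strictly positive entries, so relative reaction
#' magnitudes are preserved while the scale is stabilized.
#'
#' @param expr Gene-by-sample matrix of log2(TPM+1) expression.
#' @param network A [glc_network].
#' @param weights Gene weights from [gene_weights()]; genes absent from the
#'   table get weight 1.
#' @param scale `"linear"` (default) back-transforms to TPM before summing;
#'   `"log2"` uses the log2 values as-is.
#' @return A reaction-by-sample numeric matrix with attribute
#'   `normalization_constant` (the global median before normalization).
#' @export
activity_matrix <- function(expr, network, weights = NULL,
                            scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  expr <- as_expression_matrix(expr)
  vals <- if (scale == "linear") log2_to_tpm(expr) else expr
  w <- setNames(rep(1, nrow(expr)), rownames(expr))
  if (!is.null(weights)) {
    keep <- intersect(weights$gene, names(w))
    w[keep] <- weights$w[match(keep, weights$gene)]
  }
  rxns <- network$reactions
  E <- matrix(0, nrow = nrow(rxns), ncol = ncol(expr),
              dimnames = list(rxns$id, colnames(expr)))
  for (j in seq_len(nrow(rxns))) {
    gs <- intersect(rxns$genes[[j]], rownames(expr))
    if (length(gs) == 0) {
      abort(sprintf("Reaction '%s' has no usable genes in the expression matrix.",
                    rxns$id[j]),
            class = "glucoflux_missing_gene")
    }
    E[j, ] <- colSums(vals[gs, , drop = FALSE] * w[gs])
  }
  pos <- E[E > 0]
  if (length(pos) == 0) {
    abort("Activity matrix has no positive entries; median normalization undefined.",
          class = "glucoflux_domain_error")
  }
  med <- median(pos)
  out <- E / med
  attr(out, "normalization_constant") <- med
  out
}
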