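# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so no global state leaks.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Derive a stream-specific child seed from a master seed. Keeps every value
# inside the 32-bit integer range R requires.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 2654435761) %% 2147483647)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "glucoflux_invalid_config")
  }
  as.integer(x)
}

assert_scalar <- function(x, name, lower = -Inf, upper = Inf,
                          open_lower = FALSE, open_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (open_lower) x > lower else x >= lower) &&
    (if (open_upper) x < upper else x <= upper)
  if (!ok) {
    abort(sprintf("`%s` must be a finite scalar in %s%s, %s%s.", name,
                  if (open_lower) "(" else "[", format(lower),
                  format(upper), if (open_upper) ")" else "]"),
          class = "glucoflux_domain_error")
  }
  as.numeric(x)
}

# Coerce a gene-by-sample expression input (matrix with rownames, or a data
# frame whose first column holds gene ids) to a named numeric matrix.
as_expression_matrix <- function(expr) {
  if (is.data.frame(expr)) {
    gene_col <- names(expr)[1]
    genes <- as.character(expr[[gene_col]])
    m <- as.matrix(expr[, -1, drop = FALSE])
    rownames(m) <- genes
    storage.mode(m) <- "double"
    return(m)
  }
  if (!is.matrix(expr) || is.null(rownames(expr))) {
    abort("`expr` must be a gene-by-sample matrix with gene rownames, or a data frame with a gene id first column.",
          class = "glucoflux_domain_error")
  }
  storage.mode(expr) <- "double"
  expr
}

# log2(TPM + 1) <-> linear TPM
log2_to_tpm <- function(x) pmax(2^x - 1, 0)
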