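test_that("PLS1 identities hold and single-gene fits reduce to simple regression", {
  withr::with_seed(2, {
    n <- 80
    X <- matrix(stats::rnorm(n * 12), n, 12,
                dimnames = list(NULL, paste0("g", 1:12)))
    y <- X[, 1] - 0.5 * X[, 2] + stats::rnorm(n, 0, 0.5)
    fit <- fit_pls(X, y, k = 1)
    # first direction proportional to centered X'y
    Xc <- scale(X, scale = FALSE)
    ref <- drop(crossprod(Xc, y - mean(y)))
    ref <- ref / sqrt(sum(ref^2))
    expect_equal(abs(sum(fit$x_weights[, 1] * ref)), 1, tolerance = 1e-10)
    expect_lt(abs(mean(fit$scores[, 1])), 1e-10)
    # single-gene X: downstream R^2 equals the squared Pearson correlation
    x1 <- X[, 1, drop = FALSE]
    f1 <- fit_pls(x1, y, k = 1)
    r2 <- score_signature_regression(f1, y)$r2
    expect_equal(r2, cor(X[, 1], y)^2, tolerance = 1e-10)
    # noiseless rank-1 case reaches R^2 = 1
    Xr1 <- matrix(stats::rnorm(n), n, 1)
    yy <- 3 * Xr1[, 1] + 2
    expect_equal(score_signature_regression(fit_pls(Xr1, yy, 1), yy)$r2, 1)
  })
  expect_error(fit_pls(matrix(1:20, 10, 2), rep(1, 10)),
               class = "glucoflux_degenerate_response")
  expect_error(fit_pls(matrix(stats::rnorm(8), 4, 2), stats::rnorm(4), k = 3),
               class = "glucoflux_rank_error")
})

test_that("multi-component scores are mutually orthogonal", {
  withr::with_seed(4, {
    n <- 60
    X <- matrix(stats::rnorm(n * 10), n, 10)
    y <- X %*% stats::rnorm(10) + stats::rnorm(n)
    fit <- fit_pls(X, drop(y), k = 3)
    G <- crossprod(fit$scores)
    off <- G[upper.tri(G)]
    expect_lt(max(abs(off)), 1e-8)
    expect_true(all(abs(colMeans(fit$scores)) < 1e-10))
  })
})

test_that("PLS1 scores agree with an independent implementation", {
  withr::with_seed(6, {
    n <- 50
    X <- matrix(stats::rnorm(n * 8), n, 8,
                dimnames = list(paste0("s", 1:n), paste0("g", 1:8)))
    y <- X[, 3] + stats::rnorm(n, 0, 0.4)
    ours <- fit_pls(X, y, k = 1)
    ref <- mixOmics::pls(X, y, ncomp = 1, mode = "regression", scale = FALSE)
    ref_t <- ref$variates$X[, 1]
    # scores must match up to sign and scale
    expect_equal(abs(cor(ours$scores[, 1], ref_t)), 1, tolerance = 1e-8)
  })
})

test_that("score regression recovers planted variance fractions", {
  withr::with_seed(8, {
    # exact linear outcome: R^2 = 1
    n <- 100
    S <- matrix(stats::rnorm(n * 3), n, 3)
    y <- drop(S %*% c(1, -2, 0.5)) + 4
    expect_equal(score_signature_regression(S, y)$r2, 1, tolerance = 1e-12)
    # independent outcome at n = 200, k = 8: E[R^2] ~ k/(n-1)
    r2s <- vapply(1:60, function(i) {
      S0 <- matrix(stats::rnorm(200 * 8), 200, 8)
      score_signature_regression(S0, stats::rnorm(200))$r2
    }, numeric(1))
    expect_lt(abs(mean(r2s) - 8 / 199), 0.012)
    # planted signal fraction 0.7 at n = 500
    n2 <- 500
    s <- stats::rnorm(n2)
    signal <- s * sqrt(0.7)
    noise <- stats::rnorm(n2, 0, sqrt(0.3))
    fit <- score_signature_regression(matrix(s, n2, 1), signal + noise)
    expect_lt(abs(fit$r2 - 0.7), 0.05)
  })
  expect_error(score_signature_regression(matrix(0, 5, 1), rep(1, 4)),
               class = "glucoflux_alignment_error")
})

test_that("the Fenton fit explains a constructed linear mixture exactly", {
  withr::with_seed(10, {
    n <- 60
    sets <- lapply(1:8, function(k) paste0("p", k, "_", 1:4))
    names(sets) <- paste0("path", 1:8)
    latent <- matrix(stats::rnorm(n * 8), n, 8)
    rows <- list()
    for (k in 1:8) {
      for (g in sets[[k]]) {
        rows[[g]] <- 5 + latent[, k] + stats::rnorm(n, 0, 0.01)
      }
    }
    # Fenton genes: exact linear combination of the pathway latents
    mix <- drop(latent %*% c(0.5, -0.3, 0.2, 0.4, 0, 0.1, -0.2, 0.3))
    for (g in paste0("fen", 1:5)) {
      rows[[g]] <- 6 + mix + stats::rnorm(n, 0, 0.01)
    }
    expr <- do.call(rbind, rows)
    colnames(expr) <- paste0("s", 1:n)
    fit <- fenton_neutralization_fit(expr, paste0("fen", 1:5), sets)
    expect_gt(fit$r2, 0.99)
    coefs <- tidy(fit)
    expect_identical(coefs$term[-1], names(sets)) # all eight, in order
    sc <- attr(fit, "scores")
    expect_identical(nrow(sc), as.integer(n))
  })
})

test_that("a null Fenton score is barely explained", {
  withr::with_seed(12, {
    n <- 300
    sets <- lapply(1:8, function(k) paste0("p", k, "_", 1:4))
    names(sets) <- paste0("path", 1:8)
    genes <- c(unlist(sets), paste0("fen", 1:5))
    expr <- matrix(stats::rnorm(length(genes) * n, 5, 1),
                   nrow = length(genes),
                   dimnames = list(genes, paste0("s", 1:n)))
    fit <- fenton_neutralization_fit(expr, paste0("fen", 1:5), sets)
    expect_lt(fit$r2, 0.1)
  })
})

test_that("the migration outcome is a gene-order-invariant mean", {
  expr <- matrix(c(2, 4, 6, 1, 3, 5), nrow = 2, byrow = TRUE,
                 dimnames = list(c("m1", "m2"), paste0("s", 1:3)))
  expect_equal(unname(migration_outcome(expr, c("m1", "m2"))),
               c(1.5, 3.5, 5.5))
  expect_equal(migration_outcome(expr, c("m2", "m1")),
               migration_outcome(expr, c("m1", "m2")))
  expect_equal(unname(migration_outcome(expr, "m1")), c(2, 4, 6))
  expect_error(migration_outcome(expr, "zz"),
               class = "glucoflux_empty_signature")
})
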