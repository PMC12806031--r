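test_that("causal variables respect the filtering and standardization contracts", {
  sim <- simulate_network(3, 3, seed = 2)
  co <- simulate_cohort(sim$network,
                        sim_config(n_tumor = 30, n_normal = 20,
                                   n_genes = 300, seed = 3))
  de <- differential_expression(co$expression, co$metadata$group)
  tum <- co$metadata$sample_id[co$metadata$group == "tumor"]
  nuc <- co$gene_sets[[sim$network$sink_pathways[1]]]
  prolif <- co$gene_sets$proliferation_signature
  # overlap between the two sets must be removed from the confounder
  prolif_overlap <- c(prolif, nuc[1])
  triple <- construct_causal_variables(co$expression[, tum], de, nuc,
                                       prolif_overlap)
  expect_false(nuc[1] %in% attr(triple, "confounder_genes"))
  # only upregulated nucleotide genes enter the treatment set
  planted <- stats::setNames(co$truth$true_log2fc$log2fc,
                             co$truth$true_log2fc$gene)
  t_genes <- attr(triple, "treatment_genes")
  expect_true(all(planted[t_genes] > 0))
  expect_true(all(de$upregulated[match(t_genes, de$gene)]))
  # z-scored outputs
  for (v in c("T", "Y", "W")) {
    expect_lt(abs(mean(triple[[v]])), 1e-12)
    expect_equal(stats::sd(triple[[v]]), 1, tolerance = 1e-12)
  }
  expect_error(
    construct_causal_variables(co$expression[, tum], de, nuc, prolif,
                               mki67 = "NOT_A_GENE"),
    class = "glucoflux_missing_marker")
  expect_error(
    construct_causal_variables(co$expression[, tum], de,
                               "gene_not_present", prolif),
    class = "glucoflux_empty_signature")
})

test_that("backdoor adjustment removes the planted confounding bias", {
  d <- simulate_causal_data(2000, beta = 0.5, a = 0.8, b = 0.6, seed = 11)
  est <- estimate_ate(d)
  expect_lt(abs(est$ate - 0.5), 0.05)
  # the unadjusted slope carries the predicted bias a*b*Var(W)/Var(T)
  bias <- 0.8 * 0.6 / (0.8^2 + 1)
  expect_lt(abs((est$unadjusted - est$ate) - bias), 0.06)
  expect_gt(est$unadjusted, est$ate)
  # with no W -> T arrow the adjusted and simple slopes agree
  d0 <- simulate_causal_data(2000, beta = 0.5, a = 0, b = 0.6, seed = 12)
  est0 <- estimate_ate(d0)
  expect_lt(abs(est0$ate - est0$unadjusted), 0.05)
  # duplicated treatment is non-identifiable
  dup <- tibble::tibble(T = d$T, Y = d$Y, W = d$T)
  expect_error(estimate_ate(dup), class = "glucoflux_non_identifiable")
  expect_true(all(c("ate", "unadjusted") %in% names(glance(est))))
  expect_identical(nrow(tidy(est)), 3L)
})

test_that("the permutation p-value hits its floor under a strong effect", {
  d <- simulate_causal_data(500, beta = 1, a = 0.5, b = 0.3, seed = 21)
  p <- permutation_test(d, n_perm = 199, seed = 7)
  expect_equal(as.numeric(p), 1 / 200)
  p2 <- permutation_test(d, n_perm = 199, seed = 7)
  expect_identical(as.numeric(p), as.numeric(p2))
  expect_length(attr(p, "null_ates"), 199)
  expect_error(permutation_test(d, n_perm = 0),
               class = "glucoflux_invalid_config")
})

test_that("the permutation fast path equals per-permutation refits", {
  d <- simulate_causal_data(150, beta = 0.2, a = 0.6, b = 0.4, seed = 31)
  p <- permutation_test(d, n_perm = 25, seed = 3)
  nulls <- attr(p, "null_ates")
  # recompute the same shuffles with plain lm fits
  ref <- withr::with_seed(glucoflux:::child_seed(3, 4), {
    vapply(1:25, function(i) {
      dp <- d
      dp$T <- d$T[sample.int(nrow(d))]
      stats::coef(stats::lm(Y ~ T + W, data = dp))[["T"]]
    }, numeric(1))
  })
  expect_equal(nulls, ref, tolerance = 1e-10)
})

test_that("the refutation curve starts at the estimate and is complete", {
  d <- simulate_causal_data(400, beta = 0.5, a = 0.8, b = 0.6, seed = 41)
  est <- estimate_ate(d)
  curve <- refute_with_latent_confounder(d, strengths = c(0, 0.3, 0.6, 1),
                                         seed = 9)
  expect_identical(nrow(curve), 4L)
  expect_equal(curve$ate[curve$strength == 0], est$ate, tolerance = 1e-12)
  # determinism of the latent draw
  curve2 <- refute_with_latent_confounder(d, strengths = c(0, 0.3, 0.6, 1),
                                          seed = 9)
  expect_identical(curve, curve2)
  # on null data the induced |drift| grows with the strength in expectation
  drifts <- withr::with_seed(5, {
    colMeans(do.call(rbind, lapply(1:30, function(i) {
      dn <- simulate_causal_data(300, beta = 0, a = 0, b = 0,
                                 seed = 1000 + i)
      abs(refute_with_latent_confounder(dn, strengths = c(0, 0.5, 1),
                                        seed = i)$ate)
    })))
  })
  expect_true(all(diff(drifts) > 0))
})

test_that("ATE estimation is invariant to affine rescaling of W", {
  d <- simulate_causal_data(300, beta = 0.4, a = 0.5, b = 0.7, seed = 51)
  est <- estimate_ate(d)
  d2 <- d
  d2$W <- 3 * d$W - 7
  expect_equal(estimate_ate(d2)$ate, est$ate, tolerance = 1e-12)
})

test_that("partial regression reproduces the adjusted slope", {
  d <- simulate_causal_data(500, beta = 0.5, a = 0.8, b = 0.6, seed = 61)
  est <- estimate_ate(d)
  pr <- partial_regression(d)
  slope <- stats::coef(stats::lm(y_resid ~ t_resid, data = pr))[["t_resid"]]
  expect_equal(slope, est$ate, tolerance = 1e-12)
})
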