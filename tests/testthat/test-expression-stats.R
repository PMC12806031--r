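test_that("Welch test matches its hand-evaluated micro-example", {
  expr <- matrix(c(1, 2, 3, 2, 3, 4), nrow = 1,
                 dimnames = list("g1", c("t1", "t2", "t3", "n1", "n2", "n3")))
  de <- differential_expression(expr, c("tumor", "tumor", "tumor",
                                        "normal", "normal", "normal"))
  expect_equal(de$log2fc, -1)
  ref <- stats::t.test(c(1, 2, 3), c(2, 3, 4)) # base-R Welch as oracle
  expect_equal(de$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(de$p_value, 0.2878641, tolerance = 1e-6)
})

test_that("degenerate and identical-group genes follow the convention", {
  expr <- matrix(c(2, 2, 2, 2,  # constant, equal means -> p = 1
                   5, 5, 1, 1,  # constant within group, different means
                   1, 3, 1, 3), # identical values across groups
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("flat", "split", "same"),
                                 c("t1", "t2", "n1", "n2")))
  de <- differential_expression(expr, c("tumor", "tumor", "normal", "normal"))
  expect_equal(de$p_value[de$gene == "flat"], 1)
  expect_equal(de$log2fc[de$gene == "flat"], 0)
  expect_equal(de$p_value[de$gene == "split"], 0)
  expect_equal(de$log2fc[de$gene == "same"], 0)
  expect_error(
    differential_expression(expr, c("tumor", "normal", "normal", "normal")),
    class = "glucoflux_insufficient_data")
})

test_that("a strongly planted gene is detected with overwhelming power", {
  sim <- simulate_network(3, 3, seed = 1)
  cfg <- sim_config(n_tumor = 50, n_normal = 50, n_genes = 250,
                    noise_sd = 0.5,
                    planted_log2fc = c(BG0001 = 2), seed = 9)
  co <- simulate_cohort(sim$network, cfg)
  de <- differential_expression(co$expression, co$metadata$group)
  expect_lt(de$p_value[de$gene == "BG0001"], 1e-10)
  expect_true(de$upregulated[de$gene == "BG0001"])
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.04, 0.5)), c(0.08, 0.5))
  expect_error(bh_adjust(c(0.1, 1.2)), class = "glucoflux_domain_error")
  withr::with_seed(42, {
    for (i in 1:200) {
      p <- stats::runif(sample(1:50, 1))
      expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
    }
  })
})

test_that("gene weights evaluate and order as the formulas dictate", {
  de <- tibble::tibble(gene = c("a", "b", "c"),
                       log2fc = c(0, 1, 1),
                       p_value = c(0, 0.05, 1),
                       p_adj = c(0, 0.05, 1))
  w <- gene_weights(de, gamma = 0.75, eta = 0.7)
  expect_equal(w$w[w$gene == "a"], 1)
  expect_equal(w$w[w$gene == "b"], 1.622472, tolerance = 1e-5)
  expect_equal(w$w[w$gene == "c"], 0) # p_adj = 1 kills any fold change
  # monotone increasing in log2fc, decreasing in p_adj
  de2 <- tibble::tibble(gene = letters[1:5],
                        log2fc = c(-1, 0, 1, 1, 1),
                        p_value = 0, p_adj = c(0.2, 0.2, 0.2, 0.5, 0.9))
  w2 <- gene_weights(de2)
  expect_true(all(diff(w2$w[1:3]) > 0))
  expect_true(all(diff(w2$w[3:5]) < 0))
})

test_that("activity proxy sums weighted linear TPM and median-normalizes", {
  mets <- tibble::tibble(id = c("glc", "m1"), name = c("glucose", "m1"),
                         role = c("source", "internal"))
  rxns <- tibble::tibble(
    id = c("r_up", "r_two"),
    pathway = c("internal", "lactate"),
    stoichiometry = list(c(glc = -1, m1 = 1), c(m1 = -1)),
    ec = list("1.1.1.1", "1.1.1.2"),
    genes = list("gA", c("gB", "gC")),
    proton_coefficient = c(0, 1))
  net <- glc_network(mets, rxns)
  # log2(TPM+1) encoding of TPM values: gA = 5, gB = 3, gC = 4
  expr <- matrix(log2(c(5, 3, 4) + 1), nrow = 3,
                 dimnames = list(c("gA", "gB", "gC"), "s1"))
  w <- tibble::tibble(gene = c("gA", "gB", "gC"), w = c(1, 1, 2))
  E <- activity_matrix(expr, net, w)
  # raw entries: r_up = 5, r_two = 1*3 + 2*4 = 11; global median = 8
  expect_equal(attr(E, "normalization_constant"), 8)
  expect_equal(unname(E[, "s1"]), c(5, 11) / 8)

  # single-gene reaction with weight 1 equals the TPM row over the median
  E1 <- activity_matrix(expr, net, tibble::tibble(gene = "gC", w = 2))
  expect_equal(unname(E1["r_up", ]) * attr(E1, "normalization_constant"), 5)

  # scale equivariance: doubling all TPM leaves the normalized matrix as is
  # (the recorded normalization constant itself doubles)
  expr2 <- log2(2 * (2^expr - 1) + 1)
  E2 <- activity_matrix(expr2, net, w)
  expect_equal(as.numeric(E2), as.numeric(E), tolerance = 1e-12)
  expect_equal(attr(E2, "normalization_constant"),
               2 * attr(E, "normalization_constant"))

  # a reaction whose genes are absent is reported by name
  rxns_bad <- rxns
  rxns_bad$genes[[2]] <- "missing_gene"
  net_bad <- glc_network(mets, rxns_bad)
  err <- expect_error(activity_matrix(expr, net_bad, w),
                      class = "glucoflux_missing_gene")
  expect_match(conditionMessage(err), "r_two")

  # all-zero expression: the median is undefined
  expr0 <- matrix(0, nrow = 3, ncol = 1,
                  dimnames = list(c("gA", "gB", "gC"), "s1"))
  expect_error(activity_matrix(expr0, net, w),
               class = "glucoflux_domain_error")
})
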