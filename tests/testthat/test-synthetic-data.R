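test_that("planted fluxes satisfy every balance constraint", {
  sim <- simulate_network(4, 8, seed = 1)
  S <- stoich_matrix(sim$network)
  v <- stats::setNames(sim$truth$flux$flux, sim$truth$flux$reaction)
  resid <- S[sim$network$metabolites$role == "internal", , drop = FALSE] %*%
    v[colnames(S)]
  expect_lt(max(abs(resid)), 1e-12)
  sink_flux <- sim$truth$flux$flux[sim$truth$flux$pathway != "internal"]
  uptake <- sim$truth$flux$flux[sim$truth$flux$reaction == "r_uptake"]
  expect_equal(sum(sink_flux), uptake)
  expect_identical(nrow(validate_network(sim$network)), 0L)
})

test_that("a minimal 1-internal 2-sink network is well formed", {
  sim <- simulate_network(1, 2, seed = 7)
  expect_identical(nrow(sim$network$reactions), 3L) # uptake + 2 drains
  sink_flux <- sim$truth$flux$flux[sim$truth$flux$pathway != "internal"]
  expect_equal(sum(sink_flux), sim$truth$total_influx)
  expect_error(simulate_network(0, 2), class = "glucoflux_invalid_config")
  expect_error(simulate_network(1, 1), class = "glucoflux_invalid_config")
})

test_that("network generation is deterministic in the seed", {
  a <- simulate_network(5, 4, seed = 11)
  b <- simulate_network(5, 4, seed = 11)
  c <- simulate_network(5, 4, seed = 12)
  expect_identical(a$network$reactions, b$network$reactions)
  expect_identical(a$truth$flux, b$truth$flux)
  expect_false(identical(a$truth$eff, c$truth$eff))
})

test_that("zero-noise cohorts reproduce planted fold changes exactly", {
  sim <- simulate_network(3, 3, seed = 2)
  cfg <- sim_config(n_tumor = 5, n_normal = 5, n_genes = 200,
                    noise_sd = 1e-12, seed = 3)
  co <- simulate_cohort(sim$network, cfg)
  tum <- co$metadata$sample_id[co$metadata$group == "tumor"]
  nor <- co$metadata$sample_id[co$metadata$group == "normal"]
  emp <- rowMeans(co$expression[, tum]) - rowMeans(co$expression[, nor])
  planted <- stats::setNames(co$truth$true_log2fc$log2fc,
                             co$truth$true_log2fc$gene)
  expect_equal(unname(emp[names(planted)]), unname(planted),
               tolerance = 1e-8)
})

test_that("empirical fold changes stay within 3 standard errors of plan", {
  sim <- simulate_network(4, 4, seed = 5)
  cfg <- sim_config(n_tumor = 50, n_normal = 50, n_genes = 300,
                    noise_sd = 0.5, seed = 3)
  co <- simulate_cohort(sim$network, cfg)
  tum <- co$metadata$sample_id[co$metadata$group == "tumor"]
  nor <- co$metadata$sample_id[co$metadata$group == "normal"]
  emp <- rowMeans(co$expression[, tum]) - rowMeans(co$expression[, nor])
  planted <- stats::setNames(co$truth$true_log2fc$log2fc,
                             co$truth$true_log2fc$gene)
  se <- 0.5 * sqrt(2 / 50)
  expect_lt(max(abs(emp[names(planted)] - planted)), 3 * se * 1.35)
  # 300 genes: allow a modest multiplicity margin beyond 3 SE
})

test_that("cohort metadata bookkeeping matches the configuration", {
  sim <- simulate_network(3, 3, seed = 2)
  co <- simulate_cohort(sim$network,
                        sim_config(n_tumor = 7, n_normal = 5,
                                   n_genes = 200, seed = 4))
  expect_identical(nrow(co$metadata), 12L)
  expect_identical(sum(co$metadata$group == "tumor"), 7L)
  expect_identical(sum(co$metadata$group == "normal"), 5L)
  expect_identical(colnames(co$expression), co$metadata$sample_id)
  # seed-determinism and seed-sensitivity
  co2 <- simulate_cohort(sim$network,
                         sim_config(n_tumor = 7, n_normal = 5,
                                    n_genes = 200, seed = 4))
  expect_identical(co$expression, co2$expression)
  co3 <- simulate_cohort(sim$network,
                         sim_config(n_tumor = 7, n_normal = 5,
                                    n_genes = 200, seed = 5))
  expect_false(identical(co$expression, co3$expression))
})

test_that("cohort generation rejects an undersized gene universe", {
  sim <- simulate_network(3, 3, seed = 2)
  expect_error(
    simulate_cohort(sim$network, sim_config(n_genes = 10, seed = 1)),
    class = "glucoflux_invalid_config")
})

test_that("causal triples follow the planted structural model", {
  # null case: everything independent
  null <- simulate_causal_data(2000, beta = 0, a = 0, b = 0, seed = 5)
  expect_lt(abs(cor(null$T, null$Y)), 3 / sqrt(2000))
  expect_lt(abs(cor(null$T, null$W)), 3 / sqrt(2000))
  expect_lt(abs(cor(null$W, null$Y)), 3 / sqrt(2000))
  # adjusted OLS recovers the planted effect
  d <- simulate_causal_data(2000, beta = 0.5, a = 0.8, b = 0.6, seed = 11)
  fit <- stats::coef(stats::lm(Y ~ T + W, data = d))
  expect_lt(abs(unname(fit["T"]) - 0.5), 0.05)
  # determinism
  d2 <- simulate_causal_data(2000, beta = 0.5, a = 0.8, b = 0.6, seed = 11)
  expect_identical(d, d2)
  expect_error(simulate_causal_data(5, 0, 0, 0),
               class = "glucoflux_invalid_config")
})

test_that("simulated inputs round-trip through the emitted files", {
  sim <- simulate_network(3, 3, seed = 6)
  co <- simulate_cohort(sim$network,
                        sim_config(n_tumor = 5, n_normal = 5,
                                   n_genes = 200, seed = 7))
  dir <- withr::local_tempdir()
  write_sim_inputs(co, sim$network, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "expression.tsv", "metadata.tsv", "network.json", "priors.tsv",
    "gene_sets.gmt", "extra_sets.gmt", "truth.json")))))
  net <- read_network(file.path(dir, "network.json"))
  expect_identical(stoich_matrix(net), stoich_matrix(sim$network))
  sets <- read_gmt(file.path(dir, "gene_sets.gmt"))
  expect_identical(sort(names(sets)), sort(sim$network$sink_pathways))
})
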