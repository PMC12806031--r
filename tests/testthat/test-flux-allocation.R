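test_that("bounds and weights compose as defined", {
  expect_equal(unname(compute_flux_bounds(c(a = 1), c(a = 2))), 2)
  expect_equal(unname(compute_flux_bounds(c(a = exp(1), b = exp(-1)),
                                          c(a = 1, b = 1))),
               c(exp(1), exp(-1)))
  expect_error(compute_flux_bounds(c(a = -1), c(a = 1)),
               class = "glucoflux_domain_error")
  expect_equal(unname(compute_sink_weights(c(4, 1))), c(2 / 3, 1 / 3))
  expect_equal(unname(compute_sink_weights(c(3, 3, 3))), rep(1 / 3, 3))
  expect_equal(unname(compute_sink_weights(7)), 1)
  expect_equal(unname(compute_sink_weights(c(4, 1), method = "linear")),
               c(0.8, 0.2))
  expect_warning(w0 <- compute_sink_weights(c(0, 0)))
  expect_equal(unname(w0), c(0.5, 0.5))
})

test_that("the two-sink QP reproduces the analytic KKT solution", {
  sim <- simulate_network(1, 2, seed = 3)
  net <- sim$network
  sinks <- net$sink_pathways
  # symmetric case: equal weights, ample bounds -> even split
  sol <- solve_flux_qp(net, stats::setNames(c(10, 10), sinks),
                       weights = stats::setNames(c(0.5, 0.5), sinks),
                       vglc_in = 1, lambda_qp = 0.5)
  expect_equal(sol$sinks$flux, c(0.5, 0.5), tolerance = 1e-9)
  # asymmetric weights, the printed closed-form case
  sol2 <- solve_flux_qp(net, stats::setNames(c(10, 10), sinks),
                        weights = stats::setNames(c(0.6, 0.4), sinks),
                        vglc_in = 1, lambda_qp = 0.5)
  expect_equal(sol2$sinks$flux, c(0.6, 0.4), tolerance = 1e-9)
  expect_equal(sum(sol2$sinks$fraction), 1, tolerance = 1e-9)
  # a pinched bound forces flux through the other sink
  sol3 <- solve_flux_qp(net, stats::setNames(c(0, 10), sinks),
                        weights = stats::setNames(c(0.6, 0.4), sinks),
                        vglc_in = 1, lambda_qp = 0.5)
  expect_equal(sol3$sinks$flux, c(0, 1), tolerance = 1e-9)
  # infeasibility reports the gap
  err <- expect_error(
    solve_flux_qp(net, stats::setNames(c(0.2, 0.2), sinks), vglc_in = 1),
    class = "glucoflux_infeasible")
  expect_match(conditionMessage(err), "gap")
})

test_that("QP solutions satisfy constraints on random feasible instances", {
  withr::with_seed(17, {
    for (i in 1:40) {
      n_sinks <- sample(2:8, 1)
      sim <- simulate_network(sample(1:5, 1), n_sinks,
                              seed = sample.int(1e6, 1))
      net <- sim$network
      B <- stats::setNames(stats::rlnorm(n_sinks, 1, 1), net$sink_pathways)
      V <- stats::runif(1, 0.2, 0.95) * sum(B)
      sol <- solve_flux_qp(net, B, vglc_in = V)
      tol <- 1e-6 * max(V, 1)
      expect_lt(abs(sum(sol$sinks$flux) - V), tol)
      expect_lt(max(abs(sol$residuals)), tol)
      expect_true(all(sol$sinks$flux >= -tol))
      expect_true(all(sol$sinks$flux <= sol$sinks$bound + tol))
    }
  })
})

test_that("raising a sink weight never lowers its optimal flux", {
  sim <- simulate_network(2, 4, seed = 5)
  net <- sim$network
  sinks <- net$sink_pathways
  B <- stats::setNames(rep(10, 4), sinks)
  base_w <- c(0.25, 0.25, 0.25, 0.25)
  f1 <- solve_flux_qp(net, B, stats::setNames(base_w, sinks),
                      vglc_in = 2, lambda_qp = 0.3)$sinks$flux[1]
  for (up in c(0.3, 0.4, 0.6)) {
    w <- c(up, rep((1 - up) / 3, 3))
    f2 <- solve_flux_qp(net, B, stats::setNames(w, sinks),
                        vglc_in = 2, lambda_qp = 0.3)$sinks$flux[1]
    expect_gte(f2, f1 - 1e-9)
    f1 <- f2
  }
})

test_that("cohort allocation rescales infeasible samples and aggregates", {
  sim <- simulate_network(3, 3, seed = 8)
  net <- sim$network
  sinks <- net$sink_pathways
  B <- matrix(c(2, 1, 1,
                4, 2, 2), nrow = 3,
              dimnames = list(sinks, c("s1", "s2")))
  V <- c(s1 = 8, s2 = 4) # s1 exceeds capacity 4 and must be rescaled
  expect_message(
    alloc <- allocate_fluxes(net, B, V),
    "rescaled")
  expect_s3_class(alloc, "glc_allocation")
  expect_equal(unique(alloc$vglc_in[alloc$sample == "s1"]), 4)
  expect_equal(sum(alloc$fraction[alloc$sample == "s1"]), 1,
               tolerance = 1e-9)
  expect_error(allocate_fluxes(net, B, V, on_infeasible = "error"),
               class = "glucoflux_infeasible")
  fr <- allocation_fractions(alloc)
  expect_equal(sum(fr$mean_fraction), 1, tolerance = 1e-9)
  expect_identical(nrow(fr), 3L)
})

test_that("lactate fate weights follow compression, softmax and blending", {
  # equal scores: even split for any temperature or prior strength
  w_eq <- lactate_fate_weights(2, 2, tau = 0.7, alpha = 0.3)
  expect_equal(w_eq$w_export, 0.5)
  # the printed worked case
  w <- lactate_fate_weights(exp(1) - 1, 0, tau = 1, alpha = 0.2)
  expect_equal(w$w_export, 0.2 * 0.5 + 0.8 * exp(1) / (exp(1) + 1),
               tolerance = 1e-12)
  expect_equal(w$w_export, 0.6849, tolerance = 1e-4)
  expect_equal(w$w_export + w$w_lactylation, 1)
  # alpha -> 1 pulls any score difference back to the uniform prior
  w1 <- lactate_fate_weights(10, 0, tau = 1, alpha = 0.999)
  expect_equal(w1$w_export, 0.5, tolerance = 1e-3)
  expect_error(lactate_fate_weights(1, 1, tau = 0),
               class = "glucoflux_domain_error")
  expect_error(lactate_fate_weights(1, 1, alpha = 1),
               class = "glucoflux_domain_error")
})

test_that("lactate partition equals the clipped closed form", {
  expect_equal(partition_lactate(0, c(0.6, 0.4))$v_export, 0)
  p <- partition_lactate(1, c(0.6, 0.4), lambda_qp = 0.5)
  expect_equal(p$v_export, 0.6)
  expect_equal(p$v_lactylation, 0.4)
  peq <- partition_lactate(3, c(0.5, 0.5), lambda_qp = 0.2)
  expect_equal(peq$v_export, 1.5)
  withr::with_seed(23, {
    for (i in 1:100) {
      L <- stats::runif(1, 0, 5)
      w1 <- stats::runif(1)
      lam <- stats::runif(1, 0.05, 2)
      p <- partition_lactate(L, c(w1, 1 - w1), lambda_qp = lam)
      expect_equal(p$v_export,
                   min(max(L / 2 + (2 * w1 - 1) / (4 * lam), 0), L),
                   tolerance = 1e-12)
      expect_equal(p$v_export + p$v_lactylation, L)
    }
  })
})
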