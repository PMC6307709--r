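test_that("simulation runs are reproducible and respect absorbing states", {
  pp <- model_params(3, 3, 3, p = 0.2, z = 0.5, N = 60)
  cfg <- simulation_config(pp, m0 = 0.5, duration = 100, burn_in = 0, seed = 123)
  t1 <- run_simulation(cfg)
  t2 <- run_simulation(cfg)
  expect_identical(t1$m, t2$m)
  expect_identical(t1$t_mcs, t2$t_mcs)
  # pure conformity keeps consensus forever
  pp0 <- model_params(3, 3, 3, p = 0, z = 1, N = 50)
  tr <- run_simulation(simulation_config(pp0, m0 = 1, duration = 200,
                                         burn_in = 0, seed = 9))
  expect_true(all(tr$m == 1))
  # every recorded magnetization is realizable: m = (2n - N)/N
  expect_true(all(abs(t1$m * 60 / 2 + 30 - round(t1$m * 60 / 2 + 30)) < 1e-12))
})

test_that("simulation_config validates durations, parity, and seeds", {
  pp <- model_params(3, 3, 3, p = 0.2, z = 0.5, N = 61)
  expect_error(simulation_config(pp, m0 = 0), "parity")
  expect_error(simulation_config(pp, m0 = 1, duration = 10, burn_in = 10), "burn_in")
  expect_error(simulation_config(pp, m0 = 1, seed = 1.5), "seed")
})

test_that("global flip symmetry holds with mirrored independence draws", {
  pp <- model_params(4, 3, 2, p = 0.3, z = 0.4, N = 40)
  ops <- c(rep(1L, 30), rep(-1L, 10))
  a <- run_simulation(simulation_config(pp, opinions = ops, duration = 50,
                                        burn_in = 0, seed = 77))
  b <- run_simulation(simulation_config(pp, opinions = -ops, duration = 50,
                                        burn_in = 0, seed = 77),
                      mirror_independence = TRUE)
  expect_identical(a$m, -b$m)
  expect_identical(attr(a, "final_opinions"), -attr(b, "final_opinions"))
})

test_that("step_opinion leaves consensus alone under pure conformity", {
  pp <- model_params(3, 3, 3, p = 0, z = 1, N = 12)
  cfg <- new_configuration(rep(1L, 12))
  set.seed(4)
  for (i in 1:30) cfg <- step_opinion(cfg, pp)
  expect_true(all(cfg == 1L))
})

test_that("empirical one-step flip frequencies match the analytic rates", {
  trials <- 2e5
  cases <- list(list(n_up = 30, pp = model_params(3, 2, 2, p = 0.3, z = 0.5, N = 60)),
                list(n_up = 45, pp = model_params(5, 4, 3, p = 0.6, z = 0.2, N = 60)),
                list(n_up = 60, pp = model_params(4, 4, 4, p = 1, z = 1, N = 60)))
  for (cs in cases) {
    pp <- cs$pp
    tr <- total_rates(finite_rates(cs$n_up, pp$N, pp$q, pp$r, pp$w), pp$p, pp$z)
    freq <- step_frequencies(pp, cs$n_up, trials = trials, seed = 2024)
    for (ch in c("up", "down")) {
      lam <- if (ch == "up") tr$lambda_plus else tr$lambda_minus
      se <- sqrt(lam * (1 - lam) / trials)
      expect_lt(abs(freq[[ch]] / trials - lam), 3 * se + 1e-9,
                label = sprintf("%s-rate at n_up=%d q=%d", ch, cs$n_up, pp$q))
    }
    # chi-square over the three outcomes
    expected <- c(tr$lambda_minus, tr$lambda_zero, tr$lambda_plus)
    keep <- expected > 0
    if (sum(keep) > 1) {
      pval <- suppressWarnings(
        chisq.test(as.numeric(freq)[keep], p = expected[keep] / sum(expected[keep]))$p.value)
      expect_gt(pval, 0.01)
    }
  }
})

test_that("long-run histogram matches the exact stationary distribution", {
  pp <- model_params(3, 2, 2, p = 0.3, z = 0.5, N = 80)
  tr <- run_simulation(simulation_config(pp, m0 = 0, duration = 3e4,
                                         burn_in = 2e3, seed = 31),
                       record_histogram = TRUE)
  h <- attr(tr, "histogram")
  expect_lt(total_variation(h / sum(h),
                            stationary_distribution(build_chain(pp))), 0.05)
})

test_that("order-parameter estimate: constants, oracle, disordered scaling", {
  const <- data.frame(t_mcs = 1:100, m = rep(1, 100))
  est <- estimate_order_parameter(const)
  expect_equal(est$mean, 1)
  expect_equal(est$se, 0)
  expect_error(estimate_order_parameter(const[1:10, ]), "too few")

  # agreement with the exact-chain expectation of |m|
  pp <- model_params(3, 3, 3, p = 0.25, z = 1, N = 100)
  pi_n <- stationary_distribution(build_chain(pp))
  exact <- sum(abs(attr(pi_n, "m")) * as.numeric(pi_n))
  tr <- run_simulation(simulation_config(pp, m0 = 1, duration = 2e4, seed = 8))
  est <- estimate_order_parameter(tr)
  expect_lt(abs(est$mean - exact), 3 * est$se + 0.005)

  # disordered phase: <|m|> shrinks like 1/sqrt(N)
  mean_abs_m <- sapply(c(100, 400), function(N) {
    ppN <- model_params(3, 3, 3, p = 0.8, z = 1, N = N)
    estimate_order_parameter(
      run_simulation(simulation_config(ppN, m0 = 0, duration = 5e3, seed = 5)))$mean
  })
  expect_lt(mean_abs_m[2], mean_abs_m[1] / 1.5)
})

test_that("initial-condition dependence between the spinodals (short horizon)", {
  # q = 6, r = w = 6, z = 1, p midway between the spinodals: the exact chain
  # gives E|m(50)| = 0.15 from m0 = 0 vs 0.64 from m0 = 1 at N = 400, so the
  # two ensembles must separate cleanly over 50 MCS
  p_mid <- mean(spinodals(6, 6, 6, 1))
  pp <- model_params(6, 6, 6, p = p_mid, z = 1, N = 400)
  final_m <- function(m0, seed) {
    tr <- run_simulation(simulation_config(pp, m0 = m0, duration = 50,
                                           burn_in = 0, seed = seed))
    abs(tail(tr$m, 1))
  }
  from_ord <- sapply(1:10, function(s) final_m(1, 500 + s))
  from_dis <- sapply(1:10, function(s) final_m(0, 600 + s))
  expect_gt(mean(from_ord), 0.45)
  expect_lt(mean(from_dis), 0.30)
})
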