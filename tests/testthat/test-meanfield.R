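test_that("stationary_p matches the hand-reduced closed forms", {
  m <- seq(0.01, 0.99, by = 0.01)
  expect_equal(stationary_p(m, 3, 3, 3, z = 1), p_closed_q3_z1(m), tolerance = 1e-14)
  expect_equal(stationary_p(m, 3, 3, 3, z = 0), p_closed_q3_z0(m), tolerance = 1e-14)
  expect_equal(stationary_p(0.5, 3, 3, 3, 1), 3 / 11)
  expect_equal(stationary_p(0.5, 3, 3, 3, 0), 3 / 13)
  # unanimity closed form for a range of q at z = 1
  for (q in 2:8)
    expect_equal(stationary_p(m, q, q, q, z = 1), p_closed_unanimity_z1(m, q),
                 tolerance = 1e-13)
  # even in m
  expect_equal(stationary_p(0.37, 5, 4, 2, 0.3), stationary_p(-0.37, 5, 4, 2, 0.3))
  expect_error(stationary_p(0, 3, 3, 3, 1), "nonzero")
})

test_that("critical_p equals the small-m limits of the closed forms", {
  for (q in 2:10) {
    expect_equal(critical_p(q, q, q, z = 1), p_star_unanimity_z1(q))
    expect_equal(critical_p(q, q, q, z = 0), p_star_unanimity_z0(q))
  }
  expect_equal(critical_p(3, 3, 3, 1), 1 / 3)
  expect_equal(critical_p(4, 4, 4, 1), 3 / 11)
  # and it is the numerical m -> 0 limit of the generic relation
  expect_equal(critical_p(5, 4, 2, 0.3), stationary_p(1e-7, 5, 4, 2, 0.3),
               tolerance = 1e-6)
})

test_that("p* is monotone in q: decreasing for independence, increasing for anticonformity", {
  p_ind <- sapply(2:10, function(q) critical_p(q, q, q, z = 1))
  p_anti <- sapply(2:10, function(q) critical_p(q, q, q, z = 0))
  # (q-1)/(q-1+2^(q-1)) ties exactly at q = 2, 3 (both 1/3), then falls
  expect_true(all(diff(p_ind) <= 0))
  expect_true(all(diff(p_ind[-1]) < 0))
  expect_true(all(diff(p_anti) > 0))
})

test_that("transition classification: unanimity special cases", {
  expect_identical(classify_transition(5, 5, 5, 1)$transition_type, "continuous")
  expect_identical(classify_transition(6, 6, 6, 1)$transition_type, "discontinuous")
  expect_identical(classify_transition(6, 6, 6, 0)$transition_type, "continuous")
})

test_that("spinodals collapse iff the transition is continuous", {
  sp <- spinodals(3, 3, 3, z = 1)
  expect_equal(unname(sp["p_lower"]), 1 / 3)
  expect_equal(unname(sp["p_upper"]), 1 / 3)
  sp6 <- spinodals(6, 6, 6, z = 1)
  expect_gt(sp6[["p_upper"]], sp6[["p_lower"]] + 1e-3)
  # upper spinodal is the maximum of the closed-form curve
  opt <- optimize(function(m) p_closed_unanimity_z1(m, 6), c(0.01, 1), maximum = TRUE)
  expect_equal(sp6[["p_upper"]], opt$objective, tolerance = 1e-6)
})

test_that("potential profile: pure independence gives the parabolic well", {
  grid <- seq(-1, 1, by = 0.01)
  pp <- potential_profile(grid, 4, 3, 2, p = 1, z = 1)
  expect_equal(pp$F, -grid / 2)
  expect_equal(pp$V, grid^2 / 4, tolerance = 1e-4)
  expect_error(potential_profile(seq(-0.9, 1, by = 0.01), 4, 3, 2, 1, 1), "symmetric")
})

test_that("potential profile: F odd, V even, V' = -F, minima track the phase", {
  grid <- seq(-1, 1, by = 0.005)
  count_minima <- function(V) sum(diff(sign(diff(V))) > 0)
  # pure conformity: only the consensus wells survive
  pp0 <- potential_profile(grid, 3, 3, 3, p = 0, z = 1)
  expect_identical(which(pp0$V <= min(pp0$V) + 1e-12), c(1L, length(grid)))
  # generic parameters: symmetry and quadrature consistency
  pp <- potential_profile(grid, 5, 4, 3, p = 0.2, z = 0.6)
  expect_equal(pp$F, -rev(pp$F))
  expect_equal(pp$V, rev(pp$V))
  dV <- diff(pp$V) / diff(grid)
  Fmid <- (pp$F[-1] + pp$F[-length(grid)]) / 2
  expect_equal(dV, -Fmid, tolerance = 1e-10)
  # coexistence region of the discontinuous case: three local minima
  sp <- spinodals(6, 6, 6, 1)
  pp3 <- potential_profile(grid, 6, 6, 6, p = mean(sp), z = 1)
  expect_identical(count_minima(pp3$V), 3L)
  # deep ordered phase of the continuous case: two symmetric wells
  pp2 <- potential_profile(grid, 3, 3, 3, p = 0.1, z = 1)
  expect_identical(count_minima(pp2$V), 2L)
})

test_that("mean-field trajectories settle on roots of the closed-form relation", {
  expect_true(all(meanfield_trajectory(0, 5, 4, 3, 0.3, 0.5, t_max = 20)$m == 0))
  expect_true(all(meanfield_trajectory(1, 3, 3, 3, p = 0, z = 1, t_max = 20)$m == 1))
  tr <- meanfield_trajectory(0.9, 3, 3, 3, p = 0.1, z = 1, t_max = 300, dt = 0.01)
  expect_equal(tail(tr$m, 1), sqrt(0.7 / 0.9), tolerance = 1e-6)
})

test_that("critical_z separates the transition types", {
  # continuous at both endpoints -> no discontinuity anywhere
  expect_equal(as.numeric(critical_z(5, 5, 5)), 1)
  # discontinuous at z = 1, continuous at z = 0 -> interior boundary
  z6 <- critical_z(6, 6, 6)
  expect_lt(as.numeric(z6), 1)
  expect_gt(as.numeric(z6), 0)
  expect_identical(attr(z6, "direction"), "discontinuous_above")
  expect_identical(classify_transition(6, 6, 6, as.numeric(z6) + 1e-3)$transition_type,
                   "discontinuous")
  expect_identical(classify_transition(6, 6, 6, as.numeric(z6) - 1e-3)$transition_type,
                   "continuous")
  # below the critical conformity majority nothing is discontinuous
  expect_equal(as.numeric(critical_z(10, 7, 5)), 1)
})

test_that("critical_r records per-w results and the policies are auditable", {
  rs <- critical_r(10)
  expect_identical(as.integer(rs), 8L)
  per_w <- attr(rs, "per_w")
  # w has no influence at q = 10: whole rows flagged or clean
  expect_true(all(apply(per_w, 1, function(row) all(row) || !any(row))))
  expect_identical(as.integer(critical_r(10, w_policy = "any_w")), 8L)
})

test_that("r*/q decreases with the panel size", {
  ratios <- sapply(c(8, 10, 14), function(q) as.integer(critical_r(q)) / q)
  expect_true(all(diff(ratios) < 0))
})

test_that("tricritical_q finds the discontinuity onset and its absence", {
  expect_identical(tricritical_q(1, 1, z = 1), 6L)
  expect_identical(tricritical_q(1, 1, z = 0, q_max = 30), NA_integer_)
  # self-consistency with a dense classification scan
  q_star <- tricritical_q(0.75, 0.75, z = 0.5, q_max = 50)
  dense <- which(sapply(2:50, function(q)
    classify_transition(q, threshold_count(0.75, q), threshold_count(0.75, q),
                        0.5)$transition_type == "discontinuous"))
  expect_identical(q_star, as.integer(dense[1] + 1))
})

test_that("the spinodal gap shrinks continuously to zero at z*", {
  z6 <- as.numeric(critical_z(6, 6, 6))
  gap <- function(z) {
    sp <- spinodals(6, 6, 6, z)
    sp[["p_upper"]] - sp[["p_lower"]]
  }
  zs <- seq(z6 + 0.02, 1, length.out = 6)
  gaps <- sapply(zs, gap)
  expect_true(all(diff(gaps) > 0)) # grows with z beyond the boundary
  expect_lt(gap(z6 + 1e-4), 1e-4) # and vanishes at the boundary
})

test_that("phase_diagram tabulates spinodals over q with fractional thresholds", {
  pd <- phase_diagram(2:8, 1, 1, z = 1)
  expect_identical(pd$type, c(rep("continuous", 4), rep("discontinuous", 3)))
  expect_equal(pd$p_lower, sapply(2:8, p_star_unanimity_z1))
  expect_identical(pd$r, 2:8)
})
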