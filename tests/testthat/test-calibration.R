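test_that("quadrature oracle agrees with Monte Carlo on a small design", {
  d <- design_spec(5, 5, b = 0.2, k = 0.3)          # df = 16: heavy tails
  q <- type1_quadrature(d)
  mc <- estimate_type1(d, n_draws = 2e5, seed = 31)
  expect_lt(abs(q - mc$estimate), 4 * mc$mc_se)

  # negative k and unequal prevalence exercise the other interval branches
  d2 <- design_spec(8, 4, b = -0.4, k = -0.3)
  q2 <- type1_quadrature(d2)
  mc2 <- estimate_type1(d2, n_draws = 2e5, seed = 32)
  expect_lt(abs(q2 - mc2$estimate), 4 * mc2$mc_se)

  d3 <- design_spec(6, 6, b = 0.1, k = 0)
  q3 <- type1_quadrature(d3)
  mc3 <- estimate_type1(d3, n_draws = 2e5, seed = 33)
  expect_lt(abs(q3 - mc3$estimate), 4 * mc3$mc_se)
})

test_that("with an empty overall path the error tends to the subgroup test level", {
  # k = 1 kills the overall path; b near -1 makes the retention condition
  # nearly vacuous, so the error approaches alpha_s from below
  d <- design_spec(150, 150, alpha_s = 0.025, b = -0.99, k = 1)
  q <- type1_quadrature(d)
  expect_lte(q, 0.025 + 1e-6)
  expect_gt(q, 0.024)
})

test_that("conditional (Rao-Blackwellised) estimator matches raw draws and quadrature", {
  d <- ref_design(b = 0, k = 0.59)
  raw <- estimate_type1(d, n_draws = 2e5, seed = 41)
  cond <- estimate_type1_conditional(d, n_draws = 5e3, seed = 41)
  expect_lt(abs(cond$estimate - raw$estimate), 4 * raw$mc_se)
  # conditioning removes the normal-dimension noise entirely
  expect_lt(cond$mc_se, raw$mc_se / 5)
  q <- type1_quadrature(d, n_u = 160, n_z = 600)
  expect_lt(abs(cond$estimate - q), 5 * cond$mc_se)

  # both calibrators put the exact error curve at the target within their
  # own precision (the raw-draw k is far noisier at equal effort: its
  # k-uncertainty is SE(alpha) divided by the local slope of the curve)
  cal_raw <- solve_k(ref_design(b = 0, printed_crit = TRUE),
                     n_draws = 1e5, seed = 42)
  cal_cond <- solve_k(ref_design(b = 0, printed_crit = TRUE),
                      n_draws = 2e3, seed = 42, method = "conditional")
  qq <- function(cal) type1_quadrature(cal$design, n_u = 160, n_z = 600)
  expect_lt(abs(qq(cal_raw) - 0.025), 4 * cal_raw$mc_se)
  expect_lt(abs(qq(cal_cond) - 0.025), 4 * cal_cond$mc_se + 5e-5)
  expect_lt(cal_cond$mc_se, cal_raw$mc_se / 3)
})

test_that("type I error is monotone non-increasing in k and in b", {
  base <- ref_design(b = 0, k = NA_real_)
  est <- vapply(c(-0.5, 0, 0.3, 0.7, 0.95), function(k)
    estimate_type1(replace_k(base, k), n_draws = 1e5, seed = 7)$estimate,
    numeric(1))
  expect_true(all(diff(est) <= 0))

  est_b <- vapply(c(-0.9, -0.5, 0, 0.3), function(b)
    estimate_type1(ref_design(b = b, k = 0.2), n_draws = 1e5, seed = 7)$estimate,
    numeric(1))
  expect_true(all(diff(est_b) <= 0))
})

test_that("solve_k pins the attained error at the target and is reproducible", {
  d <- ref_design(b = 0, printed_crit = TRUE)
  cal <- solve_k(d, n_draws = 1e5, seed = 11)
  expect_lt(abs(cal$attained_alpha - 0.025), 3 * cal$mc_se + 1e-4)
  expect_gt(cal$k_star, -1); expect_lt(cal$k_star, 1)
  expect_true(cal$k_star > 0.5 && cal$k_star < 0.7)   # coarse location only
  expect_equal(cal$design$k, cal$k_star)

  cal2 <- solve_k(d, n_draws = 1e5, seed = 11)
  expect_identical(cal$k_star, cal2$k_star)
  cal3 <- solve_k(d, n_draws = 1e5, seed = 12)
  expect_lt(abs(cal3$k_star - cal$k_star), 0.1)       # different draws, same root
  expect_output(print(cal), "Calibrated k")
})

test_that("solve_k refuses targets outside the attainable range", {
  d <- ref_design(b = 0)
  expect_error(solve_k(d, target_alpha = 0.001, n_draws = 1e4, seed = 1),
               "calibration infeasible")
  expect_error(solve_k(d, target_alpha = 0.4, n_draws = 1e4, seed = 1),
               "calibration infeasible")
})

test_that("calibrated k from MC agrees with the deterministic error curve", {
  d <- ref_design(b = 0, printed_crit = TRUE)
  cal <- solve_k(d, n_draws = 1e5, seed = 5)
  q <- type1_quadrature(replace_k(d, cal$k_star))
  # the exact error at the MC-calibrated k should be the target up to MC noise
  expect_lt(abs(q - 0.025), 4 * cal$mc_se)
})

test_that("bk_contour reduces to solve_k on one cell and flags infeasible ones", {
  d <- ref_design(b = 0)
  tab <- bk_contour(d, alpha_grid = 0.025, b_grid = 0, n_draws = 1e4, seed = 9)
  cal <- solve_k(d, n_draws = 1e4, seed = 9)
  expect_equal(tab$k, cal$k_star)
  expect_true(tab$feasible)

  # at b = 0 the attainable range is about [0.0125, 0.029], so 0.035 must be
  # flagged infeasible while the two smaller targets calibrate
  tab2 <- bk_contour(d, alpha_grid = c(0.035, 0.02, 0.027), b_grid = 0,
                     n_draws = 1e4, seed = 9)
  expect_false(tab2$feasible[1])
  expect_match(tab2$message[1], "infeasible")
  # on shared draws the calibrated k decreases as the allowed error grows
  expect_gt(tab2$k[2], tab2$k[3])
})

test_that("null boundary sweep is maximised at the global null", {
  d <- ref_design(b = 0, k = 0.59)
  sw <- null_boundary_sweep(d, theta_c_grid = c(-0.5, -0.25, 0),
                            n_draws = 5e4, seed = 4)
  expect_equal(nrow(sw), 3)
  # pushing theta_c below zero only removes rejections (same draws); a tiny
  # slack covers the rare corner draws for which the overall cone flips
  expect_true(all(diff(sw$reject_prob) >= -1e-4))
  expect_error(null_boundary_sweep(d, theta_c_grid = 0.1), "<= 0")
})
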