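test_that("subgroup path matches worked numerical examples at published thresholds", {
  d <- ref_design(b = 0, k = 0.59, printed_crit = TRUE)
  T <- test_stats(T_s = c(2.0, 2.0, 1.9), T_c = c(0.1, -0.1, 5.0),
                  df = d$df, p = d$p)
  # significance plus any positive complement effect; strict thresholds
  expect_equal(condition_a(T, d), c(TRUE, FALSE, FALSE))

  # a negative b tolerates bounded reversal in the complement
  d2 <- ref_design(b = -0.25, k = 0.59, printed_crit = TRUE)
  T2 <- test_stats(T_s = c(2.0, 2.0), T_c = c(-0.4, -0.6), df = d2$df, p = d2$p)
  expect_equal(condition_a(T2, d2), c(TRUE, FALSE))
})

test_that("overall path matches worked numerical examples at published thresholds", {
  d <- ref_design(b = 0, k = 0.59, printed_crit = TRUE)
  # symmetric statistics: overall clears 1.96 and both cones hold
  # lopsided statistics: overall clears but the weak arm fails its cone
  T <- test_stats(T_s = c(1.6, 2.6), T_c = c(1.6, 0.2), df = d$df, p = d$p)
  expect_equal(condition_b(T, d), c(TRUE, FALSE))

  # at p = 1/2 the binding cone boundary is T_c = k/(2-k) T_s = 0.4184 T_s
  Tb <- test_stats(T_s = c(10, 10), T_c = c(4.19, 4.18), df = d$df, p = d$p)
  expect_equal(condition_b(Tb, d), c(TRUE, FALSE))

  # k = 1: the two cone conditions contradict each other, path is empty
  d1 <- ref_design(b = 0, k = 1)
  Tr <- random_test_stats(2000, d1, seed = 3)
  expect_false(any(condition_b(Tr, d1)))

  dna <- ref_design(b = 0, k = NA_real_)
  expect_error(condition_b(Tr, dna), "solve_k")
})

test_that("t-scale and effect-scale forms of the rules are equivalent", {
  designs <- list(ref_design(b = 0, k = 0.59),
                  ref_design(b = -0.5, k = 0.93),
                  ref_design(b = 0.2, k = 0.15, n_s = 200, n_c = 100),
                  ref_design(b = 0.3, k = -0.4, n_s = 80, n_c = 240))
  for (d in designs) {
    s <- sample_sufficient_stats(d, effect_scenario(0.2, 0.05), 1e5, seed = 8)
    T <- compute_test_statistics(s, d)
    eff <- effect_scale_decision(s, d)
    expect_identical(eff$subgroup_path, unname(condition_a(T, d)))
    expect_identical(eff$overall_path, unname(condition_b(T, d)))
  }
})

test_that("paths are monotone in their consistency fractions", {
  d_lo <- ref_design(b = -0.3, k = 0.1)
  d_hi <- ref_design(b = 0.3, k = 0.6)
  T <- random_test_stats(5e4, d_lo, seed = 21)
  # larger b / larger k can only shrink the corresponding path
  expect_true(all(condition_a(T, d_hi) <= condition_a(T, d_lo)))
  expect_true(all(condition_b(T, d_hi) <= condition_b(T, d_lo)))
})

test_that("closed test retests each claim at the full family level", {
  # enriched overall test: alpha_o = 0.0125 in the intersection, but after a
  # subgroup-path rejection the overall claim only needs the 0.025 retest
  d <- design_spec(150, 150, alpha_s = 0.025, alpha_o = 0.0125, b = 0, k = 0.26)
  T_o_target <- qt(1 - 0.023, d$df)            # overall p-value 0.023
  T_s <- 2.5
  T_c <- (T_o_target - sqrt(d$p) * T_s) / sqrt(1 - d$p)
  T <- test_stats(T_s, T_c, df = d$df, p = d$p)
  out <- closed_test(T, d)
  expect_true(out$via_condition_a)
  expect_false(out$via_condition_b)            # 0.023 > alpha_o = 0.0125
  expect_true(out$claim_s)
  expect_true(out$claim_o)                     # 0.023 < family alpha = 0.025

  # without the intersection rejection no claim is possible
  T2 <- test_stats(1.0, 3.0, df = d$df, p = d$p)
  out2 <- closed_test(T2, d)
  if (!out2$intersection_rejected) expect_false(out2$claim_s || out2$claim_o)
})

test_that("decision outcomes satisfy their structural invariants", {
  d <- ref_design(b = -0.25, k = 0.26, alpha_o = 0.0125)
  T <- random_test_stats(2e4, d, seed = 14)
  out <- closed_test(T, d)
  expect_identical(out$intersection_rejected,
                   out$via_condition_a | out$via_condition_b)
  expect_true(all(out$claim_s <= out$intersection_rejected))
  expect_true(all(out$claim_o <= out$intersection_rejected))

  outc <- closed_test(T, d, constrained = TRUE)
  expect_true(all(outc$claim_s <= out$claim_s))
  expect_true(all(outc$claim_o <= out$claim_o))
  expect_identical(outc$intersection_rejected, out$intersection_rejected)
})

test_that("analyze_trial wires patient data through to a decision", {
  d <- design_spec(150, 150, b = 0, k = 0.59)
  pd <- simulate_patients(d, effect_scenario(0.5, 0.4), seed = 2)
  an <- analyze_trial(d, data = pd)
  expect_s3_class(an, "trial_analysis")
  manual <- closed_test(compute_test_statistics(summarize_patients(pd, d), d), d)
  expect_identical(an$decision, manual)
  expect_error(analyze_trial(d), "exactly one")
  expect_error(analyze_trial(d, data = pd, stats = an$stats), "exactly one")
  expect_output(print(an), "intersection rejected")
})
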