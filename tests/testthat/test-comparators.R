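test_that("Bonferroni splits the level and Holm escalates the partner", {
  d <- ref_design()
  t_half <- qt(1 - 0.0125, d$df)     # 2.2425
  T <- test_stats(T_s = c(t_half + 0.01, t_half - 0.01),
                  T_c = c(-5, -5), df = d$df, p = d$p)
  out <- bonferroni_decision(T)
  expect_equal(out$claim_s, c(TRUE, FALSE))
  expect_false(any(out$claim_o))

  # subgroup rejects at alpha/2, overall only at the escalated full level
  T2 <- test_stats(2.3, 0.5, df = d$df, p = d$p)   # T_o about 1.98
  plain <- bonferroni_decision(T2)
  holm <- bonferroni_decision(T2, holm = TRUE)
  expect_true(plain$claim_s); expect_false(plain$claim_o)
  expect_true(holm$claim_o)
  expect_true(all(plain$claim_s <= holm$claim_s))
})

test_that("Dunnett critical value sits between the full and half-level quantiles", {
  for (p in c(0.2, 0.5, 0.8)) {
    cc <- dunnett_critical_value(p, df = 596)
    expect_gt(cc, qt(0.975, 596))
    expect_lt(cc, qt(1 - 0.0125, 596))
  }
  # independently verified value at p = 1/2 (correlation sqrt(1/2))
  expect_equal(dunnett_critical_value(0.5, 596), 2.183264, tolerance = 1e-4)
  # a higher correlation (larger p) means less multiplicity penalty
  expect_lt(dunnett_critical_value(0.8, 596), dunnett_critical_value(0.2, 596))
})

test_that("comparator family-wise error rates behave under the global null", {
  d <- ref_design()
  T <- random_test_stats(1e5, d, seed = 51)
  se <- sqrt(0.025 * 0.975 / 1e5)
  bf <- mean(bonferroni_decision(T)$intersection_rejected)
  dn <- mean(dunnett_decision(T)$intersection_rejected)
  fs <- mean(fixed_sequence_decision(T)$intersection_rejected)
  expect_lt(bf, 0.025 + 4 * se)                 # conservative
  expect_lt(abs(dn - 0.025), 4 * se)            # exact by construction
  expect_lt(abs(fs - 0.025), 4 * se)            # exact: gatekeeper at alpha
  expect_lt(bf, dn)                             # Dunnett dominates Bonferroni
})

test_that("fixed-sequence testing gatekeeps and matches closed-form power", {
  d <- ref_design()
  T <- random_test_stats(2e4, d, seed = 52)
  sf <- fixed_sequence_decision(T, order = "s_first")
  of <- fixed_sequence_decision(T, order = "o_first")
  expect_true(all(sf$claim_o <= sf$claim_s))
  expect_true(all(of$claim_s <= of$claim_o))
  expect_identical(sf$intersection_rejected, sf$claim_s)

  # first-stage power of the S-first sequence is the two-arm t-test power
  # with the pooled degrees of freedom
  sc <- effect_scenario(0.3, 0.1)
  s <- sample_sufficient_stats(d, sc, 1e5, seed = 53)
  Ta <- compute_test_statistics(s, d)
  emp <- mean(fixed_sequence_decision(Ta, order = "s_first")$claim_s)
  expect_lt(abs(emp - two_arm_power(150, 0.3, df = d$df)), 4 * sqrt(0.25 / 1e5))
})

test_that("the consistency filter shrinks claims and is idempotent", {
  d <- ref_design(b = 0.2, k = 0.4)
  T <- random_test_stats(2e4, d, seed = 54)
  for (make in list(bonferroni_decision,
                    function(T) dunnett_decision(T),
                    function(T) fixed_sequence_decision(T))) {
    out <- make(T)
    con <- constrain_decision(out, T, d)
    expect_true(all(con$claim_s <= out$claim_s))
    expect_true(all(con$claim_o <= out$claim_o))
    expect_identical(con$intersection_rejected, con$claim_s | con$claim_o)
    expect_identical(constrain_decision(con, T, d)$claim_s, con$claim_s)
  }
  expect_error(constrain_decision(bonferroni_decision(T), T,
                                  ref_design(k = NA_real_)), "no k")
})

test_that("the method dispatcher reproduces the direct decision functions", {
  d <- ref_design(b = 0, k = 0.59)
  T <- random_test_stats(1000, d, seed = 55)
  expect_identical(decide(method_spec("bonferroni"), T, d),
                   bonferroni_decision(T))
  expect_identical(decide(method_spec("dunnett"), T, d),
                   dunnett_decision(T))
  expect_identical(decide(method_spec("fixed_sequence_o_first"), T, d),
                   fixed_sequence_decision(T, order = "o_first"))
  expect_identical(decide(method_spec("consistency"), T, d)$claim_s,
                   closed_test(T, d)$claim_s)
  con <- decide(method_spec("bonferroni", constrained = TRUE), T, d)
  expect_identical(con$claim_s,
                   constrain_decision(bonferroni_decision(T), T, d)$claim_s)
  expect_error(method_spec("anova"))
})
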