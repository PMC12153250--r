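# Shared fixtures. `printed_crit = TRUE` reproduces published tables, whose
# thresholds are the two-decimal t quantiles (1.96, 2.24) stated with them.
ref_design <- function(b = 0, k = NA_real_, alpha_s = 0.025, alpha_o = 0.025,
                       n_s = 150, n_c = 150, printed_crit = FALSE) {
  df <- 2 * n_s + 2 * n_c - 4
  design_spec(n_s, n_c, alpha_s = alpha_s, alpha_o = alpha_o, b = b, k = k,
              crit_s = if (printed_crit) round(qt(1 - alpha_s, df), 2),
              crit_o = if (printed_crit) round(qt(1 - alpha_o, df), 2))
}

# Design 6 of the power study: enriched alpha on the subgroup test.
design6 <- function(printed_crit = FALSE)
  ref_design(b = -0.25, k = 0.26, alpha_s = 0.025, alpha_o = 0.0125,
             printed_crit = printed_crit)

random_test_stats <- function(n, design, seed) {
  sc <- effect_scenario(0, 0, 1)
  compute_test_statistics(sample_sufficient_stats(design, sc, n, seed), design)
}
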