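# Seed streams: one user-visible integer seed drives every simulation, but
# different purposes (calibration draws, power draws, patient simulation)
# must not silently share randomness. Each purpose gets its own stream by
# hashing (seed, purpose) into a 31-bit seed.
derive_seed <- function(seed, purpose) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483647L)
}

with_stream <- function(seed, purpose, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, purpose))
  expr
}

# Core null/alternative draw shared by the simulator and the calibrator:
# standard-normal pair (z_s, z_c) plus the scaled chi factor
# u = sigma_hat / sigma = sqrt(chisq_df / df). Drawing these primitives in a
# fixed order is what makes common-random-number comparisons across (b, k)
# and across scenarios exact.
draw_core <- function(n_draws, df, seed, purpose = "core") {
  stopifnot(n_draws >= 1)
  with_stream(seed, purpose, {
    list(z_s = stats::rnorm(n_draws),
         z_c = stats::rnorm(n_draws),
         u = sqrt(stats::rchisq(n_draws, df) / df))
  })
}
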