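#' Closed-form power of a one-sided two-arm t test
#'
#' Power of a single two-arm parallel-group comparison with `n` patients per
#' arm, true difference `delta`, common SD `sigma`, tested one-sided at
#' level `alpha` with the two-sample t statistic (`2n - 2` degrees of
#' freedom). Computed from the noncentral t distribution; used as the
#' analytic anchor for the fixed-sequence limits of the consistency design.
#'
#' @param n Patients per arm.
#' @param delta True treatment difference.
#' @param sigma Common SD.
#' @param alpha One-sided level.
#' @param df Degrees of freedom; defaults to `2n - 2`, but can be set to a
#'   pooled value when the variance is estimated from a larger trial.
#' @return The power (scalar probability).
#' @examples
#' two_arm_power(150, 0.3)  # about 0.736
#' two_arm_power(300, 0.3)  # about 0.956
#' @export
two_arm_power <- function(n, delta, sigma = 1, alpha = 0.025, df = 2 * n - 2) {
  ncp <- delta / (sigma * sqrt(2 / n))
  stats::pt(stats::qt(1 - alpha, df), df, ncp = ncp, lower.tail = FALSE)
}

#' Monte-Carlo power of a method under a scenario
#'
#' Simulates trials at the sufficient-statistic level, forms the t-statistic
#' triple, applies the method's decision and reports the claim
#' probabilities. `disjunctive` is the probability of claiming success for
#' at least one population; for the consistency method this equals the
#' probability of rejecting the intersection hypothesis, by construction of
#' the closed test.
#'
#' @param design A [design_spec()] (with `k` set when the method needs it).
#' @param scenario An [effect_scenario()].
#' @param method A [method_spec()] (default: the consistency closed test at
#'   family level `max(alpha_s, alpha_o)`).
#' @param n_draws Monte-Carlo trials (default 1e5; use 1e6 for
#'   table-grade reproduction).
#' @param seed Integer seed.
#' @return An object of class `power_result`: list with `disjunctive`,
#'   `power_s`, `power_o`, their binomial `mc_se`s, and echoes of the
#'   inputs.
#' @examples
#' \donttest{
#' d6 <- design_spec(150, 150, alpha_s = 0.025, alpha_o = 0.0125,
#'                   b = -0.25, k = 0.26)
#' estimate_power(d6, effect_scenario(0.3, 0.3), n_draws = 1e5, seed = 1)
#' }
#' @export
estimate_power <- function(design, scenario, method = method_spec("consistency"),
                           n_draws = 1e5, seed = 1) {
  stopifnot(inherits(design, "design_spec"), inherits(scenario, "effect_scenario"),
            inherits(method, "method_spec"), n_draws >= 1)
  stats_df <- sample_sufficient_stats(design, scenario, n_draws, seed)
  T <- compute_test_statistics(stats_df, design)
  out <- decide(method, T, design)
  disj <- mean(out$intersection_rejected)
  ps <- mean(out$claim_s); po <- mean(out$claim_o)
  se <- function(x) sqrt(x * (1 - x) / n_draws)
  structure(list(disjunctive = disj, power_s = ps, power_o = po,
                 mc_se = c(disjunctive = se(disj), power_s = se(ps),
                           power_o = se(po)),
                 n_draws = n_draws, seed = seed,
                 design = design, scenario = scenario, method = method),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Power (%s%s), %g draws:\n", x$method$name,
              if (x$method$constrained) ", constrained" else "", x$n_draws))
  cat(sprintf("  disjunctive = %.4f  subgroup claim = %.4f  overall claim = %.4f\n",
              x$disjunctive, x$power_s, x$power_o))
  cat(sprintf("  MC se about %.4f\n", max(x$mc_se)))
  invisible(x)
}

#' Power sweep across designs, scenarios and methods
#'
#' Runs [estimate_power()] for every combination, reusing the same seed per
#' cell (common random numbers) so power curves are smooth across the
#' sweep. For a consistency-method design whose `k` is missing, `k` is first
#' calibrated with [solve_k()] at `target_alpha` (per design, sharing the
#' calibration draws across designs).
#'
#' @param designs List of [design_spec()]s.
#' @param scenarios List of [effect_scenario()]s.
#' @param methods List of [method_spec()]s.
#' @param n_draws,seed Monte-Carlo settings per cell.
#' @param target_alpha Level used when a design's `k` must be calibrated.
#' @param calib_draws Draws used for any needed calibration.
#' @param fresh_randomness If `TRUE`, each cell uses an independent stream
#'   instead of common random numbers (useful for variance diagnostics).
#' @return Tidy data frame, one row per (design, scenario, method), with
#'   design/scenario parameters, `k` used, power estimates and their MC
#'   standard errors. Calibration failures are flagged rows, not errors.
#' @export
design_sweep <- function(designs, scenarios, methods = list(method_spec("consistency")),
                         n_draws = 1e5, seed = 1, target_alpha = 0.025,
                         calib_draws = n_draws, fresh_randomness = FALSE) {
  stopifnot(is.list(designs), is.list(scenarios), is.list(methods))
  if (length(scenarios) == 0 || length(designs) == 0 || length(methods) == 0)
    return(data.frame())
  rows <- list(); idx <- 0L; cell <- 0L
  for (di in seq_along(designs)) {
    d <- designs[[di]]
    calib_failed <- ""
    needs_k <- any(vapply(methods, function(m)
      m$name == "consistency" || m$constrained, logical(1)))
    if (is.na(d$k) && needs_k) {
      cal <- tryCatch(solve_k(d, target_alpha = target_alpha,
                              n_draws = calib_draws, seed = seed),
                      error = function(e) e)
      if (inherits(cal, "error")) calib_failed <- conditionMessage(cal)
      else d <- cal$design
    }
    for (si in seq_along(scenarios)) {
      sc <- scenarios[[si]]
      for (mi in seq_along(methods)) {
        m <- methods[[mi]]; idx <- idx + 1L; cell <- cell + 1L
        cell_seed <- if (fresh_randomness) derive_seed(seed, paste0("cell", cell)) else seed
        if (nzchar(calib_failed) && (m$name == "consistency" || m$constrained)) {
          rows[[idx]] <- data.frame(
            design = di, n_s = d$n_s, n_c = d$n_c, alpha_s = d$alpha_s,
            alpha_o = d$alpha_o, b = d$b, k = NA_real_,
            theta_s = sc$theta_s, theta_c = sc$theta_c, sigma = sc$sigma,
            method = m$name, constrained = m$constrained,
            disjunctive = NA_real_, power_s = NA_real_, power_o = NA_real_,
            mc_se = NA_real_, note = calib_failed)
          next
        }
        pr <- estimate_power(d, sc, m, n_draws = n_draws, seed = cell_seed)
        rows[[idx]] <- data.frame(
          design = di, n_s = d$n_s, n_c = d$n_c, alpha_s = d$alpha_s,
          alpha_o = d$alpha_o, b = d$b, k = d$k,
          theta_s = sc$theta_s, theta_c = sc$theta_c, sigma = sc$sigma,
          method = m$name, constrained = m$constrained,
          disjunctive = pr$disjunctive, power_s = pr$power_s,
          power_o = pr$power_o, mc_se = max(pr$mc_se), note = "")
      }
    }
  }
  do.call(rbind, rows)
}
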