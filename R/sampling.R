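#' Simulate patient-level outcomes for one trial
#'
#' Draws independent normal outcomes for the four groups (subgroup/complement
#' by control/treatment) under the equal-per-arm design: `n_s` per arm in S
#' and `n_c` per arm in C, common standard deviation `sigma`, arm means
#' separated by the scenario's true effects.
#'
#' @param design A [design_spec()].
#' @param scenario An [effect_scenario()].
#' @param seed Integer seed; the draw is reproducible.
#' @return An object of class `patient_data`: list with numeric vectors
#'   `x_s0`, `x_s1`, `x_c0`, `x_c1`.
#' @examples
#' pd <- simulate_patients(design_spec(150, 150), effect_scenario(0.3, 0.1), seed = 1)
#' summarize_patients(pd, design_spec(150, 150))
#' @export
simulate_patients <- function(design, scenario, seed = 1) {
  stopifnot(inherits(design, "design_spec"), inherits(scenario, "effect_scenario"))
  with_stream(seed, "patients", {
    out <- list(
      x_s0 = stats::rnorm(design$n_s, 0, scenario$sigma),
      x_s1 = stats::rnorm(design$n_s, scenario$theta_s, scenario$sigma),
      x_c0 = stats::rnorm(design$n_c, 0, scenario$sigma),
      x_c1 = stats::rnorm(design$n_c, scenario$theta_c, scenario$sigma)
    )
    class(out) <- "patient_data"
    out
  })
}

#' @export
as.data.frame.patient_data <- function(x, ...) {
  data.frame(
    subgroup = rep(c("S", "S", "C", "C"),
                   times = c(length(x$x_s0), length(x$x_s1),
                             length(x$x_c0), length(x$x_c1))),
    arm = rep(c(0L, 1L, 0L, 1L),
              times = c(length(x$x_s0), length(x$x_s1),
                        length(x$x_c0), length(x$x_c1))),
    outcome = c(x$x_s0, x$x_s1, x$x_c0, x$x_c1)
  )
}

#' Assemble patient data from a long data frame
#'
#' Inverse of `as.data.frame.patient_data`: accepts columns `subgroup`
#' (\"S\"/\"C\"), `arm` (0/1) and `outcome`.
#'
#' @param df A data frame with columns `subgroup`, `arm`, `outcome`.
#' @return A `patient_data` object.
#' @export
patient_data <- function(df) {
  stopifnot(all(c("subgroup", "arm", "outcome") %in% names(df)))
  if (!all(df$subgroup %in% c("S", "C")) || !all(df$arm %in% c(0, 1)))
    stop("subgroup must be 'S'/'C' and arm must be 0/1")
  out <- list(
    x_s0 = df$outcome[df$subgroup == "S" & df$arm == 0],
    x_s1 = df$outcome[df$subgroup == "S" & df$arm == 1],
    x_c0 = df$outcome[df$subgroup == "C" & df$arm == 0],
    x_c1 = df$outcome[df$subgroup == "C" & df$arm == 1]
  )
  if (any(lengths(out) == 0)) stop("all four (subgroup, arm) cells must be non-empty")
  class(out) <- "patient_data"
  out
}

#' Construct sufficient statistics for one or more realised trials
#'
#' A realised trial is summarised, without loss, by the two estimated
#' treatment differences and the pooled within-group variance:
#' `theta_hat_s`, `theta_hat_c`, `sigma_hat_sq` with its degrees of freedom.
#' All statistic columns may be vectors (one row per simulated trial).
#'
#' @param theta_hat_s Estimated difference in the subgroup.
#' @param theta_hat_c Estimated difference in the complement.
#' @param sigma_hat_sq Pooled variance estimate (> 0 for downstream testing;
#'   a zero value is tolerated here and rejected by
#'   [compute_test_statistics()]).
#' @param df Degrees of freedom of the pooled variance.
#' @return A data frame of class `sufficient_stats` with attribute `df`.
#' @export
sufficient_stats <- function(theta_hat_s, theta_hat_c, sigma_hat_sq, df) {
  stopifnot(length(df) == 1L, df > 0)
  if (any(sigma_hat_sq < 0)) stop("sigma_hat_sq must be non-negative")
  out <- data.frame(theta_hat_s = theta_hat_s, theta_hat_c = theta_hat_c,
                    sigma_hat_sq = sigma_hat_sq)
  attr(out, "df") <- as.integer(df)
  class(out) <- c("sufficient_stats", "data.frame")
  out
}

#' Reduce patient-level data to sufficient statistics
#'
#' Computes the arm-mean differences per subgroup and the pooled within-group
#' variance (residual sum of squares over all four groups divided by
#' `n_all - 4`).
#'
#' @param data A `patient_data` object (see [simulate_patients()],
#'   [patient_data()]).
#' @param design A [design_spec()]; lengths are checked against it.
#' @return A one-row [sufficient_stats()].
#' @export
summarize_patients <- function(data, design) {
  stopifnot(inherits(data, "patient_data"), inherits(design, "design_spec"))
  if (length(data$x_s0) != design$n_s || length(data$x_s1) != design$n_s ||
      length(data$x_c0) != design$n_c || length(data$x_c1) != design$n_c)
    stop("patient vectors do not match the design's per-arm sizes")
  n_all <- 2 * design$n_s + 2 * design$n_c
  rss <- sum(vapply(data, function(x) sum((x - mean(x))^2), numeric(1)))
  sufficient_stats(
    theta_hat_s = mean(data$x_s1) - mean(data$x_s0),
    theta_hat_c = mean(data$x_c1) - mean(data$x_c0),
    sigma_hat_sq = rss / (n_all - 4),
    df = n_all - 4
  )
}

#' Sample sufficient statistics directly
#'
#' Draws trials at the sufficient-statistic level: independently,
#' `theta_hat_s ~ N(theta_s, 2 sigma^2 / n_s)`,
#' `theta_hat_c ~ N(theta_c, 2 sigma^2 / n_c)`, and
#' `sigma_hat_sq ~ sigma^2 chisq(df) / df` with `df = 2 n_s + 2 n_c - 4`.
#' This is distributionally identical to simulating patients and summarising
#' them, and is the workhorse behind calibration and power estimation.
#'
#' @param design A [design_spec()].
#' @param scenario An [effect_scenario()].
#' @param n_draws Number of trials to draw.
#' @param seed Integer seed; the same seed reproduces the same draws.
#' @return A [sufficient_stats()] data frame with `n_draws` rows.
#' @examples
#' s <- sample_sufficient_stats(design_spec(150, 150), effect_scenario(0.3, 0.1),
#'                              n_draws = 100, seed = 1)
#' colMeans(s)
#' @export
sample_sufficient_stats <- function(design, scenario, n_draws, seed = 1) {
  stopifnot(inherits(design, "design_spec"), inherits(scenario, "effect_scenario"),
            n_draws >= 1)
  core <- draw_core(n_draws, design$df, seed, "sufficient_stats")
  sufficient_stats(
    theta_hat_s = scenario$theta_s + sqrt(2 / design$n_s) * scenario$sigma * core$z_s,
    theta_hat_c = scenario$theta_c + sqrt(2 / design$n_c) * scenario$sigma * core$z_c,
    sigma_hat_sq = (scenario$sigma * core$u)^2,
    df = design$df
  )
}

#' Compute the t-statistic triple from sufficient statistics
#'
#' Forms `T_s = sqrt(n_s/2) theta_hat_s / sigma_hat`,
#' `T_c = sqrt(n_c/2) theta_hat_c / sigma_hat`, and the overall statistic via
#' its exact identity `T_o = sqrt(p) T_s + sqrt(1-p) T_c` (the overall
#' statistic is a deterministic function of the two subgroup statistics for
#' the equal-per-arm design).
#'
#' @param stats A [sufficient_stats()] data frame (any number of rows).
#' @param design A [design_spec()].
#' @return A data frame of class `test_stats` with columns `T_s`, `T_c`,
#'   `T_o` and attributes `df` and `p`.
#' @examples
#' st <- sufficient_stats(0.3, 0.1, 1, df = 596)
#' compute_test_statistics(st, design_spec(150, 150))
#' @export
compute_test_statistics <- function(stats, design) {
  stopifnot(inherits(stats, "sufficient_stats"), inherits(design, "design_spec"))
  if (any(stats$sigma_hat_sq <= 0))
    stop("degenerate variance: sigma_hat_sq must be > 0 to form t statistics")
  sigma_hat <- sqrt(stats$sigma_hat_sq)
  T_s <- sqrt(design$n_s / 2) * stats$theta_hat_s / sigma_hat
  T_c <- sqrt(design$n_c / 2) * stats$theta_hat_c / sigma_hat
  test_stats(T_s, T_c, df = attr(stats, "df"), p = design$p)
}

#' Construct a `test_stats` object
#'
#' `T_o` is always derived from the identity
#' `T_o = sqrt(p) T_s + sqrt(1-p) T_c`; it cannot be set independently.
#'
#' @param T_s,T_c Subgroup and complement t statistics (vectors allowed).
#' @param df Degrees of freedom.
#' @param p Trial prevalence of the subgroup.
#' @return A data frame of class `test_stats`.
#' @export
test_stats <- function(T_s, T_c, df, p) {
  stopifnot(length(df) == 1L, df > 0, p > 0, p < 1)
  out <- data.frame(T_s = T_s, T_c = T_c,
                    T_o = sqrt(p) * T_s + sqrt(1 - p) * T_c)
  attr(out, "df") <- as.integer(df)
  attr(out, "p") <- p
  class(out) <- c("test_stats", "data.frame")
  out
}
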