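#' Subgroup path of the intersection test
#'
#' Condition (a): the subgroup statistic clears its one-sided threshold and
#' the complement retains at least a fraction `b` of the estimated subgroup
#' effect. On the t-statistic scale the retention condition is
#' `T_c > b sqrt((1-p)/p) T_s`. Both inequalities are strict.
#'
#' @param T A `test_stats` object (vectorised over rows).
#' @param design A [design_spec()] supplying `b` and the subgroup threshold.
#' @return Logical vector, one element per row of `T`.
#' @seealso [condition_b()], [closed_test()]
#' @export
condition_a <- function(T, design) {
  stopifnot(inherits(T, "test_stats"), inherits(design, "design_spec"))
  cv <- critical_values(design)
  p <- design$p
  T$T_s > cv[["s"]] & T$T_c > design$b * sqrt((1 - p) / p) * T$T_s
}

#' Overall path of the intersection test
#'
#' Condition (b): the overall statistic
#' `T_o = sqrt(p) T_s + sqrt(1-p) T_c` clears its one-sided threshold and
#' each subgroup retains at least a fraction `k` of the estimated overall
#' effect. On the t-statistic scale the two retention conditions are
#' `k T_c < ((1-k) sqrt(p/(1-p)) + sqrt((1-p)/p)) T_s` and
#' `(sqrt(p/(1-p)) + (1-k) sqrt((1-p)/p)) T_c > k T_s`. At `k = 1` the two
#' conditions contradict each other and this path is empty; negative `k`
#' makes them permissive. All inequalities are strict.
#'
#' @inheritParams condition_a
#' @return Logical vector, one element per row of `T`.
#' @export
condition_b <- function(T, design) {
  stopifnot(inherits(T, "test_stats"), inherits(design, "design_spec"))
  if (is.na(design$k)) stop("design has no k; calibrate with solve_k() first")
  cv <- critical_values(design)
  T$T_o > cv[["o"]] & k_ratio_conditions(T, design)
}

# The two k-retention cone conditions of the overall path, shared by
# condition_b(), the constrained closed test and the constrained comparators.
k_ratio_conditions <- function(T, design) {
  p <- design$p; k <- design$k
  r_sp <- sqrt(p / (1 - p)); r_cs <- sqrt((1 - p) / p)
  k * T$T_c < ((1 - k) * r_sp + r_cs) * T$T_s &
    (r_sp + (1 - k) * r_cs) * T$T_c > k * T$T_s
}

#' Decision rules evaluated on the effect scale
#'
#' Evaluates the two paths directly on the estimated effects: the subgroup
#' path requires `theta_hat_c > b * theta_hat_s` together with the subgroup
#' significance test, and the overall path requires
#' `theta_hat_s > k * theta_hat_o` and `theta_hat_c > k * theta_hat_o`
#' (with `theta_hat_o = p theta_hat_s + (1-p) theta_hat_c`) together with
#' the overall significance test. For every input this must agree with
#' [condition_a()] and [condition_b()] applied to the corresponding t
#' statistics; the agreement is the algebraic equivalence between the
#' effect-scale and t-scale forms of the rules.
#'
#' @param stats A [sufficient_stats()] data frame.
#' @param design A [design_spec()].
#' @return Data frame with logical columns `subgroup_path`, `overall_path`.
#' @export
effect_scale_decision <- function(stats, design) {
  stopifnot(inherits(stats, "sufficient_stats"), inherits(design, "design_spec"))
  T <- compute_test_statistics(stats, design)
  cv <- critical_values(design)
  p <- design$p; k <- design$k
  theta_hat_o <- p * stats$theta_hat_s + (1 - p) * stats$theta_hat_c
  sub <- T$T_s > cv[["s"]] & stats$theta_hat_c > design$b * stats$theta_hat_s
  ove <- T$T_o > cv[["o"]] &
    stats$theta_hat_s > k * theta_hat_o &
    stats$theta_hat_c > k * theta_hat_o
  data.frame(subgroup_path = sub, overall_path = ove)
}

#' Closed test of the subgroup and overall hypotheses
#'
#' The intersection hypothesis (no effect in the subgroup and none overall)
#' is rejected when either [condition_a()] or [condition_b()] holds; the
#' construction guarantees the family-wise error rate of the whole procedure
#' at the level the design's `(b, k)` pair was calibrated for. By the closed
#' testing principle, once the intersection is rejected each individual
#' hypothesis is retested at the full family level: the subgroup claim needs
#' `T_s` and the overall claim `T_o` to exceed the upper-`family_alpha`
#' t quantile. A hypothesis can therefore be claimed even when its own
#' intersection-path condition failed (for example an overall p-value of
#' 0.023 with `alpha_o = 0.0125` fails condition (b) but passes the 0.025
#' retest whenever condition (a) rejected the intersection).
#'
#' With `constrained = TRUE` the second layer also imposes the consistency
#' conditions: the subgroup claim additionally requires
#' `T_c > b sqrt((1-p)/p) T_s` and the overall claim the two k-retention
#' conditions.
#'
#' @param T A `test_stats` object (vectorised over rows).
#' @param design A [design_spec()] with calibrated `k`.
#' @param family_alpha Family-wise level for the second-layer retests;
#'   defaults to `max(alpha_s, alpha_o)`, the full level of the design.
#' @param constrained Apply the consistency conditions in the second layer.
#' @return A data frame of class `decision_outcome` with logical columns
#'   `via_condition_a`, `via_condition_b`, `intersection_rejected`,
#'   `claim_s`, `claim_o`; attribute `critical_values` records all
#'   thresholds used.
#' @examples
#' d <- design_spec(150, 150, b = 0, k = 0.59)
#' T <- test_stats(T_s = c(2.5, 0), T_c = c(1.0, 0), df = d$df, p = d$p)
#' closed_test(T, d)
#' @export
closed_test <- function(T, design, family_alpha = max(design$alpha_s, design$alpha_o),
                        constrained = FALSE) {
  stopifnot(inherits(T, "test_stats"), inherits(design, "design_spec"),
            family_alpha > 0, family_alpha <= 0.5)
  a <- condition_a(T, design)
  b <- condition_b(T, design)
  rejected <- a | b
  t_fam <- stats::qt(1 - family_alpha, design$df)
  claim_s <- rejected & T$T_s > t_fam
  claim_o <- rejected & T$T_o > t_fam
  if (constrained) {
    p <- design$p
    claim_s <- claim_s & T$T_c > design$b * sqrt((1 - p) / p) * T$T_s
    claim_o <- claim_o & k_ratio_conditions(T, design)
  }
  out <- data.frame(via_condition_a = a, via_condition_b = b,
                    intersection_rejected = rejected,
                    claim_s = claim_s, claim_o = claim_o)
  cv <- critical_values(design)
  attr(out, "critical_values") <- c(cv, family = t_fam)
  class(out) <- c("decision_outcome", "data.frame")
  out
}

#' Analyze a single realised trial
#'
#' Convenience wrapper running the full pipeline for one trial given either
#' patient-level data or sufficient statistics, returning the decision with
#' all intermediate quantities.
#'
#' @param design A [design_spec()] with calibrated `k`.
#' @param data Optional `patient_data`.
#' @param stats Optional one-row [sufficient_stats()]; exactly one of
#'   `data`/`stats` must be given.
#' @param family_alpha,constrained Passed to [closed_test()].
#' @return A list of class `trial_analysis` with elements `design`, `stats`,
#'   `test_stats`, `decision`.
#' @export
analyze_trial <- function(design, data = NULL, stats = NULL,
                          family_alpha = max(design$alpha_s, design$alpha_o),
                          constrained = FALSE) {
  if (is.null(stats) == is.null(data))
    stop("supply exactly one of `data` or `stats`")
  if (!is.null(data)) stats <- summarize_patients(data, design)
  T <- compute_test_statistics(stats, design)
  structure(list(design = design, stats = stats, test_stats = T,
                 decision = closed_test(T, design, family_alpha, constrained)),
            class = "trial_analysis")
}

#' @export
print.trial_analysis <- function(x, ...) {
  cat(sprintf("theta_hat_s = %.4f, theta_hat_c = %.4f, sigma_hat = %.4f\n",
              x$stats$theta_hat_s, x$stats$theta_hat_c, sqrt(x$stats$sigma_hat_sq)))
  cat(sprintf("T_s = %.4f, T_c = %.4f, T_o = %.4f (df = %d)\n",
              x$test_stats$T_s, x$test_stats$T_c, x$test_stats$T_o,
              attr(x$test_stats, "df")))
  d <- x$decision
  cat(sprintf("intersection rejected: %s (subgroup path %s, overall path %s)\n",
              d$intersection_rejected, d$via_condition_a, d$via_condition_b))
  cat(sprintf("claims: subgroup %s, overall %s\n", d$claim_s, d$claim_o))
  invisible(x)
}
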