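#' Specify a multiplicity-adjustment method
#'
#' Benchmarks against which the consistency-based test is compared:
#' `"consistency"` (the closed test of this package), `"bonferroni"`
#' (each hypothesis at `alpha/2`), `"dunnett"` (common critical value from
#' the bivariate t of `(T_s, T_o)`), and the two fixed-sequence orders.
#' Any method can be `constrained`, which filters its claims through the
#' design's consistency conditions (see [constrain_decision()]).
#'
#' @param name One of `"consistency"`, `"bonferroni"`, `"dunnett"`,
#'   `"fixed_sequence_s_first"`, `"fixed_sequence_o_first"`.
#' @param constrained Logical; apply the `(b, k)` consistency filter to the
#'   claims. Requires the design passed at decision time to carry `b` and
#'   `k`.
#' @param alpha Family-wise error target of the procedure.
#' @param holm For `"bonferroni"` only: escalate the smaller p-value's
#'   partner to the full level (Holm step-down). Off by default, matching
#'   the plain equal-split procedure used as the published benchmark.
#' @return An object of class `method_spec`.
#' @export
method_spec <- function(name = c("consistency", "bonferroni", "dunnett",
                                 "fixed_sequence_s_first",
                                 "fixed_sequence_o_first"),
                        constrained = FALSE, alpha = 0.025, holm = FALSE) {
  name <- match.arg(name)
  structure(list(name = name, constrained = constrained, alpha = alpha,
                 holm = holm),
            class = "method_spec")
}

as_outcome <- function(claim_s, claim_o, crit) {
  out <- data.frame(via_condition_a = claim_s, via_condition_b = claim_o,
                    intersection_rejected = claim_s | claim_o,
                    claim_s = claim_s, claim_o = claim_o)
  attr(out, "critical_values") <- crit
  class(out) <- c("decision_outcome", "data.frame")
  out
}

#' Bonferroni decision for the two-hypothesis family
#'
#' Each hypothesis is tested one-sided at `alpha/2`: the subgroup claim
#' requires `T_s` and the overall claim `T_o` to exceed the upper-`alpha/2`
#' t quantile. No step-down escalation is applied by default, so the
#' subgroup power does not depend on the complement's effect. With
#' `holm = TRUE`, whichever hypothesis rejects at `alpha/2` lets the other
#' be retested at the full `alpha`.
#'
#' @param T A `test_stats` object.
#' @param alpha Family-wise error target.
#' @param df Degrees of freedom (defaults to the `df` attribute of `T`).
#' @param holm Apply Holm step-down escalation.
#' @return A `decision_outcome` data frame.
#' @export
bonferroni_decision <- function(T, alpha = 0.025, df = attr(T, "df"),
                                holm = FALSE) {
  stopifnot(inherits(T, "test_stats"))
  t_half <- stats::qt(1 - alpha / 2, df)
  claim_s <- T$T_s > t_half
  claim_o <- T$T_o > t_half
  if (holm) {
    t_full <- stats::qt(1 - alpha, df)
    claim_s <- claim_s | (claim_o & T$T_s > t_full)
    claim_o <- claim_o | (claim_s & T$T_o > t_full)
  }
  as_outcome(claim_s, claim_o, c(bonferroni = t_half))
}

#' Equicoordinate Dunnett critical value for (T_s, T_o)
#'
#' The subgroup and overall t statistics share the pooled variance estimate
#' and overlap in their numerators; under the equal-per-arm design their
#' correlation is exactly `sqrt(p)`. The common critical value `c` solves
#' `P(T_s > c or T_o > c) = alpha` under the central bivariate t with that
#' correlation and the pooled degrees of freedom, computed with the
#' deterministic bivariate-t algorithm of \pkg{mvtnorm} and refined by
#' root-finding.
#'
#' @param p Trial prevalence of the subgroup (the correlation is `sqrt(p)`).
#' @param df Degrees of freedom.
#' @param alpha Family-wise error target.
#' @return The critical value (scalar), strictly between the `alpha` and
#'   `alpha/2` t quantiles for any `p` in (0, 1).
#' @export
dunnett_critical_value <- function(p, df, alpha = 0.025) {
  stopifnot(p > 0, p < 1, df > 0, alpha > 0, alpha < 0.5)
  corr <- matrix(c(1, sqrt(p), sqrt(p), 1), 2)
  f <- function(cc)
    1 - mvtnorm::pmvt(upper = c(cc, cc), corr = corr, df = as.integer(df),
                      algorithm = mvtnorm::TVPACK(1e-10)) - alpha
  lo <- stats::qt(1 - alpha, df); hi <- stats::qt(1 - alpha / 2, df)
  r <- stats::uniroot(f, c(lo, hi), tol = 1e-8)
  if (abs(r$f.root) > 1e-5)
    stop("Dunnett critical value did not converge: residual ", r$f.root)
  r$root
}

#' Dunnett-type decision for the two-hypothesis family
#'
#' Both hypotheses are tested against the common critical value of
#' [dunnett_critical_value()], which exploits the `sqrt(p)` correlation of
#' `(T_s, T_o)` to reduce the multiplicity penalty relative to Bonferroni.
#'
#' @param T A `test_stats` object.
#' @param alpha Family-wise error target.
#' @param p Prevalence (defaults to the `p` attribute of `T`).
#' @param df Degrees of freedom (defaults to the `df` attribute of `T`).
#' @return A `decision_outcome` data frame.
#' @export
dunnett_decision <- function(T, alpha = 0.025, p = attr(T, "p"),
                             df = attr(T, "df")) {
  stopifnot(inherits(T, "test_stats"))
  cc <- dunnett_critical_value(p, df, alpha)
  as_outcome(T$T_s > cc, T$T_o > cc, c(dunnett = cc))
}

#' Fixed-sequence decision
#'
#' Tests the hypotheses in a pre-specified order, each at the full `alpha`;
#' the second hypothesis is tested only if the first rejects.
#'
#' @param T A `test_stats` object.
#' @param alpha Family-wise error target (each test runs at this level).
#' @param order `"s_first"` (subgroup gatekeeps the overall test) or
#'   `"o_first"`.
#' @param df Degrees of freedom (defaults to the `df` attribute of `T`).
#' @return A `decision_outcome` data frame.
#' @export
fixed_sequence_decision <- function(T, alpha = 0.025,
                                    order = c("s_first", "o_first"),
                                    df = attr(T, "df")) {
  stopifnot(inherits(T, "test_stats"))
  order <- match.arg(order)
  t_full <- stats::qt(1 - alpha, df)
  if (order == "s_first") {
    claim_s <- T$T_s > t_full
    claim_o <- claim_s & T$T_o > t_full
  } else {
    claim_o <- T$T_o > t_full
    claim_s <- claim_o & T$T_s > t_full
  }
  as_outcome(claim_s, claim_o, c(fixed_sequence = t_full))
}

#' Filter a decision through the consistency conditions
#'
#' Applies the design's consistency requirements to the claims of any
#' procedure: the subgroup claim additionally requires
#' `T_c > b sqrt((1-p)/p) T_s`, and the overall claim the two k-retention
#' conditions of the overall path. The constrained claims always imply the
#' unconstrained ones, and `intersection_rejected` is recomputed as their
#' disjunction.
#'
#' @param outcome A `decision_outcome` produced by any decision function.
#' @param T The `test_stats` the outcome was computed from.
#' @param design A [design_spec()] supplying `b` and `k`.
#' @return A `decision_outcome` with filtered claims.
#' @export
constrain_decision <- function(outcome, T, design) {
  stopifnot(inherits(outcome, "decision_outcome"), inherits(T, "test_stats"),
            inherits(design, "design_spec"))
  if (is.na(design$k)) stop("design has no k; the overall constraint needs it")
  p <- design$p
  claim_s <- outcome$claim_s & T$T_c > design$b * sqrt((1 - p) / p) * T$T_s
  claim_o <- outcome$claim_o & k_ratio_conditions(T, design)
  out <- as_outcome(claim_s, claim_o, attr(outcome, "critical_values"))
  out$via_condition_a <- outcome$via_condition_a
  out$via_condition_b <- outcome$via_condition_b
  out
}

# Dispatch a method_spec to its decision function.
decide <- function(method, T, design) {
  out <- switch(method$name,
    consistency = closed_test(T, design, family_alpha = method$alpha,
                              constrained = method$constrained),
    bonferroni = bonferroni_decision(T, alpha = method$alpha, holm = method$holm),
    dunnett = dunnett_decision(T, alpha = method$alpha),
    fixed_sequence_s_first = fixed_sequence_decision(T, alpha = method$alpha,
                                                     order = "s_first"),
    fixed_sequence_o_first = fixed_sequence_decision(T, alpha = method$alpha,
                                                     order = "o_first")
  )
  if (method$constrained && method$name != "consistency")
    out <- constrain_decision(out, T, design)
  out
}
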