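#' Specify an enrichment trial design
#'
#' An enrichment design randomises `n_s` patients per arm in the
#' biomarker-positive subgroup (S) and `n_c` per arm in the marker-negative
#' complement (C), and pre-specifies one-sided significance levels for the
#' subgroup test (`alpha_s`) and the overall-population test (`alpha_o`)
#' together with two consistency fractions:
#'
#' * `b` — the minimum fraction of the estimated subgroup effect that the
#'   complement must retain before the subgroup claim can be made;
#' * `k` — the minimum fraction of the estimated overall effect that *each*
#'   subgroup must retain before the overall claim can be made.
#'
#' The subgroup prevalence in the trial, `p = n_s / (n_s + n_c)`, and the
#' pooled-variance degrees of freedom, `df = 2 n_s + 2 n_c - 4`, are derived
#' and never stored independently.
#'
#' `k` is typically left `NA` at design time and filled in by [solve_k()],
#' which calibrates it so that the intersection test has a target family-wise
#' type I error. Negative `k` values are legitimate outcomes of that
#' calibration when `b` is large.
#'
#' @param n_s Integer, patients per arm in the marker-positive subgroup
#'   (at least 2).
#' @param n_c Integer, patients per arm in the marker-negative complement
#'   (at least 2).
#' @param alpha_s One-sided level for the subgroup test, in (0, 0.5].
#' @param alpha_o One-sided level for the overall test, in (0, 0.5].
#' @param b Consistency fraction for the subgroup claim, in (-1, 1).
#' @param k Consistency fraction for the overall claim, in (-1, 1], or `NA`
#'   before calibration. At the boundary `k = 1` the overall path is empty
#'   (both subgroups would have to exceed the overall effect strictly, which
#'   is contradictory), reducing the procedure to subgroup-first
#'   fixed-sequence testing.
#' @param crit_s,crit_o Optional explicit critical values for the subgroup
#'   and overall tests. By default the exact upper-`alpha` Student-t
#'   quantiles at `df` degrees of freedom are used. Supply explicit values
#'   when a protocol fixes rounded thresholds (for example 1.96); published
#'   calibration tables for this class of designs are computed against such
#'   two-decimal thresholds, and reproducing them requires passing the same
#'   rounded values here.
#'
#' @return An object of class `design_spec`: a list with fields `n_s`,
#'   `n_c`, `alpha_s`, `alpha_o`, `b`, `k`, `crit_s`, `crit_o` and derived
#'   `p`, `df`.
#' @examples
#' d <- design_spec(n_s = 150, n_c = 150, alpha_s = 0.025, alpha_o = 0.025,
#'                  b = 0, k = 0.59)
#' d$p
#' d$df
#' critical_values(d)
#' @seealso [effect_scenario()], [solve_k()], [closed_test()]
#' @export
design_spec <- function(n_s, n_c, alpha_s = 0.025, alpha_o = 0.025,
                        b = 0, k = NA_real_,
                        crit_s = NULL, crit_o = NULL) {
  stopifnot(length(n_s) == 1L, length(n_c) == 1L)
  if (n_s < 2 || n_c < 2 || n_s != round(n_s) || n_c != round(n_c))
    stop("n_s and n_c must be integers >= 2 so each group variance is estimable")
  if (!(alpha_s > 0 && alpha_s <= 0.5) || !(alpha_o > 0 && alpha_o <= 0.5))
    stop("alpha_s and alpha_o must lie in (0, 0.5]")
  if (!(b > -1 && b < 1))
    stop("b must lie in (-1, 1)")
  if (!is.na(k) && !(k > -1 && k <= 1))
    stop("k must lie in (-1, 1] or be NA before calibration")
  if (!is.null(crit_s)) stopifnot(is.numeric(crit_s), length(crit_s) == 1L, crit_s > 0)
  if (!is.null(crit_o)) stopifnot(is.numeric(crit_o), length(crit_o) == 1L, crit_o > 0)
  out <- list(
    n_s = as.integer(n_s), n_c = as.integer(n_c),
    alpha_s = alpha_s, alpha_o = alpha_o,
    b = b, k = as.numeric(k),
    crit_s = crit_s, crit_o = crit_o,
    p = n_s / (n_s + n_c),
    df = as.integer(2 * n_s + 2 * n_c - 4)
  )
  class(out) <- "design_spec"
  out
}

#' Critical values of a design
#'
#' Returns the thresholds used for the subgroup and overall one-sided tests:
#' the explicit `crit_s`/`crit_o` stored in the design if supplied, otherwise
#' the exact upper-`alpha` Student-t quantiles at the design's degrees of
#' freedom.
#'
#' @param design A [design_spec()].
#' @return Named numeric vector with elements `s` and `o`.
#' @export
critical_values <- function(design) {
  stopifnot(inherits(design, "design_spec"))
  c(s = if (is.null(design$crit_s)) stats::qt(1 - design$alpha_s, design$df) else design$crit_s,
    o = if (is.null(design$crit_o)) stats::qt(1 - design$alpha_o, design$df) else design$crit_o)
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Enrichment design\n")
  cat(sprintf("  n_s = %d, n_c = %d per arm  (p = %.4g, df = %d)\n",
              x$n_s, x$n_c, x$p, x$df))
  cat(sprintf("  alpha_s = %g, alpha_o = %g (one-sided)\n", x$alpha_s, x$alpha_o))
  cv <- critical_values(x)
  cat(sprintf("  critical values: t_s = %.4f, t_o = %.4f%s\n", cv["s"], cv["o"],
              if (is.null(x$crit_s) && is.null(x$crit_o)) " (exact t quantiles)" else " (explicit)"))
  cat(sprintf("  consistency fractions: b = %g, k = %s\n",
              x$b, if (is.na(x$k)) "NA (uncalibrated)" else format(x$k)))
  invisible(x)
}

#' Specify a true effect scenario
#'
#' A scenario fixes the true treatment differences in the marker-positive
#' subgroup (`theta_s`) and the marker-negative complement (`theta_c`) and
#' the common within-group standard deviation `sigma`. The true overall
#' effect is the prevalence-weighted average
#' `theta_o = p * theta_s + (1 - p) * theta_c` and is derived on demand via
#' [overall_effect()], never stored.
#'
#' @param theta_s True treatment difference in the subgroup (outcome units).
#' @param theta_c True treatment difference in the complement (outcome units).
#' @param sigma Common within-group standard deviation, > 0.
#' @return An object of class `effect_scenario`.
#' @examples
#' sc <- effect_scenario(theta_s = 0.3, theta_c = 0.1, sigma = 1)
#' overall_effect(sc, design_spec(150, 150))
#' @export
effect_scenario <- function(theta_s, theta_c, sigma = 1) {
  stopifnot(is.numeric(theta_s), is.numeric(theta_c), length(theta_s) == 1L,
            length(theta_c) == 1L, length(sigma) == 1L)
  if (!(sigma > 0)) stop("sigma must be > 0")
  structure(list(theta_s = theta_s, theta_c = theta_c, sigma = sigma),
            class = "effect_scenario")
}

#' True overall effect implied by a scenario and a design
#'
#' @param scenario An [effect_scenario()].
#' @param design A [design_spec()]; supplies the trial prevalence `p`.
#' @return `p * theta_s + (1 - p) * theta_c`.
#' @export
overall_effect <- function(scenario, design) {
  stopifnot(inherits(scenario, "effect_scenario"), inherits(design, "design_spec"))
  design$p * scenario$theta_s + (1 - design$p) * scenario$theta_c
}

#' @export
print.effect_scenario <- function(x, ...) {
  cat(sprintf("Effect scenario: theta_s = %g, theta_c = %g, sigma = %g\n",
              x$theta_s, x$theta_c, x$sigma))
  invisible(x)
}
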