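#' Evaluate rejection regions on a grid
#'
#' Tabulates membership of the consistency region's two paths, the
#' Bonferroni region and the Dunnett region over a rectangular grid of
#' `(T_s, T_c)` values, either on the t-statistic scale or mapped to the
#' one-sided p-value scale through `p = 1 - F_t(T; df)` (a strictly
#' decreasing one-to-one transform, so the p-scale cells are the images of
#' the t-scale cells).
#'
#' @param design A [design_spec()] with `k` set.
#' @param scale `"t"` or `"pvalue"`.
#' @param resolution Grid points per axis (at least 50).
#' @param t_range Range of each t axis (used for both scales; the p-scale
#'   grid is the image of an equally spaced t grid).
#' @param family_alpha Level for the comparator regions.
#' @return A data frame of class `region_grid` with columns `T_s`, `T_c`
#'   (and `p_s`, `p_c` on the p-value scale) plus logical membership columns
#'   `condition_a`, `condition_b`, `consistency`, `bonferroni`, `dunnett`.
#' @examples
#' g <- region_grid(design_spec(150, 150, b = 0, k = 0.59), resolution = 50)
#' mean(g$consistency)
#' @export
region_grid <- function(design, scale = c("t", "pvalue"), resolution = 101,
                        t_range = c(-3, 5), family_alpha = max(design$alpha_s, design$alpha_o)) {
  stopifnot(inherits(design, "design_spec"), resolution >= 50)
  scale <- match.arg(scale)
  ax <- seq(t_range[1], t_range[2], length.out = resolution)
  grid <- expand.grid(T_s = ax, T_c = ax, KEEP.OUT.ATTRS = FALSE)
  T <- test_stats(grid$T_s, grid$T_c, df = design$df, p = design$p)
  grid$condition_a <- condition_a(T, design)
  grid$condition_b <- condition_b(T, design)
  grid$consistency <- grid$condition_a | grid$condition_b
  bf <- bonferroni_decision(T, alpha = family_alpha)
  grid$bonferroni <- bf$intersection_rejected
  dn <- dunnett_decision(T, alpha = family_alpha, p = design$p, df = design$df)
  grid$dunnett <- dn$intersection_rejected
  if (scale == "pvalue") {
    grid$p_s <- stats::pt(grid$T_s, design$df, lower.tail = FALSE)
    grid$p_c <- stats::pt(grid$T_c, design$df, lower.tail = FALSE)
  }
  attr(grid, "design") <- design
  attr(grid, "scale") <- scale
  class(grid) <- c("region_grid", "data.frame")
  grid
}

#' Plot a rejection-region grid
#'
#' Shades the consistency region by its path (subgroup path, overall path,
#' both) and draws the Bonferroni region boundary for comparison.
#'
#' @param x A [region_grid()].
#' @param comparator Membership column to overlay as a contour
#'   (`"bonferroni"`, `"dunnett"`, or `NULL`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.region_grid <- function(x, comparator = "bonferroni", ...) {
  scale <- attr(x, "scale")
  xs <- if (scale == "pvalue") "p_s" else "T_s"
  ys <- if (scale == "pvalue") "p_c" else "T_c"
  region <- factor(ifelse(x$condition_a & x$condition_b, "both paths",
                   ifelse(x$condition_a, "subgroup path",
                   ifelse(x$condition_b, "overall path", "accept"))),
                   levels = c("accept", "subgroup path", "overall path", "both paths"))
  df <- data.frame(x = x[[xs]], y = x[[ys]], region = region,
                   comp = if (!is.null(comparator)) as.numeric(x[[comparator]]) else NA)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$region)) +
    ggplot2::scale_fill_manual(values = c(accept = "white",
                                          `subgroup path` = "#9ecae1",
                                          `overall path` = "#fdae6b",
                                          `both paths` = "#756bb1")) +
    ggplot2::labs(x = if (scale == "pvalue") "subgroup p-value" else "T_s",
                  y = if (scale == "pvalue") "complement p-value" else "T_c",
                  fill = "rejection via") +
    ggplot2::theme_minimal()
  if (!is.null(comparator))
    gg <- gg + ggplot2::geom_contour(ggplot2::aes(z = .data$comp),
                                     breaks = 0.5, colour = "black",
                                     linetype = "dashed")
  gg
}

#' Plot disjunctive power against the complement effect
#'
#' One curve per design/method combination from a [design_sweep()] result.
#'
#' @param sweep A data frame from [design_sweep()].
#' @param y Column to plot (default `"disjunctive"`).
#' @return A ggplot object.
#' @export
plot_power_sweep <- function(sweep, y = "disjunctive") {
  stopifnot(is.data.frame(sweep), y %in% names(sweep))
  sweep$curve <- interaction(sweep$design, sweep$method, sweep$constrained,
                             drop = TRUE)
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$theta_c, y = .data[[y]],
                                      colour = .data$curve)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "true complement effect", y = y, colour = "design.method") +
    ggplot2::theme_minimal()
}

#' Write sweep or calibration tables to disk
#'
#' Writes the full-precision table as CSV (and optionally JSON), plus a
#' companion `*_rounded.csv` rendering numeric columns to two decimals for
#' side-by-side comparison with published tables. A run header with the
#' package version and timestamp is written as comment lines in front of
#' the CSV payload.
#'
#' @param results A data frame ([design_sweep()], [bk_contour()], ...).
#' @param path Output CSV path; the rounded rendering goes to
#'   `<path minus .csv>_rounded.csv`.
#' @param json Also write `<path minus .csv>.json`.
#' @return Invisibly, the paths written.
#' @export
write_tables <- function(results, path, json = FALSE) {
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0)
    warning("writing a header-only table: `results` has no rows")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  header <- sprintf("# consistenrich %s | %s",
                    as.character(utils::packageVersion("consistenrich")),
                    format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"))
  con <- file(path, "w")
  writeLines(header, con)
  utils::write.csv(results, con, row.names = FALSE)
  close(con)
  stem <- sub("\\.csv$", "", path)
  rounded <- results
  num <- vapply(rounded, is.numeric, logical(1))
  rounded[num] <- lapply(rounded[num], round, digits = 2)
  utils::write.csv(rounded, paste0(stem, "_rounded.csv"), row.names = FALSE)
  paths <- c(path, paste0(stem, "_rounded.csv"))
  if (json) {
    jsonlite::write_json(results, paste0(stem, ".json"), dataframe = "rows",
                         digits = NA, auto_unbox = TRUE)
    paths <- c(paths, paste0(stem, ".json"))
  }
  invisible(paths)
}

#' Read back a table written by [write_tables()]
#'
#' @param path CSV path.
#' @return The data frame (header comment lines skipped).
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
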