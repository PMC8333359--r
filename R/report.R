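#' Cohort tumour-volume table
#'
#' The published per-patient tumour volumes (cm^3, from T2-weighted
#' segmentation) and pre-treatment volumetric growth rates (cm^3/yr) for
#' the five-subject cohort. Two cells are missing: patient 1 at 6 months
#' and patient 3 at 8 weeks.
#'
#' @return data.frame with columns `subject`, `growth_rate`, `vol_pre`,
#'   `vol_2wk`, `vol_8wk`, `vol_6mo`.
#' @export
vs_volume_table <- function() {
  data.frame(
    subject = 1:5,
    growth_rate = c(0.24, 0.55, 0.88, 0.59, 0.71),
    vol_pre = c(0.76, 1.20, 1.07, 1.51, 1.25),
    vol_2wk = c(0.72, 1.22, 1.08, 1.54, 1.26),
    vol_8wk = c(0.70, 1.28, NA, 1.58, 1.26),
    vol_6mo = c(NA, 1.24, 1.25, 1.79, 1.24)
  )
}

#' Cohort ages at treatment
#'
#' @return numeric vector of the five patients' ages (years).
#' @export
vs_cohort_ages <- function() {
  c(70.2, 71.2, 69.9, 73.7, 79.1)
}

#' Per-timepoint tumour-volume statistics
#'
#' Mean and sample SD over the subjects with an available volume at each
#' timepoint, and the mean difference from baseline computed as the
#' difference of group means: timepoint mean (available subjects) minus the
#' pre-treatment mean over all subjects. Unrounded values are returned; the
#' report view applies half-up rounding to 2 decimals.
#'
#' @param table a volume table as from [vs_volume_table()].
#' @return list with `stats` (data.frame: timepoint, n, mean, sd,
#'   mean_diff) and `growth` (mean, sd of growth rate).
#' @export
volume_stats <- function(table) {
  vol_cols <- grep("^vol_", names(table), value = TRUE)
  tps <- sub("^vol_", "", vol_cols)
  pre_mean <- mean(table$vol_pre, na.rm = TRUE)
  rows <- lapply(seq_along(vol_cols), function(i) {
    v <- table[[vol_cols[i]]]
    v <- v[!is.na(v)]
    stop_if_not(length(v) >= 1, sprintf("timepoint %s is empty", tps[i]))
    stop_if_not(length(v) >= 2,
                sprintf("SD undefined for single-subject timepoint %s", tps[i]))
    data.frame(timepoint = tps[i], n = length(v), mean = mean(v),
               sd = sd(v),
               mean_diff = if (tps[i] == "pre") NA_real_
                           else mean(v) - pre_mean)
  })
  gr <- table$growth_rate[!is.na(table$growth_rate)]
  list(stats = do.call(rbind, rows),
       growth = list(mean = mean(gr), sd = sd(gr)))
}

#' Cohort demographic summary
#'
#' @param x numeric vector (e.g. ages).
#' @return list with `median` (midpoint convention for even n), `range`
#'   (min, max).
#' @export
cohort_summary <- function(x) {
  stop_if_not(length(x) >= 1, "empty input")
  list(median = median(x), range = range(x))
}

fmt_ci <- function(est, lo, hi, digits = 2) {
  sprintf("%.*f (%.*f, %.*f)", digits, round_half_up(est, digits),
          digits, round_half_up(lo, digits),
          digits, round_half_up(hi, digits))
}

#' Render report tables
#'
#' Writes deterministic CSV report tables from already-computed results:
#' the volume table statistics, the per-parameter voxelwise delta tables
#' (mean difference with 95\% CI and significance stars, `***` p <= 0.001,
#' `**` p <= 0.01, `*` p <= 0.05), and the compartment-percentage table.
#' Values are the statistics modules' unrounded numbers rendered half-up
#' to 2 decimals; nothing is recomputed here.
#'
#' @param results list as produced by [analyze_cohort()] (fields used:
#'   `volume`, `delta_tables`, `compartments`); any element may be NULL.
#' @param dir output directory.
#' @return invisibly, the vector of files written.
#' @export
render_tables <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (!is.null(results$volume)) {
    vs <- results$volume$stats
    tab <- data.frame(
      timepoint = vs$timepoint, n = vs$n,
      mean_sd = sprintf("%.2f (%.2f)", round_half_up(vs$mean, 2),
                        round_half_up(vs$sd, 2)),
      mean_diff = ifelse(is.na(vs$mean_diff), "",
                         sprintf("%.2f", round_half_up(vs$mean_diff, 2))))
    f <- file.path(dir, "table2_volumes.csv")
    write.csv(tab, f, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(results$delta_tables)) {
    for (nm in names(results$delta_tables)) {
      dt <- results$delta_tables[[nm]]
      dt$mean_difference <- mapply(fmt_ci, dt$estimate, dt$ci_low, dt$ci_high,
                                   MoreArgs = list(digits = 2))
      dt$stars <- signif_stars(dt$p_adj)
      f <- file.path(dir, sprintf("delta_%s.csv", nm))
      write.csv(dt[, c("subject", "timepoint", "mean_difference", "p_adj",
                       "stars")], f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  if (!is.null(results$compartments)) {
    f <- file.path(dir, "fig3_percentages.csv")
    write.csv(results$compartments, f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
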