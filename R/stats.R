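#' Build a voxel panel
#'
#' A voxel x timepoint matrix restricted to the tumour object mask (defined
#' on the pre-treatment image and applied to every co-registered map), the
#' unit of longitudinal voxelwise statistics.
#'
#' @param values named list of 3-D parameter maps, one per acquired
#'   timepoint.
#' @param mask logical tumour mask (shared across timepoints).
#' @param parameter parameter name (e.g. "tsc").
#' @param units unit label.
#' @return an object of class `vs_panel`: a matrix with one column per
#'   timepoint plus attributes.
#' @export
voxel_panel <- function(values, mask, parameter = "", units = "") {
  cols <- lapply(values, function(v) {
    vals <- if (inherits(v, "vs_tsc_map")) v$values else v
    vals[mask]
  })
  m <- do.call(cbind, cols)
  colnames(m) <- names(values)
  structure(m, class = c("vs_panel", "matrix"), parameter = parameter,
            units = units)
}

#' Voxelwise delta between two timepoints
#'
#' @param panel a [voxel_panel()] (any matrix with timepoint columns).
#' @param timepoint,baseline column labels.
#' @param subject optional subject label used in the error message for a
#'   missing visit.
#' @return numeric vector of elementwise `timepoint - baseline`
#'   differences.
#' @export
voxel_delta <- function(panel, timepoint, baseline = "pre", subject = NULL) {
  for (col in c(timepoint, baseline)) {
    if (!col %in% colnames(panel)) {
      who <- if (is.null(subject)) "" else sprintf(" for subject %s", subject)
      stop(sprintf(
        "missing visit: timepoint '%s' not acquired%s; use the earliest available visit as baseline",
        col, who), call. = FALSE)
    }
  }
  unname(panel[, timepoint] - panel[, baseline])
}

#' Baseline column of a panel
#'
#' `pre` when acquired, otherwise the earliest available visit (the
#' convention used when a subject lacks pre-treatment imaging).
#'
#' @param panel a [voxel_panel()].
#' @param order preference order of timepoint labels.
#' @return the baseline column label.
#' @export
panel_baseline <- function(panel, order = c("pre", "2wk", "8wk", "6mo")) {
  present <- order[order %in% colnames(panel)]
  stop_if_not(length(present) > 0, "panel has no known timepoints")
  present[1]
}

#' Classify sodium compartment changes
#'
#' Tabulates sign pairs of (delta TSC, delta second metric): voxels with
#' increased TSC and increased MD (or v_e) are counted as an extracellular
#' sodium increase, increased TSC with decreased MD (or v_e) as an
#' intracellular increase. Strict inequalities; exact zeros are tallied
#' separately and belong to neither population.
#'
#' @param delta_tsc,delta_other equal-length numeric vectors of voxelwise
#'   deltas.
#' @return an object of class `vs_compartments`: counts `n_up_up`,
#'   `n_up_down`, `n_up_zero`, `n_down`, `n_zero`, the total, and
#'   percentages of the total (`pct_extracellular` = up/up,
#'   `pct_intracellular` = up/down).
#' @export
classify_compartments <- function(delta_tsc, delta_other) {
  stop_if_not(length(delta_tsc) == length(delta_other),
              "delta vectors must have equal length")
  up <- delta_tsc > 0
  n <- length(delta_tsc)
  cnt <- list(
    n_up_up   = sum(up & delta_other > 0),
    n_up_down = sum(up & delta_other < 0),
    n_up_zero = sum(up & delta_other == 0),
    n_down    = sum(delta_tsc < 0),
    n_zero    = sum(delta_tsc == 0),
    total     = n
  )
  cnt$pct_up <- 100 * sum(up) / n
  cnt$pct_extracellular <- 100 * cnt$n_up_up / n
  cnt$pct_intracellular <- 100 * cnt$n_up_down / n
  structure(cnt, class = "vs_compartments")
}

vs_stat <- function(estimate = NA_real_, ci = c(NA_real_, NA_real_),
                    statistic = NA_real_, df = NA_real_, p = NA_real_,
                    p_adj = NA_real_, method = "") {
  structure(list(estimate = estimate, ci_low = ci[1], ci_high = ci[2],
                 statistic = statistic, df = df, p = p, p_adj = p_adj,
                 method = method), class = "vs_stat")
}

#' @export
print.vs_stat <- function(x, ...) {
  cat(sprintf("%s: estimate %.4g (95%% CI %.4g, %.4g), stat %.4g, p %.4g\n",
              x$method, x$estimate, x$ci_low, x$ci_high, x$statistic, x$p))
  invisible(x)
}

#' One-sample test of proportions
#'
#' Two-sided normal-approximation z-test,
#' `z = (k/n - p0) / sqrt(p0 (1 - p0) / n)`, without continuity
#' correction. Used to compare the extracellular versus intracellular share
#' among classified voxels against an equal split (`p0 = 0.5`).
#'
#' @param k successes; `n` trials (> 0); `p0` null proportion.
#' @param n number of trials.
#' @param p0 null proportion.
#' @return a `vs_stat` with the observed proportion, Wald CI, z and p.
#' @export
proportion_test <- function(k, n, p0 = 0.5) {
  stop_if_not(n > 0, "n must be > 0")
  stop_if_not(k >= 0 && k <= n, "k must lie in [0, n]")
  phat <- k / n
  z <- (phat - p0) / sqrt(p0 * (1 - p0) / n)
  se <- sqrt(phat * (1 - phat) / n)
  p <- 2 * pnorm(-abs(z))
  vs_stat(estimate = phat, ci = phat + c(-1, 1) * 1.96 * se,
          statistic = z, df = NA_real_, p = p,
          method = "one-sample proportion z-test")
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' One-way within-subject ANOVA on a complete-case panel (rows = repeated
#' units, columns = conditions/timepoints), with the sphericity estimate
#' `epsilon = (tr S)^2 / ((k - 1) tr(S^2))` computed on the double-centred
#' column covariance and clipped to `[1/(k - 1), 1]`; both F degrees of
#' freedom are multiplied by epsilon.
#'
#' @param panel numeric matrix with >= 3 rows, >= 2 columns, no missing
#'   cells.
#' @return a `vs_stat` with F, corrected df (vector of 2), p, and
#'   `epsilon` attached as `$epsilon`.
#' @export
rm_anova_gg <- function(panel) {
  x <- unclass(as.matrix(panel))
  stop_if_not(ncol(x) >= 2, "need at least 2 columns")
  stop_if_not(nrow(x) >= 3, "need at least 3 rows")
  if (anyNA(x))
    stop("missing cells: use mixed_model_timepoint for incomplete panels",
         call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  colm <- colMeans(x); rowm <- rowMeans(x)
  ss_cond <- n * sum((colm - grand)^2)
  resid <- x - outer(rowm, rep(1, k)) -
    outer(rep(1, n), colm) + grand
  ss_err <- sum(resid^2)
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  f <- (ss_cond / df1) / (ss_err / df2)

  S <- stats::cov(x)
  C <- diag(k) - matrix(1 / k, k, k)
  St <- C %*% S %*% C
  eps <- sum(diag(St))^2 / (df1 * sum(St * St))
  eps <- min(max(eps, 1 / df1), 1)

  p <- pf(f, eps * df1, eps * df2, lower.tail = FALSE)
  out <- vs_stat(estimate = ss_cond / df1, statistic = f,
                 df = NA_real_, p = p,
                 method = "rm-ANOVA (Greenhouse-Geisser)")
  out$df <- c(eps * df1, eps * df2)
  out$epsilon <- eps
  out$F_uncorrected_df <- c(df1, df2)
  out
}

#' Pairwise paired comparisons with Bonferroni correction
#'
#' Paired mean differences (timepoint - baseline) with 95\% CI from the
#' paired t distribution; `p_adj = min(1, m p)` with m the number of
#' comparisons.
#'
#' @param panel complete-case matrix with timepoint columns.
#' @param baseline baseline column label.
#' @param comparisons character vector of timepoints to compare against
#'   baseline (default: all non-baseline columns).
#' @return list of `vs_stat`, named by comparison.
#' @export
pairwise_bonferroni <- function(panel, baseline = "pre",
                                comparisons = setdiff(colnames(panel),
                                                      baseline)) {
  stop_if_not(length(comparisons) > 0, "empty comparison set")
  m <- length(comparisons)
  out <- lapply(comparisons, function(tp) {
    d <- panel[, tp] - panel[, baseline]
    tt <- t.test(d)
    st <- vs_stat(estimate = unname(tt$estimate), ci = as.numeric(tt$conf.int),
                  statistic = unname(tt$statistic),
                  df = unname(tt$parameter), p = tt$p.value,
                  p_adj = min(1, m * tt$p.value),
                  method = sprintf("paired t (%s vs %s), Bonferroni m=%d",
                                   tp, baseline, m))
    st
  })
  names(out) <- comparisons
  out
}

#' Mixed-effects timepoint model
#'
#' Repeated-measures mixed-effects model for longitudinal values with
#' missing visits: random intercept per subject, timepoint as a fixed
#' factor, REML fit, Satterthwaite degrees of freedom; reports per-timepoint
#' marginal means and Bonferroni-adjusted baseline contrasts.
#'
#' @param long data.frame with columns `value`, `subject`, `timepoint`.
#' @param baseline reference timepoint label.
#' @return list with `emmeans` (data.frame of marginal means),
#'   `contrasts` (data.frame: timepoint, estimate, ci_low, ci_high, df, p,
#'   p_adj), `fit` (the lmer model), `anova_p` (omnibus timepoint p).
#' @export
mixed_model_timepoint <- function(long, baseline = "pre") {
  stop_if_not(all(c("value", "subject", "timepoint") %in% names(long)),
              "long table needs value, subject, timepoint columns")
  long <- long[!is.na(long$value), ]
  tps <- unique(long$timepoint)
  stop_if_not(length(tps) >= 2, "need >= 2 observed timepoints")
  for (tp in tps)
    stop_if_not(length(unique(long$subject[long$timepoint == tp])) >= 2,
                sprintf("timepoint '%s' observed in < 2 subjects", tp))
  lv <- c(baseline, setdiff(unique(as.character(long$timepoint)), baseline))
  long$timepoint <- factor(long$timepoint, levels = lv)
  long$subject <- factor(long$subject)
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(value ~ timepoint + (1 | subject), data = long,
                   REML = TRUE)))
  an <- suppressWarnings(stats::anova(fit))
  emm <- suppressMessages(emmeans::emmeans(fit, "timepoint",
                                           lmer.df = "satterthwaite"))
  ctr <- suppressMessages(emmeans::contrast(
    emm, "trt.vs.ctrl", ref = baseline, adjust = "bonferroni"))
  ctr_raw <- suppressMessages(emmeans::contrast(
    emm, "trt.vs.ctrl", ref = baseline, adjust = "none"))
  cs <- as.data.frame(summary(ctr_raw, infer = c(TRUE, TRUE)))
  cs_adj <- as.data.frame(summary(ctr))
  lcl <- cs[[grep("LCL|lower", names(cs), value = TRUE)[1]]]
  ucl <- cs[[grep("UCL|upper", names(cs), value = TRUE)[1]]]
  contrasts <- data.frame(
    timepoint = sub(" - .*$", "", cs$contrast),
    estimate = cs$estimate,
    ci_low = lcl, ci_high = ucl,
    df = if (!is.null(cs$df)) cs$df else NA_real_,
    p = cs$p.value,
    p_adj = pmin(1, cs_adj$p.value),
    stringsAsFactors = FALSE)
  list(emmeans = as.data.frame(emm), contrasts = contrasts, fit = fit,
       anova_p = an[["Pr(>F)"]][1],
       method = "mixed-effects (random intercept, REML, Satterthwaite df), Bonferroni")
}

#' Global test-retest coefficient of variation
#'
#' Per subject i, `CoV_i = sigma_i / mu_i` over that subject's repeated
#' measurements; the global CoV for N subjects is
#' `sqrt(sum((sigma/mu)^2) / N)`, reported as a percentage.
#'
#' @param measurements list of per-subject numeric vectors (>= 2 values
#'   each), or a subjects x visits matrix (NAs allowed, >= 2 values per
#'   row).
#' @return global CoV, percent.
#' @export
cov_global <- function(measurements) {
  if (is.matrix(measurements))
    measurements <- split(measurements, row(measurements)) |>
      lapply(function(v) v[!is.na(v)])
  ratios <- vapply(measurements, function(v) {
    stop_if_not(length(v) >= 2, "need >= 2 visits per subject")
    mu <- mean(v)
    stop_if_not(abs(mu) > 0, "subject mean is zero")
    sd(v) / mu
  }, numeric(1))
  100 * sqrt(mean(ratios^2))
}

#' Average-measures intraclass correlation, absolute agreement
#'
#' ICC(A,k) from the two-way (subjects x visits) ANOVA mean squares:
#' `(MS_R - MS_E) / (MS_R + (MS_C - MS_E) / n)` with n subjects.
#'
#' @param mat complete subjects x visits matrix (>= 2 each).
#' @return ICC value.
#' @export
icc_a_k <- function(mat) {
  mat <- as.matrix(mat)
  stop_if_not(nrow(mat) >= 2 && ncol(mat) >= 2,
              "need >= 2 subjects and >= 2 visits")
  stop_if_not(!anyNA(mat), "matrix must be complete")
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  if (sum((mat - grand)^2) < 1e-24)
    stop("degenerate: zero total variance", call. = FALSE)
  rowm <- rowMeans(mat); colm <- colMeans(mat)
  ms_r <- k * sum((rowm - grand)^2) / (n - 1)
  ms_c <- n * sum((colm - grand)^2) / (k - 1)
  ss_e <- sum((mat - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) +
                 grand)^2)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  (ms_r - ms_e) / (ms_r + (ms_c - ms_e) / n)
}

#' Spearman rank correlation between two voxelwise maps
#'
#' Average ranks for ties; two-sided p from the t approximation
#' `t = rho sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param a,b equal-length numeric vectors (length >= 3).
#' @return a `vs_stat` with rho as the estimate.
#' @export
spearman_maps <- function(a, b) {
  stop_if_not(length(a) == length(b), "vectors must have equal length")
  n <- length(a)
  stop_if_not(n >= 3, "need length >= 3")
  if (sd(a) == 0 || sd(b) == 0) {
    warning("constant vector: Spearman rho undefined", call. = FALSE)
    return(vs_stat(method = "Spearman rho (undefined: constant input)"))
  }
  ra <- rank(a); rb <- rank(b)
  rho <- stats::cor(ra, rb)
  if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tt), n - 2)
  }
  vs_stat(estimate = rho, statistic = rho * sqrt((n - 2) / max(1 - rho^2, 1e-300)),
          df = n - 2, p = p, method = "Spearman rho (t approximation)")
}
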