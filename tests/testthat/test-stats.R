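test_that("voxel deltas are elementwise and guard missing visits", {
  pan <- cbind(pre = c(1, 2, 3), `2wk` = c(1, 2, 3), `6mo` = c(3, 4, 5))
  expect_equal(voxel_delta(pan, "2wk", "pre"), c(0, 0, 0))
  expect_equal(voxel_delta(pan, "6mo", "pre"), c(2, 2, 2))
  # column + constant
  pan2 <- cbind(pre = rnorm(5), `6mo` = 0)
  pan2[, "6mo"] <- pan2[, "pre"] + 7
  expect_equal(voxel_delta(pan2, "6mo", "pre"), rep(7, 5))
  # subject-2 pattern: no pre acquired; error directs to alternate baseline
  pan3 <- cbind(`2wk` = 1:3, `6mo` = 4:6)
  expect_error(voxel_delta(pan3, "6mo", "pre", subject = 2),
               "missing visit.*subject 2.*earliest available")
  expect_equal(panel_baseline(pan3), "2wk")
})

test_that("compartment classification tallies sign pairs exhaustively", {
  cc <- classify_compartments(c(1, 1, -1, 1), c(2, -1, 3, 0))
  expect_equal(cc$n_up_up, 1)
  expect_equal(cc$n_up_down, 1)
  expect_equal(cc$n_up_zero, 1)
  expect_equal(cc$n_down, 1)
  expect_equal(cc$pct_extracellular, 25)
  expect_equal(cc$pct_intracellular, 25)

  cc2 <- classify_compartments(rep(1, 10), rep(1, 10))
  expect_equal(cc2$pct_extracellular, 100)

  # brute-force tally oracle on random sign vectors
  set.seed(99)
  a <- sample(c(-1, 0, 1), 1e4, replace = TRUE)
  b <- sample(c(-1, 0, 1), 1e4, replace = TRUE)
  cc3 <- classify_compartments(a, b)
  tab <- table(a, b)
  expect_equal(cc3$n_up_up, sum(a == 1 & b == 1))
  expect_equal(cc3$n_up_down, sum(a == 1 & b == -1))
  expect_equal(cc3$n_up_zero, sum(a == 1 & b == 0))
  expect_equal(cc3$n_down, sum(a == -1))
  expect_equal(cc3$n_zero, sum(a == 0))
  expect_equal(cc3$n_up_up + cc3$n_up_down + cc3$n_up_zero + cc3$n_down +
                 cc3$n_zero, 1e4)
  expect_error(classify_compartments(1:3, 1:2), "equal length")
})

test_that("the one-sample proportion z-test follows its formula", {
  r <- proportion_test(50, 100, 0.5)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  # hand evaluation: z = (431/809 - 0.5) / sqrt(0.25 / 809)
  r2 <- proportion_test(431, 809, 0.5)
  expect_equal(r2$statistic, 1.863381, tolerance = 1e-6)
  expect_equal(r2$p, 0.062409, tolerance = 1e-5)
  # k = n gives z = sqrt(n)
  r3 <- proportion_test(81, 81, 0.5)
  expect_equal(r3$statistic, 9)
  expect_error(proportion_test(1, 0), "n")
})

test_that("GG rm-ANOVA reduces to the paired t-test at k = 2", {
  set.seed(5)
  x <- matrix(rnorm(20), 10, 2)
  r <- rm_anova_gg(x)
  tt <- t.test(x[, 1], x[, 2], paired = TRUE)
  expect_equal(r$epsilon, 1)
  expect_equal(r$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(r$p, tt$p.value, tolerance = 1e-10)
})

test_that("GG rm-ANOVA matches sums-of-squares and eigenvalue oracles", {
  x <- matrix(c(3, 5, 7, 4, 6,
                4, 7, 9, 5, 6,
                6, 8, 12, 8, 9), 5, 3)
  r <- rm_anova_gg(x)

  # independent F oracle: aov with a subject error stratum
  df <- data.frame(y = as.vector(x),
                   row = factor(rep(1:5, 3)),
                   col = factor(rep(1:3, each = 5)))
  a <- summary(stats::aov(y ~ col + Error(row), data = df))
  ftab <- a[["Error: Within"]][[1]]
  expect_equal(r$statistic, ftab["col", "F value"], tolerance = 1e-10)

  # epsilon oracle via eigenvalues of the double-centred covariance
  S <- cov(x)
  C <- diag(3) - 1 / 3
  ev <- eigen(C %*% S %*% C, symmetric = TRUE)$values
  eps_o <- sum(ev)^2 / (2 * sum(ev^2))
  expect_equal(r$epsilon, min(max(eps_o, 0.5), 1), tolerance = 1e-12)
  expect_equal(r$p, pf(r$statistic, r$epsilon * 2, r$epsilon * 8,
                       lower.tail = FALSE), tolerance = 1e-12)

  # epsilon bounds over random panels
  set.seed(12)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    rr <- rm_anova_gg(matrix(rnorm(20 * k), 20, k))
    expect_gte(rr$epsilon, 1 / (k - 1))
    expect_lte(rr$epsilon, 1)
    expect_gte(rr$p, 0); expect_lte(rr$p, 1)
  }

  expect_error(rm_anova_gg(matrix(1:4, 2, 2)), "3 rows")
  xm <- x; xm[1, 1] <- NA
  expect_error(rm_anova_gg(xm), "mixed_model")
})

test_that("Bonferroni pairwise comparisons adjust and detect shifts", {
  set.seed(77)
  pan <- cbind(pre = rnorm(50), `2wk` = rnorm(50), `8wk` = rnorm(50),
               `6mo` = rnorm(50))
  single <- pairwise_bonferroni(pan, "pre", "6mo")
  expect_equal(single$`6mo`$p_adj, single$`6mo`$p)
  all3 <- pairwise_bonferroni(pan, "pre")
  for (s in all3) {
    expect_equal(s$p_adj, min(1, 3 * s$p))
    expect_gte(s$p_adj, s$p)
    expect_lte(s$p_adj, 1)
  }
  expect_error(pairwise_bonferroni(pan, "pre", character(0)), "empty")

  # injected +10 shift at one timepoint is detected with a CI covering 10
  base <- rnorm(500)
  pan2 <- cbind(pre = base, `2wk` = base + rnorm(500),
                `6mo` = base + 10 + rnorm(500))
  res <- pairwise_bonferroni(pan2, "pre")
  expect_lt(res$`6mo`$p_adj, 0.001)
  expect_gt(10, res$`6mo`$ci_low)
  expect_lt(10, res$`6mo`$ci_high + 1)  # estimate within CI width of 10
  expect_lt(abs(res$`6mo`$estimate - 10), 0.2)
})

test_that("the mixed-effects timepoint model handles balance and missingness", {
  set.seed(3)
  # balanced complete data: contrasts equal paired mean differences
  n <- 8
  subj <- rep(1:n, 3)
  tp <- rep(c("pre", "2wk", "6mo"), each = n)
  base <- rnorm(n, 10)
  val <- base[subj] + ifelse(tp == "2wk", 0.5, ifelse(tp == "6mo", 1.2, 0)) +
    rnorm(24, 0, 0.1)
  long <- data.frame(value = val, subject = subj, timepoint = tp)
  mm <- mixed_model_timepoint(long, baseline = "pre")
  wide <- matrix(val, n)
  paired <- colMeans(wide[, 2:3] - wide[, 1])
  est <- mm$contrasts$estimate[match(c("2wk", "6mo"),
                                     mm$contrasts$timepoint)]
  expect_equal(est, unname(paired), tolerance = 1e-8)

  # cohort volume table with its two missing cells: no significant change
  vt <- vs_volume_table()
  vl <- data.frame(
    value = c(vt$vol_pre, vt$vol_2wk, vt$vol_8wk, vt$vol_6mo),
    subject = rep(vt$subject, 4),
    timepoint = rep(c("pre", "2wk", "8wk", "6mo"), each = 5))
  mmv <- mixed_model_timepoint(vl, baseline = "pre")
  expect_true(all(mmv$contrasts$p_adj > 0.05))

  expect_error(mixed_model_timepoint(
    data.frame(value = 1:3, subject = 1:3, timepoint = "pre")), "timepoints")
})

test_that("mixed-model effect recovery is calibrated over replicates", {
  set.seed(19)
  n_sub <- 20; eff <- 0.5
  cover <- logical(100)
  for (r in 1:100) {
    subj <- rep(1:n_sub, 2)
    tp <- rep(c("pre", "post"), each = n_sub)
    u <- rnorm(n_sub, 0, 1)
    val <- u[subj] + ifelse(tp == "post", eff, 0) + rnorm(2 * n_sub, 0, 0.1)
    mm <- mixed_model_timepoint(
      data.frame(value = val, subject = subj, timepoint = tp),
      baseline = "pre")
    ci <- mm$contrasts[1, c("ci_low", "ci_high")]
    cover[r] <- ci$ci_low <= eff && eff <= ci$ci_high
  }
  expect_gte(mean(cover), 0.90)
})

test_that("global CoV matches the hand-computed two-subject case", {
  # identical repeats give 0%
  expect_equal(cov_global(list(c(5, 5, 5), c(9, 9))), 0)
  # subjects with (mu, sigma) = (10, 1) and (20, 2): sqrt((0.01+0.01)/2) = 10%
  s1 <- c(9, 10, 11)           # mean 10, sd 1
  expect_equal(mean(s1), 10); expect_equal(sd(s1), 1)
  s2 <- c(18, 20, 22)          # mean 20, sd 2
  expect_equal(cov_global(list(s1, s2)), 10)
  # single subject reduces to sigma / mu
  expect_equal(cov_global(list(s1)), 100 * sd(s1) / mean(s1))
  expect_error(cov_global(list(c(-1, 1))), "zero")
  expect_error(cov_global(list(c(1))), "visits")
})

test_that("ICC(A,k) matches a two-way ANOVA oracle", {
  m <- matrix(c(2, 4, 6, 8), 4, 3)   # identical columns
  expect_equal(icc_a_k(m), 1)

  m2 <- matrix(c(9, 6, 8, 7,
                 8, 5, 9, 6,
                 7, 4, 7, 5), 4, 3)
  got <- icc_a_k(m2)
  # oracle mean squares from aov
  df <- data.frame(y = as.vector(m2), row = factor(rep(1:4, 3)),
                   col = factor(rep(1:3, each = 4)))
  an <- anova(stats::lm(y ~ row + col, data = df))
  msr <- an["row", "Mean Sq"]; msc <- an["col", "Mean Sq"]
  mse <- an["Residuals", "Mean Sq"]
  expect_equal(got, (msr - mse) / (msr + (msc - mse) / 4), tolerance = 1e-12)

  # uncorrelated noisy visits: poor agreement
  set.seed(4)
  rowvals <- rnorm(10)
  noisy <- cbind(rowvals + rnorm(10, 0, 5), rowvals + rnorm(10, 0, 5),
                 rowvals + rnorm(10, 0, 5))
  expect_lt(icc_a_k(noisy), 0.2)

  expect_error(icc_a_k(matrix(1, 3, 3)), "degenerate")
  expect_error(icc_a_k(matrix(1:2, 1, 2)), "subjects")
})

test_that("Spearman correlation is rank-based with a t-approximation p", {
  set.seed(6)
  a <- rnorm(30)
  expect_equal(spearman_maps(a, a)$estimate, 1)
  expect_equal(spearman_maps(a, -a)$estimate, -1)
  expect_equal(spearman_maps(a, exp(a))$estimate, 1)   # monotone invariance
  r <- spearman_maps(a, a + rnorm(30))
  expect_equal(r$estimate, cor(a, a + 0, method = "spearman"),
               tolerance = 1)      # bounded sanity
  ref <- suppressWarnings(cor.test(a, b <- a + rnorm(30, 0, 2),
                                   method = "spearman", exact = FALSE))
  got <- spearman_maps(a, b)
  expect_equal(got$estimate, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-6)
  expect_warning(spearman_maps(a, rep(1, 30)), "constant")
})
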