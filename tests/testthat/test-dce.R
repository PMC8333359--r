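make_vfa <- function(r1, m0, angles = c(2, 6, 12, 16), tr = 0.005,
                     dims = c(2, 2, 1), noise_sd = 0, seed = 1) {
  set.seed(seed)
  vols <- lapply(angles, function(a) {
    s <- array(vsqmri:::spgr_signal(m0, r1, tr, a), dims)
    if (noise_sd > 0) s <- s + array(rnorm(prod(dims), 0, noise_sd), dims)
    s
  })
  list(volumes = vols, angles = angles, tr = tr)
}

test_that("VFA R1 mapping inverts the SPGR equation", {
  vfa <- make_vfa(1.0, 1000)
  fit <- fit_r1_vfa(vfa)
  expect_equal(as.vector(fit$r1), rep(1, 4), tolerance = 1e-9)
  expect_equal(as.vector(fit$m0), rep(1000, 4), tolerance = 1e-6)

  expect_error(fit_r1_vfa(make_vfa(1, 1000, angles = c(10, 10))),
               "degenerate")
  expect_error(fit_r1_vfa(list(volumes = list(array(1, c(1, 1, 1))),
                               angles = 10, tr = 0)), "TR")
})

test_that("noisy R1 recovery is accurate and matches a grid-search oracle", {
  set.seed(8)
  n <- 1000
  r1_true <- 1.0; m0_true <- 1000
  angles <- c(2, 6, 12, 16); tr <- 0.005
  sig_true <- vsqmri:::spgr_signal(m0_true, r1_true, tr, angles)
  snr50_sd <- max(sig_true) / 50
  S <- matrix(rep(sig_true, each = n), n) +
    matrix(rnorm(n * 4, 0, snr50_sd), n)
  vfa <- list(volumes = lapply(1:4, function(j) array(S[, j], c(n, 1, 1))),
              angles = angles, tr = tr)
  fit <- fit_r1_vfa(vfa)
  r1 <- fit$r1[seq_len(n)]
  expect_lt(abs(median(r1, na.rm = TRUE) - r1_true) / r1_true, 0.02)

  # dense grid-search oracle (best M0 solved in closed form per candidate)
  grid <- seq(0.5, 2, by = 0.0005)
  for (i in 1:10) {
    sse <- vapply(grid, function(cand) {
      f <- vsqmri:::spgr_signal(1, cand, tr, angles)
      m0 <- sum(S[i, ] * f) / sum(f^2)
      sum((m0 * f - S[i, ])^2)
    }, numeric(1))
    expect_lt(abs(r1[i] - grid[which.min(sse)]), 0.003)
  }
})

test_that("signal-to-concentration conversion inverts the forward model", {
  t <- (0:99) * 1.3
  cp <- population_vif(t, t0 = 10)
  ct <- etm_forward(c(ktrans = 0.1, ve = 0.2, vp = 0.05),
                    list(cp = cp, time = t), t)
  r1n <- 0.7; r1 <- 3.5; tr <- 0.005; flip <- 16
  sig <- vsqmri:::spgr_signal(1000, r1n + r1 * ct, tr, flip)
  res <- concentration_from_signal(matrix(sig, 1), t, 5, r1n, r1, tr, flip)
  expect_lt(max(abs(res$conc - ct)), 1e-6)
  expect_equal(res$qc, 0L)

  # flat signal gives zero concentration
  flat <- concentration_from_signal(matrix(100, 1, 50), (0:49) * 1.3, 5,
                                    0.7, r1, tr, flip)
  expect_equal(max(abs(flat$conc)), 0)

  # doubling relaxivity halves the recovered concentration
  res2 <- concentration_from_signal(matrix(sig, 1), t, 5, r1n, 2 * r1, tr,
                                    flip)
  expect_equal(res2$conc, res$conc / 2, tolerance = 1e-10)

  # a frame above the SPGR ceiling is flagged and interpolated
  sig_bad <- sig
  sig_bad[50] <- 1000 * sin(flip * pi / 180) * 1.01
  resb <- concentration_from_signal(matrix(sig_bad, 1), t, 5, r1n, r1, tr,
                                    flip)
  expect_equal(resb$qc, 1L)
  expect_true(all(is.finite(resb$conc)))
  expect_error(concentration_from_signal(matrix(sig, 1), t, 2, r1n, r1, tr,
                                         flip), "baseline")
})

test_that("VIF extraction converts blood to plasma and rescales dose", {
  t <- (0:299) * 1.3
  cp_true <- population_vif(t, t0 = 10)
  hct <- 0.42
  # simulated SSS blood curves at 30% dose
  cb <- 0.3 * (1 - hct) * cp_true
  conc <- matrix(rep(cb, each = 5), 5)
  vif <- extract_vif(conc, t, hematocrit = hct, dose_fraction = 0.3)
  expect_lt(abs(max(vif$cp) - max(cp_true)) / max(cp_true), 0.02)

  vif0 <- extract_vif(matrix(cb, 1), t, hematocrit = 0, dose_fraction = 1)
  expect_equal(vif0$cp, cb)

  expect_error(extract_vif(conc[0, , drop = FALSE], t), "empty")
  expect_warning(extract_vif(matrix(0, 2, 300), t), "flat|bolus")
})

test_that("temporal-spatial fusion preserves LDHT shape at FDHS amplitude", {
  tL <- (0:299) * 1.3
  tF <- (0:59) * 10.1 - 30          # bolus-aligned FDHS clock
  cp <- population_vif(tL, t0 = 10)
  curve <- etm_forward(c(ktrans = 0.1, ve = 0.25, vp = 0.04),
                       list(cp = cp, time = tL), tL)

  # consistent FDHS curve: boxcar average of the LDHT curve per FDHS frame
  boxcar <- function(cl, tj, dt = 10.1)
    mean(cl[tL >= tj - dt / 2 & tL <= tj + dt / 2])
  cF <- vapply(tF, function(tj) boxcar(curve, tj), numeric(1))
  cF[tF < min(tL) - 5] <- 0
  cF[is.na(cF)] <- 0

  ld <- list(conc = matrix(curve, 1), time = tL, dims = c(1, 1, 1))
  fd <- list(conc = matrix(cF, 1), time = tF, dims = c(1, 1, 1))
  fused <- legatos_fuse(ld, fd)
  expect_equal(fused$scale[1], 1, tolerance = 1e-12)
  expect_equal(fused$conc[1, ], curve, tolerance = 1e-12)

  # FDHS amplitude doubled: output is exactly twice the LDHT curve
  fd2 <- fd; fd2$conc <- 2 * fd$conc
  fused2 <- legatos_fuse(ld, fd2)
  expect_equal(fused2$conc[1, ], 2 * curve, tolerance = 1e-12)

  # zero-energy parent curve falls back to the FDHS curve with a flag
  ld0 <- ld; ld0$conc[] <- 0
  fused0 <- legatos_fuse(ld0, fd)
  expect_true(fused0$fallback[1])
  expect_error(legatos_fuse(ld, list(conc = matrix(0, 1, 3),
                                     time = c(1000, 1010, 1020),
                                     dims = c(1, 1, 1))), "overlap")
})

test_that("fusion supports quantification of a heterogeneous tumour", {
  # 2x2x2 coarse grid, 4x4x4 fine grid with heterogeneous amplitudes
  set.seed(31)
  tL <- (0:299) * 1.3
  tF <- (0:59) * 10.1 - 30
  cp <- population_vif(tL, t0 = 10)
  vif <- structure(list(cp = cp, time = tL, hematocrit = 0.42,
                        dose_fraction = 1), class = "vs_vif")
  # spatially correlated heterogeneity: block-level kinetics with a small
  # within-block modulation, as in a real tumour where neighbouring voxels
  # share perfusion characteristics
  nf <- 64
  coords <- as.matrix(expand.grid(1:4, 1:4, 1:4))
  parent <- vsqmri:::parent_coarse_index(coords, c(4, 4, 4), 2L)
  kt_b <- runif(8, 0.05, 0.2); ve_b <- runif(8, 0.15, 0.4)
  vp_b <- runif(8, 0.01, 0.08)
  jit <- function(n) exp(rnorm(n, 0, 0.05))
  kt <- kt_b[parent] * jit(nf); ve <- ve_b[parent] * jit(nf)
  vp <- vp_b[parent] * jit(nf)
  fine <- t(vapply(seq_len(nf), function(i)
    etm_forward(c(ktrans = kt[i], ve = ve[i], vp = vp[i]), vif, tL),
    numeric(length(tL))))
  coarse <- vsqmri:::block_average_curves(fine, c(4, 4, 4), 2L)
  resample <- function(cl) vapply(tF, function(tj) {
    sel <- tL >= tj - 10.1 / 2 & tL <= tj + 10.1 / 2
    if (!any(sel)) 0 else mean(cl[sel])
  }, numeric(1))
  fdhs <- t(apply(fine, 1, resample))
  fused <- legatos_fuse(list(conc = coarse, time = tL, dims = c(2, 2, 2)),
                        list(conc = fdhs, time = tF, dims = c(4, 4, 4)))
  fit_fused <- fit_etm(fused$conc, vif, tL)
  fit_true <- fit_etm(fine, vif, tL)
  rel <- abs(fit_fused$ktrans - fit_true$ktrans) / fit_true$ktrans
  expect_lt(median(rel), 0.05)
})

test_that("the extended Tofts forward model matches analytic limits", {
  t <- (0:199) * 1.3
  cp <- population_vif(t, t0 = 10)
  vif <- list(cp = cp, time = t)
  expect_equal(etm_forward(c(ktrans = 0, ve = 0, vp = 0), vif, t),
               rep(0, length(t)))
  expect_equal(etm_forward(c(ktrans = 0, ve = 0.2, vp = 1), vif, t), cp)
  expect_error(etm_forward(c(ktrans = 0.1, ve = 0, vp = 0), vif, t), "ve")

  # boxcar input: closed-form exponential convolution
  tb <- seq(0, 300, by = 0.25)
  c0 <- 2
  t1 <- 50; t2 <- 100
  cpb <- ifelse(tb >= t1 & tb <= t2, c0, 0)
  kt <- 0.1; vev <- 0.2; vpv <- 0.05
  kep <- kt / vev
  tmin <- tb / 60
  analytic <- vpv * cpb + kt * c0 / kep * ifelse(
    tb < t1, 0, ifelse(
      tb <= t2, 1 - exp(-kep * (tmin - t1 / 60)),
      exp(-kep * (tmin - t2 / 60)) - exp(-kep * (tmin - t1 / 60))))
  got <- etm_forward(c(ktrans = kt, ve = vev, vp = vpv),
                     list(cp = cpb, time = tb), tb)
  expect_lt(max(abs(got - analytic)) / max(analytic), 0.005)
})

test_that("ETM fitting recovers parameters and respects bounds", {
  t <- (0:59) * 10.1
  cp <- population_vif(t, t0 = 40)
  vif <- structure(list(cp = cp, time = t, hematocrit = 0.42,
                        dose_fraction = 1), class = "vs_vif")
  cases <- rbind(c(0.1, 0.2, 0.05), c(0.05, 0.3, 0.02), c(0.3, 0.5, 0.08))
  for (i in seq_len(nrow(cases))) {
    ct <- etm_forward(c(ktrans = cases[i, 1], ve = cases[i, 2],
                        vp = cases[i, 3]), vif, t)
    fit <- fit_etm(ct, vif, t)
    expect_lt(abs(fit$ktrans - cases[i, 1]) / cases[i, 1], 0.01)
    expect_lt(abs(fit$ve - cases[i, 2]) / cases[i, 2], 0.01)
    expect_lt(abs(fit$vp - cases[i, 3]) / cases[i, 3], 0.01)
    expect_true(fit$converged)
    expect_gte(fit$rmse, 0)
  }

  # flat zero curve: all-zero parameters, converged
  fit0 <- fit_etm(rep(0, length(t)), vif, t)
  expect_equal(unlist(fit0[1, 1:3]), c(ktrans = 0, ve = 0, vp = 0))
  expect_true(fit0$converged)

  # dose linearity: doubling VIF and tissue curves leaves estimates fixed
  ct <- etm_forward(c(ktrans = 0.1, ve = 0.2, vp = 0.05), vif, t)
  vif2 <- vif; vif2$cp <- 2 * cp
  fit2 <- fit_etm(2 * ct, vif2, t)
  expect_equal(unlist(fit2[1, 1:3]),
               c(ktrans = 0.1, ve = 0.2, vp = 0.05), tolerance = 1e-4)

  expect_error(fit_etm(matrix(1, 1, 10), vif, t[1:10]), "20 frames")
  expect_error(fit_etm(ct, list(cp = rep(1, 60), time = t), t), "flat")
})
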