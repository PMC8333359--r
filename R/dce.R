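#' Fit native R1 from a variable flip angle series
#'
#' Linearised SPGR solve (S/sin(a) regressed on S/tan(a), whose slope is
#' `exp(-TR * R1)`), optionally refined per voxel by nonlinear least
#' squares on the SPGR equation. Voxels with a non-physical linear slope
#' (<= 0 or >= 1) are flagged and returned as missing.
#'
#' @param vfa list with `volumes` (list of 3-D arrays, one per angle),
#'   `angles` (degrees), `tr` (s), as produced by [simulate_vfa()].
#' @param mask logical 3-D mask of voxels to fit (default: finite,
#'   positive signal at all angles).
#' @param refine run nonlinear refinement (default TRUE).
#' @return list with `r1` and `m0` (3-D arrays, NA outside mask/failed
#'   voxels) and `qc` (count of non-physical voxels).
#' @export
fit_r1_vfa <- function(vfa, mask = NULL, refine = TRUE) {
  ang <- vfa$angles
  tr <- vfa$tr
  stop_if_not(tr > 0, "TR must be positive")
  stop_if_not(length(unique(ang)) >= 2,
              "degenerate design: need at least two distinct flip angles")
  a <- ang * pi / 180
  dims <- dim(vfa$volumes[[1]])
  S <- vapply(vfa$volumes, as.vector, numeric(prod(dims)))
  if (is.null(mask)) mask <- array(apply(S > 0, 1, all), dims)
  vox <- which(mask)
  Sv <- S[vox, , drop = FALSE]

  X <- sweep(Sv, 2, tan(a), "/")
  Y <- sweep(Sv, 2, sin(a), "/")
  mx <- rowMeans(X); my <- rowMeans(Y)
  sxy <- rowSums((X - mx) * (Y - my))
  sxx <- rowSums((X - mx)^2)
  slope <- sxy / sxx
  ok <- is.finite(slope) & slope > 0 & slope < 1
  r1v <- rep(NA_real_, length(vox))
  m0v <- rep(NA_real_, length(vox))
  r1v[ok] <- -log(slope[ok]) / tr
  m0v[ok] <- (my[ok] - slope[ok] * mx[ok]) / (1 - slope[ok])
  ok[ok] <- is.finite(r1v[ok]) & r1v[ok] > 0

  if (refine) {
    for (i in which(ok)) {
      fit <- try(minpack.lm::nls.lm(
        par = c(r1 = r1v[i], m0 = m0v[i]),
        fn = function(p) spgr_signal(p[["m0"]], p[["r1"]], tr, ang) - Sv[i, ],
        lower = c(1e-6, 0),
        control = minpack.lm::nls.lm.control(maxiter = 50)), silent = TRUE)
      if (!inherits(fit, "try-error") && fit$par[["r1"]] > 0) {
        r1v[i] <- fit$par[["r1"]]
        m0v[i] <- fit$par[["m0"]]
      }
    }
  }
  r1 <- array(NA_real_, dims); m0 <- array(NA_real_, dims)
  r1[vox] <- r1v; m0[vox] <- m0v
  list(r1 = r1, m0 = m0, qc = sum(!ok))
}

#' Convert dynamic SPGR signal to gadolinium concentration
#'
#' Fixes M0 per voxel from the pre-bolus baseline frames and the known
#' native R1, inverts the SPGR equation frame by frame for R1(t), and maps
#' `C(t) = (R1(t) - R1N) / r1`. Frames whose signal exceeds the SPGR
#' ceiling cannot be inverted; they are flagged, filled by linear
#' interpolation/extrapolation in time, and counted in the QC summary.
#'
#' @param signal nvox x nt matrix (or 4-D array) of dynamic signal.
#' @param time frame times, s.
#' @param baseline_frames number of pre-bolus frames (>= 3) used for M0.
#' @param r1n native R1 per voxel (vector or 3-D array), 1/s.
#' @param relaxivity contrast relaxivity, 1/s/mM.
#' @param tr repetition time, s.
#' @param flip flip angle, degrees.
#' @return list with `conc` (nvox x nt matrix, mM), `time`, and `qc`
#'   (count of flagged frame-values).
#' @export
concentration_from_signal <- function(signal, time, baseline_frames,
                                      r1n, relaxivity, tr, flip) {
  stop_if_not(baseline_frames >= 3,
              "need at least 3 pre-bolus baseline frames")
  if (length(dim(signal)) == 4)
    signal <- matrix(signal, prod(dim(signal)[1:3]), dim(signal)[4])
  r1n <- as.vector(r1n)
  stop_if_not(length(r1n) == nrow(signal),
              "r1n must supply one value per voxel")
  s0 <- rowMeans(signal[, seq_len(baseline_frames), drop = FALSE])
  unit <- spgr_signal(1, r1n, tr, flip)
  m0 <- s0 / unit
  nflag <- 0L
  nt <- ncol(signal)
  r1t <- matrix(NA_real_, nrow(signal), nt)
  for (j in seq_len(nt)) {
    r1t[, j] <- spgr_invert_r1(signal[, j], m0, tr, flip)
  }
  bad <- !is.finite(r1t)
  nflag <- sum(bad)
  if (nflag > 0) {
    for (i in which(rowSums(bad) > 0)) {
      good <- which(!bad[i, ])
      if (length(good) >= 2) {
        r1t[i, ] <- stats::approx(time[good], r1t[i, good], xout = time,
                                  rule = 2)$y
      } else {
        r1t[i, ] <- r1n[i]
      }
    }
  }
  conc <- (r1t - r1n) / relaxivity
  list(conc = conc, time = time, qc = nflag)
}

#' Extract a vascular input function from the superior sagittal sinus
#'
#' Averages the low-dose high-temporal concentration curves over the SSS
#' mask (whole-blood concentration), converts blood to plasma concentration
#' with `Cp = Cb / (1 - Hct)`, and rescales the low-dose curve to its
#' full-dose equivalent by `1 / dose_fraction`.
#'
#' @param conc nvox x nt matrix of SSS-restricted concentration curves
#'   (mM), or a larger matrix with `rows` selecting the SSS voxels.
#' @param time frame times, s.
#' @param hematocrit haematocrit fraction.
#' @param dose_fraction dose fraction of the acquisition the curves come
#'   from.
#' @param rows optional row indices of SSS voxels within `conc`.
#' @return an object of class `vs_vif`: `cp` (plasma concentration, mM,
#'   full-dose equivalent), `time`, `hematocrit`, `dose_fraction`.
#' @export
extract_vif <- function(conc, time, hematocrit = 0.42, dose_fraction = 1,
                        rows = NULL) {
  if (!is.null(rows)) conc <- conc[rows, , drop = FALSE]
  stop_if_not(nrow(conc) > 0, "SSS mask is empty")
  cb <- colMeans(conc)
  base_sd <- sd(cb[seq_len(min(5, length(cb)))])
  if (max(cb) < 5 * max(base_sd, 1e-12) && max(cb) < 0.1)
    warning("no bolus detected in SSS curve (flat input)", call. = FALSE)
  cp <- cb / (1 - hematocrit) / dose_fraction
  structure(list(cp = cp, time = time, hematocrit = hematocrit,
                 dose_fraction = dose_fraction), class = "vs_vif")
}

#' Fuse high-temporal and high-spatial concentration curves
#'
#' LEGATOS-style fusion: each fine-grid voxel inherits the temporally fine
#' curve of its parent coarse (block-averaged) voxel, rescaled by the
#' least-squares factor that matches its time-averaged resampling to the
#' voxel's own full-dose high-spatial (FDHS) curve over the overlapping
#' time window. The output therefore carries FDHS spatial amplitude with
#' LDHT temporal shape. Fine voxels whose parent curve has (near-)zero
#' energy fall back to the FDHS curve interpolated onto the fine time grid,
#' with a flag.
#'
#' @param ldht list with `conc` (coarse nvox x ntL matrix, mM), `time`
#'   (s), `dims` (coarse grid).
#' @param fdhs list with `conc` (fine nvox x ntF matrix), `time`, `dims`
#'   (fine grid, an integer multiple of the coarse grid).
#' @return list with `conc` (fine nvox x ntL matrix on the LDHT time
#'   grid), `time`, `scale` (per fine voxel), `fallback` (logical flags).
#' @export
legatos_fuse <- function(ldht, fdhs) {
  f <- unique(fdhs$dims %/% ldht$dims)
  stop_if_not(length(f) == 1 && all(fdhs$dims == ldht$dims * f),
              "fine grid must be an integer multiple of the coarse grid")
  tL <- ldht$time; tF <- fdhs$time
  dtF <- if (length(tF) > 1) stats::median(diff(tF)) else diff(range(tL))
  # FDHS frames whose averaging window lies inside the LDHT time range
  win_lo <- tF - dtF / 2
  win_hi <- tF + dtF / 2
  overlap <- which(win_lo >= min(tL) & win_hi <= max(tL))
  stop_if_not(length(overlap) >= 1, "time windows do not overlap")

  # boxcar time-average resampling matrix: ntL -> overlap frames
  R <- matrix(0, length(overlap), length(tL))
  for (k in seq_along(overlap)) {
    j <- overlap[k]
    sel <- tL >= win_lo[j] & tL <= win_hi[j]
    R[k, sel] <- 1 / sum(sel)
  }

  coords <- as.matrix(expand.grid(seq_len(fdhs$dims[1]),
                                  seq_len(fdhs$dims[2]),
                                  seq_len(fdhs$dims[3])))
  parent <- parent_coarse_index(coords, fdhs$dims, f)

  nf <- nrow(fdhs$conc)
  stop_if_not(nf == prod(fdhs$dims), "fdhs conc rows must fill the grid")
  out <- matrix(0, nf, length(tL))
  scale <- rep(NA_real_, nf)
  fallback <- logical(nf)
  res_parent <- ldht$conc %*% t(R)      # coarse voxel x overlap frames
  energy <- rowSums(res_parent^2)
  for (i in seq_len(nf)) {
    p <- parent[i]
    if (energy[p] < 1e-12) {
      out[i, ] <- stats::approx(tF, fdhs$conc[i, ], xout = tL, rule = 2)$y
      fallback[i] <- TRUE
      next
    }
    s <- sum(res_parent[p, ] * fdhs$conc[i, overlap]) / energy[p]
    scale[i] <- s
    out[i, ] <- s * ldht$conc[p, ]
  }
  list(conc = out, time = tL, scale = scale, fallback = fallback)
}

# trapezoidal convolution of cp with exp(-kep * (t - tau)); O(nt) recursion
exp_conv <- function(cp, tmin, kep) {
  nt <- length(tmin)
  if (kep == 0) {
    # plain cumulative trapezoid
    dt <- diff(tmin)
    return(c(0, cumsum(dt * (cp[-1] + cp[-nt]) / 2)))
  }
  dt <- diff(tmin)
  if (max(dt) - min(dt) < 1e-12 * max(dt)) {
    E <- exp(-kep * dt[1])
    u <- c(0, dt[1] / 2 * (cp[-1] + E * cp[-nt]))
    as.numeric(stats::filter(u, E, method = "recursive"))
  } else {
    I <- numeric(nt)
    for (i in 2:nt) {
      E <- exp(-kep * dt[i - 1])
      I[i] <- E * I[i - 1] + dt[i - 1] / 2 * (cp[i] + E * cp[i - 1])
    }
    I
  }
}

#' Extended Tofts model forward curve
#'
#' `C_t(t) = vp Cp(t) + Ktrans int_0^t Cp(tau) exp(-(Ktrans/ve)(t - tau))
#' dtau`, with trapezoidal convolution. The `Ktrans = 0` term is defined as
#' zero regardless of `ve`; `ve = 0` with `Ktrans > 0` is an error.
#'
#' @param params named vector or list with `ktrans` (1/min), `ve`, `vp`.
#' @param vif a [extract_vif()] object (or list with `cp`, `time`).
#' @param t output time grid, s (interpolable from the VIF grid).
#' @return tissue concentration, mM, at times `t`.
#' @export
etm_forward <- function(params, vif, t) {
  kt <- params[["ktrans"]]; vev <- params[["ve"]]; vpv <- params[["vp"]]
  stop_if_not(kt >= 0, "ktrans must be >= 0")
  if (kt > 0 && vev <= 0)
    stop("ve = 0 with ktrans > 0 is not identifiable", call. = FALSE)
  cp <- if (identical(vif$time, t)) vif$cp else
    stats::approx(vif$time, vif$cp, xout = t, rule = 2)$y
  tmin <- t / 60
  out <- vpv * cp
  if (kt > 0) out <- out + kt * exp_conv(cp, tmin, kt / vev)
  out
}

#' Fit the extended Tofts model
#'
#' Bounded nonlinear least squares per voxel with three fixed starting
#' points ((0.05, 0.2, 0.01), (0.2, 0.4, 0.05), (0.5, 0.6, 0.1) for
#' (Ktrans, ve, vp)); the lowest-RMSE solution wins, ties broken by the
#' smallest Ktrans. Bounds: Ktrans in [0, 5] /min, ve and vp in [0, 1],
#' with a soft penalty keeping `ve + vp <= 1`. Curves with (near-)zero
#' variance return (0, 0, 0) with a converged flag (ve unidentifiable at
#' zero enhancement).
#'
#' @param ct nvox x nt matrix (or vector) of tissue concentration, mM.
#' @param vif a [extract_vif()] object.
#' @param t frame times, s (>= 20 frames).
#' @return data.frame with columns `ktrans`, `ve`, `vp`, `rmse`,
#'   `converged`.
#' @export
fit_etm <- function(ct, vif, t) {
  if (is.null(dim(ct))) ct <- matrix(ct, nrow = 1)
  stop_if_not(length(t) >= 20, "need at least 20 frames")
  cp <- if (identical(vif$time, t)) vif$cp else
    stats::approx(vif$time, vif$cp, xout = t, rule = 2)$y
  stop_if_not(sd(cp) > 1e-9, "VIF is flat")
  tmin <- t / 60
  starts <- list(c(0.05, 0.2, 0.01), c(0.2, 0.4, 0.05), c(0.5, 0.6, 0.1))
  lower <- c(0, 1e-6, 0); upper <- c(5, 1, 1)
  n <- nrow(ct)
  out <- data.frame(ktrans = rep(NA_real_, n), ve = NA_real_, vp = NA_real_,
                    rmse = NA_real_, converged = FALSE)
  model <- function(p) {
    m <- p[3] * cp
    if (p[1] > 0) m <- m + p[1] * exp_conv(cp, tmin, p[1] / max(p[2], 1e-9))
    m
  }
  for (i in seq_len(n)) {
    y <- ct[i, ]
    if (sd(y) < 1e-9 && max(abs(y)) < 1e-6) {
      out[i, ] <- list(0, 0, 0, sqrt(mean(y^2)), TRUE)
      next
    }
    best <- NULL
    for (st in starts) {
      fit <- try(minpack.lm::nls.lm(
        par = st,
        fn = function(p) c(model(p) - y, 10 * max(0, p[2] + p[3] - 1)),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 100)), silent = TRUE)
      if (inherits(fit, "try-error")) next
      rmse <- sqrt(mean((model(fit$par) - y)^2))
      if (is.null(best) || rmse < best$rmse - 1e-12 ||
          (abs(rmse - best$rmse) <= 1e-12 && fit$par[1] < best$par[1])) {
        best <- list(par = fit$par, rmse = rmse,
                     converged = fit$info %in% 1:4)
      }
    }
    if (!is.null(best)) {
      tot <- best$par[2] + best$par[3]
      if (tot > 1) {
        best$par[2] <- best$par[2] / tot
        best$par[3] <- best$par[3] / tot
      }
      out[i, ] <- list(best$par[1], best$par[2], best$par[3], best$rmse,
                       best$converged)
    }
  }
  out
}
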