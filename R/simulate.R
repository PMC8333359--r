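#' Simulate a sodium image
#'
#' Produces a sodium-MRI magnitude image whose voxel signal maps back to the
#' true TSC through the two-phantom calibration line
#' `TSC = slope * signal + intercept`, i.e. `signal = (TSC - intercept) /
#' slope`, plus additive Gaussian noise. The 60 and 120 mM calibration
#' phantom ROIs emit the signal corresponding to exactly those
#' concentrations (plus noise).
#'
#' @param subject a [make_ground_truth()] subject.
#' @param cal list with `slope` (mM per signal unit, > 0) and `intercept`
#'   (mM); the scanner-side gain being simulated.
#' @param noise_sd additive Gaussian noise SD, signal units.
#' @param seed integer seed.
#' @return numeric 3-D array, signal units.
#' @export
simulate_sodium_image <- function(subject, cal = list(slope = 0.2, intercept = 0),
                                  noise_sd = 15, seed = 1) {
  stop_if_not(is.finite(cal$slope) && cal$slope > 0,
              "calibration slope must be > 0")
  sig <- (subject$tsc_true - cal$intercept) / cal$slope
  with_seed(seed, {
    if (noise_sd > 0) sig <- sig + array(rnorm(length(sig), 0, noise_sd),
                                         dim(sig))
    sig
  })
}

#' Simulate a variable flip angle (VFA) series
#'
#' One SPGR volume per flip angle, used for native R1 mapping.
#'
#' @param subject a [make_ground_truth()] subject.
#' @param preset an [acquisition_preset()] (uses `vfa_angles`, `dce_tr`,
#'   `noise_sd`).
#' @param seed integer seed.
#' @return list with `volumes` (list of 3-D arrays, one per angle),
#'   `angles`, `tr`.
#' @export
simulate_vfa <- function(subject, preset = acquisition_preset(), seed = 1) {
  stop_if_not(preset$dce_tr > 0, "TR must be positive")
  ang <- preset$vfa_angles
  stop_if_not(!anyDuplicated(ang), "flip angles must be distinct")
  with_seed(seed, {
    vols <- lapply(ang, function(a) {
      s <- spgr_signal(subject$m0_true, subject$r1n_true, preset$dce_tr, a)
      if (preset$noise_sd > 0)
        s <- s + array(rnorm(length(s), 0, preset$noise_sd), dim(s))
      s
    })
    list(volumes = vols, angles = ang, tr = preset$dce_tr)
  })
}

#' Population vascular input function
#'
#' Plasma gadolinium concentration over time for a standard bolus
#' injection: a gamma-variate first pass followed by a bi-exponential
#' washout, zero before bolus arrival, scaling linearly with the injected
#' dose fraction. This is the simulator's stand-in for a measured
#' superior-sagittal-sinus input function.
#'
#' @param t time grid, seconds (non-decreasing, starting pre-bolus).
#' @param dose_fraction fraction of the full dose (1 = full).
#' @param t0 bolus arrival time, seconds after series start.
#' @return plasma concentration, mM, same length as `t`.
#' @export
population_vif <- function(t, dose_fraction = 1, t0 = 10) {
  stop_if_not(!is.unsorted(t), "time grid must be non-decreasing")
  vif_eval(t, dose_fraction, t0)
}

# unvalidated evaluator shared with the quadrature helper
vif_eval <- function(t, dose_fraction, t0) {
  tm <- pmax(t - t0, 0) / 60            # minutes post-arrival
  bolus <- 45 * tm * exp(-tm / 0.25)
  tail <- (1 - exp(-tm / 0.20)) *
    (0.60 * exp(-0.40 * tm) + 0.45 * exp(-0.012 * tm))
  cp <- dose_fraction * (bolus + tail)
  cp[t <= t0] <- 0
  cp
}

#' Area under the population VIF
#'
#' Adaptive-quadrature integral of [population_vif()] over a time window,
#' in mM.s.
#'
#' @param from,to integration limits, seconds.
#' @inheritParams population_vif
#' @return numeric scalar.
#' @export
vif_auc <- function(from = 0, to = 300, dose_fraction = 1, t0 = 10) {
  stats::integrate(vif_eval, from, to, dose_fraction = dose_fraction,
                   t0 = t0, rel.tol = 1e-9, subdivisions = 1000L)$value
}

#' Simulate a DWI acquisition
#'
#' Monoexponential tensor signal `S(b, g) = S0 exp(-b g' D g)` from the
#' subject's true diffusion tensor, with one b = 0 volume and one volume
#' per diffusion direction at each non-zero b-value, plus additive Gaussian
#' noise.
#'
#' @param subject a [make_ground_truth()] subject.
#' @param preset an [acquisition_preset()] (uses `bvals`, `bvecs`).
#' @param noise_sd additive Gaussian noise SD, signal units (S0 is 1000 in
#'   tissue).
#' @param seed integer seed.
#' @return list with `volumes` (4-D array `[dims, nvol]`), per-volume
#'   `bvals` and 3 x nvol `bvecs`.
#' @export
simulate_dwi <- function(subject, preset = acquisition_preset(),
                         noise_sd = 20, seed = 1) {
  bv <- preset$bvecs
  stop_if_not(ncol(bv) >= 6, "need at least 6 diffusion directions")
  B <- bmatrix_rows(rep(1, ncol(bv)), bv)
  stop_if_not(qr(B)$rank == 6,
              "degenerate direction set: design rank < 6")
  dims <- subject$grid_shape
  nvox <- prod(dims)
  comps <- matrix(subject$tensor_true, nvox, 6)
  s0 <- as.vector(subject$m0_true)

  bpos <- preset$bvals[preset$bvals > 0]
  vols_b <- c(0, rep(bpos, each = ncol(bv)))
  vecs <- cbind(c(0, 0, 1), bv[, rep(seq_len(ncol(bv)), times = length(bpos))])
  nvol <- length(vols_b)
  out <- array(0, c(dims, nvol))
  for (j in seq_len(nvol)) {
    if (vols_b[j] == 0) {
      sig <- s0
    } else {
      brow <- bmatrix_rows(vols_b[j], vecs[, j, drop = FALSE])
      sig <- s0 * exp(-as.vector(comps %*% t(brow)))
    }
    out[, , , j] <- array(sig, dims)
  }
  with_seed(seed, {
    if (noise_sd > 0)
      out <- out + array(rnorm(length(out), 0, noise_sd), dim(out))
    list(volumes = out, bvals = vols_b, bvecs = vecs)
  })
}

# Rows of the diffusion design matrix: b * (gx^2, gy^2, gz^2, 2gxgy, 2gxgz,
# 2gygz) for each direction (columns of g).
bmatrix_rows <- function(b, g) {
  g <- matrix(g, nrow = 3)
  t(rbind(g[1, ]^2, g[2, ]^2, g[3, ]^2,
          2 * g[1, ] * g[2, ], 2 * g[1, ] * g[3, ], 2 * g[2, ] * g[3, ]) *
      rep(b, each = 6))
}

# Extended Tofts forward model evaluated for vectors of voxel parameters
# over a shared time grid (seconds). Cp in mM; ktrans in 1/min. Returns an
# nvox x nt concentration matrix. O(nt) recursive trapezoidal convolution
# with the exponential kernel.
etm_forward_matrix <- function(ktrans, ve, vp, cp, t) {
  nv <- length(ktrans)
  nt <- length(t)
  tmin <- t / 60
  kep <- ifelse(ktrans > 0, ktrans / ifelse(ve > 0, ve, NA_real_), 0)
  if (any(ktrans > 0 & (is.na(kep) | !is.finite(kep))))
    stop("ve = 0 with ktrans > 0 is not identifiable", call. = FALSE)
  conv <- matrix(0, nv, nt)
  if (any(ktrans > 0)) {
    I <- numeric(nv)
    for (i in 2:nt) {
      dt <- tmin[i] - tmin[i - 1]
      E <- exp(-kep * dt)
      I <- E * I + dt / 2 * (cp[i] + E * cp[i - 1])
      conv[, i] <- I
    }
  }
  out <- outer(vp, cp) + ktrans * conv
  out[ktrans == 0, ] <- outer(vp[ktrans == 0], cp)
  out
}

#' Simulate a DCE-MRI series
#'
#' Forward-models per-voxel tissue gadolinium concentration with the
#' extended Tofts model driven by `dose_fraction` times the full-dose
#' population input function, converts concentration to SPGR signal using
#' the voxel's native R1, and adds Gaussian noise. The low-dose
#' high-temporal (LDHT) variant is produced on a block-averaged coarse grid
#' (concentrations averaged within blocks before signal conversion); the
#' full-dose high-spatial (FDHS) variant stays on the fine grid.
#'
#' @param subject a [make_ground_truth()] subject.
#' @param preset an [acquisition_preset()].
#' @param dose_fraction injected dose as a fraction of the full dose,
#'   in (0, 1].
#' @param series `"ldht"` or `"fdhs"`.
#' @param seed integer seed.
#' @param bbox optional list of three index ranges (fine-grid voxel
#'   indices, each a `c(from, to)` aligned to the block factor) restricting
#'   the simulated subvolume.
#' @param t0 bolus arrival time, s after series start (default 10 s for
#'   LDHT, 40 s for FDHS so that at least three baseline frames precede
#'   the bolus at the coarser frame spacing).
#' @param keep_truth keep the noiseless concentration array alongside the
#'   signal.
#' @return an object of class `vs_dce`: `signal` (4-D array), `time` (s),
#'   `dose_fraction`, `flip`, `tr`, `grid` (voxel dims), `fine_grid`
#'   logical, `block_factor`, `bbox`, and optionally `conc_true`.
#' @export
simulate_dce <- function(subject, preset = acquisition_preset(),
                         dose_fraction = 1, series = c("fdhs", "ldht"),
                         seed = 1, bbox = NULL, keep_truth = FALSE,
                         t0 = NULL) {
  series <- match.arg(series)
  stop_if_not(dose_fraction > 0 && dose_fraction <= 1,
              "dose_fraction must be in (0, 1]")
  dt <- if (series == "ldht") preset$ldht_dt else preset$fdhs_dt
  nt <- if (series == "ldht") preset$ldht_n else preset$fdhs_n
  if (is.null(t0)) t0 <- if (series == "ldht") 10 else 40
  t <- (seq_len(nt) - 1) * dt
  cp <- population_vif(t, dose_fraction = dose_fraction, t0 = t0)

  dims <- subject$grid_shape
  if (is.null(bbox)) bbox <- lapply(dims, function(d) c(1L, d))
  ix <- seq(bbox[[1]][1], bbox[[1]][2])
  iy <- seq(bbox[[2]][1], bbox[[2]][2])
  iz <- seq(bbox[[3]][1], bbox[[3]][2])
  sub_dims <- c(length(ix), length(iy), length(iz))

  kt <- subject$ktrans_true[ix, iy, iz]
  vee <- subject$ve_true[ix, iy, iz]
  vpp <- subject$vp_true[ix, iy, iz]
  r1n <- subject$r1n_true[ix, iy, iz]
  m0 <- subject$m0_true[ix, iy, iz]

  conc <- etm_forward_matrix(as.vector(kt), as.vector(vee), as.vector(vpp),
                             cp, t)

  if (series == "ldht") {
    f <- preset$block_factor
    stop_if_not(all(sub_dims %% f == 0),
                "bbox dims must be divisible by the block factor")
    cd <- sub_dims %/% f
    conc <- block_average_curves(conc, sub_dims, f)
    r1n <- block_average(r1n, f)
    m0 <- block_average(m0, f)
    out_dims <- cd
  } else {
    out_dims <- sub_dims
  }

  r1t <- array(rep(as.vector(r1n), length(t)), c(prod(out_dims), length(t))) +
    preset$relaxivity_r1 * conc
  sig <- spgr_signal(rep(as.vector(m0), length(t)), r1t, preset$dce_tr,
                     preset$dce_flip)
  sig <- array(sig, c(out_dims, length(t)))
  with_seed(seed, {
    if (preset$noise_sd > 0)
      sig <- sig + array(rnorm(length(sig), 0, preset$noise_sd), dim(sig))
    structure(list(signal = sig, time = t,
                   dose_fraction = dose_fraction,
                   flip = preset$dce_flip, tr = preset$dce_tr,
                   relaxivity_r1 = preset$relaxivity_r1,
                   grid = out_dims, series = series,
                   block_factor = if (series == "ldht") preset$block_factor else 1L,
                   bbox = bbox,
                   conc_true = if (keep_truth) array(conc, c(out_dims, length(t)))),
              class = "vs_dce")
  })
}

# Average a 3-D array over f^3 blocks (dims divisible by f).
block_average <- function(a, f) {
  d <- dim(a)
  cd <- d %/% f
  out <- array(0, cd)
  for (dx in 0:(f - 1)) for (dy in 0:(f - 1)) for (dz in 0:(f - 1)) {
    out <- out + a[seq(1 + dx, d[1], f), seq(1 + dy, d[2], f),
                   seq(1 + dz, d[3], f)]
  }
  out / f^3
}

# Same, applied to an (nvox x nt) curve matrix laid out on a grid `dims`.
block_average_curves <- function(curves, dims, f) {
  nt <- ncol(curves)
  cd <- dims %/% f
  out <- matrix(0, prod(cd), nt)
  for (i in seq_len(nt)) {
    out[, i] <- as.vector(block_average(array(curves[, i], dims), f))
  }
  out
}

# Map fine-grid (local bbox) voxel index triples to their parent coarse
# voxel linear index for block factor f.
parent_coarse_index <- function(coords, dims, f) {
  cd <- dims %/% f
  ci <- (coords - 1L) %/% f + 1L
  (ci[, 3] - 1L) * cd[1] * cd[2] + (ci[, 2] - 1L) * cd[1] + ci[, 1]
}
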