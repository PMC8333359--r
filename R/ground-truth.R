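# Tissue parameter table for the digital phantom. TSC means follow reported
# brain/tumour values (WM 35.4, GM 39.4, ventricular CSF 113, tumour ~50 mM);
# diffusion eigenvalues, R1 and microvascular parameters are textbook 3 T
# values for each tissue class. SSS voxels behave as whole blood:
# vp = 1 - Hct, no extravasation.
default_tissue_params <- function(hematocrit = 0.42) {
  list(
    wm      = list(tsc = 35.4, tsc_sd = 2.27, ev = c(1.60, 0.35, 0.35) * 1e-3,
                   dir = c(1, 0, 0), r1 = 1.10, ktrans = 0, ve = 0, vp = 0.01),
    gm      = list(tsc = 39.4, tsc_sd = 3.11, ev = c(0.80, 0.80, 0.80) * 1e-3,
                   dir = c(1, 0, 0), r1 = 0.83, ktrans = 0, ve = 0, vp = 0.02),
    csf     = list(tsc = 113,  tsc_sd = 4.71, ev = c(3.0, 3.0, 3.0) * 1e-3,
                   dir = c(1, 0, 0), r1 = 0.25, ktrans = 0, ve = 0, vp = 0),
    tumour  = list(tsc = 50,   tsc_sd = 8,    ev = c(1.55, 1.05, 1.00) * 1e-3,
                   dir = c(0, 1, 0), r1 = 0.70,
                   ktrans = 0.10, ktrans_sd = 0.02,
                   ve = 0.25, ve_sd = 0.05, vp = 0.05, vp_sd = 0.015),
    muscle  = list(tsc = 20,   tsc_sd = 2,    ev = c(1.9, 1.3, 1.3) * 1e-3,
                   dir = c(0, 1, 0), r1 = 0.70,
                   ktrans = 0.04, ktrans_sd = 0.005,
                   ve = 0.12, ve_sd = 0.02, vp = 0.02, vp_sd = 0.004),
    sss     = list(tsc = 41,   tsc_sd = 2,    ev = c(1.5, 1.5, 1.5) * 1e-3,
                   dir = c(1, 0, 0), r1 = 0.60, ktrans = 0, ve = 0,
                   vp = 1 - hematocrit)
  )
}

sphere_mask <- function(dims, centre, radius) {
  x <- seq_len(dims[1]); y <- seq_len(dims[2]); z <- seq_len(dims[3])
  dx <- (x - centre[1])^2
  dy <- (y - centre[2])^2
  dz <- (z - centre[3])^2
  outer(outer(dx, dy, "+"), dz, "+") <= radius^2
}

#' Generate a ground-truth digital-phantom subject
#'
#' Builds per-voxel true parameter maps (TSC, diffusion tensor, K^trans,
#' v_e, v_p, native R1) together with tissue/ROI masks: a spherical tumour
#' at the cerebellopontine-angle margin of a model head, WM/GM shells, a
#' ventricular CSF pocket, a superior-sagittal-sinus blood channel, a
#' reference muscle block, and the two external sodium calibration phantoms
#' (60 and 120 mM) placed in fixed grid corners. Subject-level tissue means
#' are drawn around the configured values; voxel-level variation is a small
#' multiplicative jitter.
#'
#' @param seed integer seed; the subject is bit-identical for a fixed seed.
#' @param grid_shape voxel counts per axis (isotropic layouts need
#'   at least 32 per axis).
#' @param voxel_size voxel edge length, mm per axis.
#' @param tumour_volume_cm3 tumour sphere volume; the default 1.16 cm^3 is
#'   the cohort-mean pre-treatment volume.
#' @param tissue_params tissue parameter table, see
#'   `vsqmri:::default_tissue_params`.
#' @param voxel_jitter relative SD of within-tissue voxelwise variation.
#' @return an object of class `vs_subject`: arrays `tsc_true`,
#'   `ktrans_true`, `ve_true`, `vp_true`, `r1n_true`, `m0_true`, a
#'   `[dims, 6]` tensor component array `tensor_true` (xx, yy, zz, xy, xz,
#'   yz; mm^2/s), and a named list `masks`.
#' @export
make_ground_truth <- function(seed, grid_shape = c(40, 40, 40),
                              voxel_size = c(1, 1, 1),
                              tumour_volume_cm3 = 1.16,
                              tissue_params = default_tissue_params(),
                              voxel_jitter = 0.03) {
  dims <- as.integer(grid_shape)
  stop_if_not(length(dims) == 3 && all(dims >= 32),
              "grid too small for phantom60/phantom120 corner ROIs and tumour sphere: need >= 32 voxels per axis")
  n <- dims[1]
  ctr <- (dims + 1) / 2

  # tumour sphere radius in voxels (isotropic voxel assumption for layout)
  r_t <- (3 * tumour_volume_cm3 * 1000 / (4 * pi))^(1 / 3) / voxel_size[1]
  tumour_ctr <- c(0.34 * dims[1], 0.5 * dims[2], 0.46 * dims[3])
  if (tumour_ctr[1] - r_t < 1 || any(tumour_ctr + r_t > dims - 1))
    stop("grid too small for tumour sphere of requested volume", call. = FALSE)

  tumour <- sphere_mask(dims, tumour_ctr, r_t)
  csf <- sphere_mask(dims, c(0.66 * dims[1], 0.42 * dims[2], 0.60 * dims[3]),
                     max(2.5, 0.07 * n))

  brain_r <- 0.38 * n
  dist2 <- {
    x <- (seq_len(dims[1]) - ctr[1])^2
    y <- (seq_len(dims[2]) - ctr[2])^2
    z <- (seq_len(dims[3]) - ctr[3])^2
    sqrt(outer(outer(x, y, "+"), z, "+"))
  }
  wm <- dist2 <= 0.26 * n
  gm <- dist2 > 0.26 * n & dist2 <= brain_r

  # superior sagittal sinus: channel running antero-posteriorly near vertex
  xi <- slice.index(array(0, dims), 1)
  zi <- slice.index(array(0, dims), 3)
  sss <- (xi - ctr[1])^2 + (zi - (ctr[3] + 0.30 * n))^2 <= (0.07 * n)^2
  sss <- sss & dist2 <= brain_r + 1

  yi <- slice.index(array(0, dims), 2)
  muscle <- xi >= max(2, round(0.04 * n)) & xi <= round(0.10 * n) &
    yi >= round(0.35 * n) & yi <= round(0.65 * n) &
    zi >= round(0.20 * n) & zi <= round(0.45 * n)

  p_r <- max(2, 0.055 * n)
  p60 <- sphere_mask(dims, c(0.88 * dims[1], 0.14 * dims[2], 0.82 * dims[3]), p_r)
  p120 <- sphere_mask(dims, c(0.88 * dims[1], 0.86 * dims[2], 0.82 * dims[3]), p_r)
  if (!any(p60) || !any(p120))
    stop("grid too small for phantom60/phantom120 corner ROIs", call. = FALSE)

  # enforce disjointness by precedence: tumour > csf > sss > wm/gm; muscle and
  # phantoms sit outside the head
  csf <- csf & !tumour
  sss <- sss & !tumour & !csf
  wm <- wm & !tumour & !csf & !sss
  gm <- gm & !tumour & !csf & !sss
  head <- dist2 <= brain_r
  muscle <- muscle & !head
  p60 <- p60 & !head & !muscle
  p120 <- p120 & !head & !muscle & !p60
  stop_if_not(any(tumour), "tumour mask is empty")

  masks <- list(tumour = tumour, gm = gm, wm = wm, csf = csf, sss = sss,
                muscle = muscle, phantom60 = p60, phantom120 = p120)

  with_seed(seed, {
    tsc <- array(0, dims)
    r1n <- array(0, dims)
    m0 <- array(0, dims)
    ktrans <- array(0, dims)
    ve <- array(0, dims)
    vp <- array(0, dims)
    tens <- array(0, c(dims, 6))

    for (tis in names(tissue_params)) {
      p <- tissue_params[[tis]]
      mk <- masks[[tis]]
      nv <- sum(mk)
      if (nv == 0) next
      mu_tsc <- rnorm(1, p$tsc, p$tsc_sd)
      tsc[mk] <- mu_tsc * exp(rnorm(nv, 0, voxel_jitter))
      r1n[mk] <- p$r1
      m0[mk] <- 1000

      # tensor: eigenvalues jittered, principal axis p$dir
      evj <- matrix(rep(p$ev, each = nv), nv, 3) *
        exp(matrix(rnorm(3 * nv, 0, voxel_jitter), nv, 3))
      comps <- tensor_from_eigen(evj, p$dir)
      idx <- which(mk)
      nvox_tot <- prod(dims)
      for (k in 1:6) tens[idx + (k - 1) * nvox_tot] <- comps[, k]

      if (p$ktrans > 0) {
        kt <- pmax(rnorm(nv, p$ktrans, p$ktrans_sd), 0.01)
        vee <- pmin(pmax(rnorm(nv, p$ve, p$ve_sd), 0.05), 0.6)
        vpp <- pmin(pmax(rnorm(nv, p$vp, p$vp_sd), 0.005), 0.099)
        ktrans[mk] <- kt; ve[mk] <- vee; vp[mk] <- vpp
      } else {
        ve[mk] <- p$ve
        vp[mk] <- p$vp
      }
    }
    # calibration phantoms: known concentrations, no subject variation
    tsc[p60] <- 60
    tsc[p120] <- 120
    r1n[p60 | p120] <- 0.35
    m0[p60 | p120] <- 1000

    structure(list(
      grid_shape = dims, voxel_size = voxel_size,
      tsc_true = tsc, tensor_true = tens,
      ktrans_true = ktrans, ve_true = ve, vp_true = vp,
      r1n_true = r1n, m0_true = m0,
      masks = masks, seed = as.integer(seed)
    ), class = "vs_subject")
  })
}

# Build symmetric tensor components (xx, yy, zz, xy, xz, yz) for rows of
# eigenvalues `ev` (n x 3, decreasing) with shared principal axis `dir`;
# the two minor axes are any orthonormal completion.
tensor_from_eigen <- function(ev, dir) {
  ev <- matrix(ev, ncol = 3)
  e1 <- dir / sqrt(sum(dir^2))
  ref <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- ref - sum(ref * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  V <- cbind(e1, e2, e3)
  n <- nrow(ev)
  out <- matrix(0, n, 6)
  # D = V diag(ev) V'
  for (r in 1:3) {
    vr <- V[, r]
    out[, 1] <- out[, 1] + ev[, r] * vr[1] * vr[1]
    out[, 2] <- out[, 2] + ev[, r] * vr[2] * vr[2]
    out[, 3] <- out[, 3] + ev[, r] * vr[3] * vr[3]
    out[, 4] <- out[, 4] + ev[, r] * vr[1] * vr[2]
    out[, 5] <- out[, 5] + ev[, r] * vr[1] * vr[3]
    out[, 6] <- out[, 6] + ev[, r] * vr[2] * vr[3]
  }
  out
}

#' Apply a treatment effect to a ground-truth subject
#'
#' Multiplies tumour-mask ground truth by the per-timepoint factors of a
#' [treatment_effect()] table. Only tumour voxels change; the `pre` row (all
#' factors 1) returns the input unchanged. The `md` factor is realised as an
#' isotropic tensor addition so tumour MD scales by exactly the factor while
#' FA decreases for factors > 1. `ve`/`vp` are rescaled to keep
#' `ve + vp <= 1`.
#'
#' @param subject a [make_ground_truth()] subject.
#' @param effect a [treatment_effect()].
#' @param timepoint visit label present in the effect table.
#' @param subject_scale optional exponent applied to the log-factors to
#'   emulate between-subject heterogeneity of response (1 = as tabled).
#' @return a modified `vs_subject`.
#' @export
apply_treatment_effect <- function(subject, effect, timepoint,
                                   subject_scale = 1) {
  f <- effect$factors
  row <- f[f$timepoint == timepoint, ]
  if (nrow(row) != 1)
    stop(sprintf("unknown timepoint label '%s'", timepoint), call. = FALSE)
  fac <- unlist(row[, c("tsc", "md", "ktrans", "ve", "vp")])
  fac <- exp(log(fac) * subject_scale)
  if (all(abs(fac - 1) < 1e-15)) return(subject)

  mk <- subject$masks$tumour
  idx <- which(mk)
  s <- subject

  # optional voxelwise response heterogeneity: shared exponent on the
  # log-factors, deterministic given the subject seed and timepoint
  hsd <- if (is.null(effect$heterogeneity_sd)) 0 else effect$heterogeneity_sd
  g <- if (hsd > 0) {
    with_seed(derive_seed(subject$seed, sum(utf8ToInt(timepoint))),
              1 + rnorm(length(idx), 0, hsd))
  } else rep(1, length(idx))
  fv <- function(f) exp(log(f) * g)

  s$tsc_true[idx] <- s$tsc_true[idx] * fv(fac[["tsc"]])

  if (abs(fac[["md"]] - 1) > 1e-15 || hsd > 0) {
    comps <- tensor_comps_at(s, idx)
    nvox <- prod(s$grid_shape)
    mdv <- rowMeans(comps[, 1:3, drop = FALSE])
    add <- (fv(fac[["md"]]) - 1) * mdv
    for (k in 1:3) s$tensor_true[idx + (k - 1) * nvox] <-
      comps[, k] + add
  }

  s$ktrans_true[idx] <- s$ktrans_true[idx] * fv(fac[["ktrans"]])
  vee <- s$ve_true[idx] * fv(fac[["ve"]])
  vpp <- s$vp_true[idx] * fv(fac[["vp"]])
  tot <- vee + vpp
  over <- tot > 1
  if (any(over)) {
    vee[over] <- vee[over] / tot[over]
    vpp[over] <- vpp[over] / tot[over]
  }
  s$ve_true[idx] <- vee
  s$vp_true[idx] <- vpp
  s
}

# n x 6 tensor-component matrix for the voxels in `idx` (linear indices)
tensor_comps_at <- function(subject, idx) {
  nvox <- prod(subject$grid_shape)
  out <- matrix(0, length(idx), 6)
  for (k in 1:6) out[, k] <- subject$tensor_true[idx + (k - 1) * nvox]
  out
}
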