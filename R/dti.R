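#' Fit the diffusion tensor
#'
#' Log-linear weighted least-squares tensor fit, the standard behaviour of
#' clinical DTI pipelines: all b = 0 volumes are averaged into a reference
#' S0, then `ln(S/S0) = -b g' D g` is solved per voxel with weights equal
#' to the squared signal (WLS; `wls = FALSE` gives plain OLS). Eigenvalues
#' are computed analytically; negative eigenvalues are projected to zero
#' and the voxel flagged.
#'
#' @param volumes 4-D array `[dims, nvol]` of DWI signal.
#' @param bvals per-volume b-values, s/mm^2.
#' @param bvecs 3 x nvol matrix of gradient directions.
#' @param mask logical 3-D mask of voxels to fit (default: S0 > 0).
#' @param wls use squared-signal weights (default) or OLS.
#' @return an object of class `vs_tensor_map`: `comps` (n x 6 matrix: xx,
#'   yy, zz, xy, xz, yz; mm^2/s), `eigenvalues` (n x 3, decreasing,
#'   clamped at 0), `s0`, `voxels` (linear indices into the grid), `dims`,
#'   and `qc` (logical vector flagging clamped voxels).
#' @export
fit_tensor <- function(volumes, bvals, bvecs, mask = NULL, wls = TRUE) {
  dims <- dim(volumes)[1:3]
  nvol <- dim(volumes)[4]
  stop_if_not(length(bvals) == nvol, "bvals must match volume count")
  b0 <- bvals == 0
  stop_if_not(any(b0), "need at least one b = 0 volume")
  dwi_idx <- which(!b0)
  B <- bmatrix_rows(bvals[dwi_idx], bvecs[, dwi_idx, drop = FALSE])
  stop_if_not(qr(B)$rank == 6, "rank-deficient diffusion design matrix")

  vmat <- matrix(volumes, prod(dims), nvol)
  s0 <- rowMeans(vmat[, b0, drop = FALSE])
  if (is.null(mask)) mask <- array(s0 > 0, dims)
  vox <- which(mask)
  stop_if_not(all(vmat[vox, ] > 0),
              "all signals must be > 0 within the mask")

  S <- vmat[vox, dwi_idx, drop = FALSE]
  Y <- log(s0[vox] / S)                       # = b g' D g
  n <- length(vox)
  comps <- matrix(0, n, 6)
  if (wls) {
    W <- S^2
    for (i in seq_len(n)) {
      bw <- B * W[i, ]
      comps[i, ] <- solve(crossprod(B, bw), crossprod(bw, Y[i, ]))
    }
  } else {
    comps <- t(solve(crossprod(B), crossprod(B, t(Y))))
  }
  lam <- eig3_sym(comps)
  clamped <- lam[, 3] < 0
  lam[lam < 0] <- 0
  structure(list(comps = comps, eigenvalues = lam, s0 = s0[vox],
                 voxels = vox, dims = dims, qc = clamped),
            class = "vs_tensor_map")
}

#' Mean diffusivity
#'
#' MD = (lambda1 + lambda2 + lambda3) / 3, mm^2/s.
#'
#' @param tensor a [fit_tensor()] map.
#' @return numeric vector, one value per fitted voxel.
#' @export
md <- function(tensor) {
  rowMeans(tensor$eigenvalues)
}

#' Fractional anisotropy
#'
#' FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||, dimensionless in
#' `[0, 1]`; defined as 0 for a zero tensor (norm below 1e-12).
#'
#' @param tensor a [fit_tensor()] map.
#' @return numeric vector, one value per fitted voxel.
#' @export
fa <- function(tensor) {
  lam <- tensor$eigenvalues
  mdv <- rowMeans(lam)
  num <- (lam[, 1] - mdv)^2 + (lam[, 2] - mdv)^2 + (lam[, 3] - mdv)^2
  den <- lam[, 1]^2 + lam[, 2]^2 + lam[, 3]^2
  out <- sqrt(1.5) * sqrt(num) / sqrt(den)
  out[sqrt(den) < 1e-12] <- 0
  out
}

# Scalar map (3-D array, NA outside fitted voxels) from per-voxel values.
tensor_scalar_map <- function(tensor, values) {
  out <- array(NA_real_, tensor$dims)
  out[tensor$voxels] <- values
  out
}
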