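# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

# small default-geometry phantom subject
fixture_subject <- function(seed = 7, grid = 32) {
  key <- sprintf("gt_%d_%d", seed, grid)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- make_ground_truth(seed, rep(grid, 3))
  .fixtures[[key]]
}

noiseless_preset <- function(...) acquisition_preset(noise_sd = 0, ...)

# synthesize a DWI stack from a fixed tensor replicated on a small grid
synth_dwi <- function(comps, bvals, bvecs, dims = c(3, 3, 1), s0 = 1000,
                      noise_sd = 0, seed = 1) {
  B <- vsqmri:::bmatrix_rows(bvals, bvecs)
  sig <- s0 * exp(-as.vector(B %*% comps))
  sig[bvals == 0] <- s0
  nvol <- length(bvals)
  vols <- array(rep(sig, each = prod(dims)), c(dims, nvol))
  if (noise_sd > 0) {
    set.seed(seed)
    vols <- vols + array(rnorm(length(vols), 0, noise_sd), dim(vols))
  }
  vols
}

# tensor map object from explicit eigenvalue rows (for md()/fa() checks)
tensor_map_from_eigen <- function(lam) {
  lam <- matrix(lam, ncol = 3)
  structure(list(eigenvalues = lam, dims = c(nrow(lam), 1, 1),
                 voxels = seq_len(nrow(lam)), comps = NULL,
                 qc = rep(FALSE, nrow(lam))),
            class = "vs_tensor_map")
}

# random 3-D rotation matrix (uniform via QR of Gaussian matrix)
random_rotation <- function() {
  qrd <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qrd)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# symmetric 3x3 -> component vector (xx, yy, zz, xy, xz, yz)
mat_to_comps <- function(M) c(M[1, 1], M[2, 2], M[3, 3],
                              M[1, 2], M[1, 3], M[2, 3])
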