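#' @keywords internal
"_PACKAGE"

#' @importFrom stats median pf pnorm pt rnorm sd t.test cov anova
#' @importFrom utils read.csv write.csv
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic sub-seed derivation, kept within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset * 7919) %% 2147483647L)
}

#' Round half away from zero
#'
#' Rounding convention used for report tables (matching printed precision of
#' clinical volume tables, where 0.005 rounds to 0.01).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Significance stars
#'
#' Star convention used in the report tables: `***` for p <= 0.001, `**` for
#' p <= 0.01, `*` for p <= 0.05, empty string otherwise.
#'
#' @param p numeric vector of p values.
#' @return character vector of star labels.
#' @export
signif_stars <- function(p) {
  out <- character(length(p))
  out[p <= 0.05]  <- "*"
  out[p <= 0.01]  <- "**"
  out[p <= 0.001] <- "***"
  out[is.na(p)]   <- ""
  out
}

# Vectorised analytic eigenvalues of symmetric 3x3 tensors.
# `comps` is an n x 6 matrix with columns (xx, yy, zz, xy, xz, yz).
# Returns an n x 3 matrix with eigenvalues sorted decreasingly.
eig3_sym <- function(comps) {
  comps <- matrix(comps, ncol = 6)
  a11 <- comps[, 1]; a22 <- comps[, 2]; a33 <- comps[, 3]
  a12 <- comps[, 4]; a13 <- comps[, 5]; a23 <- comps[, 6]
  q  <- (a11 + a22 + a33) / 3
  p1 <- a12^2 + a13^2 + a23^2
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p  <- sqrt(pmax(p2, 0) / 6)
  n  <- length(q)
  lam <- matrix(q, n, 3)
  nz <- which(p > 0)
  if (length(nz)) {
    b11 <- (a11[nz] - q[nz]) / p[nz]; b22 <- (a22[nz] - q[nz]) / p[nz]
    b33 <- (a33[nz] - q[nz]) / p[nz]
    b12 <- a12[nz] / p[nz]; b13 <- a13[nz] / p[nz]; b23 <- a23[nz] / p[nz]
    detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detb / 2, -1), 1)
    phi <- acos(r) / 3
    l1 <- q[nz] + 2 * p[nz] * cos(phi)
    l3 <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)
    l2 <- 3 * q[nz] - l1 - l3
    lam[nz, 1] <- l1; lam[nz, 2] <- l2; lam[nz, 3] <- l3
  }
  lam
}

# Coordinates (1-based voxel indices) of every voxel in a logical 3-D mask.
mask_coords <- function(mask) {
  which(mask, arr.ind = TRUE)
}

stop_if_not <- function(cond, msg, call. = FALSE) {
  if (!isTRUE(cond)) stop(msg, call. = call.)
}
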