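#' Fit the two-phantom TSC calibration line
#'
#' The external 60 and 120 mM NaCl/agarose phantoms in the imaging
#' field-of-view give two (mean signal, concentration) points; the
#' calibration is the straight line through them, so the intercept absorbs
#' any constant coil/offset bias. Exact two-point interpolation is used
#' rather than regression through the origin.
#'
#' @param image sodium magnitude image (3-D array), signal units.
#' @param phantom_masks list of two logical masks (low, high concentration).
#' @param concs phantom concentrations, mM (default 60 and 120).
#' @return an object of class `vs_calibration` with `slope` (mM per signal
#'   unit), `intercept` (mM), `phantom_concs`, `phantom_means`.
#' @export
fit_calibration <- function(image, phantom_masks, concs = c(60, 120)) {
  stop_if_not(length(phantom_masks) == 2, "need exactly two phantom masks")
  stop_if_not(all(vapply(phantom_masks, any, logical(1))),
              "phantom masks must be non-empty")
  m <- vapply(phantom_masks, function(mk) mean(image[mk]), numeric(1))
  if (abs(m[2] - m[1]) < .Machine$double.eps * max(1, abs(m)))
    stop("degenerate calibration: phantom mean signals are equal",
         call. = FALSE)
  slope <- (concs[2] - concs[1]) / (m[2] - m[1])
  intercept <- concs[1] - slope * m[1]
  stop_if_not(is.finite(slope) && slope > 0,
              "calibration slope must be finite and > 0")
  structure(list(slope = slope, intercept = intercept,
                 phantom_concs = concs, phantom_means = m),
            class = "vs_calibration")
}

#' Convert a sodium image to a TSC map
#'
#' Applies the calibration line voxelwise: `TSC = slope * signal +
#' intercept`. Negative TSC values (possible in low-signal voxels under
#' noise) are preserved, not clipped -- clipping would bias ROI means --
#' and their count is reported in the attached QC summary.
#'
#' @param image sodium magnitude image (3-D array).
#' @param line a [fit_calibration()] result.
#' @param timepoint optional visit label stored with the map.
#' @return an object of class `vs_tsc_map`: `values` (mM, 3-D array),
#'   `timepoint`, and `qc` (list with `n_negative`).
#' @export
apply_calibration <- function(image, line, timepoint = NA_character_) {
  stop_if_not(inherits(line, "vs_calibration"), "line must be a calibration")
  vals <- line$slope * image + line$intercept
  structure(list(values = vals, timepoint = timepoint,
                 qc = list(n_negative = sum(vals < 0, na.rm = TRUE))),
            class = "vs_tsc_map")
}

#' Threshold tissue probability maps into masks
#'
#' Reproduces the partial-volume control used for atlas TSC statistics:
#' only voxels with tissue probability strictly larger than the threshold
#' (default 95\%) enter a tissue mask.
#'
#' @param prob_maps named list of probability volumes (values in `[0, 1]`).
#' @param threshold probability threshold in (0, 1); strict inequality.
#' @return named list of logical masks.
#' @export
threshold_tissue_masks <- function(prob_maps, threshold = 0.95) {
  stop_if_not(threshold > 0 && threshold < 1,
              "threshold must be inside (0, 1)")
  for (p in prob_maps)
    stop_if_not(all(p >= 0 & p <= 1, na.rm = TRUE),
                "probabilities must lie in [0, 1]")
  lapply(prob_maps, function(p) p > threshold)
}

#' Summarise TSC in a region
#'
#' @param tsc a [apply_calibration()] map (or bare array, mM).
#' @param mask logical mask, non-empty.
#' @return list with `mean`, `sd`, `n_voxels` (sd is 0 for a single voxel).
#' @export
summarize_tsc <- function(tsc, mask) {
  vals <- if (inherits(tsc, "vs_tsc_map")) tsc$values else tsc
  stop_if_not(any(mask), "region mask is empty")
  v <- vals[mask]
  list(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
       n_voxels = length(v))
}

#' Tumour-to-CSF TSC ratio
#'
#' @inheritParams summarize_tsc
#' @param tumour_mask,csf_mask logical masks, non-empty.
#' @return numeric scalar: tumour mean TSC / CSF mean TSC.
#' @export
tumour_to_csf_ratio <- function(tsc, tumour_mask, csf_mask) {
  summarize_tsc(tsc, tumour_mask)$mean / summarize_tsc(tsc, csf_mask)$mean
}
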