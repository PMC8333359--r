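#' Write a volume as NIfTI-1
#'
#' RAS orientation, world coordinates set by the voxel size on the
#' diagonal of the affine.
#'
#' @param values 3-D or 4-D numeric or logical array (masks are written as
#'   uint8).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size mm per axis.
#' @return the path, invisibly.
#' @export
write_volume <- function(values, path, voxel_size = c(1, 1, 1)) {
  dtype <- "auto"
  if (is.logical(values)) {
    values <- array(as.integer(values), dim(values))
    dtype <- "uint8"
  }
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Read a volume from NIfTI-1
#'
#' @param path NIfTI path.
#' @return a plain numeric array (attributes dropped).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim(img))
}

# FSL-style bval/bvec text files: one space-separated row of b-values;
# three rows of gradient components.
write_bval_bvec <- function(bvals, bvecs, stem) {
  writeLines(paste(format(bvals, trim = TRUE), collapse = " "),
             paste0(stem, ".bval"))
  writeLines(apply(bvecs, 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")),
    paste0(stem, ".bvec"))
  invisible(stem)
}

read_bval_bvec <- function(stem) {
  bvals <- scan(paste0(stem, ".bval"), quiet = TRUE)
  bvecs <- matrix(scan(paste0(stem, ".bvec"), quiet = TRUE), nrow = 3,
                  byrow = TRUE)
  list(bvals = bvals, bvecs = bvecs)
}

#' Simulate and write a cohort to disk
#'
#' Materialises the simulated cohort as NIfTI-1 volumes with a CSV
#' manifest (`subject`, `timepoint`, `modality`, `path`) and a YAML
#' configuration echoing the design and acquisition preset. Written per
#' acquired visit: the sodium image, the DWI series with FSL-style
#' bval/bvec files, one volume per VFA flip angle, and (once per subject)
#' the ROI masks as uint8.
#'
#' @param design a [cohort_design()].
#' @param dir output directory.
#' @param effect a [treatment_effect()].
#' @param preset an [acquisition_preset()].
#' @param grid_shape phantom grid.
#' @param modalities subset of `c("sodium", "dwi", "vfa", "masks")`.
#' @return path to the manifest CSV, invisibly.
#' @export
write_cohort <- function(design = cohort_design(), dir,
                         effect = treatment_effect(),
                         preset = acquisition_preset(),
                         grid_shape = c(40, 40, 40),
                         modalities = c("sodium", "dwi", "vfa", "masks")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  add_row <- function(s, tp, mod, path) {
    rows[[length(rows) + 1]] <<- data.frame(
      subject = s, timepoint = tp, modality = mod,
      path = basename(path))
  }
  for (s in seq_len(design$n_subjects)) {
    gt0 <- make_ground_truth(derive_seed(design$seed, s),
                             grid_shape = grid_shape)
    vs <- gt0$voxel_size
    if ("masks" %in% modalities) {
      for (mk in names(gt0$masks)) {
        f <- file.path(dir, sprintf("sub%02d_mask_%s.nii.gz", s, mk))
        write_volume(gt0$masks[[mk]], f, vs)
        add_row(s, "static", paste0("mask_", mk), f)
      }
    }
    for (ti in seq_along(design$timepoints)) {
      tp <- design$timepoints[ti]
      if (!visit_acquired(design, s, tp)) next
      gt <- apply_treatment_effect(gt0, effect, tp)
      seed <- derive_seed(design$seed, 10 * s + ti)
      if ("sodium" %in% modalities) {
        f <- file.path(dir, sprintf("sub%02d_%s_sodium.nii.gz", s, tp))
        write_volume(simulate_sodium_image(gt, seed = derive_seed(seed, 1)),
                     f, vs)
        add_row(s, tp, "sodium", f)
      }
      if ("dwi" %in% modalities) {
        dwi <- simulate_dwi(gt, preset, seed = derive_seed(seed, 2))
        stem <- file.path(dir, sprintf("sub%02d_%s_dwi", s, tp))
        write_volume(dwi$volumes, paste0(stem, ".nii.gz"), vs)
        write_bval_bvec(dwi$bvals, dwi$bvecs, stem)
        add_row(s, tp, "dwi", paste0(stem, ".nii.gz"))
      }
      if ("vfa" %in% modalities) {
        vfa <- simulate_vfa(gt, preset, seed = derive_seed(seed, 3))
        for (k in seq_along(vfa$angles)) {
          f <- file.path(dir, sprintf("sub%02d_%s_vfa%02d.nii.gz", s, tp,
                                      vfa$angles[k]))
          write_volume(vfa$volumes[[k]], f, vs)
          add_row(s, tp, sprintf("vfa%02d", vfa$angles[k]), f)
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  mf <- file.path(dir, "manifest.csv")
  write.csv(manifest, mf, row.names = FALSE)
  cfg <- list(
    design = list(n_subjects = design$n_subjects,
                  timepoints = design$timepoints,
                  missing = design$missing,
                  dce_timepoints = design$dce_timepoints,
                  seed = design$seed),
    preset = list(vfa_angles = preset$vfa_angles, dce_tr = preset$dce_tr,
                  dce_flip = preset$dce_flip, ldht_dt = preset$ldht_dt,
                  ldht_n = preset$ldht_n, fdhs_dt = preset$fdhs_dt,
                  fdhs_n = preset$fdhs_n, bvals = preset$bvals,
                  relaxivity_r1 = preset$relaxivity_r1,
                  hematocrit = preset$hematocrit,
                  noise_sd = preset$noise_sd,
                  ldht_dose_fraction = preset$ldht_dose_fraction,
                  block_factor = preset$block_factor),
    grid_shape = grid_shape)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(mf)
}

#' Read a cohort manifest
#'
#' @param dir cohort directory written by [write_cohort()].
#' @return list with `manifest` (data.frame) and `config` (list).
#' @export
read_cohort <- function(dir) {
  list(manifest = read.csv(file.path(dir, "manifest.csv")),
       config = yaml::read_yaml(file.path(dir, "config.yaml")))
}
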