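# Block-aligned bounding box of a mask: list of c(from, to) per axis,
# expanded to multiples of `f` and clipped to the grid.
mask_bbox <- function(mask, f = 1L, pad = 0L) {
  co <- mask_coords(mask)
  dims <- dim(mask)
  out <- vector("list", 3)
  for (a in 1:3) {
    lo <- max(1L, min(co[, a]) - pad)
    hi <- min(dims[a], max(co[, a]) + pad)
    lo <- ((lo - 1L) %/% f) * f + 1L
    hi <- min(dims[a], ((hi + f - 1L) %/% f) * f)
    out[[a]] <- c(lo, hi)
  }
  out
}

# linear indices (within a bbox-local subgrid) of the mask voxels
bbox_local_indices <- function(mask, bbox) {
  sub <- mask[seq(bbox[[1]][1], bbox[[1]][2]),
              seq(bbox[[2]][1], bbox[[2]][2]),
              seq(bbox[[3]][1], bbox[[3]][2])]
  list(idx = which(sub), dims = dim(sub), sub = sub)
}

# Quantify one visit of one subject: sodium -> TSC map, DWI -> MD/FA over
# the tumour mask, and (on DCE visits) VFA -> R1, dual-series DCE ->
# VIF -> fusion -> ETM parameters over a reproducible tumour voxel
# subsample and a muscle sample.
process_visit <- function(gt, preset, seed, dce = TRUE,
                          tum_sample, musc_sample, sodium_noise_sd = 15,
                          dwi_noise_sd = 20) {
  masks <- gt$masks
  out <- list()

  ## sodium -> TSC
  img <- simulate_sodium_image(gt, noise_sd = sodium_noise_sd,
                               seed = derive_seed(seed, 1))
  line <- fit_calibration(img, list(masks$phantom60, masks$phantom120))
  tsc <- apply_calibration(img, line)
  out$tsc <- tsc
  out$tsc_roi <- lapply(masks[c("gm", "wm", "csf", "tumour")],
                        function(mk) summarize_tsc(tsc, mk))
  out$tsc_ratio <- tumour_to_csf_ratio(tsc, masks$tumour, masks$csf)

  ## DWI -> tensor -> MD / FA over the tumour
  dwi <- simulate_dwi(gt, preset, noise_sd = dwi_noise_sd,
                      seed = derive_seed(seed, 2))
  tfit <- fit_tensor(dwi$volumes, dwi$bvals, dwi$bvecs, mask = masks$tumour)
  out$md_map <- tensor_scalar_map(tfit, md(tfit))
  out$fa_map <- tensor_scalar_map(tfit, fa(tfit))

  if (!dce) return(out)

  ## VFA -> native R1
  vfa <- simulate_vfa(gt, preset, seed = derive_seed(seed, 3))
  f <- preset$block_factor
  bbox_t <- mask_bbox(masks$tumour, f = f)
  bbox_m <- mask_bbox(masks$muscle, f = 1L)
  bbox_s <- mask_bbox(masks$sss, f = f)

  crop <- function(vols, bbox) lapply(vols, function(v)
    v[seq(bbox[[1]][1], bbox[[1]][2]), seq(bbox[[2]][1], bbox[[2]][2]),
      seq(bbox[[3]][1], bbox[[3]][2])])
  vfa_t <- list(volumes = crop(vfa$volumes, bbox_t), angles = vfa$angles,
                tr = vfa$tr)
  vfa_m <- list(volumes = crop(vfa$volumes, bbox_m), angles = vfa$angles,
                tr = vfa$tr)
  vfa_s <- list(volumes = lapply(crop(vfa$volumes, bbox_s), block_average,
                                 f = f),
                angles = vfa$angles, tr = vfa$tr)
  r1_t <- fit_r1_vfa(vfa_t, refine = FALSE)
  r1_m <- fit_r1_vfa(vfa_m, refine = FALSE)
  r1_s <- fit_r1_vfa(vfa_s, refine = TRUE)
  # coarse R1 for the LDHT tumour grid
  vfa_tc <- list(volumes = lapply(vfa_t$volumes, block_average, f = f),
                 angles = vfa$angles, tr = vfa$tr)
  r1_tc <- fit_r1_vfa(vfa_tc, refine = FALSE)

  fill_na <- function(r1, default) {
    r1[!is.finite(r1)] <- default
    r1
  }
  r1_t$r1 <- fill_na(r1_t$r1, 0.7); r1_m$r1 <- fill_na(r1_m$r1, 0.7)
  r1_s$r1 <- fill_na(r1_s$r1, 0.6); r1_tc$r1 <- fill_na(r1_tc$r1, 0.7)

  ## LDHT: VIF from the SSS + coarse tumour curves
  ld_s <- simulate_dce(gt, preset, dose_fraction = preset$ldht_dose_fraction,
                       series = "ldht", seed = derive_seed(seed, 4),
                       bbox = bbox_s)
  ld_t <- simulate_dce(gt, preset, dose_fraction = preset$ldht_dose_fraction,
                       series = "ldht", seed = derive_seed(seed, 5),
                       bbox = bbox_t)
  nbase_ld <- max(3, sum(ld_s$time < 10) - 1)
  conc_s <- concentration_from_signal(ld_s$signal, ld_s$time, nbase_ld,
                                      r1_s$r1, preset$relaxivity_r1,
                                      preset$dce_tr, preset$dce_flip)
  # use only coarse blocks fully inside the sinus: partially filled blocks
  # dilute the blood concentration and would bias the VIF low
  sss_local <- bbox_local_indices(masks$sss, bbox_s)
  par_idx <- parent_coarse_index(mask_coords(sss_local$sub),
                                 sss_local$dims, f)
  fill <- table(par_idx) / f^3
  full <- as.integer(names(fill)[fill >= 0.999])
  if (!length(full)) full <- as.integer(names(fill)[fill == max(fill)])
  sss_coarse <- full
  vif <- extract_vif(conc_s$conc, ld_s$time, hematocrit = preset$hematocrit,
                     dose_fraction = preset$ldht_dose_fraction,
                     rows = sss_coarse)
  conc_tc <- concentration_from_signal(ld_t$signal, ld_t$time, nbase_ld,
                                       r1_tc$r1, preset$relaxivity_r1,
                                       preset$dce_tr, preset$dce_flip)

  ## FDHS: fine tumour + muscle curves (bolus-aligned to the LDHT series)
  fd_t <- simulate_dce(gt, preset, dose_fraction = 1, series = "fdhs",
                       seed = derive_seed(seed, 6), bbox = bbox_t)
  fd_m <- simulate_dce(gt, preset, dose_fraction = 1, series = "fdhs",
                       seed = derive_seed(seed, 7), bbox = bbox_m)
  nbase_fd <- max(3, sum(fd_t$time < 40) - 1)
  conc_tf <- concentration_from_signal(fd_t$signal, fd_t$time, nbase_fd,
                                       r1_t$r1, preset$relaxivity_r1,
                                       preset$dce_tr, preset$dce_flip)
  conc_mf <- concentration_from_signal(fd_m$signal, fd_m$time, nbase_fd,
                                       r1_m$r1, preset$relaxivity_r1,
                                       preset$dce_tr, preset$dce_flip)

  ## fuse: LDHT temporal shape at FDHS spatial scale (bolus-relative time)
  tum_local <- bbox_local_indices(masks$tumour, bbox_t)
  fused <- legatos_fuse(
    ldht = list(conc = conc_tc$conc, time = ld_t$time,
                dims = dim(ld_t$signal)[1:3]),
    fdhs = list(conc = conc_tf$conc, time = fd_t$time - 30,
                dims = tum_local$dims))

  ## ETM fits on the tumour subsample and muscle sample
  rows_t <- tum_local$idx[tum_sample]
  etm_t <- fit_etm(fused$conc[rows_t, , drop = FALSE], vif, fused$time)
  musc_local <- bbox_local_indices(masks$muscle, bbox_m)
  rows_m <- musc_local$idx[musc_sample]
  vif_fd <- vif
  vif_fd$time <- vif$time + 30      # back to FDHS clock
  etm_m <- fit_etm(conc_mf$conc[rows_m, , drop = FALSE], vif_fd, fd_m$time)

  out$etm_tumour <- etm_t
  out$etm_muscle <- etm_m
  out$vif <- vif
  out$dce_qc <- c(ldht_sss = conc_s$qc, ldht_tum = conc_tc$qc,
                  fdhs_tum = conc_tf$qc, fdhs_mus = conc_mf$qc)
  out
}

#' Run the full synthetic-cohort analysis
#'
#' Simulates the default digital-phantom cohort (five subjects, visits
#' \{pre, 2wk, 8wk, 6mo\} with the standard three missed visits, DCE at
#' pre/2wk/6mo), runs every quantification stage (sodium TSC calibration,
#' DTI scalar maps, VFA R1 mapping, dual-series DCE with input-function
#' extraction, temporal-spatial fusion and extended Tofts fitting), and
#' computes the longitudinal statistics: pooled voxelwise baseline
#' contrasts per parameter (mixed-effects timepoint model over voxels),
#' per-subject paired deltas, sodium compartment classification with
#' proportion tests, muscle-reference stability, TSC repeatability (CoV,
#' ICC), and the tumour-volume table statistics.
#'
#' Voxelwise DCE statistics use a reproducible random subsample of tumour
#' voxels per subject (`dce_voxels`) to bound the per-voxel nonlinear
#' fitting cost; TSC/MD/FA statistics use every tumour voxel.
#'
#' @param design a [cohort_design()].
#' @param effect a [treatment_effect()].
#' @param preset an [acquisition_preset()].
#' @param grid_shape phantom grid, voxels.
#' @param dce_voxels tumour voxels per subject entering ETM fitting.
#' @param muscle_voxels muscle voxels per subject entering ETM fitting.
#' @param subject_sd between-subject SD of the log treatment-effect scale.
#' @param seed integer seed (defaults to the design seed).
#' @param verbose print progress.
#' @return list with `delta_tables` (per parameter: subject rows and a
#'   pooled `All` row with estimate, CI, p, p_adj), `pooled_contrasts`
#'   (per parameter mixed-model baseline contrasts), `compartments`
#'   (classification percentages + proportion tests per timepoint and
#'   second metric), `muscle` (per-parameter omnibus p and CoV),
#'   `repeatability` (TSC CoV/ICC per tissue), `volume` (Table-2-style
#'   statistics + mixed model), `panels`, and `per_subject` details.
#' @export
analyze_cohort <- function(design = cohort_design(),
                           effect = treatment_effect(),
                           preset = acquisition_preset(),
                           grid_shape = c(40, 40, 40),
                           dce_voxels = 250, muscle_voxels = 80,
                           subject_sd = 0.15,
                           seed = design$seed,
                           verbose = FALSE) {
  tps <- design$timepoints
  params_img <- c("tsc", "md", "fa")
  params_dce <- c("ktrans", "ve", "vp")

  panels <- list()
  per_subject <- list()
  subject_scales <- with_seed(derive_seed(seed, 900),
                              rnorm(design$n_subjects, 1, subject_sd))

  for (s in seq_len(design$n_subjects)) {
    if (verbose) message(sprintf("subject %d", s))
    gt0 <- make_ground_truth(derive_seed(seed, s), grid_shape = grid_shape)
    ntum <- sum(gt0$masks$tumour)
    nmus <- sum(gt0$masks$muscle)
    tum_sample <- with_seed(derive_seed(seed, 300 + s),
                            sort(sample.int(ntum, min(dce_voxels, ntum))))
    musc_sample <- with_seed(derive_seed(seed, 400 + s),
                             sort(sample.int(nmus, min(muscle_voxels, nmus))))
    visits <- list()
    for (ti in seq_along(tps)) {
      tp <- tps[ti]
      if (!visit_acquired(design, s, tp)) next
      gt <- apply_treatment_effect(gt0, effect, tp,
                                   subject_scale = subject_scales[s])
      dce <- tp %in% design$dce_timepoints
      visits[[tp]] <- process_visit(
        gt, preset, seed = derive_seed(seed, 10 * s + ti), dce = dce,
        tum_sample = tum_sample, musc_sample = musc_sample)
    }
    per_subject[[s]] <- visits

    tum <- gt0$masks$tumour
    panels$tsc[[s]] <- voxel_panel(lapply(visits, `[[`, "tsc"), tum,
                                   "tsc", "mM")
    panels$md[[s]] <- voxel_panel(lapply(visits, `[[`, "md_map"), tum,
                                  "md", "mm^2/s")
    panels$fa[[s]] <- voxel_panel(lapply(visits, `[[`, "fa_map"), tum,
                                  "fa", "")
    dce_vis <- visits[!vapply(lapply(visits, `[[`, "etm_tumour"), is.null,
                              logical(1))]
    for (p in params_dce) {
      m <- do.call(cbind, lapply(dce_vis, function(v) v$etm_tumour[[p]]))
      colnames(m) <- names(dce_vis)
      panels[[p]][[s]] <- structure(m, class = c("vs_panel", "matrix"),
                                    parameter = p, units = "")
    }
  }

  ## pooled + per-subject longitudinal statistics per parameter
  delta_tables <- list()
  pooled_contrasts <- list()
  for (p in c(params_img, params_dce)) {
    rows <- list()
    long <- list()
    for (s in seq_along(panels[[p]])) {
      pan <- panels[[p]][[s]]
      bl <- panel_baseline(pan)
      for (tp in setdiff(colnames(pan), bl)) {
        d <- voxel_delta(pan, tp, bl, subject = s)
        tt <- t.test(d)
        m <- ncol(pan) - 1
        rows[[length(rows) + 1]] <- data.frame(
          subject = as.character(s), timepoint = tp, baseline = bl,
          estimate = unname(tt$estimate),
          ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
          p = tt$p.value, p_adj = min(1, m * tt$p.value))
      }
      long[[s]] <- data.frame(
        value = as.vector(pan),
        subject = paste0(s, "_", rep(seq_len(nrow(pan)), ncol(pan))),
        timepoint = rep(colnames(pan), each = nrow(pan)))
    }
    long <- do.call(rbind, long)
    mm <- mixed_model_timepoint(long, baseline = "pre")
    pooled_contrasts[[p]] <- mm$contrasts
    all_rows <- data.frame(
      subject = "All", timepoint = mm$contrasts$timepoint, baseline = "pre",
      estimate = mm$contrasts$estimate,
      ci_low = mm$contrasts$ci_low, ci_high = mm$contrasts$ci_high,
      p = mm$contrasts$p, p_adj = mm$contrasts$p_adj)
    delta_tables[[p]] <- rbind(do.call(rbind, rows), all_rows)
  }

  ## compartment classification on pooled voxelwise deltas
  comp_rows <- list()
  for (tp in setdiff(tps, "pre")) {
    for (second in c("md", "ve")) {
      dt_all <- c(); ds_all <- c()
      for (s in seq_along(panels$tsc)) {
        pan_t <- panels$tsc[[s]]
        pan_o <- panels[[second]][[s]]
        bl_t <- panel_baseline(pan_t); bl_o <- panel_baseline(pan_o)
        if (!(tp %in% colnames(pan_t)) || !(tp %in% colnames(pan_o))) next
        d_t <- voxel_delta(pan_t, tp, bl_t)
        d_o <- voxel_delta(pan_o, tp, bl_o)
        if (second == "ve") {
          # align the TSC deltas onto the DCE voxel subsample
          tum_sample <- with_seed(derive_seed(seed, 300 + s),
                                  sort(sample.int(length(d_t),
                                                  nrow(pan_o))))
          d_t <- d_t[tum_sample]
        }
        dt_all <- c(dt_all, d_t); ds_all <- c(ds_all, d_o)
      }
      if (!length(dt_all)) next
      cc <- classify_compartments(dt_all, ds_all)
      pt <- if (cc$n_up_up + cc$n_up_down > 0)
        proportion_test(cc$n_up_up, cc$n_up_up + cc$n_up_down) else NULL
      comp_rows[[length(comp_rows) + 1]] <- data.frame(
        timepoint = tp, second_metric = second,
        pct_up_tsc = cc$pct_up,
        pct_extracellular = cc$pct_extracellular,
        pct_intracellular = cc$pct_intracellular,
        prop_z = if (is.null(pt)) NA_real_ else pt$statistic,
        prop_p = if (is.null(pt)) NA_real_ else pt$p)
    }
  }
  compartments <- do.call(rbind, comp_rows)

  ## muscle reference stability + repeatability
  muscle <- list()
  for (p in params_dce) {
    long <- list()
    for (s in seq_along(per_subject)) {
      for (tp in names(per_subject[[s]])) {
        em <- per_subject[[s]][[tp]]$etm_muscle
        if (is.null(em)) next
        long[[length(long) + 1]] <- data.frame(
          value = mean(em[[p]], na.rm = TRUE), subject = s, timepoint = tp)
      }
    }
    long <- do.call(rbind, long)
    mm <- mixed_model_timepoint(long, baseline = "pre")
    per_subj <- split(long$value, long$subject)
    muscle[[p]] <- list(anova_p = mm$anova_p, contrasts = mm$contrasts,
                        cov_pct = cov_global(per_subj))
  }

  repeatability <- list()
  for (tis in c("gm", "wm", "csf")) {
    vals <- lapply(seq_along(per_subject), function(s)
      vapply(per_subject[[s]], function(v) v$tsc_roi[[tis]]$mean,
             numeric(1)))
    repeatability[[tis]] <- list(cov_pct = cov_global(vals))
    complete <- vapply(vals, length, integer(1)) == length(tps)
    if (sum(complete) >= 2)
      repeatability[[tis]]$icc <-
        icc_a_k(do.call(rbind, vals[complete]))
  }

  ## tumour-volume table statistics (printed per-patient values)
  vt <- vs_volume_table()
  vstats <- volume_stats(vt)
  vol_long <- data.frame(
    value = unlist(vt[, c("vol_pre", "vol_2wk", "vol_8wk", "vol_6mo")]),
    subject = rep(vt$subject, 4),
    timepoint = rep(c("pre", "2wk", "8wk", "6mo"), each = nrow(vt)))
  vol_mm <- mixed_model_timepoint(vol_long, baseline = "pre")
  volume <- c(vstats, list(mixed_model = vol_mm))

  list(delta_tables = delta_tables, pooled_contrasts = pooled_contrasts,
       compartments = compartments, muscle = muscle,
       repeatability = repeatability, volume = volume,
       panels = panels, per_subject = per_subject,
       design = design, effect = effect, preset = preset)
}
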