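#' Acquisition preset
#'
#' Bundles the acquisition parameters shared by the simulator and the
#' quantification modules: VFA flip angles for native R1 mapping, the timing
#' of the low-dose high-temporal (LDHT) and full-dose high-spatial (FDHS)
#' DCE series of the dual-injection dual-temporal-resolution design, the DWI
#' b-values/directions, contrast-agent relaxivity, haematocrit and the noise
#' level added to simulated magnitude signals.
#'
#' Defaults mirror a 3 T dual-temporal-resolution protocol: VFA flip angles
#' 2/6/12/16 degrees, DCE flip 16 degrees, LDHT frame spacing 1.3 s
#' (300 frames), FDHS frame spacing 10.1 s (60 frames), b-values 0 and
#' 800 s/mm^2 with 15 gradient directions. TR and relaxivity are not part of
#' a printed protocol and default to TR = 5 ms and r1 = 3.5 /s/mM
#' (gadoterate at 3 T); both are carried in every derived output's metadata.
#'
#' @param vfa_angles VFA flip angles, degrees.
#' @param dce_tr repetition time of the spoiled gradient-echo readout, s.
#' @param dce_flip DCE flip angle, degrees.
#' @param ldht_dt,ldht_n LDHT frame spacing (s) and frame count.
#' @param fdhs_dt,fdhs_n FDHS frame spacing (s) and frame count.
#' @param bvals DWI b-values, s/mm^2.
#' @param bvecs 3 x n matrix of unit gradient directions (defaults to a
#'   deterministic 15-direction spherical spiral).
#' @param relaxivity_r1 longitudinal relaxivity of the contrast agent,
#'   /s/mM.
#' @param hematocrit capillary haematocrit used for blood-to-plasma
#'   concentration conversion.
#' @param noise_sd additive Gaussian noise SD on simulated signal,
#'   arbitrary signal units.
#' @param ldht_dose_fraction fraction of the full contrast dose given for
#'   the LDHT injection (fixed 3 ml bolus versus 0.1 mmol/kg full dose).
#' @param block_factor integer linear factor relating the LDHT (coarse) and
#'   FDHS (fine) spatial grids.
#' @return an object of class `vs_preset` (a named list).
#' @export
acquisition_preset <- function(vfa_angles = c(2, 6, 12, 16),
                               dce_tr = 0.005,
                               dce_flip = 16,
                               ldht_dt = 1.3, ldht_n = 300,
                               fdhs_dt = 10.1, fdhs_n = 60,
                               bvals = c(0, 800),
                               bvecs = default_bvecs(15),
                               relaxivity_r1 = 3.5,
                               hematocrit = 0.42,
                               noise_sd = 0.5,
                               ldht_dose_fraction = 0.2,
                               block_factor = 2L) {
  stop_if_not(all(c(dce_tr, ldht_dt, fdhs_dt) > 0),
              "durations must be positive")
  stop_if_not(all(c(ldht_n, fdhs_n) >= 1), "frame counts must be positive")
  stop_if_not(hematocrit > 0 && hematocrit < 1,
              "hematocrit must be in (0, 1)")
  stop_if_not(all(vfa_angles > 0 & vfa_angles <= 90),
              "flip angles must be in (0, 90] degrees")
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3 && ncol(bvecs) == 3) bvecs <- t(bvecs)
  nrm <- sqrt(colSums(bvecs^2))
  stop_if_not(all(abs(nrm - 1) < 1e-8), "bvecs must be unit norm")
  stop_if_not(ldht_dose_fraction > 0 && ldht_dose_fraction <= 1,
              "ldht_dose_fraction must be in (0, 1]")
  structure(list(
    vfa_angles = vfa_angles, dce_tr = dce_tr, dce_flip = dce_flip,
    ldht_dt = ldht_dt, ldht_n = as.integer(ldht_n),
    fdhs_dt = fdhs_dt, fdhs_n = as.integer(fdhs_n),
    bvals = bvals, bvecs = bvecs,
    relaxivity_r1 = relaxivity_r1, hematocrit = hematocrit,
    noise_sd = noise_sd, ldht_dose_fraction = ldht_dose_fraction,
    block_factor = as.integer(block_factor)
  ), class = "vs_preset")
}

#' Deterministic unit gradient directions
#'
#' Spherical (golden-angle) spiral over the upper hemisphere, a standard way
#' to obtain a well-conditioned diffusion-encoding set.
#'
#' @param n number of directions.
#' @return a 3 x n matrix of unit vectors.
#' @export
default_bvecs <- function(n = 15) {
  i <- seq_len(n) - 0.5
  z <- i / n                       # upper hemisphere only
  theta <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  rbind(r * cos(theta), r * sin(theta), z)
}

#' Cohort design
#'
#' Subjects, timepoints and the missing-visit pattern of the simulated
#' cohort. The default reproduces the study pattern: five subjects imaged at
#' \{pre, 2wk, 8wk, 6mo\} with three missed visits (subject 2 missing pre,
#' subject 3 missing 8wk, subject 1 missing 6mo), i.e. 17 of 20 visits
#' acquired. DCE is acquired at pre, 2wk and 6mo only.
#'
#' @param n_subjects number of subjects.
#' @param timepoints character vector of visit labels.
#' @param missing data.frame with columns `subject`, `timepoint` naming
#'   skipped visits.
#' @param dce_timepoints visits at which the DCE protocol is run.
#' @param seed integer cohort seed.
#' @return an object of class `vs_design`.
#' @export
cohort_design <- function(n_subjects = 5,
                          timepoints = c("pre", "2wk", "8wk", "6mo"),
                          missing = data.frame(
                            subject = c(2L, 3L, 1L),
                            timepoint = c("pre", "8wk", "6mo")),
                          dce_timepoints = c("pre", "2wk", "6mo"),
                          seed = 42L) {
  stop_if_not(all(missing$timepoint %in% timepoints),
              "missing visits must use known timepoint labels")
  stop_if_not(all(missing$subject %in% seq_len(n_subjects)),
              "missing visits must name known subjects")
  for (s in seq_len(n_subjects)) {
    kept <- sum(!(timepoints %in% missing$timepoint[missing$subject == s]))
    stop_if_not(kept >= 3, sprintf("subject %d retains < 3 timepoints", s))
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 timepoints = timepoints,
                 missing = missing,
                 dce_timepoints = dce_timepoints,
                 seed = as.integer(seed)),
            class = "vs_design")
}

#' Is a visit acquired under a design?
#' @param design a [cohort_design()].
#' @param subject subject index.
#' @param timepoint visit label.
#' @return logical.
#' @export
visit_acquired <- function(design, subject, timepoint) {
  !any(design$missing$subject == subject &
         design$missing$timepoint == timepoint)
}

#' Treatment effect table
#'
#' Per-timepoint multiplicative factors applied to the tumour-mask ground
#' truth to emulate post-radiosurgery change. Defaults encode the reported
#' response directions: an early (2wk) rise in TSC with mildly increased
#' diffusivity and microvascular parameters, heterogeneous change at 8wk,
#' and by 6mo a marked TSC and MD increase with decreases in FA and in
#' K^trans, v_e and v_p.
#'
#' The `md` factor scales the tumour mean diffusivity by exactly that
#' factor, implemented as an isotropic addition to the tensor
#' (D' = D + (f - 1) * MD * I) so that an oedema-like MD increase also
#' lowers FA, as observed after irradiation.
#'
#' @param factors data.frame with columns `timepoint`, `tsc`, `md`,
#'   `ktrans`, `ve`, `vp`; factor 1 means no change. The `pre` row must be
#'   all ones.
#' @param heterogeneity_sd SD of a voxelwise modulation of the
#'   log-factors inside the tumour (0, the default, disables it and makes
#'   each factor spatially uniform).
#' @return an object of class `vs_effect`.
#' @export
treatment_effect <- function(factors = data.frame(
                               timepoint = c("pre", "2wk", "8wk", "6mo"),
                               tsc    = c(1, 1.15, 1.08, 1.25),
                               md     = c(1, 1.06, 1.08, 1.25),
                               ktrans = c(1, 1.15, 1.05, 0.50),
                               ve     = c(1, 1.10, 1.05, 0.70),
                               vp     = c(1, 1.10, 1.05, 0.60)),
                             heterogeneity_sd = 0) {
  stop_if_not(all(unlist(factors[, -1]) > 0), "effect factors must be > 0")
  pre <- factors[factors$timepoint == "pre", -1]
  stop_if_not(nrow(pre) == 1 && all(abs(unlist(pre) - 1) < 1e-12),
              "pre timepoint must have unit factors")
  structure(list(factors = factors, heterogeneity_sd = heterogeneity_sd),
            class = "vs_effect")
}
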