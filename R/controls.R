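# Perturbation controls. Each control is a pure function of
# (session, parameters, seed): it never mutates the session or its
# veridical fit, and a fixed seed reproduces it bit for bit.

control_signal_args <- function(session, signal) {
  list(band = signal$band, woi = signal$woi,
       baseline_woi = signal$baseline_woi)
}


#' Shuffled-lead-field control
#'
#' Repeats the laminar analysis with the (smoothed) lead-field columns
#' randomly permuted before inversion, destroying the correspondence
#' between anatomy and sensors. The mean shuffled unsigned ROI change and
#' the mean shuffled pial-white difference are returned for use as a
#' shifted null in the group test.
#'
#' @param session a `laminar_session`.
#' @param signal list `(band, woi, baseline_woi)`.
#' @param repetitions number of permutations (default 10).
#' @param seed master seed; repetition seeds are derived.
#' @param patch_fwhm inversion patch FWHM.
#' @param ... passed to [laminar_analysis()].
#' @return list: `t` (per repetition), `diff` (per repetition), `mean_diff`
#'   (the shifted-null value), `mean_roi_value`, `permutations_distinct`.
#' @export
run_shuffle_control <- function(session, signal, repetitions = 10, seed = 1,
                                patch_fwhm = 0.010, ...) {
  lfs <- coherence_smooth(session$lf, session$model, patch_fwhm)
  perms <- list()
  t_rep <- diff_rep <- roi_rep <- numeric(repetitions)
  for (r in seq_len(repetitions)) {
    lfp <- shuffle_lead_fields(lfs, derive_seed(seed, "shuffle", r))
    perms[[r]] <- attr(lfp, "permutation")
    sfit <- fit_session(session, lf = lfp, band = signal$band,
                        patch_fwhm = 0)
    res <- do.call(laminar_analysis,
                   c(list(session = session, sfit = sfit),
                     control_signal_args(session, signal), list(...)))
    t_rep[r] <- res$t
    diff_rep[r] <- res$diff
    roi_rep[r] <- mean(c(res$pial_trials, res$white_trials))
  }
  list(t = t_rep, diff = diff_rep, mean_diff = mean(diff_rep),
       mean_roi_value = mean(roi_rep),
       permutations_distinct = length(unique(perms)) == repetitions)
}

#' Co-registration-error control
#'
#' Repeats the laminar analysis after applying a random rigid rotation and
#' translation to the sensor array (default moments 10 degrees / 10 mm, SD
#' 2.5 each) and rebuilding the lead field, simulating between-session
#' co-registration error.
#'
#' @inheritParams run_shuffle_control
#' @param mean_rot_deg,sd_rot_deg,mean_trans_mm,sd_trans_mm perturbation
#'   moments (see [perturb_coregistration()]).
#' @return list: `t`, `diff` per repetition, `transforms`.
#' @export
run_coreg_control <- function(session, signal, repetitions = 10, seed = 1,
                              mean_rot_deg = 10, sd_rot_deg = 2.5,
                              mean_trans_mm = 10, sd_trans_mm = 2.5,
                              patch_fwhm = 0.010, ...) {
  t_rep <- diff_rep <- numeric(repetitions)
  transforms <- list()
  for (r in seq_len(repetitions)) {
    pert <- perturb_coregistration(session$sensors, mean_rot_deg, sd_rot_deg,
                                   mean_trans_mm, sd_trans_mm,
                                   seed = derive_seed(seed, "coreg", r))
    transforms[[r]] <- attr(pert, "transform")
    lf <- build_lead_field(session$model, pert)
    lfs <- coherence_smooth(lf, session$model, patch_fwhm)
    sfit <- fit_session(session, lf = lfs, band = signal$band,
                        patch_fwhm = 0)
    res <- do.call(laminar_analysis,
                   c(list(session = session, sfit = sfit),
                     control_signal_args(session, signal), list(...)))
    t_rep[r] <- res$t
    diff_rep[r] <- res$diff
  }
  list(t = t_rep, diff = diff_rep, transforms = transforms)
}

subset_session <- function(session, idx) {
  out <- session
  out$epochs$data <- session$epochs$data[idx, , , drop = FALSE]
  out$epochs$trials <- session$epochs$trials[idx, , drop = FALSE]
  out
}

#' Trial-subsampling control
#'
#' Laminar t as a function of the number of trials: for each count a random
#' subset of trials is analyzed, repeated and averaged.
#'
#' @inheritParams run_shuffle_control
#' @param trial_counts ladder of trial counts; counts below 2 are skipped,
#'   counts above the available trials are an error.
#' @return data frame: `n_trials`, `mean_t`, `sd_t`.
#' @export
run_subsample_control <- function(session, signal, trial_counts = NULL,
                                  repetitions = 10, seed = 1,
                                  patch_fwhm = 0.010, ...) {
  n_avail <- dim(session$epochs$data)[1]
  if (is.null(trial_counts))
    trial_counts <- unique(pmin(c(10, 20, 40, 80, 160, n_avail), n_avail))
  if (max(trial_counts) > n_avail) stop("trial count exceeds available trials")
  trial_counts <- trial_counts[trial_counts >= 2]
  lfs <- coherence_smooth(session$lf, session$model, patch_fwhm)
  rows <- lapply(trial_counts, function(nt) {
    ts <- vapply(seq_len(repetitions), function(r) {
      set.seed(derive_seed(seed, paste0("subsample", nt), r))
      sub <- subset_session(session, sample.int(n_avail, nt))
      sfit <- fit_session(sub, lf = lfs, band = signal$band,
                          patch_fwhm = 0)
      do.call(laminar_analysis,
              c(list(session = sub, sfit = sfit),
                control_signal_args(sub, signal), list(...)))$t
    }, numeric(1))
    data.frame(n_trials = nt, mean_t = mean(ts), sd_t = stats::sd(ts))
  })
  do.call(rbind, rows)
}

#' White-noise-injection control
#'
#' Laminar t as a function of added sensor noise: Gaussian white noise of
#' increasing standard deviation (expressed as multiples of the session's
#' per-channel data SD) is added to the epoched sensor data and the
#' analysis re-run.
#'
#' @inheritParams run_shuffle_control
#' @param noise_sds ascending ladder of noise SDs in units of the data SD
#'   (default `c(0, 0.5, 1, 2, 4, 8)`).
#' @return data frame: `noise_sd`, `mean_t`, `sd_t`, plus one row per
#'   repetition in attribute `"per_rep"`.
#' @export
run_noise_control <- function(session, signal,
                              noise_sds = c(0, 0.5, 1, 2, 4, 8),
                              repetitions = 10, seed = 1,
                              patch_fwhm = 0.010, ...) {
  if (is.unsorted(noise_sds)) stop("noise_sds must be ascending")
  data_sd <- stats::sd(as.vector(session$epochs$data))
  lfs <- coherence_smooth(session$lf, session$model, patch_fwhm)
  per <- list()
  rows <- lapply(noise_sds, function(ns) {
    ts <- vapply(seq_len(repetitions), function(r) {
      noisy <- session
      if (ns > 0) {
        set.seed(derive_seed(seed, paste0("noise", which(noise_sds == ns)), r))
        noisy$epochs$data <- session$epochs$data +
          array(stats::rnorm(length(session$epochs$data), sd = ns * data_sd),
                dim(session$epochs$data))
      }
      sfit <- fit_session(noisy, lf = lfs, band = signal$band,
                          patch_fwhm = 0)
      do.call(laminar_analysis,
              c(list(session = noisy, sfit = sfit),
                control_signal_args(noisy, signal), list(...)))$t
    }, numeric(1))
    per[[length(per) + 1]] <<- ts
    data.frame(noise_sd = ns, mean_t = mean(ts), sd_t = stats::sd(ts))
  })
  out <- do.call(rbind, rows)
  attr(out, "per_rep") <- per
  out
}
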