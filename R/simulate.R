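#' Evoked hemodynamic response model
#'
#' Condition-dependent evoked response applied to total hemoglobin (tHb,
#' the blood-volume proxy) after each stimulus. The kernel is a gamma
#' density re-scaled to peak amplitude 1, so an amplitude of \code{a}
#' means the evoked tHb excursion peaks at \code{a}\% of baseline tHb.
#' The kernel is causal (zero before the stimulus). The evoked tHb change
#' is split between the chromophores: a fraction \code{hbo2_share} goes to
#' HbO2 and the remainder to HHb, reflecting the empirical pattern of
#' blood-volume/HbO2 increases with comparatively flat HHb.
#'
#' Amplitudes are keyed by (modality, epoch, paradigm). Defaults encode the
#' condition structure under study: a +14\% response to real pulses after
#' cTBS, no response to real pulses before TBS or after iTBS, and no
#' response to sham pulses anywhere.
#'
#' @param amplitudes Data frame with columns \code{modality}, \code{epoch},
#'   \code{paradigm}, \code{amplitude} (peak \% of baseline tHb). Conditions
#'   not listed default to amplitude 0.
#' @param peak_latency Kernel mode in s after the stimulus.
#' @param dispersion Kernel standard deviation in s.
#' @param hbo2_share Fraction of the evoked tHb change assigned to HbO2.
#' @return An object of class \code{hrf_model}.
#' @export
hrf_model <- function(amplitudes = NULL, peak_latency = 3.5, dispersion = 1.5,
                      hbo2_share = 0.8) {
  if (is.null(amplitudes))
    amplitudes <- data.frame(modality = "real", epoch = "post",
                             paradigm = "cTBS", amplitude = 14,
                             stringsAsFactors = FALSE)
  stopifnot(all(c("modality", "epoch", "paradigm", "amplitude") %in%
                  names(amplitudes)),
            peak_latency > 0, dispersion > 0,
            hbo2_share >= 0, hbo2_share <= 1)
  # gamma with mode = peak_latency, sd = dispersion:
  #   scale^2 + peak_latency*scale - dispersion^2 = 0
  scale <- (-peak_latency + sqrt(peak_latency^2 + 4 * dispersion^2)) / 2
  shape <- peak_latency / scale + 1
  out <- list(amplitudes = amplitudes, peak_latency = peak_latency,
              dispersion = dispersion, hbo2_share = hbo2_share,
              shape = shape, scale = scale)
  class(out) <- "hrf_model"
  out
}

#' Evaluate the evoked-response kernel
#'
#' @param hrf An \code{hrf_model}.
#' @param t Times in s relative to the stimulus.
#' @return Kernel values, peak-normalized to 1; 0 for \code{t < 0}.
#' @export
hrf_kernel <- function(hrf, t) {
  peak <- stats::dgamma(hrf$peak_latency, shape = hrf$shape, scale = hrf$scale)
  k <- stats::dgamma(pmax(t, 0), shape = hrf$shape, scale = hrf$scale) / peak
  k[t < 0] <- 0
  k
}

# amplitude (% of baseline tHb) for one event under an hrf_model
hrf_amplitude <- function(hrf, modality, epoch, paradigm) {
  a <- hrf$amplitudes
  hit <- a$modality == modality & a$epoch == epoch & a$paradigm == paradigm
  if (any(hit)) a$amplitude[which(hit)[1]] else 0
}

#' Physiological and instrument noise model
#'
#' Describes every stochastic nuisance component of a synthetic session:
#' three physiological oscillations (cardiac, respiratory, Mayer waves) as
#' sinusoids with session-random phase whose amplitudes are percent of
#' baseline tHb, a random-walk drift on each chromophore, multiplicative
#' instrument noise on the DC/AC intensities, additive phase noise, and
#' occasional motion artifacts (Poisson onsets) that scramble the measured
#' intensities channel by channel. Setting every field to 0 yields a
#' noise-free recording.
#'
#' @param cardiac,respiratory,mayer Length-2 vectors \code{c(freq_hz, amp_pct)};
#'   amplitude is percent of baseline tHb.
#' @param drift_sd Random-walk step SD per sample, in uM, applied
#'   independently to HbO2 and HHb.
#' @param optical_sd Relative SD of multiplicative noise on IDC and IAC.
#' @param phase_sd Additive phase noise SD in radians.
#' @param motion_rate Motion artifacts per minute (Poisson).
#' @param motion_magnitude Multiplicative excursion bound: within an
#'   artifact window each channel's intensities are scaled by a factor drawn
#'   log-uniformly in \code{[1/m, m]} and its phase offset by up to 0.5 rad.
#' @param motion_duration Artifact duration in s.
#' @return An object of class \code{noise_model}.
#' @export
noise_model <- function(cardiac = c(1.1, 1.0), respiratory = c(0.25, 0.5),
                        mayer = c(0.1, 0.5), drift_sd = 0.01,
                        optical_sd = 0.01, phase_sd = 0.005,
                        motion_rate = 0.1, motion_magnitude = 2,
                        motion_duration = 1) {
  stopifnot(drift_sd >= 0, optical_sd >= 0, phase_sd >= 0,
            motion_rate >= 0, motion_magnitude >= 1, motion_duration >= 0,
            cardiac[2] >= 0, respiratory[2] >= 0, mayer[2] >= 0)
  out <- list(cardiac = cardiac, respiratory = respiratory, mayer = mayer,
              drift_sd = drift_sd, optical_sd = optical_sd,
              phase_sd = phase_sd, motion_rate = motion_rate,
              motion_magnitude = motion_magnitude,
              motion_duration = motion_duration)
  class(out) <- "noise_model"
  out
}

#' @rdname noise_model
#' @export
noise_model_silent <- function() {
  noise_model(cardiac = c(1.1, 0), respiratory = c(0.25, 0), mayer = c(0.1, 0),
              drift_sd = 0, optical_sd = 0, phase_sd = 0,
              motion_rate = 0, motion_magnitude = 1, motion_duration = 0)
}

#' Simulate ground-truth chromophore concentrations for a session
#'
#' Builds the tissue's HbO2 and HHb concentration time series on the
#' recording sample grid: baseline plus the condition-dependent evoked
#' response after every scheduled stimulus, plus physiological oscillations
#' and random-walk drift. Oscillations and evoked responses act on total
#' hemoglobin and are split between chromophores by the model's HbO2 share.
#'
#' @param schedule A \code{session_schedule}.
#' @param hrf An \code{hrf_model}.
#' @param noise A \code{noise_model}; only its physiological components
#'   (oscillations, drift) act here. Optical noise and motion artifacts are
#'   applied by \code{\link{forward_fd}}.
#' @param baseline Named vector \code{c(HbO2 = , HHb = )} in uM.
#' @param musp Ground-truth reduced scattering coefficients (1/cm), one per
#'   wavelength, constant in time.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed; defaults to the schedule's seed.
#' @param tail Seconds of recording kept after the last event.
#' @return An object of class \code{tissue_state}: time grid, per-sample
#'   \code{C_HbO2}, \code{C_HHb} (uM), baselines, \code{musp}, \code{fs},
#'   and the schedule.
#' @export
simulate_chromophores <- function(schedule, hrf = hrf_model(),
                                  noise = noise_model(),
                                  baseline = c(HbO2 = 60, HHb = 25),
                                  musp = c(8, 7), fs = 10.4,
                                  seed = schedule$seed, tail = 60) {
  stopifnot(inherits(schedule, "session_schedule"), fs > 0,
            all(baseline > 0), all(musp > 0))
  ev <- schedule$events
  duration <- max(ev$onset) + tail
  n <- ceiling(duration * fs)
  time <- (seq_len(n) - 1) / fs
  base_thb <- sum(baseline)

  # evoked tHb change in uM
  evoked <- numeric(n)
  support <- seq(0, 15, by = 1 / fs)
  for (i in seq_len(nrow(ev))) {
    a <- hrf_amplitude(hrf, ev$modality[i], ev$epoch[i], ev$paradigm[i])
    if (a == 0) next
    i0 <- round(ev$onset[i] * fs) + 1
    idx <- i0 + seq_along(support) - 1
    keep <- idx <= n
    evoked[idx[keep]] <- evoked[idx[keep]] +
      (a / 100) * base_thb * hrf_kernel(hrf, time[idx[keep]] - ev$onset[i])
  }

  set.seed(derive_seed(seed, 2L))
  osc <- numeric(n)
  for (comp in list(noise$cardiac, noise$respiratory, noise$mayer)) {
    if (comp[2] > 0)
      osc <- osc + (comp[2] / 100) * base_thb *
        sin(2 * pi * comp[1] * time + stats::runif(1, 0, 2 * pi))
  }
  drift_hbo2 <- if (noise$drift_sd > 0) cumsum(stats::rnorm(n, 0, noise$drift_sd)) else numeric(n)
  drift_hhb  <- if (noise$drift_sd > 0) cumsum(stats::rnorm(n, 0, noise$drift_sd)) else numeric(n)

  thb_change <- evoked + osc
  C_HbO2 <- baseline[["HbO2"]] + hrf$hbo2_share * thb_change + drift_hbo2
  C_HHb  <- baseline[["HHb"]] + (1 - hrf$hbo2_share) * thb_change + drift_hhb
  if (any(C_HbO2 <= 0) || any(C_HHb <= 0))
    stop(sprintf(paste("simulated concentrations become non-positive",
                       "(min HbO2 %.3g uM, min HHb %.3g uM);",
                       "reduce amplitudes/noise or raise baselines"),
                 min(C_HbO2), min(C_HHb)))

  out <- list(time = time, C_HbO2 = unname(C_HbO2), C_HHb = unname(C_HHb),
              baseline = baseline, musp = musp, fs = fs,
              schedule = schedule, seed = seed)
  class(out) <- "tissue_state"
  out
}

#' Ground-truth chromophore series of a tissue state
#'
#' Repackages the simulated concentrations as a \code{chromophore_series}
#' (all samples valid), bypassing the optical forward/inverse stage. Useful
#' for testing downstream stages against ground truth.
#'
#' @param tissue A \code{tissue_state}.
#' @return A \code{chromophore_series}.
#' @export
as_chromophore_series <- function(tissue) {
  stopifnot(inherits(tissue, "tissue_state"))
  out <- data.frame(time = tissue$time, HbO2 = tissue$C_HbO2,
                    HHb = tissue$C_HHb,
                    tHb = tissue$C_HbO2 + tissue$C_HHb, valid = TRUE)
  attr(out, "fs") <- tissue$fs
  attr(out, "meta") <- list(subject = tissue$schedule$subject_id,
                            paradigm = tissue$schedule$paradigm,
                            artifact_windows = matrix(numeric(0), ncol = 2))
  class(out) <- c("chromophore_series", "data.frame")
  out
}

#' @export
print.tissue_state <- function(x, ...) {
  cat(sprintf("tissue_state: %d samples at %.1f Hz (%.1f s)\n",
              length(x$time), x$fs, max(x$time)))
  cat(sprintf("  baseline HbO2 %.1f uM, HHb %.1f uM; musp %s 1/cm\n",
              x$baseline[["HbO2"]], x$baseline[["HHb"]],
              paste(x$musp, collapse = "/")))
  invisible(x)
}
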