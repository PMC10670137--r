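#' Photon-density-wave attenuation wavenumbers
#'
#' Real and imaginary parts of the complex attenuation of an intensity-
#' modulated photon density wave in a homogeneous medium, defined by
#' \deqn{kr^2 - ki^2 = 3 \mu_a (\mu_a + \mu_s'), \quad
#'       2 kr ki = 3 (\mu_a + \mu_s') \omega / v.}
#' The AC amplitude decays as \code{exp(-kr r)/r^2} and the phase grows as
#' \code{ki r}; the DC attenuation coefficient is
#' \code{k0 = sqrt(3 mua (mua + musp))}.
#'
#' @param mua Absorption coefficient(s), 1/cm.
#' @param musp Reduced scattering coefficient(s), 1/cm.
#' @param omega Angular modulation frequency, rad/s.
#' @param v Speed of light in the medium, cm/s.
#' @return List with vectors \code{kr}, \code{ki}, \code{k0} (1/cm).
#' @export
fd_wavenumbers <- function(mua, musp, omega, v) {
  if (any(mua <= 0) || any(musp <= 0))
    stop("mua and musp must be positive")
  D <- 3 * mua * (mua + musp)
  E <- 3 * (mua + musp) * omega / v
  kr <- sqrt((D + sqrt(D^2 + E^2)) / 2)
  ki <- E / (2 * kr)
  list(kr = kr, ki = ki, k0 = sqrt(D))
}

#' Forward frequency-domain multi-distance measurement
#'
#' Turns a ground-truth tissue state into the raw quantities an FDMD-NIRS
#' instrument records: DC intensity, AC modulation amplitude, and phase at
#' every sample, wavelength and source-detector distance. Absorption at each
#' wavelength follows from the chromophore concentrations through the
#' extinction table; the photon-density-wave model then gives
#' \code{IAC(r) = A exp(-kr r) / r^2}, \code{phase(r) = ki r + phi0} and
#' \code{IDC(r) = A_DC exp(-k0 r) / r^2}, so the log-distance-weighted
#' intensities and the phase are exactly linear in \code{r}. Instrument
#' noise is applied multiplicatively to the intensities and additively to
#' the phase; motion artifacts scramble whole channels inside Poisson-placed
#' windows which are recorded as ground-truth labels in \code{meta}.
#'
#' @param tissue A \code{tissue_state}.
#' @param geometry An \code{fd_geometry} (wavelength count must match the
#'   extinction table and \code{tissue$musp}).
#' @param extinction An \code{extinction_table}.
#' @param noise A \code{noise_model}; only its optical components act here.
#' @param seed Integer seed; defaults to the tissue seed.
#' @param source_amplitude AC source amplitude constant (arbitrary units).
#' @param dc_amplitude DC source amplitude constant.
#' @return An object of class \code{fd_recording}: \code{time}, arrays
#'   \code{IDC}, \code{IAC}, \code{phase} of dim (samples, wavelengths,
#'   distances), \code{geometry}, \code{fs}, and \code{meta} (subject,
#'   paradigm, artifact windows).
#' @export
forward_fd <- function(tissue, geometry = fd_geometry(),
                       extinction = extinction_table(),
                       noise = noise_model(), seed = tissue$seed,
                       source_amplitude = 1e6, dc_amplitude = 1e7) {
  stopifnot(inherits(tissue, "tissue_state"), inherits(geometry, "fd_geometry"))
  nw <- length(geometry$wavelengths)
  if (nrow(extinction) != nw)
    stop("extinction table rows must match geometry wavelengths")
  if (length(tissue$musp) != nw)
    stop("tissue musp must hold one value per wavelength")
  n <- length(tissue$time)
  r <- geometry$distances
  nd <- length(r)

  IDC <- array(NA_real_, dim = c(n, nw, nd))
  IAC <- array(NA_real_, dim = c(n, nw, nd))
  phase <- array(NA_real_, dim = c(n, nw, nd))
  C_mM <- cbind(tissue$C_HbO2, tissue$C_HHb) / 1000  # uM -> mM
  for (w in seq_len(nw)) {
    mua <- log(10) * (C_mM %*% unclass(extinction)[w, ])[, 1]
    if (any(mua <= 0)) stop("non-positive absorption encountered")
    k <- fd_wavenumbers(mua, tissue$musp[w], geometry$omega, geometry$speed)
    for (d in seq_len(nd)) {
      IAC[, w, d] <- source_amplitude * exp(-k$kr * r[d]) / r[d]^2
      IDC[, w, d] <- dc_amplitude * exp(-k$k0 * r[d]) / r[d]^2
      phase[, w, d] <- k$ki * r[d]
    }
  }

  artifact_windows <- matrix(numeric(0), ncol = 2,
                             dimnames = list(NULL, c("start", "end")))
  if (noise$optical_sd > 0 || noise$phase_sd > 0 || noise$motion_rate > 0) {
    set.seed(derive_seed(seed, 3L))
    if (noise$optical_sd > 0) {
      IAC <- IAC * (1 + stats::rnorm(length(IAC), 0, noise$optical_sd))
      IDC <- IDC * (1 + stats::rnorm(length(IDC), 0, noise$optical_sd))
    }
    if (noise$phase_sd > 0)
      phase <- phase + stats::rnorm(length(phase), 0, noise$phase_sd)
    if (noise$motion_rate > 0 && noise$motion_duration > 0) {
      duration_min <- max(tissue$time) / 60
      n_art <- stats::rpois(1, noise$motion_rate * duration_min)
      if (n_art > 0) {
        starts <- sort(stats::runif(n_art, 0, max(tissue$time)))
        ends <- pmin(starts + noise$motion_duration, max(tissue$time))
        artifact_windows <- cbind(start = starts, end = ends)
        lm_ <- log(noise$motion_magnitude)
        for (a in seq_len(n_art)) {
          idx <- which(tissue$time >= starts[a] & tissue$time <= ends[a])
          if (!length(idx)) next
          for (w in seq_len(nw)) for (d in seq_len(nd)) {
            fac <- exp(stats::runif(1, -lm_, lm_))
            IAC[idx, w, d] <- IAC[idx, w, d] * fac
            IDC[idx, w, d] <- IDC[idx, w, d] * fac
            phase[idx, w, d] <- phase[idx, w, d] + stats::runif(1, -0.5, 0.5)
          }
        }
      }
    }
  }

  out <- list(time = tissue$time, IDC = IDC, IAC = IAC, phase = phase,
              geometry = geometry, fs = tissue$fs,
              meta = list(subject = tissue$schedule$subject_id,
                          paradigm = tissue$schedule$paradigm,
                          seed = seed,
                          artifact_windows = artifact_windows))
  class(out) <- "fd_recording"
  out
}

#' @export
print.fd_recording <- function(x, ...) {
  d <- dim(x$IAC)
  cat(sprintf("fd_recording: %d samples x %d wavelengths x %d distances at %.1f Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  subject %s, paradigm %s, %d labeled artifact window(s)\n",
              x$meta$subject %||% "?", x$meta$paradigm %||% "?",
              nrow(x$meta$artifact_windows)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a complete synthetic session
#'
#' Convenience wrapper chaining \code{\link{make_session_schedule}},
#' \code{\link{simulate_chromophores}} and \code{\link{forward_fd}} from one
#' seed.
#'
#' @inheritParams make_session_schedule
#' @inheritParams simulate_chromophores
#' @inheritParams forward_fd
#' @return List with \code{schedule}, \code{tissue} and \code{recording}.
#' @export
simulate_session <- function(paradigm = "cTBS", subject_id = "s01", seed = 1L,
                             hrf = hrf_model(), noise = noise_model(),
                             baseline = c(HbO2 = 60, HHb = 25),
                             musp = c(8, 7), fs = 10.4,
                             geometry = fd_geometry(),
                             extinction = extinction_table(), ...) {
  schedule <- make_session_schedule(paradigm, subject_id, seed, ...)
  tissue <- simulate_chromophores(schedule, hrf, noise, baseline, musp, fs)
  recording <- forward_fd(tissue, geometry, extinction, noise)
  list(schedule = schedule, tissue = tissue, recording = recording)
}
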