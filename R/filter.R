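#' Design the Hanning windowed-sinc bandpass kernel
#'
#' Linear-phase FIR bandpass built as the difference of two windowed-sinc
#' lowpass kernels, tapered by a Hanning window. The passband 0.02-0.7 Hz
#' keeps the evoked hemodynamic band while removing slow baseline drift
#' (below 0.02 Hz) and cardiac pulsation (around 1.1 Hz). The kernel is
#' symmetric (zero-phase when applied centered) and its gain is normalized
#' to 1 at the geometric mean of the two cutoffs.
#'
#' @param low_cut,high_cut Passband edges in Hz.
#' @param taps Odd kernel length in samples.
#' @param fs Sampling rate in Hz.
#' @return Numeric kernel of class \code{fir_kernel} with attributes
#'   \code{fs}, \code{low_cut}, \code{high_cut}.
#' @export
design_bandpass <- function(low_cut = 0.02, high_cut = 0.7, taps = 1001,
                            fs = 10.4) {
  if (taps %% 2 != 1) stop("taps must be odd (symmetric, linear-phase kernel)")
  if (!(low_cut > 0 && low_cut < high_cut && high_cut < fs / 2))
    stop("cutoffs must satisfy 0 < low_cut < high_cut < fs/2")
  m <- (taps - 1) / 2
  k <- -m:m
  sinc <- function(fc) {
    x <- 2 * fc / fs
    ifelse(k == 0, x, sin(pi * x * k) / (pi * k))
  }
  hann <- 0.5 + 0.5 * cos(pi * k / m)
  h <- (sinc(high_cut) - sinc(low_cut)) * hann
  h <- h - mean(h)   # exact DC rejection (symmetric constant offset)
  f0 <- sqrt(low_cut * high_cut)
  h <- h / sum(h * cos(2 * pi * f0 * k / fs))
  structure(h, class = "fir_kernel", fs = fs,
            low_cut = low_cut, high_cut = high_cut)
}

#' Frequency response magnitude of an FIR kernel
#'
#' @param kernel A \code{fir_kernel} (or plain numeric kernel).
#' @param freqs Frequencies in Hz.
#' @param fs Sampling rate; defaults to the kernel's.
#' @return Gain magnitude at each frequency.
#' @export
filter_gain <- function(kernel, freqs, fs = attr(kernel, "fs")) {
  h <- as.numeric(kernel)
  m <- (length(h) - 1) / 2
  k <- seq_along(h) - 1 - m
  vapply(freqs, function(f) abs(sum(h * exp(-2i * pi * f * k / fs))), 0)
}

#' Zero-phase bandpass filtering of a chromophore series
#'
#' Applies the symmetric kernel by centered convolution with reflection
#' padding, which is zero-phase for a symmetric kernel. Invalid samples are
#' linearly interpolated before filtering so they cannot poison their
#' neighborhood, and the validity mask is then dilated by half the kernel
#' width around every invalid run, marking everything the interpolated
#' values could have touched. Total hemoglobin is re-derived as the sum of
#' the filtered HbO2 and HHb so the additivity identity survives filtering.
#' The first and last half-kernel of samples sit on reflected padding; their
#' extent is stored as attribute \code{edge_halfwidth} and downstream
#' segmentation flags windows that touch it.
#'
#' @param series A \code{chromophore_series}.
#' @param kernel A \code{fir_kernel} from \code{\link{design_bandpass}}.
#' @return A filtered \code{chromophore_series} (band-passed signals are
#'   zero-mean changes, still in uM).
#' @export
apply_filter <- function(series, kernel) {
  stopifnot(inherits(series, "chromophore_series"))
  h <- as.numeric(kernel)
  n <- nrow(series)
  if (n <= length(h))
    stop(sprintf("series (%d samples) must be longer than the kernel (%d taps)",
                 n, length(h)))
  hw <- (length(h) - 1) / 2

  interp_na <- function(x) {
    if (!anyNA(x)) return(x)
    ok <- which(!is.na(x))
    if (!length(ok)) return(rep(0, length(x)))
    stats::approx(ok, x[ok], xout = seq_along(x), rule = 2)$y
  }
  nfft <- stats::nextn(n + 4 * hw, 2)
  H <- stats::fft(c(h, rep(0, nfft - length(h))))
  conv0 <- function(x) {
    # reflection padding + FFT convolution, centered (zero phase)
    xp <- c(rev(x[2:(hw + 1)]), x, rev(x[(length(x) - hw):(length(x) - 1)]))
    y <- Re(stats::fft(stats::fft(c(xp, rep(0, nfft - length(xp)))) * H,
                       inverse = TRUE)) / nfft
    y[(2 * hw + 1):(2 * hw + length(x))]
  }

  hbo2 <- conv0(interp_na(series$HbO2))
  hhb <- conv0(interp_na(series$HHb))

  valid <- series$valid
  if (any(!valid)) {
    bad <- which(!valid)
    lo <- pmax(bad - hw, 1L)
    hi <- pmin(bad + hw, n)
    dil <- rep(TRUE, n)
    for (i in seq_along(bad)) dil[lo[i]:hi[i]] <- FALSE
    valid <- dil
  }

  out <- data.frame(time = series$time, HbO2 = hbo2, HHb = hhb,
                    tHb = hbo2 + hhb, valid = valid)
  for (a in c("fs", "meta")) attr(out, a) <- attr(series, a)
  attr(out, "edge_halfwidth") <- hw
  attr(out, "filtered") <- TRUE
  # absolute concentration level removed by the bandpass; segmentation uses
  # it as the denominator of percent-of-baseline normalization
  vv <- series$valid & is.finite(series$HbO2) & is.finite(series$HHb)
  lv <- if (any(vv)) c(HbO2 = mean(series$HbO2[vv]), HHb = mean(series$HHb[vv]))
        else c(HbO2 = NA_real_, HHb = NA_real_)
  attr(out, "level") <- c(lv, tHb = unname(lv["HbO2"] + lv["HHb"]))
  class(out) <- c("chromophore_series", "data.frame")
  out
}
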