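# Shared fixtures and independent oracles, all built in code.

# chromophore_series from raw vectors
make_series <- function(HbO2, HHb, fs = 10.4, valid = TRUE,
                        meta = list(subject = "t01", paradigm = "cTBS",
                                    artifact_windows = matrix(numeric(0),
                                                              ncol = 2))) {
  n <- length(HbO2)
  out <- data.frame(time = (seq_len(n) - 1) / fs, HbO2 = HbO2, HHb = HHb,
                    tHb = HbO2 + HHb, valid = rep_len(valid, n))
  attr(out, "fs") <- fs
  attr(out, "meta") <- meta
  class(out) <- c("chromophore_series", "data.frame")
  out
}

# fd_recording from explicit channel arrays
make_recording <- function(IAC, IDC, phase, geometry = fd_geometry(),
                           fs = 10.4, meta = list()) {
  n <- dim(IAC)[1]
  out <- list(time = (seq_len(n) - 1) / fs, IDC = IDC, IAC = IAC,
              phase = phase, geometry = geometry, fs = fs, meta = meta)
  class(out) <- "fd_recording"
  out
}

# noise-free recording at constant optical properties (per wavelength)
recording_at <- function(mua, musp, geometry = fd_geometry(), n = 1,
                         A = 1e6, A_dc = 1e7) {
  nw <- length(mua)
  nd <- length(geometry$distances)
  IAC <- IDC <- phase <- array(NA_real_, c(n, nw, nd))
  for (w in seq_len(nw)) {
    k <- fd_wavenumbers(mua[w], musp[w], geometry$omega, geometry$speed)
    for (d in seq_len(nd)) {
      r <- geometry$distances[d]
      IAC[, w, d] <- A * exp(-k$kr * r) / r^2
      IDC[, w, d] <- A_dc * exp(-k$k0 * r) / r^2
      phase[, w, d] <- k$ki * r
    }
  }
  make_recording(IAC, IDC, phase, geometry)
}

# Independent oracle: solve the two attenuation equations
#   kr^2 - ki^2 = 3 mua (mua + musp)
#   2 kr ki     = 3 (mua + musp) omega / v
# for (mua, musp) numerically from observed (kr, ki), without the
# closed-form inversion.
oracle_invert <- function(kr, ki, omega, v) {
  fn <- function(p) {
    mua <- exp(p[1]); musp <- exp(p[2])
    (kr^2 - ki^2 - 3 * mua * (mua + musp))^2 +
      (2 * kr * ki - 3 * (mua + musp) * omega / v)^2
  }
  fit <- stats::optim(c(log(0.1), log(10)), fn,
                      control = list(reltol = 1e-16, maxit = 5000))
  fit <- stats::optim(fit$par, fn,
                      control = list(reltol = 1e-16, maxit = 5000))
  list(mua = exp(fit$par[1]), musp = exp(fit$par[2]), value = fit$value)
}

# textbook OLS on (x, y): slope, intercept, R^2
oracle_ols <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  intercept <- yb - slope * xb
  ssr <- sum((y - intercept - slope * x)^2)
  sst <- sum((y - yb)^2)
  list(slope = slope, intercept = intercept, r2 = 1 - ssr / sst)
}

# filter gain measured independently: RMS ratio of a filtered sinusoid
measured_gain <- function(kernel, freq, fs = 10.4, n = 12000) {
  x <- sin(2 * pi * freq * (seq_len(n) - 1) / fs)
  s <- make_series(HbO2 = x, HHb = rep(0, n), fs = fs)
  y <- apply_filter(s, kernel)$HbO2
  core <- seq(length(kernel), n - length(kernel))
  sqrt(mean(y[core]^2) / mean(x[core]^2))
}

# events data.frame for direct segmentation tests
make_events <- function(onsets, modality = "real", epoch = "post",
                        paradigm = "cTBS", block = 1L) {
  data.frame(onset = onsets,
             modality = rep_len(modality, length(onsets)),
             epoch = rep_len(epoch, length(onsets)),
             block = rep_len(block, length(onsets)),
             paradigm = rep_len(paradigm, length(onsets)),
             stringsAsFactors = FALSE)
}
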