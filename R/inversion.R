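#' Multi-distance slope fits of raw FD signals
#'
#' At every sample and wavelength, ordinary least squares fits of
#' \code{ln(r^2 IAC)}, \code{ln(r^2 IDC)} and phase against source-detector
#' distance \code{r}. The slopes (SAC, SDC, Sphase), intercepts and the
#' coefficient of determination R^2 of each fit are returned; R^2 of the
#' amplitude and phase fits feeds the quality gate. Phase is unwrapped
#' across distances before fitting (adjacent-distance jumps are assumed
#' below pi). Samples with a non-positive intensity at any distance are
#' returned as NA rather than raising an error.
#'
#' R^2 of a zero-variance response is defined as 0, so flat-line channels
#' fail the quality gate instead of passing it vacuously.
#'
#' @param recording An \code{fd_recording}.
#' @return An object of class \code{slope_series}: list of arrays
#'   (samples x wavelengths) \code{SAC}, \code{CAC}, \code{R2_AC},
#'   \code{SDC}, \code{CDC}, \code{R2_DC}, \code{Sphase}, \code{Cphase},
#'   \code{R2_phase}, plus OLS slope p-values \code{p_AC}, \code{p_phase}
#'   as diagnostics.
#' @export
fit_multidistance <- function(recording) {
  stopifnot(inherits(recording, "fd_recording"))
  r <- recording$geometry$distances
  n <- dim(recording$IAC)[1]
  nw <- dim(recording$IAC)[2]
  nd <- length(r)
  if (nd < 3) stop("at least 3 distances are required")

  nm <- c("SAC", "CAC", "R2_AC", "p_AC", "SDC", "CDC", "R2_DC",
          "Sphase", "Cphase", "R2_phase", "p_phase")
  out <- stats::setNames(rep(list(matrix(NA_real_, n, nw)), length(nm)), nm)

  rc <- r - mean(r)
  sxx <- sum(rc^2)
  for (w in seq_len(nw)) {
    iac <- recording$IAC[, w, , drop = TRUE]
    idc <- recording$IDC[, w, , drop = TRUE]
    ph <- recording$phase[, w, , drop = TRUE]
    if (n == 0) next
    if (is.null(dim(iac))) { iac <- matrix(iac, 1); idc <- matrix(idc, 1); ph <- matrix(ph, 1) }
    ok <- rowSums(iac > 0) == nd & rowSums(idc > 0) == nd &
      rowSums(is.finite(iac) & is.finite(idc) & is.finite(ph)) == nd
    ok[is.na(ok)] <- FALSE
    # unwrap phase across distances
    if (nd > 1) {
      for (d in 2:nd) {
        jump <- ph[, d] - ph[, d - 1]
        ph[, d] <- ph[, d] - 2 * pi * round(jump / (2 * pi))
      }
    }
    iac[!ok, ] <- NA_real_
    idc[!ok, ] <- NA_real_
    yac <- log(sweep(iac, 2, r^2, `*`))
    ydc <- log(sweep(idc, 2, r^2, `*`))
    fits <- lapply(list(AC = yac, DC = ydc, phase = ph), function(y) {
      y[!ok, ] <- NA_real_
      ybar <- rowMeans(y)
      slope <- (y %*% rc)[, 1] / sxx
      intercept <- ybar - slope * mean(r)
      res <- y - outer(slope, r) - intercept
      ssr <- rowSums(res^2)
      sst <- rowSums((y - ybar)^2)
      r2 <- ifelse(sst > 0, 1 - ssr / sst, 0)
      r2 <- pmin(pmax(r2, 0), 1)
      se <- sqrt(pmax(ssr, 0) / (nd - 2) / sxx)
      tval <- ifelse(se > 0, slope / se, ifelse(slope == 0, 0, Inf))
      p <- 2 * stats::pt(-abs(tval), df = nd - 2)
      list(slope = slope, intercept = intercept, r2 = r2, p = p)
    })
    out$SAC[, w] <- fits$AC$slope;    out$CAC[, w] <- fits$AC$intercept
    out$R2_AC[, w] <- fits$AC$r2;     out$p_AC[, w] <- fits$AC$p
    out$SDC[, w] <- fits$DC$slope;    out$CDC[, w] <- fits$DC$intercept
    out$R2_DC[, w] <- fits$DC$r2
    out$Sphase[, w] <- fits$phase$slope; out$Cphase[, w] <- fits$phase$intercept
    out$R2_phase[, w] <- fits$phase$r2;  out$p_phase[, w] <- fits$phase$p
  }
  out$wavelengths <- recording$geometry$wavelengths
  class(out) <- "slope_series"
  out
}

#' Invert AC and phase slopes to optical properties
#'
#' Closed-form multi-distance frequency-domain inversion from the AC
#' amplitude slope and the phase slope. With \code{a = |SAC|}:
#' \deqn{\mu_a = \frac{\omega}{2v}\left(\frac{a}{S_{phase}} -
#'       \frac{S_{phase}}{a}\right), \qquad
#'       \mu_s' = \frac{a^2 - S_{phase}^2}{3\mu_a} - \mu_a.}
#' Samples violating the physical preconditions (\code{SAC >= 0},
#' \code{Sphase <= 0}, or \code{a <= Sphase}, which would give a
#' non-positive absorption) come back as NA.
#'
#' @param SAC AC amplitude slope(s), 1/cm (negative on valid samples).
#' @param Sphase Phase slope(s), rad/cm (positive on valid samples).
#' @param omega Angular modulation frequency, rad/s.
#' @param v Speed of light in tissue, cm/s.
#' @return List of vectors \code{mua}, \code{musp} (1/cm), NA where invalid.
#' @export
invert_optical <- function(SAC, Sphase, omega, v) {
  a <- -SAC
  bad <- !is.finite(a) | !is.finite(Sphase) | a <= 0 | Sphase <= 0 | a <= Sphase
  a[bad] <- NA_real_
  mua <- (omega / (2 * v)) * (a / Sphase - Sphase / a)
  musp <- (a^2 - Sphase^2) / (3 * mua) - mua
  bad2 <- bad | !is.finite(mua) | !is.finite(musp) | mua <= 0 | musp <= 0
  mua[bad2] <- NA_real_
  musp[bad2] <- NA_real_
  list(mua = mua, musp = musp)
}

#' Solve two-wavelength absorption for chromophore concentrations
#'
#' Solves the 2x2 linear system
#' \code{mua(lambda) = ln(10) * sum_c eps_c(lambda) * C_c}
#' for HbO2 and HHb. Input absorption in 1/cm; output concentrations in uM.
#'
#' @param mua Matrix (samples x wavelengths) or vector of absorption
#'   coefficients, columns ordered as the extinction table rows.
#' @param extinction An \code{extinction_table}.
#' @return List of vectors \code{C_HbO2}, \code{C_HHb} in uM (NA where any
#'   wavelength's absorption is NA).
#' @export
solve_chromophores <- function(mua, extinction = extinction_table()) {
  E <- unclass(extinction)
  if (is.null(dim(mua))) mua <- matrix(mua, ncol = nrow(E))
  if (ncol(mua) != nrow(E))
    stop("mua must have one column per extinction-table wavelength")
  Minv <- solve(log(10) * E)           # mM per (1/cm)
  C <- mua %*% t(Minv) * 1000          # -> uM
  list(C_HbO2 = C[, 1], C_HHb = C[, 2])
}

#' Per-sample quality gate on the slope fits
#'
#' A sample is valid only if the R^2 of both the AC amplitude fit and the
#' phase fit reaches the threshold at every wavelength (the chromophore
#' solve needs both wavelengths). The DC fit's R^2 is reported as a
#' diagnostic but not gated. NA fits fail the gate.
#'
#' @param slopes A \code{slope_series}.
#' @param threshold R^2 threshold (default 0.97).
#' @return Logical vector, one entry per sample.
#' @export
qc_mask <- function(slopes, threshold = 0.97) {
  stopifnot(inherits(slopes, "slope_series"), threshold >= 0, threshold <= 1)
  ok <- slopes$R2_AC >= threshold & slopes$R2_phase >= threshold
  ok[is.na(ok)] <- FALSE
  rowSums(ok) == ncol(slopes$R2_AC)
}

#' Invert a raw FD recording to hemoglobin time series
#'
#' The per-sample pipeline: multi-distance slope fits, R^2 quality gate,
#' slope-to-optical-properties inversion, and the two-wavelength chromophore
#' solve. Total hemoglobin (the blood-volume proxy) is the exact per-sample
#' sum of HbO2 and HHb. Samples failing the gate, or whose inversion is
#' unphysical at either wavelength, are flagged invalid and carry NA
#' concentrations.
#'
#' @param recording An \code{fd_recording}.
#' @param extinction An \code{extinction_table}.
#' @param threshold R^2 gate threshold.
#' @return An object of class \code{chromophore_series}: data.frame with
#'   columns \code{time}, \code{HbO2}, \code{HHb}, \code{tHb} (uM) and
#'   \code{valid}; attributes \code{slopes} (the \code{slope_series}),
#'   \code{optical} (per-wavelength \code{mua}/\code{musp} matrices),
#'   \code{fs} and \code{meta} carried from the recording.
#' @export
invert_recording <- function(recording, extinction = extinction_table(),
                             threshold = 0.97) {
  stopifnot(inherits(recording, "fd_recording"))
  slopes <- fit_multidistance(recording)
  n <- dim(recording$IAC)[1]
  nw <- dim(recording$IAC)[2]
  g <- recording$geometry

  mua <- musp <- matrix(NA_real_, n, nw)
  for (w in seq_len(nw)) {
    op <- invert_optical(slopes$SAC[, w], slopes$Sphase[, w], g$omega, g$speed)
    mua[, w] <- op$mua
    musp[, w] <- op$musp
  }
  valid <- qc_mask(slopes, threshold) & rowSums(is.finite(mua)) == nw
  conc <- solve_chromophores(mua, extinction)
  HbO2 <- ifelse(valid, conc$C_HbO2, NA_real_)
  HHb <- ifelse(valid, conc$C_HHb, NA_real_)

  out <- data.frame(time = recording$time, HbO2 = HbO2, HHb = HHb,
                    tHb = HbO2 + HHb, valid = valid)
  attr(out, "slopes") <- slopes
  attr(out, "optical") <- list(mua = mua, musp = musp)
  attr(out, "fs") <- recording$fs
  attr(out, "meta") <- recording$meta
  class(out) <- c("chromophore_series", "data.frame")
  out
}

#' @export
print.chromophore_series <- function(x, ...) {
  cat(sprintf("chromophore_series: %d samples, %.1f%% valid\n",
              nrow(x), if (nrow(x)) 100 * mean(x$valid) else NA_real_))
  if (nrow(x) && any(x$valid))
    cat(sprintf("  median HbO2 %.1f uM, HHb %.1f uM, tHb %.1f uM\n",
                stats::median(x$HbO2[x$valid]), stats::median(x$HHb[x$valid]),
                stats::median(x$tHb[x$valid])))
  invisible(x)
}

#' @export
plot.chromophore_series <- function(x, which = c("HbO2", "HHb", "tHb"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  cols <- c(HbO2 = "firebrick", HHb = "navy", tHb = "darkgreen")
  graphics::matplot(x$time, as.matrix(x[, which, drop = FALSE]), type = "l",
                    lty = 1, col = cols[which], xlab = "time [s]",
                    ylab = "concentration [uM]", ...)
  graphics::legend("topright", legend = which, col = cols[which], lty = 1,
                   bty = "n")
  invisible(x)
}
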