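g <- fd_geometry()

test_that("slope fit reproduces a hand-computable OLS fixture", {
  # ln(r^2 IAC) = -2 r + 1 plus residuals (+d, -d, -d, +d): the residual
  # pattern is orthogonal to r and has zero mean, so slope and intercept
  # are exact and R^2 = 1 - 4 d^2 / (5 + 4 d^2) at the default distances.
  d <- 0.1
  r <- g$distances
  y <- -2 * r + 1 + c(d, -d, -d, d)
  IAC <- array(exp(y) / r^2, c(1, 1, 4))
  IDC <- array(1, c(1, 1, 4))
  phase <- array(0.3 * r, c(1, 1, 4))
  g1 <- fd_geometry(wavelengths = 690)
  rec <- make_recording(IAC, IDC, phase, g1)
  sl <- fit_multidistance(rec)
  expect_equal(sl$SAC[1, 1], -2, tolerance = 1e-12)
  expect_equal(sl$CAC[1, 1], 1, tolerance = 1e-12)
  expect_equal(sl$R2_AC[1, 1], 1 - 4 * d^2 / (5 + 4 * d^2),
               tolerance = 1e-12)
  # and agrees with the textbook formulas evaluated independently
  o <- oracle_ols(r, y)
  expect_equal(sl$R2_AC[1, 1], o$r2, tolerance = 1e-14)
  expect_equal(sl$SAC[1, 1], o$slope, tolerance = 1e-14)
})

test_that("flat phase gives zero slope and R^2 = 0 by convention", {
  rec <- recording_at(c(0.1, 0.1), c(10, 10), g)
  rec$phase[] <- 0.5
  sl <- fit_multidistance(rec)
  expect_equal(sl$Sphase[1, ], c(0, 0))
  expect_equal(sl$R2_phase[1, ], c(0, 0))
})

test_that("non-positive intensities mark the sample invalid, no error", {
  rec <- recording_at(c(0.1, 0.12), c(10, 9), g, n = 3)
  rec$IAC[2, 1, 3] <- -1
  sl <- fit_multidistance(rec)
  expect_true(is.na(sl$SAC[2, 1]))
  expect_false(anyNA(sl$SAC[c(1, 3), ]))
  expect_equal(qc_mask(sl), c(TRUE, FALSE, TRUE))
})

test_that("phase is unwrapped across distances before fitting", {
  # true phase 2.8 r crosses 2 pi between 2 and 2.5 cm; recorded phase is
  # wrapped into [0, 2 pi) and must be unwrapped before the linear fit
  rec <- recording_at(c(0.1, 0.1), c(10, 10), g)
  true_phase <- 2.8 * g$distances
  expect_true(any(diff(true_phase %/% (2 * pi)) > 0))
  rec$phase[1, 1, ] <- true_phase %% (2 * pi)
  rec$phase[1, 2, ] <- true_phase
  sl <- fit_multidistance(rec)
  expect_equal(sl$Sphase[1, 1], 2.8, tolerance = 1e-12)
  expect_equal(sl$R2_phase[1, 1], 1, tolerance = 1e-12)
  expect_equal(sl$Sphase[1, 2], 2.8, tolerance = 1e-12)
})

test_that("closed-form inversion matches a numerical solver of the model", {
  k <- fd_wavenumbers(0.1, 10, g$omega, g$speed)
  op <- invert_optical(-k$kr, k$ki, g$omega, g$speed)
  expect_equal(op$mua, 0.1, tolerance = 1e-9)
  expect_equal(op$musp, 10, tolerance = 1e-9)
  o <- oracle_invert(k$kr, k$ki, g$omega, g$speed)
  expect_equal(op$mua, o$mua, tolerance = 1e-5)
  expect_equal(op$musp, o$musp, tolerance = 1e-5)
})

test_that("inversion formula is continuous at the validity boundary", {
  sp <- 0.3
  eps <- 10^seq(-3, -8, by = -1)
  mua <- invert_optical(-sp * (1 + eps), sp, g$omega, g$speed)$mua
  expect_true(all(diff(mua) < 0))   # shrinks towards 0+
  expect_lt(mua[length(eps)], 1e-6)
  # invalid side: a <= Sphase
  expect_true(is.na(invert_optical(-sp, sp, g$omega, g$speed)$mua))
  expect_true(is.na(invert_optical(-sp * 1.01, -0.1, g$omega, g$speed)$mua))
})

test_that("mua depends on omega and v only through their ratio", {
  k <- fd_wavenumbers(0.15, 8, g$omega, g$speed)
  a <- invert_optical(-k$kr, k$ki, g$omega, g$speed)
  b <- invert_optical(-k$kr, k$ki, 3 * g$omega, 3 * g$speed)
  expect_equal(a$mua, b$mua, tolerance = 1e-14)
})

test_that("forward/inverse round trip recovers random optical properties", {
  set.seed(42)
  n <- 250
  mua <- stats::runif(n, 0.01, 0.5)
  musp <- stats::runif(n, 5, 20)
  k <- fd_wavenumbers(mua, musp, g$omega, g$speed)
  op <- invert_optical(-k$kr, k$ki, g$omega, g$speed)
  expect_lt(max(abs(op$mua - mua) / mua), 1e-10)
  expect_lt(max(abs(op$musp - musp) / musp), 1e-10)
})

test_that("|SAC| and the slope ratio increase monotonically with mua", {
  mua <- seq(0.01, 0.5, length.out = 40)
  k <- fd_wavenumbers(mua, 10, g$omega, g$speed)
  expect_true(all(diff(k$kr) > 0))
  expect_true(all(diff(k$kr / k$ki) > 0))
})

test_that("chromophore solve inverts the defining linear map", {
  E <- extinction_table()
  C <- cbind(HbO2 = c(0, 60, 45), HHb = c(0, 25, 40))  # uM
  mua <- (C / 1000) %*% t(log(10) * unclass(E))
  out <- solve_chromophores(mua, E)
  expect_equal(out$C_HbO2, unname(C[, "HbO2"]), tolerance = 1e-12)
  expect_equal(out$C_HHb, unname(C[, "HHb"]), tolerance = 1e-12)
  # permutation invariance: swap wavelength rows and mua columns together
  E2 <- extinction_table(wavelengths = c(830, 690),
                         HbO2 = c(0.974, 0.276), HHb = c(0.693, 2.052))
  out2 <- solve_chromophores(mua[, c(2, 1)], E2)
  expect_equal(out2$C_HbO2, out$C_HbO2, tolerance = 1e-12)
})

test_that("a singular extinction table is rejected at construction", {
  expect_error(extinction_table(HbO2 = c(1, 2), HHb = c(2, 4)), "singular")
})

test_that("QC gate follows the R^2 threshold on amplitude and phase", {
  rec <- recording_at(c(0.1, 0.12), c(10, 9), g, n = 4)
  sl <- fit_multidistance(rec)
  sl$R2_AC[2, 1] <- 0.98; sl$R2_phase[2, 1] <- 0.95   # phase fails
  sl$R2_AC[3, 2] <- 0.95                              # amplitude fails
  sl$R2_DC[4, ] <- 0                                  # DC not gated
  expect_equal(qc_mask(sl), c(TRUE, FALSE, FALSE, TRUE))
  # monotone in the threshold
  r2s <- seq(0, 1, by = 0.05)
  masks <- vapply(r2s, function(th) qc_mask(sl, th), logical(4))
  expect_true(all(masks[, 1]))  # threshold 0 validates all finite fits
  for (i in seq_len(4))
    expect_true(all(diff(as.integer(masks[i, ])) <= 0))
})

test_that("noise-free end-to-end inversion recovers ground truth", {
  sched <- make_session_schedule("cTBS", "s02", seed = 21L)
  tis <- simulate_chromophores(sched, hrf_model(), noise_model_silent())
  keep <- seq(1, length(tis$time), by = 40)
  for (f in c("time", "C_HbO2", "C_HHb")) tis[[f]] <- tis[[f]][keep]
  rec <- forward_fd(tis, noise = noise_model_silent())
  series <- invert_recording(rec)
  expect_true(all(series$valid))
  expect_lt(max(abs(series$HbO2 - tis$C_HbO2)), 1e-6)
  expect_lt(max(abs(series$HHb - tis$C_HHb)), 1e-6)
  expect_identical(series$tHb, series$HbO2 + series$HHb)
})

test_that("an artifact-corrupted window fails the gate under noise", {
  sched <- make_session_schedule("cTBS", "s03", seed = 31L)
  nz <- noise_model(motion_rate = 0, optical_sd = 0.01, phase_sd = 0.005)
  tis <- simulate_chromophores(sched, hrf_model(), nz)
  keep <- seq(1, 4000)
  for (f in c("time", "C_HbO2", "C_HHb")) tis[[f]] <- tis[[f]][keep]
  rec <- forward_fd(tis, noise = nz)
  # corrupt a window by scaling channels differently (breaks linearity)
  win <- rec$time >= 100 & rec$time <= 103
  rec$IAC[win, , 2] <- rec$IAC[win, , 2] * 3
  rec$phase[win, , 3] <- rec$phase[win, , 3] + 0.4
  series <- invert_recording(rec)
  expect_true(all(!series$valid[win]))
  expect_gt(mean(series$valid[!win]), 0.95)
})

test_that("an empty recording yields an empty series without error", {
  rec <- recording_at(c(0.1, 0.12), c(10, 9), g, n = 1)
  for (f in c("IAC", "IDC", "phase"))
    rec[[f]] <- rec[[f]][0, , , drop = FALSE]
  rec$time <- numeric(0)
  series <- invert_recording(rec)
  expect_equal(nrow(series), 0)
})
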