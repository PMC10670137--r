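test_that("Welch test matches the reference implementation on random data", {
  set.seed(100)
  for (i in 1:100) {
    a <- rnorm(sample(3:40, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:40, 1), mean = runif(1, -1, 1),
               sd = runif(1, 0.5, 3))
    w <- welch_test(a, b)
    ref <- stats::t.test(a, b)
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(w$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Welch test on the frozen 4-vs-4 fixture", {
  w <- welch_test(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(w$t, -1.0954451150, tolerance = 1e-9)
  expect_equal(w$df, 6, tolerance = 1e-9)
  expect_equal(w$p, 0.3153335962, tolerance = 1e-9)
})

test_that("Welch test symmetry and degenerate groups", {
  a <- c(1, 2, 3, 5)
  b <- c(0, 4, 4, 6, 7)
  w1 <- welch_test(a, b)
  w2 <- welch_test(b, a)
  expect_equal(w1$t, -w2$t)
  expect_equal(w1$p, w2$p)
  # identical constant groups
  w0 <- welch_test(c(2, 2), c(2, 2))
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
  # zero variance on both sides, different means: df clamped at n-1
  wz <- welch_test(c(2, 2), c(3, 3))
  expect_equal(wz$df, 1)
  expect_equal(wz$p, 0)
  # df always within the Welch bounds
  set.seed(7)
  for (i in 1:50) {
    a <- rnorm(sample(2:10, 1)); b <- rnorm(sample(2:10, 1))
    w <- welch_test(a, b)
    expect_gte(w$df, min(length(a), length(b)) - 1)
    expect_lte(w$df, length(a) + length(b) - 2 + 1e-9)
  }
})

# summary-level generator for LMM tests: subjects x conditions, gaussian
make_lmm_data <- function(n_subj = 5, n_per = 120, effects = c(pre = 0,
                          cTBS = 14, iTBS = 0), subj_sd = 5, resid_sd = 40,
                          seed = 1) {
  set.seed(seed)
  rows <- list()
  for (s in seq_len(n_subj)) {
    u <- rnorm(1, 0, subj_sd)
    for (cond in names(effects)) {
      epoch <- if (cond == "pre") "pre" else "post"
      paradigm <- if (cond == "pre") "cTBS" else cond
      rows[[length(rows) + 1]] <- data.frame(
        subject = sprintf("s%02d", s), paradigm = paradigm, epoch = epoch,
        modality = "real", block = 1L, onset = 0, signal = "BV",
        mean_pct = effects[[cond]] + u + rnorm(n_per, 0, resid_sd),
        valid_fraction = 1, kept = TRUE, reason = "",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("segment_summaries", "data.frame")
  out
}

test_that("LMM with zero subject variance collapses to OLS estimates", {
  d <- make_lmm_data(n_subj = 4, n_per = 60, subj_sd = 0, resid_sd = 10,
                     seed = 2)
  fit <- fit_lmm(d, "BV", "real")
  d$condition <- factor(ifelse(d$epoch == "pre", "pre", d$paradigm),
                        levels = c("pre", "cTBS", "iTBS"))
  ols <- stats::lm(mean_pct ~ condition, data = d)
  expect_equal(fit$contrasts$estimate[fit$contrasts$contrast == "cTBS - pre"],
               unname(coef(ols)["conditioncTBS"]), tolerance = 1e-4)
  expect_equal(fit$contrasts$estimate[fit$contrasts$contrast == "iTBS - pre"],
               unname(coef(ols)["conditioniTBS"]), tolerance = 1e-4)
})

test_that("LMM recovers injected condition effects across replicates", {
  nrep <- 40
  hit <- logical(nrep)
  est_c <- est_i <- se_c <- numeric(nrep)
  for (r in seq_len(nrep)) {
    d <- make_lmm_data(seed = 1000 + r)
    fit <- fit_lmm(d, "BV", "real")
    ct <- fit$contrasts
    est_c[r] <- ct$estimate[ct$contrast == "cTBS - pre"]
    se_c[r] <- ct$SE[ct$contrast == "cTBS - pre"]
    est_i[r] <- ct$estimate[ct$contrast == "iTBS - pre"]
    hit[r] <- abs(est_c[r] - 14) <= 3 * se_c[r]
  }
  expect_gte(mean(hit), 0.95)
  # near-unbiased: |bias| < 0.1 * typical SE
  expect_lt(abs(mean(est_c) - 14), 0.1 * mean(se_c) + 3 * sd(est_c) / sqrt(nrep))
  expect_lt(abs(mean(est_i)), 4 * sd(est_i) / sqrt(nrep))
})

test_that("adding a constant shifts the intercept but not the contrasts", {
  d <- make_lmm_data(n_subj = 3, n_per = 40, seed = 5)
  d2 <- d
  d2$mean_pct <- d2$mean_pct + 100
  f1 <- fit_lmm(d, "BV", "real")
  f2 <- fit_lmm(d2, "BV", "real")
  expect_equal(f1$contrasts$estimate, f2$contrasts$estimate, tolerance = 1e-6)
})

test_that("releveling reports the cTBS-vs-iTBS contrast consistently", {
  d <- make_lmm_data(seed = 77)
  fit <- fit_lmm(d, "BV", "real")
  ct <- fit$contrasts
  expect_setequal(ct$contrast, c("cTBS - pre", "iTBS - pre", "iTBS - cTBS"))
  expect_equal(ct$estimate[ct$contrast == "iTBS - cTBS"],
               ct$estimate[ct$contrast == "iTBS - pre"] -
                 ct$estimate[ct$contrast == "cTBS - pre"],
               tolerance = 1e-6)
})

test_that("contrast matrix covers the design and flags all-zero data", {
  d <- rbind(make_lmm_data(effects = c(pre = 0, cTBS = 0, iTBS = 0),
                           subj_sd = 0, resid_sd = 0, seed = 1))
  d$mean_pct <- 0
  # add sham rows mirroring the real ones
  sham <- d; sham$modality <- "sham"
  dd <- rbind(d, sham)
  class(dd) <- c("segment_summaries", "data.frame")
  res <- suppressMessages(run_comparisons(dd))
  expect_true(all(res$welch$t == 0))
  expect_true(all(res$welch$p == 1))
  expect_true(res$pooling$pooled)
  labels <- res$welch$contrast
  expect_true("pre: real vs sham" %in% labels)
  expect_true("post-cTBS: real vs sham" %in% labels)
  expect_true("real: post-cTBS vs post-iTBS" %in% labels)
  expect_true("real: post-cTBS vs pre" %in% labels)
  expect_false(is.null(res$lmm))
})

test_that("significant pre-TBS differences disable pooling with a warning", {
  d <- make_lmm_data(effects = c(pre = 0, cTBS = 0, iTBS = 0),
                     subj_sd = 0, resid_sd = 1, seed = 3)
  # shift the pre events of the iTBS paradigm only: rebuild a pre-iTBS cell
  pre_itbs <- d[d$epoch == "pre", ]
  pre_itbs$paradigm <- "iTBS"
  pre_itbs$mean_pct <- pre_itbs$mean_pct + 50
  sham <- rbind(d, pre_itbs); sham$modality <- "sham"
  dd <- rbind(d, pre_itbs, sham)
  class(dd) <- c("segment_summaries", "data.frame")
  expect_warning(res <- run_comparisons(dd), "per paradigm")
  expect_false(res$pooling$pooled)
  expect_true(any(grepl("pre \\(cTBS\\)", res$welch$contrast)))
})
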