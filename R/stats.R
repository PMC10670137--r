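#' Two-sample Welch t-test
#'
#' Welch's unequal-variance t statistic with Satterthwaite degrees of
#' freedom, the event-level comparison used throughout the contrast matrix:
#' \deqn{t = \frac{\bar A - \bar B}{\sqrt{s_A^2/n_A + s_B^2/n_B}}, \qquad
#'  df = \frac{(s_A^2/n_A + s_B^2/n_B)^2}
#'            {\frac{(s_A^2/n_A)^2}{n_A-1} + \frac{(s_B^2/n_B)^2}{n_B-1}}.}
#' Degenerate inputs are handled explicitly rather than erroring: two
#' identical-constant groups give t = 0, p = 1, and when both variances are
#' zero but means differ the test is reported as infinitely significant
#' (t = +-Inf, p = 0) with df clamped to its lower bound
#' \code{min(nA, nB) - 1}.
#'
#' @param a,b Numeric vectors (>= 2 finite values each).
#' @return An object of class \code{welch_test}: list with \code{nA},
#'   \code{nB}, \code{meanA}, \code{meanB}, \code{t}, \code{df}, \code{p}.
#' @export
welch_test <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  nA <- length(a); nB <- length(b)
  if (nA < 2 || nB < 2)
    stop("welch_test needs at least 2 finite values per group")
  mA <- mean(a); mB <- mean(b)
  vA <- stats::var(a); vB <- stats::var(b)
  se2 <- vA / nA + vB / nB
  if (se2 == 0) {
    tt <- if (mA == mB) 0 else sign(mA - mB) * Inf
    df <- min(nA, nB) - 1
    p <- if (mA == mB) 1 else 0
  } else {
    tt <- (mA - mB) / sqrt(se2)
    df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
    if (!is.finite(df)) df <- min(nA, nB) - 1
    df <- max(df, min(nA, nB) - 1)
    p <- 2 * stats::pt(-abs(tt), df)
  }
  out <- list(nA = nA, nB = nB, meanA = mA, meanB = mB,
              t = tt, df = df, p = p)
  class(out) <- "welch_test"
  out
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch two-sample t-test: t = %.4f, df = %.2f, p = %.4g\n",
              x$t, x$df, x$p))
  cat(sprintf("  mean A = %.3f (n = %d), mean B = %.3f (n = %d)\n",
              x$meanA, x$nA, x$meanB, x$nB))
  invisible(x)
}

# map (epoch, paradigm) to the LMM condition factor: pre-TBS events are one
# reference level regardless of paradigm; post events carry their paradigm
condition_of <- function(epoch, paradigm) {
  ifelse(epoch == "pre", "pre", as.character(paradigm))
}

#' Random-intercept linear mixed model over conditions
#'
#' Fits \code{mean_pct ~ condition} with a Gaussian random intercept per
#' subject by REML, on the kept event summaries of one signal and one
#' stimulus modality, where condition is pre-TBS (reference, pooled across
#' paradigms) vs after-cTBS vs after-iTBS. The cTBS-vs-iTBS contrast is
#' obtained by refitting with the cTBS level as reference rather than by
#' post-hoc contrast algebra. p-values are Wald normal-approximation by
#' default; \code{method = "t"} uses the fit's conditional t tests.
#'
#' A fit with (near-)zero between-subject variance, or one that fails to
#' converge, is reported with \code{singular = TRUE}; in the failure case
#' estimates come from pooled OLS with random-intercept SD 0.
#'
#' @param summaries A \code{segment_summaries} data.frame (or compatible:
#'   needs \code{subject}, \code{epoch}, \code{paradigm}, \code{modality},
#'   \code{signal}, \code{mean_pct}, \code{kept}).
#' @param signal Signal to analyze (\code{"BV"}, \code{"HbO2"}, \code{"HHb"}).
#' @param modality Stimulus modality to analyze.
#' @param method p-value style: \code{"wald"} (normal) or \code{"t"}.
#' @return An object of class \code{lmm_result}: \code{contrasts}
#'   (data.frame: contrast, estimate, SE, p), \code{sd_subject},
#'   \code{sd_residual}, \code{n_obs}, \code{n_subjects}, \code{logLik},
#'   \code{singular}.
#' @export
fit_lmm <- function(summaries, signal = "BV", modality = "real",
                    method = c("wald", "t")) {
  method <- match.arg(method)
  d <- summaries[summaries$signal == signal & summaries$modality == modality &
                   summaries$kept & is.finite(summaries$mean_pct), , drop = FALSE]
  if (!nrow(d)) stop("no kept summaries for signal ", signal,
                     ", modality ", modality)
  d$condition <- factor(condition_of(d$epoch, d$paradigm),
                        levels = c("pre", "cTBS", "iTBS"))
  d$condition <- droplevels(d$condition)
  d$subject <- factor(d$subject)
  if (nlevels(d$subject) < 2) stop("fit_lmm needs at least 2 subjects")
  if (nlevels(d$condition) < 2) stop("fit_lmm needs at least 2 condition levels")

  fit_one <- function(ref) {
    dd <- d
    dd$condition <- stats::relevel(dd$condition, ref = ref)
    fit <- tryCatch(
      nlme::lme(mean_pct ~ condition, random = ~ 1 | subject, data = dd,
                method = "REML"),
      error = function(e) NULL)
    if (is.null(fit)) {
      ols <- stats::lm(mean_pct ~ condition, data = dd)
      ct <- summary(ols)$coefficients
      list(coef = ct[, "Estimate"], se = ct[, "Std. Error"],
           tstat = ct[, "t value"], df = stats::df.residual(ols),
           sd_subject = 0, sd_resid = summary(ols)$sigma,
           ll = as.numeric(stats::logLik(ols)), singular = TRUE)
    } else {
      ct <- summary(fit)$tTable
      vc <- nlme::VarCorr(fit)
      sd_subj <- suppressWarnings(as.numeric(vc["(Intercept)", "StdDev"]))
      sd_res <- fit$sigma
      list(coef = ct[, "Value"], se = ct[, "Std.Error"],
           tstat = ct[, "t-value"], df = ct[, "DF"],
           sd_subject = sd_subj, sd_resid = sd_res,
           ll = as.numeric(stats::logLik(fit)),
           singular = is.finite(sd_subj) && sd_subj < 1e-6 * sd_res)
    }
  }

  pval <- function(f, row) {
    if (method == "wald") 2 * stats::pnorm(-abs(f$tstat[row]))
    else 2 * stats::pt(-abs(f$tstat[row]), f$df[row])
  }
  grab <- function(f, level, label) {
    row <- paste0("condition", level)
    if (!row %in% names(f$coef)) return(NULL)
    data.frame(contrast = label, estimate = unname(f$coef[row]),
               SE = unname(f$se[row]), p = unname(pval(f, row)),
               stringsAsFactors = FALSE)
  }

  f_pre <- fit_one("pre")
  rows <- list(grab(f_pre, "cTBS", "cTBS - pre"),
               grab(f_pre, "iTBS", "iTBS - pre"))
  if (all(c("cTBS", "iTBS") %in% levels(d$condition))) {
    f_c <- fit_one("cTBS")
    rows <- c(rows, list(grab(f_c, "iTBS", "iTBS - cTBS")))
  }
  contrasts <- do.call(rbind, rows)
  out <- list(contrasts = contrasts, sd_subject = f_pre$sd_subject,
              sd_residual = f_pre$sd_resid, n_obs = nrow(d),
              n_subjects = nlevels(d$subject), logLik = f_pre$ll,
              singular = isTRUE(f_pre$singular), signal = signal,
              modality = modality, method = method)
  class(out) <- "lmm_result"
  out
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("Random-intercept LMM: %s, %s stimuli (%d events, %d subjects)%s\n",
              x$signal, x$modality, x$n_obs, x$n_subjects,
              if (x$singular) " [singular]" else ""))
  cat(sprintf("  random intercept SD %.3f, residual SD %.3f\n",
              x$sd_subject, x$sd_residual))
  ct <- x$contrasts
  for (i in seq_len(nrow(ct)))
    cat(sprintf("  %-12s %+7.3f %% (SE %.3f, p = %.4g)\n",
                ct$contrast[i], ct$estimate[i], ct$SE[i], ct$p[i]))
  invisible(x)
}

#' Full condition contrast matrix
#'
#' Runs every pairwise Welch comparison of the study design on the kept
#' event summaries, per signal: real vs sham within pre-TBS and within each
#' post-TBS paradigm; after-cTBS vs after-iTBS for real and for sham; and
#' each post condition against the pre-TBS baseline. Pre-TBS events are
#' pooled across the two paradigms only if neither the real-vs-real nor the
#' sham-vs-sham pre-paradigm Welch test is significant at \code{alpha};
#' otherwise the pre comparisons stay per-paradigm and a warning is issued.
#' When at least two subjects completed both paradigms, random-intercept
#' LMMs are added for every signal and modality. All p-values are
#' unadjusted.
#'
#' @param summaries A \code{segment_summaries} data.frame.
#' @param alpha Significance level for the pooling gate (and reporting).
#' @param lmm_method p-value style passed to \code{\link{fit_lmm}}.
#' @return An object of class \code{fd_contrasts}: \code{welch} (data.frame:
#'   signal, contrast, nA, nB, meanA, meanB, t, df, p), \code{pooling}
#'   (gate tests and decision), \code{lmm} (list of \code{lmm_result} or
#'   NULL), \code{alpha}.
#' @export
run_comparisons <- function(summaries, alpha = 0.05,
                            lmm_method = c("wald", "t")) {
  lmm_method <- match.arg(lmm_method)
  d <- summaries[summaries$kept & is.finite(summaries$mean_pct), , drop = FALSE]
  if (!nrow(d)) stop("no kept summaries")
  signals <- intersect(c("BV", "HbO2", "HHb"), unique(d$signal))

  cell <- function(sg, modality, epoch, paradigm = NULL) {
    sel <- d$signal == sg & d$modality == modality & d$epoch == epoch
    if (!is.null(paradigm)) sel <- sel & d$paradigm == paradigm
    d$mean_pct[sel]
  }

  # pooling gate on pre-TBS events (BV is the gate signal when present)
  gate_signal <- signals[1]
  gate <- list(pooled = TRUE, tests = NULL)
  have_both <- all(c("cTBS", "iTBS") %in% unique(d$paradigm))
  if (have_both) {
    tests <- lapply(c("real", "sham"), function(m) {
      a <- cell(gate_signal, m, "pre", "cTBS")
      b <- cell(gate_signal, m, "pre", "iTBS")
      if (length(a) >= 2 && length(b) >= 2) welch_test(a, b) else NULL
    })
    names(tests) <- c("real", "sham")
    ps <- vapply(tests, function(t) if (is.null(t)) NA_real_ else t$p, 0)
    gate$tests <- tests
    gate$pooled <- all(is.na(ps) | ps > alpha)
    if (!gate$pooled)
      warning("pre-TBS events differ between paradigms (gate p <= ",
              alpha, "); pre comparisons are reported per paradigm")
  }

  rows <- list()
  add <- function(sg, label, a, b) {
    if (length(a) < 2 || length(b) < 2) {
      message("contrast skipped (empty cell): ", sg, " ", label)
      return()
    }
    w <- welch_test(a, b)
    rows[[length(rows) + 1]] <<- data.frame(
      signal = sg, contrast = label, nA = w$nA, nB = w$nB,
      meanA = w$meanA, meanB = w$meanB, t = w$t, df = w$df, p = w$p,
      stringsAsFactors = FALSE)
  }

  for (sg in signals) {
    if (gate$pooled) {
      add(sg, "pre: real vs sham", cell(sg, "real", "pre"),
          cell(sg, "sham", "pre"))
    } else {
      for (pd in unique(d$paradigm))
        add(sg, paste0("pre (", pd, "): real vs sham"),
            cell(sg, "real", "pre", pd), cell(sg, "sham", "pre", pd))
    }
    for (pd in intersect(c("cTBS", "iTBS"), unique(d$paradigm)))
      add(sg, paste0("post-", pd, ": real vs sham"),
          cell(sg, "real", "post", pd), cell(sg, "sham", "post", pd))
    if (have_both) {
      add(sg, "real: post-cTBS vs post-iTBS",
          cell(sg, "real", "post", "cTBS"), cell(sg, "real", "post", "iTBS"))
      add(sg, "sham: post-cTBS vs post-iTBS",
          cell(sg, "sham", "post", "cTBS"), cell(sg, "sham", "post", "iTBS"))
    }
    for (m in c("real", "sham")) for (pd in intersect(c("cTBS", "iTBS"),
                                                      unique(d$paradigm))) {
      pre <- if (gate$pooled) cell(sg, m, "pre") else cell(sg, m, "pre", pd)
      add(sg, paste0(m, ": post-", pd, " vs pre"),
          cell(sg, m, "post", pd), pre)
    }
  }
  welch_table <- do.call(rbind, rows)

  # LMM on crossover subjects (both paradigms completed)
  lmm <- NULL
  if (have_both) {
    tab <- table(unique(d[, c("subject", "paradigm")])$subject)
    cross <- names(tab)[tab == 2]
    if (length(cross) >= 2) {
      dc <- d[d$subject %in% cross, , drop = FALSE]
      lmm <- list()
      for (sg in signals) for (m in c("real", "sham")) {
        res <- tryCatch(fit_lmm(dc, sg, m, method = lmm_method),
                        error = function(e) NULL)
        if (!is.null(res)) lmm[[paste(sg, m, sep = ".")]] <- res
      }
    } else {
      message("LMM skipped: fewer than 2 subjects completed both paradigms")
    }
  } else {
    message("LMM skipped: only one paradigm present")
  }

  out <- list(welch = welch_table, pooling = gate, lmm = lmm, alpha = alpha)
  class(out) <- "fd_contrasts"
  out
}

#' @export
print.fd_contrasts <- function(x, digits = 4, ...) {
  cat("Condition contrast matrix (Welch t-tests, unadjusted p-values)\n")
  cat(sprintf("pre-TBS pooling across paradigms: %s\n",
              if (x$pooling$pooled) "yes" else "NO (gate significant)"))
  w <- x$welch
  w$meanA <- round(w$meanA, 3); w$meanB <- round(w$meanB, 3)
  w$t <- round(w$t, 3); w$df <- round(w$df, 1); w$p <- signif(w$p, digits)
  print(w, row.names = FALSE)
  if (!is.null(x$lmm)) {
    cat("\nRandom-intercept LMMs (crossover subjects):\n")
    for (r in x$lmm) print(r)
  }
  invisible(x)
}

#' Plot group means of the contrast matrix
#'
#' Bar plot of mean normalized change with standard-error bars per
#' condition cell, one panel per signal.
#'
#' @param x An \code{fd_contrasts} is not needed; this plots from the
#'   summaries directly.
#' @param summaries A \code{segment_summaries} data.frame.
#' @param signals Signals to show.
#' @export
plot_condition_means <- function(summaries, signals = c("BV", "HbO2", "HHb")) {
  d <- summaries[summaries$kept & is.finite(summaries$mean_pct), , drop = FALSE]
  d$condition <- condition_of(d$epoch, d$paradigm)
  signals <- intersect(signals, unique(d$signal))
  op <- graphics::par(mfrow = c(1, length(signals)))
  on.exit(graphics::par(op))
  for (sg in signals) {
    ds <- d[d$signal == sg, ]
    agg_m <- stats::aggregate(mean_pct ~ condition + modality, ds, mean)
    agg_se <- stats::aggregate(mean_pct ~ condition + modality, ds,
                               function(v) stats::sd(v) / sqrt(length(v)))
    lv <- intersect(c("pre", "cTBS", "iTBS"), agg_m$condition)
    m <- matrix(NA_real_, 2, length(lv),
                dimnames = list(c("real", "sham"), lv))
    se <- m
    for (i in seq_len(nrow(agg_m))) {
      m[agg_m$modality[i], agg_m$condition[i]] <- agg_m$mean_pct[i]
      se[agg_se$modality[i], agg_se$condition[i]] <- agg_se$mean_pct[i]
    }
    bp <- graphics::barplot(m, beside = TRUE, col = c("firebrick", "grey70"),
                            main = sg, ylab = "mean change [% baseline]",
                            ylim = range(0, m + 2 * se, m - 2 * se,
                                         na.rm = TRUE))
    graphics::arrows(bp, m - se, bp, m + se, angle = 90, code = 3,
                     length = 0.03)
    graphics::legend("topleft", c("real", "sham"),
                     fill = c("firebrick", "grey70"), bty = "n")
  }
  invisible(NULL)
}
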