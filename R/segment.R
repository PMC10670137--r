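#' Segment a chromophore series around stimulus events
#'
#' Cuts the 6 s window after every stimulus out of the series and expresses
#' it as percent change from baseline. The baseline is the sample nearest
#' the stimulus onset (mode \code{"onset-sample"}, the default) or the mean
#' over the 0.5 s before onset (mode \code{"pre-window"}); the per-sample
#' normalized value is
#' \code{100 * (x(t) - baseline) / |baseline level|}, where the baseline
#' level is the absolute concentration at the stimulus (for a band-passed
#' series this is the filtered onset value plus the concentration level the
#' filter removed, carried on the series as attribute \code{"level"}).
#' The normalized value at the baseline sample is therefore 0 and an evoked
#' excursion of a\% of baseline reads as a.
#'
#' Segments are dropped (with a reason) when their window runs past the end
#' of the recording, touches the filter's reflected edge padding, has an
#' invalid baseline sample, or has a baseline level below the stability
#' floor.
#'
#' @param series A \code{chromophore_series} (typically filtered).
#' @param events Data frame of stimulus events (\code{onset},
#'   \code{modality}, \code{epoch}, \code{block}, optionally
#'   \code{paradigm}) or a \code{session_schedule}.
#' @param window Window length in s after onset; the window holds
#'   \code{floor(window * fs)} samples covering (0, window] s.
#' @param baseline_mode \code{"onset-sample"} or \code{"pre-window"}.
#' @param baseline_floor Minimum |baseline level| in uM; below it the
#'   segment is marked unstable and not kept.
#' @return An object of class \code{event_segments}: list with \code{events}
#'   (the event table plus \code{baseline_<signal>}, \code{valid_fraction},
#'   \code{dropped}, \code{reason}), \code{normalized} (array events x
#'   window-samples x signals, percent), \code{valid} (events x
#'   window-samples), \code{signals}, \code{fs}, \code{window}.
#' @export
segment_events <- function(series, events, window = 6,
                           baseline_mode = c("onset-sample", "pre-window"),
                           baseline_floor = 1e-3) {
  stopifnot(inherits(series, "chromophore_series"), window > 0)
  baseline_mode <- match.arg(baseline_mode)
  if (inherits(events, "session_schedule")) events <- events$events
  fs <- attr(series, "fs")
  stopifnot(!is.null(fs))
  n <- nrow(series)
  nwin <- floor(window * fs)
  signals <- c(tHb = "tHb", HbO2 = "HbO2", HHb = "HHb")
  level <- attr(series, "level")
  if (is.null(level)) level <- c(HbO2 = 0, HHb = 0, tHb = 0)
  hw <- attr(series, "edge_halfwidth") %||% 0L

  ne <- nrow(events)
  normalized <- array(NA_real_, c(ne, nwin, length(signals)),
                      dimnames = list(NULL, NULL, names(signals)))
  valid <- matrix(FALSE, ne, nwin)
  ev <- events
  i0 <- round(ev$onset * fs) + 1

  dropped <- rep(FALSE, ne)
  reason <- rep("", ne)
  beyond <- i0 < 1 | i0 + nwin > n
  dropped[beyond] <- TRUE; reason[beyond] <- "window beyond recording"
  if (hw > 0) {
    edge <- !dropped & (i0 <= hw | i0 + nwin > n - hw)
    dropped[edge] <- TRUE; reason[edge] <- "filter edge"
  }
  ok <- !dropped
  nb <- if (baseline_mode == "onset-sample") 0L else floor(0.5 * fs)

  base_ok <- rep(TRUE, ne)
  baseline <- matrix(NA_real_, ne, length(signals),
                     dimnames = list(NULL, names(signals)))
  vfrac <- rep(NA_real_, ne)
  if (any(ok)) {
    io <- i0[ok]
    bmat <- outer(io, -(nb:0), `+`)         # baseline sample indices
    bmat[bmat < 1] <- 1
    base_ok[ok] <- rowSums(matrix(series$valid[bmat], nrow(bmat))) ==
      ncol(bmat)
    dropped[ok & !base_ok] <- TRUE
    reason[ok & !base_ok] <- "invalid baseline"
    ok <- ok & base_ok
  }
  if (any(ok)) {
    io <- i0[ok]
    bmat <- outer(io, -(nb:0), `+`); bmat[bmat < 1] <- 1
    wmat <- outer(io, seq_len(nwin), `+`)   # window sample indices
    vw <- matrix(series$valid[wmat], nrow(wmat))
    valid[ok, ] <- vw
    vfrac[ok] <- rowMeans(vw)
    unstable <- rep(FALSE, sum(ok))
    for (s in names(signals)) {
      x <- series[[signals[[s]]]]
      b <- rowMeans(matrix(x[bmat], nrow(bmat)))
      denom <- b + unname(level[[s]])
      baseline[ok, s] <- denom
      bad <- !is.finite(denom) | abs(denom) < baseline_floor
      unstable <- unstable | bad
      z <- 100 * (matrix(x[wmat], nrow(wmat)) - b) / abs(denom)
      z[bad, ] <- NA_real_
      normalized[ok, , s] <- z
    }
    if (any(unstable)) {
      iu <- which(ok)[unstable]
      dropped[iu] <- TRUE
      reason[iu] <- "unstable baseline"
    }
  }
  for (s in names(signals)) ev[[paste0("baseline_", s)]] <- baseline[, s]
  ev$valid_fraction <- vfrac
  ev$dropped <- dropped
  ev$reason <- reason

  out <- list(events = ev, normalized = normalized, valid = valid,
              signals = names(signals), fs = fs, window = window,
              meta = attr(series, "meta"))
  class(out) <- "event_segments"
  out
}

#' @export
print.event_segments <- function(x, ...) {
  cat(sprintf("event_segments: %d events, %d-sample window (%.0f s), %d dropped\n",
              nrow(x$events), dim(x$normalized)[2], x$window,
              sum(x$events$dropped)))
  if (any(x$events$dropped))
    print(table(reason = x$events$reason[x$events$dropped]))
  invisible(x)
}

#' Event-level quality control and summary
#'
#' Applies the event discard rules and reduces every surviving segment to
#' its mean normalized change: an event is kept only if at least two thirds
#' of its window samples are valid (i.e., it is discarded when more than
#' one third of the underlying optical data were discarded) and its window
#' does not overlap a motion-artifact interval. Means are computed over the
#' valid window samples only. One summary row is produced per event and
#' signal; total hemoglobin is reported as \code{BV}.
#'
#' @param segments An \code{event_segments}.
#' @param artifact_windows Two-column matrix (start, end) of artifact
#'   intervals in s, or NULL to use the ground-truth labels carried in the
#'   segments' metadata.
#' @param max_invalid Maximum tolerated invalid fraction of the window
#'   (default 1/3).
#' @return A data.frame of class \code{segment_summaries} with columns
#'   \code{subject}, \code{paradigm}, \code{epoch}, \code{modality},
#'   \code{block}, \code{onset}, \code{signal}, \code{mean_pct},
#'   \code{valid_fraction}, \code{kept}, \code{reason}.
#' @export
apply_event_qc <- function(segments, artifact_windows = NULL,
                           max_invalid = 1 / 3) {
  stopifnot(inherits(segments, "event_segments"),
            max_invalid >= 0, max_invalid <= 1)
  ev <- segments$events
  if (is.null(artifact_windows))
    artifact_windows <- segments$meta$artifact_windows
  if (is.null(artifact_windows))
    artifact_windows <- matrix(numeric(0), ncol = 2)

  sig_out <- c(tHb = "BV", HbO2 = "HbO2", HHb = "HHb")
  ne <- nrow(ev)
  if (ne == 0) {
    out <- data.frame(subject = character(0), paradigm = character(0),
                      epoch = character(0), modality = character(0),
                      block = integer(0), onset = numeric(0),
                      signal = character(0), mean_pct = numeric(0),
                      valid_fraction = numeric(0), kept = logical(0),
                      reason = character(0), stringsAsFactors = FALSE)
    class(out) <- c("segment_summaries", "data.frame")
    return(out)
  }

  overlap <- rep(FALSE, ne)
  for (a in seq_len(nrow(artifact_windows)))
    overlap <- overlap | (artifact_windows[a, 1] <= ev$onset + segments$window &
                            artifact_windows[a, 2] >= ev$onset)

  kept <- !ev$dropped
  reason <- ifelse(ev$dropped, ev$reason, "")
  too_invalid <- kept & (1 - ev$valid_fraction > max_invalid)
  reason[too_invalid] <- "more than 1/3 of window invalid"
  kept <- kept & !too_invalid
  hit <- kept & overlap
  reason[hit] <- "motion artifact overlap"
  kept <- kept & !hit

  # mean over valid window samples, per event and signal
  nv <- rowSums(segments$valid)
  means <- sapply(segments$signals, function(s) {
    m <- rowSums(segments$normalized[, , s, drop = FALSE][, , 1] *
                   segments$valid, na.rm = TRUE) / nv
    ifelse(kept & nv > 0, m, NA_real_)
  })
  if (is.null(dim(means))) means <- matrix(means, nrow = ne)

  ns <- length(segments$signals)
  out <- data.frame(
    subject = rep(segments$meta$subject %||% NA_character_, ne * ns),
    paradigm = rep(ev$paradigm %||%
                     rep(segments$meta$paradigm %||% NA_character_, ne),
                   each = ns),
    epoch = rep(ev$epoch, each = ns), modality = rep(ev$modality, each = ns),
    block = rep(ev$block, each = ns), onset = rep(ev$onset, each = ns),
    signal = rep(unname(sig_out[segments$signals]), ne),
    mean_pct = as.vector(t(means)),
    valid_fraction = rep(ev$valid_fraction, each = ns),
    kept = rep(kept, each = ns), reason = rep(reason, each = ns),
    stringsAsFactors = FALSE)
  class(out) <- c("segment_summaries", "data.frame")
  out
}

#' @export
print.segment_summaries <- function(x, ...) {
  k <- x[x$signal == x$signal[1], , drop = FALSE]
  cat(sprintf("segment_summaries: %d events (%d kept), %d signals\n",
              nrow(k), sum(k$kept), length(unique(x$signal))))
  if (nrow(k))
    print(stats::aggregate(kept ~ epoch + modality, data = k, FUN = sum))
  invisible(x)
}
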