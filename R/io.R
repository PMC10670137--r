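# Column naming for the recording CSV: IAC_<wavelength>_<distance>, with the
# distance printed without trailing zeros (IAC_690_2.5, IAC_690_2).
channel_names <- function(prefix, wavelengths, distances) {
  # order matches column-major flattening of the (sample, wavelength,
  # distance) arrays: wavelength varies fastest
  as.vector(outer(wavelengths, distances, function(w, r)
    sprintf("%s_%s_%s", prefix, format(w, trim = TRUE),
            sub("\\.?0+$", "", format(r, trim = TRUE)))))
}

#' Write / read a raw FD recording as CSV
#'
#' One row per sample: \code{time_s}, then \code{IDC_<wl>_<r>},
#' \code{IAC_<wl>_<r>}, \code{phase_<wl>_<r>} for every wavelength (nm) and
#' distance (cm). UTF-8, '.' decimal separator, mandatory header.
#'
#' @param recording An \code{fd_recording}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly (writer); an \code{fd_recording} (reader).
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "fd_recording"))
  g <- recording$geometry
  n <- length(recording$time)
  flat <- function(a) matrix(a, n, length(g$wavelengths) * length(g$distances))
  df <- data.frame(time_s = recording$time, flat(recording$IDC),
                   flat(recording$IAC), flat(recording$phase),
                   check.names = FALSE)
  names(df) <- c("time_s",
                 channel_names("IDC", g$wavelengths, g$distances),
                 channel_names("IAC", g$wavelengths, g$distances),
                 channel_names("phase", g$wavelengths, g$distances))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param geometry An \code{fd_geometry} describing the expected channels.
#' @param fs Sampling rate to attach.
#' @param meta Metadata list to attach.
#' @export
read_recording_csv <- function(path, geometry = fd_geometry(), fs = 10.4,
                               meta = list()) {
  df <- utils::read.csv(path, check.names = FALSE)
  g <- geometry
  need <- c("time_s",
            channel_names("IDC", g$wavelengths, g$distances),
            channel_names("IAC", g$wavelengths, g$distances),
            channel_names("phase", g$wavelengths, g$distances))
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("recording CSV is missing column(s): ",
         paste(missing, collapse = ", "))
  n <- nrow(df)
  nw <- length(g$wavelengths); nd <- length(g$distances)
  grab <- function(prefix) {
    m <- as.matrix(df[, channel_names(prefix, g$wavelengths, g$distances),
                      drop = FALSE])
    array(m, dim = c(n, nw, nd))
  }
  out <- list(time = df$time_s, IDC = grab("IDC"), IAC = grab("IAC"),
              phase = grab("phase"), geometry = g, fs = fs, meta = meta)
  class(out) <- "fd_recording"
  out
}

#' Write / read the stimulation event log as JSON
#'
#' Schema: \code{{subject, paradigm, seed, events: [{onset_s, modality,
#' epoch, block}], tbs_pulse_times_s, artifact_windows_s}}.
#'
#' @param schedule A \code{session_schedule}.
#' @param path Output JSON path.
#' @param artifact_windows Optional two-column matrix of labeled artifact
#'   windows (s) to embed.
#' @export
write_event_json <- function(schedule, path, artifact_windows = NULL) {
  stopifnot(inherits(schedule, "session_schedule"))
  ev <- schedule$events
  obj <- list(subject = schedule$subject_id, paradigm = schedule$paradigm,
              seed = schedule$seed,
              events = data.frame(onset_s = ev$onset, modality = ev$modality,
                                  epoch = ev$epoch, block = ev$block),
              tbs_pulse_times_s = schedule$tbs_pulse_times,
              artifact_windows_s = if (is.null(artifact_windows))
                list() else apply(artifact_windows, 1, as.numeric,
                                  simplify = FALSE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_event_json
#' @export
read_event_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("subject", "paradigm", "seed", "events", "tbs_pulse_times_s")
  missing <- setdiff(need, names(obj))
  if (length(missing))
    stop("event JSON is missing field(s): ", paste(missing, collapse = ", "))
  ev <- obj$events
  evneed <- c("onset_s", "modality", "epoch", "block")
  if (!all(evneed %in% names(ev)))
    stop("event JSON events lack field(s): ",
         paste(setdiff(evneed, names(ev)), collapse = ", "))
  events <- data.frame(onset = ev$onset_s, modality = ev$modality,
                       epoch = ev$epoch, block = ev$block,
                       paradigm = obj$paradigm, stringsAsFactors = FALSE)
  aw <- obj$artifact_windows_s
  aw <- if (is.matrix(aw)) aw
        else if (length(aw)) do.call(rbind, lapply(aw, as.numeric))
        else matrix(numeric(0), ncol = 2)
  colnames(aw) <- c("start", "end")[seq_len(ncol(aw))]
  out <- list(events = events, tbs_pulse_times = obj$tbs_pulse_times_s,
              paradigm = obj$paradigm, subject_id = obj$subject,
              seed = obj$seed, artifact_windows = aw)
  class(out) <- "session_schedule"
  out
}

#' Write the synthetic ground-truth sidecar JSON
#'
#' Synthetic sessions only: baselines, condition amplitudes, scattering
#' ground truth and the extinction table used, so any downstream result can
#' be checked against what was simulated.
#'
#' @param tissue A \code{tissue_state}.
#' @param hrf The \code{hrf_model} used.
#' @param extinction The \code{extinction_table} used.
#' @param path Output JSON path.
#' @export
write_truth_json <- function(tissue, hrf, extinction, path) {
  obj <- list(baseline_uM = as.list(tissue$baseline),
              musp_cm1 = tissue$musp,
              amplitudes = hrf$amplitudes,
              peak_latency_s = hrf$peak_latency,
              dispersion_s = hrf$dispersion,
              hbo2_share = hrf$hbo2_share,
              extinction = list(wavelengths_nm = attr(extinction, "wavelengths"),
                                HbO2 = unclass(extinction)[, "HbO2"],
                                HHb = unclass(extinction)[, "HHb"]),
              synthetic = TRUE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a chromophore series as CSV
#'
#' Columns: \code{time_s, HbO2_uM, HHb_uM, tHb_uM, valid}.
#'
#' @param series A \code{chromophore_series}.
#' @param path CSV path.
#' @export
write_chromophore_csv <- function(series, path) {
  stopifnot(inherits(series, "chromophore_series"))
  df <- data.frame(time_s = series$time, HbO2_uM = series$HbO2,
                   HHb_uM = series$HHb, tHb_uM = series$tHb,
                   valid = series$valid)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_chromophore_csv
#' @param fs Sampling rate to attach.
#' @param meta Metadata list to attach.
#' @export
read_chromophore_csv <- function(path, fs = 10.4, meta = list()) {
  df <- utils::read.csv(path)
  need <- c("time_s", "HbO2_uM", "HHb_uM", "tHb_uM", "valid")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("chromophore CSV is missing column(s): ",
         paste(missing, collapse = ", "))
  out <- data.frame(time = df$time_s, HbO2 = df$HbO2_uM, HHb = df$HHb_uM,
                    tHb = df$tHb_uM, valid = as.logical(df$valid))
  attr(out, "fs") <- fs
  attr(out, "meta") <- meta
  class(out) <- c("chromophore_series", "data.frame")
  out
}

#' Write the per-wavelength inversion diagnostics as CSV
#'
#' Slopes, intercepts, R-squared and inverted optical properties per sample
#' and wavelength.
#'
#' @param series A \code{chromophore_series} from
#'   \code{\link{invert_recording}} (carries the diagnostics attributes).
#' @param path CSV path.
#' @export
write_diagnostics_csv <- function(series, path) {
  sl <- attr(series, "slopes")
  op <- attr(series, "optical")
  if (is.null(sl) || is.null(op))
    stop("series carries no inversion diagnostics")
  wl <- sl$wavelengths
  df <- data.frame(time_s = series$time)
  for (w in seq_along(wl)) {
    tag <- format(wl[w], trim = TRUE)
    for (f in c("SAC", "CAC", "R2_AC", "SDC", "CDC", "R2_DC",
                "Sphase", "Cphase", "R2_phase", "p_AC", "p_phase"))
      df[[paste0(f, "_", tag)]] <- sl[[f]][, w]
    df[[paste0("mua_", tag)]] <- op$mua[, w]
    df[[paste0("musp_", tag)]] <- op$musp[, w]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read segment summaries as CSV
#'
#' Columns: \code{subject, paradigm, epoch, modality, block, onset_s,
#' signal, mean_normalized_change_pct, valid_fraction, kept, reason}.
#'
#' @param summaries A \code{segment_summaries} data.frame.
#' @param path CSV path.
#' @export
write_summary_csv <- function(summaries, path) {
  df <- data.frame(subject = summaries$subject, paradigm = summaries$paradigm,
                   epoch = summaries$epoch, modality = summaries$modality,
                   block = summaries$block, onset_s = summaries$onset,
                   signal = summaries$signal,
                   mean_normalized_change_pct = summaries$mean_pct,
                   valid_fraction = summaries$valid_fraction,
                   kept = summaries$kept, reason = summaries$reason)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_csv
#' @export
read_summary_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("subject", "paradigm", "epoch", "modality", "block", "onset_s",
            "signal", "mean_normalized_change_pct", "kept")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("summary CSV is missing column(s): ",
         paste(missing, collapse = ", "))
  out <- data.frame(subject = as.character(df$subject),
                    paradigm = df$paradigm, epoch = df$epoch,
                    modality = df$modality, block = df$block,
                    onset = df$onset_s, signal = df$signal,
                    mean_pct = df$mean_normalized_change_pct,
                    valid_fraction = df$valid_fraction %||% NA_real_,
                    kept = as.logical(df$kept),
                    reason = df$reason %||% "", stringsAsFactors = FALSE)
  class(out) <- c("segment_summaries", "data.frame")
  out
}

#' Write the contrast results as CSV + JSON report
#'
#' The CSV holds the Welch table; the JSON mirrors the condition-matrix
#' structure (per-signal cell means with SE and the pairwise p-values, plus
#' the LMM contrast tables). All p-values are unadjusted.
#'
#' @param contrasts An \code{fd_contrasts}.
#' @param summaries The \code{segment_summaries} the contrasts came from
#'   (for cell means/SEs in the JSON report).
#' @param csv_path,json_path Output paths (NULL to skip either).
#' @export
write_contrasts <- function(contrasts, summaries = NULL, csv_path = NULL,
                            json_path = NULL) {
  stopifnot(inherits(contrasts, "fd_contrasts"))
  if (!is.null(csv_path))
    utils::write.csv(contrasts$welch, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    cells <- NULL
    if (!is.null(summaries)) {
      d <- summaries[summaries$kept & is.finite(summaries$mean_pct), ]
      d$condition <- condition_of(d$epoch, d$paradigm)
      cells <- do.call(rbind, lapply(split(d, d[c("signal", "condition",
                                                  "modality")], drop = TRUE),
        function(g) data.frame(signal = g$signal[1],
                               condition = g$condition[1],
                               modality = g$modality[1], n = nrow(g),
                               mean_pct = mean(g$mean_pct),
                               se_pct = stats::sd(g$mean_pct) / sqrt(nrow(g)))))
      rownames(cells) <- NULL
    }
    obj <- list(p_value_adjustment = "none",
                pre_pooled = contrasts$pooling$pooled,
                cells = cells, welch = contrasts$welch,
                lmm = lapply(contrasts$lmm, function(r)
                  list(signal = r$signal, modality = r$modality,
                       contrasts = r$contrasts, sd_subject = r$sd_subject,
                       sd_residual = r$sd_residual, n_obs = r$n_obs,
                       n_subjects = r$n_subjects, singular = r$singular)))
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(contrasts)
}
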