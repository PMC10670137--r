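#' Run configuration
#'
#' One serializable object holding every tunable of a full run: probe
#' geometry, filter specification, quality-control threshold, baseline
#' mode, segmentation window, evoked-response amplitudes, noise model,
#' extinction coefficients, subject roster and seed. A run re-executed from
#' its persisted config and seed reproduces identical outputs.
#'
#' @param subjects Data frame with columns \code{subject}, \code{paradigm},
#'   \code{seed}; or NULL for a default 2-subject crossover roster.
#' @param geometry An \code{fd_geometry}.
#' @param extinction An \code{extinction_table}.
#' @param hrf An \code{hrf_model}.
#' @param noise A \code{noise_model}.
#' @param fs Sampling rate (Hz).
#' @param baseline Baseline concentrations, uM.
#' @param musp Ground-truth reduced scattering per wavelength (1/cm).
#' @param filter_spec List: \code{low_cut}, \code{high_cut}, \code{taps}.
#' @param qc_threshold R-squared gate threshold.
#' @param baseline_mode Segmentation baseline mode.
#' @param window Segmentation window (s).
#' @param seed Master seed; per-session seeds derive from it when the
#'   roster does not name its own.
#' @return An object of class \code{run_config}.
#' @export
fd_config <- function(subjects = NULL, geometry = fd_geometry(),
                      extinction = extinction_table(), hrf = hrf_model(),
                      noise = noise_model(), fs = 10.4,
                      baseline = c(HbO2 = 60, HHb = 25), musp = c(8, 7),
                      filter_spec = list(low_cut = 0.02, high_cut = 0.7,
                                         taps = 1001),
                      qc_threshold = 0.97,
                      baseline_mode = "onset-sample", window = 6,
                      seed = 1L) {
  if (is.null(subjects))
    subjects <- data.frame(
      subject = rep(c("s01", "s02"), each = 2),
      paradigm = rep(c("cTBS", "iTBS"), 2),
      seed = NA_integer_, stringsAsFactors = FALSE)
  stopifnot(all(c("subject", "paradigm") %in% names(subjects)))
  if (is.null(subjects$seed)) subjects$seed <- NA_integer_
  miss <- is.na(subjects$seed)
  subjects$seed[miss] <- vapply(which(miss), function(i)
    derive_seed(seed, 100L + i), 0L)
  out <- list(subjects = subjects, geometry = geometry,
              extinction = extinction, hrf = hrf, noise = noise, fs = fs,
              baseline = baseline, musp = musp, filter_spec = filter_spec,
              qc_threshold = qc_threshold, baseline_mode = baseline_mode,
              window = window, seed = seed)
  class(out) <- "run_config"
  out
}

#' Read a run configuration from YAML
#'
#' Every field is optional and falls back to the package default. Lists
#' mirror the constructor arguments, e.g. \code{geometry: {distances:
#' [2, 2.5, 3, 3.5], wavelengths: [690, 830]}}.
#'
#' @param path YAML file.
#' @return A \code{run_config}.
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  arg <- function(block, f, default) {
    v <- y[[block]][[f]]
    if (is.null(v)) default else v
  }
  geometry <- fd_geometry(
    distances = arg("geometry", "distances", c(2, 2.5, 3, 3.5)),
    wavelengths = arg("geometry", "wavelengths", c(690, 830)),
    modulation_freq = arg("geometry", "modulation_freq", 110e6),
    refractive_index = arg("geometry", "refractive_index", 1.4))
  extinction <- extinction_table(
    wavelengths = arg("extinction", "wavelengths", c(690, 830)),
    HbO2 = arg("extinction", "HbO2", c(0.276, 0.974)),
    HHb = arg("extinction", "HHb", c(2.052, 0.693)))
  amp <- y$hrf$amplitudes
  hrf <- hrf_model(
    amplitudes = if (is.null(amp)) NULL else as.data.frame(amp),
    peak_latency = arg("hrf", "peak_latency", 3.5),
    dispersion = arg("hrf", "dispersion", 1.5),
    hbo2_share = arg("hrf", "hbo2_share", 0.8))
  noise <- noise_model(
    cardiac = arg("noise", "cardiac", c(1.1, 1.0)),
    respiratory = arg("noise", "respiratory", c(0.25, 0.5)),
    mayer = arg("noise", "mayer", c(0.1, 0.5)),
    drift_sd = arg("noise", "drift_sd", 0.01),
    optical_sd = arg("noise", "optical_sd", 0.01),
    phase_sd = arg("noise", "phase_sd", 0.005),
    motion_rate = arg("noise", "motion_rate", 0.1),
    motion_magnitude = arg("noise", "motion_magnitude", 2),
    motion_duration = arg("noise", "motion_duration", 1))
  subjects <- if (is.null(y$subjects)) NULL else {
    s <- as.data.frame(do.call(rbind, lapply(y$subjects, function(r)
      c(subject = r$subject, paradigm = r$paradigm,
        seed = r$seed %||% NA))), stringsAsFactors = FALSE)
    s$seed <- suppressWarnings(as.integer(s$seed))
    s
  }
  bad <- setdiff(unique(subjects$paradigm), c("cTBS", "iTBS"))
  if (length(bad))
    stop("unknown paradigm in config: ", paste(bad, collapse = ", "))
  fd_config(subjects = subjects, geometry = geometry,
            extinction = extinction, hrf = hrf, noise = noise,
            fs = y$fs %||% 10.4,
            baseline = c(HbO2 = arg("baseline", "HbO2", 60),
                         HHb = arg("baseline", "HHb", 25)),
            musp = unlist(y$musp) %||% c(8, 7),
            filter_spec = list(low_cut = arg("filter", "low_cut", 0.02),
                               high_cut = arg("filter", "high_cut", 0.7),
                               taps = arg("filter", "taps", 1001)),
            qc_threshold = y$qc_threshold %||% 0.97,
            baseline_mode = y$baseline_mode %||% "onset-sample",
            window = y$window %||% 6,
            seed = y$seed %||% 1L)
}

session_tag <- function(subject, paradigm) paste(subject, paradigm, sep = "_")

write_manifest <- function(dir, files) {
  files <- files[file.exists(file.path(dir, files))]
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(dir, files))))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Pipeline stage runners
#'
#' File-based stage execution binding the simulator, inversion,
#' preprocessing and statistics into reproducible runs. Each stage reads
#' the previous stage's files from \code{dir}, writes its own outputs
#' there, appends to \code{manifest.csv} (md5 content hashes) and logs
#' kept/discarded counts. \code{run_all} chains all four.
#'
#' Files per session \code{<subject>_<paradigm>}: \code{*_recording.csv},
#' \code{*_events.json}, \code{*_truth.json}, \code{*_chromophores.csv},
#' \code{*_diagnostics.csv}, \code{*_summaries.csv}; cohort level:
#' \code{contrasts.csv}, \code{report.json}.
#'
#' @param config A \code{run_config}.
#' @param dir Working/output directory.
#' @param quiet Suppress progress messages.
#' @return \code{run_all} returns the \code{fd_contrasts}; the stage
#'   runners return the written file names, invisibly.
#' @export
run_simulate <- function(config, dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (i in seq_len(nrow(config$subjects))) {
    s <- config$subjects[i, ]
    tag <- session_tag(s$subject, s$paradigm)
    sess <- simulate_session(s$paradigm, s$subject, s$seed,
                             hrf = config$hrf, noise = config$noise,
                             baseline = config$baseline, musp = config$musp,
                             fs = config$fs, geometry = config$geometry,
                             extinction = config$extinction)
    write_recording_csv(sess$recording, file.path(dir, paste0(tag, "_recording.csv")))
    write_event_json(sess$schedule, file.path(dir, paste0(tag, "_events.json")),
                     artifact_windows = sess$recording$meta$artifact_windows)
    write_truth_json(sess$tissue, config$hrf, config$extinction,
                     file.path(dir, paste0(tag, "_truth.json")))
    files <- c(files, paste0(tag, c("_recording.csv", "_events.json",
                                    "_truth.json")))
    if (!quiet) message("simulated session ", tag, " (",
                        nrow(sess$schedule$events), " events)")
  }
  write_manifest(dir, files)
  invisible(files)
}

#' @rdname run_simulate
#' @export
run_invert <- function(config, dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  files <- character(0)
  for (i in seq_len(nrow(config$subjects))) {
    s <- config$subjects[i, ]
    tag <- session_tag(s$subject, s$paradigm)
    rec_path <- file.path(dir, paste0(tag, "_recording.csv"))
    if (!file.exists(rec_path)) stop("missing recording: ", rec_path)
    sched <- read_event_json(file.path(dir, paste0(tag, "_events.json")))
    rec <- read_recording_csv(rec_path, config$geometry, config$fs,
                              meta = list(subject = sched$subject_id,
                                          paradigm = sched$paradigm,
                                          artifact_windows = sched$artifact_windows))
    series <- invert_recording(rec, config$extinction, config$qc_threshold)
    write_chromophore_csv(series, file.path(dir, paste0(tag, "_chromophores.csv")))
    write_diagnostics_csv(series, file.path(dir, paste0(tag, "_diagnostics.csv")))
    files <- c(files, paste0(tag, c("_chromophores.csv", "_diagnostics.csv")))
    if (!quiet) message(sprintf("inverted %s: %.1f%% samples valid", tag,
                                100 * mean(series$valid)))
  }
  write_manifest(dir, files)
  invisible(files)
}

#' @rdname run_simulate
#' @export
run_preprocess <- function(config, dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  kernel <- design_bandpass(config$filter_spec$low_cut,
                            config$filter_spec$high_cut,
                            config$filter_spec$taps, config$fs)
  files <- character(0)
  for (i in seq_len(nrow(config$subjects))) {
    s <- config$subjects[i, ]
    tag <- session_tag(s$subject, s$paradigm)
    sched <- read_event_json(file.path(dir, paste0(tag, "_events.json")))
    series <- read_chromophore_csv(
      file.path(dir, paste0(tag, "_chromophores.csv")), config$fs,
      meta = list(subject = sched$subject_id, paradigm = sched$paradigm,
                  artifact_windows = sched$artifact_windows))
    filtered <- apply_filter(series, kernel)
    segments <- segment_events(filtered, sched$events, config$window,
                               config$baseline_mode)
    summaries <- apply_event_qc(segments, sched$artifact_windows)
    write_summary_csv(summaries, file.path(dir, paste0(tag, "_summaries.csv")))
    files <- c(files, paste0(tag, "_summaries.csv"))
    if (!quiet) {
      k <- summaries[summaries$signal == "BV", ]
      message(sprintf("preprocessed %s: %d/%d events kept", tag,
                      sum(k$kept), nrow(k)))
      disc <- k$reason[!k$kept]
      if (length(disc)) for (r in names(table(disc)))
        message("  discarded ", table(disc)[[r]], ": ", r)
    }
  }
  write_manifest(dir, files)
  invisible(files)
}

#' @rdname run_simulate
#' @export
run_analyze <- function(config, dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  tags <- session_tag(config$subjects$subject, config$subjects$paradigm)
  paths <- file.path(dir, paste0(tags, "_summaries.csv"))
  ok <- file.exists(paths)
  if (!any(ok)) stop("no summary CSVs found in ", dir)
  summaries <- do.call(rbind, lapply(paths[ok], read_summary_csv))
  class(summaries) <- c("segment_summaries", "data.frame")
  contrasts <- run_comparisons(summaries, lmm_method = "wald")
  write_contrasts(contrasts, summaries,
                  csv_path = file.path(dir, "contrasts.csv"),
                  json_path = file.path(dir, "report.json"))
  write_manifest(dir, c("contrasts.csv", "report.json"))
  if (!quiet) print(contrasts)
  invisible(contrasts)
}

#' @rdname run_simulate
#' @export
run_all <- function(config, dir, quiet = FALSE) {
  run_simulate(config, dir, quiet)
  run_invert(config, dir, quiet)
  run_preprocess(config, dir, quiet)
  run_analyze(config, dir, quiet = quiet)
}
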