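#' Theta-burst stimulation pulse trains
#'
#' Theta-burst stimulation (TBS) delivers bursts of 3 pulses at 50 Hz,
#' repeated at 5 Hz (every 200 ms). The continuous variant (cTBS) runs one
#' uninterrupted 40 s train; the intermittent variant (iTBS) delivers a 2 s
#' train (10 bursts) every 10 s, for trains starting across 190 s. Both
#' deliver exactly 600 pulses.
#'
#' @return Strictly increasing pulse times in seconds, starting at 0.
#' @examples
#' length(make_ctbs_schedule())  # 600
#' length(make_itbs_schedule())  # 600
#' @export
make_ctbs_schedule <- function() {
  burst_onsets <- seq(0, 39.8, by = 0.2)           # 200 bursts
  sort(as.vector(outer(c(0, 0.02, 0.04), burst_onsets, `+`)))
}

#' @rdname make_ctbs_schedule
#' @export
make_itbs_schedule <- function() {
  train_onsets <- seq(0, 190, by = 10)             # 20 trains
  burst_onsets <- as.vector(outer(seq(0, 1.8, by = 0.2), train_onsets, `+`))
  sort(as.vector(outer(c(0, 0.02, 0.04), burst_onsets, `+`)))
}

#' Build a full stimulation session schedule
#'
#' Lays out the single-pulse TMS (spTMS) probe blocks around one TBS train:
#' 3 blocks before TBS and 5 after, each holding 25 real and 25 sham pulses
#' in seeded random order with inter-stimulus intervals drawn uniformly from
#' 6-8 s; blocks are separated by 6-10 s. The TBS train (cTBS or iTBS)
#' starts a fixed gap after the last pre-TBS event, and the first post-TBS
#' block starts the same gap after the last TBS pulse. A lead-in before the
#' first block leaves room for filter edge effects.
#'
#' All randomness flows from \code{seed}; calling twice with the same
#' arguments yields an identical schedule.
#'
#' @param paradigm \code{"cTBS"} or \code{"iTBS"}.
#' @param subject_id Subject label.
#' @param seed Integer seed.
#' @param n_pre_blocks,n_post_blocks Number of probe blocks before/after TBS.
#' @param n_real,n_sham Real and sham pulses per block.
#' @param isi_range Inter-stimulus interval bounds in s.
#' @param ibi_range Inter-block interval bounds in s.
#' @param tbs_gap Gap (s) between the last pre event and TBS onset, and
#'   between the last TBS pulse and the first post block.
#' @param lead_in Time (s) before the first event.
#' @return An object of class \code{session_schedule}: list with
#'   \code{events} (data.frame: onset, modality, epoch, block),
#'   \code{tbs_pulse_times}, \code{paradigm}, \code{subject_id}, \code{seed}.
#' @export
make_session_schedule <- function(paradigm = c("cTBS", "iTBS"),
                                  subject_id = "s01", seed = 1L,
                                  n_pre_blocks = 3L, n_post_blocks = 5L,
                                  n_real = 25L, n_sham = 25L,
                                  isi_range = c(6, 8), ibi_range = c(6, 10),
                                  tbs_gap = 60, lead_in = 60) {
  paradigm <- match.arg(paradigm)
  stopifnot(isi_range[1] <= isi_range[2], ibi_range[1] <= ibi_range[2],
            tbs_gap >= 0, lead_in >= 0)
  one_block <- function(start, block_index, epoch) {
    n <- n_real + n_sham
    modality <- sample(rep(c("real", "sham"), c(n_real, n_sham)))
    onsets <- start + cumsum(c(0, stats::runif(n - 1, isi_range[1], isi_range[2])))
    data.frame(onset = onsets, modality = modality, epoch = epoch,
               block = block_index, stringsAsFactors = FALSE)
  }

  set.seed(derive_seed(seed, 1L))
  blocks <- list()
  cursor <- lead_in
  bi <- 0L
  for (b in seq_len(n_pre_blocks)) {
    bi <- bi + 1L
    blk <- one_block(cursor, bi, "pre")
    blocks[[bi]] <- blk
    cursor <- max(blk$onset) + stats::runif(1, ibi_range[1], ibi_range[2])
  }
  pre_end <- max(blocks[[bi]]$onset)
  tbs_start <- pre_end + tbs_gap
  train <- if (paradigm == "cTBS") make_ctbs_schedule() else make_itbs_schedule()
  tbs_pulse_times <- tbs_start + train
  cursor <- max(tbs_pulse_times) + tbs_gap
  for (b in seq_len(n_post_blocks)) {
    bi <- bi + 1L
    blk <- one_block(cursor, bi, "post")
    blocks[[bi]] <- blk
    cursor <- max(blk$onset) + stats::runif(1, ibi_range[1], ibi_range[2])
  }
  events <- do.call(rbind, blocks)
  events$paradigm <- paradigm
  rownames(events) <- NULL

  out <- list(events = events, tbs_pulse_times = tbs_pulse_times,
              paradigm = paradigm, subject_id = subject_id, seed = seed,
              isi_range = isi_range, ibi_range = ibi_range)
  class(out) <- "session_schedule"
  out
}

#' @export
print.session_schedule <- function(x, ...) {
  ev <- x$events
  cat(sprintf("spTMS session schedule: subject %s, paradigm %s, seed %d\n",
              x$subject_id, x$paradigm, x$seed))
  cat(sprintf("  %d events in %d blocks (%d real / %d sham), %d TBS pulses\n",
              nrow(ev), length(unique(ev$block)),
              sum(ev$modality == "real"), sum(ev$modality == "sham"),
              length(x$tbs_pulse_times)))
  cat(sprintf("  span: %.1f - %.1f s\n", min(ev$onset), max(ev$onset)))
  invisible(x)
}
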