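# Epoched single-channel EEG recordings.

#' Construct an epoched EEG recording
#'
#' Bundles a referenced single-channel EEG trace (in microvolts) with its
#' sampling rate, segmented into whole 30-second scoring epochs. The vector
#' length must be exactly `n_epochs * 30 * fs`; use [segment_into_epochs()]
#' to build one from an arbitrary-length trace.
#'
#' @param samples numeric vector of amplitudes in microvolts.
#' @param fs sampling rate in Hz (integer, >= 100).
#' @param channel_label channel name, e.g. `"C3-M2"`.
#' @return an object of class `eeg_epochs` with fields `samples`, `fs`,
#'   `epoch_len_s` (always 30), `n_epochs` and `channel_label`.
#' @seealso [segment_into_epochs()], [read_psg_edf()]
#' @export
eeg_epochs <- function(samples, fs, channel_label = "") {
  if (!is.numeric(samples) || length(samples) == 0L)
    stop("'samples' must be a non-empty numeric vector")
  if (!is_count(fs, min = 100L))
    stop("'fs' must be an integer sampling rate >= 100 Hz")
  fs <- as.integer(fs)
  spe <- EPOCH_LEN_S * fs
  if (length(samples) %% spe != 0L)
    stop("length(samples) is not a whole number of 30-s epochs; ",
         "use segment_into_epochs() to trim the trace")
  n_epochs <- length(samples) %/% spe
  if (n_epochs < 1L) stop("recording too short: less than one 30-s epoch")
  structure(
    list(samples = as.numeric(samples), fs = fs,
         epoch_len_s = EPOCH_LEN_S, n_epochs = n_epochs,
         channel_label = as.character(channel_label)),
    class = "eeg_epochs")
}

#' Segment a trace into 30-second epochs
#'
#' Keeps `floor(length(trace) / (30 * fs))` whole epochs and discards any
#' trailing partial epoch with a warning (sleep scoring operates on whole
#' 30-s epochs only).
#'
#' @param trace numeric vector, microvolts.
#' @param fs sampling rate in Hz (integer, >= 100).
#' @param channel_label optional channel name carried into the result.
#' @return an [eeg_epochs] object.
#' @export
segment_into_epochs <- function(trace, fs, channel_label = "") {
  if (!is_count(fs, min = 100L))
    stop("'fs' must be an integer sampling rate >= 100 Hz")
  fs <- as.integer(fs)
  spe <- EPOCH_LEN_S * fs
  if (length(trace) < spe)
    stop("recording too short: ", length(trace), " samples is less than one ",
         "30-s epoch at ", fs, " Hz")
  n_epochs <- length(trace) %/% spe
  discarded <- length(trace) - n_epochs * spe
  if (discarded > 0L)
    warning("discarding ", discarded,
            " trailing samples (partial final epoch)")
  eeg_epochs(trace[seq_len(n_epochs * spe)], fs, channel_label)
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %s: %d epochs (%.1f min) at %d Hz, %d samples\n",
              if (nzchar(x$channel_label)) x$channel_label else "unnamed",
              x$n_epochs, x$n_epochs * x$epoch_len_s / 60, x$fs,
              length(x$samples)))
  invisible(x)
}

# samples of epoch e (1-based) as a vector
epoch_samples <- function(rec, e) {
  spe <- rec$epoch_len_s * rec$fs
  rec$samples[((e - 1L) * spe + 1L):(e * spe)]
}
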