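# Minimal EDF (European Data Format) input/output for PSG signals.
#
# EDF stores an ASCII header (256 bytes + 256 per signal) followed by data
# records of 16-bit little-endian integers; physical values are recovered by
# linear rescaling between the digital and physical ranges declared per
# signal. Only the subset needed for single-rate EEG traces is implemented:
# continuous records, one-second record duration, identical rate across the
# channels being derived. No R package for EDF is used because none is
# required beyond this subset.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)
}

num_field <- function(x, width) pad_field(format(x, scientific = FALSE), width)

#' Write signals to an EDF file
#'
#' Writes one or more equally sampled microvolt traces as 16-bit EDF with
#' one-second data records. Each channel is scaled to its own symmetric
#' physical range, so the quantization step is
#' `2 * max(abs(x)) / 65535` microvolts.
#'
#' @param path output file path.
#' @param signals named list of numeric vectors (microvolts), all covering
#'   the same duration.
#' @param fs sampling rate in Hz; a scalar shared by all channels or a
#'   vector with one rate per channel.
#' @return `path`, invisibly.
#' @seealso [read_psg_edf()], [write_night_edf()]
#' @export
write_edf <- function(path, signals, fs) {
  if (!is.list(signals) || length(signals) == 0L || is.null(names(signals)) ||
      any(!nzchar(names(signals))))
    stop("'signals' must be a non-empty named list of numeric vectors")
  ns <- length(signals)
  if (!all(vapply(fs, is_count, logical(1))))
    stop("'fs' must be positive integer rate(s)")
  fs <- rep_len(as.integer(fs), ns)
  len <- vapply(signals, length, integer(1))
  if (any(len %% fs != 0L))
    stop("signal lengths must be whole numbers of seconds")
  n_rec <- unique(len %/% fs)
  if (length(n_rec) != 1L)
    stop("all signals must cover the same duration")

  dig_min <- -32768; dig_max <- 32767
  phys_max <- vapply(signals, function(x) {
    m <- max(abs(x), na.rm = TRUE)
    if (!is.finite(m) || m == 0) 1 else m
  }, numeric(1))
  phys_min <- -phys_max

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8L),
    pad_field("X X X X", 80L),                      # patient id
    pad_field("Startdate X X X X", 80L),            # recording id
    pad_field("01.01.00", 8L), pad_field("00.00.00", 8L),
    num_field(256L * (1L + ns), 8L),
    pad_field("", 44L),
    num_field(n_rec, 8L),
    num_field(1L, 8L),                              # record duration [s]
    num_field(ns, 4L))
  sig_hdr <- paste0(
    paste0(vapply(names(signals), pad_field, "", width = 16L), collapse = ""),
    strrep(pad_field("", 80L), ns),                 # transducer
    strrep(pad_field("uV", 8L), ns),                # physical dimension
    paste0(vapply(phys_min, num_field, "", width = 8L), collapse = ""),
    paste0(vapply(phys_max, num_field, "", width = 8L), collapse = ""),
    strrep(num_field(dig_min, 8L), ns),
    strrep(num_field(dig_max, 8L), ns),
    strrep(pad_field("", 80L), ns),                 # prefiltering
    paste0(vapply(fs, num_field, "", width = 8L), collapse = ""),
    strrep(pad_field("", 32L), ns))
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)

  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  dig <- lapply(seq_len(ns), function(i) {
    d <- round((signals[[i]] - phys_min[i]) * scale[i]) + dig_min
    as.integer(pmin(pmax(d, dig_min), dig_max))
  })
  # records are channel-sequential within each one-second record
  offsets <- c(0L, cumsum(fs))
  out <- matrix(0L, nrow = sum(fs), ncol = n_rec)
  for (i in seq_len(ns))
    out[(offsets[i] + 1L):offsets[i + 1L], ] <- matrix(dig[[i]],
                                                       nrow = fs[i])
  writeBin(as.integer(out), con, size = 2L, endian = "little")
  invisible(path)
}

#' Write an epoched recording as a single-channel EDF
#'
#' @param rec an [eeg_epochs] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_night_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_epochs"))
  label <- if (nzchar(rec$channel_label)) rec$channel_label else "EEG"
  sigs <- list(rec$samples)
  names(sigs) <- label
  write_edf(path, sigs, rec$fs)
}

read_edf_raw <- function(path) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  fixed <- readChar(con, 256L, useBytes = TRUE)
  if (nchar(fixed, type = "bytes") < 256L) stop("not a valid EDF file: ", path)
  fld <- function(s, from, len) substr(s, from, from + len - 1L)
  n_rec <- as.integer(fld(fixed, 237L, 8L))
  rec_dur <- as.numeric(fld(fixed, 245L, 8L))
  ns <- as.integer(fld(fixed, 253L, 4L))
  if (is.na(ns) || ns < 1L) stop("not a valid EDF file: ", path)
  sig <- readChar(con, 256L * ns, useBytes = TRUE)
  grab <- function(offset, width, n = ns) {
    start <- offset * ns
    vapply(seq_len(n), function(i)
      trimws(substr(sig, start + (i - 1L) * width + 1L, start + i * width)),
      character(1))
  }
  labels <- grab(0L, 16L)
  dims <- grab(16L + 80L, 8L)
  phys_min <- as.numeric(grab(16L + 80L + 8L, 8L))
  phys_max <- as.numeric(grab(16L + 80L + 16L, 8L))
  dig_min <- as.numeric(grab(16L + 80L + 24L, 8L))
  dig_max <- as.numeric(grab(16L + 80L + 32L, 8L))
  spr <- as.integer(grab(16L + 80L + 8L + 32L + 80L, 8L))
  total <- sum(spr) * n_rec
  raw <- readBin(con, integer(), n = total, size = 2L, endian = "little",
                 signed = TRUE)
  if (length(raw) < total) stop("truncated EDF data section: ", path)
  offsets <- c(0L, cumsum(spr))
  signals <- vector("list", ns)
  for (i in seq_len(ns)) {
    idx <- as.vector(outer(offsets[i] + seq_len(spr[i]),
                           (seq_len(n_rec) - 1L) * sum(spr), `+`))
    x <- phys_min[i] +
      (raw[idx] - dig_min[i]) * (phys_max[i] - phys_min[i]) /
        (dig_max[i] - dig_min[i])
    # normalise physical units to microvolts
    dim_i <- tolower(dims[i])
    if (dim_i == "mv") {
      x <- x * 1e3
    } else if (dim_i == "v") {
      x <- x * 1e6
    } else if (!dim_i %in% c("", "uv", "µv")) {
      warning("unknown physical dimension '", dims[i], "' for channel ",
              labels[i], "; assuming microvolts")
    }
    signals[[i]] <- x
  }
  names(signals) <- labels
  list(signals = signals, fs = spr / rec_dur, labels = labels,
       n_rec = n_rec, rec_dur = rec_dur)
}

#' Read a referenced EEG channel from an EDF file
#'
#' Reads `active` (and optionally subtracts `reference`, e.g. C3 minus M2),
#' converts physical units to microvolts, and segments the derived trace
#' into 30-second epochs. Pre-referenced channels (a channel already named
#' `"C3-M2"` in the file) are read by passing `reference = NULL`.
#'
#' @param path EDF/EDF+ file path.
#' @param active name of the active channel as stored in the file.
#' @param reference name of the reference channel to subtract, or `NULL`.
#' @return an [eeg_epochs] object with `channel_label` set to
#'   `"active-reference"` (or `active`).
#' @export
read_psg_edf <- function(path, active, reference = NULL) {
  edf <- read_edf_raw(path)
  pick <- function(name) {
    i <- match(name, edf$labels)
    if (is.na(i))
      stop("channel not found: '", name, "'; available channels: ",
           paste(edf$labels, collapse = ", "))
    i
  }
  ia <- pick(active)
  if (!is.null(reference)) {
    ir <- pick(reference)
    if (edf$fs[ia] != edf$fs[ir])
      stop("rate mismatch: ", active, " at ", edf$fs[ia], " Hz but ",
           reference, " at ", edf$fs[ir], " Hz")
    trace <- edf$signals[[ia]] - edf$signals[[ir]]
    label <- paste0(active, "-", reference)
  } else {
    trace <- edf$signals[[ia]]
    label <- active
  }
  fs <- edf$fs[ia]
  if (abs(fs - round(fs)) > 1e-9)
    stop("non-integer sampling rate in EDF: ", fs)
  if (length(trace) < EPOCH_LEN_S * round(fs))
    stop("recording too short: total duration under 30 s")
  segment_into_epochs(trace, round(fs), label)
}
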