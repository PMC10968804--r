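# Seeded generator of synthetic polysomnography nights.
#
# The generator emulates only the statistical structure the classifier
# senses: alpha-dominated wake epochs, high-amplitude slow-wave N3 epochs,
# mixed-frequency light/REM epochs, and movement epochs that are either
# high-amplitude broadband bursts or flat electrode-loss segments. All
# stochastic content (background noise, rhythm placement, burst/dropout
# draws) is driven by the config seed, so nights regenerate identically.

SYNTH_STAGES <- c("WAKE", "N3", "LIGHT", "REM", "MOVEMENT")

#' Configuration of a synthetic night
#'
#' Stage morphology defaults mirror the AASM scoring definitions: wake
#' epochs carry a 10 Hz, 30 uV alpha sinusoid in 22 (> 15) randomly placed
#' seconds; N3 epochs a 1 Hz slow wave of 150 uV peak-to-peak (twice the
#' 75 uV scoring floor) over 80% of the epoch; light/REM epochs a 5 Hz,
#' 20 uV theta rhythm; movement epochs a 500 uV broadband burst over 20
#' (> 15) contiguous seconds, or a flat electrode-loss segment with
#' probability `dropout_prob`. Background activity is Gaussian noise
#' band-limited to the 0.3-35 Hz recording passband at 10 uV RMS; the
#' movement burst is band-limited the same way, since everything a real
#' channel records has passed the amplifier's AASM filter settings.
#'
#' @param fs sampling rate in Hz (default 256; see [hospital_profiles()]).
#' @param stage_script explicit per-epoch truth sequence over
#'   `WAKE, N3, LIGHT, REM, MOVEMENT` (recycled to the requested length),
#'   or `NULL` to use `markov` or the built-in cyclic template.
#' @param markov optional Markov-chain spec: list with `states` (subset of
#'   the five stage names), `P` (transition matrix, rows summing to 1) and
#'   `init` (initial distribution).
#' @param alpha_freq,alpha_amp,alpha_seconds_wake alpha rhythm frequency
#'   (Hz), amplitude (uV) and number of alpha seconds per wake epoch
#'   (must exceed 15).
#' @param delta_freq,delta_p2p,delta_fraction_n3 slow-wave frequency (Hz),
#'   peak-to-peak amplitude (uV, at least the 75 uV scoring floor) and
#'   fraction of each N3 epoch covered.
#' @param theta_freq,theta_amp mixed-frequency rhythm of light/REM epochs.
#' @param background_rms background noise RMS (uV).
#' @param movement_amp burst amplitude (uV, uniform in `+/- movement_amp`
#'   before band-limiting).
#' @param movement_seconds burst/dropout duration per movement epoch
#'   (must exceed 15).
#' @param dropout_prob probability a movement epoch is flat electrode loss
#'   instead of a burst.
#' @param movement_alpha if `TRUE`, movement bursts additionally carry an
#'   explicit alpha sinusoid (exercises the "alpha during movement"
#'   branch; bursts already contain alpha-band energy regardless).
#' @param seed RNG seed, or `NULL` to use the ambient RNG.
#' @return an object of class `synthetic_night_config`.
#' @export
synthetic_night_config <- function(fs = 256L, stage_script = NULL,
                                   markov = NULL,
                                   alpha_freq = 10, alpha_amp = 30,
                                   alpha_seconds_wake = 22L,
                                   delta_freq = 1, delta_p2p = 150,
                                   delta_fraction_n3 = 0.8,
                                   theta_freq = 5, theta_amp = 20,
                                   background_rms = 10,
                                   movement_amp = 500,
                                   movement_seconds = 20L,
                                   dropout_prob = 0.3,
                                   movement_alpha = FALSE, seed = NULL) {
  if (!is_count(fs, 100L)) stop("'fs' must be an integer >= 100")
  if (delta_p2p < 75)
    stop("'delta_p2p' below the 75 uV slow-wave scoring floor")
  if (!(delta_fraction_n3 > 0 && delta_fraction_n3 <= 1))
    stop("'delta_fraction_n3' must be in (0, 1]")
  if (!is_count(alpha_seconds_wake, 16L) || alpha_seconds_wake > 30L)
    stop("'alpha_seconds_wake' must be an integer in 16..30")
  if (!is_count(movement_seconds, 16L) || movement_seconds > 30L)
    stop("'movement_seconds' must be an integer in 16..30")
  if (!(dropout_prob >= 0 && dropout_prob <= 1))
    stop("'dropout_prob' must be a probability")
  if (!is.null(stage_script)) {
    bad <- setdiff(unique(stage_script), SYNTH_STAGES)
    if (length(bad)) stop("unknown stage(s) in script: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(fs = as.integer(fs), stage_script = stage_script,
                 markov = markov, alpha_freq = alpha_freq,
                 alpha_amp = alpha_amp,
                 alpha_seconds_wake = as.integer(alpha_seconds_wake),
                 delta_freq = delta_freq, delta_p2p = delta_p2p,
                 delta_fraction_n3 = delta_fraction_n3,
                 theta_freq = theta_freq, theta_amp = theta_amp,
                 background_rms = background_rms,
                 movement_amp = movement_amp,
                 movement_seconds = as.integer(movement_seconds),
                 dropout_prob = dropout_prob,
                 movement_alpha = movement_alpha, seed = seed),
            class = "synthetic_night_config")
}

#' Sampling-rate presets of the three source hospitals
#'
#' @return named integer vector of sampling rates (200, 256, 512 Hz).
#' @export
hospital_profiles <- function() {
  c(hospital_200 = 200L, hospital_256 = 256L, hospital_512 = 512L)
}

# stylized 20-epoch sleep cycle: a wake run, light sleep descending into a
# slow-wave block, brief REM, and interspersed movement epochs (10%)
SYNTH_TEMPLATE <- c("WAKE", "WAKE", "WAKE", "WAKE",
                    "LIGHT", "LIGHT", "LIGHT",
                    "N3", "N3", "N3", "N3", "N3", "N3",
                    "LIGHT", "MOVEMENT", "LIGHT",
                    "REM", "REM", "MOVEMENT", "LIGHT")

gen_stages_impl <- function(cfg, n_epochs) {
  if (!is.null(cfg$stage_script))
    return(rep_len(cfg$stage_script, n_epochs))
  if (!is.null(cfg$markov)) {
    mk <- cfg$markov
    states <- mk$states
    P <- as.matrix(mk$P)
    if (is.null(states) || nrow(P) != length(states) ||
        ncol(P) != length(states))
      stop("markov spec needs 'states' and a square transition matrix 'P'")
    if (any(abs(rowSums(P) - 1) > 1e-9))
      stop("markov transition rows must sum to 1")
    init <- if (is.null(mk$init)) rep(1 / length(states), length(states))
            else mk$init
    if (abs(sum(init) - 1) > 1e-9)
      stop("markov initial distribution must sum to 1")
    s <- integer(n_epochs)
    s[1L] <- sample.int(length(states), 1L, prob = init)
    for (e in seq_len(n_epochs - 1L))
      s[e + 1L] <- sample.int(length(states), 1L, prob = P[s[e], ])
    return(states[s])
  }
  rep_len(SYNTH_TEMPLATE, n_epochs)
}

#' Generate a truth stage sequence
#'
#' Draws the per-epoch truth stages from the explicit script, the Markov
#' spec, or the built-in cyclic template (in that order of precedence).
#' Seeded-reproducible via `cfg$seed`.
#'
#' @param cfg a [synthetic_night_config()].
#' @param n_epochs number of epochs (>= 1).
#' @return character vector of stages over
#'   `WAKE, N3, LIGHT, REM, MOVEMENT`.
#' @export
generate_stage_sequence <- function(cfg, n_epochs) {
  stopifnot(inherits(cfg, "synthetic_night_config"), is_count(n_epochs))
  with_seed(cfg$seed, gen_stages_impl(cfg, n_epochs))
}

# Gaussian noise band-limited to [lo, hi] Hz by an FFT brick-wall, scaled
# to the requested RMS
band_noise <- function(n, fs, rms, lo = 0.3, hi = 35) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(0:(n %/% 2), -rev(seq_len(n - n %/% 2 - 1L))) * fs / n
  X[!(abs(f) >= lo & abs(f) <= hi)] <- 0
  x <- Re(stats::fft(X, inverse = TRUE) / n)
  x * rms / stats::sd(x)
}

synth_epoch_impl <- function(stage, cfg) {
  fs <- cfg$fs
  n <- EPOCH_LEN_S * fs
  t <- (0:(n - 1L)) / fs
  x <- band_noise(n, fs, cfg$background_rms)
  flat <- FALSE
  sec_idx <- function(s0, len) (s0 * fs + 1L):((s0 + len) * fs)
  if (stage == "WAKE") {
    secs <- sample(0:(EPOCH_LEN_S - 1L), cfg$alpha_seconds_wake)
    for (s in secs) {
      i <- sec_idx(s, 1L)
      x[i] <- x[i] + cfg$alpha_amp * sin(2 * pi * cfg$alpha_freq * t[i])
    }
  } else if (stage == "N3") {
    len <- max(1L, round(cfg$delta_fraction_n3 * EPOCH_LEN_S))
    s0 <- sample(0:(EPOCH_LEN_S - len), 1L)
    i <- sec_idx(s0, len)
    x[i] <- x[i] + (cfg$delta_p2p / 2) * sin(2 * pi * cfg$delta_freq * t[i])
  } else if (stage %in% c("LIGHT", "REM")) {
    x <- x + cfg$theta_amp * sin(2 * pi * cfg$theta_freq * t)
  } else if (stage == "MOVEMENT") {
    s0 <- sample(0:(EPOCH_LEN_S - cfg$movement_seconds), 1L)
    i <- sec_idx(s0, cfg$movement_seconds)
    flat <- stats::runif(1L) < cfg$dropout_prob
    if (flat) {
      x[i] <- 0  # electrode loss: exactly no signal
    } else {
      burst_rms <- cfg$movement_amp / sqrt(3)  # RMS of U(-amp, amp)
      x[i] <- x[i] + band_noise(length(i), fs, burst_rms)
      if (cfg$movement_alpha)
        x[i] <- x[i] + cfg$alpha_amp * sin(2 * pi * cfg$alpha_freq * t[i])
    }
  } else stop("unknown stage: ", stage)
  list(samples = x, flat = flat)
}

#' Synthesize one 30-second epoch waveform
#'
#' Uses the ambient RNG stream (seed handling belongs to
#' [generate_night()]).
#'
#' @param stage one of `WAKE, N3, LIGHT, REM, MOVEMENT`.
#' @param cfg a [synthetic_night_config()].
#' @return numeric vector of `30 * fs` microvolt samples.
#' @export
synthesize_epoch_waveform <- function(stage, cfg) {
  stopifnot(inherits(cfg, "synthetic_night_config"),
            stage %in% SYNTH_STAGES)
  synth_epoch_impl(stage, cfg)$samples
}

#' Generate a synthetic night
#'
#' Draws the stage sequence, synthesizes the per-epoch waveforms, and
#' builds the technician truth hypnogram. Movement epochs are labelled the
#' way a technician scores them under the AASM movement rule: a burst
#' epoch (which carries alpha-band activity) is scored `W`; a flat
#' electrode-loss epoch takes the stage of an adjacent wake epoch or,
#' failing that, of the following epoch. Remaining stages map
#' `WAKE -> W`, `N3 -> N3`, `LIGHT -> N2`, `REM -> REM`.
#'
#' @param cfg a [synthetic_night_config()].
#' @param n_epochs number of epochs.
#' @param edf_path optional path: write the signal as EDF.
#' @param hypnogram_path optional path: write the truth hypnogram CSV.
#' @return list with `recording` (an [eeg_epochs]), `truth` (a technician
#'   [hypnogram]), `stages` (the raw generator sequence, including
#'   `MOVEMENT`), and `movement_flat` (per-epoch logical; `TRUE` where a
#'   movement epoch was electrode loss).
#' @export
generate_night <- function(cfg, n_epochs, edf_path = NULL,
                           hypnogram_path = NULL) {
  stopifnot(inherits(cfg, "synthetic_night_config"), is_count(n_epochs))
  out <- with_seed(cfg$seed, {
    stages <- gen_stages_impl(cfg, n_epochs)
    ep <- lapply(stages, synth_epoch_impl, cfg = cfg)
    list(stages = stages,
         samples = unlist(lapply(ep, `[[`, "samples")),
         flat = vapply(ep, `[[`, logical(1), "flat"))
  })
  rec <- eeg_epochs(out$samples, cfg$fs, "C3-M2")
  base <- c(WAKE = "W", N3 = "N3", LIGHT = "N2", REM = "REM",
            MOVEMENT = NA)[out$stages]
  movement <- out$stages == "MOVEMENT"
  labels <- if (any(movement)) {
    resolve_movement_epochs(movement,
                            alpha_present = movement & !out$flat,
                            base_stages = base, wake = "W")
  } else unname(base)
  truth <- hypnogram(labels, "technician")
  if (!is.null(edf_path)) write_night_edf(rec, edf_path)
  if (!is.null(hypnogram_path)) write_hypnogram(truth, hypnogram_path)
  list(recording = rec, truth = truth, stages = out$stages,
       movement_flat = out$flat & movement)
}
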