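# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures are stored.

# one second of a sinusoid, in microvolts
tone_second <- function(freq, amp, fs = 256L, phase = 0) {
  amp * sin(2 * pi * freq * (0:(fs - 1)) / fs + phase)
}

# a band-energy table from explicit per-second columns
toy_energy_table <- function(delta, theta, alpha, total, fs = 256L) {
  E <- cbind(delta = delta, theta = theta, alpha = alpha, total = total)
  structure(list(per_second = E, totals = colSums(E), fs = fs,
                 n_seconds = nrow(E)),
            class = "band_energy_table")
}

# a feature series from explicit per-second vectors (lengths multiple of 30)
toy_features <- function(pm, pw, pn3) {
  stopifnot(length(pm) == length(pw), length(pw) == length(pn3),
            length(pm) %% 30L == 0L)
  structure(list(pm = pm, pw = pw, pn3 = pn3, n_seconds = length(pm),
                 n_epochs = length(pm) %/% 30L),
            class = "feature_series")
}

# per-second repetition helper: one value per second -> per-epoch blocks
per_epoch_seconds <- function(...) unlist(list(...))

# the 2N-FFT "folded squared DFT magnitude" oracle for the marginal
# spectrum of a one-second segment (independent of the lag-kernel route)
fft_marginal_oracle <- function(z) {
  N <- length(z)
  Z <- stats::fft(c(z, rep(0 + 0i, N)))
  S <- Mod(Z)^2
  (S[1:N] + S[(N + 1):(2 * N)]) / (2 * N)
}

# hypnogram pair realizing exact 3x3 confusion counts (predicted by row,
# technician by column, stage order WAKE, N3, OTHER)
hypnograms_from_counts <- function(counts) {
  stages <- c("WAKE", "N3", "OTHER")
  pred <- character(0); truth <- character(0)
  for (i in 1:3) for (j in 1:3) {
    pred <- c(pred, rep(stages[i], counts[i, j]))
    truth <- c(truth, rep(stages[j], counts[i, j]))
  }
  list(pred = hypnogram(pred, "predicted"),
       truth = hypnogram(truth, "predicted"))
}

# small synthetic night with a fast sampling rate kept at the package
# minimum to hold test runtime down
quick_night <- function(n_epochs, seed, fs = 200L, ...) {
  generate_night(synthetic_night_config(fs = fs, seed = seed, ...),
                 n_epochs)
}
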