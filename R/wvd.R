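# Discrete Wigner-Ville distribution on one-second blocks, its marginal
# spectrum, and band-energy extraction.
#
# The WVD of a signal x(t) is W(t, f) = Int x(t + tau/2) x*(t - tau/2)
# exp(-i 2 pi f tau) dtau: a real-valued quadratic time-frequency energy
# density whose time integral (the marginal spectrum) equals the power
# spectrum. Discretely, each one-second block of N = fs samples is
# transformed via the instantaneous autocorrelation kernel
#   K[n, m] = z[n + m] * Conj(z[n - m]),   z zero-extended outside the block,
# and an N-point DFT over the lag index m. Because the kernel advances two
# signal samples per unit lag, frequency bin k sits at k * fs / (2N) Hz:
# with N = fs this is exactly 0.5 Hz spacing, which places the clinical
# band edges (0.5, 4, 8, 13 Hz) on bin centers. Oscillatory cross-terms
# between signal components are present in the matrix but integrate to the
# spectral-leakage level in the marginal, which is why band energies are
# read off the marginal rather than a smoothed distribution.

#' Analytic signal via the discrete Hilbert transform
#'
#' Returns the complex analytic extension of a real segment: the real part
#' equals the input and the negative-frequency DFT bins are zero. The
#' discrete WVD of a real signal aliases above fs/4 and mixes positive and
#' negative frequencies; computing it from the analytic signal confines all
#' energy to `[0, fs/2)`.
#'
#' @param segment numeric vector (one second of samples, microvolts).
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(segment) {
  n <- length(segment)
  if (n == 0L) stop("empty segment")
  if (!all(is.finite(segment))) stop("segment contains non-finite values")
  X <- stats::fft(segment)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    if (n > 1L) h[2:((n + 1L) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# folded lag kernel for time index n (1-based), length-N complex vector
wvd_lag_kernel <- function(z, n) {
  N <- length(z)
  kv <- complex(length.out = N)
  kv[1L] <- Re(z[n])^2 + Im(z[n])^2
  mmax <- min(n - 1L, N - n)
  if (mmax > 0L) {
    m <- seq_len(mmax)
    cm <- z[n + m] * Conj(z[n - m])
    kv[1L + m] <- cm
    kv[N + 1L - m] <- Conj(cm)
  }
  kv
}

#' Discrete Wigner-Ville distribution of a one-second segment
#'
#' @param segment complex vector of exactly `fs` samples (one second),
#'   normally from [analytic_signal()].
#' @param fs sampling rate in Hz; must equal `length(segment)` (the
#'   per-second block contract).
#' @return a real `N x N` matrix, rows indexed by time sample `n` and
#'   columns by frequency bins `0, 0.5, ..., (N-1)/2 * fs/N` Hz at
#'   `fs/(2N)` Hz spacing. Scaling is such that `sum(W)` equals the segment
#'   energy `sum(Mod(segment)^2)`; columns may be locally negative, as is
#'   inherent to the WVD.
#' @export
wvd_matrix <- function(segment, fs = length(segment)) {
  N <- length(segment)
  if (N == 0L) stop("empty segment")
  if (N != fs)
    stop("per-second contract violated: segment has ", N,
         " samples but fs = ", fs)
  segment <- as.complex(segment)
  K <- vapply(seq_len(N), function(n) wvd_lag_kernel(segment, n),
              complex(N))
  # columns of K are per-time lag kernels; DFT down each column
  W <- t(Re(stats::mvfft(K))) / N
  colnames(W) <- format((seq_len(N) - 1L) * fs / (2 * N))
  W
}

#' Marginal spectrum of the per-second WVD
#'
#' Integrates the WVD over the time axis of the block without materializing
#' the matrix: summing the lag kernel over `n` first and transforming once
#' is algebraically identical to `colSums(wvd_matrix(segment))`. Entries
#' below zero (rounding noise) are clipped to 0.
#'
#' @inheritParams wvd_matrix
#' @return numeric vector of `N` energies, one per frequency bin at
#'   `fs/(2N)` Hz spacing; sums to the segment energy `sum(Mod(segment)^2)`.
#' @export
marginal_spectrum <- function(segment, fs = length(segment)) {
  N <- length(segment)
  if (N == 0L) stop("empty segment")
  if (N != fs)
    stop("per-second contract violated: segment has ", N,
         " samples but fs = ", fs)
  z <- as.complex(segment)
  M0 <- (N - 1L) %/% 2L
  kv <- complex(length.out = N)
  kv[1L] <- sum(Re(z)^2 + Im(z)^2)
  for (m in seq_len(M0)) {
    cm <- sum(z[(1L + 2L * m):N] * Conj(z[1:(N - 2L * m)]))
    kv[1L + m] <- cm
    kv[N + 1L - m] <- Conj(cm)
  }
  pmax(Re(stats::fft(kv)) / N, 0)
}

#' Clinical EEG band definitions
#'
#' The four bands used for staging, as half-open intervals `[f_lo, f_hi)`
#' so that shared edges are never double-counted (4 Hz belongs to theta,
#' 8 Hz to alpha, 13 Hz to neither):
#' delta `[0.5, 4)`, theta `[4, 8)`, alpha `[8, 13)` and the whole
#' recorded band `[0.3, 35)` Hz (the AASM filter passband, labelled
#' `total`).
#'
#' @return a data frame with columns `name`, `f_lo`, `f_hi`.
#' @export
default_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "total"),
             f_lo = c(0.5, 4, 8, 0.3),
             f_hi = c(4, 8, 13, 35))
}

validate_bands <- function(bands, fs) {
  req <- c("delta", "theta", "alpha", "total")
  if (!is.data.frame(bands) ||
      !all(c("name", "f_lo", "f_hi") %in% names(bands)) ||
      !setequal(bands$name, req))
    stop("'bands' must be a data frame with rows named ",
         paste(req, collapse = ", "), "; see default_bands()")
  if (any(bands$f_lo < 0) || any(bands$f_lo >= bands$f_hi))
    stop("each band needs 0 <= f_lo < f_hi")
  if (any(bands$f_hi > fs / 2))
    stop("band upper edge ", max(bands$f_hi), " Hz exceeds the Nyquist ",
         "frequency ", fs / 2, " Hz")
  bands[match(req, bands$name), ]
}

#' Per-second band energies of a night
#'
#' For every second of the recording, computes the analytic signal, its
#' WVD marginal spectrum, and the energy falling in each band (bins whose
#' center frequency lies in `[f_lo, f_hi)`), plus the all-night totals.
#' Energies are in microvolt-squared-seconds: one second of an A-microvolt
#' sinusoid carries `A^2 / 2`. The factor-of-two inflation the analytic
#' signal introduces at positive frequencies is divided back out so that
#' band energies refer to the real trace.
#'
#' @param rec an [eeg_epochs] recording.
#' @param bands band definitions as from [default_bands()].
#' @return an object of class `band_energy_table`: list with `per_second`
#'   (matrix `n_seconds x 4`, columns `delta, theta, alpha, total`),
#'   `totals` (named vector, the column sums), `fs` and `n_seconds`.
#' @export
band_energies_per_second <- function(rec, bands = default_bands()) {
  stopifnot(inherits(rec, "eeg_epochs"))
  bands <- validate_bands(bands, rec$fs)
  fs <- rec$fs
  n_seconds <- length(rec$samples) %/% fs
  centers <- (seq_len(fs) - 1L) * fs / (2 * fs)  # = (0:(N-1)) * 0.5 Hz
  bin_idx <- lapply(seq_len(nrow(bands)), function(i)
    which(centers >= bands$f_lo[i] & centers < bands$f_hi[i]))
  E <- matrix(0, n_seconds, 4L,
              dimnames = list(NULL, c("delta", "theta", "alpha", "total")))
  for (s in seq_len(n_seconds)) {
    x <- rec$samples[((s - 1L) * fs + 1L):(s * fs)]
    mg <- marginal_spectrum(analytic_signal(x)) / (2 * fs)
    E[s, ] <- vapply(bin_idx, function(ix) sum(mg[ix]), numeric(1))
  }
  structure(list(per_second = E, totals = colSums(E), fs = fs,
                 n_seconds = n_seconds),
            class = "band_energy_table")
}

#' @export
print.band_energy_table <- function(x, ...) {
  cat(sprintf("<band_energy_table> %d seconds (%d epochs) at %d Hz\n",
              x$n_seconds, x$n_seconds %/% EPOCH_LEN_S, x$fs))
  cat("all-night totals (uV^2 s):\n")
  print(signif(x$totals, 4))
  invisible(x)
}

#' Export per-second band energies as CSV
#'
#' Writes `second,E_delta,E_theta,E_alpha,E_total` rows with 0-based
#' second indices.
#'
#' @param energies a [band_energies_per_second()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_band_energies <- function(energies, path) {
  stopifnot(inherits(energies, "band_energy_table"))
  d <- data.frame(second = seq_len(energies$n_seconds) - 1L,
                  E_delta = energies$per_second[, "delta"],
                  E_theta = energies$per_second[, "theta"],
                  E_alpha = energies$per_second[, "alpha"],
                  E_total = energies$per_second[, "total"])
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
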