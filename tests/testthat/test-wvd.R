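# Analytic signal, discrete WVD, marginal spectrum and band energies.

test_that("analytic signal preserves the real part and is one-sided", {
  expect_identical(analytic_signal(numeric(8) + 0), complex(8))
  set.seed(21)
  for (n in c(200L, 256L, 255L)) {
    x <- rnorm(n)
    z <- analytic_signal(x)
    expect_lt(max(abs(Re(z) - x)), 1e-10)
    Z <- fft(z)
    neg <- if (n %% 2 == 0) (n / 2 + 2):n else ((n + 1) / 2 + 1):n
    expect_lt(max(Mod(Z[neg])), 1e-9 * max(Mod(Z)))
  }
  # a 10 Hz cosine concentrates at +10 Hz only
  fs <- 256L
  z <- analytic_signal(tone_second(10, 1, fs, phase = pi / 2))
  Z <- Mod(fft(z))
  expect_identical(which.max(Z), 11L)            # bin at +10 Hz (1-based)
  expect_lt(sum(Z[-11L]), 1e-8 * Z[11L])
  expect_error(analytic_signal(numeric(0)), "empty")
})

test_that("wvd_matrix conserves energy and localizes a pure tone", {
  fs <- 256L
  expect_true(all(wvd_matrix(complex(fs), fs) == 0))
  expect_error(wvd_matrix(complex(100), 256), "per-second")
  set.seed(22)
  z <- complex(real = rnorm(fs), imaginary = rnorm(fs))
  W <- wvd_matrix(z)
  expect_identical(dim(W), c(fs, fs))
  expect_true(is.numeric(W))
  expect_lt(abs(sum(W) - sum(Mod(z)^2)), 1e-6 * sum(Mod(z)^2))
  # unit complex exponential at 10 Hz: every interior time slice peaks at
  # the 10 Hz bin (the first and last samples have no lag support)
  z10 <- exp(2i * pi * 10 * (0:(fs - 1)) / fs)
  W10 <- wvd_matrix(z10)
  peak_bin <- 10 / 0.5 + 1
  expect_true(all(apply(W10[2:(fs - 1), ], 1L, which.max) == peak_bin))
})

test_that("marginal spectrum equals the time-integral of the matrix", {
  fs <- 200L
  set.seed(23)
  z <- analytic_signal(rnorm(fs))
  mg <- marginal_spectrum(z)
  expect_lt(max(abs(mg - pmax(colSums(wvd_matrix(z)), 0))),
            1e-10 * max(mg))
  expect_true(all(mg >= 0))
  expect_identical(marginal_spectrum(complex(fs), fs), numeric(fs))
})

test_that("marginal spectrum matches the squared-DFT oracle", {
  set.seed(24)
  for (fs in c(200L, 256L)) {
    for (i in 1:100) {
      z <- analytic_signal(rnorm(fs, sd = 20))
      mg <- marginal_spectrum(z)
      oracle <- fft_marginal_oracle(z)
      expect_lt(max(abs(mg - oracle)), 1e-8 * max(oracle))
      # energy conservation (discrete Moyal/marginal identity)
      expect_lt(abs(sum(mg) - sum(Mod(z)^2)), 1e-6 * sum(Mod(z)^2))
    }
  }
})

test_that("cross-terms of a two-tone second vanish in the marginal", {
  fs <- 256L
  x <- tone_second(6, 1, fs) + tone_second(11, 1, fs)
  z <- analytic_signal(x)
  mg <- marginal_spectrum(z)
  freqs <- (0:(fs - 1)) * 0.5
  expect_setequal(order(-mg)[1:2], which(freqs %in% c(6, 11)))
  # the matrix carries a strong oscillatory cross-term at the 8.5 Hz
  # midpoint; in the marginal it integrates down to spectral-leakage level
  W <- wvd_matrix(z)
  mid <- which(freqs == 8.5)
  expect_gt(max(abs(W[, mid])), 0.1 * max(W))
  expect_lt(mg[mid], 1e-3 * max(mg))
  # and the marginal still agrees with the leakage-only FFT oracle
  expect_lt(max(abs(mg - fft_marginal_oracle(z))), 1e-8 * max(mg))
})

test_that("marginal is invariant to time shifts of a bin-centered tone", {
  fs <- 256L
  z <- exp(2i * pi * 12 * (0:(fs - 1)) / fs)
  m1 <- marginal_spectrum(z)
  for (s in c(1L, 7L, 128L)) {
    zs <- c(z[(s + 1):fs], z[1:s])
    expect_lt(max(abs(marginal_spectrum(zs) - m1)), 1e-8 * max(m1))
  }
})

test_that("band energies localize tones into their clinical bands", {
  fs <- 256L
  alpha_epoch <- rep(tone_second(10, 30, fs), 30)
  rec <- eeg_epochs(alpha_epoch, fs)
  E <- band_energies_per_second(rec)
  # a few percent of a tone's energy leaks out of its band: the 1-s
  # untapered block bounds the attainable concentration
  expect_true(all(E$per_second[, "alpha"] / E$per_second[, "total"] > 0.95))
  expect_true(all(E$per_second[, "theta"] / E$per_second[, "total"] < 0.02))
  # one second of a 30 uV sinusoid carries ~ 30^2/2 uV^2 s
  expect_equal(unname(E$per_second[1, "total"]), 450, tolerance = 0.01)

  delta_rec <- eeg_epochs(rep(tone_second(1, 80, fs), 30), fs)
  Ed <- band_energies_per_second(delta_rec)
  expect_true(all(Ed$per_second[, "delta"] / Ed$per_second[, "total"] > 0.98))

  zero <- band_energies_per_second(eeg_epochs(numeric(30 * fs) + 0, fs))
  expect_true(all(zero$per_second == 0))
})

test_that("band energy table invariants hold on a synthetic night", {
  night <- quick_night(10, seed = 25)
  E <- band_energies_per_second(night$recording)
  expect_true(all(E$per_second >= 0))
  expect_equal(unname(E$totals), unname(colSums(E$per_second)))
  sub <- rowSums(E$per_second[, c("delta", "theta", "alpha")])
  expect_true(all(sub <= E$per_second[, "total"] * (1 + 1e-9)))
})

test_that("disjoint band energies add up to the covering band", {
  night <- quick_night(2, seed = 26)
  fs <- night$recording$fs
  bands <- default_bands()
  bands$f_lo <- c(0.5, 4, 8, 0.5)   # total redefined as [0.5, 13)
  bands$f_hi <- c(4, 8, 13, 13)
  E <- band_energies_per_second(night$recording, bands)
  sub <- rowSums(E$per_second[, c("delta", "theta", "alpha")])
  expect_lt(max(abs(sub - E$per_second[, "total"])),
            1e-9 * max(E$per_second[, "total"]))
  bad <- default_bands()
  bad$f_hi[4] <- fs  # beyond Nyquist
  expect_error(band_energies_per_second(night$recording, bad), "Nyquist")
})
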