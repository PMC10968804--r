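# The synthetic night generator.

test_that("explicit stage scripts are honored exactly", {
  cfg <- synthetic_night_config(stage_script = c(rep("WAKE", 5),
                                                 rep("LIGHT", 5),
                                                 rep("N3", 5)), seed = 71)
  expect_identical(generate_stage_sequence(cfg, 15),
                   c(rep("WAKE", 5), rep("LIGHT", 5), rep("N3", 5)))
  expect_error(synthetic_night_config(stage_script = c("WAKE", "DEEP")),
               "unknown stage")
})

test_that("stage sequences are reproducible and Markov specs validated", {
  cfg <- synthetic_night_config(seed = 72)
  expect_identical(generate_stage_sequence(cfg, 40),
                   generate_stage_sequence(cfg, 40))
  # absorbing N3 chain: once entered, never left
  mk <- list(states = c("WAKE", "N3"),
             P = matrix(c(0.7, 0, 0.3, 1), 2, 2), init = c(1, 0))
  cfg2 <- synthetic_night_config(markov = mk, seed = 73)
  s <- generate_stage_sequence(cfg2, 60)
  first <- match("N3", s)
  expect_false(is.na(first))
  expect_true(all(s[first:60] == "N3"))
  bad <- list(states = c("WAKE", "N3"),
              P = matrix(c(0.7, 0, 0.4, 1), 2, 2), init = c(1, 0))
  cfg3 <- synthetic_night_config(markov = bad, seed = 74)
  expect_error(generate_stage_sequence(cfg3, 10), "sum to 1")
})

test_that("nights regenerate identically under a fixed seed", {
  cfg <- synthetic_night_config(fs = 200L, seed = 75)
  n1 <- generate_night(cfg, 20)
  n2 <- generate_night(cfg, 20)
  expect_identical(n1$recording$samples, n2$recording$samples)
  expect_identical(n1$truth, n2$truth)
  expect_identical(n1$stages, n2$stages)
})

test_that("N3 epochs satisfy the slow-wave amplitude floor", {
  cfg <- synthetic_night_config(fs = 200L, stage_script = "N3", seed = 76)
  night <- generate_night(cfg, 5)
  fs <- 200L
  for (e in 1:5) {
    x <- sleepwvd:::epoch_samples(night$recording, e)
    p2p <- vapply(1:30, function(s)
      diff(range(x[((s - 1) * fs + 1):(s * fs)])), numeric(1))
    expect_gte(max(p2p), 0.9 * cfg$delta_p2p)
    # >= 20% of the epoch carries the slow wave (AASM N3 criterion)
    expect_gte(sum(p2p >= 75), 6)
  }
})

test_that("dropout movement epochs have over 15 flat seconds", {
  cfg <- synthetic_night_config(fs = 200L, dropout_prob = 1,
                                stage_script = c("LIGHT", "MOVEMENT",
                                                 "LIGHT"), seed = 77)
  night <- generate_night(cfg, 3)
  expect_identical(night$movement_flat, c(FALSE, TRUE, FALSE))
  x <- sleepwvd:::epoch_samples(night$recording, 2)
  flat_secs <- sum(vapply(1:30, function(s)
    all(x[((s - 1) * 200 + 1):(s * 200)] == 0), logical(1)))
  expect_gt(flat_secs, 15)
  # and those seconds carry exactly zero normalized energy
  f <- extract_features(night$recording)
  expect_gt(sum(f$pm[31:60] <= 1e-12), 15)
})

test_that("generated wake epochs are wake-positive after extraction", {
  night <- quick_night(20, seed = 78)
  f <- extract_features(night$recording)
  wake_counts <- colSums(matrix(f$pw > 1e-6, nrow = 30))
  expect_true(all(wake_counts[night$stages == "WAKE"] > 15))
})

test_that("truth labels follow the technician movement rule", {
  # burst movement epochs read as wake (alpha-band content present);
  # flat ones inherit the following epoch's stage
  cfg <- synthetic_night_config(fs = 200L, dropout_prob = 0,
                                stage_script = c("LIGHT", "MOVEMENT",
                                                 "N3"), seed = 79)
  expect_identical(generate_night(cfg, 3)$truth$labels,
                   c("N2", "W", "N3"))
  cfg2 <- synthetic_night_config(fs = 200L, dropout_prob = 1,
                                 stage_script = c("LIGHT", "MOVEMENT",
                                                  "N3"), seed = 80)
  expect_identical(generate_night(cfg2, 3)$truth$labels,
                   c("N2", "N3", "N3"))
})

test_that("a single-epoch script yields exactly 30 * fs samples", {
  cfg <- synthetic_night_config(fs = 200L, stage_script = "N3", seed = 81)
  night <- generate_night(cfg, 1)
  expect_identical(length(night$recording$samples), 30L * 200L)
  expect_identical(night$truth$labels, "N3")
})

test_that("generate_night writes EDF and CSV sidecars on request", {
  cfg <- synthetic_night_config(fs = 200L, seed = 82)
  edf <- withr::local_tempfile(fileext = ".edf")
  csv <- withr::local_tempfile(fileext = ".csv")
  night <- generate_night(cfg, 5, edf_path = edf, hypnogram_path = csv)
  back <- read_psg_edf(edf, "C3-M2")
  expect_identical(back$n_epochs, 5L)
  qstep <- 2 * max(abs(night$recording$samples)) / 65535
  expect_lt(max(abs(back$samples - night$recording$samples)), qstep)
  expect_identical(read_hypnogram(csv), night$truth)
})

test_that("config invariants are enforced", {
  expect_error(synthetic_night_config(delta_p2p = 60), "75")
  expect_error(synthetic_night_config(alpha_seconds_wake = 15), "16..30")
  expect_error(synthetic_night_config(movement_seconds = 10), "16..30")
  expect_error(synthetic_night_config(dropout_prob = 1.4), "probability")
  expect_error(synthetic_night_config(delta_fraction_n3 = 0), "0, 1")
})
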