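# The rule engine: strict boundaries, precedence, movement resolution.

test_that("movement seconds use strict pm > tm, and pm = 0 flags loss", {
  tm <- 5e-4
  expect_identical(movement_flags(c(5e-4, 0, 6e-4, 4e-4), tm),
                   c(FALSE, TRUE, TRUE, FALSE))
  # robustness margin around exact zero
  expect_true(movement_flags(1e-13, tm))
})

test_that("movement epochs need strictly more than 15 flagged seconds", {
  flag16 <- c(rep(TRUE, 16), rep(FALSE, 14))
  flag15 <- c(rep(TRUE, 15), rep(FALSE, 15))
  flags <- c(flag16, flag15, rep(FALSE, 30))
  expect_identical(detect_movement_epochs(flags), c(TRUE, FALSE, FALSE))
})

test_that("wake epochs need strictly more than 15 seconds above t1", {
  t1 <- 0.5
  ep16 <- c(rep(1, 16), rep(0, 14))
  ep15 <- c(rep(1, 15), rep(0, 15))
  expect_identical(score_wake(c(ep16, ep15, rep(0, 30)), t1),
                   c(TRUE, FALSE, FALSE))
  # values exactly at t1 do not count
  expect_false(score_wake(rep(t1, 30), t1))
})

test_that("N3 scoring thresholds the epoch 80th percentile strictly", {
  t2 <- 5.87e-5
  ep <- c(rep(1e-4, 24), rep(0, 6))     # p80 = 1e-4 > t2
  expect_true(score_n3(ep, t2))
  expect_false(score_n3(rep(t2, 30), t2))  # p80 == t2 exactly
  # at the 20% boundary: 6 slow-wave seconds leave the rank-24 value in
  # the background, 7 lift it to the slow-wave level
  ep6 <- c(rep(1, 6), rep(1e-9, 24))
  expect_identical(percentile_value(ep6, 80), 1e-9)
  expect_false(score_n3(ep6, t2))
  ep7 <- c(rep(1, 7), rep(1e-9, 23))
  expect_identical(percentile_value(ep7, 80), 1)
  expect_true(score_n3(ep7, t2))
})

test_that("movement resolution follows alpha, neighbors, then the next epoch", {
  # alpha anywhere in the epoch wins, however brief
  expect_identical(
    resolve_movement_epochs(c(FALSE, TRUE, FALSE),
                            c(FALSE, TRUE, FALSE),
                            c("OTHER", NA, "N3")),
    c("OTHER", "WAKE", "N3"))
  # no alpha, preceding epoch wake
  expect_identical(
    resolve_movement_epochs(c(FALSE, TRUE, FALSE),
                            c(FALSE, FALSE, FALSE),
                            c("WAKE", NA, "N3")),
    c("WAKE", "WAKE", "N3"))
  # no alpha, following epoch wake
  expect_identical(
    resolve_movement_epochs(c(FALSE, TRUE, FALSE),
                            c(FALSE, FALSE, FALSE),
                            c("N3", NA, "WAKE")),
    c("N3", "WAKE", "WAKE"))
  # otherwise: stage of the following epoch, composed over a run
  expect_identical(
    resolve_movement_epochs(c(FALSE, TRUE, TRUE, FALSE, FALSE),
                            rep(FALSE, 5),
                            c("OTHER", NA, NA, "N3", "OTHER")),
    c("OTHER", "N3", "N3", "N3", "OTHER"))
  # trailing run inherits the preceding stage
  expect_identical(
    resolve_movement_epochs(c(FALSE, FALSE, FALSE, TRUE, TRUE),
                            rep(FALSE, 5),
                            c("OTHER", "N3", "N3", NA, NA)),
    c("OTHER", "N3", "N3", "N3", "N3"))
  # a run before a wake epoch becomes wake (rule b via the run tail)
  expect_identical(
    resolve_movement_epochs(c(FALSE, TRUE, TRUE, FALSE),
                            rep(FALSE, 4),
                            c("N3", NA, NA, "WAKE")),
    c("N3", "WAKE", "WAKE", "WAKE"))
  expect_error(resolve_movement_epochs(c(TRUE, TRUE), c(FALSE, FALSE),
                                       c(NA, NA)),
               "unresolvable")
})

test_that("wake takes precedence over N3 when both rules fire", {
  # epoch 1: both wake- and N3-positive; epoch 2: neither
  pm <- rep(1e-5, 60)
  pw <- c(rep(1, 30), rep(-1, 30))
  pn3 <- c(rep(0.9, 30), rep(0, 30))
  f <- toy_features(pm, pw, pn3)
  h <- stage_night(f, thresholds(t1 = 0.5, t2 = 0.5))
  expect_identical(h$labels, c("WAKE", "OTHER"))
})

test_that("stage_night assigns exactly one stage per epoch", {
  night <- quick_night(20, seed = 41)
  f <- extract_features(night$recording)
  h <- stage_night(f, thresholds(t1 = 1e-5, t2 = 1e-4))
  expect_identical(length(h), 20L)
  expect_true(all(h$labels %in% c("WAKE", "N3", "OTHER")))
  tr <- attr(h, "trace")
  expect_identical(nrow(tr), 20L)
  expect_true(all(tr$wake_seconds >= 0 & tr$wake_seconds <= 30))
  expect_true(all(tr$movement_seconds >= 0 & tr$movement_seconds <= 30))
})

test_that("staging is deterministic and monotone in its thresholds", {
  night <- quick_night(20, seed = 42)
  f <- extract_features(night$recording)
  th <- thresholds(t1 = 2e-5, t2 = 2e-4)
  expect_identical(stage_night(f, th)$labels, stage_night(f, th)$labels)
  # raising t1 never increases wake calls among non-movement epochs;
  # raising t2 never increases N3 calls
  movement <- detect_movement_epochs(movement_flags(f$pm, th$tm))
  n_wake <- function(t1) sum(score_wake(f$pw, t1)[!movement])
  n_n3 <- function(t2) sum(score_n3(f$pn3, t2)[!movement])
  t1s <- c(0, 1e-6, 1e-5, 1e-4, 1e-3)
  expect_true(all(diff(vapply(t1s, n_wake, numeric(1))) <= 0))
  t2s <- c(0, 1e-5, 1e-4, 1e-3, 1e-2)
  expect_true(all(diff(vapply(t2s, n_n3, numeric(1))) <= 0))
})

test_that("with an infinite movement threshold no epoch is movement", {
  night <- quick_night(10, seed = 43, dropout_prob = 0)  # no flat seconds
  f <- extract_features(night$recording)
  flags <- movement_flags(f$pm, tm = Inf)
  expect_false(any(detect_movement_epochs(flags)))
  # staging then never needs the resolution branch
  h <- stage_night(f, thresholds(t1 = 1e-5, t2 = 1e-4, tm = Inf))
  base_wake <- score_wake(f$pw, 1e-5)
  expect_identical(h$labels == "WAKE", unname(base_wake))
})

test_that("degenerate feature inputs error cleanly", {
  f <- toy_features(rep(1 / 30, 30), rep(0, 30), rep(1 / 30, 30))
  f$n_seconds <- 0L; f$n_epochs <- 0L; f$pm <- numeric(0)
  f$pw <- numeric(0); f$pn3 <- numeric(0)
  expect_error(stage_night(f, thresholds(1e-6, 1e-5)), "inconsistent")
})
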