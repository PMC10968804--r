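# Normalized per-second staging features and the percentile statistic.
#
# All three features divide a per-second band energy by an all-night total,
# which removes inter-subject amplitude differences: scaling the whole
# trace by c > 0 scales every band energy by c^2 and leaves the features
# unchanged.

#' Movement feature: normalized whole-band energy
#'
#' `pm[s] = E_total[s] / E_total_all`. High values mark seconds whose EEG
#' is dominated by movement or muscle artifact; exact zeros mark electrode
#' loss. Sums to 1 over the night by construction.
#'
#' @param energies a [band_energies_per_second()] table.
#' @return numeric vector, one value per second.
#' @export
compute_pm <- function(energies) {
  stopifnot(inherits(energies, "band_energy_table"))
  tot <- energies$totals[["total"]]
  if (tot <= 0) stop("degenerate recording: all-night total energy is zero")
  energies$per_second[, "total"] / tot
}

#' Wake feature: alpha-theta energy difference
#'
#' `pw[s] = (E_alpha[s] - E_theta[s]) / E_theta_all`. Positive when the
#' alpha rhythm dominates theta activity, as in relaxed wakefulness;
#' negative values are meaningful and retained.
#'
#' @inheritParams compute_pm
#' @return numeric vector, one value per second (may be negative).
#' @export
compute_pw <- function(energies) {
  stopifnot(inherits(energies, "band_energy_table"))
  tot <- energies$totals[["theta"]]
  if (tot <= 0) stop("degenerate recording: all-night theta energy is zero")
  (energies$per_second[, "alpha"] - energies$per_second[, "theta"]) / tot
}

#' Deep-sleep feature: normalized delta energy
#'
#' `pn3[s] = E_delta[s] / E_delta_all`. Large during slow-wave activity.
#' Sums to 1 over the night by construction.
#'
#' @inheritParams compute_pm
#' @return numeric vector, one value per second.
#' @export
compute_pn3 <- function(energies) {
  stopifnot(inherits(energies, "band_energy_table"))
  tot <- energies$totals[["delta"]]
  if (tot <= 0) stop("degenerate recording: all-night delta energy is zero")
  energies$per_second[, "delta"] / tot
}

#' Bundle the three staging features for one night
#'
#' @inheritParams compute_pm
#' @return an object of class `feature_series`: list with per-second
#'   vectors `pm`, `pw`, `pn3`, plus `n_seconds` and `n_epochs`.
#' @export
feature_series <- function(energies) {
  stopifnot(inherits(energies, "band_energy_table"))
  ns <- energies$n_seconds
  if (ns %% EPOCH_LEN_S != 0L)
    stop("band energy table does not cover whole 30-s epochs")
  structure(list(pm = compute_pm(energies), pw = compute_pw(energies),
                 pn3 = compute_pn3(energies), n_seconds = ns,
                 n_epochs = ns %/% EPOCH_LEN_S),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> %d epochs (%d seconds)\n",
              x$n_epochs, x$n_seconds))
  cat(sprintf("  pw range [%.3g, %.3g]; pn3 range [%.3g, %.3g]\n",
              min(x$pw), max(x$pw), min(x$pn3), max(x$pn3)))
  invisible(x)
}

#' Export a feature series as CSV
#'
#' Writes `second,pm,pw,pn3` rows with 0-based second indices.
#'
#' @param features a [feature_series()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "feature_series"))
  d <- data.frame(second = seq_len(features$n_seconds) - 1L,
                  pm = features$pm, pw = features$pw, pn3 = features$pn3)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Rank-based percentile of a sample
#'
#' The P-th percentile of M sorted observations is the n-th smallest with
#' `n = ceiling(P/100 * M)`; an exactly integer product is kept as is, so
#' for the scoring case P = 80, M = 30 the rank is exactly 24 (the 6th
#' largest value of the epoch).
#'
#' @param values numeric vector (at least one value).
#' @param p percent, in `(0, 100]`.
#' @return a single number: the rank-n order statistic.
#' @export
percentile_value <- function(values, p) {
  if (length(values) == 0L) stop("empty vector")
  if (!is_number(p) || p <= 0 || p > 100) stop("'p' must be in (0, 100]")
  m <- length(values)
  n_exact <- p * m / 100
  n <- if (abs(n_exact - round(n_exact)) < 1e-9) round(n_exact)
       else ceiling(n_exact)
  sort(values, partial = n)[n]
}

#' Staging thresholds
#'
#' `tm` flags movement seconds from the normalized whole-band energy (the
#' fixed default 5e-4 was calibrated on full clinical nights); `t1` and
#' `t2` are the trainable wake and N3 baselines for `pw` and the 80th
#' percentile of `pn3`, normally obtained with [train_thresholds()].
#'
#' @param t1 wake threshold on `pw` (dimensionless, >= 0).
#' @param t2 N3 threshold on the epoch 80th percentile of `pn3` (>= 0).
#' @param tm movement threshold on `pm` (> 0), default `5e-4`.
#' @return an object of class `sleep_thresholds`.
#' @export
thresholds <- function(t1, t2, tm = 5e-4) {
  if (!is.numeric(tm) || length(tm) != 1L || is.na(tm) || tm <= 0)
    stop("'tm' must be a positive number")  # Inf disables movement flags
  for (v in list(t1 = t1, t2 = t2))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("'t1' and 't2' must be single non-negative numbers")
  structure(list(tm = tm, t1 = t1, t2 = t2), class = "sleep_thresholds")
}

#' @export
print.sleep_thresholds <- function(x, ...) {
  cat(sprintf("<sleep_thresholds> tm = %.3g, t1 = %.4g, t2 = %.4g\n",
              x$tm, x$t1, x$t2))
  fit <- attr(x, "fitness")
  if (!is.null(fit))
    cat(sprintf("  training accuracy %.4f (seed %s)\n", fit,
                format(attr(x, "seed"))))
  invisible(x)
}
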