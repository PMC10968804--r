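# The rule engine: movement detection, wake and N3 scoring, resolution of
# movement-obscured epochs, and full-night staging.
#
# All duration rules follow the AASM wording "more than 15 s of an epoch"
# and are strict: exactly 15 qualifying seconds do not trigger a rule.
# Threshold comparisons are likewise strict (a feature exactly equal to its
# threshold does not fire).

# tolerance below which a second's pm counts as "no signal" (electrode loss)
PM_FLAT_EPS <- 1e-12

#' Flag movement seconds
#'
#' A second is flagged when its normalized whole-band energy exceeds the
#' movement threshold (`pm > tm`, high-amplitude artifact) or is
#' numerically zero (`pm <= 1e-12`, electrode loss).
#'
#' @param pm per-second movement feature from [compute_pm()].
#' @param tm movement threshold (default the fixed `5e-4`).
#' @return logical vector, one flag per second.
#' @export
movement_flags <- function(pm, tm = 5e-4) {
  stopifnot(is.numeric(pm), all(is.finite(pm)), all(pm >= 0),
            is.numeric(tm), length(tm) == 1L, !is.na(tm))
  pm > tm | pm <= PM_FLAT_EPS
}

epoch_matrix <- function(x) {
  if (length(x) %% EPOCH_LEN_S != 0L)
    stop("length not divisible by the 30-s epoch grid")
  matrix(x, nrow = EPOCH_LEN_S)
}

#' Detect major-body-movement epochs
#'
#' An epoch is a movement epoch when strictly more than 15 of its 30
#' seconds are flagged.
#'
#' @param flags per-second logical vector from [movement_flags()].
#' @return logical vector, one flag per epoch.
#' @export
detect_movement_epochs <- function(flags) {
  colSums(epoch_matrix(flags)) > 15L
}

#' Score wake-positive epochs
#'
#' An epoch is wake-positive when strictly more than 15 seconds have
#' `pw > t1`.
#'
#' @param pw per-second wake feature from [compute_pw()].
#' @param t1 wake threshold.
#' @return logical vector, one flag per epoch.
#' @export
score_wake <- function(pw, t1) {
  colSums(epoch_matrix(pw) > t1) > 15L
}

#' Score N3-positive epochs
#'
#' An epoch is N3-positive when the 80th percentile of its 30 per-second
#' `pn3` values (the 24th order statistic, reflecting the "at least 20%
#' slow-wave activity" criterion) strictly exceeds `t2`.
#'
#' @param pn3 per-second deep-sleep feature from [compute_pn3()].
#' @param t2 N3 threshold.
#' @return logical vector, one flag per epoch.
#' @export
score_n3 <- function(pn3, t2) {
  apply(epoch_matrix(pn3), 2L, percentile_value, p = 80) > t2
}

#' Resolve movement epochs to a stage
#'
#' Implements the technician rule for epochs obscured by major body
#' movement, in order of precedence:
#' \enumerate{
#'   \item alpha rhythm anywhere in the epoch (however brief) -> wake;
#'   \item an adjacent epoch staged wake -> wake;
#'   \item otherwise the epoch takes the stage of the epoch that follows
#'     it. Runs of consecutive movement epochs are resolved right to left,
#'     so a whole run inherits the first non-movement stage after it; a
#'     run at the end of the night (no following epoch) inherits the
#'     preceding stage instead.
#' }
#'
#' @param movement per-epoch logical vector from [detect_movement_epochs()].
#' @param alpha_present per-epoch logical: any alpha activity in the epoch.
#' @param base_stages per-epoch stage labels, valid at non-movement
#'   positions (entries at movement positions are ignored).
#' @param wake label denoting wake in `base_stages` (default `"WAKE"`;
#'   pass `"W"` to resolve technician-labelled sequences).
#' @return character vector of per-epoch stages with every movement epoch
#'   resolved.
#' @export
resolve_movement_epochs <- function(movement, alpha_present, base_stages,
                                    wake = "WAKE") {
  n <- length(movement)
  stopifnot(length(alpha_present) == n, length(base_stages) == n)
  if (all(movement))
    stop("unresolvable night: every epoch is flagged as movement")
  resolved <- as.character(base_stages)
  resolved[movement] <- NA_character_
  # rule (a) does not depend on neighbors; assign first so that an
  # alpha-wake movement epoch counts as a wake neighbor in rule (b)
  resolved[movement & alpha_present] <- wake
  for (e in n:1) {
    if (!movement[e]) next
    if (!alpha_present[e]) {
      prev_wake <- e > 1L && identical(resolved[e - 1L], wake)
      next_stage <- if (e < n) resolved[e + 1L] else NA_character_
      if (prev_wake || identical(next_stage, wake)) {
        resolved[e] <- wake
      } else if (!is.na(next_stage)) {
        resolved[e] <- next_stage
      }
      # else: trailing movement run; filled from the left below
    }
  }
  for (e in seq_len(n)) {
    if (is.na(resolved[e])) resolved[e] <- resolved[e - 1L]
  }
  resolved
}

# shared by stage_night() and the cached PSO fitness: stages one night from
# precomputed components
stage_from_components <- function(movement, wake_counts, p80, t1, t2) {
  wake_pos <- wake_counts > 15L
  base <- ifelse(wake_pos, "WAKE", ifelse(p80 > t2, "N3", "OTHER"))
  resolve_movement_epochs(movement, alpha_present = wake_counts > 0L,
                          base_stages = base)
}

#' Stage a full night
#'
#' Orchestrates the rule engine over one night of features: non-movement
#' epochs are scored wake first (wake takes precedence; a wake-positive
#' epoch is not examined further), then N3, else OTHER. Movement epochs
#' are resolved via [resolve_movement_epochs()], with alpha presence
#' operationalized as any second in the epoch having `pw > t1` (the same
#' alpha criterion the wake rule uses).
#'
#' @param features a [feature_series()] for the night.
#' @param th a [thresholds()] object.
#' @return a predicted [hypnogram] (`WAKE`/`N3`/`OTHER`), with the
#'   per-epoch decision trace attached as attribute `"trace"`.
#' @export
stage_night <- function(features, th) {
  stopifnot(inherits(features, "feature_series"),
            inherits(th, "sleep_thresholds"))
  if (features$n_seconds != EPOCH_LEN_S * features$n_epochs ||
      features$n_epochs < 1L)
    stop("inconsistent feature series")
  movement <- detect_movement_epochs(movement_flags(features$pm, th$tm))
  wake_counts <- colSums(epoch_matrix(features$pw) > th$t1)
  p80 <- apply(epoch_matrix(features$pn3), 2L, percentile_value, p = 80)
  stages <- stage_from_components(movement, wake_counts, p80, th$t1, th$t2)
  h <- hypnogram(stages, "predicted")
  attr(h, "trace") <- data.frame(
    epoch = seq_along(stages) - 1L,
    movement_seconds = colSums(epoch_matrix(
      movement_flags(features$pm, th$tm))),
    wake_seconds = as.integer(wake_counts),
    pn3_p80 = p80,
    stage = stages)
  h
}

#' Export the per-epoch decision trace as CSV
#'
#' Writes `epoch,movement_seconds,wake_seconds,pn3_p80,stage` for audit of
#' individual staging decisions.
#'
#' @param h a [stage_night()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_decision_trace <- function(h, path) {
  tr <- attr(h, "trace")
  if (is.null(tr)) stop("hypnogram has no decision trace attached")
  utils::write.csv(tr, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
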