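# Orchestration: feature extraction, threshold training, scoring and
# evaluation of whole nights.

#' Extract the staging features of a recording
#'
#' Convenience wrapper: band energies then [feature_series()].
#'
#' @param rec an [eeg_epochs] recording.
#' @param bands band definitions, see [default_bands()].
#' @return a [feature_series()].
#' @export
extract_features <- function(rec, bands = default_bands()) {
  feature_series(band_energies_per_second(rec, bands))
}

as_training_night <- function(night, bands) {
  rec <- night$recording
  truth <- night$truth
  if (is.character(rec)) stop("pass loaded recordings; see load_manifest()")
  if (!is.null(night$features)) {
    f <- night$features
  } else {
    stopifnot(inherits(rec, "eeg_epochs"))
    f <- extract_features(rec, bands)
  }
  stopifnot(inherits(truth, "hypnogram"))
  if (length(truth) != f$n_epochs)
    stop("epoch count mismatch: hypnogram has ", length(truth),
         " epochs but the recording has ", f$n_epochs)
  list(features = f, truth = truth)
}

#' Train the wake and N3 thresholds by PSO
#'
#' Extracts features once per training night, caches the per-epoch staging
#' summaries, and searches `(t1, t2)` with [pso_optimize()] to maximize
#' pooled epoch accuracy against the technician hypnograms.
#'
#' @param training list of labelled nights; each element is a list with
#'   `recording` (an [eeg_epochs]) or `features` (a [feature_series()]),
#'   and `truth` (a technician [hypnogram]). [generate_night()] output can
#'   be passed directly.
#' @param bands band definitions used for extraction.
#' @param tm fixed movement threshold.
#' @param pso a [pso_config()]; set its `seed` for reproducible training.
#' @return a [thresholds()] object with attributes `fitness` (pooled
#'   training accuracy), `seed`, and `pso` (the full [pso_optimize()]
#'   result).
#' @export
train_thresholds <- function(training, bands = default_bands(), tm = 5e-4,
                             pso = pso_config()) {
  if (length(training) == 0L) stop("empty training set")
  nights <- lapply(training, as_training_night, bands = bands)
  fit <- make_cached_fitness(nights, tm)
  res <- pso_optimize(fit, pso)
  th <- thresholds(t1 = res$best_position[[1L]],
                   t2 = res$best_position[[2L]], tm = tm)
  attr(th, "fitness") <- res$best_fitness
  attr(th, "seed") <- res$seed
  attr(th, "pso") <- res
  th
}

#' Score one night
#'
#' @param rec an [eeg_epochs] recording (or a [feature_series()]).
#' @param th a [thresholds()] object.
#' @param bands band definitions used for extraction.
#' @return a predicted [hypnogram].
#' @export
score_night <- function(rec, th, bands = default_bands()) {
  f <- if (inherits(rec, "feature_series")) rec
       else extract_features(rec, bands)
  stage_night(f, th)
}

#' Evaluate predicted against technician hypnograms
#'
#' Pools epochs over all nights and reports the three layouts used for
#' agreement assessment: binary wake-vs-rest, binary N3-vs-rest (each with
#' sensitivity, accuracy and Cohen's kappa) and the 3-class matrix with
#' global accuracy and per-class TP rates.
#'
#' @param scored list of nights, each a list with `pred` (predicted
#'   [hypnogram]) and `truth` (technician [hypnogram]).
#' @return an object of class `staging_report`.
#' @export
evaluate_nights <- function(scored) {
  if (length(scored) == 0L) stop("empty evaluation set")
  pool_pred <- character(0); pool_truth <- character(0)
  for (night in scored) {
    p <- as_3class(night$pred); t3 <- as_3class(night$truth)
    if (length(p) != length(t3))
      stop("length mismatch: ", length(p), " predicted vs ", length(t3),
           " technician epochs")
    pool_pred <- c(pool_pred, p$labels)
    pool_truth <- c(pool_truth, t3$labels)
  }
  pred <- hypnogram(pool_pred, "predicted")
  truth <- hypnogram(pool_truth, "predicted")
  # a class absent from a pooled set leaves its sensitivity or kappa
  # undefined; report NA rather than refuse the whole evaluation
  binary_summary <- function(m) {
    po <- (m$A + m$D) / m$N
    pc <- ((m$N1 * m$N3 / m$N) + (m$N2 * m$N4 / m$N)) / m$N
    list(matrix = m,
         sensitivity = if (m$N1 > 0L) m$A / m$N1 else NA_real_,
         accuracy = po,
         kappa = if (pc < 1) (po - pc) / (1 - pc) else NA_real_)
  }
  wake <- confusion_counts(pred, truth, positive = "WAKE")
  n3 <- confusion_counts(pred, truth, positive = "N3")
  mc <- confusion_counts(pred, truth, positive = "multiclass")
  structure(list(
    n_epochs = length(pred),
    wake = binary_summary(wake),
    n3 = binary_summary(n3),
    multiclass = c(list(matrix = mc), global_accuracy(mc))),
    class = "staging_report")
}

#' @export
print.staging_report <- function(x, ...) {
  pct <- function(v) sprintf("%.2f%%", 100 * v)
  cat(sprintf("<staging_report> %d epochs pooled\n", x$n_epochs))
  cat(sprintf("  wake: sensitivity %s, accuracy %s, kappa %.2f\n",
              pct(x$wake$sensitivity), pct(x$wake$accuracy), x$wake$kappa))
  cat(sprintf("  N3:   sensitivity %s, accuracy %s, kappa %.2f\n",
              pct(x$n3$sensitivity), pct(x$n3$accuracy), x$n3$kappa))
  cat(sprintf("  3-class global accuracy %s (TP rates %s)\n",
              pct(x$multiclass$accuracy),
              paste(names(x$multiclass$tp_rates),
                    pct(x$multiclass$tp_rates), collapse = ", ")))
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report a [evaluate_nights()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "staging_report"))
  mat2 <- function(m) list(A = m$A, B = m$B, C = m$C, D = m$D)
  out <- list(
    n_epochs = report$n_epochs,
    wake = list(counts = mat2(report$wake$matrix),
                sensitivity = report$wake$sensitivity,
                accuracy = report$wake$accuracy,
                kappa = report$wake$kappa),
    n3 = list(counts = mat2(report$n3$matrix),
              sensitivity = report$n3$sensitivity,
              accuracy = report$n3$accuracy,
              kappa = report$n3$kappa),
    multiclass = list(counts = report$multiclass$matrix$counts,
                      accuracy = report$multiclass$accuracy,
                      tp_rates = as.list(report$multiclass$tp_rates)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write trained thresholds as JSON
#'
#' @param th a [thresholds()] object, e.g. from [train_thresholds()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_thresholds <- function(th, path) {
  stopifnot(inherits(th, "sleep_thresholds"))
  jsonlite::write_json(
    list(tm = th$tm, t1 = th$t1, t2 = th$t2,
         seed = attr(th, "seed"), fitness = attr(th, "fitness")),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read thresholds from JSON
#'
#' @param path a file written by [write_thresholds()].
#' @return a [thresholds()] object.
#' @export
read_thresholds <- function(path) {
  if (!file.exists(path)) stop("thresholds file not found: ", path)
  x <- jsonlite::read_json(path)
  th <- thresholds(t1 = x$t1, t2 = x$t2, tm = x$tm)
  attr(th, "fitness") <- x$fitness
  attr(th, "seed") <- x$seed
  th
}

#' Load a manifest of labelled nights
#'
#' Reads a CSV with header `edf_path,hypnogram_path` and returns loaded
#' nights suitable for [train_thresholds()]. Relative paths are resolved
#' against the manifest's directory.
#'
#' @param path manifest CSV path.
#' @param active,reference channel derivation passed to [read_psg_edf()].
#' @return list of nights (`recording`, `truth`).
#' @export
load_manifest <- function(path, active = "C3", reference = "M2") {
  if (!file.exists(path)) stop("manifest not found: ", path)
  d <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  if (!all(c("edf_path", "hypnogram_path") %in% names(d)))
    stop("manifest CSV must have columns edf_path,hypnogram_path")
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  lapply(seq_len(nrow(d)), function(i) {
    list(recording = read_psg_edf(resolve(d$edf_path[i]), active, reference),
         truth = read_hypnogram(resolve(d$hypnogram_path[i])))
  })
}

#' Read and validate a run configuration
#'
#' YAML with optional top-level keys `bands`, `thresholds`, `pso`, `io`
#' and `seed`; unknown keys are rejected. Band entries override
#' [default_bands()] rows by name; `thresholds` may set `tm`, `t1`, `t2`;
#' `pso` any [pso_config()] argument.
#'
#' @param path YAML file path.
#' @return list with `bands` (data frame), `thresholds`, `pso`
#'   (a [pso_config()]), `io` and `seed`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("bands", "thresholds", "pso", "io", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         "; accepted keys: ", paste(known, collapse = ", "))
  bands <- default_bands()
  for (nm in names(raw$bands)) {
    i <- match(nm, bands$name)
    if (is.na(i)) stop("unknown band in config: ", nm)
    b <- raw$bands[[nm]]
    if (!is.null(b$f_lo)) bands$f_lo[i] <- b$f_lo
    if (!is.null(b$f_hi)) bands$f_hi[i] <- b$f_hi
  }
  th <- raw$thresholds
  pso_args <- raw$pso
  if (!is.null(pso_args$bounds))
    pso_args$bounds <- cbind(lo = vapply(pso_args$bounds, `[[`, 0, 1L),
                             hi = vapply(pso_args$bounds, `[[`, 0, 2L))
  if (is.null(pso_args$seed) && !is.null(raw$seed))
    pso_args$seed <- raw$seed
  list(bands = bands,
       thresholds = th,
       pso = do.call(pso_config, if (is.null(pso_args)) list()
                     else pso_args),
       io = raw$io, seed = raw$seed)
}
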