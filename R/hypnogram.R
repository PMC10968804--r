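# Hypnograms: per-epoch stage label sequences.

TECH_STAGES <- c("W", "N1", "N2", "N3", "REM")
PRED_STAGES <- c("WAKE", "N3", "OTHER")

#' Construct a hypnogram
#'
#' A hypnogram is the per-epoch sequence of sleep-stage labels for one
#' night. Two label sets are supported: `"technician"` uses the five AASM
#' stages `W, N1, N2, N3, REM`; `"predicted"` uses the three classes this
#' classifier emits, `WAKE, N3, OTHER`.
#'
#' @param labels character vector of stage codes, one per 30-s epoch.
#' @param label_set `"technician"` or `"predicted"`.
#' @return an object of class `hypnogram`.
#' @export
hypnogram <- function(labels, label_set = c("technician", "predicted")) {
  label_set <- match.arg(label_set)
  valid <- if (label_set == "technician") TECH_STAGES else PRED_STAGES
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("a hypnogram needs at least one epoch")
  bad <- setdiff(unique(labels), valid)
  if (length(bad))
    stop("unknown stage token(s) ", paste0("'", bad, "'", collapse = ", "),
         "; accepted tokens for the ", label_set, " label set are: ",
         paste(valid, collapse = ", "))
  structure(list(labels = labels, label_set = label_set,
                 epoch_len_s = EPOCH_LEN_S),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d epochs (%s labels): %s%s\n",
              length(x$labels), x$label_set,
              paste(utils::head(x$labels, 12L), collapse = " "),
              if (length(x$labels) > 12L) " ..." else ""))
  print(table(factor(x$labels,
                     if (x$label_set == "technician") TECH_STAGES
                     else PRED_STAGES)))
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$labels)

#' Read a hypnogram from CSV
#'
#' Expects a header `epoch,stage` with 0-based, contiguous epoch indices.
#' The label set is inferred from the tokens present unless given
#' explicitly (a file containing only `N3` is ambiguous and defaults to
#' the technician set).
#'
#' @param path CSV file path.
#' @param label_set `"auto"` (default), `"technician"` or `"predicted"`.
#' @return a [hypnogram].
#' @export
read_hypnogram <- function(path, label_set = c("auto", "technician",
                                               "predicted")) {
  label_set <- match.arg(label_set)
  if (!file.exists(path)) stop("hypnogram file not found: ", path)
  d <- utils::read.csv(path, colClasses = c("integer", "character"),
                       strip.white = TRUE)
  if (!identical(names(d), c("epoch", "stage")))
    stop("hypnogram CSV must have header 'epoch,stage'")
  if (!identical(d$epoch, seq_len(nrow(d)) - 1L))
    stop("epoch indices must be contiguous starting at 0; got a gap near ",
         "index ", d$epoch[which(d$epoch != seq_len(nrow(d)) - 1L)[1L]])
  if (label_set == "auto") {
    toks <- unique(d$stage)
    label_set <-
      if (all(toks %in% TECH_STAGES)) "technician"
      else if (all(toks %in% PRED_STAGES)) "predicted"
      else stop("unknown stage token(s) ",
                paste0("'", setdiff(toks, c(TECH_STAGES, PRED_STAGES)),
                       "'", collapse = ", "),
                "; accepted tokens: ", paste(TECH_STAGES, collapse = ", "),
                " (technician) or ", paste(PRED_STAGES, collapse = ", "),
                " (predicted)")
  }
  hypnogram(d$stage, label_set)
}

#' Write a hypnogram to CSV
#'
#' Writes `epoch,stage` rows with 0-based epoch indices, LF line endings
#' and no quoting, so that [read_hypnogram()] is its exact inverse.
#'
#' @param h a [hypnogram].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(h, path) {
  stopifnot(inherits(h, "hypnogram"))
  con <- file(path, "wb")  # binary mode keeps LF endings on all platforms
  on.exit(close(con))
  writeLines(c("epoch,stage",
               paste0(seq_along(h$labels) - 1L, ",", h$labels)),
             con, sep = "\n")
  invisible(path)
}

#' Collapse technician stages to the classifier's three classes
#'
#' Maps `W -> WAKE`, `N3 -> N3` and `N1, N2, REM -> OTHER`. Predicted
#' hypnograms pass through unchanged. This mapping is applied exactly once,
#' at evaluation time.
#'
#' @param h a [hypnogram].
#' @return a [hypnogram] with the `"predicted"` label set.
#' @export
as_3class <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  if (h$label_set == "predicted") return(h)
  map <- c(W = "WAKE", N1 = "OTHER", N2 = "OTHER", N3 = "N3", REM = "OTHER")
  hypnogram(unname(map[h$labels]), "predicted")
}
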