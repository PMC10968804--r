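# Agreement metrics against the technician gold standard: confusion
# matrices, sensitivity, accuracy and Cohen's kappa.

#' Confusion counts between predicted and technician hypnograms
#'
#' Technician labels are collapsed to the three classifier classes
#' (`W -> WAKE`, `N3 -> N3`, `N1/N2/REM -> OTHER`) before counting. In
#' binary mode every non-positive stage is collapsed to the negative
#' class, giving the 2x2 layout TP = A, FP = B, FN = C, TN = D with row
#' totals `N3 = A + B`, `N4 = C + D` and column totals `N1 = A + C`,
#' `N2 = B + D` (predictions by row, technician by column).
#'
#' @param pred predicted [hypnogram].
#' @param truth technician (or predicted-class) [hypnogram] of equal length.
#' @param positive `"multiclass"` for the full 3x3 matrix, or one of
#'   `"WAKE"`, `"N3"`, `"OTHER"` for a one-vs-rest 2x2 matrix.
#' @return a `confusion_matrix2` (fields `A`, `B`, `C`, `D`, `N1`..`N4`,
#'   `N`, `positive`) or a `confusion_matrix_k` (3x3 `counts` matrix,
#'   predicted by row).
#' @export
confusion_counts <- function(pred, truth, positive = "multiclass") {
  stopifnot(inherits(pred, "hypnogram"), inherits(truth, "hypnogram"))
  p <- as_3class(pred)$labels
  t3 <- as_3class(truth)$labels
  if (length(p) != length(t3))
    stop("length mismatch: ", length(p), " predicted vs ", length(t3),
         " technician epochs")
  if (identical(positive, "multiclass")) {
    counts <- table(factor(p, PRED_STAGES), factor(t3, PRED_STAGES))
    counts <- unclass(matrix(counts, 3L, 3L,
                             dimnames = list(predicted = PRED_STAGES,
                                             technician = PRED_STAGES)))
    return(structure(list(counts = counts), class = "confusion_matrix_k"))
  }
  if (!positive %in% PRED_STAGES)
    stop("'positive' must be \"multiclass\" or one of: ",
         paste(PRED_STAGES, collapse = ", "))
  confusion_matrix2(A = sum(p == positive & t3 == positive),
                    B = sum(p == positive & t3 != positive),
                    C = sum(p != positive & t3 == positive),
                    D = sum(p != positive & t3 != positive),
                    positive = positive)
}

#' Build a 2x2 confusion matrix from raw counts
#'
#' @param A,B,C,D true-positive, false-positive, false-negative and
#'   true-negative epoch counts.
#' @param positive optional label of the positive class.
#' @return a `confusion_matrix2` object.
#' @export
confusion_matrix2 <- function(A, B, C, D, positive = NA_character_) {
  for (v in list(A, B, C, D))
    if (!is_count(v, min = 0L)) stop("counts must be non-negative integers")
  structure(list(A = A, B = B, C = C, D = D,
                 N1 = A + C, N2 = B + D, N3 = A + B, N4 = C + D,
                 N = A + B + C + D, positive = positive),
            class = "confusion_matrix2")
}

#' @export
print.confusion_matrix2 <- function(x, ...) {
  cat(sprintf("<confusion_matrix2>%s N = %d\n",
              if (is.na(x$positive)) "" else paste0(" positive = ",
                                                    x$positive), x$N))
  m <- matrix(c(x$A, x$C, x$B, x$D), 2L, 2L,
              dimnames = list(predicted = c("yes", "no"),
                              technician = c("yes", "no")))
  print(m)
  invisible(x)
}

#' @export
print.confusion_matrix_k <- function(x, ...) {
  cat("<confusion_matrix_k>\n")
  print(x$counts)
  invisible(x)
}

#' Sensitivity and accuracy of a 2x2 matrix
#'
#' `sensitivity = TP / (TP + FN)`; `accuracy = (TP + TN) / N`. Returned at
#' full precision as proportions in `[0, 1]`; multiply by 100 and round to
#' two decimals for display.
#'
#' @param m a `confusion_matrix2`.
#' @return list with `sensitivity` and `accuracy`.
#' @export
sensitivity_accuracy <- function(m) {
  stopifnot(inherits(m, "confusion_matrix2"))
  if (m$N == 0L) stop("empty confusion matrix")
  if (m$N1 == 0L)
    stop("sensitivity undefined: no positive epochs in the gold standard")
  list(sensitivity = m$A / m$N1, accuracy = (m$A + m$D) / m$N)
}

#' Cohen's kappa of a 2x2 matrix
#'
#' Chance-corrected agreement `kappa = (po - pc) / (1 - pc)` with observed
#' agreement `po = (A + D) / N` and chance agreement
#' `pc = [(N1 * N3 / N) + (N2 * N4 / N)] / N`.
#'
#' @param m a `confusion_matrix2`.
#' @return list with `po`, `pc` and `kappa`.
#' @export
cohen_kappa <- function(m) {
  stopifnot(inherits(m, "confusion_matrix2"))
  if (m$N == 0L) stop("empty confusion matrix")
  po <- (m$A + m$D) / m$N
  pc <- ((m$N1 * m$N3 / m$N) + (m$N2 * m$N4 / m$N)) / m$N
  if (pc >= 1)
    stop("kappa undefined: chance agreement is 1 (single-cell matrix)")
  list(po = po, pc = pc, kappa = (po - pc) / (1 - pc))
}

#' Global accuracy of a K-class confusion matrix
#'
#' @param m a `confusion_matrix_k` (predictions by row, technician by
#'   column).
#' @return list with `accuracy` (trace over grand total) and `tp_rates`
#'   (per-technician-class recall, named by stage).
#' @export
global_accuracy <- function(m) {
  stopifnot(inherits(m, "confusion_matrix_k"))
  n <- sum(m$counts)
  if (n == 0L) stop("empty confusion matrix")
  list(accuracy = sum(diag(m$counts)) / n,
       tp_rates = diag(m$counts) / colSums(m$counts))
}
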