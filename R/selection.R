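# Corrected-AIC model selection across the eleven calibrated variants.

#' Corrected Akaike information criterion for a least-squares fit
#'
#' \code{AICc = 2k + n * log(RSS / n) + 2k(k + 1)/(n - k - 1)}, the
#' least-squares form with the small-sample correction. Strictly increasing
#' in \code{k} at fixed RSS and \code{n}. A zero RSS returns \code{-Inf}
#' (documented sentinel for a degenerate perfect fit).
#'
#' @param rss Residual sum of squares.
#' @param n_points Number of data points used for calibration.
#' @param k Number of calibrated parameters.
#' @return AICc value.
#' @examples
#' aicc(100, 1000, 12)  # 24 + 1000 * log(0.1) + 312/987
#' @export
aicc <- function(rss, n_points, k) {
  if (n_points <= k + 1)
    stop("n_points must exceed k + 1 for the AICc correction")
  if (rss < 0) stop("rss must be non-negative")
  if (rss == 0) return(-Inf)
  2 * k + n_points * log(rss / n_points) +
    2 * k * (k + 1) / (n_points - k - 1)
}

#' Select the best model for one tumour
#'
#' Scores one tumour's calibrations (one \code{tumour_fit} per variant)
#' with AICc and selects the minimum; ties (within \code{tol}) are broken
#' toward the fewest parameters, then the lowest variant index. Records
#' correctness against the generating variant if given.
#'
#' @param fits Named list of \code{tumour_fit} objects (names = variant
#'   ids). A single candidate is allowed (degenerate selection).
#' @param generating Optional id of the generating variant.
#' @param tol Numerical tie tolerance on AICc (default 1e-9).
#' @return Object of class \code{model_selection}: \code{aic_by_model},
#'   \code{selected}, \code{generating}, \code{correct}.
#' @export
select_model <- function(fits, generating = NULL, tol = 1e-9) {
  if (!length(fits)) stop("no calibrations supplied")
  ids <- names(fits)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- vapply(fits, function(f) f$variant$id, character(1))
  n0 <- fits[[1]]$n_points
  for (f in fits) if (f$n_points != n0)
    stop("all calibrations of one tumour must share n_points")
  aic <- vapply(fits, function(f) aicc(f$rss, f$n_points, f$k), numeric(1))
  names(aic) <- ids
  kk <- vapply(fits, function(f) f$k, numeric(1))
  vn <- suppressWarnings(as.integer(sub("^M", "", ids)))
  if (anyNA(vn)) vn <- seq_along(ids)
  best <- min(aic)
  cand <- which(aic <= best + tol)
  cand <- cand[order(kk[cand], vn[cand])]
  sel <- ids[cand[1]]
  structure(list(aic_by_model = aic, selected = sel,
                 generating = generating,
                 correct = if (is.null(generating)) NA else
                   identical(sel, generating)),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("<model_selection: %s selected%s>\n", x$selected,
              if (is.na(x$correct)) "" else
                sprintf(" (generating %s, %s)", x$generating,
                        if (x$correct) "correct" else "incorrect")))
  print(round(sort(x$aic_by_model), 2))
  invisible(x)
}

#' Tally selection outcomes into a confusion matrix
#'
#' @param results List of \code{model_selection} objects carrying both
#'   generating and selected labels.
#' @param ids Variant ids ordering the table (default M1..M11).
#' @return Object of class \code{selection_tally}: \code{counts}
#'   (generating x selected), \code{per_model_rate}, \code{overall_rate}
#'   (percent), and \code{within_class_fraction} — the fraction of
#'   incorrect selections that stayed within the generating model's
#'   treatment-coupling class.
#' @export
tally_selections <- function(results, ids = names(.variant_table)) {
  counts <- matrix(0L, length(ids), length(ids), dimnames = list(
    generating = ids, selected = ids))
  n_wrong <- 0L; n_wrong_same_class <- 0L
  for (r in results) {
    stopifnot(inherits(r, "model_selection"), !is.null(r$generating))
    counts[r$generating, r$selected] <- counts[r$generating, r$selected] + 1L
    if (!r$correct) {
      n_wrong <- n_wrong + 1L
      if (identical(coupling_class(r$generating), coupling_class(r$selected)))
        n_wrong_same_class <- n_wrong_same_class + 1L
    }
  }
  row_tot <- rowSums(counts)
  per_model <- ifelse(row_tot > 0, 100 * diag(counts) / row_tot, NA_real_)
  overall <- 100 * sum(diag(counts)) / max(1, sum(counts))
  structure(list(counts = counts, per_model_rate = per_model,
                 overall_rate = overall,
                 within_class_fraction = if (n_wrong > 0)
                   n_wrong_same_class / n_wrong else NA_real_),
            class = "selection_tally")
}

#' @export
print.selection_tally <- function(x, ...) {
  cat(sprintf("<selection_tally: %.1f%% correct over %d tumours>\n",
              x$overall_rate, sum(x$counts)))
  print(x$counts)
  if (!is.na(x$within_class_fraction))
    cat(sprintf("  %.1f%% of incorrect selections stayed within the coupling class\n",
                100 * x$within_class_fraction))
  invisible(x)
}
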