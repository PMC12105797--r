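# End-to-end experiments: parameter identifiability (calibrate each tumour
# with its generating model and score parameter recovery) and model
# identifiability (calibrate all variants, select by AICc, predict at the
# post-treatment day and score calibration/prediction accuracy).

#' Parameter-identifiability experiment
#'
#' For each tumour and noise level, calibrates only the generating variant
#' and reports the absolute percentage error of every calibrated parameter
#' against its ground-truth value, with median/IQR summaries per model and
#' noise level.
#'
#' @param cohort A \code{virtual_cohort}.
#' @param noise_levels Subset of the cohort's noise levels (default all).
#' @param bounds Calibration bounds (default the cohort-sampling defaults).
#' @param control [calibration_control()].
#' @param sim_ctrl [sim_control()].
#' @param verbose Print one line per calibration.
#' @return Object of class \code{identifiability_report}: \code{errors}
#'   (one row per tumour x noise x parameter), \code{fits},
#'   \code{summary} (median/IQR of absolute percentage error per model x
#'   noise level), \code{failed}.
#' @export
run_parameter_identifiability <- function(cohort,
                                          noise_levels = cohort$noise_levels,
                                          bounds = default_parameter_bounds(),
                                          control = calibration_control(),
                                          sim_ctrl = sim_control(),
                                          verbose = FALSE) {
  stopifnot(inherits(cohort, "virtual_cohort"))
  rows <- list(); fits <- list(); failed <- list()
  for (tm in cohort$tumours) {
    for (lv in noise_levels) {
      obs <- tm$observations[[as.character(lv)]]
      if (is.null(obs)) stop("cohort has no observations at level ", lv)
      fit <- tryCatch(
        calibrate_tumour(obs, tm$variant, tm$anatomy, tm$schedule,
                         bounds, control, sim_ctrl),
        error = function(e) e)
      key <- sprintf("t%d_%s_n%g", tm$patient, tm$variant$id, lv)
      if (inherits(fit, "error")) {
        failed[[key]] <- conditionMessage(fit)
        next
      }
      fits[[key]] <- fit
      est <- coef(fit); tru <- tm$true_params[fit$free]
      rows[[key]] <- data.frame(
        patient = tm$patient, variant = tm$variant$id, noise = lv,
        parameter = fit$free, truth = as.numeric(tru),
        estimate = as.numeric(est),
        abs_pct_error = abs(100 * (as.numeric(est) - as.numeric(tru)) /
                              as.numeric(tru)),
        rss = fit$rss, converged = fit$converged)
      if (verbose)
        message(sprintf("%s: rss %.3g, median |%%err| %.3g", key, fit$rss,
                        median(rows[[key]]$abs_pct_error)))
    }
  }
  errors <- do.call(rbind, rows)
  summ <- NULL
  if (!is.null(errors)) {
    summ <- do.call(rbind, lapply(
      split(errors, list(errors$variant, errors$noise), drop = TRUE),
      function(d) data.frame(variant = d$variant[1], noise = d$noise[1],
                             median = median(d$abs_pct_error),
                             iqr = unname(summarize_metric(d$abs_pct_error)["iqr"]))))
    rownames(summ) <- NULL
  }
  structure(list(errors = errors, fits = fits, summary = summ,
                 failed = failed),
            class = "identifiability_report")
}

#' @export
print.identifiability_report <- function(x, ...) {
  cat("<identifiability_report>\n")
  if (!is.null(x$summary)) print(x$summary, row.names = FALSE)
  if (length(x$failed)) cat(length(x$failed), "calibrations failed\n")
  invisible(x)
}

#' Model-identifiability and prediction experiment
#'
#' For each tumour and noise level, calibrates every candidate variant,
#' selects the AICc-minimal model, predicts forward to the held-out
#' post-treatment day with the selected model, and scores calibration
#' (week-3) and prediction accuracy against the clean ground truth.
#'
#' @inheritParams run_parameter_identifiability
#' @param variants Candidate variants (default all eleven).
#' @return Object of class \code{selection_report}: \code{records} (one
#'   row per tumour x noise with selection and metrics), \code{tally}
#'   (confusion matrices per noise level), \code{summary} (median/IQR of
#'   each metric per generating model x noise x time point),
#'   \code{selections}, \code{failed}.
#' @export
run_model_identifiability <- function(cohort,
                                      noise_levels = cohort$noise_levels,
                                      variants = model_family(),
                                      bounds = default_parameter_bounds(),
                                      control = calibration_control(),
                                      sim_ctrl = sim_control(),
                                      verbose = FALSE) {
  stopifnot(inherits(cohort, "virtual_cohort"))
  records <- list(); selections <- list(); failed <- list()
  for (tm in cohort$tumours) {
    days <- cohort$observation_days
    cal_day <- days[length(days) - 1]   # week 3, last day used to fit
    pred_day <- days[length(days)]      # held-out post-treatment day
    truth_cal <- tm$truth$states[[match(cal_day, days)]]
    truth_pred <- tm$truth$states[[match(pred_day, days)]]
    for (lv in noise_levels) {
      obs <- tm$observations[[as.character(lv)]]
      key <- sprintf("t%d_%s_n%g", tm$patient, tm$variant$id, lv)
      res <- tryCatch({
        fits <- lapply(variants, function(v)
          calibrate_tumour(obs, v, tm$anatomy, tm$schedule, bounds,
                           control, sim_ctrl))
        names(fits) <- vapply(variants, function(v) v$id, character(1))
        sel <- select_model(fits, generating = tm$variant$id)
        best <- fits[[sel$selected]]
        pred <- predict(best, days = c(days[1], cal_day, pred_day))
        m <- tm$anatomy$grid$brain_mask
        mc <- metrics_report(pred$states[[2]], truth_cal, m,
                             time_label = "calibration")
        mp <- metrics_report(pred$states[[3]], truth_pred, m,
                             time_label = "prediction")
        list(sel = sel,
             rec = data.frame(
               patient = tm$patient, generating = tm$variant$id, noise = lv,
               selected = sel$selected, correct = sel$correct,
               dsc_cal = mc$dsc, ccc_cal = mc$ccc, pe_ttc_cal = mc$pe_ttc,
               dsc_pred = mp$dsc, ccc_pred = mp$ccc,
               pe_ttc_pred = mp$pe_ttc))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failed[[key]] <- conditionMessage(res)
        next
      }
      selections[[key]] <- res$sel
      records[[key]] <- res$rec
      if (verbose)
        message(sprintf("%s -> %s (%s)", key, res$sel$selected,
                        if (res$sel$correct) "correct" else "incorrect"))
    }
  }
  records <- do.call(rbind, records)
  tallies <- lapply(setNames(nm = as.character(noise_levels)), function(lv) {
    keep <- grepl(sprintf("_n%g$", as.numeric(lv)), names(selections),
                  fixed = FALSE)
    tally_selections(selections[keep],
                     ids = vapply(variants, function(v) v$id, character(1)))
  })
  summ <- NULL
  if (!is.null(records)) {
    long <- lapply(c("dsc_cal", "ccc_cal", "pe_ttc_cal",
                     "dsc_pred", "ccc_pred", "pe_ttc_pred"), function(mcol) {
      do.call(rbind, lapply(
        split(records, list(records$generating, records$noise), drop = TRUE),
        function(d) {
          v <- d[[mcol]][!is.na(d[[mcol]])]
          data.frame(generating = d$generating[1],
                     noise = d$noise[1], metric = mcol,
                     median = if (length(v)) median(v) else NA_real_,
                     iqr = if (length(v))
                       unname(summarize_metric(v)["iqr"]) else NA_real_)
        }))
    })
    summ <- do.call(rbind, long)
    rownames(summ) <- NULL
  }
  structure(list(records = records, tally = tallies, summary = summ,
                 selections = selections, failed = failed),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n")
  for (lv in names(x$tally)) {
    cat(sprintf("noise %s: %.1f%% correct\n", lv,
                x$tally[[lv]]$overall_rate))
  }
  if (length(x$failed)) cat(length(x$failed), "cases failed\n")
  invisible(x)
}

#' Write voxel fields as NIfTI-1 volumes
#'
#' @param fields Named list of numeric or logical arrays.
#' @param dir Output directory (created if needed).
#' @param spacing Voxel spacing in mm, stored in the header.
#' @return Invisibly, the written file paths.
#' @export
export_fields <- function(fields, dir, spacing = c(0.5, 0.5, 2.0)) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    is_mask <- is.logical(f)
    arr <- if (is_mask) array(as.integer(f), dim(f)) else f
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- spacing
    path <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(img, path,
                       datatype = if (is_mask) "uint8" else "double")
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read voxel fields written by [export_fields()]
#'
#' @param paths NIfTI file paths.
#' @return Named list of arrays (with pixdim attributes preserved).
#' @export
import_fields <- function(paths) {
  out <- lapply(paths, function(p) {
    img <- RNifti::readNifti(p)
    arr <- array(as.numeric(img), dim(img))
    attr(arr, "pixdim") <- RNifti::pixdim(img)
    arr
  })
  names(out) <- sub("\\.nii(\\.gz)?$", "", basename(paths))
  out
}
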