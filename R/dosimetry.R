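#' Dose metrics over contours
#'
#' Dose grids may live on a coarser grid than the masks (clinical dose
#' voxels are 2-4 mm); masks are transferred to the dose grid by
#' nearest-neighbor resampling in physical coordinates before any dose
#' statistic is computed.
#'
#' @param mask a [mask3d()].
#' @param dose a [dose_grid()].
#' @param name label used in error messages (e.g. the OAR name).
#' @return `mean_dose()` / `max_dose()`: the mean / maximum dose in Gy
#'   over the dose-grid voxels covered by the resampled mask.
#' @export
mean_dose <- function(mask, dose, name = "mask") {
  sel <- resample_mask_to_dose(mask, dose)
  if (!any(sel))
    stop("'", name, "' is empty after resampling to the dose grid")
  mean(dose$data[sel])
}

#' @rdname mean_dose
#' @export
max_dose <- function(mask, dose, name = "mask") {
  sel <- resample_mask_to_dose(mask, dose)
  if (!any(sel))
    stop("'", name, "' is empty after resampling to the dose grid")
  max(dose$data[sel])
}

# logical array on the dose grid: nearest mask voxel is foreground
resample_mask_to_dose <- function(mask, dose) {
  stopifnot(inherits(mask, "mask3d"), inherits(dose, "dose_grid"))
  if (same_grid(mask, dose)) return(mask$data != 0)
  dm <- dim(mask$data); dd <- dim(dose$data)
  idx <- valid <- vector("list", 3)
  for (a in 1:3) {
    p <- axis_coords(dd[a], dose$spacing[a], dose$origin[a])
    i <- as.integer(round((p - mask$origin[a]) / mask$spacing[a]))
    valid[[a]] <- i >= 0L & i < dm[a]
    idx[[a]] <- pmin(pmax(i, 0L), dm[a] - 1L) + 1L
  }
  sel <- mask$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE] != 0
  inb <- outer(outer(valid[[1]], valid[[2]], `&`), valid[[3]], `&`)
  sel & inb
}

#' Cumulative dose-volume histogram
#'
#' Fraction of the structure's volume receiving at least each dose
#' level: starts at 1.0 at 0 Gy, is monotone non-increasing, and
#' reaches 0 beyond the maximum dose.
#'
#' @param mask a [mask3d()] (nonempty on the dose grid).
#' @param dose a [dose_grid()].
#' @param bin_width_gy dose bin width in Gy (> 0).
#' @return a `"dvh_curve"` data.frame with columns `dose_gy`,
#'   `frac_volume`.
#' @export
dvh <- function(mask, dose, bin_width_gy = 1) {
  if (bin_width_gy <= 0) stop("bin_width_gy must be positive")
  sel <- resample_mask_to_dose(mask, dose)
  if (!any(sel)) stop("mask is empty after resampling to the dose grid")
  d <- dose$data[sel]
  edges <- seq(0, max(d) + bin_width_gy, by = bin_width_gy)
  frac <- vapply(edges, function(e) mean(d >= e), 0)
  structure(data.frame(dose_gy = edges, frac_volume = frac),
            class = c("dvh_curve", "data.frame"))
}

diff_pct <- function(sub, ref) (sub - ref) / ref * 100

dose_diff_rows <- function(ref_set, sub_set, dose, mode) {
  common <- intersect(names(ref_set$masks), names(sub_set$masks))
  if (length(common) == 0)
    stop("the reference and substitute sets share no OAR names")
  rows <- lapply(common, function(nm) {
    mr <- mean_dose(ref_set$masks[[nm]], dose, nm)
    ms <- mean_dose(sub_set$masks[[nm]], dose, nm)
    xr <- max_dose(ref_set$masks[[nm]], dose, nm)
    xs <- max_dose(sub_set$masks[[nm]], dose, nm)
    if (mr == 0 || xr == 0)
      stop("reference dose for '", nm, "' is zero; the percentage ",
           "difference is undefined")
    data.frame(oar = nm, mean_ref_gy = mr, mean_sub_gy = ms,
               diff_mean_pct = diff_pct(ms, mr), max_ref_gy = xr,
               max_sub_gy = xs, diff_max_pct = diff_pct(xs, xr))
  })
  per_oar <- do.call(rbind, rows)
  summ <- data.frame(
    mode = mode, n = nrow(per_oar),
    diff_mean_pct_signed = mean(per_oar$diff_mean_pct),
    diff_mean_pct_abs = mean(abs(per_oar$diff_mean_pct)),
    diff_max_pct_signed = mean(per_oar$diff_max_pct),
    diff_max_pct_abs = mean(abs(per_oar$diff_max_pct)),
    frac_mean_gt10 = mean(abs(per_oar$diff_mean_pct) > 10),
    frac_mean_gt30 = mean(abs(per_oar$diff_mean_pct) > 30),
    frac_max_gt10 = mean(abs(per_oar$diff_max_pct) > 10),
    frac_max_gt30 = mean(abs(per_oar$diff_max_pct) > 30))
  structure(list(per_oar = per_oar, summary = summ, mode = mode),
            class = "dose_diff_report")
}

#' Direct and clinical dosimetric difference statistics
#'
#' `diff_direct()` fixes the reference dose grid and swaps the
#' contours: per OAR, the signed percentage change of the mean
#' (respectively maximum) dose when the reference contour is replaced
#' by the substitute contour, both evaluated on the reference dose
#' grid.
#'
#' `diff_clinical()` evaluates the effect of replanning on the
#' substitute contours: both terms are computed on the substitute
#' (replanned) dose grid, comparing the substitute contour against the
#' reference contour.  Replanning itself (IMRT optimization) is out of
#' scope; the replanned dose grid is an input.
#'
#' Summaries report the signed mean, the mean absolute value, and the
#' fraction of OAR instances exceeding 10% and 30% absolute
#' difference.
#'
#' @param ref reference [structure_set()].
#' @param substitute substitute [structure_set()] (e.g. predicted or
#'   perturbed contours).
#' @param dose_ref the reference (original plan) [dose_grid()].
#' @return a `"dose_diff_report"`: `per_oar` data.frame, `summary`,
#'   and `mode` (`"direct"` or `"clinical"`).
#' @export
diff_direct <- function(ref, substitute, dose_ref) {
  dose_diff_rows(ref, substitute, dose_ref, "direct")
}

#' @rdname diff_direct
#' @param dose_substitute the replanned [dose_grid()] generated with
#'   the substitute contours.
#' @param substitute_name label recorded in the report.
#' @export
diff_clinical <- function(ref, substitute, dose_substitute,
                          substitute_name = "substitute") {
  rep <- dose_diff_rows(ref, substitute, dose_substitute, "clinical")
  rep$substitute_name <- substitute_name
  rep
}

#' @export
print.dose_diff_report <- function(x, ...) {
  cat(sprintf("<dose_diff_report> mode %s, %d OARs\n", x$mode,
              x$summary$n))
  cat(sprintf("  mean-dose diff: %+.2f%% signed, %.2f%% |.|\n",
              x$summary$diff_mean_pct_signed, x$summary$diff_mean_pct_abs))
  cat(sprintf("  max-dose  diff: %+.2f%% signed, %.2f%% |.|\n",
              x$summary$diff_max_pct_signed, x$summary$diff_max_pct_abs))
  invisible(x)
}

#' Write a dose-difference report / DVH to CSV
#'
#' @param report a `"dose_diff_report"`.
#' @param csv_path,json_path output paths (either may be NULL).
#' @export
write_dose_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(report$per_oar, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(report$summary, json_path, digits = NA,
                         pretty = TRUE)
  invisible(report)
}

#' @rdname write_dose_report
#' @param curve a `"dvh_curve"`.
#' @param path CSV path.
#' @export
write_dvh <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
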