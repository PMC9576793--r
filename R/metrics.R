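#' Segmentation metrics in physical units
#'
#' Dice similarity coefficient, Hausdorff distance and average surface
#' distance between binary masks.  Surfaces are mask voxels with at
#' least one 6-connected background neighbor (or on the volume
#' border); distances are Euclidean distances between surface-voxel
#' centers in mm under the grid's anisotropic spacing, computed with
#' an exact separable distance transform.
#'
#' @param a,b [mask3d()] objects on the same grid.
#' @return `dsc()`: `2|A n B| / (|A| + |B|)` in [0, 1]; two empty
#'   masks give 1.0 with attribute `both_empty = TRUE`.
#' @examples
#' m <- array(0L, c(4, 4, 4)); m[2, 2, 2] <- 1L
#' dsc(mask3d(m), mask3d(m))
#' @export
dsc <- function(a, b) {
  stopifnot(inherits(a, "mask3d"), inherits(b, "mask3d"))
  stop_if_grid_mismatch(a, b, "masks")
  na <- sum(a$data != 0); nb <- sum(b$data != 0)
  if (na + nb == 0) return(structure(1.0, both_empty = TRUE))
  2 * sum(a$data != 0 & b$data != 0) / (na + nb)
}

surface_voxels <- function(m) {
  d <- dim(m$data)
  array(cpp_surface(as.vector(m$data != 0), d), d)
}

# directed nearest-surface distances (mm) from each surface voxel of
# `from` to the surface of `to`
directed_surface_dist <- function(from_surf, to_surf, spacing) {
  d <- dim(from_surf)
  edt <- sqrt(cpp_edt_sq(as.vector(to_surf), d, spacing))
  edt[as.vector(from_surf)]
}

surface_dists <- function(a, b) {
  stop_if_grid_mismatch(a, b, "masks")
  if (mask_volume_vox(a) == 0 || mask_volume_vox(b) == 0)
    stop("surface distances are undefined for an empty mask")
  sa <- surface_voxels(a); sb <- surface_voxels(b)
  list(ab = directed_surface_dist(sa, sb, a$spacing),
       ba = directed_surface_dist(sb, sa, a$spacing))
}

#' @rdname dsc
#' @return `hausdorff()`: a list with `hd_mm` (the maximum over both
#'   directions of the largest nearest-surface distance) and `hd95_mm`
#'   (the 95th-percentile variant, reported alongside).
#' @export
hausdorff <- function(a, b) {
  sd <- surface_dists(a, b)
  list(hd_mm = max(max(sd$ab), max(sd$ba)),
       hd95_mm = max(quantile(sd$ab, 0.95, names = FALSE),
                     quantile(sd$ba, 0.95, names = FALSE)))
}

#' @rdname dsc
#' @return `asd()`: the symmetric mean of the two directed average
#'   nearest-surface distances, in mm.
#' @export
asd <- function(a, b) {
  sd <- surface_dists(a, b)
  (mean(sd$ab) + mean(sd$ba)) / 2
}

#' Evaluate a predicted structure set against a reference
#'
#' Computes DSC/HD/HD95/ASD for every OAR present in both sets, plus
#' per-stratum and overall means over the available OARs (mirroring
#' cohorts where only a subset of OAR types is annotated).  Distances
#' are NA when either mask is empty.
#'
#' @param pred,ref [structure_set()]s on a shared grid.
#' @param registry OAR registry (stratum lookup).
#' @return a `"seg_metrics_report"`: list with `per_oar` (data.frame
#'   with columns `oar`, `stratum`, `dsc`, `hd_mm`, `hd95_mm`,
#'   `asd_mm`), `stratum_means`, `overall`, and `skipped` (names in
#'   only one set).
#' @export
evaluate_case <- function(pred, ref, registry = build_registry()) {
  common <- intersect(names(pred$masks), names(ref$masks))
  if (length(common) == 0)
    stop("the two structure sets share no OAR names")
  skipped <- setdiff(union(names(pred$masks), names(ref$masks)), common)
  rows <- lapply(common, function(nm) {
    p <- pred$masks[[nm]]; r <- ref$masks[[nm]]
    stop_if_grid_mismatch(p, r, paste0("masks for '", nm, "'"))
    d <- as.numeric(dsc(p, r))
    if (mask_volume_vox(p) > 0 && mask_volume_vox(r) > 0) {
      h <- hausdorff(p, r); a <- asd(p, r)
      data.frame(oar = nm, dsc = d, hd_mm = h$hd_mm,
                 hd95_mm = h$hd95_mm, asd_mm = a)
    } else {
      data.frame(oar = nm, dsc = d, hd_mm = NA_real_,
                 hd95_mm = NA_real_, asd_mm = NA_real_)
    }
  })
  per_oar <- do.call(rbind, rows)
  per_oar$stratum <- registry$stratum[match(per_oar$oar, registry$name)]
  per_oar <- per_oar[, c("oar", "stratum", "dsc", "hd_mm", "hd95_mm",
                         "asd_mm")]
  agg <- function(df) data.frame(
    n = nrow(df), dsc = mean(df$dsc),
    hd_mm = mean(df$hd_mm, na.rm = TRUE),
    hd95_mm = mean(df$hd95_mm, na.rm = TRUE),
    asd_mm = mean(df$asd_mm, na.rm = TRUE))
  stratum_means <- do.call(rbind, lapply(split(per_oar, per_oar$stratum),
                                         agg))
  stratum_means$stratum <- rownames(stratum_means)
  rownames(stratum_means) <- NULL
  structure(list(per_oar = per_oar, stratum_means = stratum_means,
                 overall = agg(per_oar), skipped = skipped),
            class = "seg_metrics_report")
}

#' @export
print.seg_metrics_report <- function(x, ...) {
  cat("<seg_metrics_report>\n")
  print(x$stratum_means, digits = 3)
  cat(sprintf("overall: DSC %.3f, HD %.2f mm, ASD %.2f mm over %d OARs\n",
              x$overall$dsc, x$overall$hd_mm, x$overall$asd_mm,
              x$overall$n))
  if (length(x$skipped))
    cat("skipped (present in one set only):",
        paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Write a metrics report to CSV / JSON
#'
#' @param report a `"seg_metrics_report"`.
#' @param csv_path,json_path output paths (either may be NULL).
#' @export
write_metrics_report <- function(report, csv_path = NULL,
                                 json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(report$per_oar, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(stratum_means = report$stratum_means,
                              overall = report$overall,
                              skipped = report$skipped),
                         json_path, digits = NA, pretty = TRUE)
  invisible(report)
}
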