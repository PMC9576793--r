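#' Stratified inference pipeline
#'
#' Whole-case segmentation runs in three guided stages: the anchor
#' branch segments high-contrast structures from the volume alone; its
#' foreground probability maps are concatenated to the volume as extra
#' input channels for the mid-level branch and for the S&H detection
#' branch; each detected S&H center seeds a volume-of-interest crop
#' (three times the class's maximum extent) inside which the zoom-in
#' branch segments the fine boundary from the cropped volume alone.
#'
#' @name pipeline
NULL

prediction_maps <- function(probs, class_names, spacing, origin) {
  structure(list(probs = probs, class_names = class_names,
                 spacing = spacing, origin = origin),
            class = "prediction_maps")
}

#' @export
print.prediction_maps <- function(x, ...) {
  cat(sprintf("<prediction_maps> %s voxels x %d classes\n",
              paste(dim(x$probs)[1:3], collapse = "x"),
              dim(x$probs)[4]))
  invisible(x)
}

check_role <- function(model, role) {
  if (!inherits(model, "branch_model") || model$role != role)
    stop("expected a branch model with role '", role, "', got '",
         if (inherits(model, "branch_model")) model$role else
           class(model)[1], "'")
}

infer_tile <- function(model) model$config$patch

#' @rdname pipeline
#' @param x a [volume3d()].
#' @param model the `anchor_seg` branch model.
#' @return [predict_anchor()] returns a `"prediction_maps"`: per-voxel
#'   softmax probabilities over background + the anchor classes, on
#'   the input grid.
#' @export
predict_anchor <- function(x, model) {
  check_role(model, "anchor_seg")
  xin <- array(znorm(x$data), c(dim(x$data), 1L))
  logits <- net_predict(model$net, xin, tile = infer_tile(model))
  prediction_maps(softmax_channels(logits),
                  c("background", oar_names(model$registry, "anchor")),
                  x$spacing, x$origin)
}

# anchor foreground probability channels (background dropped)
guidance_channels <- function(anchor_pred) {
  p <- anchor_pred$probs
  p[, , , -1L, drop = FALSE]
}

check_guidance_arity <- function(model, n_guidance) {
  expected <- model$net$in_ch
  got <- 1L + n_guidance
  if (expected != got)
    stop("guidance channel mismatch: model expects ", expected,
         " input channels, got ", got, " (volume + ", n_guidance,
         " anchor maps)")
}

#' @rdname pipeline
#' @param anchor_pred the anchor `"prediction_maps"` on the same grid.
#' @return [predict_midlevel()] returns mid-level class probabilities;
#'   the network input is the channel concatenation of the volume and
#'   the anchor foreground maps.
#' @export
predict_midlevel <- function(x, anchor_pred, model) {
  check_role(model, "mid_seg")
  if (!identical(dim(anchor_pred$probs)[1:3], dim(x$data)))
    stop("anchor prediction geometry does not match the volume")
  g <- guidance_channels(anchor_pred)
  check_guidance_arity(model, dim(g)[4])
  xin <- array(c(znorm(x$data), g), c(dim(x$data), 1L + dim(g)[4]))
  logits <- net_predict(model$net, xin, tile = infer_tile(model))
  prediction_maps(softmax_channels(logits),
                  c("background", oar_names(model$registry, "mid-level")),
                  x$spacing, x$origin)
}

#' 3D Gaussian heatmap target
#'
#' The detection branch regresses heatmaps whose training labels are
#' generated at each organ center with a 3D Gaussian kernel in
#' physical coordinates: `h(v) = exp(-||p(v) - p(center)||^2 /
#' (2 sigma^2))`, peak value exactly 1 at the center voxel.
#'
#' @param center 0-based voxel index (z, y, x) of the organ center
#'   (the mask centroid rounded to the nearest voxel).
#' @param sigma_mm Gaussian standard deviation in mm.
#' @param grid a [volume3d()] (or any list with `data`, `spacing`,
#'   `origin`) defining the output geometry.
#' @return a 3D array heatmap on the grid.
#' @export
gaussian_target <- function(center, sigma_mm, grid) {
  d <- dim(grid$data)
  center <- as.numeric(center)
  if (sigma_mm <= 0) stop("sigma_mm must be positive")
  if (any(center < 0) || any(center > d - 1))
    stop("center (", paste(center, collapse = ","),
         ") is outside the grid ", paste(d, collapse = "x"))
  s2 <- 2 * sigma_mm^2
  gz <- exp(-((seq_len(d[1]) - 1 - center[1]) * grid$spacing[1])^2 / s2)
  gy <- exp(-((seq_len(d[2]) - 1 - center[2]) * grid$spacing[2])^2 / s2)
  gx <- exp(-((seq_len(d[3]) - 1 - center[3]) * grid$spacing[3])^2 / s2)
  outer(outer(gz, gy, `*`), gx, `*`)
}

#' @rdname pipeline
#' @return [predict_heatmaps()] returns a `"heatmap_set"`: one
#'   regressed heatmap per S&H OAR, clamped to [0, 1].
#' @export
predict_heatmaps <- function(x, anchor_pred, model) {
  check_role(model, "sh_detect")
  if (!identical(dim(anchor_pred$probs)[1:3], dim(x$data)))
    stop("anchor prediction geometry does not match the volume")
  g <- guidance_channels(anchor_pred)
  check_guidance_arity(model, dim(g)[4])
  xin <- array(c(znorm(x$data), g), c(dim(x$data), 1L + dim(g)[4]))
  maps <- net_predict(model$net, xin, tile = infer_tile(model))
  maps <- pmin(pmax(maps, 0), 1)
  structure(list(maps = maps,
                 names = oar_names(model$registry, "small_hard"),
                 spacing = x$spacing, origin = x$origin),
            class = "heatmap_set")
}

#' Extract the peak voxel of a heatmap
#'
#' Returns the 0-based (z, y, x) index of the global maximum; ties are
#' broken by the lexicographically smallest (z, y, x).  An
#' all-constant heatmap warns and returns (0, 0, 0) by the tie rule.
#'
#' @param h a 3D array (one heatmap channel).
#' @return integer vector length 3, 0-based (z, y, x).
#' @export
extract_peak <- function(h) {
  if (length(h) == 0) stop("empty heatmap")
  mx <- max(h)
  if (mx == min(h))
    warning("all-constant heatmap; returning (0,0,0) by the tie rule")
  w <- which(h == mx, arr.ind = TRUE)
  if (nrow(w) > 1) w <- w[order(w[, 1], w[, 2], w[, 3]), , drop = FALSE]
  as.integer(w[1, ] - 1L)
}

#' Crop a volume of interest around a detected center
#'
#' The VOI spans three times the class's maximum per-axis extent:
#' `size = round(3 * extent_mm / spacing)` voxels, centered at the
#' detected peak.  Windows that would cross the volume bounds are
#' shifted inward so the full size is retained whenever possible, and
#' truncated only when the volume itself is smaller than the window.
#'
#' @param x a [volume3d()].
#' @param center 0-based (z, y, x) voxel index.
#' @param entry a one-row registry entry with its `extent_*_mm` set
#'   (see [estimate_extents()]).
#' @return a `"voi_crop"`: 0-based `start`, `size`, the cropped
#'   `volume`, and the source geometry.  [paste_voi()] inverts it.
#' @export
crop_voi <- function(x, center, entry) {
  d <- dim(x$data)
  ext <- c(entry$extent_z_mm, entry$extent_y_mm, entry$extent_x_mm)
  if (any(is.na(ext)))
    stop("max extent is unset for '", entry$name,
         "'; supply it or estimate it from a training set")
  center <- as.numeric(center)
  if (any(center < 0) || any(center > d - 1))
    stop("center is outside the volume")
  size <- pmax(1L, as.integer(round(3 * ext / x$spacing)))
  size <- pmin(size, d)
  start <- as.integer(center - size %/% 2L)
  start <- pmin(pmax(start, 0L), d - size)
  iz <- start[1] + seq_len(size[1]); iy <- start[2] + seq_len(size[2])
  ix <- start[3] + seq_len(size[3])
  vol <- volume3d(x$data[iz, iy, ix, drop = FALSE], x$spacing,
                  x$origin + start * x$spacing)
  structure(list(start = start, size = size, volume = vol,
                 source_dim = d, spacing = x$spacing,
                 source_origin = x$origin, name = entry$name),
            class = "voi_crop")
}

#' @rdname pipeline
#' @param v a `"voi_crop"` from [crop_voi()].
#' @return [predict_sh()] returns class probabilities over the VOI
#'   grid (background + the S&H classes); the network input is the
#'   cropped volume alone.
#' @export
predict_sh <- function(v, model) {
  check_role(model, "sh_seg")
  stopifnot(inherits(v, "voi_crop"))
  xin <- array(znorm(v$volume$data), c(dim(v$volume$data), 1L))
  logits <- net_predict(model$net, xin, tile = infer_tile(model))
  prediction_maps(softmax_channels(logits),
                  c("background", oar_names(model$registry, "small_hard")),
                  v$volume$spacing, v$volume$origin)
}

#' Paste a VOI prediction back into the full grid
#'
#' Thresholds the VOI prediction by per-voxel argmax and places the
#' resulting mask at the crop location; voxels outside the crop window
#' are always 0.  With [crop_voi()] this is an exact round trip on the
#' window.
#'
#' @param full_geometry a [volume3d()] carrying the target geometry.
#' @param voi_pred a `"prediction_maps"` over the VOI.
#' @param crop the `"voi_crop"` the prediction came from.
#' @param class_name restrict the mask to one class (default: any
#'   foreground argmax).
#' @return a [mask3d()] on the full grid.
#' @export
paste_voi <- function(full_geometry, voi_pred, crop, class_name = NULL) {
  d <- dim(full_geometry$data)
  if (!identical(crop$source_dim, d))
    stop("crop source geometry ", paste(crop$source_dim, collapse = "x"),
         " does not match the full grid ", paste(d, collapse = "x"))
  pd <- dim(voi_pred$probs)
  if (!identical(pd[1:3], crop$size))
    stop("VOI prediction shape does not match the crop window")
  n <- prod(pd[1:3])
  am <- max.col(matrix(voi_pred$probs, n, pd[4]), "first") - 1L
  sel <- if (is.null(class_name)) am > 0L
         else am == (match(class_name, voi_pred$class_names) - 1L)
  full <- array(0L, d)
  iz <- crop$start[1] + seq_len(crop$size[1])
  iy <- crop$start[2] + seq_len(crop$size[2])
  ix <- crop$start[3] + seq_len(crop$size[3])
  full[iz, iy, ix] <- as.integer(array(sel, pd[1:3]))
  mask3d(full, full_geometry$spacing, full_geometry$origin)
}

# per-class argmax masks from a prediction_maps; every OAR is one
# connected organ, so each class keeps its largest 6-connected
# component (standard postprocessing for single-structure classes)
argmax_masks <- function(pred, largest_component = TRUE) {
  d <- dim(pred$probs)
  n <- prod(d[1:3])
  am <- max.col(matrix(pred$probs, n, d[4]), "first") - 1L
  am <- array(am, d[1:3])
  out <- list()
  for (c in seq_len(d[4] - 1L)) {
    m <- am == c
    if (largest_component && any(m))
      m <- array(cpp_largest_component(as.vector(m), d[1:3]), d[1:3])
    out[[pred$class_names[c + 1L]]] <-
      mask3d(array(as.integer(m), d[1:3]), pred$spacing, pred$origin)
  }
  out
}

#' @rdname pipeline
#' @param models named list with elements `anchor_seg`, `mid_seg`,
#'   `sh_detect`, `sh_seg` (trained [train_branch()] models).
#' @param registry registry with `extent_*_mm` set for every S&H entry
#'   (the 3x VOI rule needs them).
#' @return [run_inference()] returns a [structure_set()] with one mask
#'   per registry entry (possibly empty); every S&H mask is confined
#'   to its VOI window.
#' @export
run_inference <- function(x, models, registry = build_registry()) {
  need <- c("anchor_seg", "mid_seg", "sh_detect", "sh_seg")
  if (!all(need %in% names(models)))
    stop("models must contain: ", paste(need, collapse = ", "))
  for (r in need) check_role(models[[r]], r)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  anchor_pred <- stage("anchor", predict_anchor(x, models$anchor_seg))
  masks <- stage("anchor", argmax_masks(anchor_pred))
  mid_pred <- stage("mid-level",
                    predict_midlevel(x, anchor_pred, models$mid_seg))
  masks <- c(masks, stage("mid-level", argmax_masks(mid_pred)))
  heat <- stage("detection",
                predict_heatmaps(x, anchor_pred, models$sh_detect))
  for (nm in heat$names) {
    i <- match(nm, heat$names)
    entry <- registry[registry$name == nm, , drop = FALSE]
    masks[[nm]] <- stage(paste0("zoom-in '", nm, "'"), {
      peak <- extract_peak(heat$maps[, , , i])
      crop <- crop_voi(x, peak, entry)
      voi_pred <- predict_sh(crop, models$sh_seg)
      paste_voi(x, voi_pred, crop, class_name = nm)
    })
  }
  masks <- masks[registry$name[registry$name %in% names(masks)]]
  structure_set(masks, canonicalize = FALSE)
}
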