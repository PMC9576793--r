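#' 3D volume, mask, structure-set and dose-grid containers
#'
#' The package works on regular 3D scalar grids with anisotropic voxel
#' spacing.  The axis order is fixed to (z, y, x) everywhere: array
#' dimension 1 is the through-plane (slice) axis, dimensions 2 and 3
#' are in-plane.  Voxel indices are 0-based in all geometry arithmetic
#' (crops, centers, peaks); R's 1-based subscripting is confined to the
#' implementation.  All crop windows are half-open intervals
#' `[start, start + size)`.
#'
#' @param data numeric 3D array, dim = (nz, ny, nx).  For [volume3d()]
#'   the values are scalars (HU-like for CT, unitless for phantoms);
#'   for [mask3d()] they must be 0/1.
#' @param spacing numeric length-3, voxel size in mm per (z, y, x) axis;
#'   all components must be positive.
#' @param origin numeric length-3, physical position in mm of the voxel
#'   with 0-based index (0, 0, 0).
#' @return An object of class `"volume3d"` (or `c("mask3d","volume3d")`,
#'   `c("dose_grid","volume3d")`): a list with elements `data`,
#'   `spacing`, `origin`.
#' @examples
#' v <- volume3d(array(0, c(4, 5, 6)), spacing = c(3, 1, 1))
#' dim(v$data)
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (z, y, x); got ",
         paste(dim(data), collapse = "x"))
  if (any(dim(data) < 1L)) stop("all three extents must be positive")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume3d")
}

#' @rdname volume3d
#' @export
mask3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  v <- volume3d(data, spacing, origin)
  u <- unique(as.vector(v$data))
  if (!all(u %in% c(0, 1)))
    stop("mask values must be 0/1; found ",
         paste(utils::head(setdiff(u, c(0, 1)), 3), collapse = ", "))
  storage.mode(v$data) <- "integer"
  class(v) <- c("mask3d", "volume3d")
  v
}

#' @rdname volume3d
#' @param dose numeric 3D array of doses in Gy (all values >= 0).
#' @export
dose_grid <- function(dose, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  v <- volume3d(dose, spacing, origin)
  if (any(v$data < 0)) stop("doses must be nonnegative (Gy)")
  class(v) <- c("dose_grid", "volume3d")
  v
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin %s mm\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!same_grid(a, b))
    stop(what, " are on different grids: ",
         paste(dim(a$data), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"))
  invisible(TRUE)
}

#' Named collection of masks on one grid
#'
#' A structure set holds one binary mask per OAR, all sharing a single
#' grid geometry.  Names are canonicalized through the registry synonym
#' table (see [canonical_name()]).
#'
#' @param masks named list of [mask3d()] objects on a common grid.
#' @param canonicalize canonicalize names through the registry synonym
#'   table (default TRUE; unknown names are kept verbatim).
#' @return An object of class `"structure_set"`.
#' @export
structure_set <- function(masks, canonicalize = TRUE) {
  if (length(masks) == 0) stop("a structure set needs at least one mask")
  if (is.null(names(masks)) || any(!nzchar(names(masks))))
    stop("all masks must be named")
  if (canonicalize)
    names(masks) <- vapply(names(masks), canonical_name, "", strict = FALSE)
  if (anyDuplicated(names(masks)))
    stop("duplicate mask names after canonicalization: ",
         paste(unique(names(masks)[duplicated(names(masks))]), collapse = ", "))
  ref <- masks[[1]]
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!inherits(m, "mask3d")) stop("entry '", nm, "' is not a mask3d")
    if (!same_grid(ref, m))
      stop("mask '", nm, "' is not on the shared grid")
  }
  structure(list(masks = masks, spacing = ref$spacing, origin = ref$origin,
                 dim = dim(ref$data)),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d masks on %s grid (%s mm)\n",
              length(x$masks), paste(x$dim, collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' @export
names.structure_set <- function(x) names(x$masks)

# physical coordinates (mm) of 0-based voxel indices, one axis
axis_coords <- function(n, spacing, origin) origin + spacing * (seq_len(n) - 1)

# 0-based centroid of a mask in voxel units (numeric, not rounded)
mask_centroid <- function(mask) {
  w <- which(mask$data != 0, arr.ind = TRUE)
  if (nrow(w) == 0) stop("cannot take the centroid of an empty mask")
  colMeans(w) - 1
}

mask_volume_vox <- function(mask) sum(mask$data != 0)
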