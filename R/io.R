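#' NIfTI volume I/O
#'
#' Volumes, masks and dose grids are interchanged as NIfTI files.  On
#' disk the payload is stored in (x, y, z) axis order with the voxel
#' spacing in `pixdim` and the origin in an axis-aligned qform; in
#' memory the package convention is (z, y, x), so arrays are
#' transposed on the way through.  Round trips preserve data, spacing
#' and origin to stored precision.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns a [volume3d()]; `read_mask()` a
#'   [mask3d()]; `read_dose()` a [dose_grid()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("'", path, "' is ", length(d), "D; a 3D volume is required")
  sp_xyz <- RNifti::pixdim(img)
  if (length(sp_xyz) != 3L || any(!is.finite(sp_xyz)) || any(sp_xyz <= 0))
    stop("'", path, "' has no valid 3D voxel spacing")
  xf <- RNifti::xform(img)
  origin_xyz <- xf[1:3, 4]
  volume3d(aperm(as.array(img), 3:1), spacing = rev(sp_xyz),
           origin = rev(origin_xyz))
}

#' @rdname read_volume
#' @param volume a [volume3d()] (or mask / dose grid).
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume3d"))
  img <- RNifti::asNifti(aperm(volume$data, 3:1))
  RNifti::pixdim(img) <- rev(volume$spacing)
  xf <- diag(c(rev(volume$spacing), 1))
  xf[1:3, 4] <- rev(volume$origin)
  img <- RNifti::`qform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  mask3d(array(as.integer(v$data != 0), dim(v$data)), v$spacing, v$origin)
}

#' @rdname read_volume
#' @export
read_dose <- function(path) {
  v <- read_volume(path)
  dose_grid(v$data, v$spacing, v$origin)
}

#' Structure-set I/O via a JSON manifest
#'
#' A structure set on disk is a directory of per-OAR NIfTI masks plus
#' a JSON manifest mapping OAR names to file paths.  Names are
#' canonicalized through the registry synonym table on read, so
#' clinical spellings like `"TMJ_Lt"` resolve to `"tmj_left"`.
#'
#' @param manifest_path path to the manifest JSON.
#' @return `read_structures()` returns a [structure_set()].
#' @export
read_structures <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (is.null(man$masks) || length(man$masks) == 0)
    stop("manifest has no 'masks' entries")
  base <- dirname(manifest_path)
  masks <- list()
  for (nm in names(man$masks)) {
    p <- man$masks[[nm]]
    if (!file.exists(p)) p <- file.path(base, man$masks[[nm]])
    masks[[nm]] <- read_mask(p)
  }
  structure_set(masks, canonicalize = TRUE)
}

#' @rdname read_structures
#' @param set a [structure_set()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix for the masks.
#' @param extra named list merged into the manifest (e.g. seeds,
#'   config digest).
#' @return `write_structures()` returns the manifest path.
#' @export
write_structures <- function(set, dir, prefix = "", extra = list()) {
  stopifnot(inherits(set, "structure_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reg <- build_registry()
  files <- list()
  for (nm in names(set$masks)) {
    f <- paste0(prefix, nm, ".nii.gz")
    write_volume(set$masks[[nm]], file.path(dir, f))
    files[[nm]] <- f
  }
  strata <- reg$stratum[match(names(files), reg$name)]
  man <- c(list(masks = files,
                strata = as.list(stats::setNames(strata, names(files))),
                spacing_mm = set$spacing, shape = set$dim),
           extra)
  mp <- file.path(dir, paste0(prefix, "manifest.json"))
  jsonlite::write_json(man, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  mp
}

# short provenance digest of an R object (seed/config stamping)
config_digest <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp, version = 2, ascii = TRUE)
  unname(tools::md5sum(tmp))
}
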