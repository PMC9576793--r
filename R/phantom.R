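#' Synthetic phantom configuration
#'
#' The phantom generator emulates the study conditions of a stratified
#' OAR cohort at desk scale: a background volume containing
#' high-contrast larger ellipsoids (anchor-like), medium-contrast
#' mid-size ellipsoids (mid-level-like), and tiny low-contrast
#' ellipsoids (S&H-like), plus additive Gaussian noise.  Structures are
#' placed by rejection sampling so they never overlap and lie strictly
#' inside the volume, and are named after registry entries of the
#' matching stratum, so a phantom is directly consumable by every
#' pipeline stage.
#'
#' Defaults: a 64x96x96 voxel grid at 1.5 mm isotropic spacing (a
#' head-and-neck-like field of view trainable on a CPU in minutes),
#' the full registry complement of 9/19/14 structures, contrast
#' offsets 300/100/30 intensity units above background for the three
#' strata (mirroring the bone-to-soft-tissue-to-small-structure
#' contrast ordering of CT anatomy), and noise with standard
#' deviation 10.
#'
#' @param shape integer length-3 voxel extents (z, y, x).
#' @param spacing numeric length-3 voxel size in mm.
#' @param n_anchor,n_midlevel,n_small_hard structure counts per stratum
#'   (at most the registry stratum sizes 9/19/14).
#' @param radius_anchor_mm,radius_midlevel_mm,radius_small_hard_mm
#'   length-2 ranges of ellipsoid semi-axes in mm.
#' @param contrast_anchor,contrast_midlevel,contrast_small_hard
#'   intensity offset of each stratum above background.
#' @param background background intensity.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed integer seed; mandatory, all generation is a pure
#'   function of (config, seed).
#' @return an object of class `"phantom_config"`.
#' @export
phantom_config <- function(shape = c(64, 96, 96),
                           spacing = c(1.5, 1.5, 1.5),
                           n_anchor = 9, n_midlevel = 19,
                           n_small_hard = 14,
                           radius_anchor_mm = c(8, 14),
                           radius_midlevel_mm = c(5, 9),
                           radius_small_hard_mm = c(2, 4),
                           contrast_anchor = 300,
                           contrast_midlevel = 100,
                           contrast_small_hard = 30,
                           background = 0, noise_sd = 10, seed = 1L) {
  cfg <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
              n = c(anchor = n_anchor, `mid-level` = n_midlevel,
                    small_hard = n_small_hard),
              radius_mm = list(anchor = radius_anchor_mm,
                               `mid-level` = radius_midlevel_mm,
                               small_hard = radius_small_hard_mm),
              contrast = c(anchor = contrast_anchor,
                           `mid-level` = contrast_midlevel,
                           small_hard = contrast_small_hard),
              background = background, noise_sd = noise_sd,
              seed = as.integer(seed))
  if (any(cfg$n < 0)) stop("structure counts must be >= 0")
  if (is.na(cfg$seed)) stop("a seed is mandatory")
  for (s in STRATA) {
    r <- cfg$radius_mm[[s]]
    if (any(2 * max(r) >= cfg$shape * cfg$spacing))
      stop("radii for stratum '", s, "' do not fit inside the volume")
  }
  class(cfg) <- "phantom_config"
  cfg
}

# voxelize an ellipsoid: semi-axes r (mm), center cz/cy/cx (mm)
ellipsoid_mask <- function(shape, spacing, center_mm, r_mm) {
  qz <- ((axis_coords(shape[1], spacing[1], 0) - center_mm[1]) / r_mm[1])^2
  qy <- ((axis_coords(shape[2], spacing[2], 0) - center_mm[2]) / r_mm[2])^2
  qx <- ((axis_coords(shape[3], spacing[3], 0) - center_mm[3]) / r_mm[3])^2
  q <- outer(outer(qz, qy, `+`), qx, `+`)
  array(as.integer(q <= 1), shape)
}

#' Generate a synthetic phantom
#'
#' @param config a [phantom_config()].
#' @param max_attempts rejection-sampling attempts per structure before
#'   a placement error is raised.
#' @return `list(image = volume3d, labels = structure_set)`.
#' @examples
#' ph <- generate_phantom(phantom_config(n_anchor = 2, n_midlevel = 2,
#'                                       n_small_hard = 2, seed = 7))
#' length(ph$labels$masks)
#' @export
generate_phantom <- function(config, max_attempts = 1000L) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  shape <- config$shape
  spacing <- config$spacing
  extent_mm <- shape * spacing
  img <- array(config$background, shape)
  occupied <- array(FALSE, shape)
  reg <- build_registry()
  masks <- list()

  for (s in STRATA) {
    ns <- config$n[[s]]
    if (ns == 0) next
    nms <- oar_names(reg, s)
    if (ns > length(nms))
      stop("stratum '", s, "' has only ", length(nms), " registry names")
    rng <- config$radius_mm[[s]]
    # class identity within a stratum is carried by size: structure k
    # draws its semi-axes from the k-th sub-band of the stratum's
    # radius range.  Organs differ in geometry, and the pipeline's
    # instance-normalized networks retain shape (not absolute
    # intensity), so size is the appearance cue that makes classes
    # decodable from a local patch.
    band <- (rng[2] - rng[1]) / ns
    for (k in seq_len(ns)) {
      lo_r <- rng[1] + (k - 1) * band
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        # 30% guard spacing between consecutive bands keeps classes
        # separable even at band boundaries
        r <- runif(3, lo_r, lo_r + 0.7 * band)
        # keep the whole ellipsoid strictly inside the bounds
        lo <- r + 1.5 * spacing
        hi <- extent_mm - spacing - r - 0.5 * spacing
        if (any(hi <= lo)) next
        ctr <- runif(3, lo, hi)
        m <- ellipsoid_mask(shape, spacing, ctr, r)
        if (sum(m) == 0L) next
        if (!any(occupied & (m == 1L))) {
          occupied <- occupied | (m == 1L)
          img <- img + config$contrast[[s]] * m
          masks[[nms[k]]] <- m
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place structure ", k, " of stratum '", s,
             "' without overlap after ", max_attempts, " attempts")
    }
  }

  if (config$noise_sd > 0)
    img <- img + array(rnorm(prod(shape), 0, config$noise_sd), shape)

  labels <- structure_set(lapply(masks, mask3d, spacing = spacing),
                          canonicalize = FALSE)
  list(image = volume3d(img, spacing), labels = labels)
}

#' Analytic dose-field configuration and generation
#'
#' Emulates an IMRT-like dose distribution as an isotropic Gaussian
#' falloff around a target: `dose(v) = background + (prescription -
#' background) * exp(-d(v)^2 / (2 sigma^2))` with `d` the physical
#' distance (mm) from the voxel center to the target centroid.
#'
#' @param prescription_dose dose in Gy at the target center (default
#'   70 Gy, a standard head-and-neck prescription).
#' @param falloff_sigma_mm Gaussian falloff scale in mm.
#' @param background_dose background dose in Gy.
#' @return a `"dose_field_config"`.
#' @export
dose_field_config <- function(prescription_dose = 70,
                              falloff_sigma_mm = 20,
                              background_dose = 0) {
  if (!(prescription_dose > background_dose && background_dose >= 0))
    stop("need prescription_dose > background_dose >= 0")
  if (falloff_sigma_mm <= 0) stop("falloff_sigma_mm must be positive")
  structure(list(prescription_dose = prescription_dose,
                 falloff_sigma_mm = falloff_sigma_mm,
                 background_dose = background_dose),
            class = "dose_field_config")
}

#' @rdname dose_field_config
#' @param target a nonempty [mask3d()] defining the target centroid.
#' @param config a [dose_field_config()].
#' @param dose_spacing optional dose-grid voxel size in mm (clinical
#'   dose grids are coarser than the CT, 2-4 mm); default: the target
#'   mask's grid.
#' @return `generate_dose_grid()` returns a [dose_grid()].
#' @export
generate_dose_grid <- function(target, config = dose_field_config(),
                               dose_spacing = NULL) {
  stopifnot(inherits(target, "mask3d"), inherits(config, "dose_field_config"))
  if (mask_volume_vox(target) == 0) stop("target mask is empty")
  ctr_vox <- mask_centroid(target)
  ctr_mm <- target$origin + ctr_vox * target$spacing
  if (is.null(dose_spacing)) {
    shape <- dim(target$data); spacing <- target$spacing; origin <- target$origin
  } else {
    dose_spacing <- rep_len(as.numeric(dose_spacing), 3)
    shape <- pmax(1L, as.integer(ceiling(dim(target$data) * target$spacing /
                                         dose_spacing)))
    spacing <- dose_spacing; origin <- target$origin
  }
  s2 <- 2 * config$falloff_sigma_mm^2
  gz <- exp(-(axis_coords(shape[1], spacing[1], origin[1]) - ctr_mm[1])^2 / s2)
  gy <- exp(-(axis_coords(shape[2], spacing[2], origin[2]) - ctr_mm[2])^2 / s2)
  gx <- exp(-(axis_coords(shape[3], spacing[3], origin[3]) - ctr_mm[3])^2 / s2)
  d <- config$background_dose +
    (config$prescription_dose - config$background_dose) *
    outer(outer(gz, gy, `*`), gx, `*`)
  dose_grid(array(d, shape), spacing, origin)
}

#' Perturb a mask to emulate inter-reader contour variation
#'
#' Displaces the mask boundary by a smooth spatially-correlated random
#' field: the mask's signed distance function is offset by a field of
#' random Gaussian bumps scaled so that the mean absolute boundary
#' displacement equals `magnitude_mm`, then re-thresholded.  Positive
#' field values dilate the contour locally, negative values erode it,
#' so the perturbation combines smooth deformation with local
#' dilation/erosion.  Magnitude 0 returns the input unchanged;
#' identical (mask, magnitude, seed) triples give identical output.
#'
#' @param mask a [mask3d()].
#' @param magnitude_mm expected boundary displacement in mm (>= 0).
#' @param seed integer seed.
#' @param corr_length_mm correlation length of the random field (mm).
#' @param n_bumps number of Gaussian bumps composing the field.
#' @return a perturbed [mask3d()] on the same grid.
#' @export
perturb_mask <- function(mask, magnitude_mm, seed,
                         corr_length_mm = 8, n_bumps = 24L) {
  stopifnot(inherits(mask, "mask3d"), magnitude_mm >= 0)
  if (magnitude_mm == 0) return(mask)
  if (mask_volume_vox(mask) == 0) return(mask)
  set.seed(as.integer(seed))
  shape <- dim(mask$data)
  spacing <- mask$spacing

  # work inside a padded bounding box; the field cannot move the
  # boundary further than a few magnitudes outward
  w <- which(mask$data != 0, arr.ind = TRUE)
  pad <- ceiling((3 * magnitude_mm + 3) / spacing)
  lo <- pmax(apply(w, 2, min) - pad, 1L)
  hi <- pmin(apply(w, 2, max) + pad, shape)
  sub <- mask$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sdim <- dim(sub)

  inside <- sub != 0
  d_out <- sqrt(cpp_edt_sq(as.vector(inside), sdim, spacing))
  d_in <- sqrt(cpp_edt_sq(as.vector(!inside), sdim, spacing))
  sdf <- array(d_out - d_in, sdim)  # negative inside the mask

  ext <- sdim * spacing
  f <- array(0, sdim)
  s2 <- 2 * corr_length_mm^2
  for (b in seq_len(n_bumps)) {
    a <- rnorm(1)
    ctr <- runif(3, 0, ext)
    bz <- exp(-(axis_coords(sdim[1], spacing[1], 0) - ctr[1])^2 / s2)
    by <- exp(-(axis_coords(sdim[2], spacing[2], 0) - ctr[2])^2 / s2)
    bx <- exp(-(axis_coords(sdim[3], spacing[3], 0) - ctr[3])^2 / s2)
    f <- f + a * outer(outer(bz, by, `*`), bx, `*`)
  }
  surf <- array(cpp_surface(as.vector(inside), sdim), sdim)
  msurf <- mean(abs(f[surf]))
  if (msurf > 0) f <- f * (magnitude_mm / msurf)

  newsub <- array(as.integer(sdf < f), sdim)
  out <- mask$data
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- newsub
  mask3d(out, spacing, mask$origin)
}
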