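#' The stratified head-and-neck OAR registry
#'
#' The framework partitions 42 head-and-neck organs at risk into three
#' difficulty strata that drive the pipeline topology:
#'
#' * **anchor** (9): high-contrast, low-variability structures
#'   (brainstem, cerebellum, eyes, mandible halves, spinal cord,
#'   temporomandibular joints) segmented first and used as guidance;
#' * **mid-level** (19): low-contrast soft-tissue structures segmented
#'   with the anchor predictions as extra input channels;
#' * **small_hard** (14): very small or very low-contrast structures
#'   handled by detection (heatmap regression) followed by zoom-in
#'   segmentation inside a cropped volume of interest.
#'
#' Canonical names are lowercase snake_case with explicit `_left` /
#' `_right` suffixes; [canonical_name()] maps the abbreviation styles
#' common in clinical tables (e.g. `"TMJ_Lt"`, `"SMG_Rt"`) onto them.
#'
#' @return `build_registry()` returns an object of class
#'   `"oar_registry"`: a data.frame with columns `name`, `stratum`
#'   (`"anchor"`, `"mid-level"`, `"small_hard"`), `laterality`
#'   (`"left"`, `"right"`, `"none"`), `class_index` (1-based position
#'   within the stratum; background is always class 0 in every branch),
#'   and per-axis maximum extents `extent_z_mm`, `extent_y_mm`,
#'   `extent_x_mm` (NA until supplied or estimated from training data
#'   with [estimate_extents()]).
#' @examples
#' reg <- build_registry()
#' table(reg$stratum)
#' stratum_of("TMJ_Lt")
#' @export
build_registry <- function() {
  anchor <- c("brainstem", "cerebellum", "eye_left", "eye_right",
              "mandible_left", "mandible_right", "spinal_cord",
              "tmj_left", "tmj_right")
  mid <- c("brachial_plexus_left", "brachial_plexus_right",
           "basal_ganglia_left", "basal_ganglia_right",
           "constrictor_inferior", "constrictor_middle",
           "constrictor_superior", "esophagus", "gsl", "glottic_area",
           "oral_cavity", "parotid_left", "parotid_right",
           "submandibular_left", "submandibular_right",
           "temporal_lobe_left", "temporal_lobe_right",
           "thyroid_left", "thyroid_right")
  sh <- c("cochlea_left", "cochlea_right", "hypothalamus",
          "inner_ear_left", "inner_ear_right", "lacrimal_gland_left",
          "lacrimal_gland_right", "lens_left", "lens_right",
          "optic_nerve_left", "optic_nerve_right", "optic_chiasm",
          "pineal_gland", "pituitary")
  name <- c(anchor, mid, sh)
  stratum <- rep(c("anchor", "mid-level", "small_hard"),
                 c(length(anchor), length(mid), length(sh)))
  laterality <- ifelse(grepl("_left$", name), "left",
                       ifelse(grepl("_right$", name), "right", "none"))
  class_index <- c(seq_along(anchor), seq_along(mid), seq_along(sh))
  reg <- data.frame(name = name, stratum = stratum,
                    laterality = laterality, class_index = class_index,
                    extent_z_mm = NA_real_, extent_y_mm = NA_real_,
                    extent_x_mm = NA_real_, stringsAsFactors = FALSE)
  class(reg) <- c("oar_registry", "data.frame")
  reg
}

STRATA <- c("anchor", "mid-level", "small_hard")

# synonym table: normalized clinical-table spellings -> canonical names
oar_synonyms <- function() {
  c(brainstem = "brainstem", spinalcord = "spinal_cord",
    tmjoint_left = "tmj_left", tmjoint_right = "tmj_right",
    basalganglia_left = "basal_ganglia_left",
    basalganglia_right = "basal_ganglia_right",
    brachial_left = "brachial_plexus_left",
    brachial_right = "brachial_plexus_right",
    brachialplexus_left = "brachial_plexus_left",
    brachialplexus_right = "brachial_plexus_right",
    const_inf = "constrictor_inferior", const_mid = "constrictor_middle",
    const_sup = "constrictor_superior",
    glotticarea = "glottic_area", oralcavity = "oral_cavity",
    smg_left = "submandibular_left", smg_right = "submandibular_right",
    submandibulargland_left = "submandibular_left",
    submandibulargland_right = "submandibular_right",
    templobe_left = "temporal_lobe_left",
    templobe_right = "temporal_lobe_right",
    innerear_left = "inner_ear_left", innerear_right = "inner_ear_right",
    lacrimalgland_left = "lacrimal_gland_left",
    lacrimalgland_right = "lacrimal_gland_right",
    opticnerve_left = "optic_nerve_left",
    opticnerve_right = "optic_nerve_right",
    opticchiasm = "optic_chiasm", pinealgland = "pineal_gland",
    larynx_gsl = "gsl")
}

#' Canonicalize an OAR name
#'
#' Lowercases, converts separators to underscores, expands `_Lt`/`_Rt`
#' suffixes to `_left`/`_right`, and applies the synonym table for the
#' abbreviation styles found in clinical report tables.
#'
#' @param name a single OAR name in any supported spelling.
#' @param strict if TRUE (default), error when the result is not a
#'   registry member, listing near matches.
#' @return the canonical name string.
#' @examples
#' canonical_name("TMJ_Lt")
#' canonical_name("SMG_Rt")
#' @export
canonical_name <- function(name, strict = TRUE) {
  stopifnot(is.character(name), length(name) == 1L)
  n <- tolower(trimws(name))
  n <- gsub("[ .-]+", "_", n)
  n <- sub("_lt$", "_left", n)
  n <- sub("_rt$", "_right", n)
  n <- sub("_l$", "_left", n)
  n <- sub("_r$", "_right", n)
  syn <- oar_synonyms()
  if (n %in% names(syn)) n <- unname(syn[n])
  if (strict) {
    reg <- build_registry()
    if (!n %in% reg$name) {
      near <- utils::head(agrep(n, reg$name, max.distance = 0.3,
                                value = TRUE), 3)
      stop("unknown OAR name '", name, "'",
           if (length(near)) paste0("; did you mean: ",
                                    paste(near, collapse = ", "), "?")
           else "")
    }
  }
  n
}

#' @rdname build_registry
#' @param name an OAR name (any supported spelling).
#' @param registry a registry from [build_registry()].
#' @export
stratum_of <- function(name, registry = build_registry()) {
  cn <- canonical_name(name)
  registry$stratum[registry$name == cn]
}

#' @rdname build_registry
#' @param stratum one of `"anchor"`, `"mid-level"`, `"small_hard"`, or
#'   NULL for all names in registry order.
#' @export
oar_names <- function(registry = build_registry(), stratum = NULL) {
  if (is.null(stratum)) return(registry$name)
  stratum <- match.arg(stratum, STRATA)
  registry$name[registry$stratum == stratum]
}

n_classes <- function(registry, stratum)
  sum(registry$stratum == stratum)

#' Estimate per-class maximum extents from training labels
#'
#' The zoom-in branch crops a volume of interest sized at three times
#' the maximum spatial extent of the OAR class.  The extents are
#' measured from training labels: for each registry entry, the
#' per-axis physical bounding-box size (mm) of its mask, maximized
#' over the cases in which it appears.
#'
#' @param train_set a [training_set()].
#' @param registry a registry from [build_registry()].
#' @return the registry with `extent_*_mm` columns filled for every
#'   entry present in the training set.
#' @export
estimate_extents <- function(train_set, registry = build_registry()) {
  for (case in train_set$cases) {
    ss <- case$labels
    for (nm in names(ss$masks)) {
      i <- match(nm, registry$name)
      if (is.na(i)) next
      m <- ss$masks[[nm]]
      w <- which(m$data != 0, arr.ind = TRUE)
      if (nrow(w) == 0) next
      ext <- (apply(w, 2, max) - apply(w, 2, min) + 1) * ss$spacing
      old <- c(registry$extent_z_mm[i], registry$extent_y_mm[i],
               registry$extent_x_mm[i])
      ext <- pmax(ext, old, na.rm = TRUE)
      registry$extent_z_mm[i] <- ext[1]
      registry$extent_y_mm[i] <- ext[2]
      registry$extent_x_mm[i] <- ext[3]
    }
  }
  registry
}

#' Serialize a registry to / from JSON
#'
#' @param registry a registry from [build_registry()].
#' @param path file path.
#' @return `registry_from_json()` returns an `"oar_registry"`.
#' @export
registry_to_json <- function(registry, path) {
  jsonlite::write_json(as.data.frame(registry), path, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname registry_to_json
#' @export
registry_from_json <- function(path) {
  reg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (col in c("extent_z_mm", "extent_y_mm", "extent_x_mm"))
    reg[[col]] <- as.numeric(reg[[col]])
  class(reg) <- c("oar_registry", "data.frame")
  reg
}

#' A training set of (volume, labels) cases
#'
#' @param cases list of `list(image = volume3d, labels = structure_set)`
#'   pairs; every label name must be a registry member.
#' @param registry a registry from [build_registry()].
#' @return an object of class `"training_set"` with elements `cases`, `n`.
#' @export
training_set <- function(cases, registry = build_registry()) {
  if (length(cases) < 1) stop("a training set needs at least one case")
  for (i in seq_along(cases)) {
    case <- cases[[i]]
    if (!inherits(case$image, "volume3d") ||
        !inherits(case$labels, "structure_set"))
      stop("case ", i, " must be list(image = volume3d, labels = structure_set)")
    bad <- setdiff(names(case$labels$masks), registry$name)
    if (length(bad))
      stop("case ", i, " has non-registry OAR names: ",
           paste(bad, collapse = ", "))
  }
  structure(list(cases = cases, n = length(cases)), class = "training_set")
}
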