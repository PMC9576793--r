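# Independent brute-force oracles used to validate the package's
# distance-transform-based metrics, plus small fixture builders.

# surface voxels by direct neighbourhood inspection (R, no package code)
oracle_surface <- function(m) {
  d <- dim(m)
  s <- array(FALSE, d)
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1])) {
    if (m[z, y, x] == 0) next
    if (z == 1 || z == d[1] || y == 1 || y == d[2] || x == 1 || x == d[3]) {
      s[z, y, x] <- TRUE
      next
    }
    if (m[z - 1, y, x] == 0 || m[z + 1, y, x] == 0 ||
        m[z, y - 1, x] == 0 || m[z, y + 1, x] == 0 ||
        m[z, y, x - 1] == 0 || m[z, y, x + 1] == 0)
      s[z, y, x] <- TRUE
  }
  s
}

# all pairwise surface distances (mm), exhaustively
oracle_surface_metrics <- function(a, b, spacing) {
  sa <- which(oracle_surface(a), arr.ind = TRUE)
  sb <- which(oracle_surface(b), arr.ind = TRUE)
  pa <- sweep(sa - 1, 2, spacing, `*`)
  pb <- sweep(sb - 1, 2, spacing, `*`)
  d2 <- outer(pa[, 1], pb[, 1], `-`)^2 +
    outer(pa[, 2], pb[, 2], `-`)^2 +
    outer(pa[, 3], pb[, 3], `-`)^2
  dm <- sqrt(d2)
  dab <- apply(dm, 1, min)  # each A-surface voxel -> nearest B surface
  dba <- apply(dm, 2, min)
  list(
    hd = max(max(dab), max(dba)),
    hd95 = max(quantile(dab, 0.95, names = FALSE),
               quantile(dba, 0.95, names = FALSE)),
    asd = (mean(dab) + mean(dba)) / 2)
}

oracle_dsc <- function(a, b) {
  na <- sum(a != 0); nb <- sum(b != 0)
  if (na + nb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (na + nb)
}

# random blob-ish mask: union of a few random boxes/spheres, nonempty
random_mask_array <- function(dim3, p = 0.15) {
  m <- array(as.integer(runif(prod(dim3)) < p), dim3)
  if (sum(m) == 0) m[ceiling(dim3[1] / 2), ceiling(dim3[2] / 2),
                     ceiling(dim3[3] / 2)] <- 1L
  m
}

# solid sphere mask of radius r_mm on an isotropic grid
sphere_mask <- function(dim3, spacing, center_vox, r_mm) {
  cz <- (seq_len(dim3[1]) - 1 - center_vox[1]) * spacing[1]
  cy <- (seq_len(dim3[2]) - 1 - center_vox[2]) * spacing[2]
  cx <- (seq_len(dim3[3]) - 1 - center_vox[3]) * spacing[3]
  q <- outer(outer(cz^2, cy^2, `+`), cx^2, `+`)
  mask3d(array(as.integer(q <= r_mm^2), dim3), spacing)
}
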