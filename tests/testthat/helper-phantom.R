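# Shared fixtures and independent oracles, all built in code.

# Compact phantom grid (64x64x96 voxels at 3 mm -> 192x192x288 mm extent)
# used for seeded multi-phantom properties; uptake parameters stay at the
# generator defaults unless a test overrides them explicitly.
compact_spec <- function(seed, lesions = list(), ...) {
  phantom_spec(shape = c(64, 64, 96), spacing = c(3, 3, 3),
               lesions = lesions, seed = seed, ...)
}

# Standard lesion pair on the compact grid: one lesion inside the third
# vertebra, one hot soft-tissue node touching the fifth vertebra so that
# its blurred skirt spills into bone.
compact_lesion_inside <- function(peak = 12)
  phantom_lesion(c(96, 120, 151), radius_mm = 6, peak_suv = peak,
                 inside_bone = TRUE)
compact_lesion_node <- function(peak = 25)
  phantom_lesion(c(96, 140, 205), radius_mm = 6, peak_suv = peak,
                 inside_bone = FALSE)

# mm coordinates of voxel centres for a mask/volume on an origin-0 grid
coords_mm <- function(shape, spacing = c(3, 3, 3))
  lapply(1:3, function(a) (seq_len(shape[a]) - 1) * spacing[a])

# distances (mm) of the TRUE voxels of a mask to a physical point
mask_dist_to_point <- function(voxels, spacing, point) {
  idx <- which(voxels, arr.ind = TRUE)
  if (nrow(idx) == 0) return(numeric(0))
  co <- coords_mm(dim(voxels), spacing)
  pos <- cbind(co[[1]][idx[, 1]], co[[2]][idx[, 2]], co[[3]][idx[, 3]])
  sqrt(rowSums((pos - matrix(point, nrow(pos), 3, byrow = TRUE))^2))
}

# Brute-force Euclidean distance oracle: for every TRUE voxel of `inside`,
# the exact min distance (mm) to any FALSE voxel, by chunked all-pairs
# distance. Independent of the package's distance transform.
brute_force_boundary_dist <- function(inside, spacing) {
  co <- coords_mm(dim(inside), spacing)
  iin <- which(inside, arr.ind = TRUE)
  iout <- which(!inside, arr.ind = TRUE)
  pin <- cbind(co[[1]][iin[, 1]], co[[2]][iin[, 2]], co[[3]][iin[, 3]])
  pout <- cbind(co[[1]][iout[, 1]], co[[2]][iout[, 2]], co[[3]][iout[, 3]])
  out <- numeric(nrow(pin))
  chunk <- 500L
  for (s in seq(1, nrow(pin), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(pin))
    d2 <- outer(rowSums(pin[s:e, , drop = FALSE]^2), rowSums(pout^2), `+`) -
      2 * pin[s:e, , drop = FALSE] %*% t(pout)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

# one-voxel-shell volume (mL) around a region: voxels within one voxel
# spacing of the region boundary, on either side
shell_volume_ml <- function(voxels, spacing) {
  din <- array(sqrt(tsau:::.edt3d_sq(!voxels, dim(voxels), spacing)),
               dim(voxels))
  dout <- array(sqrt(tsau:::.edt3d_sq(voxels, dim(voxels), spacing)),
                dim(voxels))
  shell <- (voxels & din <= max(spacing) + 1e-9) |
           (!voxels & dout <= max(spacing) + 1e-9)
  sum(shell) * prod(spacing) / 1000
}

# tiny SUV volume + single-bone label fixture on an isotropic grid
tiny_bone_fixture <- function(n = 12, spacing = c(1, 1, 1),
                              bone_radius = 4) {
  co <- coords_mm(c(n, n, n), spacing)
  ctr <- rep((n - 1) * spacing[1] / 2, 3)
  d2 <- outer(outer((co[[1]] - ctr[1])^2, (co[[2]] - ctr[2])^2, `+`),
              (co[[3]] - ctr[3])^2, `+`)
  labels <- array(0L, c(n, n, n))
  labels[d2 <= bone_radius^2] <- 1L
  bone_label_volume(labels, data.frame(label = 1, name = "vertebra"),
                    spacing = spacing)
}
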