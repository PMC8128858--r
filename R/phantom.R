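#' Phantom specification
#'
#' Parameters of the synthetic staging phantom: a PET-like grid (3 mm
#' isotropic by default) holding a labelled geometric skeleton (a
#' vertebral cylinder stack with sacrum and coccyx, hip-bone spheres at a
#' configurable distance from the spine, femoral and humeral tubes, rib
#' arcs, sternum, scapulae, clavicles), a liver ellipsoid, and the uptake
#' regimes the detector assumes: marrow SUV ~ Normal(`mu_marrow`,
#' `sd_marrow`) clipped at 0, a cortical shell at a fixed level, liver SUV
#' ~ Normal(`mu_liver`, `sd_liver`), soft-tissue background noise, focal
#' lesions stamped as spherical plateaus, and a Gaussian point-spread
#' blur applied to the whole volume (which is what creates realistic
#' spill-over from hot nodes adjacent to bone).
#'
#' Default uptake levels are typical of an untreated staging examination:
#' marrow 1.5 +/- 0.2, liver 2.0 +/- 0.2 (diffuse index 0.75, low),
#' soft tissue 0.7, scanner PSF 6 mm FWHM.
#'
#' @param shape Grid dimensions in voxels, default `c(96, 96, 192)`.
#' @param spacing Voxel spacing in mm, default 3 mm isotropic.
#' @param mu_marrow,sd_marrow Marrow SUV mean and SD.
#' @param cortical_suv Cortical-shell SUV level.
#' @param cortical_thickness_mm Depth of the cortical shell (mm) inside
#'   each bone before marrow-type uptake begins.
#' @param soft_tissue_suv,noise_sd Background level and noise SD.
#' @param mu_liver,sd_liver Liver SUV mean and SD.
#' @param lesions List of [phantom_lesion()] entries.
#' @param psf_fwhm_mm Gaussian PSF full width at half maximum (mm).
#' @param hip_offset_mm Lateral distance of each hip-bone centre from the
#'   spine axis; the default leaves each hip straddling the 50 mm
#'   sacroiliac shell.
#' @param seed Integer seed; fixes the generated volume bit-for-bit.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96, 96, 192), spacing = c(3, 3, 3),
                         mu_marrow = 1.5, sd_marrow = 0.2,
                         cortical_suv = 1.0, cortical_thickness_mm = 2,
                         soft_tissue_suv = 0.7, noise_sd = 0.1,
                         mu_liver = 2.0, sd_liver = 0.2,
                         lesions = list(), psf_fwhm_mm = 6,
                         hip_offset_mm = 55, seed = 1) {
  stopifnot(length(shape) == 3, all(shape >= 16),
            length(spacing) == 3, all(spacing > 0))
  pars <- c(mu_marrow, sd_marrow, cortical_suv, cortical_thickness_mm,
            soft_tissue_suv, noise_sd, mu_liver, sd_liver, psf_fwhm_mm,
            hip_offset_mm)
  if (any(pars < 0)) stop("uptake and geometry parameters must be >= 0")
  lesions <- lapply(lesions, function(l)
    if (inherits(l, "phantom_lesion")) l else do.call(phantom_lesion, l))
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 mu_marrow = mu_marrow, sd_marrow = sd_marrow,
                 cortical_suv = cortical_suv,
                 cortical_thickness_mm = cortical_thickness_mm,
                 soft_tissue_suv = soft_tissue_suv, noise_sd = noise_sd,
                 mu_liver = mu_liver, sd_liver = sd_liver,
                 lesions = lesions, psf_fwhm_mm = psf_fwhm_mm,
                 hip_offset_mm = hip_offset_mm, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Describe a focal lesion for the phantom
#'
#' @param center Physical centre in mm (length 3).
#' @param radius_mm Sphere radius in mm, > 0.
#' @param peak_suv Plateau SUV of the lesion before PSF blur.
#' @param inside_bone Whether the centre lies inside a bone (an in-bone
#'   lesion the detector should keep) or outside (a hot node whose
#'   blurred skirt spills into adjacent bone and should be removed).
#' @return An object of class `phantom_lesion`.
#' @export
phantom_lesion <- function(center, radius_mm, peak_suv, inside_bone) {
  if (radius_mm <= 0) stop("lesion radius must be > 0")
  if (peak_suv < 0) stop("peak SUV must be >= 0")
  structure(list(center = as.numeric(center), radius_mm = radius_mm,
                 peak_suv = peak_suv, inside_bone = isTRUE(inside_bone)),
            class = "phantom_lesion")
}

# run code with a local RNG stream, leaving the caller's stream untouched
with_seed <- function(seed, fn) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  fn()
}

# separable Gaussian blur with row-normalized (edge-renormalized) kernels
blur_gaussian <- function(values, spacing, fwhm_mm) {
  if (fwhm_mm <= 0) return(values)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  d <- dim(values)
  v <- values
  for (a in 1:3) {
    n <- d[a]
    pos <- (seq_len(n) - 1) * spacing[a]
    dd <- outer(pos, pos, `-`)
    K <- exp(-dd^2 / (2 * sigma^2))
    K[abs(dd) > 4 * sigma] <- 0
    K <- K / rowSums(K)
    perm <- c(a, setdiff(1:3, a))
    p <- aperm(v, perm)
    dp <- dim(p)
    p <- array(K %*% matrix(p, n, prod(dp[-1])), dp)
    v <- aperm(p, match(1:3, perm))
  }
  v
}

# mm coordinates of voxel centres along each axis (origin at 0)
grid_coords <- function(shape, spacing)
  lapply(1:3, function(a) (seq_len(shape[a]) - 1) * spacing[a])

erode_mask <- function(voxels, spacing, margin_mm) {
  if (margin_mm <= 0 || !any(voxels)) return(voxels)
  sl <- bbox_slices(voxels)
  crop <- voxels[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]
  d2 <- .edt3d_sq(!crop, dim(crop), spacing)
  out <- array(FALSE, dim(voxels))
  out[sl[[1]], sl[[2]], sl[[3]]] <- crop & array(d2 >= margin_mm^2, dim(crop))
  out
}

# ---- geometric primitives on the coordinate grid ------------------------

mask_ellipsoid <- function(co, center, semi) {
  dx <- ((co[[1]] - center[1]) / semi[1])^2
  dy <- ((co[[2]] - center[2]) / semi[2])^2
  dz <- ((co[[3]] - center[3]) / semi[3])^2
  outer(outer(dx, dy, `+`), dz, `+`) <= 1
}

mask_sphere <- function(co, center, r)
  mask_ellipsoid(co, center, rep(r, 3))

mask_cyl_z <- function(co, cx, cy, r, z0, z1) {
  m2 <- outer((co[[1]] - cx)^2, (co[[2]] - cy)^2, `+`) <= r^2
  outer(m2, co[[3]] >= z0 & co[[3]] <= z1, `&`)
}

mask_cyl_x <- function(co, cy, cz, r, x0, x1) {
  m2 <- outer((co[[2]] - cy)^2, (co[[3]] - cz)^2, `+`) <= r^2
  inx <- co[[1]] >= x0 & co[[1]] <= x1
  aperm(outer(m2, inx, `&`), c(3, 1, 2))
}

mask_box <- function(co, lo, hi) {
  outer(outer(co[[1]] >= lo[1] & co[[1]] <= hi[1],
              co[[2]] >= lo[2] & co[[2]] <= hi[2], `&`),
        co[[3]] >= lo[3] & co[[3]] <= hi[3], `&`)
}

# tube along a sampled curve: union of spheres stamped on cropped boxes
mask_tube <- function(co, points, r, shape) {
  m <- array(FALSE, shape)
  for (k in seq_len(nrow(points))) {
    p <- points[k, ]
    xi <- which(abs(co[[1]] - p[1]) <= r)
    yi <- which(abs(co[[2]] - p[2]) <= r)
    zi <- which(abs(co[[3]] - p[3]) <= r)
    if (!length(xi) || !length(yi) || !length(zi)) next
    d2 <- outer(outer((co[[1]][xi] - p[1])^2, (co[[2]][yi] - p[2])^2, `+`),
                (co[[3]][zi] - p[3])^2, `+`)
    m[xi, yi, zi] <- m[xi, yi, zi] | (d2 <= r^2)
  }
  m
}

# ---- skeleton + liver geometry ------------------------------------------

build_phantom_anatomy <- function(shape, spacing, hip_offset_mm) {
  co <- grid_coords(shape, spacing)
  E <- shape * spacing
  labels <- array(0L, shape)
  tax <- data.frame(label = integer(), name = character())
  next_id <- 0L
  stamp <- function(mask, name) {
    id <- next_id + 1L
    if (any(labels[mask] != 0L))
      stop("overlapping labels: '", name, "' collides with an earlier structure")
    if (!any(mask)) stop("structure '", name, "' covers no voxels")
    labels[mask] <<- id
    tax <<- rbind(tax, data.frame(label = id, name = name))
    next_id <<- id
    id
  }

  sx <- E[1] / 2            # spine axis
  sy <- 0.625 * E[2]
  zs <- 0.30 * E[3]         # bottom of the vertebral stack

  n_vert <- max(3L, floor((0.88 * E[3] - zs) / 27))
  for (k in seq_len(n_vert)) {
    z0 <- zs + (k - 1) * 27
    stamp(mask_cyl_z(co, sx, sy, 14, z0, z0 + 21), "vertebra")
  }
  stamp(mask_sphere(co, c(sx, sy, zs - 25), 20), "sacrum")
  stamp(mask_sphere(co, c(sx, sy, zs - 54), 7), "coccyx")
  for (s in c(-1, 1)) {
    hx <- sx + s * hip_offset_mm
    stamp(mask_sphere(co, c(hx, sy, zs - 25), 22), "hip_bone")
    stamp(mask_cyl_z(co, hx, sy, 10, 0.05 * E[3], zs - 53), "femur")
  }
  for (s in c(-1, 1)) {
    stamp(mask_cyl_z(co, sx + s * 0.33 * E[1], 0.55 * E[2], 9,
                     0.70 * E[3], 0.92 * E[3]), "humerus")
    stamp(mask_box(co,
                   c(sx + min(s * 0.18, s * 0.26) * E[1], 0.66 * E[2], 0.72 * E[3]),
                   c(sx + max(s * 0.18, s * 0.26) * E[1], 0.72 * E[2], 0.80 * E[3])),
          "scapula")
    stamp(mask_cyl_x(co, 0.55 * E[2], 0.90 * E[3], 4,
                     sx + min(s * 0.08, s * 0.27) * E[1],
                     sx + max(s * 0.08, s * 0.27) * E[1]), "clavicle")
  }
  rib_cy <- 0.52 * E[2]
  rx <- 0.23 * E[1]; ry <- 0.16 * E[2]
  for (k in 0:5) {
    zk <- (0.70 + 0.03 * k) * E[3]
    t <- seq(pi + 0.35, 2 * pi - 0.35, length.out = 48)
    pts <- cbind(sx + rx * cos(t), rib_cy + ry * sin(t), zk)
    stamp(mask_tube(co, pts, 4, shape), "rib")
  }
  stamp(mask_box(co, c(sx - 9, rib_cy - ry - 16, 0.70 * E[3]),
                 c(sx + 9, rib_cy - ry - 8, 0.85 * E[3])), "sternum")
  stamp(mask_ellipsoid(co, c(0.36 * E[1], 0.40 * E[2], 0.57 * E[3]),
                       c(0.17 * E[1], 0.13 * E[2], 0.073 * E[3])), "liver")
  list(labels = labels, taxonomy = tax, coords = co, extent = E)
}

#' Generate a synthetic staging phantom with ground truth
#'
#' Builds the labelled anatomy, draws the uptake regimes, stamps focal
#' lesions as spherical plateaus, convolves the whole volume with the
#' Gaussian PSF, and records a truth manifest: per-lesion true and
#' post-blur suprathreshold volumes, the analytic marrow threshold
#' mu + 2 sigma, per-group truth TSAU, the expected focal verdict under
#' the default cut-offs, and the true diffuse index mu_marrow / mu_liver.
#' Deterministic for a fixed `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `bmu_phantom`: list with `suv`
#'   ([suv_volume()]), `labels` ([bone_label_volume()]), `truth`
#'   (manifest list) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  anat <- build_phantom_anatomy(spec$shape, spec$spacing,
                                spec$hip_offset_mm)
  labels <- anat$labels
  co <- anat$coords
  n <- prod(spec$shape)
  voxvol <- prod(spec$spacing) / 1000
  skeletal_ids <- anat$taxonomy$label[anat$taxonomy$name != "liver"]
  bone <- array(labels %in% skeletal_ids, spec$shape)
  liver_id <- anat$taxonomy$label[anat$taxonomy$name == "liver"]
  liver <- labels == liver_id

  vol <- with_seed(spec$seed, function() {
    v <- spec$soft_tissue_suv + rnorm(n, sd = spec$noise_sd)
    v <- array(v, spec$shape)
    v[bone] <- spec$cortical_suv + rnorm(sum(bone), sd = spec$noise_sd)
    marrow <- array(FALSE, spec$shape)
    for (id in skeletal_ids)
      marrow <- marrow | erode_mask(labels == id, spec$spacing,
                                    spec$cortical_thickness_mm)
    v[marrow] <- rnorm(sum(marrow), spec$mu_marrow, spec$sd_marrow)
    v[liver] <- rnorm(sum(liver), spec$mu_liver, spec$sd_liver)
    pmax(v, 0)
  })

  # stamp lesions as plateaus, then blur
  lesion_voxels <- vector("list", length(spec$lesions))
  for (i in seq_along(spec$lesions)) {
    l <- spec$lesions[[i]]
    if (any(l$center < 0) || any(l$center > anat$extent))
      stop("lesion ", i, " centre outside the grid")
    sph <- mask_sphere(co, l$center, l$radius_mm)
    if (!any(sph)) stop("lesion ", i, " covers no voxels")
    ci <- vapply(1:3, function(a) which.min(abs(co[[a]] - l$center[a])), 1L)
    center_in_bone <- bone[ci[1], ci[2], ci[3]]
    if (center_in_bone != l$inside_bone)
      stop("lesion ", i, ": inside_bone = ", l$inside_bone,
           " but its centre is ", if (center_in_bone) "inside" else "outside",
           " the skeleton")
    vol[sph] <- pmax(vol[sph], l$peak_suv)
    lesion_voxels[[i]] <- sph
  }
  vol <- pmax(blur_gaussian(vol, spec$spacing, spec$psf_fwhm_mm), 0)

  suv <- suv_volume(vol, spec$spacing)
  lab <- bone_label_volume(labels, anat$taxonomy, spec$spacing)

  # truth manifest, recomputed from the post-blur volume
  thr <- spec$mu_marrow + 2 * spec$sd_marrow
  nbhd_mm <- function(l) l$radius_mm +
    max(2 * spec$psf_fwhm_mm, 2 * max(spec$spacing))
  spine_ids <- anat$taxonomy$label[anat$taxonomy$name %in% spine_core_classes()]
  group_tsau <- c(spine = 0, other = 0)
  lesion_rows <- lapply(seq_along(spec$lesions), function(i) {
    l <- spec$lesions[[i]]
    near <- mask_sphere(co, l$center, nbhd_mm(l))
    supra <- near & (vol > thr)
    supra_bone <- supra & bone
    ci <- vapply(1:3, function(a) which.min(abs(co[[a]] - l$center[a])), 1L)
    grp <- if (!l$inside_bone) NA_character_
           else if (labels[ci[1], ci[2], ci[3]] %in% spine_ids) "spine"
           else "other"
    tsau_i <- if (l$inside_bone)
      sum((vol[supra_bone] - thr)^2) * voxvol else 0
    if (l$inside_bone && !is.na(grp))
      group_tsau[grp] <<- group_tsau[grp] + tsau_i
    data.frame(lesion = i,
               cx = l$center[1], cy = l$center[2], cz = l$center[3],
               radius_mm = l$radius_mm, peak_suv = l$peak_suv,
               inside_bone = l$inside_bone, group = grp,
               true_volume_ml = sum(lesion_voxels[[i]]) * voxvol,
               supra_volume_ml = sum(supra) * voxvol,
               supra_bone_volume_ml = sum(supra_bone) * voxvol,
               tsau_truth = tsau_i)
  })
  lesions_df <- if (length(lesion_rows)) do.call(rbind, lesion_rows)
                else data.frame()
  cfg <- focal_config()
  truth <- list(
    thr = thr,
    lesions = lesions_df,
    group_tsau = group_tsau,
    expected_focal = group_tsau[["spine"]] > cfg$cutoff_spine ||
                     group_tsau[["other"]] > cfg$cutoff_other,
    true_diffuse_index = spec$mu_marrow / spec$mu_liver
  )
  structure(list(suv = suv, labels = lab, truth = truth, spec = spec),
            class = "bmu_phantom")
}

#' Write a phantom to disk
#'
#' Writes `suv.nii.gz`, `labels.nii.gz`, `taxonomy.csv` and `truth.json`
#' into a directory.
#'
#' @param phantom A [generate_phantom()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_suv_volume(phantom$suv, file.path(dir, "suv.nii.gz"))
  write_label_volume(phantom$labels, file.path(dir, "labels.nii.gz"),
                     file.path(dir, "taxonomy.csv"))
  jsonlite::write_json(phantom$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Generate a synthetic reader-study rating fixture
#'
#' Draws a latent per-case truth (focal involvement and high diffuse
#' uptake) and simulates observers who independently flip each dimension
#' of the truth with a given probability, then encodes the four-category
#' classification. Default prevalences match an untreated staging
#' cohort: 14/48 focal-positive and 32/48 high-diffuse.
#'
#' @param n_cases,n_observers Dimensions of the rating matrix.
#' @param flip_prob Per-observer probability of flipping each latent
#'   dimension; scalar or length `n_observers`, all in `[0, 1]`.
#' @param p_focal,p_diffuse Latent prevalences in `[0, 1]`.
#' @param seed Integer seed; fixes the fixture.
#' @return List with `ratings` (a [rating_matrix()]) and `truth`
#'   (data frame of the latent `focal` and `diffuse` booleans).
#' @export
make_rating_fixture <- function(n_cases = 48, n_observers = 10,
                                flip_prob = 0.1, p_focal = 14 / 48,
                                p_diffuse = 32 / 48, seed = 1) {
  stopifnot(n_cases >= 1, n_observers >= 1)
  flip_prob <- rep_len(flip_prob, n_observers)
  if (any(flip_prob < 0 | flip_prob > 1) ||
      p_focal < 0 || p_focal > 1 || p_diffuse < 0 || p_diffuse > 1)
    stop("probabilities must be in [0, 1]")
  with_seed(seed, function() {
    focal <- runif(n_cases) < p_focal
    diffuse <- runif(n_cases) < p_diffuse
    m <- matrix(0L, n_cases, n_observers)
    for (o in seq_len(n_observers)) {
      f <- xor(focal, runif(n_cases) < flip_prob[o])
      d <- xor(diffuse, runif(n_cases) < flip_prob[o])
      m[, o] <- 1L + as.integer(f) + 2L * as.integer(d)
    }
    list(ratings = rating_matrix(m),
         truth = data.frame(focal = focal, diffuse = diffuse))
  })
}
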