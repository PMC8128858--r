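#' Marrow extraction configuration
#'
#' Per-class erosion margins defining the bone marrow: 7 mm for the long
#' bones (humeri, femora), 5 mm for the vertebrae and hip bones, 3 mm for
#' all remaining bones; plus the 50 mm radius within which hip-bone voxels
#' are attributed to the spine group (covering the sacroiliac joints).
#'
#' @param margins Named numeric vector of erosion margins in mm, one entry
#'   per skeletal class. Defaults to the published 7/5/3 mm scheme.
#' @param sacroiliac_radius_mm Distance (mm) from the vertebrae/sacrum/
#'   coccyx within which hip-bone voxels join the spine group.
#' @return An object of class `marrow_config`.
#' @export
marrow_config <- function(margins = NULL, sacroiliac_radius_mm = 50) {
  default <- c(humerus = 7, femur = 7,
               vertebra = 5, hip_bone = 5,
               sacrum = 3, coccyx = 3, scapula = 3, clavicle = 3,
               rib = 3, sternum = 3)
  if (!is.null(margins)) {
    if (is.null(names(margins)) || any(!names(margins) %in% names(default)))
      stop("margins must be named by skeletal class: ",
           paste(names(default), collapse = ", "))
    default[names(margins)] <- margins
  }
  if (any(default < 0)) stop("margins must be >= 0")
  if (sacroiliac_radius_mm < 0) stop("sacroiliac_radius_mm must be >= 0")
  structure(list(margins = default,
                 sacroiliac_radius_mm = sacroiliac_radius_mm),
            class = "marrow_config")
}

# mm distance from every voxel to the nearest TRUE voxel of `feature`
distance_to_mm <- function(feature, spacing) {
  d <- .edt3d_sq(as.logical(feature), dim(feature), as.numeric(spacing))
  array(sqrt(d), dim(feature))
}

# bounding box of a logical array, padded by `pad` voxels, clamped to grid
bbox_slices <- function(mask, pad = 1L) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  lapply(1:3, function(a) {
    max(1L, min(idx[, a]) - pad):min(d[a], max(idx[, a]) + pad)
  })
}

#' Extract the bone-marrow mask by per-bone erosion
#'
#' Each individually labelled bone is eroded by its class margin: a voxel
#' belongs to the marrow when its Euclidean distance (mm, anisotropy-aware)
#' to the bone's boundary is at least the margin. Boundaries between
#' touching bones count as edges, so marrow never bleeds across joints.
#' Bones whose inradius is below the margin simply contribute nothing.
#'
#' @param labels A [bone_label_volume()].
#' @param config A [marrow_config()].
#' @return A [binary_mask()]; always a subset of the skeletal voxels.
#' @export
extract_marrow <- function(labels, config = marrow_config()) {
  stopifnot(inherits(labels, "bone_label_volume"),
            inherits(config, "marrow_config"))
  lab <- labels$labels
  out <- array(FALSE, dim(lab))
  skel <- labels$taxonomy[labels$taxonomy$name != "liver", , drop = FALSE]
  present <- setdiff(sort(unique(as.vector(lab))), 0L)
  for (id in intersect(skel$label, present)) {
    cls <- skel$name[skel$label == id]
    if (!cls %in% names(config$margins))
      stop("no erosion margin configured for class '", cls, "'")
    margin <- config$margins[[cls]]
    bone <- array(lab == id, dim(lab))
    out <- out | erode_mask(bone, labels$spacing, margin)
  }
  binary_mask(out, labels$spacing)
}

#' Partition the skeleton into spine and other-bones groups
#'
#' The spine group is the vertebrae, sacrum and coccyx plus any hip-bone
#' voxel within `sacroiliac_radius_mm` (default 50 mm) of those structures,
#' which captures the sacroiliac joints. Every remaining skeletal voxel
#' (humeri, scapulae, clavicles, ribs, sternum, femora and the rest of the
#' hip bones) forms the other-bones group. The marrow mask is intersected
#' with each group.
#'
#' @param labels A [bone_label_volume()].
#' @param marrow A [binary_mask()] from [extract_marrow()].
#' @param config A [marrow_config()].
#' @return An object of class `group_masks`: list with binary masks
#'   `spine`, `other`, `marrow_spine`, `marrow_other`.
#' @export
assign_groups <- function(labels, marrow, config = marrow_config()) {
  stopifnot(inherits(labels, "bone_label_volume"),
            inherits(marrow, "binary_mask"))
  core <- class_mask(labels, spine_core_classes())
  hip <- class_mask(labels, "hip_bone")
  skel <- class_mask(labels, skeletal_classes())
  if (!any(core))
    stop("empty spine group: no vertebra/sacrum/coccyx voxels labelled")
  spine <- core
  if (any(hip)) {
    d <- distance_to_mm(core, labels$spacing)
    spine <- spine | (hip & d <= config$sacroiliac_radius_mm)
  }
  other <- skel & !spine
  structure(list(
    spine = binary_mask(spine, labels$spacing),
    other = binary_mask(other, labels$spacing),
    marrow_spine = binary_mask(spine & marrow$voxels, labels$spacing),
    marrow_other = binary_mask(other & marrow$voxels, labels$spacing)
  ), class = "group_masks")
}
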