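#' Diffuse bone-marrow uptake index from masks
#'
#' The diffuse SUV index is the median SUV over the vertebral marrow
#' divided by the median SUV over the liver. An index strictly greater
#' than 1.0 classifies the case as high diffuse bone-marrow uptake; an
#' index of exactly 1.0 is low. The median is used rather than the
#' maximum to keep the index robust to focal lesion uptake.
#'
#' @param suv An [suv_volume()].
#' @param spine_marrow Non-empty [binary_mask()] of the vertebral marrow.
#' @param liver Non-empty [binary_mask()] of the liver reference region.
#' @return An object of class `diffuse_result`: list with
#'   `spine_marrow_median`, `liver_median`, `index` and logical `high`.
#' @export
compute_diffuse_index <- function(suv, spine_marrow, liver) {
  check_same_grid(suv, spine_marrow)
  check_same_grid(suv, liver)
  if (!any(spine_marrow$voxels)) stop("empty spine marrow mask")
  if (!any(liver$voxels)) stop("empty liver mask")
  sm <- median(suv$values[spine_marrow$voxels])
  lm <- median(suv$values[liver$voxels])
  diffuse_result(sm, lm)
}

diffuse_result <- function(spine_marrow_median, liver_median) {
  idx <- spine_marrow_median / liver_median
  structure(list(spine_marrow_median = spine_marrow_median,
                 liver_median = liver_median,
                 index = idx, high = idx > 1.0),
            class = "diffuse_result")
}

#' @export
print.diffuse_result <- function(x, ...) {
  cat(sprintf(
    "Diffuse BMU: index %.3f (spine marrow median %.3f / liver median %.3f) -> %s\n",
    x$index, x$spine_marrow_median, x$liver_median,
    if (x$high) "HIGH" else "low"))
  invisible(x)
}

#' Diffuse index for a full staging case
#'
#' Automated path: the numerator median is taken over the marrow of the
#' vertebrae, sacrum and coccyx (hip-bone portions of the spine group are
#' excluded -- the index is a vertebral marrow statistic); the denominator
#' is the median over the liver label after an optional edge erosion.
#'
#' @param suv An [suv_volume()].
#' @param labels A [bone_label_volume()] including a liver label.
#' @param marrow Optional precomputed [extract_marrow()] mask.
#' @param marrow_cfg A [marrow_config()].
#' @param liver_margin_mm Erosion applied to the liver before taking its
#'   median, to exclude edge voxels; default 5 mm.
#' @return A `diffuse_result`, see [compute_diffuse_index()].
#' @export
diffuse_index <- function(suv, labels, marrow = NULL,
                          marrow_cfg = marrow_config(),
                          liver_margin_mm = 5) {
  check_same_grid(suv, labels)
  if (is.null(marrow)) marrow <- extract_marrow(labels, marrow_cfg)
  vert <- class_mask(labels, spine_core_classes())
  liver <- class_mask(labels, "liver")
  if (!any(liver)) stop("empty liver mask: no liver label present")
  if (liver_margin_mm > 0) {
    eroded <- erode_mask(liver, labels$spacing, liver_margin_mm)
    # a liver thinner than the margin falls back to the full label
    if (any(eroded)) liver <- eroded
  }
  compute_diffuse_index(suv,
                        binary_mask(vert & marrow$voxels, suv$spacing),
                        binary_mask(liver, suv$spacing))
}

#' Region-of-interest specification
#'
#' A simple geometric ROI used to emulate the manual quality-control
#' procedure (small ROIs in the L3/L4 marrow and the upper right liver).
#'
#' @param center Physical centre in mm (length 3).
#' @param shape `"sphere"` or `"box"`.
#' @param extent_mm Diameter of the sphere, or edge length(s) of the box
#'   (scalar or length 3), in mm.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(center, shape = c("sphere", "box"), extent_mm) {
  shape <- match.arg(shape)
  center <- as.numeric(center)
  if (length(center) != 3L || anyNA(center)) stop("center must be 3 mm coordinates")
  extent_mm <- as.numeric(extent_mm)
  if (any(extent_mm <= 0)) stop("extent_mm must be > 0")
  if (shape == "box" && length(extent_mm) == 1L) extent_mm <- rep(extent_mm, 3)
  structure(list(center = center, shape = shape, extent_mm = extent_mm),
            class = "roi_spec")
}

roi_mask <- function(suv, roi) {
  d <- dim(suv$values)
  coords <- lapply(1:3, function(a)
    suv$origin[a] + (seq_len(d[a]) - 1) * suv$spacing[a])
  if (roi$shape == "sphere") {
    r2 <- (roi$extent_mm[1] / 2)^2
    dx2 <- (coords[[1]] - roi$center[1])^2
    dy2 <- (coords[[2]] - roi$center[2])^2
    dz2 <- (coords[[3]] - roi$center[3])^2
    m <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r2
  } else {
    h <- roi$extent_mm / 2
    inx <- abs(coords[[1]] - roi$center[1]) <= h[1]
    iny <- abs(coords[[2]] - roi$center[2]) <= h[2]
    inz <- abs(coords[[3]] - roi$center[3]) <= h[3]
    m <- outer(outer(inx, iny, `&`), inz, `&`)
  }
  if (!any(m)) stop("ROI does not intersect the volume")
  binary_mask(array(m, d), suv$spacing)
}

#' Diffuse index from manually placed ROIs
#'
#' Same computation as [compute_diffuse_index()], but over small caller-
#' supplied ROIs instead of the automated whole-structure masks. This
#' emulates the manual quality-control procedure, where an operator
#' places a 1-3 cm3 ROI in the L3/L4 marrow and a small ROI in the upper
#' homogeneous right part of the liver.
#'
#' @param suv An [suv_volume()].
#' @param marrow_roi,liver_roi [roi_spec()] objects.
#' @return A `diffuse_result`.
#' @export
manual_roi_index <- function(suv, marrow_roi, liver_roi) {
  compute_diffuse_index(suv, roi_mask(suv, marrow_roi),
                        roi_mask(suv, liver_roi))
}

#' Bland-Altman limits of agreement
#'
#' Method-comparison statistics for paired index measurements: mean
#' difference, SD of the differences, and the 95% limits of agreement
#' (mean difference +/- 1.96 SD).
#'
#' @param a,b Equal-length numeric vectors of paired measurements
#'   (differences are `a - b`).
#' @return List with `mean_diff`, `sd_diff`, `loa_lower`, `loa_upper`,
#'   `n`, and the per-pair `differences` and `means`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("paired lists must have equal length")
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  m <- mean(d)
  s <- sd(d)
  list(mean_diff = m, sd_diff = s,
       loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
       n = length(d), differences = d, means = (a + b) / 2)
}
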