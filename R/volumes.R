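#' Controlled vocabulary of anatomical structure names
#'
#' Names accepted in a label taxonomy. Skeletal classes carry the erosion
#' margin that defines the bone marrow; `"liver"` is the reference organ
#' for the diffuse uptake index and is never part of the skeleton.
#'
#' @return Character vector of valid anatomical class names.
#' @export
anatomy_vocabulary <- function() {
  c("vertebra", "sacrum", "coccyx", "hip_bone", "humerus", "scapula",
    "clavicle", "rib", "sternum", "femur", "liver")
}

skeletal_classes <- function() setdiff(anatomy_vocabulary(), "liver")
spine_core_classes <- function() c("vertebra", "sacrum", "coccyx")

#' Construct an SUV volume
#'
#' A 3D scalar field of standardized uptake values (SUV, dimensionless)
#' on a regular grid with physical voxel spacing in mm.
#'
#' @param values 3D numeric array of SUV; all finite and >= 0.
#' @param spacing Numeric length-3, voxel edge lengths in mm (x, y, z).
#' @param origin Numeric length-3, physical offset of voxel (1,1,1) in mm.
#' @return An object of class `suv_volume` with elements `values`,
#'   `spacing` and `origin`.
#' @examples
#' v <- suv_volume(array(1, c(4, 4, 4)), spacing = c(3, 3, 3))
#' voxel_volume_ml(v)  # 0.027
#' @export
suv_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("expected 3D volume, got ", length(dim(values)), " dimension(s)")
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values)))
    stop("SUV values must all be finite")
  if (any(values < 0))
    stop("SUV values must be >= 0")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive voxel edge lengths in mm")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite mm coordinates")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "suv_volume")
}

#' Voxel volume in millilitres
#'
#' @param x An object with mm voxel `spacing` (an [suv_volume()],
#'   [bone_label_volume()] or [binary_mask()]).
#' @return Voxel volume in mL: prod(spacing) / 1000.
#' @export
voxel_volume_ml <- function(x) prod(x$spacing) / 1000

#' Construct a labelled anatomy volume
#'
#' Integer labels identifying individual bones and the liver on the same
#' grid as a paired SUV volume. Label 0 is background; every nonzero label
#' present in the array must be named in the taxonomy, and each taxonomy
#' name must come from [anatomy_vocabulary()].
#'
#' @param labels 3D integer array.
#' @param taxonomy Named integer vector or two-column data.frame
#'   (`label`, `name`) mapping label integers to anatomical class names.
#' @param spacing,origin Grid geometry, as in [suv_volume()].
#' @return An object of class `bone_label_volume`.
#' @export
bone_label_volume <- function(labels, taxonomy, spacing, origin = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("expected 3D label volume")
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 0))
    stop("labels must be non-negative integers")
  tax <- as_taxonomy(taxonomy)
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  unknown <- setdiff(present, tax$label)
  if (length(unknown))
    stop("label(s) not in taxonomy: ", paste(unknown, collapse = ", "))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive voxel edge lengths in mm")
  structure(list(labels = labels, taxonomy = tax, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "bone_label_volume")
}

as_taxonomy <- function(taxonomy) {
  if (is.data.frame(taxonomy)) {
    tax <- data.frame(label = as.integer(taxonomy[[1]]),
                      name = as.character(taxonomy[[2]]),
                      stringsAsFactors = FALSE)
  } else {
    tax <- data.frame(label = as.integer(taxonomy),
                      name = names(taxonomy), stringsAsFactors = FALSE)
  }
  if (anyNA(tax$label) || is.null(tax$name) || anyNA(tax$name))
    stop("taxonomy must map integer labels to anatomical names")
  if (anyDuplicated(tax$label))
    stop("duplicated label in taxonomy")
  bad <- setdiff(unique(tax$name), anatomy_vocabulary())
  if (length(bad))
    stop("unknown anatomical name(s): ", paste(bad, collapse = ", "),
         "; valid names: ", paste(anatomy_vocabulary(), collapse = ", "))
  if (any(tax$label == 0L))
    stop("label 0 is reserved for background")
  tax
}

#' Construct a binary mask on a volume grid
#'
#' @param voxels 3D logical array.
#' @param spacing Numeric length-3 voxel spacing in mm, inherited from the
#'   parent grid.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("expected 3D mask")
  storage.mode(voxels) <- "logical"
  if (anyNA(voxels)) stop("mask must not contain NA")
  structure(list(voxels = voxels, spacing = as.numeric(spacing)),
            class = "binary_mask")
}

#' Physical volume of a binary mask in mL
#' @param mask A [binary_mask()].
#' @return Number of TRUE voxels times the voxel volume in mL.
#' @export
mask_volume_ml <- function(mask) sum(mask$voxels) * voxel_volume_ml(mask)

#' Check that two volumes share a grid
#'
#' Shape must be identical and spacing equal within a small relative
#' tolerance; no resampling is ever performed.
#'
#' @param a,b Volumes or masks carrying `spacing` and a 3D array.
#' @return Invisibly TRUE; stops with a descriptive error on mismatch.
#' @export
check_same_grid <- function(a, b) {
  da <- dim(volume_array(a)); db <- dim(volume_array(b))
  if (!identical(da, db))
    stop("grid mismatch: shapes ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"), " (resampling is not supported)")
  if (max(abs(a$spacing - b$spacing) / a$spacing) > 1e-4)
    stop("grid mismatch: spacings (", paste(a$spacing, collapse = ", "),
         ") vs (", paste(b$spacing, collapse = ", "), ") mm")
  invisible(TRUE)
}

volume_array <- function(x) {
  if (inherits(x, "suv_volume")) x$values
  else if (inherits(x, "bone_label_volume")) x$labels
  else if (inherits(x, "binary_mask")) x$voxels
  else stop("not a volume object")
}

#' @export
print.suv_volume <- function(x, ...) {
  cat("SUV volume: ", paste(dim(x$values), collapse = " x "),
      " voxels @ ", paste(x$spacing, collapse = " x "), " mm",
      " (voxel ", signif(voxel_volume_ml(x), 4), " mL)\n",
      "  SUV range [", signif(min(x$values), 4), ", ",
      signif(max(x$values), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
print.bone_label_volume <- function(x, ...) {
  present <- setdiff(sort(unique(as.vector(x$labels))), 0L)
  cat("Label volume: ", paste(dim(x$labels), collapse = " x "),
      " voxels @ ", paste(x$spacing, collapse = " x "), " mm; ",
      length(present), " labelled structure(s)\n", sep = "")
  invisible(x)
}

nifti_xform <- function(spacing, origin) {
  m <- rbind(cbind(diag(spacing), origin), c(0, 0, 0, 1))
  structure(m, code = 2L)
}

#' Read an SUV volume from a NIfTI file
#'
#' @param path Path to a 3D NIfTI file (.nii or .nii.gz).
#' @return An [suv_volume()] with spacing and origin taken from the header.
#' @export
read_suv_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected 3D volume, got ", length(d), "D in ", path)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  if (any(spacing <= 0)) stop("non-positive voxel spacing in ", path)
  xf <- RNifti::xform(img)
  origin <- if (attr(xf, "code") > 0) xf[1:3, 4] else c(0, 0, 0)
  suv_volume(array(as.numeric(img), dim = d), spacing = spacing,
             origin = origin)
}

#' Write an SUV volume to NIfTI
#'
#' @param vol An [suv_volume()].
#' @param path Output path (.nii or .nii.gz).
#' @return Invisibly, `path`.
#' @export
write_suv_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  img <- RNifti::`sform<-`(img, nifti_xform(vol$spacing, vol$origin))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a labelled anatomy volume and its taxonomy
#'
#' @param path Path to an integer NIfTI label volume.
#' @param taxonomy_path Path to a two-column CSV (`label,name`); names must
#'   come from [anatomy_vocabulary()].
#' @param reference Optional [suv_volume()] to check grid compatibility
#'   against (shape and spacing must match exactly).
#' @return A [bone_label_volume()].
#' @export
read_label_volume <- function(path, taxonomy_path, reference = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(taxonomy_path)) stop("no such file: ", taxonomy_path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected 3D label volume, got ", length(d), "D in ", path)
  tax <- read.csv(taxonomy_path, stringsAsFactors = FALSE)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  xf <- RNifti::xform(img)
  origin <- if (attr(xf, "code") > 0) xf[1:3, 4] else c(0, 0, 0)
  lab <- bone_label_volume(array(as.integer(round(img)), dim = d),
                           taxonomy = tax, spacing = spacing,
                           origin = origin)
  if (!is.null(reference)) check_same_grid(reference, lab)
  lab
}

#' Write a labelled anatomy volume and its taxonomy
#'
#' @param lab A [bone_label_volume()].
#' @param path Output NIfTI path.
#' @param taxonomy_path Optional CSV path for the `label,name` table.
#' @return Invisibly, `path`.
#' @export
write_label_volume <- function(lab, path, taxonomy_path = NULL) {
  img <- RNifti::asNifti(lab$labels)
  RNifti::pixdim(img) <- lab$spacing
  img <- RNifti::`sform<-`(img, nifti_xform(lab$spacing, lab$origin))
  RNifti::writeNifti(img, path, datatype = "int16")
  if (!is.null(taxonomy_path))
    write.csv(lab$taxonomy, taxonomy_path, row.names = FALSE)
  invisible(path)
}

#' Write a binary mask to NIfTI (0/1 bytes)
#' @param mask A [binary_mask()].
#' @param path Output NIfTI path.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask$voxels), dim(mask$voxels)))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

# voxels of the given anatomical classes as a logical array
class_mask <- function(lab, classes) {
  ids <- lab$taxonomy$label[lab$taxonomy$name %in% classes]
  array(lab$labels %in% ids, dim(lab$labels))
}
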