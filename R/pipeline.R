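#' Score a full staging case: focal and diffuse bone-marrow uptake
#'
#' Runs the complete pipeline on one examination: marrow extraction,
#' spine/other grouping, the focal TSAU detector, and the diffuse SUV
#' index, sharing the intermediate masks between the two read-outs.
#'
#' @param suv An [suv_volume()].
#' @param labels A [bone_label_volume()] on the same grid (with a liver
#'   label if the diffuse index is wanted).
#' @param focal_cfg A [focal_config()].
#' @param marrow_cfg A [marrow_config()].
#' @param liver_margin_mm Liver edge erosion for the diffuse index (mm).
#' @return An object of class `bmu_report`: list with `focal`
#'   (a `focal_verdict`), `diffuse` (a `diffuse_result`, or `NULL` when
#'   no liver label is present), and the intermediate `groups`.
#' @export
stage_case <- function(suv, labels, focal_cfg = focal_config(),
                       marrow_cfg = marrow_config(), liver_margin_mm = 5) {
  check_same_grid(suv, labels)
  marrow <- extract_marrow(labels, marrow_cfg)
  groups <- assign_groups(labels, marrow, marrow_cfg)
  focal <- score_focal_uptake(suv, labels, focal_cfg, marrow_cfg,
                              groups = groups)
  has_liver <- any(class_mask(labels, "liver"))
  diffuse <- if (has_liver)
    diffuse_index(suv, labels, marrow = marrow, marrow_cfg = marrow_cfg,
                  liver_margin_mm = liver_margin_mm) else NULL
  structure(list(focal = focal, diffuse = diffuse, groups = groups),
            class = "bmu_report")
}

#' @export
print.bmu_report <- function(x, ...) {
  print(x$focal)
  if (!is.null(x$diffuse)) print(x$diffuse)
  invisible(x)
}

#' Serialize a staging report to a JSON-ready list
#'
#' @param report A [stage_case()] result.
#' @return A plain list (numbers and booleans) suitable for
#'   `jsonlite::write_json()`.
#' @export
report_to_list <- function(report) {
  f <- report$focal
  out <- list(focal = list(
    verdict = f$focal,
    spine = list(thr = f$spine$thr, msau = f$spine$msau,
                 tsau = f$spine$tsau,
                 abnormal_volume_ml = f$spine$abnormal_volume_ml,
                 cutoff = f$config$cutoff_spine),
    other = list(thr = f$other$thr, msau = f$other$msau,
                 tsau = f$other$tsau,
                 abnormal_volume_ml = f$other$abnormal_volume_ml,
                 cutoff = f$config$cutoff_other)))
  if (!is.null(report$diffuse)) {
    d <- report$diffuse
    out$diffuse <- list(spine_marrow_median = d$spine_marrow_median,
                        liver_median = d$liver_median,
                        index = d$index, high = d$high)
  }
  out
}
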