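# Volumetry and probabilistic maps for the mapped area.

#' Cavalieri volume estimate from serial sections
#'
#' `volume = sum(areas) * thickness * interval * shrinkage`, i.e. each
#' measured section stands for `interval` consecutive sections of the given
#' thickness, and the result is corrected for histological shrinkage.
#'
#' @param areas_mm2 per-section delineated areas, mm^2.
#' @param thickness_um section thickness, micrometers.
#' @param interval sampling interval (every n-th section measured).
#' @param shrinkage shrinkage correction factor (> 0; 1 = none).
#' @return volume in mm^3.
#' @export
area_volume <- function(areas_mm2, thickness_um = 20, interval = 15,
                        shrinkage = 1) {
  if (!length(areas_mm2)) stop_invalid("empty section list")
  if (any(!is.finite(areas_mm2)) || any(areas_mm2 < 0))
    stop_invalid("areas must be finite and nonnegative")
  .chk_num(thickness_um, "thickness_um", lower = 0, strict_lower = TRUE)
  .chk_num(interval, "interval", lower = 0, strict_lower = TRUE)
  .chk_num(shrinkage, "shrinkage", lower = 0, strict_lower = TRUE)
  sum(areas_mm2) * (thickness_um / 1000) * interval * shrinkage
}

#' Build a probabilistic map from aligned individual masks
#'
#' Voxelwise fraction of brains in which the area is present. All masks
#' must share grid dimensions and affine. The conservation identity
#' `sum(map) * voxel_volume = mean individual volume` holds exactly.
#'
#' @param masks list of binary `volume_grid`s in a common space.
#' @return a `volume_grid` with values in \[0, 1\].
#' @export
build_prob_map <- function(masks) {
  if (length(masks) < 1L) stop_invalid("need at least one mask")
  ref <- masks[[1]]
  for (m in masks[-1]) {
    if (!.check_same_grid(ref, m))
      stop("build_prob_map: masks are not aligned (grid or affine differs)",
           call. = FALSE)
  }
  acc <- Reduce(`+`, lapply(masks, function(m) (m$data != 0) * 1))
  volume_grid(acc / length(masks), ref$affine)
}

#' Left-right volume asymmetry test
#'
#' Paired t test on per-brain left vs right volumes; delegates to
#' [paired_t()].
#'
#' @param left,right per-brain volumes, mm^3.
#' @param tail passed to [paired_t()].
#' @return as [paired_t()].
#' @export
asymmetry_test <- function(left, right, tail = "two.sided") {
  paired_t(left, right, tail = tail)
}
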