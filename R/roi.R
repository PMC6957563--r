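# ROI-level statistics and functional-anatomical integration: interaction
# tests on PSC, behavior-BOLD coupling, conjunction, overlap fractions,
# peak probability, centers of mass, threshold ROIs.

#' Polarity x Probe type interaction test on percent signal change
#'
#' Same repeated-measures engine as [rm_anova_2x2()] but on raw PSC values
#' (no log transform; PSC can be negative).
#'
#' @param psc a `psc_table`.
#' @param phase phase to analyze when the table holds several.
#' @return an `anova_result` data frame.
#' @export
psc_interaction_test <- function(psc, phase = NULL) {
  if (!is.null(phase)) psc <- psc[psc$phase == phase, ]
  if ("phase" %in% names(psc) && length(unique(psc$phase)) > 1L)
    stop_invalid("psc table contains several phases; pass `phase`")
  rm_anova_2x2(psc, value = "psc", log_transform = FALSE)
}

#' Behavior-BOLD correlation across subjects
#'
#' Pearson correlation between per-subject behavioral NetNegInt effects (ms)
#' and BOLD NetNegInt effects (PSC). The default tail is one-sided positive,
#' the directional hypothesis for a region whose activity tracks the
#' behavioral negation cost.
#'
#' @param behavioral_net,bold_net numeric vectors, equal length >= 3.
#' @param tail `"greater"` (default), `"two.sided"` or `"less"`.
#' @return list with `r`, `p`, `n`, `tail`, `degenerate`.
#' @export
behavior_bold_correlation <- function(behavioral_net, bold_net,
                                      tail = c("greater", "two.sided", "less")) {
  tail <- match.arg(tail)
  if (length(behavioral_net) != length(bold_net))
    stop_invalid("vectors must have equal length")
  n <- length(behavioral_net)
  if (n < 3L) stop_invalid("need at least 3 subjects")
  if (stats::sd(behavioral_net) == 0 || stats::sd(bold_net) == 0) {
    warning("zero variance in one input; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = n, tail = tail, degenerate = TRUE))
  }
  r <- stats::cor(behavioral_net, bold_net)
  if (abs(r) >= 1) {
    p <- switch(tail, two.sided = 0,
                greater = if (r > 0) 0 else 1,
                less = if (r < 0) 0 else 1)
    return(list(r = r, p = p, n = n, tail = tail, degenerate = FALSE))
  }
  ht <- stats::cor.test(behavioral_net, bold_net, alternative = tail)
  list(r = unname(ht$estimate), p = ht$p.value, n = n, tail = tail,
       degenerate = FALSE)
}

.check_same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$affine, b$affine, tolerance = 1e-8))
}

#' Voxelwise conjunction of two binary masks
#'
#' @param a,b binary `volume_grid`s on the same grid.
#' @param resample resample `b` onto `a`'s grid (nearest neighbor) if the
#'   grids differ; otherwise differing grids are an error.
#' @return a binary `volume_grid`; the shared voxel count is in
#'   `attr(, "count")`.
#' @export
conjunction <- function(a, b, resample = FALSE) {
  if (!.check_same_grid(a, b)) {
    if (!resample) stop("incompatible grids; pass resample = TRUE", call. = FALSE)
    b <- .resample_to_grid(b, dim(a$data), a$affine)
  }
  out <- volume_grid((a$data != 0) * (b$data != 0), a$affine)
  attr(out, "count") <- sum(out$data)
  out
}

#' Overlap fractions between a functional cluster and an anatomical area
#'
#' Both binary masks are resampled to a common isotropic grid (default
#' 1 mm, nearest neighbor) covering their joint extent, then
#' `pct_anatomical = 100 |A ∩ F| / |A|` and
#' `pct_functional = 100 |A ∩ F| / |F|` are reported.
#'
#' @param functional,anatomical nonempty binary `volume_grid`s.
#' @param target_res common resolution in mm (default 1).
#' @return an `overlap_report` list: `n_shared`, `n_functional`,
#'   `n_anatomical`, `pct_functional`, `pct_anatomical`, `target_res`.
#' @export
overlap_fractions <- function(functional, anatomical, target_res = 1) {
  if (sum(functional$data != 0) == 0 || sum(anatomical$data != 0) == 0)
    stop("overlap_fractions: empty mask", call. = FALSE)
  lo <- pmin(.grid_bbox(functional)$lo, .grid_bbox(anatomical)$lo)
  hi <- pmax(.grid_bbox(functional)$hi, .grid_bbox(anatomical)$hi)
  out_dim <- pmax(1L, as.integer(ceiling((hi - lo) / target_res - 1e-9)))
  out_aff <- diag(c(rep(target_res, 3), 1))
  out_aff[1:3, 4] <- lo + target_res / 2
  f <- .resample_to_grid(functional, out_dim, out_aff)$data != 0
  a <- .resample_to_grid(anatomical, out_dim, out_aff)$data != 0
  shared <- sum(f & a)
  structure(list(n_shared = shared,
                 n_functional = sum(f), n_anatomical = sum(a),
                 pct_functional = 100 * shared / sum(f),
                 pct_anatomical = 100 * shared / sum(a),
                 target_res = target_res),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap: %d shared voxels at %g mm = %.1f%% of anatomical, %.1f%% of functional\n",
              x$n_shared, x$target_res, x$pct_anatomical, x$pct_functional))
  invisible(x)
}

#' Probability-map value at an mm coordinate
#'
#' Looks up the voxel containing the coordinate via the inverse affine.
#' Coordinates on a voxel boundary are assigned by rounding the continuous
#' index half-up (toward the higher index).
#'
#' @param coord_mm numeric length-3 mm coordinate.
#' @param map a `volume_grid` (probability map).
#' @return the map value at that voxel.
#' @export
peak_probability <- function(coord_mm, map) {
  if (length(coord_mm) != 3L) stop_invalid("coord_mm must have length 3")
  ci <- .mm_to_vox(map$affine, matrix(coord_mm, 1))
  nn <- floor(ci + 0.5)
  d <- dim(map$data)
  if (any(nn < 0) || any(nn >= d))
    stop("coordinate (", paste(coord_mm, collapse = ", "),
         ") outside the grid", call. = FALSE)
  map$data[nn[1] + 1L, nn[2] + 1L, nn[3] + 1L]
}

#' Intensity-weighted center of mass, in mm
#'
#' @param map a `volume_grid` with nonnegative weights, not all zero.
#' @return numeric length-3 mm coordinate.
#' @export
center_of_mass <- function(map) {
  w <- map$data
  if (all(w == 0)) stop("center_of_mass: all-zero map", call. = FALSE)
  nz <- which(w != 0, arr.ind = TRUE)
  mm <- .vox_to_mm(map$affine, nz - 1)
  ww <- w[nz]
  colSums(mm * ww) / sum(ww)
}

#' Threshold a probability map into a binary ROI
#'
#' Voxels with `value >= thr` and positive support form the mask (so
#' `thr = 0` returns the support of the map). An empty result triggers a
#' warning, not an error.
#'
#' @param map a `volume_grid` with values in \[0, 1\].
#' @param thr threshold in \[0, 1\].
#' @return a binary `volume_grid`.
#' @export
threshold_roi <- function(map, thr) {
  .chk_num(thr, "thr", lower = 0, upper = 1)
  mask <- (map$data >= thr) & (map$data > 0)
  if (!any(mask)) warning("threshold_roi: empty mask at thr = ", thr)
  volume_grid(mask * 1, map$affine)
}
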