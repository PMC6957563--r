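# 3D scalar/binary grids with an affine (0-based voxel index -> mm at voxel
# centers), NIfTI-1 I/O, and a synthetic blob generator.

#' Construct a volume grid
#'
#' @param data 3D numeric array.
#' @param affine 4x4 matrix mapping homogeneous 0-based voxel indices to mm
#'   coordinates at voxel centers (NIfTI convention). Default: identity
#'   spacing `voxel_size` with the first voxel center at the origin.
#' @param voxel_size isotropic spacing in mm used when `affine` is NULL.
#' @return a `volume_grid` (list with `data` and `affine`).
#' @export
volume_grid <- function(data, affine = NULL, voxel_size = 1) {
  if (length(dim(data)) != 3L) stop_invalid("data must be a 3D array")
  if (is.null(affine)) {
    affine <- diag(c(rep(voxel_size, 3), 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop_invalid("affine must be 4x4")
  if (abs(det(affine[1:3, 1:3])) < 1e-12) stop_invalid("affine must be invertible")
  structure(list(data = data, affine = affine), class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("volume_grid ", paste(dim(x$data), collapse = " x "),
      ", voxel volume ", signif(abs(det(x$affine[1:3, 1:3])), 4), " mm^3, ",
      sum(x$data != 0), " nonzero voxels\n", sep = "")
  invisible(x)
}

# mm coordinates of voxel centers for an index matrix (rows = 0-based ijk)
.vox_to_mm <- function(affine, ijk0) {
  t(affine %*% rbind(t(ijk0), 1))[, 1:3, drop = FALSE]
}

.mm_to_vox <- function(affine, xyz) {
  t(solve(affine) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

#' Generate a synthetic volume from blob specifications
#'
#' Blobs are painted in order; where labels overlap, the later blob wins
#' (a message reports the overlap). Supported blob types:
#' `list(type = "sphere", center = c(i, j, k), radius = r, value = v)`,
#' `list(type = "box", lower = c(..), upper = c(..), value = v)` and
#' `list(type = "voxels", index = <n x 3 matrix>, value = v)`. Centers,
#' bounds and indices are 0-based voxel coordinates; radii are in voxel
#' units.
#'
#' @param shape integer vector of 3 grid dimensions.
#' @param affine optional 4x4 affine (default 1 mm isotropic).
#' @param blobs list of blob specifications.
#' @return a `volume_grid`.
#' @export
gen_volume <- function(shape, affine = NULL, blobs = list()) {
  shape <- vapply(shape, .chk_count, integer(1), name = "shape")
  arr <- array(0, dim = shape)
  vg <- volume_grid(arr, affine)
  idx <- as.matrix(expand.grid(i = seq_len(shape[1]) - 1L,
                               j = seq_len(shape[2]) - 1L,
                               k = seq_len(shape[3]) - 1L))
  for (b in blobs) {
    val <- b$value %||% 1
    sel <- switch(b$type %||% "sphere",
      sphere = {
        if (length(b$center) != 3L) stop_invalid("sphere blob needs center of length 3")
        .chk_num(b$radius, "radius", lower = 0, strict_lower = TRUE)
        rowSums((idx - matrix(b$center, nrow(idx), 3, byrow = TRUE))^2) <= b$radius^2
      },
      box = {
        apply(idx, 1, function(v) all(v >= b$lower) && all(v <= b$upper))
      },
      voxels = {
        m <- matrix(as.integer(b$index), ncol = 3)
        if (any(m < 0) || any(t(t(m) >= shape)))
          stop_invalid("voxel index out of range")
        sel <- rep(FALSE, nrow(idx))
        sel[m[, 1] + shape[1] * m[, 2] + shape[1] * shape[2] * m[, 3] + 1L] <- TRUE
        sel
      },
      stop_invalid("unknown blob type: ", b$type)
    )
    if (!any(sel)) next
    if (any(vg$data[sel] != 0 & vg$data[sel] != val))
      message("gen_volume: blob overlaps earlier labels; later blob wins")
    vg$data[sel] <- val
  }
  vg
}

#' Read and write volumes as NIfTI-1
#'
#' @param vol a `volume_grid`.
#' @param path file path (`.nii` / `.nii.gz`).
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  dat <- array(as.numeric(img), dim = dim(img))
  volume_grid(dat, affine = aff)
}

# Nearest-neighbor resampling of `vol` onto an explicit output grid.
.resample_to_grid <- function(vol, out_dim, out_affine) {
  ijk_out <- as.matrix(expand.grid(i = seq_len(out_dim[1]) - 1L,
                                   j = seq_len(out_dim[2]) - 1L,
                                   k = seq_len(out_dim[3]) - 1L))
  mm <- .vox_to_mm(out_affine, ijk_out)
  cin <- .mm_to_vox(vol$affine, mm)
  nn <- floor(cin + 0.5)  # round half up on the continuous index
  d <- dim(vol$data)
  inside <- nn[, 1] >= 0 & nn[, 1] < d[1] &
            nn[, 2] >= 0 & nn[, 2] < d[2] &
            nn[, 3] >= 0 & nn[, 3] < d[3]
  vals <- numeric(nrow(nn))
  vals[inside] <- vol$data[cbind(nn[inside, 1] + 1L, nn[inside, 2] + 1L,
                                 nn[inside, 3] + 1L)]
  volume_grid(array(vals, dim = out_dim), out_affine)
}

# mm bounding box of the voxel *edges* of a grid
.grid_bbox <- function(vol) {
  d <- dim(vol$data)
  corners <- as.matrix(expand.grid(i = c(-0.5, d[1] - 0.5),
                                   j = c(-0.5, d[2] - 0.5),
                                   k = c(-0.5, d[3] - 0.5)))
  mm <- .vox_to_mm(vol$affine, corners)
  list(lo = apply(mm, 2, min), hi = apply(mm, 2, max))
}

#' Resample a volume to an isotropic resolution (nearest neighbor)
#'
#' Label-preserving nearest-neighbor resampling onto an axis-aligned grid
#' covering the input's extent. Used before overlap computations so that
#' voxel counts from differently-gridded masks are comparable.
#'
#' @param vol a `volume_grid`.
#' @param target_res isotropic output resolution in mm.
#' @return a `volume_grid` at the requested resolution.
#' @export
resample_volume <- function(vol, target_res = 1) {
  .chk_num(target_res, "target_res", lower = 0, strict_lower = TRUE)
  bb <- .grid_bbox(vol)
  out_dim <- pmax(1L, as.integer(ceiling((bb$hi - bb$lo) / target_res - 1e-9)))
  out_affine <- diag(c(rep(target_res, 3), 1))
  out_affine[1:3, 4] <- bb$lo + target_res / 2
  .resample_to_grid(vol, out_dim, out_affine)
}
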