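# Laminar histology phantoms: 2D grey-level-index images with a cortical
# ribbon whose laminar template switches at known traverse positions.

#' Built-in laminar GLI templates
#'
#' Smooth grey-level-index curves over relative cortical depth (0-100%,
#' layer I/II at 0, layer VI/white matter at 100), built as sums of
#' layer-wise Gaussian density peaks. `"granular"` has a conspicuous inner
#' granular layer (IV) peak near 55% depth; `"dysgranular"` has that peak
#' strongly attenuated with denser deep layers III/V, the pattern that
#' distinguishes dysgranular insular cortex from its granular neighbors.
#'
#' @param depth_pct numeric vector of depths in \[0, 100\].
#' @param type `"granular"` or `"dysgranular"`.
#' @return GLI values in \[0, 1\].
#' @export
gli_template <- function(depth_pct, type = c("granular", "dysgranular")) {
  type <- match.arg(type)
  d <- depth_pct
  base <- 0.30 + 0.16 * exp(-(d - 10)^2 / (2 * 6^2))
  v <- switch(type,
    granular = base + 0.24 * exp(-(d - 55)^2 / (2 * 7^2)) +
      0.08 * exp(-(d - 85)^2 / (2 * 9^2)),
    dysgranular = base + 0.06 * exp(-(d - 55)^2 / (2 * 7^2)) +
      0.16 * exp(-(d - 35)^2 / (2 * 9^2)) + 0.14 * exp(-(d - 78)^2 / (2 * 10^2))
  )
  pmin(pmax(v, 0), 1)
}

.resolve_template <- function(tpl) {
  if (is.function(tpl)) return(tpl)
  if (is.character(tpl)) return(function(d) gli_template(d, tpl))
  if (is.numeric(tpl)) {
    if (any(tpl < 0 | tpl > 1)) stop_invalid("numeric templates must lie in [0, 1]")
    dd <- seq(0, 100, length.out = length(tpl))
    return(function(d) stats::approx(dd, tpl, xout = d, rule = 2)$y)
  }
  stop_invalid("template must be a function, template name, or numeric vector")
}

#' Specify a histology phantom
#'
#' The phantom is a grayscale image with a horizontal cortical ribbon
#' (rows `ribbon_top` to `ribbon_bottom`); within the ribbon the GLI at a
#' pixel is the area's laminar template evaluated at the pixel's relative
#' depth, plus Gaussian pixel noise (clipped to \[0, 1\]). `n_traverses`
#' equally spaced vertical traverses span the ribbon between `margin_px`
#' and `width_px - margin_px`; `borders` gives, for each areal border, the
#' index of the first traverse belonging to the next area (the template
#' switches at the pixel column midway between traverses `b - 1` and `b`).
#' An empty `borders` vector with a single template yields a homogeneous
#' phantom.
#'
#' @param width_px,height_px image dimensions in pixels.
#' @param pixel_size_um physical pixel size (metadata only).
#' @param ribbon_top,ribbon_bottom first and last ribbon row.
#' @param margin_px horizontal margin before the first traverse.
#' @param n_traverses number of traverses covering the ribbon.
#' @param templates list of per-area templates (names, functions or numeric
#'   vectors), length `length(borders) + 1`.
#' @param borders integer traverse indices of area switches (ascending,
#'   within `2 .. n_traverses`).
#' @param noise_sd pixel noise SD.
#' @return a `histology_phantom_spec`.
#' @export
histology_phantom_spec <- function(width_px = 800, height_px = 160,
                                   pixel_size_um = 20,
                                   ribbon_top = 31, ribbon_bottom = 130,
                                   margin_px = 10, n_traverses = 81,
                                   templates = list("dysgranular", "granular"),
                                   borders = 41L, noise_sd = 0.05) {
  width_px <- .chk_count(width_px, "width_px", 10)
  height_px <- .chk_count(height_px, "height_px", 10)
  n_traverses <- .chk_count(n_traverses, "n_traverses", 3)
  .chk_num(noise_sd, "noise_sd", lower = 0)
  if (ribbon_top >= ribbon_bottom || ribbon_top < 1 || ribbon_bottom > height_px)
    stop_invalid("ribbon rows must satisfy 1 <= ribbon_top < ribbon_bottom <= height_px")
  borders <- as.integer(borders)
  if (length(borders)) {
    if (is.unsorted(borders, strictly = TRUE) ||
        any(borders < 2L) || any(borders > n_traverses))
      stop_invalid("borders must be strictly increasing traverse indices in 2..n_traverses")
  }
  if (length(templates) != length(borders) + 1L)
    stop_invalid("need length(borders) + 1 = ", length(borders) + 1L, " templates")
  structure(list(width_px = width_px, height_px = height_px,
                 pixel_size_um = pixel_size_um,
                 ribbon_top = ribbon_top, ribbon_bottom = ribbon_bottom,
                 margin_px = margin_px, n_traverses = n_traverses,
                 templates = templates, borders = borders,
                 noise_sd = noise_sd),
            class = "histology_phantom_spec")
}

#' Generate a histology phantom image with known borders
#'
#' @param spec a [histology_phantom_spec()].
#' @param seed integer seed.
#' @return list with `image` (a `gli_image` matrix, rows = y), `contours`
#'   (outer/inner polylines in pixel coordinates), `spacing` (traverse
#'   spacing in px), `traverse_x` (pixel column of each traverse) and
#'   `borders` (the ground-truth traverse indices).
#' @export
gen_histology_phantom <- function(spec, seed) {
  if (!inherits(spec, "histology_phantom_spec"))
    stop_invalid("spec must be a histology_phantom_spec")
  set.seed(as.integer(seed))
  W <- spec$width_px; H <- spec$height_px
  tx <- seq(spec$margin_px, W - spec$margin_px, length.out = spec$n_traverses)
  # area id per pixel column: switches midway between traverses b-1 and b
  switch_px <- if (length(spec$borders))
    (tx[spec$borders - 1L] + tx[spec$borders]) / 2 else numeric(0)
  col_area <- findInterval(seq_len(W), switch_px) + 1L

  tfun <- lapply(spec$templates, .resolve_template)
  rib <- spec$ribbon_top:spec$ribbon_bottom
  depth <- (rib - spec$ribbon_top) / (spec$ribbon_bottom - spec$ribbon_top) * 100

  img <- matrix(0, H, W)
  for (a in seq_along(tfun)) {
    cols <- which(col_area == a)
    if (!length(cols)) next
    img[rib, cols] <- matrix(tfun[[a]](depth), length(rib), length(cols))
  }
  if (spec$noise_sd > 0) {
    img[rib, ] <- img[rib, ] + stats::rnorm(length(rib) * W, 0, spec$noise_sd)
    img <- pmin(pmax(img, 0), 1)
  }
  attr(img, "pixel_size_um") <- spec$pixel_size_um
  class(img) <- c("gli_image", "matrix")

  contours <- list(outer = cbind(x = range(tx), y = rep(spec$ribbon_top, 2)),
                   inner = cbind(x = range(tx), y = rep(spec$ribbon_bottom, 2)))
  list(image = img, contours = contours,
       spacing = diff(tx[1:2]), traverse_x = tx,
       borders = spec$borders, spec = spec)
}

#' Read/write GLI images as 16-bit grayscale TIFF
#'
#' @param image a `gli_image` (matrix in \[0, 1\]).
#' @param path file path.
#' @export
write_gli_image <- function(image, path) {
  tiff::writeTIFF(unclass(image), path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_gli_image
#' @param pixel_size_um optional pixel size to attach.
#' @export
read_gli_image <- function(path, pixel_size_um = NULL) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  if (!is.null(pixel_size_um)) attr(img, "pixel_size_um") <- pixel_size_um
  class(img) <- c("gli_image", "matrix")
  img
}
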