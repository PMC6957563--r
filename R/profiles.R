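# GLI profile extraction along cortical traverses and the moment feature
# vectors entering the multivariate border analysis.

# Bilinear interpolation of a matrix image at continuous pixel coordinates
# (x = column, y = row, both 1-based). Errors if a point falls outside.
.interp_bilinear <- function(img, x, y) {
  H <- nrow(img); W <- ncol(img)
  if (any(x < 1 | x > W | y < 1 | y > H)) return(NULL)
  x0 <- pmin(floor(x), W - 1L); y0 <- pmin(floor(y), H - 1L)
  fx <- x - x0; fy <- y - y0
  img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    img[cbind(y0, x0 + 1L)] * fx * (1 - fy) +
    img[cbind(y0 + 1L, x0)] * (1 - fx) * fy +
    img[cbind(y0 + 1L, x0 + 1L)] * fx * fy
}

# Arc-length parameterization of a polyline; returns a function mapping an
# arc fraction in [0, 1] to an (x, y) point.
.polyline_param <- function(p) {
  seg <- sqrt(rowSums(diff(p)^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  if (L <= 0) stop_invalid("contour has zero length")
  list(length = L, at = function(frac) {
    s <- frac * L
    cbind(stats::approx(cum, p[, 1], xout = s)$y,
          stats::approx(cum, p[, 2], xout = s)$y)
  })
}

#' Extract depth-normalized GLI profiles along a cortical ribbon
#'
#' Traverses run as straight segments between arc-length-matched points on
#' the outer (layer I/II) and inner (layer VI/white matter) contours,
#' spaced `spacing` pixels apart along the outer contour. Each traverse is
#' sampled at `n_depth` equidistant relative depths (0-100%) with bilinear
#' interpolation, giving fixed-length profiles regardless of local cortical
#' thickness.
#'
#' @param image a `gli_image` matrix (rows = y) with values in \[0, 1\].
#' @param contours list with `outer` and `inner` polylines (n x 2 matrices
#'   of x, y pixel coordinates, same orientation).
#' @param spacing traverse spacing in pixels along the outer contour.
#' @param n_depth samples per profile (default 100).
#' @return an `n_traverses x n_depth` matrix of class `gli_profiles`.
#' @export
extract_profiles <- function(image, contours, spacing, n_depth = 100) {
  .chk_num(spacing, "spacing", lower = 0, strict_lower = TRUE)
  n_depth <- .chk_count(n_depth, "n_depth", 5)
  outer <- .polyline_param(as.matrix(contours$outer))
  inner <- .polyline_param(as.matrix(contours$inner))
  n_prof <- floor(outer$length / spacing + 1e-9) + 1L
  fr <- (seq_len(n_prof) - 1L) * spacing / outer$length
  fr <- pmin(fr, 1)
  po <- outer$at(fr); pi_ <- inner$at(fr)
  tdepth <- seq(0, 1, length.out = n_depth)
  prof <- matrix(NA_real_, n_prof, n_depth)
  for (i in seq_len(n_prof)) {
    xs <- po[i, 1] + tdepth * (pi_[i, 1] - po[i, 1])
    ys <- po[i, 2] + tdepth * (pi_[i, 2] - po[i, 2])
    v <- .interp_bilinear(unclass(image), xs, ys)
    if (is.null(v))
      stop("traverse ", i, " leaves the image", call. = FALSE)
    prof[i, ] <- v
  }
  structure(prof, class = c("gli_profiles", "matrix"),
            depth_pct = tdepth * 100)
}

# Weighted moments of a nonnegative curve y over positions d.
.curve_moments <- function(d, y) {
  tot <- sum(y)
  if (tot <= 1e-12) return(c(mean = mean(y), centroid = 0, sd = 0,
                             skew = 0, kurt = 0))
  c0 <- sum(d * y) / tot
  m2 <- sum(y * (d - c0)^2) / tot
  if (m2 <= 1e-12) {
    sk <- 0; ku <- 0
  } else {
    sk <- (sum(y * (d - c0)^3) / tot) / m2^1.5
    ku <- (sum(y * (d - c0)^4) / tot) / m2^2
  }
  c(mean = mean(y), centroid = c0, sd = sqrt(m2), skew = sk, kurt = ku)
}

#' Moment feature vector of a GLI profile
#'
#' Ten features per profile: mean amplitude, centroid depth, SD, skewness
#' and kurtosis of the profile treated as a density over cortical depth,
#' and the same five moments of the absolute first derivative (central
#' differences; one-sided at the ends). This is the canonical feature set
#' of observer-independent cytoarchitectonic mapping; profiles whose total
#' weight vanishes get zeroed moment features and a `flagged` attribute.
#'
#' @param profiles a `gli_profiles` matrix (or a single numeric profile).
#' @return an `n x 10` feature matrix with columns
#'   `amp.mean, amp.centroid, amp.sd, amp.skew, amp.kurt,
#'    der.mean, der.centroid, der.sd, der.skew, der.kurt`.
#' @export
profile_features <- function(profiles) {
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1)
  n_depth <- ncol(profiles)
  if (n_depth < 5L) stop_invalid("profiles must have length >= 5")
  d <- attr(profiles, "depth_pct") %||% seq(0, 100, length.out = n_depth)
  step <- d[2] - d[1]
  feats <- t(apply(profiles, 1, function(y) {
    dy <- c(y[2] - y[1],
            (y[-(1:2)] - y[-((n_depth - 1):n_depth)]) / 2,
            y[n_depth] - y[n_depth - 1]) / step
    c(.curve_moments(d, y), .curve_moments(d, abs(dy)))
  }))
  colnames(feats) <- c(paste0("amp.", c("mean", "centroid", "sd", "skew", "kurt")),
                       paste0("der.", c("mean", "centroid", "sd", "skew", "kurt")))
  feats
}

#' Standardize feature columns across a region of interest
#'
#' Columns are centered and scaled to unit variance (constant columns are
#' centered only). Standardizing an already standardized matrix is a no-op.
#'
#' @param features numeric feature matrix (rows = traverses).
#' @return standardized matrix.
#' @export
standardize_features <- function(features) {
  m <- colMeans(features)
  s <- apply(features, 2, stats::sd)
  s[s < 1e-12] <- 1
  out <- scale(features, center = m, scale = s)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}
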