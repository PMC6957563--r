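# Gaussian tuning-curve fits: baseline + amplitude * exp(-(u-center)^2/2w^2)
# with a fixed center. Baseline and amplitude are linear given the width, so
# they are profiled out and the fit reduces to a deterministic 1-D
# minimization over the width.

# Weighted least squares for fixed width(s); vectorized over `widths`.
# The fit is box-constrained: baseline >= 0 and 0 <= amplitude <= A_max.
# Nonnegativity reflects the science (an RT floor and a difficulty cost
# cannot be negative); the amplitude cap removes a degenerate large-width
# basin in which the Gaussian is nearly constant over the sampled axis and
# an amplitude of the order of the whole mean level trades off against the
# baseline. The constrained optimum is found by KKT candidate enumeration
# (interior solution plus each active-constraint reduced model). Returns a
# matrix with rows (baseline, amplitude, sse), one column per width.
.gauss_wls <- function(u, y, w, center, widths, A_max = Inf) {
  du2 <- (u - center)^2
  Sw <- sum(w); Sy <- sum(w * y); Syy <- sum(w * y * y)
  out <- vapply(widths, function(wd) {
    g <- exp(-du2 / (2 * wd * wd))
    Sg <- sum(w * g); Sgg <- sum(w * g * g); Sgy <- sum(w * g * y)
    den <- Sw * Sgg - Sg * Sg
    # candidate (b, A) pairs: interior solution and each active constraint
    cb <- numeric(0); ca <- numeric(0)
    if (den > .Machine$double.eps * Sw * Sgg) {
      A <- (Sw * Sgy - Sg * Sy) / den
      b <- (Sy - A * Sg) / Sw
      if (A >= 0 && b >= 0 && A <= A_max) { cb <- b; ca <- A }
    }
    cb <- c(cb, max(Sy / Sw, 0), 0)                                 # A = 0; b = 0
    ca <- c(ca, 0, min(max(Sgy / Sgg, 0), A_max))
    if (is.finite(A_max)) {                                         # A = A_max
      cb <- c(cb, max((Sy - A_max * Sg) / Sw, 0)); ca <- c(ca, A_max)
    }
    sses <- Syy + cb * cb * Sw + ca * ca * Sgg + 2 * ca * cb * Sg -
      2 * cb * Sy - 2 * ca * Sgy
    k <- which.min(sses)
    c(cb[k], ca[k], max(sses[k], 0))
  }, numeric(3))
  out
}

# Core profiled fit. Deterministic local descent: the profiled SSE over the
# width can have a second, wide-width basin where the Gaussian is nearly
# flat over the sampled axis and mimics a mean level; the scientifically
# meaningful fit is the basin reachable from a width of half the axis span.
# We evaluate a dense log-spaced width grid, walk downhill from the grid
# point nearest span/2 to the nearest local minimum, and refine by
# golden-section search in its bracket.
.fit_gauss_core <- function(u, y, w, center, width_init = NULL,
                            refine = c("precise", "fast")) {
  refine <- match.arg(refine)
  span <- diff(range(u))
  if (span <= 0) stop_invalid("need at least two distinct axis positions")
  if (max(y) - min(y) <= 1e-12 * max(abs(y), 1)) {
    # constant data: degenerate flat fit
    return(list(baseline = sum(w * y) / sum(w), amplitude = 0, width = NA_real_,
                sse = 0, degenerate = TRUE))
  }
  A_max <- 4 * (max(y) - min(y))
  grid <- exp(seq(log(span / 50), log(span * 5), length.out = 40))
  sse <- .gauss_wls(u, y, w, center, grid, A_max)[3, ]
  i <- which.min(abs(grid - (width_init %||% (span / 2))))
  repeat {
    left <- if (i > 1L) sse[i - 1L] else Inf
    right <- if (i < length(grid)) sse[i + 1L] else Inf
    if (left < sse[i] && left <= right) i <- i - 1L
    else if (right < sse[i]) i <- i + 1L
    else break
  }
  w_best <- grid[i]; s_best <- sse[i]
  if (refine == "precise") {
    blo <- grid[max(i - 1L, 1L)]; bhi <- grid[min(i + 1L, length(grid))]
    opt <- stats::optimize(function(wd) .gauss_wls(u, y, w, center, wd, A_max)[3, 1],
                           interval = c(blo, bhi), tol = 1e-10 * span)
    if (opt$objective < s_best) { w_best <- opt$minimum; s_best <- opt$objective }
  } else if (i > 1L && i < length(grid)) {
    # one parabolic interpolation step on the log-width grid
    lw <- log(grid[(i - 1L):(i + 1L)]); sv <- sse[(i - 1L):(i + 1L)]
    den <- (sv[1] - 2 * sv[2] + sv[3])
    if (den > 0) {
      wd <- exp(lw[2] - 0.5 * (lw[2] - lw[1]) * (sv[3] - sv[1]) / den)
      sp <- .gauss_wls(u, y, w, center, wd, A_max)[3, 1]
      if (sp < s_best) { w_best <- wd; s_best <- sp }
    }
  }
  best <- .gauss_wls(u, y, w, center, w_best, A_max)
  list(baseline = best[1, 1], amplitude = best[2, 1], width = w_best,
       sse = best[3, 1], degenerate = FALSE)
}

.new_gaussian_fit <- function(core, u, y, w, center, compress, sst) {
  fitted <- core$baseline +
    if (is.na(core$width)) 0 else
      core$amplitude * exp(-(u - center)^2 / (2 * core$width^2))
  r2 <- if (sst > 0) 1 - core$sse / sst else NA_real_
  structure(list(baseline = core$baseline, amplitude = core$amplitude,
                 width = core$width, center = center, compress = compress,
                 r_squared = r2, sse = core$sse,
                 fitted = fitted, residuals = y - fitted,
                 degenerate = core$degenerate),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("Gaussian fit (%s axis): baseline %.2f, amplitude %.2f, width %s, R2 %s%s\n",
              x$compress, x$baseline, x$amplitude,
              if (is.na(x$width)) "NA" else sprintf("%.4f", x$width),
              if (is.na(x$r_squared)) "NA" else sprintf("%.4f", x$r_squared),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

# Default fixed center: position of the hardest (closest-to-equal)
# proportion on the chosen axis.
.default_center <- function(x, compress) {
  i <- which.min(abs(log(x)))
  if (compress == "log") log(x[i]) else x[i]
}

#' Weber's-law Gaussian fit to proportion means
#'
#' Fits `baseline + amplitude * exp(-(u - center)^2 / (2 width^2))` to mean
#' RT per proportion by least squares, where `u` is the proportion ratio
#' either untransformed (`compress = "linear"`) or log-compressed
#' (`compress = "log"`). Comparing the coefficient of determination across
#' the two axes tests compliance with Weber's law: performance curves for
#' numerosity comparison become Gaussian on a log-ratio axis.
#'
#' The center is fixed (three free parameters in the trial-level
#' decomposition use the same convention); by default it sits at the
#' hardest, closest-to-equal ratio.
#'
#' @param means numeric vector of mean RTs, one per proportion.
#' @param x proportion ratios (> 0), same length as `means`.
#' @param compress `"log"` or `"linear"` axis.
#' @param center optional fixed center on the chosen axis.
#' @return a `gaussian_fit` with `baseline`, `amplitude`, `width`,
#'   `r_squared`; constant means give a flagged degenerate fit with
#'   amplitude 0 and undefined R-squared.
#' @export
fit_weber <- function(means, x, compress = c("log", "linear"), center = NULL) {
  compress <- match.arg(compress)
  if (length(means) != length(x)) stop_invalid("means and x must match in length")
  if (length(unique(x)) < 4L) stop_invalid("need at least 4 distinct proportions")
  if (any(!is.finite(means))) stop_invalid("means must be finite")
  if (any(x <= 0)) stop_invalid("proportions must be positive")
  u <- if (compress == "log") log(x) else x
  center <- center %||% .default_center(x, compress)
  w <- rep(1, length(u))
  core <- .fit_gauss_core(u, means, w, center)
  sst <- sum((means - mean(means))^2)
  .new_gaussian_fit(core, u, means, w, center, compress, sst)
}

#' Three-parameter Gaussian decomposition of trial-level RTs
#'
#' Fits baseline, amplitude and width (center fixed) to the full set of RT
#' values of one condition, minimizing the trial-level sum of squared
#' errors. Because the mean structure is constant within a proportion, the
#' minimization is carried out on per-proportion means weighted by trial
#' counts, which yields the identical minimizer. The baseline parameter
#' captures an RT offset common to all proportions -- the component of the
#' negation cost that is independent of comparison difficulty.
#'
#' @param trials a `trial_table` (typically one condition, e.g. all `less`
#'   trials).
#' @param proportions ratio axis mapping the proportion index to a ratio;
#'   defaults to `attr(trials, "proportions")`.
#' @param compress `"log"` (default) or `"linear"` axis.
#' @param center optional fixed center.
#' @return a `gaussian_fit`; `r_squared` is computed at the trial level.
#' @export
fit_gaussian_3param <- function(trials, proportions = attr(trials, "proportions"),
                                compress = c("log", "linear"), center = NULL) {
  compress <- match.arg(compress)
  if (is.null(proportions)) stop_invalid("proportions axis missing")
  idx <- sort(unique(trials$proportion))
  if (length(idx) < 3L) stop_invalid("need at least 3 proportions represented")
  sums <- tapply(trials$rt_ms, trials$proportion, sum)
  cnts <- tapply(trials$rt_ms, trials$proportion, length)
  means <- sums / cnts
  x <- proportions[as.integer(names(means))]
  u <- if (compress == "log") log(x) else x
  center <- center %||% .default_center(proportions, compress)
  core <- .fit_gauss_core(u, as.numeric(means), as.numeric(cnts), center)
  # trial-level SSE = weighted-mean SSE + within-proportion SS
  within_ss <- sum(trials$rt_ms^2) - sum(cnts * means^2)
  core$sse <- core$sse + within_ss
  sst <- sum((trials$rt_ms - mean(trials$rt_ms))^2)
  fit <- .new_gaussian_fit(core, u, as.numeric(means), as.numeric(cnts),
                           center, compress, sst)
  fit$fitted <- fit$baseline +
    if (is.na(fit$width)) 0 else
      fit$amplitude * exp(-(u - center)^2 / (2 * fit$width^2))
  fit$residuals <- as.numeric(means) - fit$fitted
  fit
}
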