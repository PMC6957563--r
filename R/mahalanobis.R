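# Sliding-window Mahalanobis distance between blocks of profile feature
# vectors, Hotelling T^2 significance, and blocksize-stable border calls.

#' Sliding-window Mahalanobis distance along the cortical ribbon
#'
#' At each admissible position `x` (1-based index of the first profile of
#' the right block), the squared Mahalanobis distance
#' `D^2 = (m_L - m_R)' S_p^{-1} (m_L - m_R)` is computed between the mean
#' feature vectors of the `b` profiles left of `x` and the `b` profiles
#' from `x` onward, with `S_p` the pooled within-block covariance.
#' Significance comes from Hotelling's T^2,
#' `T^2 = (b/2) D^2`, via `F = T^2 (2b - d - 1) / (d (2b - 2))` with
#' `(d, 2b - d - 1)` degrees of freedom. A singular pooled covariance is
#' ridge-regularized (escalating multiple of the mean diagonal) and the
#' result flagged.
#'
#' @param features ordered numeric matrix of feature vectors (rows =
#'   traverses), typically [standardize_features()] output.
#' @param blocksize block width `b` in profiles; positions
#'   `b + 1 .. N - b + 1` are admissible.
#' @param alpha retained in the output for downstream border calling.
#' @return a `distance_profile` data frame with columns `position`, `d2`,
#'   `statistic` (F), `p`; attributes `blocksize`, `dim`, `ridge`.
#' @export
sliding_mahalanobis <- function(features, blocksize, alpha = 0.05) {
  X <- as.matrix(features)
  N <- nrow(X); d <- ncol(X)
  b <- .chk_count(blocksize, "blocksize", 2)
  if (N < 2 * b) stop_invalid("need at least 2 * blocksize = ", 2 * b, " profiles")
  if (b < d / 2)
    warning("blocksize ", b, " is small for ", d, " features; ",
            "covariance estimates will be unstable")
  df2 <- 2 * b - d - 1
  positions <- seq.int(b + 1L, N - b + 1L)
  d2 <- stat <- p <- rep(NA_real_, length(positions))
  ridge_used <- 0
  for (ii in seq_along(positions)) {
    x <- positions[ii]
    L <- X[(x - b):(x - 1L), , drop = FALSE]
    R <- X[x:(x + b - 1L), , drop = FALSE]
    mL <- colMeans(L); mR <- colMeans(R)
    CL <- crossprod(sweep(L, 2, mL)); CR <- crossprod(sweep(R, 2, mR))
    Sp <- (CL + CR) / (2 * b - 2)
    dm <- mL - mR
    eps <- 0
    scale0 <- mean(diag(Sp))
    if (scale0 <= 0) scale0 <- 1
    sol <- tryCatch(solve(Sp, dm), error = function(e) NULL)
    while (is.null(sol)) {
      eps <- if (eps == 0) 1e-8 else eps * 100
      if (eps > 1) stop("pooled covariance irreparably singular", call. = FALSE)
      sol <- tryCatch(solve(Sp + diag(eps * scale0, d), dm),
                      error = function(e) NULL)
    }
    ridge_used <- max(ridge_used, eps)
    d2[ii] <- max(sum(dm * sol), 0)
    if (df2 >= 1) {
      t2 <- (b / 2) * d2[ii]
      stat[ii] <- t2 * df2 / (d * (2 * b - 2))
      p[ii] <- stats::pf(stat[ii], d, df2, lower.tail = FALSE)
    }
  }
  if (ridge_used > 0)
    warning("singular pooled covariance; ridge regularization used (eps = ",
            ridge_used, ")")
  structure(data.frame(position = positions, d2 = d2, statistic = stat, p = p),
            class = c("distance_profile", "data.frame"),
            blocksize = b, n_features = d, df2 = df2, alpha = alpha,
            ridge = ridge_used)
}

# significant local maxima of one distance profile, with per-blocksize
# non-maximum suppression: blocks of width b straddle any border within b of
# their split position, so a weaker maximum closer than b to a stronger one
# is a flank of the same border, not a second border
.sig_maxima <- function(dp, alpha, p_adjust) {
  d2 <- dp$d2
  n <- length(d2)
  if (n < 3L) return(integer(0))
  int <- 2:(n - 1)
  is_max <- d2[int] > d2[int - 1] & d2[int] >= d2[int + 1]
  pv <- dp$p
  if (p_adjust == "bonferroni") pv <- pmin(pv * n, 1)
  keep <- int[is_max & !is.na(pv[int]) & pv[int] < alpha]
  if (length(keep) > 1L) {
    b <- attr(dp, "blocksize")
    ord <- keep[order(-d2[keep])]
    kept <- integer(0)
    for (k in ord) {
      if (!length(kept) || all(abs(dp$position[kept] - dp$position[k]) >= b))
        kept <- c(kept, k)
    }
    keep <- sort(kept)
  }
  dp$position[keep]
}

#' Blocksize-stable border detection
#'
#' For every blocksize, significant local maxima of the Mahalanobis
#' distance are candidate borders; a position recurring (within
#' `tolerance` traverse indices) in at least `k_stability` blocksizes is
#' accepted. Accepted positions closer than `tolerance` to each other are
#' merged, keeping the best-supported position.
#'
#' Per-position p-values are Bonferroni-adjusted across positions by
#' default: the distance curves of neighboring blocksizes share profiles,
#' so chance exceedances persist across blocksizes and per-position testing
#' alone does not control false borders (see the package vignette).
#'
#' @param distance_profiles list of [sliding_mahalanobis()] outputs for a
#'   range of blocksizes (>= 3).
#' @param alpha significance level for maxima.
#' @param k_stability minimum number of supporting blocksizes; default is a
#'   majority of the supplied blocksizes.
#' @param tolerance positional tolerance (traverse indices) when matching
#'   maxima across blocksizes.
#' @param p_adjust `"bonferroni"` (default) or `"none"`.
#' @param min_separation minimum distance (traverse indices) between
#'   distinct borders; defaults to the smallest blocksize. Blocks narrower
#'   than a candidate pair's separation cannot straddle one border without
#'   touching the other, so closer calls are shoulders of a single border:
#'   the strongest call (highest support, then highest mean D^2) is kept.
#' @return a `border_call_set` data frame with columns `position`,
#'   `support` (number of blocksizes), `stability` (support / number of
#'   blocksizes); the per-blocksize maxima are kept in `attr(, "calls")`.
#'   An empty set is a valid result.
#' @export
detect_borders <- function(distance_profiles, alpha = 0.05, k_stability = NULL,
                           tolerance = 2, p_adjust = c("bonferroni", "none"),
                           min_separation = NULL) {
  p_adjust <- match.arg(p_adjust)
  if (length(distance_profiles) < 3L)
    stop_invalid("need distance profiles for at least 3 blocksizes")
  nb <- length(distance_profiles)
  k <- k_stability %||% (floor(nb / 2) + 1L)
  calls <- lapply(distance_profiles, .sig_maxima, alpha = alpha, p_adjust = p_adjust)
  bs <- vapply(distance_profiles, function(d) attr(d, "blocksize"), numeric(1))

  cand <- sort(unique(unlist(calls)))
  empty <- data.frame(position = integer(0), support = integer(0),
                      stability = numeric(0))
  if (!length(cand)) {
    return(structure(empty, class = c("border_call_set", "data.frame"),
                     calls = calls, blocksizes = bs, k = k))
  }
  support <- vapply(cand, function(x)
    sum(vapply(calls, function(pos) any(abs(pos - x) <= tolerance), logical(1))),
    numeric(1))
  acc <- cand[support >= k]
  sup <- support[support >= k]
  if (!length(acc)) {
    out <- empty
  } else {
    # mean D^2 at each accepted position across blocksizes, for tie-breaking
    strength <- vapply(acc, function(x) {
      v <- vapply(distance_profiles, function(dp) {
        j <- match(x, dp$position)
        if (is.na(j)) NA_real_ else dp$d2[j]
      }, numeric(1))
      mean(v, na.rm = TRUE)
    }, numeric(1))
    grp <- cumsum(c(1, diff(acc) > tolerance))
    out <- do.call(rbind, lapply(split(seq_along(acc), grp), function(ix) {
      best <- ix[order(-sup[ix], -strength[ix])[1]]
      data.frame(position = acc[best], support = sup[best],
                 stability = sup[best] / nb, strength = strength[best])
    }))
    rownames(out) <- NULL
    # non-maximum suppression below the resolution limit of the smallest block
    sep <- min_separation %||% min(bs)
    ord <- order(-out$support, -out$strength)
    kept <- integer(0)
    for (i in ord) {
      if (!length(kept) || all(abs(out$position[kept] - out$position[i]) >= sep))
        kept <- c(kept, i)
    }
    out <- out[sort(kept), setdiff(names(out), "strength"), drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("border_call_set", "data.frame"),
            calls = calls, blocksizes = bs, k = k)
}

#' One-call border detection on a profile matrix
#'
#' Convenience wrapper: standardizes features, runs [sliding_mahalanobis()]
#' over a blocksize range and calls [detect_borders()].
#'
#' @param features feature matrix (unstandardized is fine).
#' @param blocksizes integer vector of block widths (default `seq(8, 24, 2)`).
#' @param ... passed to [detect_borders()].
#' @return a `border_call_set`.
#' @export
find_borders <- function(features, blocksizes = seq(8L, 24L, 2L), ...) {
  Z <- standardize_features(features)
  bmax <- max(blocksizes)
  if (nrow(Z) < 2 * bmax)
    stop_invalid("need at least ", 2 * bmax, " profiles for blocksize ", bmax)
  dps <- lapply(blocksizes, function(b)
    suppressWarnings(sliding_mahalanobis(Z, b)))
  detect_borders(dps, ...)
}
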