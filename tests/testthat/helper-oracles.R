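# Brute-force reference implementations and small fixture builders, kept
# deliberately naive and independent of the package internals.

# Double-loop Mahalanobis reference: explicit sums for means and pooled
# covariance, full matrix inverse.
naive_sliding_mahalanobis <- function(X, b) {
  N <- nrow(X); d <- ncol(X)
  positions <- seq(b + 1, N - b + 1)
  d2 <- numeric(length(positions))
  for (ii in seq_along(positions)) {
    x <- positions[ii]
    L <- X[(x - b):(x - 1), , drop = FALSE]
    R <- X[x:(x + b - 1), , drop = FALSE]
    mL <- numeric(d); mR <- numeric(d)
    for (j in 1:d) { mL[j] <- sum(L[, j]) / b; mR[j] <- sum(R[, j]) / b }
    Sp <- matrix(0, d, d)
    for (j in 1:d) for (k in 1:d) {
      sL <- 0; sR <- 0
      for (i in 1:b) {
        sL <- sL + (L[i, j] - mL[j]) * (L[i, k] - mL[k])
        sR <- sR + (R[i, j] - mR[j]) * (R[i, k] - mR[k])
      }
      Sp[j, k] <- (sL + sR) / (2 * b - 2)
    }
    dm <- mL - mR
    d2[ii] <- drop(t(dm) %*% solve(Sp) %*% dm)
  }
  data.frame(position = positions, d2 = d2)
}

# A small balanced trial table built by hand from per-subject cell means
# (no generator involved).
cellmeans_table <- function(means_by_cell, n_subjects = nrow(means_by_cell)) {
  cells <- expand.grid(polarity = c("positive", "negative"),
                       probe_type = c("linguistic", "symbolic"),
                       stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    data.frame(subject = s,
               polarity = cells$polarity,
               probe_type = cells$probe_type,
               rt_ms = means_by_cell[s, ])
  }))
}

# linguistic condition pair from a generated table, with the ratio axis kept
split_ling_pair <- function(trials) {
  pr <- attr(trials, "proportions")
  more <- trials[trials$polarity == "positive" & trials$probe_type == "linguistic", ]
  less <- trials[trials$polarity == "negative" & trials$probe_type == "linguistic", ]
  attr(more, "proportions") <- pr
  attr(less, "proportions") <- pr
  list(more = more, less = less)
}
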