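# Permutation decomposition of the negation cost: which Gaussian parameter
# (baseline, amplitude, width) differs between the `more` and `less`
# conditions?

# Per-condition sufficient statistics: subject x proportion sums and counts.
.perm_suffstats <- function(trials, subjects, prop_idx) {
  s <- matrix(0, length(subjects), length(prop_idx),
              dimnames = list(subjects, prop_idx))
  n <- s
  ts <- tapply(trials$rt_ms, list(trials$subject, trials$proportion), sum)
  tn <- tapply(trials$rt_ms, list(trials$subject, trials$proportion), length)
  s[rownames(ts), colnames(ts)] <- ifelse(is.na(ts), 0, ts)
  n[rownames(tn), colnames(tn)] <- ifelse(is.na(tn), 0, tn)
  list(sum = s, n = n)
}

.perm_fit_params <- function(sums, cnts, u, center) {
  ok <- cnts > 0
  core <- .fit_gauss_core(u[ok], (sums / cnts)[ok], cnts[ok], center,
                          refine = "fast")
  c(baseline = core$baseline, amplitude = core$amplitude, width = core$width)
}

#' Permutation test on the Gaussian decomposition of two conditions
#'
#' Fits the three-parameter Gaussian ([fit_gaussian_3param()]) separately to
#' the two conditions and tests each parameter difference (b minus a)
#' against a null distribution built by exchanging the two condition labels
#' within subject (each subject's complete trial sets for the two conditions
#' are swapped or not). The baseline parameter isolates an RT offset common
#' to all proportions, so with conditions `more` vs `less` it isolates the
#' negation cost; amplitude and width capture difficulty tuning, which
#' negation should leave untouched.
#'
#' Two-sided p-values use the add-one correction
#' `p = (1 + #\{|null| >= |obs|\}) / (1 + n_perm)`. If `n_perm` meets or
#' exceeds the number of distinct within-subject flips (`2^S`), the test
#' switches to exhaustive enumeration (noted by a message) and p becomes the
#' exact proportion over all flips.
#'
#' @param trials_a,trials_b `trial_table`s for the two conditions (e.g.
#'   `more` and `less`), same subjects in both.
#' @param n_perm number of label permutations (>= 99).
#' @param seed integer seed for the Monte-Carlo draw.
#' @param proportions ratio axis (defaults to the attribute on `trials_a`).
#' @param compress,center passed to the Gaussian fit.
#' @param unit `"subject"` (default; within-subject condition flips,
#'   respecting the paired design) or `"trial"` (trial-level label
#'   shuffling within subject).
#' @param exhaustive force (`TRUE`) or suppress (`FALSE`) exhaustive
#'   enumeration; `NULL` (default) enumerates when `n_perm >= 2^S`.
#' @return a `perm_test_result` list: `observed` (named differences),
#'   `p` (named p-values), `n_perm`, `exhaustive`, `seed`.
#' @export
permutation_baseline_test <- function(trials_a, trials_b, n_perm = 999, seed = 1,
                                      proportions = attr(trials_a, "proportions"),
                                      compress = c("log", "linear"), center = NULL,
                                      unit = c("subject", "trial"),
                                      exhaustive = NULL) {
  compress <- match.arg(compress)
  unit <- match.arg(unit)
  if (n_perm < 99) stop_invalid("n_perm must be >= 99")
  if (is.null(proportions)) stop_invalid("proportions axis missing")
  subjects <- sort(unique(c(trials_a$subject, trials_b$subject)))
  if (!setequal(unique(trials_a$subject), unique(trials_b$subject)))
    stop_invalid("both conditions must come from the same subjects")
  prop_idx <- sort(unique(c(trials_a$proportion, trials_b$proportion)))
  x <- proportions[prop_idx]
  u <- if (compress == "log") log(x) else x
  center <- center %||% .default_center(proportions, compress)

  A <- .perm_suffstats(trials_a, subjects, prop_idx)
  B <- .perm_suffstats(trials_b, subjects, prop_idx)
  S <- length(subjects)

  fit_diff <- function(sumA, cntA, sumB, cntB)
    .perm_fit_params(sumB, cntB, u, center) - .perm_fit_params(sumA, cntA, u, center)

  totSA <- colSums(A$sum); totNA <- colSums(A$n)
  totSB <- colSums(B$sum); totNB <- colSums(B$n)
  obs <- fit_diff(totSA, totNA, totSB, totNB)

  dS <- B$sum - A$sum
  dN <- B$n - A$n

  if (is.null(exhaustive))
    exhaustive <- unit == "subject" && S <= 30 && n_perm >= 2^S
  if (exhaustive && (unit != "subject" || S > 30))
    stop_invalid("exhaustive enumeration requires subject-level flips and <= 30 subjects")
  if (exhaustive) {
    message("permutation_baseline_test: n_perm >= 2^", S,
            " distinct flips; using exhaustive enumeration")
    flips <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), S)))
  } else {
    set.seed(as.integer(seed))
    flips <- matrix(stats::runif(n_perm * S) < 0.5, n_perm, S)
  }

  null_mat <- matrix(NA_real_, nrow(flips), 3,
                     dimnames = list(NULL, names(obs)))
  if (unit == "subject") {
    for (i in seq_len(nrow(flips))) {
      f <- flips[i, ]
      mS <- colSums(dS[f, , drop = FALSE]); mN <- colSums(dN[f, , drop = FALSE])
      null_mat[i, ] <- fit_diff(totSA + mS, totNA + mN, totSB - mS, totNB - mN)
    }
  } else {
    set.seed(as.integer(seed))
    pool <- rbind(cbind(as.data.frame(trials_a)[c("subject", "proportion", "rt_ms")]),
                  cbind(as.data.frame(trials_b)[c("subject", "proportion", "rt_ms")]))
    nA <- nrow(trials_a)
    for (i in seq_len(nrow(null_mat))) {
      lab <- rep(FALSE, nrow(pool))
      for (sbj in subjects) {
        rows <- which(pool$subject == sbj)
        nb <- sum(trials_b$subject == sbj)
        lab[sample(rows, nb)] <- TRUE
      }
      pa <- pool[!lab, ]; pb <- pool[lab, ]
      SA <- tapply(pa$rt_ms, factor(pa$proportion, levels = prop_idx), sum)
      CA <- tapply(pa$rt_ms, factor(pa$proportion, levels = prop_idx), length)
      SB <- tapply(pb$rt_ms, factor(pb$proportion, levels = prop_idx), sum)
      CB <- tapply(pb$rt_ms, factor(pb$proportion, levels = prop_idx), length)
      SA[is.na(SA)] <- 0; SB[is.na(SB)] <- 0
      CA[is.na(CA)] <- 0; CB[is.na(CB)] <- 0
      null_mat[i, ] <- fit_diff(SA, CA, SB, CB)
    }
  }

  tol <- 1e-12
  pvals <- vapply(seq_along(obs), function(j) {
    exceed <- sum(abs(null_mat[, j]) >= abs(obs[j]) - tol, na.rm = TRUE)
    if (exhaustive) exceed / nrow(null_mat)
    else (1 + exceed) / (1 + nrow(null_mat))
  }, numeric(1))
  names(pvals) <- names(obs)

  structure(list(observed = obs, p = pvals,
                 n_perm = nrow(null_mat), exhaustive = exhaustive,
                 seed = seed, unit = unit, null = null_mat),
            class = "perm_test_result")
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat("Permutation decomposition (", x$n_perm, " ",
      if (x$exhaustive) "exhaustive" else "Monte-Carlo",
      " permutations, unit = ", x$unit, ")\n", sep = "")
  for (nm in names(x$observed))
    cat(sprintf("  %-9s diff = %9.3f   p = %.5f\n", nm, x$observed[nm], x$p[nm]))
  invisible(x)
}
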