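# Trial filtering, condition summaries, the NetNegInt statistic and
# repeated-measures inference on the 2x2 within-subject design.

#' Trial filtering policy
#'
#' By default only incorrect responses are removed; no RT trimming is
#' applied. An optional per-subject upper cutoff at `mean + sd_limit * SD`
#' (computed on the trials surviving the accuracy filter) is available.
#'
#' @param correct_only drop incorrect trials (default TRUE).
#' @param sd_limit if non-NULL, drop trials with RT above the subject's
#'   mean + `sd_limit` * SD.
#' @return a `filter_policy` list.
#' @export
filter_policy <- function(correct_only = TRUE, sd_limit = NULL) {
  if (!is.null(sd_limit)) .chk_num(sd_limit, "sd_limit", lower = 0, strict_lower = TRUE)
  structure(list(correct_only = isTRUE(correct_only), sd_limit = sd_limit),
            class = "filter_policy")
}

#' Apply a filtering policy to a trial table
#'
#' Removed-row counts are reported via a message and stored in
#' `attr(, "n_removed")`. If any subject is left without trials in one of
#' the four Polarity x Probe type cells, filtering fails with an error
#' naming the cell.
#'
#' @param trials a `trial_table`.
#' @param policy a [filter_policy()].
#' @return the filtered `trial_table`.
#' @export
filter_trials <- function(trials, policy = filter_policy()) {
  n0 <- nrow(trials)
  keep <- rep(TRUE, n0)
  if (policy$correct_only) keep <- keep & trials$correct == 1
  n_acc <- sum(!keep)
  if (!is.null(policy$sd_limit)) {
    sub <- trials[keep, ]
    mu <- tapply(sub$rt_ms, sub$subject, mean)
    sd_ <- tapply(sub$rt_ms, sub$subject, stats::sd)
    cut <- mu + policy$sd_limit * sd_
    keep <- keep & trials$rt_ms <= cut[as.character(trials$subject)]
  }
  out <- trials[keep, , drop = FALSE]
  counts <- table(out$subject, out$polarity, out$probe_type)
  if (any(counts == 0)) {
    idx <- which(counts == 0, arr.ind = TRUE)[1, ]
    stop("empty cell after filtering: subject ", dimnames(counts)[[1]][idx[1]],
         ", ", dimnames(counts)[[2]][idx[2]], " ", dimnames(counts)[[3]][idx[3]],
         call. = FALSE)
  }
  removed <- c(incorrect = n_acc, rt_cutoff = n0 - n_acc - nrow(out))
  message("filter_trials: removed ", removed[["incorrect"]], " incorrect and ",
          removed[["rt_cutoff"]], " slow trials (", nrow(out), " of ", n0, " kept)")
  attr(out, "proportions") <- attr(trials, "proportions")
  attr(out, "n_removed") <- removed
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Condition means and SDs
#'
#' Mean, SD (n-1 denominator) and trial count per Polarity x Probe type
#' cell, optionally broken down by proportion.
#'
#' @param trials a `trial_table`.
#' @param by_proportion report the 2 x 2 x 5 breakdown instead of 2 x 2.
#' @return data frame with one row per cell.
#' @export
condition_summary <- function(trials, by_proportion = FALSE) {
  f <- if (by_proportion) rt_ms ~ polarity + probe_type + proportion
       else rt_ms ~ polarity + probe_type
  mean_df <- stats::aggregate(f, data = trials, FUN = mean)
  sd_df <- stats::aggregate(f, data = trials, FUN = stats::sd)
  n_df <- stats::aggregate(f, data = trials, FUN = length)
  out <- mean_df
  names(out)[names(out) == "rt_ms"] <- "mean_rt"
  out$sd_rt <- sd_df$rt_ms
  out$n <- n_df$rt_ms
  out
}

#' The net negation interaction (NetNegInt) statistic
#'
#' The processing signature of implicit negation: the linguistic polarity
#' difference (less - more) minus the symbolic difference (< - >),
#' `net = delta_ling - delta_symb`, computed on untransformed milliseconds
#' (or PSC units) both at the group level (grand cell means) and per
#' subject.
#'
#' @param x a `trial_table`, or any data frame with columns `subject`,
#'   `polarity`, `probe_type` and a value column.
#' @param value name of the value column (default `"rt_ms"`).
#' @return a `netnegint` list: `delta_ling`, `delta_symb`, `net`, and a
#'   `per_subject` data frame with the same three quantities per subject.
#' @export
net_neg_int <- function(x, value = "rt_ms") {
  if (!all(c("subject", "polarity", "probe_type", value) %in% names(x)))
    stop_invalid("x must have subject, polarity, probe_type and ", value, " columns")
  x$..v <- x[[value]]
  agg <- stats::aggregate(..v ~ subject + polarity + probe_type, data = x, FUN = mean)
  cell <- function(pol, pt) {
    v <- agg[agg$polarity == pol & agg$probe_type == pt, c("subject", "..v")]
    if (nrow(v) == 0) stop("missing cell: ", pol, " ", pt, call. = FALSE)
    v[order(v$subject), ]
  }
  nl <- cell("negative", "linguistic"); pl <- cell("positive", "linguistic")
  ns <- cell("negative", "symbolic");  ps <- cell("positive", "symbolic")
  subj <- nl$subject
  if (!all(sapply(list(pl$subject, ns$subject, ps$subject), identical, subj)))
    stop("missing cell for some subject", call. = FALSE)
  per <- data.frame(subject = subj,
                    delta_ling = nl$..v - pl$..v,
                    delta_symb = ns$..v - ps$..v)
  per$net <- per$delta_ling - per$delta_symb
  grand <- function(pol, pt) mean(x$..v[x$polarity == pol & x$probe_type == pt])
  dl <- grand("negative", "linguistic") - grand("positive", "linguistic")
  ds <- grand("negative", "symbolic") - grand("positive", "symbolic")
  structure(list(delta_ling = dl, delta_symb = ds, net = dl - ds,
                 per_subject = per),
            class = "netnegint")
}

#' @export
print.netnegint <- function(x, ...) {
  cat("NetNegInt: delta_ling =", round(x$delta_ling, 1),
      " delta_symb =", round(x$delta_symb, 1),
      " net =", round(x$net, 1), "\n")
  invisible(x)
}

#' Repeated-measures 2x2 ANOVA on subject cell means
#'
#' Aggregates to per-subject cell means (of `log(value)` when
#' `log_transform` is TRUE, the convention for judgment times) and fits the
#' classical fully-within ANOVA
#' `value ~ polarity * probe_type + Error(subject/(polarity * probe_type))`.
#' Each effect has 1 numerator df and `n_subjects - 1` denominator df.
#'
#' @param x a `trial_table` or a data frame of per-subject values with
#'   columns `subject`, `polarity`, `probe_type` and the value column.
#' @param value value column name (default `"rt_ms"`).
#' @param log_transform analyze `log(value)` (default TRUE; set FALSE for
#'   PSC, which can be negative).
#' @return an `anova_result` data frame with columns `effect`, `F`, `df1`,
#'   `df2`, `p`.
#' @export
rm_anova_2x2 <- function(x, value = "rt_ms", log_transform = TRUE) {
  x$..v <- if (log_transform) log(x[[value]]) else x[[value]]
  if (log_transform && any(!is.finite(x$..v)))
    stop_invalid("log transform requires strictly positive values")
  agg <- stats::aggregate(..v ~ subject + polarity + probe_type, data = x, FUN = mean)
  counts <- table(agg$subject)
  bad <- names(counts)[counts != 4L]
  if (length(bad))
    stop("subjects with missing cells: ", paste(bad, collapse = ", "), call. = FALSE)
  if (length(counts) < 2L) stop_invalid("need at least 2 subjects")
  agg$subject <- factor(agg$subject)
  agg$polarity <- factor(agg$polarity)
  agg$probe_type <- factor(agg$probe_type)
  fit <- stats::aov(..v ~ polarity * probe_type +
                      Error(subject / (polarity * probe_type)), data = agg)
  sm <- summary(fit)
  sstot <- sum((agg$..v - mean(agg$..v))^2)
  effects <- c("polarity", "probe_type", "polarity:probe_type")
  res <- data.frame(effect = effects, F = NA_real_, df1 = NA_real_,
                    df2 = NA_real_, p = NA_real_)
  for (stratum in sm) {
    tab <- stratum[[1]]
    rn <- trimws(rownames(tab))
    for (i in seq_along(effects)) {
      j <- which(rn == effects[i])
      if (length(j) != 1L) next
      ss_eff <- tab[j, "Sum Sq"]
      ss_res <- tab[rn == "Residuals", "Sum Sq"]
      res$df1[i] <- tab[j, "Df"]
      res$df2[i] <- tab[rn == "Residuals", "Df"]
      if (ss_eff + ss_res < 1e-14 * max(sstot, .Machine$double.xmin)) {
        # stratum numerically null (e.g. identical cells): define F = 0
        res$F[i] <- 0
        res$p[i] <- 1
      } else if (!is.na(tab[j, "F value"])) {
        res$F[i] <- tab[j, "F value"]
        res$p[i] <- tab[j, "Pr(>F)"]
      }
    }
  }
  class(res) <- c("anova_result", "data.frame")
  res
}

#' @rdname rm_anova_2x2
#' @export
rm_anova_2x2_log <- function(x, value = "rt_ms") {
  rm_anova_2x2(x, value = value, log_transform = TRUE)
}

#' Paired t test with explicit degenerate handling
#'
#' Classical paired t with `df = n - 1`. When the paired differences have
#' zero variance the statistic is degenerate: t = 0 and p = 1 when the mean
#' difference is also zero, otherwise t = +/-Inf with p = 0, and the result
#' is flagged.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @param tail "two.sided" (default), "greater" (a > b) or "less".
#' @return list with `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_t <- function(a, b, tail = c("two.sided", "greater", "less")) {
  tail <- match.arg(tail)
  if (length(a) != length(b)) stop_invalid("a and b must have equal length")
  if (length(a) < 2L) stop_invalid("need at least 2 pairs")
  d <- a - b
  n <- length(d)
  if (stats::sd(d) == 0) {
    md <- mean(d)
    if (md == 0) {
      return(list(t = 0, df = n - 1, p = if (tail == "two.sided") 1 else 1,
                  mean_diff = 0, degenerate = TRUE))
    }
    tt <- sign(md) * Inf
    p <- switch(tail,
                two.sided = 0,
                greater = if (md > 0) 0 else 1,
                less = if (md < 0) 0 else 1)
    return(list(t = tt, df = n - 1, p = p, mean_diff = md, degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, paired = TRUE, alternative = tail)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = unname(ht$estimate), degenerate = FALSE)
}
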