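# Trial-table generator for the 2 (Polarity) x 2 (Probe type) x 5
# (Proportion) within-subject verification design.

#' Generate a synthetic trial table
#'
#' Draws per-trial reaction times from the additive mean structure described
#' in [rt_model_params()] with multiplicative lognormal noise, plus a
#' Bernoulli accuracy flag independent of RT. The expected cell mean equals
#' the deterministic model formula exactly (the lognormal draw is
#' mean-corrected). Identical seeds reproduce the table bit-identically.
#'
#' @param design a [design_spec()].
#' @param params an [rt_model_params()].
#' @param seed integer seed.
#' @return a `trial_table` data frame with columns `subject`, `polarity`,
#'   `probe_type`, `proportion` (index 1-5), `token`, `rt_ms`, `correct`,
#'   and the ratio axis stored in `attr(, "proportions")`.
#' @export
gen_trials <- function(design, params, seed) {
  if (!inherits(design, "design_spec")) stop_invalid("design must be a design_spec")
  if (!inherits(params, "rt_model_params")) stop_invalid("params must be rt_model_params")
  set.seed(as.integer(seed))

  tab <- expand.grid(
    token = seq_len(design$tokens_per_cell),
    proportion = seq_along(design$proportions),
    probe_type = design$probe_types,
    polarity = design$polarities,
    subject = seq_len(design$n_subjects),
    stringsAsFactors = FALSE
  )[, c("subject", "polarity", "probe_type", "proportion", "token")]

  u <- log(design$proportions)[tab$proportion]
  bump <- params$amp * exp(-(u - params$center)^2 / (2 * params$width^2))
  neg <- tab$polarity == "negative"
  delta <- ifelse(neg & tab$probe_type == "linguistic", params$delta_ling,
           ifelse(neg & tab$probe_type == "symbolic", params$delta_symb, 0))
  # subject intercepts clipped at +/- 3 SD so the model mean stays positive
  # at realistic parameter values
  b_subj <- stats::rnorm(design$n_subjects, 0, params$tau_subj)
  b_subj <- pmin(pmax(b_subj, -3 * params$tau_subj), 3 * params$tau_subj)
  m <- params$mu0 + delta + bump + b_subj[tab$subject]
  if (any(m <= 0))
    stop_invalid("model mean non-positive for some trials; ",
                 "reduce tau_subj or effect magnitudes")
  eps <- stats::rnorm(nrow(tab), 0, params$sigma_e)
  tab$rt_ms <- m * exp(eps - params$sigma_e^2 / 2)
  tab$correct <- as.integer(stats::runif(nrow(tab)) >= params$err_rate)

  attr(tab, "proportions") <- design$proportions
  class(tab) <- c("trial_table", "data.frame")
  tab
}

#' Read/write trial tables as CSV
#'
#' The CSV dialect has header
#' `subject,polarity,probe_type,proportion,token,rt_ms,correct`. The ratio
#' axis is not stored in the CSV; supply it to downstream fits explicitly or
#' keep it with the in-memory table.
#'
#' @param trials a `trial_table`.
#' @param path file path.
#' @return `write_trials` returns `path` invisibly; `read_trials` returns a
#'   `trial_table`.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(as.data.frame(trials)[, c("subject", "polarity", "probe_type",
                                             "proportion", "token", "rt_ms", "correct")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @param proportions optional ratio axis to attach to the table read back.
#' @export
read_trials <- function(path, proportions = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject", "polarity", "probe_type", "proportion", "token", "rt_ms", "correct")
  if (!all(req %in% names(tab)))
    stop_invalid("trial CSV must have columns ", paste(req, collapse = ", "))
  if (any(tab$rt_ms <= 0)) stop_invalid("trial table contains non-positive RTs")
  if (!is.null(proportions)) attr(tab, "proportions") <- proportions
  class(tab) <- c("trial_table", "data.frame")
  tab
}
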