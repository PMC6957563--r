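# Experimental design and generative model parameters.

#' Specify the 2 x 2 x 5 within-subject verification design
#'
#' The behavioral task crosses Polarity (positive/negative) with Probe type
#' (linguistic quantifiers more/less vs. symbolic inequalities >/<), and each
#' of the four condition cells is presented at five blue/yellow proportions
#' with a fixed number of tokens per cell.
#'
#' The five proportion ratios are configuration values: real designs fix one
#' numerosity and vary the other, producing log-spaced ratios straddling
#' equality. The default, `exp(c(-1.2, -0.6, -0.1, 0.5, 1.1))` (about 0.30
#' to 3.0), is asymmetric around the hardest (closest-to-equal) ratio: the
#' five log-distances from that ratio are then all distinct, which is what
#' identifies the three-parameter Gaussian decomposition (a symmetric set
#' collapses to three effective support points).
#'
#' @param n_subjects number of subjects (default 21).
#' @param tokens_per_cell tokens of each proportion within each condition cell
#'   (default 6).
#' @param proportions numeric vector of five blue/yellow ratios (> 0).
#' @return an object of class `design_spec`.
#' @export
design_spec <- function(n_subjects = 21, tokens_per_cell = 6,
                        proportions = exp(c(-1.2, -0.6, -0.1, 0.5, 1.1))) {
  n_subjects <- .chk_count(n_subjects, "n_subjects")
  tokens_per_cell <- .chk_count(tokens_per_cell, "tokens_per_cell")
  if (!is.numeric(proportions) || length(proportions) != 5L ||
      any(!is.finite(proportions)) || any(proportions <= 0))
    stop_invalid("proportions must be 5 finite positive ratios")
  structure(list(
    polarities = c("positive", "negative"),
    probe_types = c("linguistic", "symbolic"),
    proportions = as.numeric(proportions),
    tokens_per_cell = tokens_per_cell,
    n_subjects = n_subjects
  ), class = "design_spec")
}

#' Generative reaction-time model parameters
#'
#' The trial generator draws
#' \deqn{RT = (\mu_0 + \delta \cdot cond + A e^{-(\log p - c)^2 / 2w^2} + b_s)
#'   \cdot e^{\epsilon - \sigma_e^2/2}}
#' where the negation cost `delta_ling` applies to negative linguistic trials
#' (less), the reversal cost `delta_symb` to negative symbolic trials (<),
#' the Gaussian bump captures Weber-type comparison difficulty on the
#' log-proportion axis, `b_s ~ N(0, tau_subj^2)` is a subject intercept and
#' `epsilon ~ N(0, sigma_e^2)` lognormal trial noise. The `-sigma_e^2/2`
#' correction makes the expected cell mean equal the deterministic part
#' exactly.
#'
#' Defaults reflect the group statistics of the study the package models:
#' a 152.5 ms negation cost and an 83.4 ms symbol-reversal cost on a
#' baseline near 880 ms. The noise split follows the same source: condition
#' SDs near 300 ms are dominated by between-subject spread (`tau_subj`),
#' while the group proportion-mean curve is very clean (Gaussian fits with
#' R-squared near 0.99), implying small trial-level noise (`sigma_e`);
#' subject intercepts cancel in that curve's shape.
#'
#' @param mu0 grand baseline, ms.
#' @param delta_ling negation cost added to negative linguistic trials, ms.
#' @param delta_symb reversal cost added to negative symbolic trials, ms.
#' @param amp amplitude of the difficulty bump, ms.
#' @param width bump width on the log-proportion axis (> 0).
#' @param center bump center on the log-proportion axis.
#' @param tau_subj between-subject SD of the intercept, ms.
#' @param sigma_e lognormal residual scale (SD of `log RT` at fixed mean).
#' @param err_rate probability that a trial is answered incorrectly.
#' @return an object of class `rt_model_params`.
#' @export
rt_model_params <- function(mu0 = 880, delta_ling = 152.5, delta_symb = 83.4,
                            amp = 180, width = 0.4, center = -0.1,
                            tau_subj = 250, sigma_e = 0.12, err_rate = 0.16) {
  .chk_num(mu0, "mu0", lower = 0, strict_lower = TRUE)
  .chk_num(width, "width", lower = 0, strict_lower = TRUE)
  .chk_num(sigma_e, "sigma_e", lower = 0)
  .chk_num(tau_subj, "tau_subj", lower = 0)
  .chk_num(err_rate, "err_rate", lower = 0, upper = 1, strict_upper = TRUE)
  .chk_num(delta_ling, "delta_ling")
  .chk_num(delta_symb, "delta_symb")
  .chk_num(amp, "amp")
  .chk_num(center, "center")
  structure(list(mu0 = mu0, delta_ling = delta_ling, delta_symb = delta_symb,
                 amp = amp, width = width, center = center,
                 tau_subj = tau_subj, sigma_e = sigma_e, err_rate = err_rate),
            class = "rt_model_params")
}

#' Percent-signal-change generative parameters
#'
#' Condition-by-phase cell means for an ROI plus a coupling level `rho`
#' between the subject-level behavioral NetNegInt effect (ms) and the
#' subject-level BOLD NetNegInt effect (PSC %). The subject BOLD effect is
#' `net_mean + sigma_net * (rho * z_s + sqrt(1 - rho^2) * e_s)` with `z_s`
#' the standardized behavioral effect, so the population correlation is
#' exactly `rho`. Cell-level noise (`sigma_psc`) is drawn orthogonal to the
#' interaction contrast, so it perturbs individual cells without diluting
#' the coupling.
#'
#' Default cell means mirror the insular ROI pattern of the modeled study:
#' higher PSC for the negative quantifier (0.25) than the positive (0.20),
#' with a much smaller symbolic difference.
#'
#' @param cell_means data frame with columns `phase`, `polarity`,
#'   `probe_type`, `mean` (PSC %). Default covers phases "I" and "II".
#' @param sigma_psc SD of cell-level PSC noise (>= 0).
#' @param sigma_net between-subject SD of the BOLD NetNegInt effect (>= 0).
#' @param rho target behavior-BOLD correlation, in \[-1, 1\].
#' @return an object of class `psc_model_params`.
#' @export
psc_model_params <- function(cell_means = default_psc_cell_means(),
                             sigma_psc = 0.05, sigma_net = 0.08, rho = 0.4) {
  .chk_num(sigma_psc, "sigma_psc", lower = 0)
  .chk_num(sigma_net, "sigma_net", lower = 0)
  .chk_num(rho, "rho", lower = -1, upper = 1)
  req <- c("phase", "polarity", "probe_type", "mean")
  if (!is.data.frame(cell_means) || !all(req %in% names(cell_means)))
    stop_invalid("cell_means must be a data frame with columns ",
                 paste(req, collapse = ", "))
  for (ph in unique(cell_means$phase)) {
    sub <- cell_means[cell_means$phase == ph, ]
    if (nrow(sub) != 4L)
      stop_invalid("cell_means must have exactly 4 condition cells per phase")
  }
  structure(list(cell_means = cell_means, sigma_psc = sigma_psc,
                 sigma_net = sigma_net, rho = rho),
            class = "psc_model_params")
}

#' @rdname psc_model_params
#' @export
default_psc_cell_means <- function() {
  expand.grid(polarity = c("positive", "negative"),
              probe_type = c("linguistic", "symbolic"),
              phase = c("I", "II"),
              stringsAsFactors = FALSE)[, c("phase", "polarity", "probe_type")] |>
    within({
      mean <- ifelse(polarity == "negative" & probe_type == "linguistic", 0.25,
              ifelse(polarity == "negative" & probe_type == "symbolic", 0.21, 0.20))
    })
}
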