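# Percent-signal-change generator with tunable behavior-BOLD coupling.

#' Generate per-subject per-condition percent signal change for an ROI
#'
#' Builds a PSC table whose subject-level NetNegInt contrast
#' `(negL - posL) - (negS - posS)` correlates with a supplied behavioral
#' NetNegInt vector at level `rho`. The coupling mixes the standardized
#' behavioral effect with independent noise at weight `rho`; cell noise is
#' drawn orthogonal to the interaction contrast so the construction is exact
#' (sample correlation converges to `rho` as the number of subjects grows;
#' with `rho = 1` and `sigma_psc = 0` the BOLD effect is an exact affine
#' function of the behavioral one).
#'
#' @param design a [design_spec()] (only `n_subjects` is used).
#' @param params a [psc_model_params()].
#' @param behavioral_effects numeric vector of per-subject behavioral
#'   NetNegInt effects (ms), length `design$n_subjects`.
#' @param seed integer seed.
#' @return a `psc_table` data frame with columns `subject`, `polarity`,
#'   `probe_type`, `phase`, `psc`.
#' @export
gen_psc <- function(design, params, behavioral_effects, seed) {
  if (!inherits(design, "design_spec")) stop_invalid("design must be a design_spec")
  if (!inherits(params, "psc_model_params")) stop_invalid("params must be psc_model_params")
  S <- design$n_subjects
  if (length(behavioral_effects) != S)
    stop_invalid("behavioral_effects must have length n_subjects = ", S)
  set.seed(as.integer(seed))

  sdb <- stats::sd(behavioral_effects)
  z <- if (isTRUE(sdb > 0)) (behavioral_effects - mean(behavioral_effects)) / sdb
       else rep(0, S)

  cm <- params$cell_means
  phases <- unique(cm$phase)
  # interaction contrast over cells, in the fixed cell order used below
  cells <- data.frame(polarity = c("positive", "negative", "positive", "negative"),
                      probe_type = c("linguistic", "linguistic", "symbolic", "symbolic"))
  cvec <- c(-1, 1, 1, -1)  # negL - posL - (negS - posS)

  out <- list()
  for (ph in phases) {
    sub <- cm[cm$phase == ph, ]
    mu <- vapply(seq_len(4), function(i) {
      v <- sub$mean[sub$polarity == cells$polarity[i] &
                    sub$probe_type == cells$probe_type[i]]
      if (length(v) != 1L) stop_invalid("cell_means missing a condition cell")
      v
    }, numeric(1))
    net_mean <- sum(cvec * mu)
    eps <- stats::rnorm(S)
    b <- net_mean + params$sigma_net * (params$rho * z + sqrt(1 - params$rho^2) * eps)
    eta <- matrix(stats::rnorm(S * 4, 0, params$sigma_psc), S, 4)
    eta <- eta - (eta %*% cvec / sum(cvec^2)) %*% t(cvec)  # remove contrast component
    vals <- matrix(mu, S, 4, byrow = TRUE) +
      (b - net_mean) %*% t(cvec / sum(cvec^2)) + eta
    out[[ph]] <- data.frame(subject = rep(seq_len(S), times = 4),
                            polarity = rep(cells$polarity, each = S),
                            probe_type = rep(cells$probe_type, each = S),
                            phase = ph,
                            psc = as.vector(vals))
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  class(tab) <- c("psc_table", "data.frame")
  tab
}

#' Per-subject BOLD NetNegInt effects from a PSC table
#'
#' @param psc a `psc_table`.
#' @param phase phase label to extract (required if the table has several).
#' @return named numeric vector of `(negL - posL) - (negS - posS)` per subject.
#' @export
psc_net_effects <- function(psc, phase = NULL) {
  if (!is.null(phase)) psc <- psc[psc$phase == phase, ]
  if (length(unique(psc$phase)) > 1L)
    stop_invalid("psc table contains several phases; pass `phase`")
  agg <- stats::aggregate(psc ~ subject + polarity + probe_type, data = psc, FUN = mean)
  cell <- function(pol, pt) {
    v <- agg[agg$polarity == pol & agg$probe_type == pt, ]
    v <- v[order(v$subject), ]
    stats::setNames(v$psc, v$subject)
  }
  (cell("negative", "linguistic") - cell("positive", "linguistic")) -
    (cell("negative", "symbolic") - cell("positive", "symbolic"))
}

#' @rdname gen_psc
#' @param psc a `psc_table`.
#' @param path file path for the CSV (`subject,polarity,probe_type,phase,psc`).
#' @export
write_psc <- function(psc, path) {
  utils::write.csv(as.data.frame(psc), path, row.names = FALSE)
  invisible(path)
}

#' @rdname gen_psc
#' @export
read_psc <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject", "polarity", "probe_type", "phase", "psc")
  if (!all(req %in% names(tab)))
    stop_invalid("PSC CSV must have columns ", paste(req, collapse = ", "))
  class(tab) <- c("psc_table", "data.frame")
  tab
}
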