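# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed error so callers can distinguish bad parameters from other failures.
stop_invalid <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("negmap_invalid_parameter", "error", "condition")))
}

.chk_num <- function(x, name, lower = -Inf, upper = Inf,
                     strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(name, " must be a single finite number")
  if (x < lower || (strict_lower && x <= lower))
    stop_invalid(name, " must be ", if (strict_lower) "> " else ">= ", lower,
                 " (got ", x, ")")
  if (x > upper || (strict_upper && x >= upper))
    stop_invalid(name, " must be ", if (strict_upper) "< " else "<= ", upper,
                 " (got ", x, ")")
  invisible(x)
}

.chk_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop_invalid(name, " must be an integer >= ", min)
  as.integer(x)
}

#' Write an analysis result as JSON
#'
#' Serializes a (possibly nested) list of scalar results to a JSON file,
#' unboxing length-one vectors. Used by the analysis drivers.
#'
#' @param x named list of results.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
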