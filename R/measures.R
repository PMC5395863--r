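MEASURES <- c("RR", "OR", "RD", "MD", "SMD")
LABELS <- c("non_english", "unpublished", "dissertation")
GROUPS <- c("ARI", "ID", "DPLP", "other")
MODELS <- c("fixed", "random")
METHODS <- c("inverse_variance", "mantel_haenszel")

#' Summary measure descriptor
#'
#' Describes the effect scale a meta-analysis is pooled on. Ratio
#' measures (risk ratio `RR`, odds ratio `OR`) are analysed on the log
#' scale and back-transformed for reporting, with a null value of 1 on
#' the natural scale. Difference measures (risk difference `RD`, mean
#' difference `MD`, standardized mean difference `SMD`) are analysed on
#' the identity scale with a null value of 0.
#'
#' @param code One of `"RR"`, `"OR"`, `"RD"`, `"MD"`, `"SMD"`, or an
#'   existing `summary_measure` object (returned unchanged).
#' @return An object of class `summary_measure`: a list with elements
#'   `code`, `log_scale` (logical) and `null_value` (natural scale).
#' @examples
#' summary_measure("RR")
#' summary_measure("MD")$null_value
#' @export
summary_measure <- function(code) {
  if (inherits(code, "summary_measure")) return(code)
  if (length(code) != 1 || !is.character(code) || !(code %in% MEASURES))
    stop_input("unknown summary measure '%s' (expected one of %s)",
               paste(code, collapse = ","), paste(MEASURES, collapse = ", "))
  log_scale <- code %in% c("RR", "OR")
  structure(list(code = code,
                 log_scale = log_scale,
                 null_value = if (log_scale) 1 else 0),
            class = "summary_measure")
}

#' @export
print.summary_measure <- function(x, ...) {
  cat(sprintf("<summary measure %s: %s scale, null value %g>\n", x$code,
              if (x$log_scale) "log" else "identity", x$null_value))
  invisible(x)
}

is_dichotomous_measure <- function(measure) {
  summary_measure(measure)$code %in% c("RR", "OR", "RD")
}
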