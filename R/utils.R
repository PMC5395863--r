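# internal helpers shared across modules

# normal quantile for 95% confidence intervals; fixed at 1.96 (not
# qnorm(0.975)) to match the convention of the review software whose
# printed intervals the impact metrics are compared against
Z95 <- 1.96

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (2.5 -> 3, -2.5 -> -3), the convention used for all reported
#' percentages and estimates. Base [round()] rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_away(c(2.5, -2.5, 10.15), c(0, 0, 1))
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  # tiny epsilon guards against binary representations such as
  # 10.15 * 10 == 101.4999... flipping an exact half downward
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_count <- function(x, name, min = 0) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != trunc(x))
    stop_input("'%s' must be a single integer >= %d (got %s)", name, min,
               paste(format(x), collapse = ","))
  as.integer(x)
}

check_number <- function(x, name) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x))
    stop_input("'%s' must be a single finite number", name)
  as.numeric(x)
}

check_prob <- function(x, name) {
  x <- check_number(x, name)
  if (x < 0 || x > 1) stop_input("'%s' must be in [0, 1] (got %g)", name, x)
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_num <- function(x, digits) {
  ifelse(is.na(x), "NA", formatC(round_half_away(x, digits), format = "f", digits = digits))
}
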