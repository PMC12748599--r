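#' Round half away from zero
#'
#' Reported map-accuracy percentages are conventionally rounded half-up
#' (0.5 -> 1), unlike base [round()] which rounds half to even.
#'
#' @param x numeric vector
#' @param digits integer, decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bd <- function(...) stop(..., call. = FALSE)

assert <- function(ok, ...) if (!isTRUE(ok)) stop_bd(...)

#' @useDynLib borealdist, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx pf rnorm runif sd
#' @importFrom utils read.csv write.csv head tail
NULL
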