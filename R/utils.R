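## Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

#' @importFrom stats pnorm qnorm dnorm rnorm runif rbinom rlnorm rnbinom rbeta
#'   rmultinom aov anova lm coef pt p.adjust phyper wilcox.test sd cor median
#'   var optim setNames complete.cases
#' @importFrom utils read.csv write.csv packageVersion head combn
#' @import methods
NULL

stop_input <- function(..., call. = FALSE) {
  stop(..., call. = call.)
}

check_number <- function(x, name, lower = -Inf, upper = Inf, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x)) {
    stop_input(sprintf("'%s' must be a numeric vector of length %d with no NA", name, len))
  }
  if (any(x < lower) || any(x > upper)) {
    stop_input(sprintf("'%s' must lie in [%s, %s]", name, format(lower), format(upper)))
  }
  invisible(x)
}

check_percent17 <- function(x, name, lower = 0, upper = 100) {
  if (!is.numeric(x) || length(x) != 17L || anyNA(x)) {
    stop_input(sprintf("'%s' must be a length-17 numeric vector with no NA", name))
  }
  if (any(x < lower) || any(x > upper)) {
    stop_input(sprintf("'%s' must lie in [%s, %s]", name, format(lower), format(upper)))
  }
  invisible(x)
}

## Deterministic substream seeds: one master seed fans out to named stages so
## each matrix / animal block can be regenerated independently (kept < 2^31).
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(key)) * seq_along(utf8ToInt(as.character(key))))
  as.integer((abs(seed) * 48271 + h * 9973 + 12345) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
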