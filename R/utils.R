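#' @importFrom stats cor pt sd var convolve rnorm runif sd setNames aov
#' @importFrom stats p.adjust t.test qnorm quantile lm.fit coef
#' @importFrom rlang .data
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a per-stage seed from a master seed
#'
#' Stable integer hash of (seed, label) so that pipeline stages draw from
#' independent, reproducible streams. Result is always in [1, 2^31 - 2].
#'
#' @param seed master seed (non-negative integer)
#' @param label character tag of the consuming stage
#' @return a single integer seed
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((seed * 48271 + h * 16807) %% 2147483646 + 1)
}

# population (1/N) standard deviation; fixed-map standardization convention
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

zscore_pop <- function(x) {
  s <- pop_sd(x)
  if (s == 0) return(x * 0)
  (x - mean(x)) / s
}

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
}
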