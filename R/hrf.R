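#' Canonical double-gamma hemodynamic response function
#'
#' The standard double-gamma HRF used by mainstream fMRI GLM software: a
#' positive gamma density peaking around 5 s minus a scaled gamma undershoot.
#' Parameters follow the de-facto defaults (response delay 6, undershoot delay
#' 16, both dispersions 1, undershoot ratio 1/6), with time measured in
#' seconds from stimulus onset.
#'
#' @param t numeric vector of times (seconds, >= 0)
#' @param peak_delay,peak_disp shape parameters of the response gamma
#'   (shape = peak_delay / peak_disp, scale = peak_disp)
#' @param under_delay,under_disp shape parameters of the undershoot gamma
#' @param ratio undershoot amplitude relative to the response
#' @return numeric vector, same length as `t`
#' @export
hrf_double_gamma <- function(t, peak_delay = 6, peak_disp = 1,
                             under_delay = 16, under_disp = 1, ratio = 1 / 6) {
  out <- stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    ratio * stats::dgamma(t, shape = under_delay / under_disp, scale = under_disp)
  out[t < 0] <- 0
  out
}

#' Sampled HRF basis set
#'
#' Samples the canonical kernel (and optionally its temporal and dispersion
#' derivatives) on the microtime grid used for design-matrix construction.
#' The temporal derivative is a finite difference with respect to a 1 s onset
#' shift; the dispersion derivative a finite difference with respect to the
#' response dispersion parameter (step 0.01), matching common GLM practice.
#'
#' @param tr_seconds repetition time in seconds (> 0)
#' @param duration_seconds kernel support length in seconds (default 32)
#' @param kind `"canonical"` (1 kernel) or `"canonical+derivatives"` (3 kernels)
#' @param microtime number of sub-TR bins used to sample the kernel
#' @return a matrix with one column per kernel (`canonical`, `tderiv`,
#'   `ddisp`), with attributes `dt` (sampling step, seconds) and `tr`
#' @export
hrf_basis <- function(tr_seconds, duration_seconds = 32,
                      kind = c("canonical", "canonical+derivatives"),
                      microtime = 16L) {
  assert_scalar_pos(tr_seconds, "tr_seconds")
  kind <- match.arg(kind)
  dt <- tr_seconds / microtime
  t <- seq(0, duration_seconds, by = dt)
  h <- hrf_double_gamma(t)
  if (kind == "canonical") {
    basis <- cbind(canonical = h)
  } else {
    shift <- 1
    td <- (h - hrf_double_gamma(t - shift)) / shift
    dd_step <- 0.01
    dd <- (h - hrf_double_gamma(t, peak_disp = 1 + dd_step)) / dd_step
    basis <- cbind(canonical = h, tderiv = td, ddisp = dd)
  }
  attr(basis, "dt") <- dt
  attr(basis, "tr") <- tr_seconds
  basis
}

# causal convolution of a microtime stimulus train with a sampled kernel,
# keeping the first length(x) samples
convolve_stim <- function(x, kernel) {
  n <- length(x)
  out <- convolve(c(x, numeric(length(kernel))), rev(kernel), type = "open")
  out[seq_len(n)]
}
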