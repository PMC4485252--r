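.hrf_cache <- new.env(parent = emptyenv())

#' Canonical haemodynamic response function
#'
#' The canonical double-gamma HRF: a positive gamma-density lobe (shape 6,
#' rate 1) minus one sixth of a delayed gamma-density undershoot (shape 16,
#' rate 1), normalised to unit peak so that GLM betas are in signal units.
#' Support is effectively \[0, 32\] s; the function is 0 at t = 0 and peaks
#' close to 5 s.
#'
#' @param t Time(s) after event onset, in seconds (>= 0; negative inputs
#'   return 0).
#' @return HRF value(s), peak-normalised to 1.
#' @export
canonical_hrf <- function(t) {
  raw <- function(x) {
    stats::dgamma(x, shape = 6, rate = 1) -
      stats::dgamma(x, shape = 16, rate = 1) / 6
  }
  if (is.null(.hrf_cache$peak)) {
    .hrf_cache$peak <- max(raw(seq(0, 32, by = 0.001)))
  }
  out <- ifelse(t < 0, 0, raw(pmax(t, 0)))
  out / .hrf_cache$peak
}
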