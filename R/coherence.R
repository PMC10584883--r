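#' Cardiorespiratory phase coherence
#'
#' \eqn{\lambda(t_k) = | \frac{1}{N} \sum_j e^{i\psi_j} |^2} over the
#' trailing window of `N` samples ending at `t_k`, where `psi` is the
#' instantaneous phase difference between RSA and respiration. `lambda` is 1
#' for perfect phase locking and has expectation `1/N` for independent
#' uniform phase differences. The first `N - 1` positions use the available
#' (shrinking) trailing window; interior values are unaffected.
#'
#' @param psi phase-difference series, radians
#' @param n_window window length `N` in samples (`>= 2`); the default 100
#'   corresponds to 10 s at the 10 Hz analysis rate
#' @return numeric series in `[0, 1]`, same length as `psi`
#' @export
phase_coherence <- function(psi, n_window = 100) {
  stopifnot(n_window >= 2)
  n <- length(psi)
  if (n_window > n) stop("coherence window longer than the phase series")
  z <- exp(1i * psi)
  cs <- cumsum(z)
  k <- seq_len(n)
  start <- pmax(k - n_window, 0)
  sums <- cs - c(0 + 0i, cs)[start + 1]
  counts <- k - start
  lam <- Mod(sums / counts)^2
  pmin(lam, 1)
}
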