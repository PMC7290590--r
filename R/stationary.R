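#' Analytic stationary distribution of the sampler
#'
#' At fixed pH the sampler's stationary distribution over insertion depth and
#' protonation state is
#' `pi(d, s) / Z = exp(-U_s(d)) * 10^(s * (pKa_water - pH)) / Z`, with `Z`
#' obtained by 1D numerical integration over `d` for both states.
#' `stationary_bin_probabilities()` integrates this density over half-open
#' depth bins, yielding the exact expected occupancies against which
#' simulated (d, s) histograms can be compared.
#'
#' @param config a [sim_config()] object.
#' @param pH imposed pH.
#' @param breaks increasing vector of bin edges for `d`.
#' @return a data.frame with `d_lo`, `d_hi`, `prot_state` and `prob` (the
#'   probabilities over all `(bin, state)` cells sum to the probability mass
#'   inside `range(breaks)`).
#' @export
stationary_bin_probabilities <- function(config, pH, breaks) {
  stopifnot(length(breaks) >= 2, !is.unsorted(breaks))
  dens <- function(d, s) {
    exp(-potential_energy(d, s, config)) * 10^(s * (config$pka_water - pH))
  }
  lo_all <- config$walls$water - 15
  hi_all <- config$walls$deep + 15
  Z <- sum(vapply(0:1, function(s) {
    stats::integrate(dens, lo_all, hi_all, s = s, rel.tol = 1e-10,
                     subdivisions = 500L)$value
  }, 0))
  out <- expand.grid(i = seq_len(length(breaks) - 1), prot_state = 0:1)
  out$d_lo <- breaks[out$i]
  out$d_hi <- breaks[out$i + 1]
  out$prob <- mapply(function(i, s) {
    stats::integrate(dens, breaks[i], breaks[i + 1], s = s, rel.tol = 1e-10,
                     subdivisions = 500L)$value / Z
  }, out$i, out$prot_state)
  out$i <- NULL
  out[, c("d_lo", "d_hi", "prot_state", "prob")]
}
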