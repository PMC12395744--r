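#' Probability/odds conversions
#'
#' @param p Probability(ies) strictly in (0, 1).
#' @param o Odds, strictly positive.
#' @return `to_odds()` returns `p/(1-p)`; `odds_to_prob()` its inverse
#'   `o/(1+o)`.
#' @export
to_odds <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p >= 1)) {
    stop("probability must lie strictly in (0, 1)")
  }
  p / (1 - p)
}

#' @rdname to_odds
#' @export
odds_to_prob <- function(o) {
  if (any(!is.finite(o) | o <= 0)) stop("odds must be finite and > 0")
  o / (1 + o)
}

#' Bayesian combination of clinical risk and PRS
#'
#' The clinical 5-year risk is taken as the prior probability of breast
#' cancer; the mean-centered PRS acts as a likelihood-ratio multiplier on
#' the prior odds:
#' \deqn{\mathrm{posterior\ odds} = \frac{p}{1-p} \cdot \mathrm{PRS}^\alpha}
#' with \eqn{\alpha = 1} by default. A PRS of exactly 1 (the population
#' mean) leaves the clinical risk unchanged. The optional attenuation
#' exponent `alpha` allows calibrations that shrink the PRS effect (for
#' instance in the presence of family history) to be expressed; no such
#' attenuation is applied by default, and no PRS-by-family-history or
#' PRS-by-density interaction is modelled.
#'
#' @param bcsc_5yr Prior (clinical) 5-year risk(s), strictly in (0, 1).
#' @param prs Centered PRS value(s), > 0.
#' @param alpha Attenuation exponent on the PRS (default 1).
#' @return Posterior probability(ies), strictly inside (0, 1).
#' @export
combine_bcsc_prs <- function(bcsc_5yr, prs, alpha = 1) {
  if (any(!is.finite(prs) | prs <= 0)) stop("prs must be finite and > 0")
  odds_to_prob(to_odds(bcsc_5yr) * prs^alpha)
}
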