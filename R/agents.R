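#' Stochastic yes/no decision ("dice roll")
#'
#' Every stochastic cell behaviour is decided by comparing one uniform draw
#' with the behaviour's probability; exactly one draw from R's global RNG
#' is consumed per call.
#'
#' @param p probability in `[0, 1]`.
#' @return `TRUE` with probability `p`.
#' @export
decide <- function(p) {
  stopifnot(length(p) == 1L, p >= 0, p <= 1)
  runif(1) < p
}

#' MIC division fate draw
#'
#' A dividing MIC either self-renews (two MIC daughters), divides
#' asymmetrically (one MIC, one PC) or differentiates (two PCs). One
#' categorical draw against the fate triple.
#'
#' @param probs numeric triple `(self, asym, diff)` summing to 1.
#' @return One of `"SELF_RENEW"`, `"ASYMMETRIC"`, `"DIFFERENTIATE"`.
#' @export
mic_division_fate <- function(probs) {
  stopifnot(length(probs) == 3L, all(probs >= 0),
            abs(sum(probs) - 1) < 1e-9)
  u <- runif(1)
  if (u < probs[1]) "SELF_RENEW"
  else if (u < probs[1] + probs[2]) "ASYMMETRIC"
  else "DIFFERENTIATE"
}

#' Choose a migration or daughter-placement site
#'
#' Among the free in-domain sites within Chebyshev distance
#' `search_distance` of a cell, samples one with weight
#' `exp(beta * E(site))` — cells with positive `beta` preferentially move
#' toward stiffer stroma. Returns `NA` when no free site exists (the
#' no-space signal: a blocked M-phase cell retries next step).
#'
#' @param site the cell's current linear site index.
#' @param state an `mm_lattice` state.
#' @param search_distance Chebyshev reach in sites.
#' @param beta stiffness-preference coefficient.
#' @return A linear site index, or `NA_integer_`.
#' @export
choose_target_site <- function(site, state, search_distance, beta) {
  g <- state$geometry
  occ <- as.integer(state$occupancy != 0L)
  cpp_choose_target(as.integer(site), as.integer(search_distance), occ,
                    as.numeric(state$stiffness), beta,
                    c(g$nx, g$ny, g$nz), as.logical(g$domain_mask))
}
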