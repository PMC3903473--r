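#' Advance the SDF-1 field by one macro time step
#'
#' Advances `dS/dt = D Lap(S) + secretion - lambda S` (secretion
#' `sigma` per hour at each MIC-occupied site) by one macro step with the
#' explicit 7-point forward-time central-space scheme, sub-stepped so that
#' `dt_sub * (6 D / spacing^2 + lambda) <= 1` — in particular
#' `D * dt_sub / spacing^2 <= 1/6` — and re-imposes the Dirichlet boundary
#' value on out-of-domain sites after each macro step. Because diffusion,
#' secretion and decay advance together within every sub-step, the scheme's
#' fixed point is exactly the steady discrete reaction-diffusion equation
#' on the lattice. A reflecting (zero-flux) mode is provided as a solver
#' self-check for mass conservation; the model itself always uses the
#' Dirichlet sink boundary.
#'
#' @param field SDF-1 concentration array (same dimensions as the lattice).
#' @param mic_sites integer vector of linear site indices currently occupied
#'   by live, non-dying MICs (the only secreting type).
#' @param p an [sdf1_params()].
#' @param dt macro step in hours.
#' @param spacing lattice spacing in micrometres.
#' @param mask domain mask (from the geometry).
#' @param reflecting use zero-flux boundaries instead of Dirichlet
#'   (self-check mode only).
#' @return Updated concentration array (non-negative everywhere).
#' @export
step_sdf1 <- function(field, mic_sites, p, dt, spacing, mask,
                      reflecting = FALSE) {
  stopifnot(inherits(p, "sdf1_params"), dt > 0)
  dims <- dim(field)
  out <- cpp_step_sdf1(as.numeric(field), as.integer(dims),
                       as.logical(mask), as.integer(mic_sites),
                       p$D, p$lambda, p$sigma, p$S_boundary, dt, spacing,
                       reflecting)
  array(out, dims)
}

#' Locally sensed SDF-1
#'
#' Mean of the field over the in-domain Chebyshev neighbourhood of a site
#' (radius 0 returns the site value itself). This is what a stromal cell
#' "sees" when it decides how far to contract.
#'
#' @param field concentration array.
#' @param site linear site index (1-based).
#' @param radius Chebyshev sensing radius in sites.
#' @param mask domain mask; defaults to all-in.
#' @return Scalar mean concentration.
#' @export
local_sdf1 <- function(field, site, radius = 1L, mask = NULL) {
  dims <- dim(field)
  if (is.null(mask)) mask <- array(TRUE, dims)
  if (!mask[site]) stop("site is outside the domain")
  m <- cpp_box_mean(as.numeric(field), as.integer(dims), as.logical(mask),
                    as.integer(radius))
  m[site]
}
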