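#' Hill transfer functions
#'
#' Saturating transfer functions map a microenvironmental input (SDF-1
#' concentration, niche stiffness, drug dose) to a bounded response such as a
#' per-step behaviour probability or a fractional stromal activation. Every
#' response in the model is of the form
#' `floor + (ceiling - floor) * x^n / (K^n + x^n)`, so baselines and
#' saturation levels are parameters rather than hard-coded constants.
#'
#' @param K half-maximal input, same units as the input; must be positive.
#' @param n Hill coefficient (cooperativity), `n >= 1`.
#' @param floor,ceiling output bounds in `[0, 1]`, `floor <= ceiling`.
#' @return An object of class `hill_response`.
#' @examples
#' r <- hill_response(K = 2, n = 2)
#' hill(c(0, 2, 1e6), r) # floor, midpoint, ceiling
#' @export
hill_response <- function(K, n = 1, floor = 0, ceiling = 1) {
  stopifnot(is.numeric(K), length(K) == 1L, K > 0,
            is.numeric(n), length(n) == 1L, n >= 1,
            floor >= 0, ceiling <= 1, floor <= ceiling)
  structure(list(K = K, n = n, floor = floor, ceiling = ceiling),
            class = "hill_response")
}

#' Evaluate a Hill response
#'
#' @param x non-negative input (vectorised).
#' @param r a [hill_response()].
#' @return Response values in `[floor, ceiling]`, monotone non-decreasing
#'   in `x`.
#' @export
hill <- function(x, r) {
  stopifnot(inherits(r, "hill_response"))
  if (any(x < 0)) stop("hill() input must be non-negative")
  cpp_hill(as.numeric(x), r$K, r$n, r$floor, r$ceiling)
}

#' @export
print.hill_response <- function(x, ...) {
  cat(sprintf("Hill response: K = %g, n = %g, range [%g, %g]\n",
              x$K, x$n, x$floor, x$ceiling))
  invisible(x)
}

as_hill <- function(x) {
  if (inherits(x, "hill_response")) return(x)
  hill_response(x$K, x$n, x$floor, x$ceiling)
}
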