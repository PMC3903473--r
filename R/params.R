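#' SDF-1 reaction-diffusion parameters
#'
#' @param D diffusion coefficient (um^2/h).
#' @param lambda first-order decay rate (1/h).
#' @param sigma secretion rate per MIC (relative concentration units per
#'   site per hour).
#' @param S0 initial uniform concentration (relative units).
#' @param S_boundary fixed Dirichlet boundary value.
#' @return A list of class `sdf1_params`.
#' @export
sdf1_params <- function(D = 200, lambda = 0.3, sigma = 6, S0 = 0,
                        S_boundary = 0) {
  stopifnot(D >= 0, lambda >= 0, sigma >= 0, S0 >= 0, S_boundary >= 0)
  structure(list(D = D, lambda = lambda, sigma = sigma, S0 = S0,
                 S_boundary = S_boundary), class = "sdf1_params")
}

#' Model parameter set
#'
#' Assembles every model constant for one niche type: the stromal
#' stiffness response to SDF-1, the SDF-1 field parameters, lineage rules
#' (passage limits, cycle lengths, apoptosis), per-type behaviour responses
#' to local stiffness, and drug potencies. Values are the shipped calibrated
#' defaults; any component can be overridden.
#'
#' Niche biology encoded here: myeloma-associated stroma (`MBMSC`) responds
#' strongly to SDF-1 (low `K`, full activation ceiling) and therefore
#' stiffens around MIC clusters, while normal stroma (`NBMSC`) is nearly
#' inert (high `K`, low ceiling), so its stiffness stays close to `E_base`.
#'
#' @param niche `"MBMSC"` (myeloma-associated) or `"NBMSC"` (normal stroma).
#' @param ... named overrides merged into the default list (nested lists are
#'   merged recursively).
#' @return A list of class `mm_params`.
#' @examples
#' p <- mm_params("NBMSC")
#' p$stiffness_response
#' @export
mm_params <- function(niche = c("MBMSC", "NBMSC"), ...) {
  niche <- match.arg(niche)
  p <- list(
    niche = niche,
    E_base = 1,
    E_max = 10,
    # stromal contraction: fractional activation as a Hill response of the
    # locally sensed effective SDF-1
    stiffness_response = if (niche == "MBMSC")
      hill_response(K = 1.2, n = 2, floor = 0, ceiling = 1)
    else
      hill_response(K = 4, n = 2, floor = 0, ceiling = 0.07),
    k_contract = 0.06,   # 1/h, first-order relaxation toward target stiffness
    sense_radius = 1,    # Chebyshev radius of paracrine sensing (sites)
    sdf1 = sdf1_params(lambda = 0.3, sigma = 5),
    K_A = 0.06,           # AMD3100 competition constant (1x dose units)
    lineage = list(
      LGN_PC = 2L,       # PC passages before maturing to MM
      LGN_MM = 1L,       # MM passages before terminal arrest
      apoptosis_duration = 20,                    # hours
      cycle_length = c(MIC = 36, PC = 30, MM = 36, TMM = Inf),   # hours
      base_apop = c(MIC = 0.0008, PC = 0.0012, MM = 0.0015,
                    TMM = 0.0040)                 # 1/h
    ),
    behavior = list(
      # per-step division-entry probability as a function of local stiffness
      div = list(
        MIC = hill_response(K = 3.5, n = 2, floor = 0.25, ceiling = 0.46),
        PC  = hill_response(K = 4, n = 2, floor = 0.25, ceiling = 0.38),
        MM  = hill_response(K = 4, n = 2, floor = 0.16, ceiling = 0.26),
        TMM = hill_response(K = 1, n = 1, floor = 0, ceiling = 0)
      ),
      # MIC self-renewal probability at division
      self = hill_response(K = 3.5, n = 2, floor = 0.32, ceiling = 0.43),
      asym_share = 0.5,  # asymmetric share of the non-self-renewal remainder
      # stiffness shields MICs from baseline apoptosis
      apop_protect = hill_response(K = 4, n = 2, floor = 0, ceiling = 0.6),
      p_mig = c(MIC = 0.18, PC = 0.13, MM = 0.09, TMM = 0.05),  # per step
      beta = c(MIC = 1.00, PC = 0.05, MM = 0.05, TMM = 0),      # exp(beta*E)
      search_distance = 2L,     # migration reach (sites, Chebyshev)
      division_distance = 1L    # daughter placement reach
    ),
    drug = list(
      # BZM dose -> per-step apoptosis increment, per cell type
      bzm = list(
        MIC = hill_response(K = 4, n = 2, floor = 0, ceiling = 1.00),
        PC  = hill_response(K = 4, n = 2, floor = 0, ceiling = 1.00),
        MM  = hill_response(K = 4, n = 2, floor = 0, ceiling = 1.00),
        TMM = hill_response(K = 4, n = 2, floor = 0, ceiling = 0.90)
      ),
      mic_resistance = 0.85,  # baseline MIC resistance multiplier, in (0, 1]
      # stiffness -> fractional reduction of the MIC drug hazard
      protection = hill_response(K = 4, n = 2, floor = 0, ceiling = 0.93)
    )
  )
  dots <- list(...)
  if (length(dots)) p <- merge_params(p, dots)
  validate_params(p)
  structure(p, class = "mm_params")
}

merge_params <- function(base, over) {
  for (nm in names(over)) {
    if (!nm %in% names(base))
      stop("unknown parameter: ", nm, call. = FALSE)
    if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
        !inherits(base[[nm]], "hill_response") &&
        !inherits(over[[nm]], "hill_response")) {
      base[[nm]] <- merge_params(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

validate_params <- function(p) {
  stopifnot(p$E_base < p$E_max, p$k_contract >= 0, p$K_A > 0,
            p$lineage$LGN_PC >= 1, p$lineage$LGN_MM >= 1,
            p$lineage$apoptosis_duration > 0,
            all(p$lineage$base_apop >= 0),
            p$behavior$asym_share >= 0, p$behavior$asym_share <= 1,
            all(p$behavior$p_mig >= 0), all(p$behavior$p_mig <= 1),
            p$behavior$search_distance >= 1,
            p$behavior$division_distance >= 1,
            p$drug$mic_resistance > 0, p$drug$mic_resistance <= 1)
  invisible(p)
}

#' @export
print.mm_params <- function(x, ...) {
  cat(sprintf("Myeloma niche parameter set (%s)\n", x$niche))
  cat(sprintf("  stiffness range [%g, %g]; contraction rate %g/h\n",
              x$E_base, x$E_max, x$k_contract))
  cat(sprintf("  SDF-1: D = %g um^2/h, decay %g/h, secretion %g/h per MIC\n",
              x$sdf1$D, x$sdf1$lambda, x$sdf1$sigma))
  cat(sprintf("  lineage: LGN_PC = %d, LGN_MM = %d, apoptosis %g h\n",
              x$lineage$LGN_PC, x$lineage$LGN_MM,
              x$lineage$apoptosis_duration))
  invisible(x)
}

# flatten an mm_params into the list consumed by the C++ step
flatten_params <- function(p) {
  hp <- function(r) c(r$K, r$n, r$floor, r$ceiling)
  bh <- p$behavior
  list(
    cycle_len = as.numeric(p$lineage$cycle_length[c("MIC", "PC", "MM", "TMM")]),
    p_mig = as.numeric(bh$p_mig[c("MIC", "PC", "MM", "TMM")]),
    beta = as.numeric(bh$beta[c("MIC", "PC", "MM", "TMM")]),
    base_apop = as.numeric(p$lineage$base_apop[c("MIC", "PC", "MM", "TMM")]),
    div_K = vapply(bh$div, function(r) r$K, 0)[c("MIC", "PC", "MM", "TMM")],
    div_n = vapply(bh$div, function(r) r$n, 0)[c("MIC", "PC", "MM", "TMM")],
    div_lo = vapply(bh$div, function(r) r$floor, 0)[c("MIC", "PC", "MM", "TMM")],
    div_hi = vapply(bh$div, function(r) r$ceiling, 0)[c("MIC", "PC", "MM", "TMM")],
    self_par = hp(bh$self),
    asym_share = bh$asym_share,
    apop_prot = hp(bh$apop_protect),
    bzm_K = vapply(p$drug$bzm, function(r) r$K, 0)[c("MIC", "PC", "MM", "TMM")],
    bzm_n = vapply(p$drug$bzm, function(r) r$n, 0)[c("MIC", "PC", "MM", "TMM")],
    bzm_hi = vapply(p$drug$bzm, function(r) r$ceiling, 0)[c("MIC", "PC", "MM", "TMM")],
    mic_resist = p$drug$mic_resistance,
    prot = hp(p$drug$protection),
    lgn_pc = as.integer(p$lineage$LGN_PC),
    lgn_mm = as.integer(p$lineage$LGN_MM),
    apop_dur = p$lineage$apoptosis_duration,
    mig_dist = as.integer(bh$search_distance),
    div_dist = as.integer(bh$division_distance)
  )
}
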