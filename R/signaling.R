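#' Effective SDF-1 under AMD3100 competition
#'
#' AMD3100 is a competitive CXCR4 antagonist: it does not kill cells but
#' competes with SDF-1 for the receptor, which rescales the ligand
#' concentration the stroma actually senses to `S / (1 + A / K_A)`
#' (classical competitive-inhibition form).
#'
#' @param S SDF-1 concentration (relative units, `>= 0`; vectorised).
#' @param A AMD3100 dose (relative 1x units, `>= 0`).
#' @param K_A competition constant in the same dose units.
#' @return Effective concentration, same shape as `S`.
#' @export
effective_sdf1 <- function(S, A, K_A) {
  if (any(S < 0) || any(A < 0) || K_A <= 0)
    stop("effective_sdf1() requires S >= 0, A >= 0, K_A > 0")
  S / (1 + A / K_A)
}

#' Target stiffness of the stromal niche
#'
#' Stromal cells contract in response to the effective SDF-1 they sense;
#' the fully relaxed state is `E_base` and full contraction `E_max`, with
#' the fractional activation given by the niche's Hill response. The
#' myeloma-associated parameterisation responds at lower SDF-1 and to a
#' higher ceiling than the normal one.
#'
#' @param S_eff effective SDF-1 (vectorised).
#' @param params an [mm_params()] set (carries the niche response and the
#'   stiffness bounds).
#' @return Target stiffness in `[E_base, E_max]`.
#' @export
stiffness_target <- function(S_eff, params) {
  params$E_base + (params$E_max - params$E_base) *
    hill(S_eff, params$stiffness_response)
}

#' Relax stiffness toward its target
#'
#' First-order relaxation `E + (E_target - E) * (1 - exp(-k * dt))`:
#' monotone convergence to the target, instant contraction in the
#' `k_contract -> Inf` limit, and values always within the bounds spanned
#' by the current and target stiffness.
#'
#' @param E_now current stiffness (vectorised).
#' @param E_target target stiffness.
#' @param k_contract relaxation rate (1/h).
#' @param dt time step (hours).
#' @return Updated stiffness.
#' @export
update_stiffness <- function(E_now, E_target, k_contract, dt) {
  E_now + (E_target - E_now) * (1 - exp(-k_contract * dt))
}

#' Behaviour probabilities of a myeloma cell
#'
#' Maps a cell's type and the local niche stiffness to its per-time-step
#' behaviour probabilities: division entry (`p_div`; identically zero for
#' terminal cells), baseline apoptosis (`p_apop`, stiffness-shielded for
#' MICs), migration (`p_mig`), and, for MICs, the division fate triple
#' `(self-renewal, asymmetric, differentiation)` where self-renewal is an
#' increasing Hill response of stiffness and the remainder is split by the
#' fixed `asym_share` ratio.
#'
#' @param cell_type `"MIC"`, `"PC"`, `"MM"` or `"TMM"`.
#' @param E_local local stiffness, within `[E_base, E_max]`.
#' @param params an [mm_params()] set.
#' @param dt time step in hours (baseline apoptosis is a rate per hour).
#' @return A list with `p_div`, `p_apop`, `p_mig` and, for MICs, `fate`
#'   (a named triple summing to 1).
#' @export
myeloma_behavior <- function(cell_type, E_local, params, dt = 2) {
  if (!cell_type %in% names(CELL_TYPES))
    stop("unknown cell type: ", cell_type)
  stopifnot(E_local >= params$E_base - 1e-9, E_local <= params$E_max + 1e-9)
  bh <- params$behavior
  p_div <- hill(E_local, bh$div[[cell_type]])
  p_apop <- params$lineage$base_apop[[cell_type]] * dt
  if (cell_type == "MIC")
    p_apop <- p_apop * (1 - hill(E_local, bh$apop_protect))
  out <- list(p_div = min(p_div, 1),
              p_apop = min(max(p_apop, 0), 1),
              p_mig = bh$p_mig[[cell_type]])
  if (cell_type == "MIC") {
    p_self <- hill(E_local, bh$self)
    rest <- 1 - p_self
    fate <- c(self = p_self, asym = rest * bh$asym_share,
              diff = rest * (1 - bh$asym_share))
    out$fate <- fate / sum(fate)
  }
  out
}
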