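#' The 12-level geometric dose ladder
#'
#' Level 0 is the untreated control; levels 1..11 form a geometric sequence
#' from 0.1x to 10x of the reference (1x) dose, i.e.
#' `0.1 * 10^(0.2 * (i - 1))`, so level 6 is exactly the 1x dose.
#'
#' @return Numeric vector of the 12 multipliers (names `"0"`..`"11"`).
#' @export
dose_ladder <- function() {
  lv <- c(0, 0.1 * 10^(0.2 * (0:10)))
  names(lv) <- as.character(0:11)
  lv
}

#' Dose multiplier at a ladder index
#'
#' @param i ladder index (or vector of indices) in `0..11`.
#' @return Dose multiplier(s) relative to the 1x dose.
#' @export
ladder_level <- function(i) {
  if (any(i < 0 | i > 11 | i != round(i)))
    stop("ladder index must be an integer in 0..11")
  unname(dose_ladder()[as.character(i)])
}

#' Treatment schedule
#'
#' Drugs are delivered from `t_onset` for a `t_treat`-hour treatment period
#' followed by `t_rest` hours of rest per cycle; levels are constant within
#' the treatment window (no pharmacokinetics) and zero outside it. The
#' defaults are the clinical-style schedule: onset 200 h after seeding,
#' 400 h treatment, 500 h rest, one cycle.
#'
#' @param bzm_dose,amd_dose dose multipliers relative to 1x.
#' @param t_onset,t_treat,t_rest schedule times in hours.
#' @param n_cycles number of treatment cycles.
#' @return An object of class `mm_schedule`.
#' @export
dose_schedule <- function(bzm_dose = 0, amd_dose = 0, t_onset = 200,
                          t_treat = 400, t_rest = 500, n_cycles = 1L) {
  stopifnot(t_onset >= 0, t_treat > 0, t_rest > 0, n_cycles >= 1,
            bzm_dose >= 0, amd_dose >= 0)
  structure(list(bzm_dose = bzm_dose, amd_dose = amd_dose,
                 t_onset = t_onset, t_treat = t_treat, t_rest = t_rest,
                 n_cycles = as.integer(n_cycles)),
            class = "mm_schedule")
}

#' @export
print.mm_schedule <- function(x, ...) {
  cat(sprintf(
    "Schedule: BZM %gx + AMD %gx from %g h, %g h on / %g h off, %d cycle(s)\n",
    x$bzm_dose, x$amd_dose, x$t_onset, x$t_treat, x$t_rest, x$n_cycles))
  invisible(x)
}

#' Drug levels at a given time
#'
#' @param t time in hours.
#' @param schedule a [dose_schedule()].
#' @return Named numeric `c(bzm, amd)`.
#' @export
doses_at <- function(t, schedule) {
  s <- schedule
  on <- FALSE
  if (t >= s$t_onset) {
    rel <- t - s$t_onset
    cycle_len <- s$t_treat + s$t_rest
    cyc <- floor(rel / cycle_len)
    on <- cyc < s$n_cycles && (rel - cyc * cycle_len) < s$t_treat
  }
  if (on) c(bzm = s$bzm_dose, amd = s$amd_dose) else c(bzm = 0, amd = 0)
}

#' Drug-induced apoptosis increment
#'
#' Bortezomib adds a per-step apoptosis hazard given by a per-type Hill
#' response of the dose. MICs are intrinsically resistant
#' (`mic_resistance < 1`) and are further shielded by stiff niches: the MIC
#' increment is multiplied by `1 - hill(E_local, protection)`. AMD3100
#' contributes no direct kill; its entire effect is the reduction of
#' effective SDF-1 (see [effective_sdf1()]).
#'
#' @param cell_type `"MIC"`, `"PC"`, `"MM"` or `"TMM"`.
#' @param bzm_level Bortezomib dose (relative 1x units).
#' @param E_local local stiffness.
#' @param params an [mm_params()] set.
#' @return Per-step apoptosis probability increment in `[0, 1]`.
#' @export
drug_apoptosis <- function(cell_type, bzm_level, E_local, params) {
  if (!cell_type %in% names(CELL_TYPES))
    stop("unknown cell type: ", cell_type)
  stopifnot(bzm_level >= 0)
  h <- hill(bzm_level, params$drug$bzm[[cell_type]])
  if (cell_type == "MIC")
    h <- h * params$drug$mic_resistance *
      (1 - hill(E_local, params$drug$protection))
  min(max(h, 0), 1)
}
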