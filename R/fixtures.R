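#' Deterministic test fixtures
#'
#' Generates small, fully reproducible scenario bundles used by the test
#' suite and examples:
#'
#' * `"tiny_config"` — a 12^3-lattice configuration that simulates 40 h in
#'   well under five seconds.
#' * `"tiny_run"` — the completed `mm_sim` for that configuration.
#' * `"additive_surface"` — a synthetic Loewe-additive effect surface built
#'   from two Hill dose-effect curves by dose equivalence (combined
#'   effective dose `d_A + (K_A / K_B) * d_B`), on which the combination
#'   index is 1 by construction.
#' * `"synergistic_surface"` — the additive construction with the combined
#'   dose inflated by a potentiation factor, yielding CI < 1 off-axis.
#' * `"sweep_store"` — a pre-populated in-memory sweep store with
#'   analytically generated replicate counts (control mean 100 MICs,
#'   dose-dependent kill), for exercising the synergy pipeline without
#'   simulation.
#' * `"digital_ball"` — a solid ball of occupied sites of known radius in a
#'   31^3 array, for frontier-metric checks.
#'
#' @param kind fixture kind (see above).
#' @param seed RNG seed; identical seeds give byte-identical bundles.
#' @param ... kind-specific overrides (e.g. `radius` for the ball,
#'   `n_reps` for the store).
#' @return The fixture object.
#' @export
make_fixture <- function(kind = c("tiny_config", "tiny_run",
                                  "additive_surface",
                                  "synergistic_surface", "sweep_store",
                                  "digital_ball"),
                         seed = 1L, ...) {
  kind <- match.arg(kind)
  set.seed(as.integer(seed))
  opts <- list(...)
  switch(kind,
    tiny_config = sim_config(
      niche = "MBMSC", geometry = lattice_geometry(12, 12, 12, 20),
      t_end = 40, n_seed_per_type = 5L, record_events = TRUE),
    tiny_run = run_sim(make_fixture("tiny_config", seed), seed = seed),
    additive_surface = hill_combo_surface(potentiation = 1, seed = seed),
    synergistic_surface = hill_combo_surface(
      potentiation = if (is.null(opts$potentiation)) 3 else
        opts$potentiation, seed = seed),
    sweep_store = synthetic_sweep_store(
      n_reps = if (is.null(opts$n_reps)) 5L else opts$n_reps, seed = seed),
    digital_ball = {
      radius <- if (is.null(opts$radius)) 6 else opts$radius
      n <- if (is.null(opts$n)) 31L else opts$n
      ctr <- (n + 1) / 2
      xyz <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
      ball <- with(xyz, sqrt((x - ctr)^2 + (y - ctr)^2 + (z - ctr)^2)
                   <= radius)
      array(as.integer(ball), c(n, n, n))
    })
}

# Loewe dose-equivalence construction: with single-agent curves
# E_X(d) = d^n / (K_X^n + d^n), the additive surface is
# E(dA, dB) = E_A(dA + (K_A/K_B) dB); a potentiation factor > 1 on the
# combined dose makes every off-axis combination super-additive.
hill_combo_surface <- function(K_A = 1, K_B = 2, n = 2, potentiation = 1,
                               seed = 1L) {
  bl <- 0:11
  al <- 0:11
  bd <- ladder_level(bl)
  ad <- ladder_level(al)
  grid <- outer(bd, ad, function(dA, dB) {
    boost <- ifelse(dA > 0 & dB > 0, potentiation, 1)
    deff <- (dA + (K_A / K_B) * dB) * boost
    deff^n / (K_A^n + deff^n)
  })
  dimnames(grid) <- list(bzm = bl, amd = al)
  structure(list(grid = grid, bzm_levels = bl, amd_levels = al,
                 bzm_doses = bd, amd_doses = ad,
                 effect_kind = "mic_reduction", niche = "synthetic",
                 smoothed = FALSE, n_reps = NA_integer_),
            class = "mm_effect_surface")
}

# Analytic stand-in for a completed sweep: replicate MIC counts are
# Poisson around a dose-dependent survival surface.
synthetic_sweep_store <- function(n_reps = 5L, seed = 1L) {
  design <- sweep_design(bzm_levels = 0:11, amd_levels = 0:11,
                         niches = "MBMSC", n_reps = n_reps)
  conds <- enumerate_conditions(design)
  mic0 <- 100
  results <- lapply(seq_len(nrow(conds)), function(i) {
    cond <- conds[i, ]
    surv <- 1 / (1 + (cond$bzm_dose + 0.5 * cond$amd_dose)^2)
    mic <- stats::rpois(n_reps, mic0 * surv)
    cbind(MIC = as.integer(mic), PC = 50L, MM = 200L, TMM = 150L)
  })
  names(results) <- vapply(seq_len(nrow(conds)),
                           function(i) condition_key(conds[i, ]), "")
  structure(list(design = design, conditions = conds, results = results,
                 t_eval = 600, seed_base = as.integer(seed)),
            class = "mm_sweep")
}
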