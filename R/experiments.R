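#' Factorial dose-sweep design
#'
#' The full design crosses 12 Bortezomib dose levels with 12 AMD3100 levels
#' under both stromal niches, 20 replicates each: 288 conditions, 5,760
#' runs. The desk preset (`sweep_design("desk")`) covers dose levels
#' `{0, 2, 6, 9, 11}` at 5 replicates for routine use.
#'
#' @param preset `"full"` or `"desk"`, or leave `NULL` and give fields.
#' @param bzm_levels,amd_levels ladder indices in `0..11`.
#' @param niches subset of `c("NBMSC", "MBMSC")`.
#' @param n_reps replicates per condition.
#' @param points recorded time points per run.
#' @param quantities recorded quantities per point (five cell-type counts
#'   plus an SDF-1 field summary by default).
#' @return An object of class `mm_design`.
#' @export
sweep_design <- function(preset = NULL, bzm_levels = 0:11, amd_levels = 0:11,
                         niches = c("NBMSC", "MBMSC"), n_reps = 20L,
                         points = 400L, quantities = 6L) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("full", "desk"))
    if (preset == "desk") {
      bzm_levels <- c(0L, 2L, 6L, 9L, 11L)
      amd_levels <- c(0L, 2L, 6L, 9L, 11L)
      n_reps <- 5L
      points <- 300L
    }
  }
  stopifnot(all(bzm_levels %in% 0:11), all(amd_levels %in% 0:11),
            all(niches %in% c("NBMSC", "MBMSC")), n_reps >= 1)
  structure(list(bzm_levels = as.integer(bzm_levels),
                 amd_levels = as.integer(amd_levels),
                 niches = niches, n_reps = as.integer(n_reps),
                 points = as.integer(points),
                 quantities = as.integer(quantities)),
            class = "mm_design")
}

#' @export
print.mm_design <- function(x, ...) {
  cat(sprintf(
    "Dose sweep: %d x %d dose grid x %d niche(s), %d reps -> %d conditions, %d runs\n",
    length(x$bzm_levels), length(x$amd_levels), length(x$niches), x$n_reps,
    nrow(enumerate_conditions(x)), nrow(enumerate_conditions(x)) * x$n_reps))
  invisible(x)
}

#' Enumerate sweep conditions
#'
#' Full Cartesian product of niches and dose levels in deterministic
#' niche-major, then BZM, then AMD order.
#'
#' @param design an [sweep_design()].
#' @return Data frame with `niche`, `bzm_level`, `amd_level`, `bzm_dose`,
#'   `amd_dose` and the condition `index`.
#' @export
enumerate_conditions <- function(design) {
  grid <- expand.grid(amd_level = design$amd_levels,
                      bzm_level = design$bzm_levels,
                      niche = design$niches,
                      stringsAsFactors = FALSE)
  out <- data.frame(index = seq_len(nrow(grid)),
                    niche = grid$niche,
                    bzm_level = grid$bzm_level,
                    amd_level = grid$amd_level,
                    bzm_dose = ladder_level(grid$bzm_level),
                    amd_dose = ladder_level(grid$amd_level))
  out
}

#' Sweep record bookkeeping
#'
#' Total number of recorded data points:
#' `conditions * n_reps * points * quantities`. For the full design this is
#' the 13,824,000 records of the complete factorial experiment.
#'
#' @param design an [sweep_design()].
#' @return Total record count.
#' @export
record_budget <- function(design) {
  n_cond <- length(design$bzm_levels) * length(design$amd_levels) *
    length(design$niches)
  n_cond * design$n_reps * design$points * design$quantities
}

condition_key <- function(cond) {
  sprintf("%s_b%02d_a%02d", cond$niche, cond$bzm_level, cond$amd_level)
}

#' Run a dose sweep
#'
#' Runs every condition of the design with [replicate_runs()]; per-condition
#' seeds are a deterministic function of `seed_base` and the condition
#' index, so the sweep is reproducible and executor-independent. When `dir`
#' is given the per-condition final-count tables are persisted as CSV and
#' completed conditions are skipped on restart (resumable store).
#'
#' @param design an [sweep_design()].
#' @param base_config an [sim_config()] template (its schedule's dose fields
#'   are overridden per condition; its `t_end` sets the evaluation time).
#' @param seed_base base seed.
#' @param dir optional store directory for resumable execution.
#' @param executor an `lapply`-compatible function applying the run over the
#'   condition list (swap in a parallel variant if desired).
#' @param progress print one line per condition.
#' @return An object of class `mm_sweep`: `conditions`, per-condition
#'   `results` (replicate x type final-count matrices), `t_eval`, `design`.
#' @export
run_sweep <- function(design, base_config, seed_base = 1L, dir = NULL,
                      executor = lapply, progress = FALSE) {
  conds <- enumerate_conditions(design)
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  if (!is.null(dir)) {
    manifest <- list(seed_base = as.integer(seed_base),
                     t_eval = base_config$t_end,
                     n_reps = design$n_reps,
                     bzm_levels = design$bzm_levels,
                     amd_levels = design$amd_levels,
                     niches = design$niches)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE)
  }

  run_condition <- function(i) {
    cond <- conds[i, ]
    key <- condition_key(cond)
    if (!is.null(dir)) {
      f <- file.path(dir, paste0(key, ".csv"))
      if (file.exists(f)) {
        m <- as.matrix(read.csv(f))
        storage.mode(m) <- "integer"
        return(m)
      }
    }
    cfg <- base_config
    cfg$niche <- cond$niche
    cfg$params <- mm_params(cond$niche)
    cfg$schedule$bzm_dose <- cond$bzm_dose
    cfg$schedule$amd_dose <- cond$amd_dose
    reps <- replicate_runs(cfg, design$n_reps,
                           seed_base = as.integer(seed_base) +
                             1000L * (cond$index - 1L))
    if (progress)
      message(sprintf("[%d/%d] %s: mean MIC %.1f", i, nrow(conds), key,
                      mean(reps$final[, "MIC"])))
    m <- reps$final
    if (!is.null(dir))
      write.csv(as.data.frame(m), file.path(dir, paste0(key, ".csv")),
                row.names = FALSE)
    m
  }

  results <- executor(seq_len(nrow(conds)), run_condition)
  names(results) <- vapply(seq_len(nrow(conds)),
                           function(i) condition_key(conds[i, ]), "")
  structure(list(design = design, conditions = conds, results = results,
                 t_eval = base_config$t_end, seed_base = as.integer(seed_base)),
            class = "mm_sweep")
}

#' @export
print.mm_sweep <- function(x, ...) {
  cat(sprintf("Dose-sweep store: %d conditions x %d reps at t = %g h\n",
              nrow(x$conditions), x$design$n_reps, x$t_eval))
  invisible(x)
}

sweep_complete <- function(store, niche) {
  conds <- store$conditions[store$conditions$niche == niche, ]
  missing <- conds[!vapply(seq_len(nrow(conds)), function(i) {
    key <- condition_key(conds[i, ])
    !is.null(store$results[[key]]) &&
      nrow(store$results[[key]]) == store$design$n_reps
  }, TRUE), ]
  if (nrow(missing))
    stop("sweep store incomplete for niche ", niche, ": missing ",
         nrow(missing), " condition(s)")
  invisible(TRUE)
}
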