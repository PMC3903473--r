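#' Simulation configuration
#'
#' Bundles the lattice geometry, niche parameter set, treatment schedule and
#' run controls for one simulation. Time resolution is 2 h; the tumour is
#' seeded as a mixed central sphere of 100 cells per myeloma type.
#'
#' @param niche `"MBMSC"` or `"NBMSC"`.
#' @param geometry a [lattice_geometry()].
#' @param params an [mm_params()]; defaults to the shipped calibrated set
#'   for `niche`.
#' @param schedule a [dose_schedule()].
#' @param dt macro time step in hours.
#' @param t_end simulated horizon in hours (multiple of `dt`).
#' @param n_seed_per_type initial cells per myeloma type.
#' @param record_every record the population series every this many steps.
#' @param snapshot_every store a coded occupancy snapshot every this many
#'   steps (0 = never; the final state is always kept).
#' @param record_events keep the per-cell event ledger.
#' @return An object of class `mm_config`.
#' @examples
#' cfg <- sim_config("NBMSC", geometry = lattice_geometry(16, 16, 16),
#'                   t_end = 20)
#' sim <- run_sim(cfg, seed = 1)
#' tail(sim$series, 2)
#' @export
sim_config <- function(niche = c("MBMSC", "NBMSC"),
                       geometry = lattice_geometry(),
                       params = NULL,
                       schedule = dose_schedule(),
                       dt = 2, t_end = 600,
                       n_seed_per_type = 100L,
                       record_every = 1L,
                       snapshot_every = 0L,
                       record_events = FALSE) {
  niche <- match.arg(niche)
  if (is.null(params)) params <- mm_params(niche)
  stopifnot(inherits(geometry, "mm_geometry"),
            inherits(params, "mm_params"),
            inherits(schedule, "mm_schedule"))
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  if (t_end < 0 || abs(t_end / dt - round(t_end / dt)) > 1e-9)
    stop("t_end must be a non-negative multiple of dt")
  if (params$niche != niche)
    stop("params$niche does not match the configured niche")
  # explicit-diffusion stability is handled by sub-stepping; reject only
  # configurations whose sub-step count would be astronomical
  if (params$sdf1$D * dt / geometry$spacing^2 > 1e5)
    stop("SDF-1 diffusion stability bound unsatisfiable at this spacing")
  structure(list(niche = niche, geometry = geometry, params = params,
                 schedule = schedule, dt = dt, t_end = t_end,
                 n_seed_per_type = n_seed_per_type,
                 record_every = as.integer(record_every),
                 snapshot_every = as.integer(snapshot_every),
                 record_events = isTRUE(record_events)),
            class = "mm_config")
}

#' @export
print.mm_config <- function(x, ...) {
  cat(sprintf("Simulation config: %s niche, %g h horizon at dt = %g h\n",
              x$niche, x$t_end, x$dt))
  print(x$geometry)
  print(x$schedule)
  invisible(x)
}

SERIES_COLS <- c("time", "MIC", "PC", "MM", "TMM", "total", "dying",
                 "mean_stiffness", "max_stiffness", "total_sdf1", "bzm",
                 "amd")

record_row <- function(t, cells, stiffness, sdf1, maskv, bzm, amd) {
  live <- cells$dying < 0
  n <- tabulate(cells$type[live], 4L)
  es <- stiffness[maskv]
  c(t, n[1], n[2], n[3], n[4], sum(n), sum(!live),
    mean(es), max(es), sum(sdf1[maskv]), bzm, amd)
}

snapshot_codes <- function(state) {
  g <- state$geometry
  snap <- array(0L, c(g$nx, g$ny, g$nz))
  cells <- state$cells
  live <- cells$dying < 0
  snap[cells$site[live]] <- cells$type[live]
  snap[cells$site[!live]] <- 5L
  snap
}

take_snapshot <- function(state, stiffness, sdf1, dims) {
  list(occupancy = snapshot_codes(state),
       stiffness = array(stiffness, dims),
       sdf1 = array(sdf1, dims))
}

#' Export simulation snapshots
#'
#' Writes the stored 3D snapshots of a run (coded occupancy grid --
#' 0 empty, 1 MIC, 2 PC, 3 MM, 4 TMM, 5 dying -- plus the stiffness and
#' SDF-1 fields, one group per recorded time point) to a compressed array
#' container (an `.rds` file, gzip-compressed by R's serializer).
#'
#' @param sim an [run_sim()] result produced with `snapshot_every > 0`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_snapshots <- function(sim, path) {
  stopifnot(inherits(sim, "mm_sim"))
  if (!length(sim$snapshots))
    stop("no snapshots recorded; set snapshot_every > 0 in the config")
  saveRDS(sim$snapshots, path, compress = "gzip")
  invisible(path)
}

#' Run one simulation
#'
#' Executes the full multi-scale loop: at every 2 h macro step the drug
#' levels are read from the schedule, the SDF-1 field is advanced
#' (secretion by MICs, diffusion, decay, Dirichlet boundary), stromal
#' stiffness relaxes toward the Hill-response target of the locally sensed
#' effective SDF-1, and then every cell is updated in a freshly shuffled
#' order (dying progression, apoptosis decision, division with fate and
#' passage rules, migration). Runs are bit-for-bit reproducible for a fixed
#' `(config, seed)`.
#'
#' @param config an [sim_config()].
#' @param seed integer RNG seed for this run.
#' @return An object of class `mm_sim`: `series` (population time series),
#'   `final_state`, optional `events` ledger and `snapshots`, plus the
#'   config and seed.
#' @export
run_sim <- function(config, seed = 1L) {
  stopifnot(inherits(config, "mm_config"))
  set.seed(as.integer(seed))
  p <- config$params
  g <- config$geometry
  dims <- c(g$nx, g$ny, g$nz)
  mask <- g$domain_mask
  dt <- config$dt
  fpar <- flatten_params(p)
  contract_f <- 1 - exp(-p$k_contract * dt)

  state <- make_lattice(g, p)
  state <- seed_tumor(state, config$n_seed_per_type, p)

  n_steps <- round(config$t_end / dt)
  events <- list()
  snapshots <- list()

  cells <- state$cells
  next_id <- state$next_id
  sdf1 <- as.numeric(state$sdf1)
  stiffness <- as.numeric(state$stiffness)
  maskv <- as.logical(mask)

  series <- matrix(NA_real_, n_steps + 1L, length(SERIES_COLS),
                   dimnames = list(NULL, SERIES_COLS))
  series[1L, ] <- record_row(0, cells, stiffness, sdf1, maskv, 0, 0)

  for (k in seq_len(n_steps)) {
    t_now <- (k - 1) * dt
    d <- doses_at(t_now, config$schedule)
    state$bzm <- d[["bzm"]]
    state$amd <- d[["amd"]]

    mic_sites <- cells$site[cells$type == 1L & cells$dying < 0]
    sdf1 <- cpp_step_sdf1(sdf1, dims, maskv, mic_sites, p$sdf1$D,
                          p$sdf1$lambda, p$sdf1$sigma, p$sdf1$S_boundary,
                          dt, g$spacing, FALSE)

    s_eff <- sdf1 / (1 + state$amd / p$K_A)
    s_loc <- cpp_box_mean(s_eff, dims, maskv, p$sense_radius)
    e_tgt <- p$E_base + (p$E_max - p$E_base) *
      cpp_hill(s_loc, p$stiffness_response$K, p$stiffness_response$n,
               p$stiffness_response$floor, p$stiffness_response$ceiling)
    stiffness <- stiffness + (e_tgt - stiffness) * contract_f
    stiffness[!maskv] <- p$E_base

    res <- cpp_cells_step(cells$id, cells$type, cells$site, cells$passage,
                          cells$cycle, cells$dying, stiffness, dims, maskv,
                          fpar, state$bzm, dt, next_id, t_now,
                          config$record_events)
    cells <- list(id = res$id, type = res$type, site = res$site,
                  passage = res$passage, cycle = res$cycle,
                  dying = res$dying)
    next_id <- res$next_id
    if (config$record_events && nrow(res$events) > 0)
      events[[length(events) + 1L]] <- res$events

    if (k %% config$record_every == 0L || k == n_steps)
      series[k + 1L, ] <- record_row(k * dt, cells, stiffness, sdf1, maskv,
                                     state$bzm, state$amd)
    if (config$snapshot_every > 0L && k %% config$snapshot_every == 0L) {
      state$cells <- cells
      snapshots[[as.character(k * dt)]] <- take_snapshot(state, stiffness,
                                                         sdf1, dims)
    }
  }
  state$cells <- cells
  state$sdf1 <- array(sdf1, dims)
  state$stiffness <- array(stiffness, dims)

  occ <- array(0L, dims)
  occ[cells$site] <- cells$id
  state$occupancy <- occ
  state$next_id <- next_id

  series_df <- as.data.frame(series[!is.na(series[, 1]), , drop = FALSE])
  for (nm in c("MIC", "PC", "MM", "TMM", "total", "dying"))
    series_df[[nm]] <- as.integer(series_df[[nm]])
  structure(list(
    series = series_df,
    final_state = state,
    events = if (config$record_events && length(events))
      do.call(rbind, events) else NULL,
    snapshots = snapshots,
    config = config, seed = as.integer(seed)
  ), class = "mm_sim")
}

#' @export
print.mm_sim <- function(x, ...) {
  last <- x$series[nrow(x$series), ]
  cat(sprintf("Myeloma niche simulation (%s, seed %d): %g h simulated\n",
              x$config$niche, x$seed, last$time))
  cat(sprintf("  final counts: %d MIC, %d PC, %d MM, %d TMM (total %d)\n",
              last$MIC, last$PC, last$MM, last$TMM, last$total))
  invisible(x)
}

#' @export
summary.mm_sim <- function(object, ...) {
  s <- object$series
  first <- s[1, ]
  last <- s[nrow(s), ]
  out <- list(niche = object$config$niche, t_end = last$time,
              initial_total = first$total, final_total = last$total,
              growth_fold = last$total / max(first$total, 1),
              final_counts = unlist(last[c("MIC", "PC", "MM", "TMM")]),
              cd138_fraction = (last$MM + last$TMM) / max(last$total, 1),
              max_stiffness = max(s$max_stiffness))
  class(out) <- "summary.mm_sim"
  out
}

#' @export
print.summary.mm_sim <- function(x, ...) {
  cat(sprintf("%s niche, %g h: total %d -> %d (%.2f-fold)\n", x$niche,
              x$t_end, x$initial_total, x$final_total, x$growth_fold))
  cat(sprintf("  final: %s; CD138+ fraction %.1f%%; peak stiffness %.2f\n",
              paste(names(x$final_counts), x$final_counts, collapse = ", "),
              100 * x$cd138_fraction, x$max_stiffness))
  invisible(x)
}

#' @export
plot.mm_sim <- function(x, ...) {
  s <- x$series
  matplot(s$time, s[, c("MIC", "PC", "MM", "TMM", "total")], type = "l",
          lty = 1, lwd = 2, col = c("#D62728", "#FF7F0E", "#2CA02C",
                                    "#1F77B4", "black"),
          xlab = "time (h)", ylab = "cell count",
          main = sprintf("Myeloma growth (%s)", x$config$niche), ...)
  legend("topleft", c("MIC", "PC", "MM", "TMM", "total"), lty = 1, lwd = 2,
         col = c("#D62728", "#FF7F0E", "#2CA02C", "#1F77B4", "black"),
         bty = "n")
  invisible(x)
}

#' Replicate runs of one condition
#'
#' Runs `n_reps` independent simulations with seeds
#' `seed_base + 0:(n_reps - 1)` and aggregates the population series
#' (mean and sd on a fixed reporting cadence, 20 h by default).
#'
#' @param config an [sim_config()].
#' @param n_reps number of replicates.
#' @param seed_base first seed.
#' @param aggregate_every reporting cadence in hours.
#' @param keep_states keep each replicate's final lattice state (memory!).
#' @return An object of class `mm_replicates` with `runs` (series per
#'   replicate), `final` (replicate x type count matrix at `t_end`),
#'   `aggregate` (mean/sd series) and the seeds used.
#' @export
replicate_runs <- function(config, n_reps = 20L, seed_base = 1L,
                           aggregate_every = 20, keep_states = FALSE) {
  stopifnot(n_reps >= 1)
  seeds <- as.integer(seed_base) + seq_len(n_reps) - 1L
  runs <- vector("list", n_reps)
  final <- matrix(0L, n_reps, 4,
                  dimnames = list(NULL, c("MIC", "PC", "MM", "TMM")))
  states <- if (keep_states) vector("list", n_reps) else NULL
  for (r in seq_len(n_reps)) {
    sim <- run_sim(config, seeds[r])
    runs[[r]] <- sim$series
    last <- sim$series[nrow(sim$series), ]
    final[r, ] <- as.integer(last[c("MIC", "PC", "MM", "TMM")])
    if (keep_states) states[[r]] <- sim$final_state
  }
  agg <- aggregate_series(runs, aggregate_every)
  structure(list(runs = runs, final = final, aggregate = agg,
                 states = states, config = config, seeds = seeds),
            class = "mm_replicates")
}

aggregate_series <- function(runs, aggregate_every) {
  times <- runs[[1]]$time
  keep <- times %% aggregate_every == 0 | times == max(times)
  cols <- c("MIC", "PC", "MM", "TMM", "total")
  arr <- vapply(runs, function(s) as.matrix(s[keep, cols]),
                matrix(0, sum(keep), length(cols)))
  mean_m <- apply(arr, c(1, 2), mean)
  sd_m <- apply(arr, c(1, 2), sd)
  colnames(sd_m) <- paste0(cols, "_sd")
  data.frame(time = times[keep], mean_m, sd_m, check.names = FALSE)
}

#' @export
print.mm_replicates <- function(x, ...) {
  cat(sprintf("%d replicate runs (%s, %g h): mean final total %.1f (sd %.1f)\n",
              length(x$runs), x$config$niche, x$config$t_end,
              mean(rowSums(x$final)), sd(rowSums(x$final))))
  cat(sprintf("  mean final MIC %.1f; MIC-free replicates: %d\n",
              mean(x$final[, "MIC"]), sum(x$final[, "MIC"] == 0)))
  invisible(x)
}
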