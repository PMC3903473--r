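#' Serialise a configuration to a plain list / YAML
#'
#' Configurations round-trip through a canonical nested-list form: Hill
#' responses become `{K, n, floor, ceiling}` maps and geometry is reduced
#' to its four defining numbers. `save_config()` then `load_config()`
#' reproduces the identical canonical configuration.
#'
#' @param config an [sim_config()].
#' @return A plain nested list.
#' @export
config_to_list <- function(config) {
  p <- config$params
  hl <- function(r) list(K = r$K, n = r$n, floor = r$floor,
                         ceiling = r$ceiling)
  list(
    niche = config$niche,
    geometry = list(nx = config$geometry$nx, ny = config$geometry$ny,
                    nz = config$geometry$nz,
                    spacing = config$geometry$spacing),
    dt = config$dt, t_end = config$t_end,
    n_seed_per_type = config$n_seed_per_type,
    record_every = config$record_every,
    snapshot_every = config$snapshot_every,
    record_events = config$record_events,
    schedule = unclass(config$schedule),
    params = list(
      E_base = p$E_base, E_max = p$E_max,
      stiffness_response = hl(p$stiffness_response),
      k_contract = p$k_contract, sense_radius = p$sense_radius,
      sdf1 = unclass(p$sdf1), K_A = p$K_A,
      lineage = list(LGN_PC = p$lineage$LGN_PC, LGN_MM = p$lineage$LGN_MM,
                     apoptosis_duration = p$lineage$apoptosis_duration,
                     cycle_length = as.list(p$lineage$cycle_length),
                     base_apop = as.list(p$lineage$base_apop)),
      behavior = list(
        div = lapply(p$behavior$div, hl),
        self = hl(p$behavior$self),
        asym_share = p$behavior$asym_share,
        apop_protect = hl(p$behavior$apop_protect),
        p_mig = as.list(p$behavior$p_mig),
        beta = as.list(p$behavior$beta),
        search_distance = p$behavior$search_distance,
        division_distance = p$behavior$division_distance),
      drug = list(bzm = lapply(p$drug$bzm, hl),
                  mic_resistance = p$drug$mic_resistance,
                  protection = hl(p$drug$protection))
    )
  )
}

list_to_config <- function(lst) {
  allowed <- c("niche", "geometry", "dt", "t_end", "n_seed_per_type",
               "record_every", "snapshot_every", "record_events",
               "schedule", "params")
  unknown <- setdiff(names(lst), allowed)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  niche <- if (is.null(lst$niche)) "MBMSC" else lst$niche
  if (!niche %in% c("MBMSC", "NBMSC"))
    stop("field 'niche' must be MBMSC or NBMSC")
  ge <- lst$geometry
  geometry <- if (is.null(ge)) lattice_geometry() else {
    unknown <- setdiff(names(ge), c("nx", "ny", "nz", "spacing"))
    if (length(unknown))
      stop("unknown geometry key(s): ", paste(unknown, collapse = ", "))
    do.call(lattice_geometry, ge)
  }
  if (!is.null(lst$dt) && (!is.numeric(lst$dt) || lst$dt <= 0))
    stop("field 'dt' must be positive")
  params <- mm_params(niche)
  if (!is.null(lst$params)) {
    pl <- lst$params
    hill_fields <- function(x) do.call(hill_response, x)
    if (!is.null(pl$stiffness_response))
      pl$stiffness_response <- hill_fields(pl$stiffness_response)
    for (nm in c("self", "apop_protect"))
      if (!is.null(pl$behavior[[nm]]))
        pl$behavior[[nm]] <- hill_fields(pl$behavior[[nm]])
    if (!is.null(pl$behavior$div))
      pl$behavior$div <- lapply(pl$behavior$div, hill_fields)
    if (!is.null(pl$drug$bzm))
      pl$drug$bzm <- lapply(pl$drug$bzm, hill_fields)
    if (!is.null(pl$drug$protection))
      pl$drug$protection <- hill_fields(pl$drug$protection)
    if (!is.null(pl$sdf1)) pl$sdf1 <- do.call(sdf1_params, pl$sdf1)
    for (nm in c("cycle_length", "base_apop"))
      if (!is.null(pl$lineage[[nm]]))
        pl$lineage[[nm]] <- unlist(pl$lineage[[nm]])
    for (nm in c("p_mig", "beta"))
      if (!is.null(pl$behavior[[nm]]))
        pl$behavior[[nm]] <- unlist(pl$behavior[[nm]])
    params <- do.call(mm_params, c(list(niche = niche), pl))
  }
  schedule <- if (is.null(lst$schedule)) dose_schedule() else
    do.call(dose_schedule, lst$schedule)
  args <- list(niche = niche, geometry = geometry, params = params,
               schedule = schedule)
  for (nm in c("dt", "t_end", "n_seed_per_type", "record_every",
               "snapshot_every", "record_events"))
    if (!is.null(lst[[nm]])) args[[nm]] <- lst[[nm]]
  do.call(sim_config, args)
}

#' Load a simulation configuration
#'
#' Parses a YAML (or JSON, a YAML subset) configuration file, applies the
#' shipped defaults for omitted fields, validates every invariant and
#' rejects unknown keys.
#'
#' @param path file path.
#' @return An [sim_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lst <- yaml::read_yaml(path)
  if (is.null(lst)) lst <- list()
  # YAML reads Inf as the string ".inf" in some emitters; normalise
  lst <- rapply(lst, function(x)
    if (is.character(x) && all(x %in% c(".inf", "Inf"))) Inf else x,
    how = "replace")
  list_to_config(lst)
}

#' Save a simulation configuration
#'
#' @param config an [sim_config()].
#' @param path destination YAML file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  lst <- config_to_list(config)
  yaml::write_yaml(lst, path)
  invisible(path)
}

# Deterministic polynomial hash (mod the Mersenne prime 2^31 - 1) of the
# canonical config serialisation; used to stamp run manifests.
config_hash <- function(config) {
  txt <- paste(deparse(config_to_list(config)), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 17
  p <- 2147483647
  for (b in bytes) h <- (h * 131 + b) %% p
  sprintf("%08x", h)
}

#' Write a run manifest
#'
#' Append-only JSON-lines manifest recording the configuration hash, seed,
#' package version, wall-clock times and output paths of a run, so any
#' output directory is reconstructible from manifest + config + seed.
#'
#' @param config the run's [sim_config()].
#' @param seed the run's seed.
#' @param outputs character vector of output paths.
#' @param path manifest file (JSON lines, appended).
#' @param status run status string.
#' @return The manifest entry, invisibly.
#' @export
write_manifest <- function(config, seed, outputs, path,
                           status = "completed") {
  entry <- list(
    config_hash = config_hash(config),
    seed = as.integer(seed),
    version = as.character(utils::packageVersion("micniche")),
    time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs, status = status)
  con <- file(path, open = "a")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE), con)
  invisible(entry)
}
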