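#' Bone-marrow lattice geometry
#'
#' The simulation domain is a cylinder embedded in an `nx x ny x nz`
#' rectangular site lattice: a site is in-domain iff the xy-distance of its
#' centre from the cylinder axis (along z) is at most
#' `min(nx, ny) * spacing / 2`. One site holds at most one myeloma cell;
#' stroma is a stationary per-site property (the stiffness field), so
#' myeloma and stroma coexist at a site.
#'
#' @param nx,ny,nz site counts per axis.
#' @param spacing site edge length in micrometres (about one myeloma cell
#'   diameter).
#' @return An object of class `mm_geometry` with the boolean `domain_mask`.
#' @examples
#' g <- lattice_geometry(20, 20, 20, spacing = 20)
#' sum(g$domain_mask)
#' @export
lattice_geometry <- function(nx = 40, ny = 40, nz = 40, spacing = 20) {
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("spacing must be a positive number")
  dims <- c(nx, ny, nz)
  if (any(dims < 1) || any(dims != round(dims)))
    stop("lattice dimensions must be positive integers")
  nx <- as.integer(nx); ny <- as.integer(ny); nz <- as.integer(nz)
  cx <- (nx + 1) / 2
  cy <- (ny + 1) / 2
  radius_sites <- min(nx, ny) / 2
  x <- rep(seq_len(nx), times = ny)
  y <- rep(seq_len(ny), each = nx)
  in_xy <- sqrt((x - cx)^2 + (y - cy)^2) <= radius_sites
  mask <- array(rep(in_xy, nz), dim = c(nx, ny, nz))
  structure(list(nx = nx, ny = ny, nz = nz, spacing = spacing,
                 center = c(cx, cy, (nz + 1) / 2),
                 radius_um = radius_sites * spacing,
                 domain_mask = mask),
            class = "mm_geometry")
}

#' @export
print.mm_geometry <- function(x, ...) {
  cat(sprintf(
    "Bone-marrow lattice: %d x %d x %d sites, %g um spacing (%d in-domain)\n",
    x$nx, x$ny, x$nz, x$spacing, sum(x$domain_mask)))
  invisible(x)
}

site_index <- function(x, y, z, g) {
  x + g$nx * (y - 1L + g$ny * (z - 1L))
}

site_coords <- function(i, g) {
  i0 <- i - 1L
  x <- i0 %% g$nx + 1L
  y <- (i0 %/% g$nx) %% g$ny + 1L
  z <- i0 %/% (g$nx * g$ny) + 1L
  cbind(x = x, y = y, z = z)
}

#' Initialise an empty lattice state
#'
#' The state couples the occupancy grid (one myeloma cell per site), the
#' relative stiffness field set by stromal contraction, the SDF-1
#' concentration field, and the spatially uniform drug levels. Stiffness is
#' initialised uniformly at `E_base`, SDF-1 at `S0`, occupancy empty, drugs
#' at zero.
#'
#' @param geometry a [lattice_geometry()].
#' @param params an [mm_params()] set.
#' @return An object of class `mm_lattice`.
#' @export
make_lattice <- function(geometry, params) {
  stopifnot(inherits(geometry, "mm_geometry"), inherits(params, "mm_params"))
  dims <- c(geometry$nx, geometry$ny, geometry$nz)
  structure(list(
    geometry = geometry,
    occupancy = array(0L, dims),
    stiffness = array(params$E_base, dims),
    sdf1 = array(params$sdf1$S0, dims),
    bzm = 0,
    amd = 0,
    cells = empty_cells(),
    next_id = 1L
  ), class = "mm_lattice")
}

empty_cells <- function() {
  list(id = integer(0), type = integer(0), site = integer(0),
       passage = integer(0), cycle = numeric(0), dying = numeric(0))
}

#' @export
print.mm_lattice <- function(x, ...) {
  print(x$geometry)
  n <- tabulate(x$cells$type, 4L)
  cat(sprintf("  cells: %d MIC, %d PC, %d MM, %d TMM (%d dying)\n",
              n[1], n[2], n[3], n[4], sum(x$cells$dying >= 0)))
  cat(sprintf("  stiffness [%g, %g]; total SDF-1 %.3g; doses BZM %g, AMD %g\n",
              min(x$stiffness), max(x$stiffness), sum(x$sdf1), x$bzm, x$amd))
  invisible(x)
}

#' Neighbouring sites on the lattice
#'
#' Moore neighbourhood of Chebyshev radius `order` around a site, restricted
#' to in-domain sites and excluding the query site, in deterministic
#' lexicographic order (x fastest) so that any downstream random tie-breaking
#' is the only stochastic element.
#'
#' @param site linear site index (1-based) or a length-3 integer coordinate.
#' @param geometry a [lattice_geometry()].
#' @param order Chebyshev radius, `>= 1`.
#' @return Integer vector of linear site indices.
#' @export
site_neighbors <- function(site, geometry, order = 1L) {
  g <- geometry
  stopifnot(order >= 1)
  if (length(site) == 3L) site <- site_index(site[1], site[2], site[3], g)
  if (site < 1 || site > length(g$domain_mask) || !g$domain_mask[site])
    stop("query site is outside the bone-marrow domain")
  xyz <- site_coords(site, g)
  r <- as.integer(order)
  off <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  x <- xyz[1, "x"] + off$dx
  y <- xyz[1, "y"] + off$dy
  z <- xyz[1, "z"] + off$dz
  ok <- x >= 1 & x <= g$nx & y >= 1 & y <= g$ny & z >= 1 & z <= g$nz
  idx <- site_index(x[ok], y[ok], z[ok], g)
  sort(idx[g$domain_mask[idx]])
}

#' Seed the initial tumour
#'
#' Places `n_per_type` cells of each myeloma type (MIC, PC, MM, TMM) on the
#' free in-domain sites nearest the domain centre, forming a compact mixed
#' sphere; distance ties are broken at random, and the type assignment over
#' the chosen sites is a random permutation. Division clocks are randomised
#' uniformly over each type's cycle length to avoid synchronised divisions;
#' passage counts start at zero. Uses R's global RNG.
#'
#' @param state an [make_lattice()] state.
#' @param n_per_type scalar count per type, or a named vector with entries
#'   `MIC`, `PC`, `MM`, `TMM`.
#' @param params an [mm_params()] set.
#' @return The updated state.
#' @export
seed_tumor <- function(state, n_per_type, params) {
  stopifnot(inherits(state, "mm_lattice"))
  if (length(n_per_type) == 1L && is.null(names(n_per_type)))
    n_per_type <- setNames(rep(as.integer(n_per_type), 4), names(CELL_TYPES))
  n_per_type <- n_per_type[names(CELL_TYPES)]
  n_per_type[is.na(n_per_type)] <- 0L
  n_total <- sum(n_per_type)
  if (n_total == 0L) return(state)

  g <- state$geometry
  free <- which(g$domain_mask & state$occupancy == 0L)
  if (length(free) < n_total)
    stop("not enough free in-domain sites to seed the tumour")
  xyz <- site_coords(free, g)
  d <- sqrt((xyz[, "x"] - g$center[1])^2 + (xyz[, "y"] - g$center[2])^2 +
              (xyz[, "z"] - g$center[3])^2)
  ord <- order(d, runif(length(d)))
  sites <- free[ord[seq_len(n_total)]]

  types <- rep(CELL_TYPES, times = n_per_type)
  types <- sample(types, n_total)
  cyc_len <- params$lineage$cycle_length[type_name(types)]
  cycle <- ifelse(is.finite(cyc_len), runif(n_total) * cyc_len, Inf)

  ids <- state$next_id - 1L + seq_len(n_total)
  state$cells <- list(id = as.integer(ids), type = as.integer(types),
                      site = as.integer(sites),
                      passage = integer(n_total),
                      cycle = as.numeric(cycle),
                      dying = rep(-1, n_total))
  state$next_id <- state$next_id + n_total
  state$occupancy[sites] <- ids
  state
}
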