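# Independent oracles and small shared fixtures for the test suite.

# Dense linear-solve oracle for the steady SDF-1 field:
#   0 = D * Lap(S) - lambda * S + sources, Dirichlet S = S_b outside the mask.
# Assembled with Matrix and solved directly; independent of the explicit
# time stepper it checks.
steady_sdf1_oracle <- function(dims, mask, source_sites, p, spacing) {
  n <- prod(dims)
  idx_in <- which(mask)
  pos <- match(seq_len(n), idx_in)  # site -> row in the reduced system
  coords <- arrayInd(idx_in, dims)
  m <- length(idx_in)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  rhs <- numeric(m)
  h2 <- spacing^2
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                c(0, 0, -1), c(0, 0, 1))
  for (r in seq_len(m)) {
    diag_val <- -p$lambda - 6 * p$D / h2
    for (q in 1:6) {
      nb <- coords[r, ] + offs[q, ]
      if (any(nb < 1) || any(nb > dims)) next  # Dirichlet S_boundary
      j <- nb[1] + dims[1] * (nb[2] - 1 + dims[2] * (nb[3] - 1))
      if (!mask[j]) {
        rhs[r] <- rhs[r] - p$D / h2 * p$S_boundary
      } else {
        trip_i <- c(trip_i, r); trip_j <- c(trip_j, pos[j])
        trip_x <- c(trip_x, p$D / h2)
      }
    }
    if (p$S_boundary != 0) {
      n_out <- sum(vapply(1:6, function(q) {
        nb <- coords[r, ] + offs[q, ]
        any(nb < 1) || any(nb > dims)
      }, TRUE))
      rhs[r] <- rhs[r] - n_out * p$D / h2 * p$S_boundary
    }
    trip_i <- c(trip_i, r); trip_j <- c(trip_j, r); trip_x <- c(trip_x, diag_val)
  }
  for (s in source_sites)
    rhs[pos[s]] <- rhs[pos[s]] - p$sigma
  A <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(m, m))
  sol <- as.numeric(Matrix::solve(A, rhs))
  out <- array(p$S_boundary, dims)
  out[idx_in] <- sol
  out
}

# Run a field to quasi-steady state with the production stepper.
iterate_sdf1 <- function(field, sites, p, dt, spacing, mask, n = 400) {
  for (i in seq_len(n))
    field <- step_sdf1(field, sites, p, dt, spacing, mask)
  field
}

tiny_geometry <- function(n = 12, spacing = 20)
  lattice_geometry(n, n, n, spacing)

# Small engine config for trace-level tests.
trace_config <- function(niche = "MBMSC", t_end = 60, n_seed = 10L, ...) {
  sim_config(niche, geometry = lattice_geometry(14, 14, 14),
             t_end = t_end, n_seed_per_type = n_seed,
             record_events = TRUE, ...)
}

# Audit an event ledger against the observed type counts of a run:
# every change in per-type population must be explained by recorded
# birth / conversion / removal events.
audit_ledger <- function(sim) {
  ev <- sim$events
  s <- sim$series
  init <- as.integer(s[1, c("MIC", "PC", "MM", "TMM")])
  delta <- integer(4)
  if (!is.null(ev)) {
    for (r in seq_len(nrow(ev))) {
      code <- ev[r, "event"]
      from <- ev[r, "from"]; to <- ev[r, "to"]
      if (code == 1) delta[to] <- delta[to] + 1L            # birth
      else if (code == 3) {                                 # conversion
        delta[from] <- delta[from] - 1L
        delta[to] <- delta[to] + 1L
      } else if (code == 5) delta[from] <- delta[from] - 1L # removal
    }
  }
  final_live <- init + delta
  # dying cells keep their type until removal; add them back per type
  cells <- sim$final_state$cells
  observed <- tabulate(cells$type, 4L)
  list(expected = final_live, observed = observed)
}
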