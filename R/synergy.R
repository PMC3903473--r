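#' Dose-effect surface from a sweep store
#'
#' Builds the |BZM levels| x |AMD levels| effect grid for one niche from the
#' replicate final counts of a completed sweep. Effect kinds:
#' `mic_reduction` is `1 - mean MIC / mean MIC(control)` at the evaluation
#' time, `tumor_reduction` the same for the total population, and
#' `mic_eradication` the fraction of replicates ending with zero MICs (the
#' estimable per-replicate version of complete MIC elimination). Values are
#' clamped to `[0, 1]`.
#'
#' @param store an [run_sweep()] result.
#' @param effect_kind one of `"mic_reduction"`, `"mic_eradication"`,
#'   `"tumor_reduction"`.
#' @param niche which niche's conditions to use.
#' @return An object of class `mm_effect_surface`: the effect `grid` with
#'   BZM levels as rows and AMD levels as columns, the dose vectors, and
#'   metadata.
#' @export
effect_surface <- function(store,
                           effect_kind = c("mic_reduction",
                                           "mic_eradication",
                                           "tumor_reduction"),
                           niche = "MBMSC") {
  effect_kind <- match.arg(effect_kind)
  stopifnot(inherits(store, "mm_sweep"))
  sweep_complete(store, niche)
  bl <- store$design$bzm_levels
  al <- store$design$amd_levels
  if (!(0L %in% bl) || !(0L %in% al))
    stop("effect surfaces need the zero-dose control row and column")
  grid <- matrix(NA_real_, length(bl), length(al),
                 dimnames = list(bzm = bl, amd = al))
  get_final <- function(b, a) {
    key <- sprintf("%s_b%02d_a%02d", niche, b, a)
    store$results[[key]]
  }
  ctrl <- get_final(0L, 0L)
  ctrl_mic <- mean(ctrl[, "MIC"])
  ctrl_tot <- mean(rowSums(ctrl))
  for (i in seq_along(bl)) {
    for (j in seq_along(al)) {
      m <- get_final(bl[i], al[j])
      grid[i, j] <- switch(effect_kind,
        mic_reduction = 1 - mean(m[, "MIC"]) / max(ctrl_mic, 1e-12),
        tumor_reduction = 1 - mean(rowSums(m)) / max(ctrl_tot, 1e-12),
        mic_eradication = mean(m[, "MIC"] == 0))
    }
  }
  grid <- pmin(pmax(grid, 0), 1)
  structure(list(grid = grid, bzm_levels = bl, amd_levels = al,
                 bzm_doses = ladder_level(bl), amd_doses = ladder_level(al),
                 effect_kind = effect_kind, niche = niche,
                 smoothed = FALSE, n_reps = store$design$n_reps),
            class = "mm_effect_surface")
}

#' @export
print.mm_effect_surface <- function(x, ...) {
  cat(sprintf("%s effect surface (%s niche%s), %d x %d dose grid\n",
              x$effect_kind, x$niche,
              if (x$smoothed) ", smoothed" else "",
              nrow(x$grid), ncol(x$grid)))
  print(round(x$grid, 3))
  invisible(x)
}

#' @export
plot.mm_effect_surface <- function(x, levels = c(0.5, 0.999), ...) {
  image(seq_len(nrow(x$grid)), seq_len(ncol(x$grid)), x$grid,
        col = hcl.colors(64, "YlOrRd", rev = TRUE),
        xlab = "BZM ladder level", ylab = "AMD ladder level", axes = FALSE,
        main = sprintf("%s (%s)", x$effect_kind, x$niche), ...)
  axis(1, seq_len(nrow(x$grid)), labels = x$bzm_levels)
  axis(2, seq_len(ncol(x$grid)), labels = x$amd_levels)
  for (lv in levels) {
    cl <- contourLines(seq_len(nrow(x$grid)), seq_len(ncol(x$grid)), x$grid,
                       levels = lv)
    for (ctr in cl) lines(ctr$x, ctr$y, lwd = 2,
                          col = if (lv >= 0.999) "darkgreen" else "red")
  }
  invisible(x)
}

#' Gaussian smoothing of an effect surface
#'
#' 2D Gaussian convolution with standard deviation `theta` in grid-index
#' units. The kernel is renormalised over the in-grid support at edges, so
#' constant surfaces pass through unchanged and there is no padding bias;
#' output is re-clamped to `[0, 1]`. Used for robust visualisation only —
#' combination-index arithmetic always runs on raw (monotonised) surfaces.
#'
#' @param surface an [effect_surface()].
#' @param theta kernel standard deviation in index units.
#' @return A smoothed `mm_effect_surface`.
#' @export
smooth_surface <- function(surface, theta = 2) {
  stopifnot(inherits(surface, "mm_effect_surface"), theta >= 0)
  g <- surface$grid
  if (theta == 0) return(surface)
  n <- nrow(g); m <- ncol(g)
  r <- max(1L, ceiling(3 * theta))
  out <- matrix(0, n, m, dimnames = dimnames(g))
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      ii <- max(1, i - r):min(n, i + r)
      jj <- max(1, j - r):min(m, j + r)
      w <- outer(exp(-(ii - i)^2 / (2 * theta^2)),
                 exp(-(jj - j)^2 / (2 * theta^2)))
      out[i, j] <- sum(w * g[ii, jj, drop = FALSE]) / sum(w)
    }
  }
  surface$grid <- pmin(pmax(out, 0), 1)
  surface$smoothed <- TRUE
  surface
}

#' Iso-effect contour (isobole) extraction
#'
#' Marching-squares contour of the surface at an effect level, with linear
#' interpolation between grid nodes. Contours are computed in grid-index
#' space and mapped to dose space through the ladder; the zero-dose
#' row/column is anchored at a pseudo-dose of half the lowest ladder level
#' for the log-scaled dose coordinates (plotting convenience only — never
#' used in combination-index arithmetic). E100 on an eradication surface is
#' conventionally queried as `level = 0.999`.
#'
#' @param surface an [effect_surface()].
#' @param level effect level in `(0, 1]`.
#' @return A list of contour polylines, each a data frame with index
#'   coordinates (`bzm_index`, `amd_index`, 1-based fractional) and dose
#'   coordinates (`bzm_dose`, `amd_dose`); empty list when the level is
#'   never reached.
#' @export
isobole <- function(surface, level) {
  stopifnot(inherits(surface, "mm_effect_surface"), level > 0, level <= 1)
  g <- surface$grid
  cl <- contourLines(seq_len(nrow(g)), seq_len(ncol(g)), g, levels = level)
  pseudo <- function(doses) {
    lo <- min(doses[doses > 0])
    ifelse(doses == 0, lo / 2, doses)
  }
  bd <- pseudo(surface$bzm_doses)
  ad <- pseudo(surface$amd_doses)
  idx_to_dose <- function(idx, doses) {
    # linear interpolation of log-dose between grid nodes
    exp(approx(seq_along(doses), log(doses), xout = idx, rule = 2)$y)
  }
  lapply(cl, function(ctr) {
    data.frame(bzm_index = ctr$x, amd_index = ctr$y,
               bzm_dose = idx_to_dose(ctr$x, bd),
               amd_dose = idx_to_dose(ctr$y, ad))
  })
}

# Interpolated single-agent dose achieving `level` on a monotonised
# dose-effect curve; NA when the level is never reached. Inversion runs on
# the log-dose axis (the ladder is geometric), falling back to linear dose
# when the crossing involves the zero-dose control point.
single_agent_dose <- function(doses, effects, level) {
  ord <- order(doses)
  doses <- doses[ord]
  effects <- effects[ord]
  iso <- isoreg(doses, effects)$yf
  if (max(iso) < level) return(NA_real_)
  k <- which(iso >= level)[1]
  if (k == 1L) return(doses[1])
  if (iso[k] == iso[k - 1]) return(doses[k])
  w <- (level - iso[k - 1]) / (iso[k] - iso[k - 1])
  if (doses[k - 1] > 0)
    exp(log(doses[k - 1]) + w * (log(doses[k]) - log(doses[k - 1])))
  else
    doses[k - 1] + w * (doses[k] - doses[k - 1])
}

#' Loewe combination index
#'
#' Dose-equivalence synergy index
#' `CI = d_A / D_A(E) + d_B / D_B(E)`, where `D_X(E)` is the single-agent
#' dose of drug X achieving effect `E` (interpolated on the monotonised
#' zero-partner row/column of the surface). `CI < 1` indicates synergy,
#' `CI = 1` Loewe additivity, `CI > 1` antagonism. When `level` is omitted
#' the combination's own effect (the surface value at that grid point) is
#' used, which equals 1 everywhere on an additive reference surface.
#'
#' An agent that never reaches the level on its own contributes a vanishing
#' term (its equivalent dose is effectively infinite) — the AMD3100/E100
#' situation, where eradication is unreachable by the niche inhibitor
#' alone. The index is `NA` (undefined) only when no positive-dose agent
#' has a finite equivalent dose.
#'
#' @param d_A,d_B Bortezomib and AMD3100 doses of the combination
#'   (1x units).
#' @param surface an [effect_surface()] (raw, not smoothed).
#' @param level effect level; default the surface effect at `(d_A, d_B)`.
#' @return The combination index (possibly `NA`).
#' @export
loewe_ci <- function(d_A, d_B, surface, level = NULL) {
  stopifnot(inherits(surface, "mm_effect_surface"))
  g <- surface$grid
  bz <- surface$bzm_doses
  am <- surface$amd_doses
  if (is.null(level)) {
    i <- which.min(abs(bz - d_A))
    j <- which.min(abs(am - d_B))
    level <- g[i, j]
  }
  if (level <= 0) return(NA_real_)
  D_A <- single_agent_dose(bz, g[, which(am == 0)[1]], level)
  D_B <- single_agent_dose(am, g[which(bz == 0)[1], ], level)
  ci <- 0
  any_defined <- FALSE
  for (k in 1:2) {
    d <- c(d_A, d_B)[k]
    D <- c(D_A, D_B)[k]
    if (d == 0) next
    if (is.na(D)) next  # unreachable alone: infinite equivalent dose
    any_defined <- TRUE
    ci <- ci + d / D
  }
  if (!any_defined) return(NA_real_)
  ci
}

#' Combination index along an isobole
#'
#' Extracts the iso-effect contour at `level` and evaluates the Loewe
#' combination index at each contour vertex (every vertex achieves the
#' level by construction).
#'
#' @param surface an [effect_surface()].
#' @param level effect level.
#' @return A data frame of contour vertices with their `ci`; zero rows when
#'   the level is never reached.
#' @export
isobole_ci <- function(surface, level) {
  ctrs <- isobole(surface, level)
  if (!length(ctrs))
    return(data.frame(bzm_dose = numeric(0), amd_dose = numeric(0),
                      ci = numeric(0)))
  out <- do.call(rbind, ctrs)
  # a contour vertex sitting on the zero-dose pseudo-axis is a single-agent
  # point; its pseudo-dose must not enter the CI arithmetic
  zb <- out$bzm_index <= 1
  za <- out$amd_index <= 1
  d_A <- ifelse(zb, 0, out$bzm_dose)
  d_B <- ifelse(za, 0, out$amd_dose)
  out$ci <- vapply(seq_len(nrow(out)), function(k)
    loewe_ci(d_A[k], d_B[k], surface, level = level), 0)
  out
}

#' Fold change between two replicate sets
#'
#' Ratio of mean counts at a time point between two replicate run sets,
#' e.g. MBMSC over NBMSC total tumour at 600 h.
#'
#' @param reps_A,reps_B [replicate_runs()] results (numerator,
#'   denominator).
#' @param t time in hours (must be a recorded time).
#' @param quantity one of `"MIC"`, `"PC"`, `"MM"`, `"TMM"`, `"total"`.
#' @return The ratio of means.
#' @export
fold_change <- function(reps_A, reps_B, t, quantity = "total") {
  val <- function(reps) {
    x <- vapply(reps$runs, function(s) {
      row <- which(abs(s$time - t) < 1e-9)
      if (!length(row)) stop("time ", t, " h was not recorded")
      s[[quantity]][row]
    }, 0)
    mean(x)
  }
  denom <- val(reps_B)
  if (denom == 0) stop("fold_change denominator is zero")
  val(reps_A) / denom
}

#' Infiltration frontier diameter
#'
#' Robust diameter of the tumour infiltration frontier: twice the 95th
#' percentile of the radial distances of occupied tumour sites from the
#' seeding centroid, converted to micrometres, plus one site width (a
#' single-cell tumour has diameter ~ one cell).
#'
#' @param x an `mm_sim`, an `mm_lattice` state, or a coded occupancy array
#'   (non-zero = tumour site).
#' @param spacing lattice spacing in um (taken from the object when
#'   available).
#' @param center seeding centroid in site coordinates (defaults to the
#'   domain centre).
#' @return Diameter in micrometres.
#' @export
infiltration_diameter <- function(x, spacing = NULL, center = NULL) {
  if (inherits(x, "mm_sim")) x <- x$final_state
  if (inherits(x, "mm_lattice")) {
    g <- x$geometry
    if (is.null(spacing)) spacing <- g$spacing
    if (is.null(center)) center <- g$center
    occ <- x$occupancy
  } else {
    occ <- x
    if (is.null(spacing)) stop("spacing required for a bare occupancy array")
    if (is.null(center)) center <- (dim(occ) + 1) / 2
  }
  idx <- which(occ != 0)
  if (!length(idx)) return(0)
  d <- dim(occ)
  i0 <- idx - 1L
  xs <- i0 %% d[1] + 1L
  ys <- (i0 %/% d[1]) %% d[2] + 1L
  zs <- i0 %/% (d[1] * d[2]) + 1L
  r <- sqrt((xs - center[1])^2 + (ys - center[2])^2 + (zs - center[3])^2)
  2 * as.numeric(quantile(r, 0.95)) * spacing + spacing
}
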