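test_that("effect surfaces compute the documented arithmetic from a store", {
  store <- make_fixture("sweep_store", seed = 1)
  # construct a deterministic store on top of the fixture for exact checks
  ctrl_key <- "MBMSC_b00_a00"
  half_key <- "MBMSC_b06_a00"
  store$results[[ctrl_key]][, "MIC"] <- 100L
  store$results[[half_key]][, "MIC"] <- 50L
  surf <- effect_surface(store, "mic_reduction", "MBMSC")
  expect_equal(surf$grid["0", "0"], 0)
  expect_equal(surf$grid["6", "0"], 0.5)
  expect_true(all(surf$grid >= 0 & surf$grid <= 1))
  # eradication probability: fraction of replicates with zero MICs
  store$results[["MBMSC_b11_a00"]][, "MIC"] <- 0L
  store$results[["MBMSC_b09_a00"]][, "MIC"] <- c(0L, 0L, 3L, 0L, 0L)
  er <- effect_surface(store, "mic_eradication", "MBMSC")
  expect_equal(er$grid["11", "0"], 1)
  expect_equal(er$grid["9", "0"], 0.8)
  expect_equal(er$grid["0", "0"], 0)
})

test_that("Gaussian smoothing is edge-renormalised and mean-preserving", {
  surf <- make_fixture("additive_surface")
  # constant surface passes through unchanged
  const <- surf
  const$grid[] <- 0.37
  sm <- smooth_surface(const, theta = 2)
  expect_equal(sm$grid, const$grid, tolerance = 1e-12)
  # interior-supported spike (kernel support never truncated for any output
  # cell it reaches): mass preserved to 1e-9, peak reduced
  spike <- surf
  spike$grid[] <- 0
  spike$grid[6, 6] <- 1
  sm2 <- smooth_surface(spike, theta = 0.6)
  expect_equal(sum(sm2$grid), 1, tolerance = 1e-9)
  expect_lt(max(sm2$grid), 1)
  expect_equal(which.max(sm2$grid), which.max(spike$grid))
  # theta -> 0 is the identity
  expect_equal(smooth_surface(spike, theta = 0)$grid, spike$grid)
})

test_that("isoboles match an analytic level set on a separable surface", {
  surf <- make_fixture("additive_surface")  # E = f(dA + r dB), known form
  level <- 0.5
  ctrs <- isobole(surf, level)
  expect_gt(length(ctrs), 0)
  pts <- do.call(rbind, ctrs)
  # analytic level set: dA + (K_A/K_B) dB = K (f = 0.5 at the half-dose);
  # verify in index space within half a grid cell by re-evaluating the
  # surface construction at the contour vertices
  K_A <- 1; K_B <- 2; n <- 2
  eff <- function(dA, dB) {
    d <- dA + (K_A / K_B) * dB
    d^n / (K_A^n + d^n)
  }
  vals <- eff(pts$bzm_dose, pts$amd_dose)
  # surface value along the contour should be the level, up to the local
  # linear-interpolation error of one cell
  expect_lt(max(abs(vals - level)), 0.06)
  # a level never reached yields no contour
  expect_length(isobole(surf, 0.9999), 0)
})

test_that("the combination index is 1 on additive surfaces and at single-agent points", {
  surf <- make_fixture("additive_surface")
  bz <- surf$bzm_doses
  am <- surf$amd_doses
  # all interior combos where both doses are positive and the effect is
  # within the invertible range
  cis <- c()
  for (i in 2:12) for (j in 2:12) {
    e <- surf$grid[i, j]
    if (e > 0.05 && e < 0.95)
      cis <- c(cis, loewe_ci(bz[i], am[j], surf))
  }
  expect_gt(length(cis), 30)
  expect_true(all(abs(cis - 1) < 0.05))
  # single-agent points: CI = 1 by construction
  D_A <- micniche:::single_agent_dose(bz, surf$grid[, 1], 0.5)
  expect_equal(loewe_ci(D_A, 0, surf, level = 0.5), 1, tolerance = 1e-6)
  D_B <- micniche:::single_agent_dose(am, surf$grid[1, ], 0.5)
  expect_equal(loewe_ci(0, D_B, surf, level = 0.5), 1, tolerance = 1e-6)
  # synergistic construction: CI < 1 off-axis
  syn <- make_fixture("synergistic_surface")
  ci_syn <- loewe_ci(syn$bzm_doses[6], syn$amd_doses[6], syn)
  expect_lt(ci_syn, 0.8)
})

test_that("an agent that never reaches the level contributes a vanishing term", {
  surf <- make_fixture("additive_surface")
  # cap the zero-BZM column so AMD alone never reaches 0.9
  surf$grid[1, ] <- pmin(surf$grid[1, ], 0.4)
  ci <- loewe_ci(surf$bzm_doses[10], surf$amd_doses[5], surf, level = 0.9)
  D_A <- micniche:::single_agent_dose(surf$bzm_doses, surf$grid[, 1], 0.9)
  expect_equal(ci, surf$bzm_doses[10] / D_A, tolerance = 1e-9)
  # undefined when no positive-dose agent reaches the level
  expect_true(is.na(loewe_ci(0, surf$amd_doses[5], surf, level = 0.9)))
})

test_that("E100 super-level region is inside the E50 region on monotone surfaces", {
  surf <- make_fixture("additive_surface")
  e100 <- surf$grid >= 0.95
  e50 <- surf$grid >= 0.5
  expect_true(all(e50[e100]))
})

test_that("fold change compares replicate means at a time point", {
  cfg <- trace_config("NBMSC", t_end = 20)
  reps <- replicate_runs(cfg, 2, seed_base = 3)
  expect_equal(fold_change(reps, reps, 20, "total"), 1)
  expect_error(fold_change(reps, reps, 19, "total"), "not recorded")
})

test_that("the infiltration diameter recovers known geometries", {
  # single cell at the centre: about one site
  occ <- array(0L, c(15, 15, 15))
  occ[8, 8, 8] <- 1L
  expect_equal(infiltration_diameter(occ, spacing = 20), 20)
  # solid digital ball of radius r sites: diameter within one spacing of 2r
  for (r in c(4, 6)) {
    ball <- make_fixture("digital_ball", radius = r)
    d <- infiltration_diameter(ball, spacing = 20)
    expect_lt(abs(d - 2 * r * 20), 2 * 20)
  }
})
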