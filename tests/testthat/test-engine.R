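test_that("a zero-length run reports only the seeded populations", {
  cfg <- sim_config("MBMSC", geometry = lattice_geometry(16, 16, 16),
                    t_end = 0, n_seed_per_type = 100L)
  sim <- run_sim(cfg, seed = 1)
  expect_equal(nrow(sim$series), 1)
  expect_equal(as.integer(sim$series[1, c("MIC", "PC", "MM", "TMM")]),
               rep(100L, 4))
  expect_equal(sim$series$total[1], 400)
})

test_that("identical config and seed reproduce the run bit-for-bit", {
  cfg <- trace_config("MBMSC", t_end = 60)
  a <- run_sim(cfg, seed = 42)
  b <- run_sim(cfg, seed = 42)
  expect_identical(a$series, b$series)
  expect_identical(a$events, b$events)
  expect_identical(a$final_state$occupancy, b$final_state$occupancy)
  expect_identical(a$final_state$sdf1, b$final_state$sdf1)
  c <- run_sim(cfg, seed = 43)
  expect_false(identical(a$final_state$occupancy, c$final_state$occupancy))
})

test_that("a single MIC locally elevates SDF-1 after one step", {
  cfg <- sim_config("MBMSC", geometry = lattice_geometry(14, 14, 14),
                    t_end = 2, n_seed_per_type = c(MIC = 1, PC = 0,
                                                   MM = 0, TMM = 0))
  sim <- run_sim(cfg, seed = 2)
  site <- sim$final_state$cells$site[1]
  expect_gt(sim$final_state$sdf1[site], 0)
  expect_gt(sum(sim$final_state$sdf1), 0)
})

test_that("death-only dynamics decline monotonically", {
  cfg <- trace_config("NBMSC", t_end = 200)
  for (nm in names(cfg$params$behavior$div))
    cfg$params$behavior$div[[nm]] <- hill_response(K = 1, n = 1, floor = 0,
                                                   ceiling = 0)
  cfg$params$lineage$base_apop[] <- 0.01
  sim <- run_sim(cfg, seed = 3)
  totals <- sim$series$total + sim$series$dying
  expect_true(all(diff(totals) <= 0))
  expect_lt(sim$series$total[nrow(sim$series)], 40)
})

test_that("full traces respect occupancy exclusivity and domain containment", {
  cfg <- trace_config("MBMSC", t_end = 100)
  cfg$snapshot_every <- 5L
  sim <- run_sim(cfg, seed = 4)
  g <- cfg$geometry
  cells <- sim$final_state$cells
  expect_equal(anyDuplicated(cells$site), 0L)
  expect_true(all(g$domain_mask[cells$site]))
  for (snap in sim$snapshots) {
    occupied <- which(snap$occupancy != 0L)
    expect_true(all(g$domain_mask[occupied]))
    expect_true(all(snap$sdf1 >= 0))
  }
  # snapshot export round-trips through the compressed container
  tmp <- tempfile(fileext = ".rds")
  write_snapshots(sim, tmp)
  back <- readRDS(tmp)
  expect_identical(back, sim$snapshots)
  # stiffness bounds hold everywhere on the trace end state
  p <- cfg$params
  expect_true(all(sim$final_state$stiffness >= p$E_base - 1e-9))
  expect_true(all(sim$final_state$stiffness <= p$E_max + 1e-9))
  expect_true(all(sim$final_state$sdf1 >= 0))
})

test_that("the event ledger fully explains every population change", {
  for (seed in c(5, 6)) {
    sim <- run_sim(trace_config("MBMSC", t_end = 80), seed = seed)
    audit <- audit_ledger(sim)
    expect_equal(audit$observed, audit$expected)
  }
})

test_that("replicate runs aggregate on the reporting cadence", {
  cfg <- trace_config("NBMSC", t_end = 60)
  reps <- replicate_runs(cfg, 3, seed_base = 11, aggregate_every = 20)
  expect_length(reps$runs, 3)
  expect_equal(reps$aggregate$time, c(0, 20, 40, 60))
  expect_equal(dim(reps$final), c(3L, 4L))
  # n_reps = 1 equals a plain run with the same seed
  one <- replicate_runs(cfg, 1, seed_base = 11)
  solo <- run_sim(cfg, seed = 11)
  expect_identical(one$runs[[1]], solo$series)
  # replicate means from different seed bases are statistically compatible
  r1 <- replicate_runs(cfg, 6, seed_base = 100)
  r2 <- replicate_runs(cfg, 6, seed_base = 900)
  m1 <- mean(rowSums(r1$final)); s1 <- sd(rowSums(r1$final))
  m2 <- mean(rowSums(r2$final)); s2 <- sd(rowSums(r2$final))
  expect_lt(abs(m1 - m2), 3 * sqrt(s1^2 / 6 + s2^2 / 6) + 1e-9)
})

test_that("the calibration harness bisects monotone responses and reports infeasibility", {
  params <- list(a = 1, nested = list(b = 2))
  evalf <- function(p) c(sq = p$a^2, lin = p$nested$b * 3)
  # already-satisfied targets are a fixed point
  fix <- calibrate_model(params, c(sq = 1), list(sq = list(path = "a",
                                                           lower = 0,
                                                           upper = 10)),
                         evalf)
  expect_true(fix$converged)
  expect_identical(fix$params, params)
  expect_equal(fix$passes, 0L)
  # monotone single-parameter search converges to tolerance
  cal <- calibrate_model(params, c(sq = 9),
                         list(sq = list(path = "a", lower = 0, upper = 10)),
                         evalf, tol = 0.01)
  expect_true(cal$converged)
  expect_equal(cal$params$a, 3, tolerance = 0.05)
  # two coupled coordinates
  cal2 <- calibrate_model(params, c(sq = 4, lin = 30),
                          list(sq = list(path = "a", lower = 0, upper = 10),
                               lin = list(path = c("nested", "b"),
                                          lower = 0, upper = 100)),
                          evalf, tol = 0.01)
  expect_true(cal2$converged)
  expect_equal(cal2$params$nested$b, 10, tolerance = 0.05)
  # infeasible target: explicit failure report, no silent clamp
  bad <- calibrate_model(params, c(sq = 1e6),
                         list(sq = list(path = "a", lower = 0, upper = 10)),
                         evalf)
  expect_false(bad$converged)
  expect_true("sq" %in% attr(bad$report, "infeasible"))
})
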