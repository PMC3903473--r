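test_that("the full factorial design reproduces the published bookkeeping", {
  full <- sweep_design("full")
  conds <- enumerate_conditions(full)
  expect_equal(nrow(conds), 288)                       # 12 x 12 x 2
  expect_equal(nrow(conds) * full$n_reps, 5760)        # runs
  expect_equal(record_budget(full), 13824000)          # data records
})

test_that("condition enumeration is a deterministic Cartesian product", {
  d <- sweep_design(bzm_levels = c(0, 6), amd_levels = c(0, 6),
                    niches = "MBMSC", n_reps = 2)
  conds <- enumerate_conditions(d)
  expect_equal(nrow(conds), 4)
  expect_identical(conds, enumerate_conditions(d))
  expect_equal(conds$bzm_dose[conds$bzm_level == 6][1], 1.0)
  # niche-major, then BZM, then AMD ordering
  d2 <- sweep_design(bzm_levels = c(0, 1), amd_levels = c(0, 1),
                     niches = c("NBMSC", "MBMSC"))
  c2 <- enumerate_conditions(d2)
  expect_equal(c2$niche, rep(c("NBMSC", "MBMSC"), each = 4))
  expect_equal(c2$bzm_level[1:4], c(0L, 0L, 1L, 1L))
})

test_that("record bookkeeping identities hold for arbitrary designs", {
  expect_equal(record_budget(sweep_design(bzm_levels = 0, amd_levels = 0,
                                          niches = "MBMSC", n_reps = 1,
                                          points = 1, quantities = 6)), 6)
  expect_equal(record_budget(sweep_design(bzm_levels = 0:4, amd_levels = 0:4,
                                          niches = c("NBMSC", "MBMSC"),
                                          n_reps = 5, points = 100,
                                          quantities = 6)), 150000)
  set.seed(17)
  for (i in 1:20) {
    nb <- sample(1:12, 1); na <- sample(1:12, 1)
    nn <- sample(1:2, 1); nr <- sample(1:20, 1)
    np <- sample(1:400, 1); nq <- sample(1:6, 1)
    d <- sweep_design(bzm_levels = seq_len(nb) - 1L,
                      amd_levels = seq_len(na) - 1L,
                      niches = c("NBMSC", "MBMSC")[seq_len(nn)],
                      n_reps = nr, points = np, quantities = nq)
    expect_equal(nrow(enumerate_conditions(d)), nb * na * nn)
    expect_equal(record_budget(d), nb * na * nn * nr * np * nq)
  }
})

test_that("sweeps are reproducible, resumable and executor-independent", {
  d <- sweep_design(bzm_levels = c(0L, 9L), amd_levels = 0L,
                    niches = "NBMSC", n_reps = 2)
  cfg <- trace_config("NBMSC", t_end = 40)
  s1 <- run_sweep(d, cfg, seed_base = 5)
  # degenerate single condition equals replicate_runs with the same seeds
  cond <- enumerate_conditions(d)[1, ]
  cfg1 <- cfg
  cfg1$schedule$bzm_dose <- cond$bzm_dose
  reps <- replicate_runs(cfg1, 2, seed_base = 5 + 1000 * (cond$index - 1))
  expect_equal(unname(s1$results[[1]]), unname(reps$final))
  # serial executor swap: identical results
  s2 <- run_sweep(d, cfg, seed_base = 5,
                  executor = function(x, f) Map(f, x))
  expect_equal(s1$results, s2$results)
  # resumable store: interrupting after one condition then restarting gives
  # the identical final store
  dir1 <- tempfile("sweep1_")
  d_first <- d
  d_first$bzm_levels <- 0L
  run_sweep(d_first, cfg, seed_base = 5, dir = dir1)  # partial store
  s3 <- run_sweep(d, cfg, seed_base = 5, dir = dir1)  # completes the rest
  expect_equal(s3$results, s1$results)
  # completeness check flags a missing condition
  s_missing <- s1
  s_missing$results[[2]] <- NULL
  expect_error(effect_surface(s_missing, "mic_reduction", "NBMSC"),
               "incomplete")
})
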