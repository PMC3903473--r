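test_that("dice-roll decisions match their probabilities", {
  set.seed(1)
  expect_false(any(replicate(200, decide(0))))
  expect_true(all(replicate(200, decide(1))))
  n <- 10000
  hits <- sum(replicate(n, decide(0.3)))
  sigma <- sqrt(n * 0.3 * 0.7)
  expect_lt(abs(hits - n * 0.3), 3 * sigma)
})

test_that("MIC fate draws follow the fate triple", {
  set.seed(2)
  expect_true(all(replicate(100, mic_division_fate(c(1, 0, 0))) ==
                    "SELF_RENEW"))
  expect_true(all(replicate(100, mic_division_fate(c(0, 0, 1))) ==
                    "DIFFERENTIATE"))
  n <- 10000
  draws <- replicate(n, mic_division_fate(c(0.5, 0.25, 0.25)))
  for (pair in list(c("SELF_RENEW", 0.5), c("ASYMMETRIC", 0.25),
                    c("DIFFERENTIATE", 0.25))) {
    p <- as.numeric(pair[2])
    expect_lt(abs(sum(draws == pair[1]) - n * p),
              3 * sqrt(n * p * (1 - p)))
  }
  expect_error(mic_division_fate(c(0.5, 0.2, 0.2)))
})

test_that("target-site choice weights free sites by stiffness preference", {
  g <- lattice_geometry(9, 9, 9)
  p <- mm_params("MBMSC")
  st <- make_lattice(g, p)
  ctr <- site_index(5L, 5L, 5L, g)
  nb <- site_neighbors(ctr, g, 1)
  # fully surrounded: NONE
  st_full <- st
  st_full$occupancy[nb] <- 1L
  st_full$occupancy[site_neighbors(ctr, g, 2)] <- 1L
  expect_true(is.na(choose_target_site(ctr, st_full, 1, beta = 1)))
  expect_true(is.na(choose_target_site(ctr, st_full, 2, beta = 1)))
  # exactly one free site is always chosen
  st_one <- st_full
  free_site <- nb[14]
  st_one$occupancy[free_site] <- 0L
  set.seed(3)
  expect_true(all(replicate(50, choose_target_site(ctr, st_one, 1, 1)) ==
                    free_site))
  # two free sites: frequencies follow exp(beta * E)
  st_two <- st_full
  s1 <- nb[1]; s2 <- nb[26]
  st_two$occupancy[c(s1, s2)] <- 0L
  st_two$stiffness[s1] <- 6
  st_two$stiffness[s2] <- 2
  beta <- 0.5
  p1 <- exp(beta * 6) / (exp(beta * 6) + exp(beta * 2))
  set.seed(4)
  n <- 10000
  picks <- replicate(n, choose_target_site(ctr, st_two, 1, beta))
  expect_setequal(unique(picks), c(s1, s2))
  expect_lt(abs(sum(picks == s1) - n * p1), 3 * sqrt(n * p1 * (1 - p1)))
})

test_that("apoptosis removes a cell exactly ten 2-hour steps after entry", {
  # cohort with certain immediate apoptosis entry and nothing else
  cfg <- trace_config("NBMSC", t_end = 40, n_seed = 8L)
  cfg$params$lineage$base_apop[] <- 1e9   # enter apoptosis at the first step
  cfg$params$behavior$p_mig[] <- 0
  sim <- run_sim(cfg, seed = 5)
  ev <- as.data.frame(sim$events)
  entries <- ev[ev$event == 4, ]
  deaths <- ev[ev$event == 5, ]
  expect_equal(nrow(entries), 32)
  expect_equal(nrow(deaths), 32)
  lag <- deaths$time[match(entries$id, deaths$id)] - entries$time
  expect_true(all(lag == 20))            # 20 h = 10 steps at dt = 2
  expect_equal(sim$series$total[nrow(sim$series)], 0)
})

test_that("a cohort under constant hazard decays geometrically", {
  cfg <- sim_config("NBMSC", geometry = lattice_geometry(24, 24, 8),
                    t_end = 20, n_seed_per_type = c(MIC = 0, PC = 0,
                                                    MM = 0, TMM = 250))
  p_step <- 0.1
  cfg$params$lineage$base_apop["TMM"] <- p_step / 2  # per hour * dt = p_step
  cfg$params$behavior$p_mig[] <- 0
  set.seed(6)
  survivors <- vapply(1:4, function(s) {
    sim <- run_sim(cfg, seed = s)
    # live TMM after k = 5 steps (dying cells excluded from the count)
    sim$series$TMM[sim$series$time == 10]
  }, 0)
  n0 <- 250 * 4
  k <- 5
  expected <- n0 * (1 - p_step)^k
  sigma <- sqrt(n0 * (1 - p_step)^k * (1 - (1 - p_step)^k))
  expect_lt(abs(sum(survivors) - expected), 3 * sigma)
})

test_that("zero apoptosis probability means no cell ever dies", {
  cfg <- trace_config("MBMSC", t_end = 60)
  cfg$params$lineage$base_apop[] <- 0
  sim <- run_sim(cfg, seed = 7)
  ev <- as.data.frame(sim$events)
  expect_equal(sum(ev$event %in% c(4, 5)), 0)
  # and TMM count is non-decreasing without apoptosis
  expect_true(all(diff(sim$series$TMM) >= 0))
})

test_that("passage limits convert PC to MM and MM to TMM at division", {
  # PC-only seed with certain division and ample space
  cfg <- sim_config("NBMSC", geometry = lattice_geometry(20, 20, 20),
                    t_end = 300, record_events = TRUE,
                    n_seed_per_type = c(MIC = 0, PC = 30, MM = 0, TMM = 0))
  cfg$params$lineage$base_apop[] <- 0
  sim <- run_sim(cfg, seed = 8)
  cells <- sim$final_state$cells
  lin <- cfg$params$lineage
  expect_true(all(cells$passage[cells$type == 2L] <= lin$LGN_PC))
  expect_true(all(cells$passage[cells$type == 3L] <= lin$LGN_MM))
  ev <- as.data.frame(sim$events)
  conv <- ev[ev$event == 3, ]
  expect_true(all(conv$from %in% c(2, 3)))
  expect_true(any(conv$from == 2 & conv$to == 3))  # PC -> MM observed
  expect_true(any(conv$from == 3 & conv$to == 4))  # MM -> TMM observed
  # by 300 h every surviving lineage member has matured out of PC
  expect_equal(sim$series$PC[nrow(sim$series)], 0)
})

test_that("MIC growth with pure self-renewal matches the branching expectation", {
  # fate locked to self-renewal, no apoptosis, ample space
  cfg <- sim_config("NBMSC", geometry = lattice_geometry(26, 26, 26),
                    t_end = 200,
                    n_seed_per_type = c(MIC = 40, PC = 0, MM = 0, TMM = 0))
  cfg$params$behavior$self <- hill_response(K = 1, n = 1, floor = 1,
                                            ceiling = 1)
  cfg$params$lineage$base_apop[] <- 0
  p_div <- 0.3
  cfg$params$behavior$div$MIC <- hill_response(K = 1, n = 1, floor = p_div,
                                               ceiling = p_div)
  cfg$t_end <- 160
  sim <- run_sim(cfg, seed = 10)
  # expected multiplication for unconstrained branching: cycle 36 h plus a
  # geometric division wait of mean dt / p_div per generation
  t <- 160
  expected <- 40 * 2^(t / (36 + 2 / p_div))
  got <- sim$series$MIC[sim$series$time == t]
  # crowding can only slow growth below the free-branching expectation
  expect_lt(got, expected * 1.15)
  expect_gt(got, expected * 0.55)
})
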