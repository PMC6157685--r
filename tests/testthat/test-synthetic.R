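test_that("the default design produces the full field layout", {
  sim <- simulate_dataset(simulation_config(seed = 2))
  obs <- sim$observations
  key <- paste(obs$block_id, obs$transect_id, obs$ramet_id)
  expect_equal(length(unique(key)), 10 * 4 * 5)    # 200 marked ramets
  expect_equal(nrow(obs), 200 * 3 * 3)             # 9 census slots each
  expect_true(all(table(key) == 9))
  # two treatments with two replicate transects per block
  tt <- unique(obs[c("block_id", "transect_id", "treatment")])
  per_block <- table(tt$block_id, tt$treatment)
  expect_true(all(per_block == 2))
  # five distance classes per transect
  expect_setequal(unique(obs$distance_class), 0:4)
  # generated tables satisfy the full data model
  expect_equal(nrow(validate_observations(obs)), 0)
})

test_that("generation is deterministic in the seed and leaves the RNG alone", {
  cfg <- simulation_config(seed = 9, n_blocks = 2)
  set.seed(1234); before <- .Random.seed
  s1 <- simulate_dataset(cfg)
  expect_identical(.Random.seed, before)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$observations, s2$observations)
  s3 <- simulate_dataset(simulation_config(seed = 10, n_blocks = 2))
  expect_false(identical(s1$observations, s3$observations))
})

test_that("scenario presets encode the multiannual induction pattern", {
  cfg <- scenario_paper_like(seed = 1)
  tr <- cfg$truth
  # grazing suppressed most strongly in year 2 at the treated ramet
  g_eff <- tr$grazed_ratio$alpha["meja_d0", ] - tr$grazed_ratio$alpha["control", ]
  expect_lt(g_eff[2], 0)
  expect_equal(which.min(g_eff), 2L)
  # browsing suppressed most strongly in year 3
  b_eff <- tr$browsed_shoots$alpha["meja_d0", ] - tr$browsed_shoots$alpha["control", ]
  expect_lt(b_eff[3], 0)
  expect_equal(which.min(b_eff), 3L)
  # flowers and berries up in year 3
  expect_gt(tr$flowers$alpha["meja_d0", 3] - tr$flowers$alpha["control", 3], 0)
  expect_gt(tr$berries$alpha["meja_d0", 3] - tr$berries$alpha["control", 3], 0)
  # neighbour effects decay monotonically with distance class
  for (resp in names(tr)) {
    eff <- abs(tr[[resp]]$alpha[paste0("meja_d", 0:4), ] -
               rep(tr[[resp]]$alpha["control", ], each = 5))
    for (y in 1:3) expect_true(all(diff(eff[, y]) <= 0))
  }
  # the truth record serializes every cell
  sim <- simulate_dataset(simulation_config(seed = 3, n_blocks = 2))
  expect_true(all(c("response", "parameter", "group", "year", "value")
                  %in% names(sim$truth)))
  expect_equal(sum(sim$truth$parameter == "alpha"), 5 * 6 * 3)
})

test_that("the null scenario injects exactly zero contrasts", {
  tr <- null_scenario(seed = 4)$truth
  for (resp in names(tr)) {
    for (par in c("alpha", "beta")) {
      m <- tr[[resp]][[par]]
      if (is.null(m)) next
      for (g in rownames(m)) expect_equal(m[g, ], m["control", ])
    }
  }
})

test_that("without extra variance sources Poisson cells are equidispersed", {
  # sigma_eps = 0, psi = 1, sigma_u = 0, no mortality: browsed-shoot counts
  # within a group x year x census cell are plain Poisson, so the index of
  # dispersion (variance / mean) should sit near 1
  tr <- default_truth("null")
  tr$browsed_shoots$sigma_u <- 0
  tr$browsed_shoots$sigma_eps <- 0
  tr$browsed_shoots$psi <- 1
  cfg <- simulation_config(seed = 88, n_blocks = 30, mortality_hazard = 0,
                           truth = tr)
  obs <- simulate_dataset(cfg)$observations
  cell <- paste(obs$treatment, obs$distance_class, obs$year, obs$census)
  disp <- vapply(split(obs$n_browsed_shoots, cell), function(v) {
    if (mean(v) == 0) NA_real_ else var(v) / mean(v)
  }, numeric(1))
  expect_equal(mean(disp, na.rm = TRUE), 1, tolerance = 0.1)
  # with the observation-level effect back on, the same cells overdisperse
  tr2 <- default_truth("null")
  tr2$browsed_shoots$sigma_u <- 0
  tr2$browsed_shoots$sigma_eps <- 1
  tr2$browsed_shoots$psi <- 1
  obs2 <- simulate_dataset(simulation_config(seed = 88, n_blocks = 30,
                                             mortality_hazard = 0,
                                             truth = tr2))$observations
  cell2 <- paste(obs2$treatment, obs2$distance_class, obs2$year, obs2$census)
  disp2 <- vapply(split(obs2$n_browsed_shoots, cell2), function(v) {
    if (mean(v) == 0) NA_real_ else var(v) / mean(v)
  }, numeric(1))
  expect_gt(mean(disp2, na.rm = TRUE), 1.5)
})

test_that("mortality thins later years monotonically", {
  obs <- simulate_dataset(simulation_config(seed = 6,
                                            mortality_hazard = 0.25))$observations
  usable <- tapply(obs$alive, obs$year, sum)
  expect_true(all(diff(usable) <= 0))
  expect_lt(usable[3], usable[1])
  # hazard 0 keeps everything
  obs0 <- simulate_dataset(simulation_config(seed = 6, n_blocks = 2,
                                             mortality_hazard = 0))$observations
  expect_true(all(obs0$alive))
})

test_that("generated tables respect census-level count structure", {
  for (seed in c(11, 12)) {
    obs <- simulate_dataset(simulation_config(seed = seed,
                                              n_blocks = 3))$observations
    live <- obs[obs$alive, ]
    expect_true(all(live$n_grazed_leaves <= live$n_leaves))
    expect_true(all(is.na(obs$n_berries[obs$year == 1 & obs$census == 1])))
    expect_true(all(!is.na(live$n_berries[live$year > 1 | live$census > 1])))
    # sizes reconstruct the simulated dry mass on a plausible scale
    m <- log2_dry_mass(live$stem_diameter_mm, live$height_cm, live$n_shoots)
    expect_true(all(is.finite(m)))
    expect_true(all(live$height_cm >= 10 & live$height_cm <= 25))
  }
})
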