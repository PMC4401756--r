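test_that("species pool lies exactly on the trade-off line when noiseless", {
  cfg <- scenario_config(tradeoff_noise_sd = 0, seed = 5L)
  pool <- generate_species_pool(cfg)
  expect_equal(log10(pool$latent_recruitment),
               cfg$tradeoff_intercept + cfg$tradeoff_slope * pool$body_length_mm,
               tolerance = 1e-12)
  # negative slope + zero noise -> recruitment strictly decreasing in size
  o <- order(pool$body_length_mm)
  expect_true(all(diff(pool$latent_recruitment[o]) < 0))
  # determinism
  expect_identical(pool, generate_species_pool(cfg))
  expect_error(scenario_config(n_species = 2L), "at least 3")
  expect_error(scenario_config(tradeoff_slope = 0.1), "negative")
  expect_error(scenario_config(persistence_prob = 1.4), "persistence")
  expect_error(scenario_config(hotspots = c(rep(FALSE, 8), TRUE, TRUE)), "hotspot")
})

test_that("default survey has the stated dimensions and valid ranges", {
  sv <- generate_survey(scenario_config(seed = 9L))
  expect_equal(nrow(sv$plants), 10 * 30 * 2)
  expect_equal(nrow(sv$populations), 10)
  expect_true(all(sv$plants$n_leaves > 0))
  expect_true(all(sv$ant_observations$count >= 1))
  expect_true(all(sv$leaflets$efn_count_base >= 0))
  expect_true(all(sv$leaflets$damaged_area_mm2 >= 0 &
                    sv$leaflets$damaged_area_mm2 <= sv$leaflets$total_area_mm2))
  # relative leaf production >= -1 by construction
  w <- merge(sv$plants[sv$plants$census == "t0", c("plant_id", "n_leaves")],
             sv$plants[sv$plants$census == "t1", c("plant_id", "n_leaves")],
             by = "plant_id")
  expect_true(all((w$n_leaves.y - w$n_leaves.x) / w$n_leaves.x >= -1))
  # ground truth covers every population exactly once, 8 matched labels
  gt <- sv$ground_truth$populations
  expect_setequal(gt$population_id, sv$populations$population_id)
  expect_equal(sum(gt$matched), 8)
  expect_equal(sum(gt$hotspot), 3)
  # coordinates span roughly 600 km of savanna
  dm <- geographic_distance_matrix(sv$populations)
  expect_gt(max(dm), 450); expect_lt(max(dm), 800)
})

test_that("identical config and seed give identical surveys", {
  cfg <- scenario_config(seed = 123L)
  s1 <- generate_survey(cfg); s2 <- generate_survey(cfg)
  expect_identical(s1$plants, s2$plants)
  expect_identical(s1$ant_observations, s2$ant_observations)
  expect_identical(s1$leaflets, s2$leaflets)
})

test_that("EFN counts have the configured mean (mismatched scenario fixes it)", {
  cfg <- scenario_config(n_populations = 1L, n_plants_per_pop = 300L,
                         scenarios = "mismatched", hotspots = FALSE, seed = 17L)
  pop <- generate_population(cfg, "mismatched", generate_species_pool(cfg),
                             seed = 99L, population_id = "m")
  per_plant <- tapply(pop$leaflets$efn_count_base, pop$leaflets$plant_id, mean)
  mu <- cfg$efn_mean_by_scenario[["mismatched"]]
  se <- sd(per_plant) / sqrt(length(per_plant))
  expect_lt(abs(mean(per_plant) - mu), 3 * se + 1e-9)
})

test_that("tau = 0 assigns every plant the species nearest its preferred size", {
  pool <- data.frame(species = c("small", "mid", "big"),
                     body_length_mm = c(3, 6, 9),
                     latent_recruitment = c(30, 12, 5),
                     niche_offset_mm = 0)
  cfg <- scenario_config(n_populations = 1L, n_plants_per_pop = 40L,
                         scenarios = "matched_big", hotspots = FALSE,
                         visitation_kernel_sd = 0, efn_dispersion = 1e6,
                         occupancy_prob_matched = 1, seed = 2L)
  pop <- generate_population(cfg, "matched_big", pool, seed = 7L, population_id = "x")
  # with negligible phenotype spread every plant's preferred size is
  # g(45) = 2.6 + 0.123 * 45 = 8.1 -> nearest pool species is "big"
  expect_setequal(unique(pop$ant_obs$species), "big")
})

test_that("no herbivory effect decouples damage from ant abundance", {
  cfg <- scenario_config(n_populations = 1L, n_plants_per_pop = 300L,
                         scenarios = "matched_big", hotspots = FALSE,
                         herbivory_effect = 0, seed = 4L)
  pop <- generate_population(cfg, "matched_big", generate_species_pool(cfg),
                             seed = 21L, population_id = "x")
  t0 <- pop$plants[pop$plants$census == "t0", ]
  obs <- stats::aggregate(count ~ plant_id, data = pop$ant_obs[pop$ant_obs$census == "t0", ], FUN = sum)
  m <- merge(t0, obs, by = "plant_id", all.x = TRUE)
  m$count[is.na(m$count)] <- 0
  m$std <- m$count / m$n_leaves * 100
  herb <- tapply(pop$leaflets$damaged_area_mm2 / pop$leaflets$total_area_mm2,
                 pop$leaflets$plant_id, mean)
  r <- cor(m$std, herb[m$plant_id])
  expect_lt(abs(r), 0.12)
  expect_error(generate_population(cfg, "weird", generate_species_pool(cfg), 1), "unknown scenario")
})

test_that("surveys round-trip through CSV unchanged", {
  dir <- withr::local_tempdir()
  sv <- generate_survey(scenario_config(n_populations = 3L,
                                        scenarios = c("matched_small", "matched_big", "mismatched"),
                                        hotspots = c(TRUE, FALSE, FALSE),
                                        n_plants_per_pop = 10L, seed = 6L))
  write_survey(sv, dir)
  back <- read_survey(dir)
  for (tb in c("plants", "ant_observations", "leaflets", "ant_species", "populations"))
    expect_equal(back[[tb]], as.data.frame(sv[[tb]]), tolerance = 1e-12,
                 ignore_attr = TRUE)
  expect_equal(back$ground_truth$populations$matched, sv$ground_truth$populations$matched)
})

test_that("ground truth bookkeeping matches the scenario vector", {
  cfg <- scenario_config(scenarios = c("matched_small", rep("matched_big", 7),
                                       "mismatched", "mismatched"),
                         hotspots = rep(FALSE, 10), seed = 3L)
  gt <- generate_survey(cfg)$ground_truth$populations
  expect_equal(sum(gt$matched), 8)
  expect_equal(gt$matching_type[gt$scenario == "matched_small"], "small-ant/low-EFN")
  expect_equal(unique(gt$matching_type[gt$scenario == "mismatched"]), "not-applicable")
})
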