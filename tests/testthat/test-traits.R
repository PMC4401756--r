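test_that("abundance standardization rescales to 100 leaves", {
  expect_equal(standardize_abundance(5, 100), 5)
  expect_equal(standardize_abundance(3, 50), 6)
  expect_equal(standardize_abundance(0, 80), 0)
  expect_error(standardize_abundance(2, 0), "positive")
})

test_that("plant ant abundance averages the two censuses and refuses missing ones", {
  expect_equal(plant_ant_abundance(4, 4), 4)
  expect_equal(plant_ant_abundance(2, 6), 4)
  expect_equal(plant_ant_abundance(0, 0), 0)
  expect_error(plant_ant_abundance(NA, 3), "both censuses")
})

test_that("species recruitment is the maximum standardized abundance", {
  expect_equal(species_recruitment(3.2), 3.2)
  expect_equal(species_recruitment(c(2, 8, 5)), 8)
  expect_error(species_recruitment(numeric(0)), "never observed")
  # exhaustive-scan oracle: standardization first, then max over all
  # plant-census observations
  set.seed(10)
  counts <- sample(0:20, 30, replace = TRUE)
  leaves <- sample(40:200, 30, replace = TRUE)
  std <- counts / leaves * 100
  best <- -Inf
  for (i in 1:30) best <- max(best, counts[i] / leaves[i] * 100)
  expect_equal(species_recruitment(standardize_abundance(counts, leaves)), best)
})

test_that("species profiles aggregate visited-plant phenotypes with the >5-plant filter", {
  sv <- toy_survey()
  ptr <- plant_phenotypes(sv$leaflets)
  prof <- species_profiles(sv$plants, sv$ant_observations, sv$ant_species, ptr)
  expect_s3_class(prof, "ant_species_profiles")
  # antA visited p1 (both censuses -> one distinct plant) and p5
  expect_equal(prof$n_plants_visited[prof$species == "antA"], 2L)
  expect_false(any(prof$eligible))   # nobody reaches 6 distinct plants here
  # recruitment = max standardized abundance: antA max(5/100, 4/110, 2/66)*100
  expect_equal(prof$recruitment[prof$species == "antA"], 5)
  # a plant hosting two species contributes its phenotype to both
  obs2 <- rbind(sv$ant_observations,
                data.frame(plant_id = "p1", census = "t0", species = "antB", count = 1L))
  prof2 <- species_profiles(sv$plants, obs2, sv$ant_species, ptr)
  p1_efn <- ptr$efn_per_leaflet[ptr$plant_id == "p1"]
  for (sp in c("antA", "antB")) {
    visited <- prof2[prof2$species == sp, ]
    expect_true(visited$n_plants_visited >= 2)
  }

  # eligibility boundary: exactly 5 distinct plants -> excluded, 6 -> eligible
  plants <- data.frame(population_id = "A", plant_id = paste0("q", 1:6),
                       census = "t0", n_leaves = 100, flowering = FALSE,
                       n_seedlings_2m = 0L)
  lf <- data.frame(plant_id = rep(paste0("q", 1:6), each = 2), leaflet_id = 1:2,
                   total_area_mm2 = 100, damaged_area_mm2 = 10,
                   efn_count_base = rep(c(10L, 20L, 30L, 40L, 50L, 60L), each = 2),
                   efn_diameter_mm = 0.2)
  spt <- data.frame(species = c("five", "six"), body_length_mm = c(4, 5))
  obs <- rbind(data.frame(plant_id = paste0("q", 1:5), census = "t0",
                          species = "five", count = 1L),
               data.frame(plant_id = paste0("q", 1:6), census = "t0",
                          species = "six", count = 1L))
  prof3 <- species_profiles(plants, obs, spt, plant_phenotypes(lf))
  expect_false(prof3$eligible[prof3$species == "five"])
  expect_true(prof3$eligible[prof3$species == "six"])
  expect_equal(prof3$mean_efn_visited[prof3$species == "six"], 35)
})

test_that("community-level traits are occupancy-weighted means within species bounds", {
  expect_equal(community_level_trait(c(a = 4), c(a = 2)), 4)
  expect_equal(community_level_trait(c(a = 4, b = 8), c(a = 1, b = 3)), 7)
  expect_equal(community_level_trait(c(a = 4, b = 8), c(a = 2, b = 2)), 6)
  expect_true(is.na(community_level_trait(c(a = 4), c(a = 0))))
  # scale equivariance and bounds on random weights
  set.seed(77)
  for (i in 1:50) {
    tr <- stats::setNames(runif(4, 2, 9), letters[1:4])
    w <- stats::setNames(sample(0:5, 4, replace = TRUE), letters[1:4])
    if (all(w == 0)) next
    ct <- community_level_trait(tr, w)
    expect_gte(ct, min(tr[w > 0])); expect_lte(ct, max(tr[w > 0]))
    expect_equal(community_level_trait(tr * 3, w), 3 * ct, tolerance = 1e-12)
  }
})

test_that("occupancy stability tallies both/neither/same-species proportions", {
  # 10 plants: 5 occupied in both (4 same species), 2 in neither, 3 in one
  plants <- data.frame(population_id = "A",
                       plant_id = rep(paste0("p", 1:10), each = 2),
                       census = rep(c("t0", "t1"), 10),
                       n_leaves = 100, flowering = FALSE, n_seedlings_2m = 0L)
  occ <- rbind(
    data.frame(plant_id = paste0("p", 1:5), census = "t0",
               species = c("x", "x", "x", "x", "y"), count = 1L),
    data.frame(plant_id = paste0("p", 1:5), census = "t1",
               species = c("x", "x", "x", "x", "z"), count = 1L),
    data.frame(plant_id = paste0("p", 6:8), census = "t0", species = "x", count = 1L))
  st <- occupancy_stability(plants, occ)
  expect_equal(st$prop_both, 0.5)
  expect_equal(st$prop_neither, 0.2)
  expect_equal(st$prop_same_species, 0.8)
  expect_equal(st$n_plants, 10L)
})

test_that("full persistence yields identical occupants among doubly occupied plants", {
  cfg <- scenario_config(n_populations = 2L, scenarios = c("matched_big", "matched_big"),
                         hotspots = c(FALSE, FALSE), persistence_prob = 1,
                         seed = 33L)
  sv <- generate_survey(cfg)
  st <- occupancy_stability(sv$plants, sv$ant_observations)
  expect_equal(st$prop_same_species, 1)
})

test_that("community traits table covers every population and census handling modes", {
  sv <- toy_survey()
  ptr <- plant_phenotypes(sv$leaflets)
  prof <- species_profiles(sv$plants, sv$ant_observations, sv$ant_species, ptr)
  for (mode in c("union", "t0", "t1", "pairs")) {
    ct <- community_traits(sv$plants, sv$ant_observations, prof, mode)
    expect_setequal(ct$population_id, c("A", "B"))
    ok <- !is.na(ct$community_size_mm)
    expect_true(all(ct$community_size_mm[ok] >= min(prof$body_length_mm) &
                      ct$community_size_mm[ok] <= max(prof$body_length_mm)))
  }
})
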