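# Shared fixtures and independent oracles used across the test files.

# Independent PS oracle: literal evaluation of 2W/(A+B) over the union of
# species names, with no shared code with the implementation.
ps_oracle <- function(a, b) {
  species <- union(names(a), names(b))
  W <- 0; A <- 0; B <- 0
  for (sp in species) {
    xa <- if (sp %in% names(a)) sum(a[names(a) == sp]) else 0
    xb <- if (sp %in% names(b)) sum(b[names(b) == sp]) else 0
    W <- W + min(xa, xb); A <- A + xa; B <- B + xb
  }
  2 * W / (A + B)
}

random_assemblage <- function(n_species_max = 8, pool = paste0("sp", 1:12)) {
  k <- sample(1:n_species_max, 1)
  sp <- sample(pool, k)
  stats::setNames(sample(1:50, k, replace = TRUE), sp)
}

# Independent full-permutation generator (recursive, distinct from the
# package internals).
perms_oracle <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms_oracle(n - 1)) {
    for (i in 0:(n - 1)) out[[length(out) + 1L]] <- append(p, n, after = i)
  }
  out
}

# A minimal hand-built survey: 2 populations x 3 plants, 2 censuses.
toy_survey <- function() {
  plants <- expand.grid(plant_id = paste0("p", 1:6), census = c("t0", "t1"),
                        stringsAsFactors = FALSE)
  plants$population_id <- rep(c("A", "B"), each = 3)[match(plants$plant_id, paste0("p", 1:6))]
  plants$n_leaves <- c(100, 50, 80, 120, 60, 90, 110, 50, 70, 120, 66, 95)
  plants$flowering <- rep(c(TRUE, FALSE), 6)
  plants$n_seedlings_2m <- rep(2L, 12)
  ant_obs <- data.frame(
    plant_id = c("p1", "p2", "p1", "p4", "p4", "p5"),
    census = c("t0", "t0", "t1", "t0", "t1", "t1"),
    species = c("antA", "antB", "antA", "antB", "antB", "antA"),
    count = c(5L, 3L, 4L, 6L, 6L, 2L), stringsAsFactors = FALSE)
  leaflets <- do.call(rbind, lapply(paste0("p", 1:6), function(id) {
    data.frame(plant_id = id, leaflet_id = 1:4,
               total_area_mm2 = c(500, 600, 550, 480),
               damaged_area_mm2 = c(50, 120, 0, 48),
               efn_count_base = c(10L, 12L, 8L, 11L),
               efn_diameter_mm = 0.17, stringsAsFactors = FALSE)
  }))
  populations <- data.frame(population_id = c("A", "B"),
                            lat = c(-12.5, -14.0), lon = c(-41.5, -42.1),
                            stringsAsFactors = FALSE)
  ant_species <- data.frame(species = c("antA", "antB"),
                            body_length_mm = c(3.1, 7.4), stringsAsFactors = FALSE)
  list(plants = plants, ant_observations = ant_obs, leaflets = leaflets,
       populations = populations, ant_species = ant_species,
       herbivore_observations = data.frame(
         plant_id = "p1", census = "t0", species = "herb01", count = 2L,
         stringsAsFactors = FALSE))
}

# Hand-built species profile table for interface tests.
toy_profiles <- function(y = NULL) {
  x <- c(2.5, 3.5, 4.5, 5.5, 6.5, 7.5)
  data.frame(species = paste0("ant", 1:6),
             body_length_mm = x,
             recruitment = c(40, 30, 22, 15, 10, 6),
             n_plants_visited = c(10L, 12L, 9L, 8L, 11L, 10L),
             mean_efn_visited = if (is.null(y)) 8 * x - 10 else y,
             mean_herbivory_visited = c(0.12, 0.18, 0.25, 0.28, 0.33, 0.36),
             eligible = TRUE, stringsAsFactors = FALSE)
}

classify_survey <- function(sv, ...) {
  ptr <- plant_phenotypes(sv$leaflets)
  prof <- species_profiles(sv$plants, sv$ant_observations, sv$ant_species, ptr)
  pheno <- population_phenotypes(sv$plants, sv$ant_observations, sv$leaflets, prof)
  pe <- merge(ptr[, c("plant_id", "efn_per_leaflet")],
              unique(sv$plants[, c("plant_id", "population_id")]), by = "plant_id")
  classify_mosaic(pheno, prof, pe, ...)
}
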