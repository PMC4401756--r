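#' Standardize an ant count by plant size
#'
#' Ant abundance per plant is re-scaled to an intermediate plant size of 100
#' leaves: \code{count / n_leaves * 100}.
#'
#' @param count Non-negative ant count(s).
#' @param n_leaves Positive leaf count(s) of the censused plant.
#' @return Ants per 100 leaves (vectorized).
#' @export
standardize_abundance <- function(count, n_leaves) {
  if (any(n_leaves <= 0)) stop("n_leaves must be positive for standardization")
  if (any(count < 0)) stop("ant counts must be non-negative")
  count / n_leaves * 100
}

#' Per-plant ant abundance across the two censuses
#'
#' The abundance assigned to a plant is the arithmetic mean of its
#' standardized abundances at the first (t0) and second (t1) census. A plant
#' missing either census has no defined abundance; see Details.
#'
#' @param std_t0,std_t1 Standardized abundances (ants per 100 leaves) at t0
#'   and t1. \code{NA} marks a missing census and is an error.
#' @return Mean standardized abundance (vectorized).
#' @export
plant_ant_abundance <- function(std_t0, std_t1) {
  if (anyNA(std_t0) || anyNA(std_t1))
    stop("both censuses are required; plants missing a census must be excluded, not imputed")
  (std_t0 + std_t1) / 2
}

#' Species recruitment from standardized observations
#'
#' Recruitment capacity of an ant species is operationalized as the maximum
#' standardized per-plant abundance observed for that species across all
#' plants sampled and both censuses.
#'
#' @param std_observations Numeric vector of standardized abundances (ants
#'   per 100 leaves), one per plant-census observation of the species.
#' @return The maximum (ants per 100 leaves).
#' @export
species_recruitment <- function(std_observations) {
  if (length(std_observations) < 1L) stop("species never observed")
  if (anyNA(std_observations)) stop("missing standardized observations")
  max(std_observations)
}

#' Species-level functional profiles from survey tables
#'
#' Builds one row per ant species: mean body length, recruitment (maximum
#' standardized abundance over all plant-census observations, all
#' populations pooled), the number of distinct plants visited, and the mean
#' EFN abundance and herbivory of those plants. A plant hosting two species
#' contributes its phenotype to both. Species visiting fewer than
#' \code{min_plants} distinct plants are retained but flagged ineligible for
#' interface regressions.
#'
#' @param plants Plant census table (\code{population_id, plant_id, census,
#'   n_leaves, flowering, n_seedlings_2m}).
#' @param ant_obs Ant observation table (\code{plant_id, census, species,
#'   count}).
#' @param ant_species Species table (\code{species, body_length_mm}).
#' @param plant_traits Per-plant phenotypes as returned by
#'   [plant_phenotypes()] (\code{plant_id, efn_per_leaflet, herbivory}).
#' @param min_plants Minimum distinct plants for eligibility (default 6,
#'   i.e. species must visit more than five plants).
#' @param per_population Compute recruitment within each population instead
#'   of over the pooled plant sample (default \code{FALSE}, pooled).
#' @return Data frame of class \code{ant_species_profiles} with columns
#'   \code{species, body_length_mm, recruitment, n_plants_visited,
#'   mean_efn_visited, mean_herbivory_visited, eligible}.
#' @export
species_profiles <- function(plants, ant_obs, ant_species, plant_traits,
                             min_plants = 6L, per_population = FALSE) {
  obs <- merge(ant_obs, plants[, c("plant_id", "census", "population_id", "n_leaves")],
               by = c("plant_id", "census"))
  if (nrow(obs) < nrow(ant_obs))
    warning(nrow(ant_obs) - nrow(obs), " ant observation(s) dropped: no matching plant-census record")
  if (nrow(obs) == 0L) stop("no ant observations match the plant table")
  obs$std <- standardize_abundance(obs$count, obs$n_leaves)

  if (per_population) {
    rec_tab <- stats::aggregate(std ~ species + population_id, data = obs, FUN = max)
    recruitment <- tapply(rec_tab$std, rec_tab$species, max)  # pooled column still reported
  } else {
    recruitment <- tapply(obs$std, obs$species, max)
  }

  visited <- unique(obs[, c("species", "plant_id")])
  visited <- merge(visited, plant_traits[, c("plant_id", "efn_per_leaflet", "herbivory")],
                   by = "plant_id")
  n_visited <- tapply(visited$plant_id, visited$species, function(p) length(unique(p)))
  mean_efn <- tapply(visited$efn_per_leaflet, visited$species, mean)
  mean_herb <- tapply(visited$herbivory, visited$species, mean)

  sp <- sort(unique(obs$species))
  size <- stats::setNames(ant_species$body_length_mm, ant_species$species)[sp]
  if (anyNA(size)) stop("species missing from ant_species table: ",
                        paste(sp[is.na(size)], collapse = ", "))
  out <- data.frame(
    species = sp,
    body_length_mm = unname(size),
    recruitment = unname(recruitment[sp]),
    n_plants_visited = as.integer(unname(n_visited[sp])),
    mean_efn_visited = unname(mean_efn[sp]),
    mean_herbivory_visited = unname(mean_herb[sp]),
    stringsAsFactors = FALSE
  )
  out$eligible <- out$n_plants_visited >= min_plants
  class(out) <- c("ant_species_profiles", "data.frame")
  out
}

#' Community-level weighted trait mean
#'
#' Population-level functional trait of the ant visitor assemblage: the mean
#' of a species trait weighted by the number of plants each species occupied
#' in that population.
#'
#' @param trait_values Named numeric vector of species trait values.
#' @param weights Named numeric vector of occupancy weights (distinct plants
#'   occupied); names must be a subset of \code{names(trait_values)}.
#' @return The weighted mean, or \code{NA_real_} with class note when no
#'   species has positive weight.
#' @export
community_level_trait <- function(trait_values, weights) {
  weights <- weights[weights > 0]
  if (length(weights) == 0L) return(NA_real_)
  tv <- trait_values[names(weights)]
  if (anyNA(tv)) stop("trait value missing for species: ",
                      paste(names(weights)[is.na(tv)], collapse = ", "))
  sum(tv * weights) / sum(weights)
}

#' Community-level ant traits for every population
#'
#' @inheritParams species_profiles
#' @param profiles Output of [species_profiles()].
#' @param census_handling How occupancy weights count plants:
#'   \code{"union"} (default) distinct plants occupied in either census;
#'   \code{"t0"} or \code{"t1"} a single census; \code{"pairs"} plant-census
#'   pairs.
#' @return Data frame with one row per population: \code{population_id,
#'   community_size_mm, community_recruitment, n_occupied_plants}.
#' @export
community_traits <- function(plants, ant_obs, profiles,
                             census_handling = c("union", "t0", "t1", "pairs")) {
  census_handling <- match.arg(census_handling)
  obs <- merge(ant_obs, plants[, c("plant_id", "census", "population_id")],
               by = c("plant_id", "census"))
  obs <- switch(census_handling,
                union = unique(obs[, c("population_id", "plant_id", "species")]),
                t0 = unique(obs[obs$census == "t0", c("population_id", "plant_id", "species")]),
                t1 = unique(obs[obs$census == "t1", c("population_id", "plant_id", "species")]),
                pairs = obs[, c("population_id", "plant_id", "species")])
  size <- stats::setNames(profiles$body_length_mm, profiles$species)
  rec <- stats::setNames(profiles$recruitment, profiles$species)
  pops <- sort(unique(plants$population_id))
  rows <- lapply(pops, function(p) {
    sub <- obs[obs$population_id == p, ]
    if (nrow(sub) == 0L)
      return(data.frame(population_id = p, community_size_mm = NA_real_,
                        community_recruitment = NA_real_, n_occupied_plants = 0L))
    w <- table(sub$species)
    w <- stats::setNames(as.numeric(w), names(w))
    data.frame(population_id = p,
               community_size_mm = community_level_trait(size, w),
               community_recruitment = community_level_trait(rec, w),
               n_occupied_plants = length(unique(sub$plant_id)))
  })
  do.call(rbind, rows)
}

#' Seasonal occupancy stability
#'
#' Summarizes how stable ant occupancy is between the two censuses:
#' proportions of plants occupied in both censuses, in neither, and — among
#' plants occupied in both — by the same ant species.
#'
#' @inheritParams species_profiles
#' @return List of class \code{occupancy_stability}: \code{prop_both},
#'   \code{prop_neither}, \code{prop_same_species}, \code{n_plants},
#'   \code{per_population} (data frame of per-population proportions of
#'   occupied plants at t0 and t1, for regression use).
#' @export
occupancy_stability <- function(plants, ant_obs) {
  wide <- occupancy_table(plants, ant_obs)
  if (nrow(wide) == 0L) stop("no plants with both censuses")
  both <- wide$occ_t0 & wide$occ_t1
  neither <- !wide$occ_t0 & !wide$occ_t1
  same <- wide$species_t0[both] == wide$species_t1[both]
  per_pop <- stats::aggregate(cbind(occ_t0, occ_t1) ~ population_id, data = wide, FUN = mean)
  structure(list(prop_both = mean(both),
                 prop_neither = mean(neither),
                 prop_same_species = if (any(both)) mean(same) else NA_real_,
                 n_plants = nrow(wide),
                 per_population = per_pop),
            class = "occupancy_stability")
}

# One row per plant having both censuses, with occupancy flags and the
# dominant (most abundant) occupant species per census.
occupancy_table <- function(plants, ant_obs) {
  has_both <- tapply(plants$census, plants$plant_id,
                     function(cc) all(c("t0", "t1") %in% cc))
  keep <- names(has_both)[has_both]
  dropped <- setdiff(unique(plants$plant_id), keep)
  if (length(dropped) > 0L)
    warning(length(dropped), " plant(s) missing a census excluded from stability: ",
            paste(utils::head(dropped, 5L), collapse = ", "))
  pl <- unique(plants[plants$plant_id %in% keep, c("plant_id", "population_id")])
  occ <- function(cen) {
    sub <- ant_obs[ant_obs$census == cen & ant_obs$plant_id %in% keep, ]
    if (nrow(sub) == 0L)
      return(data.frame(plant_id = character(), species = character()))
    sub <- sub[order(sub$plant_id, -sub$count), ]
    sub[!duplicated(sub$plant_id), c("plant_id", "species")]
  }
  o0 <- occ("t0"); o1 <- occ("t1")
  pl$occ_t0 <- pl$plant_id %in% o0$plant_id
  pl$occ_t1 <- pl$plant_id %in% o1$plant_id
  pl$species_t0 <- stats::setNames(o0$species, o0$plant_id)[pl$plant_id]
  pl$species_t1 <- stats::setNames(o1$species, o1$plant_id)[pl$plant_id]
  pl
}

#' @export
print.occupancy_stability <- function(x, ...) {
  cat(sprintf("Occupancy stability over %d plants: %.0f%% occupied in both censuses, %.0f%% in neither;\n",
              x$n_plants, 100 * x$prop_both, 100 * x$prop_neither))
  cat(sprintf("among doubly occupied plants, %.0f%% kept the same ant species.\n",
              100 * x$prop_same_species))
  invisible(x)
}
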