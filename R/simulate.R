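#' Scenario configuration for the synthetic survey generator
#'
#' Builds the parameter set describing a multi-population ant-plant-herbivore
#' survey: a regional ant species pool with a size-recruitment trade-off,
#' per-population scenarios (phenotypically matched with small or big ants,
#' or mismatched with scarce unselective ants), EFN abundance distributions,
#' visitation driven by a Gaussian kernel between ant body size and the
#' plant's EFN phenotype, herbivory that decreases with ant visitation, and
#' plant performance that rises as herbivory falls. Defaults emulate a
#' 10-population, 30-plants-per-population, two-census survey of a savanna
#' EFN shrub spanning ~600 km, with one small-ant matched population, seven
#' big-ant matched populations and two mismatched populations; three of the
#' matched populations are designed evolutionary hotspots (boosted ant
#' guarding, performance, and narrow EFN variation).
#'
#' @param n_populations,n_plants_per_pop,n_species Survey dimensions.
#' @param scenarios Character vector (length \code{n_populations}) of
#'   \code{"matched_small"}, \code{"matched_big"}, \code{"mismatched"}.
#' @param hotspots Logical vector marking designed hotspot populations
#'   (must be matched).
#' @param size_log_mean,size_log_sd Log-scale parameters (natural log, mm)
#'   of ant body length.
#' @param tradeoff_intercept,tradeoff_slope,tradeoff_noise_sd Parameters of
#'   the species-level trade-off \code{log10(recruitment) = intercept +
#'   slope * size + noise}; slope must be negative.
#' @param efn_mean_by_scenario Named vector of expected EFN counts per
#'   leaflet for each scenario.
#' @param efn_mean_range_big Range over which the matched_big populations'
#'   EFN means are evenly spread (surveys sample a continuum of population
#'   phenotypes, not one value).
#' @param efn_dispersion Gamma shape of the among-plant EFN phenotype
#'   (leaflet counts are Poisson around the plant phenotype, giving a
#'   negative-binomial leaflet distribution); among-plant CV is
#'   \code{1/sqrt(shape)}.
#' @param hotspot_efn_dispersion Narrower dispersion used in hotspot
#'   populations.
#' @param visitation_kernel_sd Kernel width tau (mm): occupant species are
#'   drawn with probability proportional to
#'   \code{exp(-(size - g(EFN))^2 / (2 tau^2))} in matched populations;
#'   \code{tau = 0} degenerates to the nearest-size species.
#' @param centre_jitter_sd Standard deviation (mm) of the random
#'   displacement of each population's assemblage centre around its
#'   scenario value: real population phenotypes scatter around the
#'   regional gradient instead of sitting on an exact ladder.
#' @param turnover_kernel_sd Width (mm) of the assemblage-turnover kernel
#'   deciding which species are present in a population; narrower than the
#'   within-site visitation kernel, so assemblages turn over between
#'   populations faster than individual plants sort species within a site.
#' @param local_richness Expected number of ant species present in a
#'   population (assemblages are local draws from the regional pool, so
#'   different localities host different, partially overlapping sets of
#'   dominant ants).
#' @param niche_offset_sd Standard deviation (mm) of each species'
#'   idiosyncratic niche offset: body size is only a proxy for a species'
#'   EFN use, so species enter the visitation kernel at
#'   \code{size + offset}. This is what gives the cross-species
#'   phenotype-function regression its realistic residual scatter.
#' @param pref_size_intercept,pref_size_slope The increasing affine map
#'   \code{g(EFN) = intercept + slope * EFN} from a plant's EFN abundance to
#'   its preferred ant size (mm).
#' @param occupancy_prob_matched,occupancy_prob_mismatched Per-census
#'   probability that a plant hosts an ant; mismatched populations have
#'   scarce guards.
#' @param persistence_prob Probability that the t1 occupant equals the t0
#'   occupant.
#' @param herbivory_baseline Expected damage proportion on an unvisited
#'   plant.
#' @param herbivory_effect Logit-scale decrease of damage per unit
#'   standardized ant abundance (ants per 100 leaves).
#' @param herbivory_precision Beta precision of per-plant damage.
#' @param hotspot_visitation_boost Multiplier on ant counts in hotspot
#'   populations.
#' @param hotspot_herbivory_shift Extra logit-scale reduction of herbivory
#'   in hotspots.
#' @param hotspot_performance_boost Additive boost to relative leaf
#'   production in hotspots.
#' @param leaves_mean,leaves_dispersion Negative-binomial parameters of
#'   leaf counts at t0.
#' @param production_intercept,production_herbivory_slope,production_noise_sd
#'   Relative leaf production model: \code{intercept + slope *
#'   (herbivory_ref - herbivory) + noise}, floored at total leaf loss.
#' @param herbivory_ref Reference herbivory around which production is
#'   centred.
#' @param n_herbivore_species,herbivore_rate,mismatched_herbivore_boost
#'   Herbivore assemblage parameters (mean herbivores per plant-census;
#'   mismatched populations suffer herbivore outbreaks).
#' @param seed Master seed; all population- and stage-level streams are
#'   derived from it deterministically.
#' @return A list of class \code{scenario_config}.
#' @export
scenario_config <- function(n_populations = 10L,
                            n_plants_per_pop = 30L,
                            n_species = 15L,
                            scenarios = c("matched_small", rep("matched_big", 7L),
                                          "mismatched", "mismatched"),
                            hotspots = c(TRUE, TRUE, TRUE, rep(FALSE, 7L)),
                            size_log_mean = log(5),
                            size_log_sd = 0.55,
                            tradeoff_intercept = 1.9,
                            tradeoff_slope = -0.15,
                            tradeoff_noise_sd = 0.12,
                            efn_mean_by_scenario = c(matched_small = 3.2,
                                                     matched_big = 45,
                                                     mismatched = 12),
                            efn_mean_range_big = c(28, 56),
                            efn_dispersion = 5,
                            hotspot_efn_dispersion = 25,
                            visitation_kernel_sd = 1.5,
                            niche_offset_sd = 1.1,
                            local_richness = 4L,
                            turnover_kernel_sd = 1.0,
                            centre_jitter_sd = 0,
                            pref_size_intercept = 2.6,
                            pref_size_slope = 0.123,
                            occupancy_prob_matched = 0.7,
                            occupancy_prob_mismatched = 0.10,
                            persistence_prob = 0.74,
                            herbivory_baseline = 0.45,
                            herbivory_effect = 0.05,
                            herbivory_precision = 15,
                            hotspot_visitation_boost = 1.8,
                            hotspot_herbivory_shift = 1.0,
                            hotspot_performance_boost = 0.15,
                            leaves_mean = 80,
                            leaves_dispersion = 8,
                            production_intercept = 0.05,
                            production_herbivory_slope = 1.2,
                            production_noise_sd = 0.15,
                            herbivory_ref = 0.3,
                            n_herbivore_species = 8L,
                            herbivore_rate = 1.2,
                            mismatched_herbivore_boost = 2.5,
                            seed = 20260921L) {
  cfg <- as.list(environment())
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario_config <- function(cfg) {
  stopifnot_msg(cfg$n_populations >= 1 && cfg$n_plants_per_pop >= 1 && cfg$n_species >= 1,
                "all counts must be >= 1")
  stopifnot_msg(cfg$n_species >= 3, "need at least 3 ant species")
  stopifnot_msg(cfg$tradeoff_slope < 0, "tradeoff_slope must be negative")
  stopifnot_msg(cfg$persistence_prob >= 0 && cfg$persistence_prob <= 1,
                "persistence_prob must be in [0, 1]")
  stopifnot_msg(all(cfg$efn_mean_by_scenario > 0), "EFN scenario means must be positive")
  stopifnot_msg(length(cfg$scenarios) == cfg$n_populations,
                "scenarios must have one entry per population")
  stopifnot_msg(all(cfg$scenarios %in% c("matched_small", "matched_big", "mismatched")),
                "unknown scenario label")
  stopifnot_msg(length(cfg$hotspots) == cfg$n_populations,
                "hotspots must have one flag per population")
  stopifnot_msg(!any(cfg$hotspots & cfg$scenarios == "mismatched"),
                "a designed hotspot must be a matched population")
  stopifnot_msg(cfg$visitation_kernel_sd >= 0, "visitation_kernel_sd must be >= 0")
  invisible(cfg)
}

stopifnot_msg <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Generate the regional ant species pool
#'
#' Draws \code{n_species} ant species with log-normally distributed body
#' lengths and a latent recruitment capacity on the species-level trade-off
#' line \code{log10(recruitment) = tradeoff_intercept + tradeoff_slope *
#' size + Normal(0, tradeoff_noise_sd)}; smaller species recruit more
#' nestmates than bigger ones.
#'
#' @param config A \code{scenario_config}.
#' @return Data frame: \code{species, body_length_mm, latent_recruitment}.
#' @export
generate_species_pool <- function(config) {
  validate_scenario_config(config)
  old <- set_local_seed(derive_seed(config$seed, "species_pool"))
  on.exit(restore_seed(old), add = TRUE)
  # truncated log-normal: EFN-visiting ants span roughly 1.5-14 mm
  # (Crematogaster ~3 mm to the largest Camponotus/Cephalotes foragers)
  lo <- stats::plnorm(1.5, config$size_log_mean, config$size_log_sd)
  hi <- stats::plnorm(14, config$size_log_mean, config$size_log_sd)
  size <- stats::qlnorm(stats::runif(config$n_species, lo, hi),
                        config$size_log_mean, config$size_log_sd)
  log_rec <- config$tradeoff_intercept + config$tradeoff_slope * size +
    stats::rnorm(config$n_species, 0, config$tradeoff_noise_sd)
  niche <- stats::rnorm(config$n_species, 0, config$niche_offset_sd %||% 0)
  data.frame(species = sprintf("ant%02d", seq_len(config$n_species)),
             body_length_mm = size,
             latent_recruitment = 10^log_rec,
             niche_offset_mm = niche,
             stringsAsFactors = FALSE)
}

# Local assemblage of a population: each species is present with
# probability proportional to the availability kernel around the
# population's local preferred ant size (ant assemblages differ among
# localities), scaled so that on average local_richness species are
# present. Mismatched populations host regionally common (mid-to-large)
# ants -- their assemblage does not track the local EFN phenotype but is
# not a random grab-bag either. With tau = 0 every species is nominally
# present and the plant-level kernel degenerates below.
local_assemblage <- function(pool, config, scenario, pop_efn_mean) {
  n_local <- config$local_richness %||% 3L
  if (config$visitation_kernel_sd == 0) return(pool$species)
  eff_size <- pool$body_length_mm + (pool$niche_offset_mm %||% rep(0, nrow(pool)))
  centre_efn <- if (scenario == "mismatched")
    regional_efn_mean(config) else pop_efn_mean
  g_pop <- config$pref_size_intercept + config$pref_size_slope * centre_efn +
    stats::rnorm(1L, 0, config$centre_jitter_sd %||% 0)
  tk <- config$turnover_kernel_sd %||% config$visitation_kernel_sd
  w <- exp(-(eff_size - g_pop)^2 / (2 * tk^2))
  if (sum(w) == 0) return(pool$species[which.min(abs(eff_size - g_pop))])
  p <- pmin(1, n_local * w / sum(w))
  present <- pool$species[stats::runif(nrow(pool)) < p]
  if (length(present) == 0L) present <- pool$species[which.max(w)]
  present
}

# Regional mean EFN phenotype over the configured scenario mix: the
# abundance-weighted backdrop that regionally common ants experience.
regional_efn_mean <- function(config) {
  # dominated by the widespread big-ant populations (Camponotus-type ants
  # are the regionally common EFN visitors)
  mean(config$efn_mean_range_big)
}

# EFN abundance implied by a realized local assemblage: matched
# populations carry plants whose mean EFN phenotype has adapted to the
# community-level trait of the local ants -- the mean body size of the
# species present, weighted by their expected share of occupied plants
# (the visitation kernel at the assemblage centre) -- inverted through the
# preferred-size map.
implied_efn_mean <- function(pool, present, config, centre_efn, dispersion) {
  local <- pool[pool$species %in% present, , drop = FALSE]
  eff <- local$body_length_mm + (local$niche_offset_mm %||% rep(0, nrow(local)))
  g_c <- config$pref_size_intercept + config$pref_size_slope * centre_efn
  # expected occupancy share: visitation kernel marginalized over the
  # among-plant spread of EFN phenotypes
  sigma_g <- config$pref_size_slope * centre_efn / sqrt(dispersion)
  v <- config$visitation_kernel_sd^2 + sigma_g^2
  w <- exp(-(eff - g_c)^2 / (2 * v))
  if (sum(w) == 0) w <- rep(1, nrow(local))
  comm_size <- sum(w * local$body_length_mm) / sum(w)
  max(0.5, (comm_size - config$pref_size_intercept) / config$pref_size_slope)
}

# Draw one occupant for a plant with EFN phenotype efn from the species
# present in the population. Species enter the kernel at size +
# idiosyncratic niche offset (body size is only a proxy for a species'
# actual EFN use); with tau = 0 the draw degenerates to the species whose
# size is nearest g(EFN_plant); mismatched populations are unselective.
draw_occupant <- function(efn, pool, config, scenario, present) {
  local <- pool[pool$species %in% present, , drop = FALSE]
  if (scenario == "mismatched")
    return(local$species[sample.int(nrow(local), 1L)])
  g <- config$pref_size_intercept + config$pref_size_slope * efn
  if (config$visitation_kernel_sd == 0)
    return(pool$species[which.min(abs(pool$body_length_mm - g))])
  eff_size <- local$body_length_mm + (local$niche_offset_mm %||% rep(0, nrow(local)))
  w <- exp(-(eff_size - g)^2 / (2 * config$visitation_kernel_sd^2))
  if (sum(w) == 0) return(local$species[which.min(abs(eff_size - g))])
  local$species[sample.int(nrow(local), 1L, prob = w)]
}

#' Generate census records for one population
#'
#' Simulates all plants of one population across both censuses: plant EFN
#' phenotypes (gamma-mixed Poisson leaflet counts), leaf counts, ant
#' occupancy driven by the size-EFN visitation kernel (uniform and sparse
#' under the mismatched scenario), per-census ant counts from each
#' occupant's recruitment, beta-distributed herbivory decreasing with
#' standardized ant abundance, leaf production rising as herbivory falls,
#' flowering and seedling fitness descriptors, and a local herbivore
#' assemblage.
#'
#' @param config A \code{scenario_config}.
#' @param scenario One of \code{"matched_small"}, \code{"matched_big"},
#'   \code{"mismatched"}.
#' @param species_pool Output of [generate_species_pool()].
#' @param seed Integer seed for this population's stream.
#' @param population_id Label used in the output tables.
#' @param hotspot Is this population a designed evolutionary hotspot?
#' @param efn_mean Expected EFN count per leaflet for this population;
#'   defaults to the scenario's entry in \code{efn_mean_by_scenario}.
#'   [generate_survey()] spreads the matched_big populations over
#'   \code{efn_mean_range_big} so the survey samples a continuum of EFN
#'   phenotypes, as real population means do.
#' @return List of data frames: \code{plants} (one row per plant-census),
#'   \code{ant_obs}, \code{leaflets}, \code{herbivore_obs}.
#' @export
generate_population <- function(config, scenario, species_pool, seed,
                                population_id = "pop1", hotspot = FALSE,
                                efn_mean = NULL) {
  if (!scenario %in% c("matched_small", "matched_big", "mismatched"))
    stop("unknown scenario: ", scenario)
  if (nrow(species_pool) == 0L) stop("empty species pool")
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  n <- config$n_plants_per_pop
  efn_mean <- efn_mean %||% config$efn_mean_by_scenario[[scenario]]
  k <- if (hotspot) config$hotspot_efn_dispersion else config$efn_dispersion
  p_occ <- if (scenario == "mismatched") config$occupancy_prob_mismatched
           else config$occupancy_prob_matched
  vis_boost <- if (hotspot) config$hotspot_visitation_boost else 1
  rec <- stats::setNames(species_pool$latent_recruitment, species_pool$species)

  # assemblage first, phenotype second: in matched populations the plant
  # trait has evolved toward the value implied by the realized local
  # assemblage (efn_mean fixes the assemblage centre); in mismatched
  # populations the trait ignores the (regionally typical) local ants
  present <- local_assemblage(species_pool, config, scenario, efn_mean)
  if (scenario != "mismatched" && config$visitation_kernel_sd > 0)
    efn_mean <- implied_efn_mean(species_pool, present, config, efn_mean, k)

  plant_ids <- sprintf("%s_p%02d", population_id, seq_len(n))
  efn_pheno <- stats::rgamma(n, shape = k, scale = efn_mean / k)
  leaves_t0 <- pmax(10L, stats::rnbinom(n, mu = config$leaves_mean,
                                        size = config$leaves_dispersion))

  # leaflet sample per plant (collected once, between censuses)
  leaflets <- do.call(rbind, lapply(seq_len(n), function(i) {
    nl <- sample(5:9, 1L)
    total <- stats::rgamma(nl, shape = 6, scale = 100)
    data.frame(plant_id = plant_ids[i], leaflet_id = seq_len(nl),
               total_area_mm2 = total,
               damaged_area_mm2 = NA_real_,   # filled after herbivory below
               efn_count_base = stats::rpois(nl, efn_pheno[i]),
               efn_diameter_mm = pmax(0.05, stats::rnorm(nl, 0.17, 0.02)),
               stringsAsFactors = FALSE)
  }))

  occ_t0 <- stats::runif(n) < p_occ
  sp_t0 <- rep(NA_character_, n)
  sp_t0[occ_t0] <- vapply(which(occ_t0), function(i)
    draw_occupant(efn_pheno[i], species_pool, config, scenario, present), character(1L))
  persist <- stats::runif(n) < config$persistence_prob
  occ_t1 <- logical(n); sp_t1 <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (occ_t0[i] && persist[i]) {
      occ_t1[i] <- TRUE; sp_t1[i] <- sp_t0[i]
    } else if (stats::runif(1) < p_occ) {
      occ_t1[i] <- TRUE
      sp_t1[i] <- draw_occupant(efn_pheno[i], species_pool, config, scenario, present)
    }
  }

  count_for <- function(sp, leaves) {
    if (is.na(sp)) return(0L)
    max(1L, stats::rpois(1L, rec[[sp]] * leaves / 100 * vis_boost))
  }
  cnt_t0 <- vapply(seq_len(n), function(i) count_for(sp_t0[i], leaves_t0[i]), integer(1L))
  std_t0 <- cnt_t0 / leaves_t0 * 100

  # herbivory responds to the t0 standardized abundance (guards present
  # through the damage-accumulation season)
  h_shift <- if (hotspot) config$hotspot_herbivory_shift else 0
  mu_h <- stats::plogis(stats::qlogis(config$herbivory_baseline) -
                          config$herbivory_effect * std_t0 - h_shift)
  phi <- config$herbivory_precision
  herb <- stats::rbeta(n, mu_h * phi, (1 - mu_h) * phi)
  herb <- pmin(pmax(herb, 1e-4), 1 - 1e-4)

  perf_boost <- if (hotspot) config$hotspot_performance_boost else 0
  rp <- config$production_intercept +
    config$production_herbivory_slope * (config$herbivory_ref - herb) +
    perf_boost + stats::rnorm(n, 0, config$production_noise_sd)
  rp <- pmax(rp, -1)
  leaves_t1 <- pmax(1L, as.integer(round(leaves_t0 * (1 + rp))))
  rp_real <- (leaves_t1 - leaves_t0) / leaves_t0

  cnt_t1 <- vapply(seq_len(n), function(i) count_for(sp_t1[i], leaves_t1[i]), integer(1L))

  p_flower <- stats::plogis(-0.5 + 2 * rp_real + perf_boost)
  flowering_t0 <- stats::runif(n) < p_flower
  flowering_t1 <- stats::runif(n) < p_flower
  seedlings <- stats::rpois(n, exp(0.3 + 1 * rp_real + perf_boost))

  # leaflet damage shares the plant's expected damage proportion
  for (i in seq_len(n)) {
    sel <- leaflets$plant_id == plant_ids[i]
    nl <- sum(sel)
    frac <- stats::rbeta(nl, herb[i] * 20, (1 - herb[i]) * 20)
    leaflets$damaged_area_mm2[sel] <- leaflets$total_area_mm2[sel] * frac
  }

  plants <- rbind(
    data.frame(population_id = population_id, plant_id = plant_ids, census = "t0",
               n_leaves = leaves_t0, flowering = flowering_t0,
               n_seedlings_2m = seedlings, stringsAsFactors = FALSE),
    data.frame(population_id = population_id, plant_id = plant_ids, census = "t1",
               n_leaves = leaves_t1, flowering = flowering_t1,
               n_seedlings_2m = seedlings, stringsAsFactors = FALSE))

  ant_obs <- rbind(
    data.frame(plant_id = plant_ids[occ_t0], census = rep("t0", sum(occ_t0)),
               species = sp_t0[occ_t0], count = cnt_t0[occ_t0],
               stringsAsFactors = FALSE),
    data.frame(plant_id = plant_ids[occ_t1], census = rep("t1", sum(occ_t1)),
               species = sp_t1[occ_t1], count = cnt_t1[occ_t1],
               stringsAsFactors = FALSE))

  herbivore_obs <- simulate_herbivores(config, scenario, population_id, plant_ids)

  list(plants = plants, ant_obs = ant_obs, leaflets = leaflets,
       herbivore_obs = herbivore_obs)
}

simulate_herbivores <- function(config, scenario, population_id, plant_ids) {
  nh <- config$n_herbivore_species
  hsp <- sprintf("herb%02d", seq_len(nh))
  # regional abundance profile (geometric ranks) with population-level jitter
  base <- 0.6 ^ seq_len(nh)
  comp <- base * stats::rlnorm(nh, 0, 1.0)
  comp <- comp / sum(comp)
  rate <- config$herbivore_rate *
    if (scenario == "mismatched") config$mismatched_herbivore_boost else 1
  rows <- list()
  for (cen in c("t0", "t1")) for (pid in plant_ids) {
    tot <- stats::rpois(1L, rate)
    if (tot == 0L) next
    counts <- stats::rmultinom(1L, tot, comp)[, 1L]
    keep <- counts > 0L
    rows[[length(rows) + 1L]] <- data.frame(
      plant_id = pid, census = cen, species = hsp[keep],
      count = as.integer(counts[keep]), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(plant_id = character(), census = character(),
                      species = character(), count = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Generate a complete synthetic survey
#'
#' Runs [generate_species_pool()] and [generate_population()] for every
#' population of the configuration and assembles the full set of survey
#' tables plus the ground-truth labels. Population coordinates are placed
#' along a ~600 km latitudinal span of savanna with longitudinal jitter.
#'
#' @param config A \code{scenario_config}.
#' @return Object of class \code{synthetic_survey}: list with tables
#'   \code{plants}, \code{ant_observations}, \code{leaflets},
#'   \code{herbivore_observations}, \code{ant_species},
#'   \code{populations}, plus \code{ground_truth} (per-population scenario,
#'   matched flag, matching type, hotspot flag; per-species true traits)
#'   and the \code{config} echo.
#' @export
generate_survey <- function(config = scenario_config()) {
  validate_scenario_config(config)
  pool <- generate_species_pool(config)
  pop_ids <- sprintf("pop%02d", seq_len(config$n_populations))

  old <- set_local_seed(derive_seed(config$seed, "coordinates"))
  lat <- seq(-17, -17 + 600 / 111.19, length.out = config$n_populations) +
    stats::runif(config$n_populations, -0.2, 0.2)
  lon <- -41.5 + stats::runif(config$n_populations, -1.5, 1.5)
  restore_seed(old)

  # matched_big populations sample a continuum of EFN phenotypes, as real
  # population means do; the other scenarios use their scenario mean
  pop_efn <- config$efn_mean_by_scenario[config$scenarios]
  big <- which(config$scenarios == "matched_big")
  if (length(big) > 1L)
    pop_efn[big] <- seq(config$efn_mean_range_big[1L],
                        config$efn_mean_range_big[2L], length.out = length(big))

  parts <- lapply(seq_len(config$n_populations), function(i) {
    generate_population(config, config$scenarios[i], pool,
                        seed = derive_seed(config$seed, pop_ids[i]),
                        population_id = pop_ids[i],
                        hotspot = config$hotspots[i],
                        efn_mean = pop_efn[[i]])
  })
  bind <- function(name) do.call(rbind, lapply(parts, `[[`, name))

  gt_pop <- data.frame(
    population_id = pop_ids,
    scenario = config$scenarios,
    matched = config$scenarios != "mismatched",
    matching_type = c(matched_small = "small-ant/low-EFN",
                      matched_big = "big-ant/high-EFN",
                      mismatched = "not-applicable")[config$scenarios],
    hotspot = config$hotspots,
    stringsAsFactors = FALSE)
  rownames(gt_pop) <- NULL

  structure(list(
    plants = bind("plants"),
    ant_observations = bind("ant_obs"),
    leaflets = bind("leaflets"),
    herbivore_observations = bind("herbivore_obs"),
    ant_species = pool[, c("species", "body_length_mm")],
    populations = data.frame(population_id = pop_ids, lat = lat, lon = lon,
                             stringsAsFactors = FALSE),
    ground_truth = list(populations = gt_pop, species = pool),
    config = config), class = "synthetic_survey")
}

#' Write a survey to CSV tables (plus a ground-truth JSON sidecar)
#'
#' @param survey A \code{synthetic_survey} (or a plain list of survey
#'   tables).
#' @param dir Output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_survey <- function(survey, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("plants", "ant_observations", "leaflets",
              "herbivore_observations", "ant_species", "populations")
  for (tb in tables)
    utils::write.csv(survey[[tb]], file.path(dir, paste0(tb, ".csv")),
                     row.names = FALSE)
  if (!is.null(survey$ground_truth))
    jsonlite::write_json(survey$ground_truth,
                         file.path(dir, "ground_truth.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read survey tables from a directory of CSVs
#'
#' @param dir Directory containing the survey CSV tables (the layout
#'   written by [write_survey()]).
#' @return List of survey tables (and \code{ground_truth} when the sidecar
#'   is present).
#' @export
read_survey <- function(dir) {
  tables <- c("plants", "ant_observations", "leaflets",
              "herbivore_observations", "ant_species", "populations")
  out <- list()
  for (tb in tables) {
    path <- file.path(dir, paste0(tb, ".csv"))
    if (!file.exists(path)) {
      if (tb == "herbivore_observations") next  # optional table
      stop("missing survey table: ", path)
    }
    out[[tb]] <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  gt <- file.path(dir, "ground_truth.json")
  if (file.exists(gt)) out$ground_truth <- jsonlite::read_json(gt, simplifyVector = TRUE)
  out
}

#' @export
print.synthetic_survey <- function(x, ...) {
  cat(sprintf("Synthetic survey: %d populations x %d plants x 2 censuses; %d ant species.\n",
              x$config$n_populations, x$config$n_plants_per_pop, x$config$n_species))
  cat("Scenarios:", paste(x$config$scenarios, collapse = ", "), "\n")
  invisible(x)
}
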