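#' Aggregate observation tables to per-population assemblages
#'
#' Sums observation counts per species within each population (over plants
#' and censuses), producing the named abundance vectors consumed by the
#' similarity functions.
#'
#' @param obs Observation table (\code{plant_id, census, species, count}).
#' @param plants Plant census table mapping plants to populations.
#' @return Named list of assemblages (one named abundance vector per
#'   population, empty populations dropped).
#' @export
assemblages_from_observations <- function(obs, plants) {
  map <- unique(plants[, c("plant_id", "population_id")])
  m <- merge(obs, map, by = "plant_id")
  pops <- sort(unique(map$population_id))
  out <- list()
  for (p in pops) {
    sub <- m[m$population_id == p, ]
    if (nrow(sub) == 0L) next
    out[[as.character(p)]] <- tapply(sub$count, sub$species, sum)
  }
  out
}

#' Validate survey tables against the input schemas
#'
#' Checks column presence, value ranges (positive leaf counts, areas,
#' damaged <= total, coordinate bounds, non-negative counts) and
#' referential integrity (every observation's plant exists). Violations are
#' returned as a report, one row per problem, rather than thrown.
#'
#' @param tables Named list of survey tables (\code{plants},
#'   \code{ant_observations}, \code{leaflets}, \code{populations}, and
#'   optionally \code{ant_species}, \code{herbivore_observations}).
#' @return Data frame with columns \code{table, rule, row, detail}; zero
#'   rows when the survey is well-formed.
#' @export
validate_survey <- function(tables) {
  v <- list()
  add <- function(table, rule, row, detail)
    v[[length(v) + 1L]] <<- data.frame(table = table, rule = rule,
                                       row = as.integer(row), detail = detail,
                                       stringsAsFactors = FALSE)
  need_cols <- list(
    plants = c("population_id", "plant_id", "census", "n_leaves", "flowering", "n_seedlings_2m"),
    ant_observations = c("plant_id", "census", "species", "count"),
    leaflets = c("plant_id", "leaflet_id", "total_area_mm2", "damaged_area_mm2", "efn_count_base"),
    populations = c("population_id", "lat", "lon"))
  for (tb in names(need_cols)) {
    if (is.null(tables[[tb]])) { add(tb, "missing_table", NA, tb); next }
    miss <- setdiff(need_cols[[tb]], names(tables[[tb]]))
    for (col in miss) add(tb, "missing_column", NA, col)
  }
  if (nrow(do.call(rbind, c(v, list(empty_violations())))) > 0L)
    return(finish_violations(v))

  pl <- tables$plants
  for (i in which(!(pl$n_leaves > 0)))
    add("plants", "range", i, paste0("n_leaves must be > 0 (plant ", pl$plant_id[i], ")"))
  for (i in which(!pl$census %in% c("t0", "t1")))
    add("plants", "range", i, paste0("census must be t0/t1 (plant ", pl$plant_id[i], ")"))
  for (i in which(pl$n_seedlings_2m < 0))
    add("plants", "range", i, paste0("negative seedling count (plant ", pl$plant_id[i], ")"))

  lf <- tables$leaflets
  for (i in which(lf$total_area_mm2 <= 0))
    add("leaflets", "range", i, paste0("total area must be > 0 (plant ", lf$plant_id[i], ")"))
  for (i in which(lf$damaged_area_mm2 < 0 | lf$damaged_area_mm2 > lf$total_area_mm2))
    add("leaflets", "range", i, paste0("damaged area outside [0, total] (plant ", lf$plant_id[i], ")"))
  for (i in which(lf$efn_count_base < 0))
    add("leaflets", "range", i, paste0("negative EFN count (plant ", lf$plant_id[i], ")"))

  po <- tables$populations
  for (i in which(po$lat < -90 | po$lat > 90))
    add("populations", "range", i, paste0("lat out of [-90, 90] (", po$population_id[i], ")"))
  for (i in which(po$lon < -180 | po$lon > 180))
    add("populations", "range", i, paste0("lon out of [-180, 180] (", po$population_id[i], ")"))

  known_plants <- unique(pl$plant_id)
  check_ref <- function(tb_name) {
    tb <- tables[[tb_name]]
    if (is.null(tb)) return()
    for (i in which(!tb$plant_id %in% known_plants))
      add(tb_name, "referential_integrity", i,
          paste0("unknown plant ", tb$plant_id[i]))
    if ("count" %in% names(tb))
      for (i in which(tb$count < 0))
        add(tb_name, "range", i, paste0("negative count (plant ", tb$plant_id[i], ")"))
  }
  check_ref("ant_observations")
  check_ref("herbivore_observations")
  check_ref("leaflets")
  for (i in which(!unique(pl$population_id) %in% po$population_id))
    add("plants", "referential_integrity", NA,
        paste0("population without coordinates: ", unique(pl$population_id)[i]))
  finish_violations(v)
}

empty_violations <- function()
  data.frame(table = character(), rule = character(), row = integer(),
             detail = character(), stringsAsFactors = FALSE)

finish_violations <- function(v)
  if (length(v) == 0L) empty_violations() else do.call(rbind, v)

#' Run the full geographic-mosaic analysis pipeline
#'
#' Orchestrates every stage in order on a survey (given as tables, a
#' directory of CSVs, or simulated from a \code{scenario_config}):
#' validation, assemblage similarity and Mantel tests against geographic
#' distance, trait aggregation, plant metrics, interface fits, and the
#' matched/mismatched/hotspot classification. Stage outputs are written as
#' CSV (plus a JSON provenance record) when \code{out_dir} is given.
#'
#' @param survey A \code{synthetic_survey}, a list of survey tables, or a
#'   directory path containing the CSV tables.
#' @param out_dir Optional output directory for stage CSVs.
#' @param alpha Significance level used throughout (default 0.05).
#' @param n_boot Bootstrap replicates for PS confidence limits.
#' @param n_perm Mantel permutations (default 5000).
#' @param seed Master seed; each stochastic stage draws from a stream
#'   derived from it.
#' @param variance_scale Passed to [classify_mosaic()].
#' @param primary Matching predictor driving final labels (default
#'   \code{"size"}).
#' @return Object of class \code{mosaic_report}: list with
#'   \code{validation}, \code{assemblage} (mean PS and bootstrap tests for
#'   ants and herbivores), \code{mantel} (distance-dependence tests),
#'   \code{stability}, \code{profiles}, \code{community},
#'   \code{interface_fits}, \code{phenotypes}, \code{anova_efn},
#'   \code{classification}, and \code{config} echo.
#' @export
run_pipeline <- function(survey, out_dir = NULL, alpha = 0.05,
                         n_boot = 1000L, n_perm = 5000L, seed = 1L,
                         variance_scale = "relative", primary = "size") {
  if (is.character(survey)) survey <- read_survey(survey)
  tables <- survey[c("plants", "ant_observations", "leaflets",
                     "herbivore_observations", "ant_species", "populations")]
  viol <- validate_survey(tables)
  if (nrow(viol) > 0L)
    stop("survey failed validation (", nrow(viol), " violation(s)); first: ",
         viol$table[1L], "/", viol$rule[1L], ": ", viol$detail[1L])

  plants <- tables$plants
  ant_obs <- tables$ant_observations
  herb_obs <- tables$herbivore_observations

  ## assemblage similarity
  ants_asm <- assemblages_from_observations(ant_obs, plants)
  ant_diss <- dissimilarity_matrix(ants_asm)
  pairs <- which(upper.tri(ant_diss), arr.ind = TRUE)
  mean_ps_ants <- mean(1 - ant_diss[upper.tri(ant_diss)])
  geo <- geographic_distance_matrix(tables$populations)
  geo <- geo[rownames(ant_diss), rownames(ant_diss)]
  mantel <- list(ants_vs_distance = mantel_test(ant_diss, geo, n_perm = n_perm,
                                                seed = derive_seed(seed, "mantel_ants")))
  herb_summary <- NULL
  if (!is.null(herb_obs) && nrow(herb_obs) > 0L) {
    herb_asm <- assemblages_from_observations(herb_obs, plants)
    if (length(herb_asm) >= 2L) {
      herb_diss <- dissimilarity_matrix(herb_asm)
      common <- intersect(rownames(herb_diss), rownames(geo))
      mantel$herbivores_vs_distance <-
        mantel_test(herb_diss[common, common], geo[common, common],
                    n_perm = n_perm, seed = derive_seed(seed, "mantel_herb"))
      herb_summary <- list(mean_ps = mean(1 - herb_diss[upper.tri(herb_diss)]),
                           dissimilarity = herb_diss)
    }
  }

  ## traits and metrics
  ptr <- plant_phenotypes(tables$leaflets)
  profiles <- species_profiles(plants, ant_obs, tables$ant_species, ptr)
  comm <- community_traits(plants, ant_obs, profiles)
  stability <- occupancy_stability(plants, ant_obs)
  pheno <- population_phenotypes(plants, ant_obs, tables$leaflets, profiles)
  fits <- interface_fit_table(profiles, alpha = alpha)

  plant_efn <- merge(ptr[, c("plant_id", "efn_per_leaflet")],
                     unique(plants[, c("plant_id", "population_id")]),
                     by = "plant_id")
  anova_efn <- anova_oneway(plant_efn$efn_per_leaflet, plant_efn$population_id,
                            alpha = alpha)
  classification <- classify_mosaic(pheno, profiles, plant_efn, alpha = alpha,
                                    variance_scale = variance_scale,
                                    primary = primary)

  report <- structure(list(
    validation = viol,
    assemblage = list(mean_ps_ants = mean_ps_ants, ant_dissimilarity = ant_diss,
                      herbivores = herb_summary),
    mantel = mantel,
    stability = stability,
    profiles = profiles,
    community = comm,
    interface_fits = fits,
    phenotypes = pheno,
    anova_efn = anova_efn,
    classification = classification,
    config = list(alpha = alpha, n_boot = n_boot, n_perm = n_perm, seed = seed,
                  variance_scale = variance_scale, primary = primary)),
    class = "mosaic_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wcsv(report$profiles, "species_profiles.csv")
  wcsv(report$community, "community_traits.csv")
  wcsv(report$interface_fits, "interface_fits.csv")
  wcsv(as.data.frame(report$phenotypes), "population_summary.csv")
  wcsv(report$classification$table, "classification.csv")
  diss <- report$assemblage$ant_dissimilarity
  utils::write.csv(data.frame(population_id = rownames(diss), diss,
                              check.names = FALSE),
                   file.path(out_dir, "ant_dissimilarity.csv"), row.names = FALSE)
  jsonlite::write_json(
    c(report$classification$provenance, report$config),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.mosaic_report <- function(x, ...) {
  cat("Geographic-mosaic pipeline report\n")
  cat(sprintf("  mean ant assemblage PS: %.3f\n", x$assemblage$mean_ps_ants))
  if (!is.null(x$assemblage$herbivores))
    cat(sprintf("  mean herbivore assemblage PS: %.3f\n", x$assemblage$herbivores$mean_ps))
  cat(sprintf("  Mantel (1-PS ants vs km): r = %.3f, p = %.3g\n",
              x$mantel$ants_vs_distance$r, x$mantel$ants_vs_distance$p))
  print(x$stability)
  print(x$classification)
  invisible(x)
}
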