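#' Population-level phenotype table
#'
#' Aggregates the survey tables to one row per population: mean EFN
#' abundance per leaflet and its among-plant variance (raw and relative to
#' the population mean), community-level ant traits, mean standardized ant
#' abundance per plant, proportion of plants occupied, mean herbivory, and
#' the three performance descriptors.
#'
#' @inheritParams species_profiles
#' @param leaflets Leaflet table (see [plant_phenotypes()]).
#' @param profiles Output of [species_profiles()].
#' @param census_handling Passed to [community_traits()].
#' @return Data frame of class \code{population_phenotypes}, one row per
#'   population.
#' @export
population_phenotypes <- function(plants, ant_obs, leaflets, profiles,
                                  census_handling = "union") {
  ptr <- plant_phenotypes(leaflets)
  comm <- community_traits(plants, ant_obs, profiles, census_handling)

  # per plant-census standardized total ant abundance (0 when unoccupied)
  obs_tot <- stats::aggregate(count ~ plant_id + census, data = ant_obs, FUN = sum)
  pc <- merge(plants, obs_tot, by = c("plant_id", "census"), all.x = TRUE)
  pc$count[is.na(pc$count)] <- 0
  pc$std <- standardize_abundance(pc$count, pc$n_leaves)

  wide <- merge(pc[pc$census == "t0", c("plant_id", "population_id", "n_leaves", "flowering",
                                        "n_seedlings_2m", "std")],
                pc[pc$census == "t1", c("plant_id", "n_leaves", "flowering", "std")],
                by = "plant_id", suffixes = c("_t0", "_t1"))
  wide$ant_abundance <- plant_ant_abundance(wide$std_t0, wide$std_t1)
  wide$rel_production <- relative_leaf_production(wide$n_leaves_t0, wide$n_leaves_t1)
  wide$flowering <- wide$flowering_t0 | wide$flowering_t1
  wide$occupied <- wide$std_t0 > 0 | wide$std_t1 > 0
  wide <- merge(wide, ptr[, c("plant_id", "efn_per_leaflet", "herbivory")], by = "plant_id")

  pops <- sort(unique(plants$population_id))
  rows <- lapply(pops, function(p) {
    sub <- wide[wide$population_id == p, ]
    if (nrow(sub) == 0L) stop("population with no complete plant records: ", p)
    perf <- population_performance(sub$rel_production, sub$flowering, sub$n_seedlings_2m)
    data.frame(population_id = p,
               n_plants = nrow(sub),
               mean_efn = mean(sub$efn_per_leaflet),
               var_efn = stats::var(sub$efn_per_leaflet),
               var_efn_relative = stats::var(sub$efn_per_leaflet / mean(sub$efn_per_leaflet)),
               mean_ant_abundance = mean(sub$ant_abundance),
               prop_occupied = mean(sub$occupied),
               mean_herbivory = mean(sub$herbivory),
               mean_rel_production = perf$mean_rel_production,
               prop_flowering = perf$prop_flowering,
               mean_seedlings = perf$mean_seedlings)
  })
  out <- do.call(rbind, rows)
  out <- merge(out, comm, by = "population_id")
  class(out) <- c("population_phenotypes", "data.frame")
  out
}

#' Classify one population as phenotypically matched or mismatched
#'
#' A population is matched (for a given interface model) when its mean EFN
#' abundance lies within the model's mean-response confidence band
#' evaluated at the population's community-level ant trait; mismatched
#' otherwise. Populations without occupied plants have no community trait
#' and are unclassifiable.
#'
#' @param mean_efn Population mean EFN abundance per leaflet.
#' @param community_trait Community-level value of the model's predictor,
#'   on the raw scale (transformed internally to match the model).
#' @param model An \code{interface_model} with response \code{"efn"}.
#' @param alpha Band level (default: model's alpha).
#' @return List: \code{matched} (logical, NA when unclassifiable),
#'   \code{fit}, \code{lower}, \code{upper}, \code{offset} (signed distance
#'   from the fitted line), \code{band_halfwidth}.
#' @export
classify_matching <- function(mean_efn, community_trait, model, alpha = NULL) {
  if (model$response != "efn") stop("matching classification needs an EFN-response model")
  if (is.na(community_trait))
    return(list(matched = NA, fit = NA_real_, lower = NA_real_, upper = NA_real_,
                offset = NA_real_, band_halfwidth = NA_real_))
  x0 <- if (model$transform == "log10") log10(community_trait) else community_trait
  band <- predict_band(model, x0, alpha)
  list(matched = mean_efn >= band$lower && mean_efn <= band$upper,
       fit = band$fit, lower = band$lower, upper = band$upper,
       offset = mean_efn - band$fit,
       band_halfwidth = (band$upper - band$lower) / 2)
}

#' Matching type by cohort quadrant
#'
#' Among matched populations, distinguishes the two flavours of phenotypic
#' matching: small ants with few EFNs vs big ants with abundant EFNs,
#' assigned by quadrants of the cohort medians of community ant size and
#' mean EFN abundance. Values at the median count as "at or above".
#'
#' @param community_size,mean_efn Values for the focal population.
#' @param cohort_sizes,cohort_efns Numeric vectors over the whole cohort
#'   (>= 3 populations) used for the medians.
#' @param matched Logical; mismatched populations get
#'   \code{"not-applicable"}.
#' @return One of \code{"small-ant/low-EFN"}, \code{"big-ant/high-EFN"},
#'   \code{"not-applicable"}.
#' @export
matching_type <- function(community_size, mean_efn, cohort_sizes, cohort_efns,
                          matched = TRUE) {
  if (length(cohort_sizes) < 3L || length(cohort_efns) < 3L)
    stop("cohort must contain at least 3 populations")
  if (!isTRUE(matched) || is.na(community_size)) return("not-applicable")
  ms <- stats::median(cohort_sizes, na.rm = TRUE)
  me <- stats::median(cohort_efns, na.rm = TRUE)
  if (community_size < ms && mean_efn < me) return("small-ant/low-EFN")
  if (community_size >= ms && mean_efn >= me) return("big-ant/high-EFN")
  "not-applicable"
}

#' Hotspot / coldspot classification for one population
#'
#' A population is a plant evolutionary hotspot when it is phenotypically
#' matched AND at least 2 of its 3 performance descriptors strictly exceed
#' the cohort median AND its herbivory is strictly below the cohort median
#' AND its EFN variance falls in the narrow variance letter group (the
#' group sharing a letter with the minimum-variance population). Otherwise
#' it is a coldspot, qualified by its matching label.
#'
#' @param matched Logical matching flag for the population.
#' @param performance Numeric length-3 vector (mean relative production,
#'   proportion flowering, mean seedlings).
#' @param cohort_performance Matrix/data frame with the same 3 columns over
#'   the cohort.
#' @param herbivory,cohort_herbivory Herbivory mean for the population and
#'   the cohort vector.
#' @param in_narrow_variance_group Logical: does the population share a
#'   variance letter with the minimum-variance population?
#' @return List: \code{label} (\code{"hotspot"},
#'   \code{"coldspot-matched"}, \code{"coldspot-mismatched"}) and
#'   \code{criteria} (named logical breakdown).
#' @export
classify_hotspot <- function(matched, performance, cohort_performance,
                             herbivory, cohort_herbivory,
                             in_narrow_variance_group) {
  if (anyNA(performance) || is.na(herbivory)) stop("missing performance or herbivory aggregate")
  cohort_performance <- as.matrix(cohort_performance)
  if (ncol(cohort_performance) != 3L || length(performance) != 3L)
    stop("expect exactly 3 performance descriptors")
  med <- apply(cohort_performance, 2L, stats::median)
  perf_above <- performance > med
  crit <- c(matched = isTRUE(matched),
            performance_above_median = sum(perf_above) >= 2L,
            herbivory_below_median = herbivory < stats::median(cohort_herbivory),
            narrow_variance = isTRUE(in_narrow_variance_group))
  label <- if (all(crit)) "hotspot"
  else if (isTRUE(matched)) "coldspot-matched"
  else "coldspot-mismatched"
  list(label = label, criteria = crit)
}

#' Classify every population of a survey
#'
#' End-to-end classifier: fits the EFN-vs-size and EFN-vs-recruitment
#' interface models across ant species, projects each population's
#' community-level ant traits onto them, assigns matched/mismatched flags
#' (final label from the size model, the better descriptor of matching in
#' this system; the recruitment flag is co-reported and disagreements
#' flagged), matching types, and hotspot/coldspot labels using the
#' Fligner-Killeen variance letter groups.
#'
#' @param pheno A \code{population_phenotypes} data frame.
#' @param profiles An \code{ant_species_profiles} data frame.
#' @param plant_efn Data frame \code{population_id, plant_id,
#'   efn_per_leaflet} of per-plant EFN values (for the variance
#'   comparison); see [plant_phenotypes()].
#' @param alpha Band and letter significance level (default 0.05).
#' @param variance_scale \code{"relative"} (default; per-plant EFN divided
#'   by the population mean, comparing relative variation) or \code{"raw"}.
#' @param primary Predictor driving the final label (default
#'   \code{"size"}).
#' @return Object of class \code{mosaic_classification}: data frame
#'   \code{table} (one row per population with flags, type, hotspot label
#'   and criteria), plus \code{model_size}, \code{model_recruitment},
#'   \code{variance_test}, and \code{provenance} (thresholds and bands
#'   used).
#' @export
classify_mosaic <- function(pheno, profiles, plant_efn, alpha = 0.05,
                            variance_scale = c("relative", "raw"),
                            primary = c("size", "recruitment")) {
  variance_scale <- match.arg(variance_scale)
  primary <- match.arg(primary)
  m_size <- fit_interface(profiles, "size", "efn", alpha = alpha)
  m_rec <- fit_interface(profiles, "recruitment", "efn", alpha = alpha)

  vals <- plant_efn$efn_per_leaflet
  if (variance_scale == "relative") {
    pop_means <- tapply(vals, plant_efn$population_id, mean)
    vals <- vals / pop_means[as.character(plant_efn$population_id)]
  }
  vt <- fligner_killeen(as.numeric(vals), plant_efn$population_id, alpha = alpha)
  min_pop <- names(which.min(vt$variances))
  min_letters <- strsplit(vt$letters[[min_pop]], "")[[1L]]
  narrow <- vapply(vt$letters, function(l)
    any(strsplit(l, "")[[1L]] %in% min_letters), logical(1L))

  ord <- order(pheno$population_id)
  pheno <- pheno[ord, , drop = FALSE]
  perf_cols <- c("mean_rel_production", "prop_flowering", "mean_seedlings")
  rows <- lapply(seq_len(nrow(pheno)), function(i) {
    p <- pheno[i, ]
    cs <- classify_matching(p$mean_efn, p$community_size_mm, m_size, alpha)
    cr <- classify_matching(p$mean_efn, p$community_recruitment, m_rec, alpha)
    matched <- if (primary == "size") cs$matched else cr$matched
    final <- if (is.na(matched)) "unclassifiable" else if (matched) "matched" else "mismatched"
    type <- matching_type(p$community_size_mm, p$mean_efn,
                          pheno$community_size_mm, pheno$mean_efn,
                          matched = isTRUE(matched))
    hs <- if (is.na(matched)) {
      list(label = "unclassifiable",
           criteria = c(matched = NA, performance_above_median = NA,
                        herbivory_below_median = NA, narrow_variance = NA))
    } else {
      classify_hotspot(matched,
                       unlist(p[perf_cols]), pheno[, perf_cols],
                       p$mean_herbivory, pheno$mean_herbivory,
                       narrow[[as.character(p$population_id)]])
    }
    data.frame(population_id = p$population_id,
               matched_by_size = cs$matched, matched_by_recruitment = cr$matched,
               predictor_disagreement = !is.na(cs$matched) && !is.na(cr$matched) &&
                 cs$matched != cr$matched,
               label = final, matching_type = type,
               hotspot_label = hs$label,
               crit_matched = hs$criteria[["matched"]],
               crit_performance = hs$criteria[["performance_above_median"]],
               crit_herbivory = hs$criteria[["herbivory_below_median"]],
               crit_narrow_variance = hs$criteria[["narrow_variance"]],
               offset_size = cs$offset, band_halfwidth_size = cs$band_halfwidth,
               offset_recruitment = cr$offset,
               band_halfwidth_recruitment = cr$band_halfwidth,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab, model_size = m_size, model_recruitment = m_rec,
                 variance_test = vt,
                 provenance = list(alpha = alpha, primary = primary,
                                   variance_scale = variance_scale,
                                   band_type = "mean-response",
                                   narrow_group = names(narrow)[narrow],
                                   performance_thresholds = apply(pheno[, perf_cols], 2L, stats::median),
                                   herbivory_threshold = stats::median(pheno$mean_herbivory))),
            class = "mosaic_classification")
}

#' @export
print.mosaic_classification <- function(x, ...) {
  tab <- x$table
  cat(sprintf("Mosaic classification of %d populations (%d matched, %d mismatched, %d hotspot):\n",
              nrow(tab), sum(tab$label == "matched"), sum(tab$label == "mismatched"),
              sum(tab$hotspot_label == "hotspot")))
  print(tab[, c("population_id", "label", "matching_type", "hotspot_label")],
        row.names = FALSE)
  invisible(x)
}
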