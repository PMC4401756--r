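#' Mean proportion of leaflet area damaged for one plant
#'
#' Absolute herbivory per plant: the mean over sampled leaflets of
#' damaged area / total area.
#'
#' @param total_area_mm2,damaged_area_mm2 Numeric vectors, one entry per
#'   leaflet of the plant; \code{0 <= damaged <= total}, total > 0.
#' @return A fraction in \code{[0, 1]}.
#' @export
herbivory_proportion <- function(total_area_mm2, damaged_area_mm2) {
  if (length(total_area_mm2) < 1L) stop("need at least one leaflet")
  if (length(total_area_mm2) != length(damaged_area_mm2)) stop("area vectors differ in length")
  if (any(total_area_mm2 <= 0)) stop("leaflet with zero or negative total area")
  if (any(damaged_area_mm2 < 0) || any(damaged_area_mm2 > total_area_mm2))
    stop("damaged area must lie in [0, total area]")
  mean(damaged_area_mm2 / total_area_mm2)
}

#' Relative leaf production between censuses
#'
#' \code{(n_t1 - n_t0) / n_t0}: 0 for an unchanged plant, -1 when all leaves
#' are lost, unbounded above.
#'
#' @param n_t0,n_t1 Leaf counts at the first and second census; \code{n_t0 > 0}.
#' @return Dimensionless production (vectorized), \code{>= -1}.
#' @export
relative_leaf_production <- function(n_t0, n_t1) {
  if (any(n_t0 <= 0)) stop("n_t0 must be positive")
  if (any(n_t1 < 0)) stop("n_t1 must be non-negative")
  (n_t1 - n_t0) / n_t0
}

#' Per-plant phenotypes from the leaflet table
#'
#' Aggregates leaflet measurements to one row per plant: EFN abundance at
#' the leaflet base (mean count per leaflet), mean EFN head diameter, and
#' herbivory (mean proportion of leaflet area damaged).
#'
#' @param leaflets Leaflet table (\code{plant_id, leaflet_id, total_area_mm2,
#'   damaged_area_mm2, efn_count_base, efn_diameter_mm}).
#' @return Data frame: \code{plant_id, efn_per_leaflet, efn_diameter_mm,
#'   herbivory, n_leaflets}.
#' @export
plant_phenotypes <- function(leaflets) {
  need <- c("plant_id", "total_area_mm2", "damaged_area_mm2", "efn_count_base")
  if (!all(need %in% names(leaflets)))
    stop("leaflets table needs columns: ", paste(need, collapse = ", "))
  ids <- sort(unique(leaflets$plant_id))
  rows <- lapply(ids, function(id) {
    sub <- leaflets[leaflets$plant_id == id, ]
    data.frame(plant_id = id,
               efn_per_leaflet = mean(sub$efn_count_base),
               efn_diameter_mm = if ("efn_diameter_mm" %in% names(sub))
                 mean(sub$efn_diameter_mm) else NA_real_,
               herbivory = herbivory_proportion(sub$total_area_mm2, sub$damaged_area_mm2),
               n_leaflets = nrow(sub))
  })
  do.call(rbind, rows)
}

#' Population-level performance descriptors
#'
#' Three fitness-related aggregates per population: mean relative leaf
#' production, proportion of flowering plants, and mean number of seedlings
#' within 2 m of each adult plant.
#'
#' @param rel_production Numeric vector of per-plant relative leaf
#'   production values.
#' @param flowering Logical vector (was the plant flowering?).
#' @param n_seedlings Non-negative integer vector of seedlings around each
#'   plant.
#' @return Named list: \code{mean_rel_production}, \code{prop_flowering},
#'   \code{mean_seedlings}, \code{n_plants}.
#' @export
population_performance <- function(rel_production, flowering, n_seedlings) {
  n <- length(rel_production)
  if (n < 1L) stop("empty population")
  if (length(flowering) != n || length(n_seedlings) != n)
    stop("descriptor vectors differ in length")
  list(mean_rel_production = mean(rel_production),
       prop_flowering = mean(as.logical(flowering)),
       mean_seedlings = mean(n_seedlings),
       n_plants = n)
}

#' One-way ANOVA across populations with a Tukey letter display
#'
#' Standard one-way fixed-effects ANOVA followed by Tukey HSD pairwise
#' comparisons at \code{alpha}; groups sharing a letter are not
#' significantly different (Tukey-Kramer for unequal group sizes, as
#' provided by [stats::TukeyHSD()]).
#'
#' @param values Numeric response vector.
#' @param groups Grouping vector (population ids) of the same length; at
#'   least 2 groups with at least 2 values each.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return Object of class \code{anova_oneway}: \code{F}, \code{df_between},
#'   \code{df_within}, \code{p}, \code{letters} (named character vector, one
#'   letter string per group, ordered by group mean), \code{means},
#'   \code{tukey} (the matrix of pairwise comparisons).
#' @export
anova_oneway <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  check_groups(values, groups, min_per_group = 2L)
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  means <- tapply(values, groups, mean)
  letters <- letter_display(pairwise_p_matrix(rownames(tk), tk[, "p adj"], levels(groups)),
                            order_by = means, alpha = alpha)
  structure(list(F = tab[1L, "F value"], df_between = tab[1L, "Df"],
                 df_within = tab[2L, "Df"], p = tab[1L, "Pr(>F)"],
                 letters = letters, means = means, tukey = tk, alpha = alpha),
            class = "anova_oneway")
}

#' Fligner-Killeen comparison of variances across populations
#'
#' Rank-based median-centered test of the null hypothesis of equal
#' variances (robust to non-normality), plus Holm-adjusted pairwise
#' Fligner-Killeen tests assembled into a letter display: groups sharing a
#' letter do not differ significantly in spread.
#'
#' @inheritParams anova_oneway
#' @return Object of class \code{fligner_killeen}: \code{statistic} (the
#'   chi-squared normal-score statistic), \code{df}, \code{p},
#'   \code{letters}, \code{variances} (per-group variances),
#'   \code{pairwise_p} (Holm-adjusted matrix).
#' @export
fligner_killeen <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  check_groups(values, groups, min_per_group = 2L)
  ft <- stats::fligner.test(values, groups)
  lev <- levels(groups)
  k <- length(lev)
  praw <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    sel <- groups %in% lev[c(i, j)]
    praw[i, j] <- praw[j, i] <-
      stats::fligner.test(values[sel], droplevels(groups[sel]))$p.value
  }
  padj <- praw
  ut <- upper.tri(praw)
  padj[ut] <- stats::p.adjust(praw[ut], method = "holm")
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  vars <- tapply(values, groups, stats::var)
  letters <- letter_display(padj, order_by = vars, alpha = alpha)
  structure(list(statistic = unname(ft$statistic), df = unname(ft$parameter),
                 p = ft$p.value, letters = letters, variances = vars,
                 pairwise_p = padj, alpha = alpha),
            class = "fligner_killeen")
}

check_groups <- function(values, groups, min_per_group) {
  if (length(values) != length(groups)) stop("values and groups differ in length")
  if (anyNA(values)) stop("missing values are not allowed")
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("need at least 2 groups")
  if (any(sizes < min_per_group))
    stop("every group needs at least ", min_per_group, " values; too small: ",
         paste(names(sizes)[sizes < min_per_group], collapse = ", "))
  invisible(TRUE)
}

# Symmetric matrix of pairwise adjusted p-values from TukeyHSD row labels
# of the form "g2-g1".
pairwise_p_matrix <- function(pair_labels, p_values, levels) {
  k <- length(levels)
  m <- matrix(NA_real_, k, k, dimnames = list(levels, levels))
  for (idx in seq_along(pair_labels)) {
    parts <- strsplit(pair_labels[idx], "-", fixed = TRUE)[[1L]]
    # group labels may themselves contain "-": split at every boundary and
    # find the split where both halves are valid levels
    lab <- pair_labels[idx]
    found <- FALSE
    for (pos in seq_len(nchar(lab) - 1L)) {
      g1 <- substr(lab, 1L, pos); g2 <- substr(lab, pos + 2L, nchar(lab))
      if (substr(lab, pos + 1L, pos + 1L) == "-" && g1 %in% levels && g2 %in% levels) {
        m[g1, g2] <- m[g2, g1] <- p_values[idx]
        found <- TRUE
        break
      }
    }
    if (!found) stop("cannot parse Tukey pair label: ", lab)
  }
  m
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Orders groups by a summary statistic and sweeps maximal contiguous runs
#' of mutually non-significant groups into letters, the display style used
#' under ANOVA/Tukey and variance-comparison figures.
#'
#' @param p_matrix Symmetric matrix of pairwise p-values (NA diagonal ok).
#' @param order_by Named numeric vector (e.g. group means or variances)
#'   used to order groups before assembling runs.
#' @param alpha Significance threshold.
#' @return Named character vector of letter strings in the original group
#'   order of \code{p_matrix}.
#' @export
letter_display <- function(p_matrix, order_by, alpha = 0.05) {
  lev <- rownames(p_matrix)
  ord <- lev[order(order_by[lev])]
  k <- length(ord)
  ns <- function(g1, g2) isTRUE(p_matrix[g1, g2] > alpha)
  # maximal run from each start: largest j with all pairs in i..j non-significant
  runs <- lapply(seq_len(k), function(i) {
    j <- i
    while (j < k && all(vapply(i:j, function(u) ns(ord[u], ord[j + 1L]), logical(1L))))
      j <- j + 1L
    i:j
  })
  # drop runs contained in another run
  keep <- vapply(seq_along(runs), function(r) {
    !any(vapply(seq_along(runs), function(s)
      s != r && all(runs[[r]] %in% runs[[s]]), logical(1L)))
  }, logical(1L))
  runs <- unique(runs[keep])
  lab <- stats::setNames(rep("", k), ord)
  for (r in seq_along(runs))
    lab[runs[[r]]] <- paste0(lab[runs[[r]]], letters[(r - 1L) %% 26L + 1L])
  lab[lev]
}

#' @export
print.anova_oneway <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  cat("Tukey letters:", paste(names(x$letters), x$letters, sep = ":", collapse = "  "), "\n")
  invisible(x)
}

#' @export
print.fligner_killeen <- function(x, ...) {
  cat(sprintf("Fligner-Killeen: chi-squared = %.3f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p))
  cat("Variance letters:", paste(names(x$letters), x$letters, sep = ":", collapse = "  "), "\n")
  invisible(x)
}
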