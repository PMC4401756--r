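#' Proportional (Steinhaus) similarity between two assemblages
#'
#' Compares two species-abundance assemblages with the proportional
#' similarity index \code{PS = 2W / (A + B)}, where \code{W} is the sum over
#' species of the minimum abundance in the two assemblages and \code{A},
#' \code{B} are the assemblage totals. The index works directly on raw
#' abundances; real-valued (e.g. standardized) abundances are accepted.
#'
#' @param a,b Named non-negative numeric vectors mapping species to
#'   abundance. Names are species identifiers; species absent from one
#'   assemblage contribute zero to \code{W}.
#' @return A single number in \code{[0, 1]}; 1 for identical assemblages,
#'   0 when no species is shared.
#' @examples
#' proportional_similarity(c(s1 = 3, s2 = 1), c(s1 = 1, s2 = 1))  # 2/3
#' @seealso [bootstrap_ps_test()], [dissimilarity_matrix()]
#' @export
proportional_similarity <- function(a, b) {
  a <- check_assemblage(a, "a")
  b <- check_assemblage(b, "b")
  species <- union(names(a), names(b))
  av <- ifelse(species %in% names(a), a[species], 0)
  bv <- ifelse(species %in% names(b), b[species], 0)
  av[is.na(av)] <- 0
  bv[is.na(bv)] <- 0
  W <- sum(pmin(av, bv))
  2 * W / (sum(av) + sum(bv))
}

check_assemblage <- function(x, label) {
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == ""))
    stop("assemblage '", label, "' must be a named vector (species -> abundance)")
  if (!is.numeric(x) || anyNA(x)) stop("assemblage '", label, "' has non-numeric or missing abundances")
  if (any(x < 0)) stop("assemblage '", label, "' has negative abundances")
  x <- tapply(x, names(x), sum)   # collapse duplicated species names
  if (sum(x) <= 0) stop("assemblage '", label, "' is empty (total abundance is 0)")
  x
}

#' Bootstrap significance test for proportional similarity
#'
#' Tests the null hypothesis of dissimilar assemblage composition
#' (\code{PS = 0}: no species in common) by resampling individual specimens
#' (species tokens) with replacement within each assemblage, recomputing PS
#' for each bootstrap replicate, and reporting percentile confidence limits.
#' The null is rejected when the lower confidence limit excludes zero.
#'
#' @inheritParams proportional_similarity
#' @param n_boot Number of bootstrap replicates (>= 200).
#' @param alpha Two-sided error rate for the percentile interval (default
#'   0.05, i.e. 95\% limits).
#' @param seed Integer seed controlling the resampling.
#' @param unit Resampling unit: \code{"within"} (default) resamples
#'   specimens independently within each assemblage; \code{"joint"} resamples
#'   both assemblages from their pooled specimen list, preserving totals.
#' @return An object of class \code{ps_test}: list with \code{ps},
#'   \code{ci_low}, \code{ci_high}, \code{n_boot}, \code{alpha}, \code{seed},
#'   \code{reject_dissimilarity}.
#' @export
bootstrap_ps_test <- function(a, b, n_boot = 1000L, alpha = 0.05, seed = 1L,
                              unit = c("within", "joint")) {
  unit <- match.arg(unit)
  a <- check_assemblage(a, "a")
  b <- check_assemblage(b, "b")
  if (n_boot < 200L) stop("n_boot must be at least 200")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  ps <- proportional_similarity(a, b)
  n_a <- max(1L, round(sum(a)))
  n_b <- max(1L, round(sum(b)))
  species <- union(names(a), names(b))
  pa <- ifelse(species %in% names(a), a[species], 0); pa[is.na(pa)] <- 0
  pb <- ifelse(species %in% names(b), b[species], 0); pb[is.na(pb)] <- 0

  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  k <- length(species)
  boot_ps <- vapply(seq_len(n_boot), function(i) {
    if (unit == "within") {
      ra <- stats::rmultinom(1L, n_a, pa / sum(pa))[, 1L]
      rb <- stats::rmultinom(1L, n_b, pb / sum(pb))[, 1L]
    } else {
      pooled <- pa + pb
      ra <- stats::rmultinom(1L, n_a, pooled / sum(pooled))[, 1L]
      rb <- stats::rmultinom(1L, n_b, pooled / sum(pooled))[, 1L]
    }
    W <- sum(pmin(ra, rb))
    tot <- sum(ra) + sum(rb)
    if (tot == 0) 0 else 2 * W / tot
  }, numeric(1L))
  ci <- unname(stats::quantile(boot_ps, c(alpha / 2, 1 - alpha / 2)))
  structure(list(ps = ps, ci_low = ci[1L], ci_high = ci[2L],
                 n_boot = as.integer(n_boot), alpha = alpha, seed = seed,
                 reject_dissimilarity = ci[1L] > 0),
            class = "ps_test")
}

#' @export
print.ps_test <- function(x, ...) {
  cat(sprintf("Proportional similarity PS = %.4f, %d%% CI [%.4f, %.4f] (%d bootstrap replicates)\n",
              x$ps, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high, x$n_boot))
  cat(if (x$reject_dissimilarity)
    "Null of dissimilar composition (PS = 0) rejected.\n"
  else
    "Null of dissimilar composition (PS = 0) not rejected.\n")
  invisible(x)
}

#' Pairwise 1 - PS dissimilarity matrix
#'
#' @param assemblages Named list of assemblages (each a named abundance
#'   vector); list names are locality labels.
#' @return A symmetric matrix of \code{1 - PS} values with zero diagonal and
#'   locality labels as dimnames.
#' @export
dissimilarity_matrix <- function(assemblages) {
  if (length(assemblages) < 2L) stop("need at least 2 localities")
  labels <- names(assemblages)
  if (is.null(labels) || anyDuplicated(labels))
    stop("assemblages must be a named list with unique locality labels")
  n <- length(assemblages)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- 1 - proportional_similarity(assemblages[[i]], assemblages[[j]])
    m[i, j] <- m[j, i] <- d
  }
  m
}

#' Pairwise distance matrix of a per-locality scalar
#'
#' Dissimilarity of a simple (scalar) population descriptor as the usual
#' Euclidean distance \code{|x_i - x_j|}.
#'
#' @param values Named numeric vector, one finite value per locality.
#' @return Symmetric matrix of absolute differences.
#' @export
scalar_dissimilarity <- function(values) {
  if (length(values) < 2L) stop("need at least 2 localities")
  if (is.null(names(values)) || anyDuplicated(names(values)))
    stop("values must be named with unique locality labels")
  if (anyNA(values) || any(!is.finite(values))) stop("all locality values must be finite")
  m <- abs(outer(values, values, "-"))
  dimnames(m) <- list(names(values), names(values))
  m
}

#' Great-circle distance matrix between localities
#'
#' Haversine distances on a sphere of radius 6371 km.
#'
#' @param coords Data frame with columns \code{population_id}, \code{lat},
#'   \code{lon} (decimal degrees).
#' @return Symmetric matrix of distances in kilometres.
#' @export
geographic_distance_matrix <- function(coords) {
  need <- c("population_id", "lat", "lon")
  if (!all(need %in% names(coords))) stop("coords needs columns population_id, lat, lon")
  if (any(coords$lat < -90 | coords$lat > 90)) stop("latitude out of [-90, 90]")
  if (any(coords$lon < -180 | coords$lon > 180)) stop("longitude out of [-180, 180]")
  labels <- as.character(coords$population_id)
  if (anyDuplicated(labels)) stop("duplicate population_id in coords")
  n <- nrow(coords)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- geosphere::distHaversine(c(coords$lon[i], coords$lat[i]),
                                  c(coords$lon[j], coords$lat[j]),
                                  r = 6371000) / 1000
    m[i, j] <- m[j, i] <- d
  }
  m
}

#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation of the upper-triangle entries of two distance
#' matrices, with significance from joint row/column permutations of one
#' matrix. The permutation p-value uses the add-one correction
#' \code{p = (1 + extreme) / (n_perm + 1)} so p is never zero. With
#' \code{exact = TRUE} all \code{n!} relabelings are enumerated instead and
#' p is the exact fraction of permutations as or more extreme than the
#' observed statistic (identity included).
#'
#' @param d1,d2 Symmetric distance matrices with identical locality labels
#'   in identical order (labels optional but must match when present).
#' @param n_perm Number of random permutations (ignored when
#'   \code{exact = TRUE}).
#' @param tail \code{"greater"} (default; positive distance dependence),
#'   \code{"less"}, or \code{"two.sided"}.
#' @param seed Integer seed for the permutations.
#' @param exact Enumerate all permutations (only sensible for small n).
#' @return An object of class \code{mantel_result}: list with \code{r},
#'   \code{p}, \code{n_perm}, \code{tail}, \code{seed}, \code{exact}.
#' @export
mantel_test <- function(d1, d2, n_perm = 5000L, tail = c("greater", "less", "two.sided"),
                        seed = 1L, exact = FALSE) {
  tail <- match.arg(tail)
  check_dist_pair(d1, d2)
  n <- nrow(d1)
  if (n < 3L) stop("Mantel test needs at least 3 localities")
  ut <- upper.tri(d1)
  v1 <- d1[ut]
  r_obs <- mantel_stat(v1, d2, ut)
  if (exact) {
    perms <- all_permutations(n)
    stats_all <- vapply(perms, function(p) mantel_stat(v1, d2[p, p, drop = FALSE], ut), numeric(1L))
    k <- count_extreme(stats_all, r_obs, tail)
    p <- k / length(perms)
    n_perm <- length(perms)
  } else {
    old <- set_local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    stats_perm <- vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      mantel_stat(v1, d2[p, p, drop = FALSE], ut)
    }, numeric(1L))
    k <- count_extreme(stats_perm, r_obs, tail)
    p <- (1 + k) / (n_perm + 1)
  }
  structure(list(r = r_obs, p = p, n_perm = as.integer(n_perm), tail = tail,
                 seed = seed, exact = exact),
            class = "mantel_result")
}

mantel_stat <- function(v1, m2, ut) {
  v2 <- m2[ut]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("degenerate distance matrix: zero variance among pairwise distances")
  stats::cor(v1, v2)
}

count_extreme <- function(stats_perm, obs, tail) {
  eps <- sqrt(.Machine$double.eps)
  switch(tail,
         greater   = sum(stats_perm >= obs - eps),
         less      = sum(stats_perm <= obs + eps),
         two.sided = sum(abs(stats_perm) >= abs(obs) - eps))
}

all_permutations <- function(n) {
  if (n > 8L) stop("exact enumeration limited to n <= 8")
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (pos in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(p, n, after = pos - 1L)
  }
  out
}

check_dist_pair <- function(d1, d2) {
  if (!is.matrix(d1) || !is.matrix(d2)) stop("d1 and d2 must be matrices")
  if (!all(dim(d1) == dim(d2)) || nrow(d1) != ncol(d1))
    stop("d1 and d2 must be square matrices of equal dimension")
  l1 <- rownames(d1); l2 <- rownames(d2)
  if (!is.null(l1) && !is.null(l2) && !identical(l1, l2))
    stop("locality labels of d1 and d2 differ or are ordered differently")
  invisible(TRUE)
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.4f, p = %.4g (%s, %s permutations)\n",
              x$r, x$p, x$tail,
              if (x$exact) paste0("exact, ", x$n_perm) else format(x$n_perm)))
  invisible(x)
}
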