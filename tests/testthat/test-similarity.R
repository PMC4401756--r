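test_that("proportional similarity matches hand-evaluated cases", {
  expect_equal(proportional_similarity(c(s1 = 4, s2 = 6), c(s1 = 4, s2 = 6)), 1)
  expect_equal(proportional_similarity(c(s1 = 4), c(s2 = 7)), 0)
  # W = min(3,1) + min(1,1) = 2, A = 4, B = 2 -> 2*2/6
  expect_equal(proportional_similarity(c(s1 = 3, s2 = 1), c(s1 = 1, s2 = 1)),
               2 / 3, tolerance = 1e-12)
  # real-valued (standardized) abundances are accepted unchanged
  expect_equal(proportional_similarity(c(a = 1.5, b = 0.5), c(a = 0.5, b = 1.5)),
               ps_oracle(c(a = 1.5, b = 0.5), c(a = 0.5, b = 1.5)))
  expect_error(proportional_similarity(c(s1 = 0), c(s1 = 2)), "empty")
  expect_error(proportional_similarity(c(4, 6), c(s1 = 1)), "named")
})

test_that("PS is symmetric, bounded and equals the direct formula on random pairs", {
  set.seed(421)
  for (i in 1:200) {
    a <- random_assemblage(); b <- random_assemblage()
    ps <- proportional_similarity(a, b)
    expect_equal(ps, ps_oracle(a, b), tolerance = 1e-12)
    expect_equal(ps, proportional_similarity(b, a), tolerance = 1e-12)
    expect_gte(ps, 0); expect_lte(ps, 1)
  }
  # PS = 1 iff identical as raw-abundance multisets
  expect_equal(proportional_similarity(c(x = 2, y = 3), c(y = 3, x = 2)), 1)
  expect_lt(proportional_similarity(c(x = 2, y = 3), c(x = 4, y = 6)), 1)
})

test_that("bootstrap PS test handles boundary and deterministic cases", {
  disj <- bootstrap_ps_test(c(s1 = 20), c(s2 = 30), n_boot = 300, seed = 5)
  expect_equal(disj$ps, 0)
  expect_equal(c(disj$ci_low, disj$ci_high), c(0, 0))
  expect_false(disj$reject_dissimilarity)

  a <- c(s1 = 60, s2 = 40)
  same <- bootstrap_ps_test(a, a, n_boot = 1000, seed = 7)
  expect_true(same$reject_dissimilarity)
  expect_true(same$ci_low <= same$ps && same$ps <= same$ci_high)

  again <- bootstrap_ps_test(a, a, n_boot = 1000, seed = 7)
  expect_identical(same, again)
  expect_error(bootstrap_ps_test(a, a, n_boot = 50), "at least 200")
  expect_error(bootstrap_ps_test(a, a, alpha = 1.2), "alpha")
})

test_that("bootstrap CI width shrinks with specimen counts on average", {
  widths <- sapply(c(20, 2000), function(total) {
    mean(sapply(1:20, function(i) {
      a <- c(s1 = 0.6, s2 = 0.4) * total
      b <- c(s1 = 0.3, s2 = 0.7) * total
      r <- bootstrap_ps_test(a, b, n_boot = 300, seed = i)
      r$ci_high - r$ci_low
    }))
  })
  expect_lt(widths[2], widths[1])
})

test_that("dissimilarity matrices match per-pair hand computation", {
  asm <- list(L1 = c(s1 = 3, s2 = 1), L2 = c(s1 = 1, s2 = 1), L3 = c(s3 = 5))
  m <- dissimilarity_matrix(asm)
  expect_equal(diag(m), c(L1 = 0, L2 = 0, L3 = 0))
  expect_equal(m["L1", "L2"], 1 - 2 / 3, tolerance = 1e-12)
  expect_equal(m["L1", "L3"], 1)
  expect_equal(m, t(m))
  same <- list(A = c(x = 2), B = c(x = 2))
  expect_true(all(dissimilarity_matrix(same) == 0))
  expect_error(dissimilarity_matrix(asm["L1"]), "at least 2")
  expect_error(dissimilarity_matrix(stats::setNames(asm, c("L", "L", "M"))), "unique")
})

test_that("scalar dissimilarity is the absolute difference", {
  m <- scalar_dissimilarity(c(a = 1, b = 4, c = 6))
  expect_equal(m["a", "b"], 3); expect_equal(m["a", "c"], 5); expect_equal(m["b", "c"], 2)
  expect_true(all(scalar_dissimilarity(c(a = 2, b = 2)) == 0))
  expect_error(scalar_dissimilarity(c(a = 1, b = NA)), "finite")
})

test_that("great-circle distances match closed forms on a 6371 km sphere", {
  co <- data.frame(population_id = c("o", "e", "anti"),
                   lat = c(0, 0, 0), lon = c(0, 1, 180))
  m <- geographic_distance_matrix(co)
  expect_equal(m["o", "o"], 0)
  expect_equal(m["o", "e"], 6371 * pi / 180, tolerance = 1e-6)
  expect_equal(m["o", "anti"], 6371 * pi, tolerance = 1e-6)
  expect_error(geographic_distance_matrix(
    data.frame(population_id = "x", lat = 95, lon = 0)), "latitude")
})

test_that("Mantel exact mode equals a brute-force permutation oracle", {
  set.seed(11)
  pts <- matrix(rnorm(8), 4, 2)
  d1 <- as.matrix(dist(pts)); d2 <- as.matrix(dist(pts + rnorm(8, sd = 2)))
  dimnames(d1) <- dimnames(d2) <- list(letters[1:4], letters[1:4])
  res <- mantel_test(d1, d2, exact = TRUE, tail = "greater")
  ut <- upper.tri(d1)
  obs <- cor(d1[ut], d2[ut])
  stats_all <- sapply(perms_oracle(4), function(p) cor(d1[ut], d2[p, p][ut]))
  p_oracle <- mean(stats_all >= obs - 1e-12)
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
  expect_equal(res$r, obs, tolerance = 1e-12)
})

test_that("Mantel on identical matrices gives r = 1 and agrees with vegan", {
  set.seed(3)
  d <- as.matrix(dist(matrix(rnorm(12), 6, 2)))
  res <- mantel_test(d, d, n_perm = 199, seed = 1)
  expect_equal(res$r, 1)
  expect_lte(res$p, 0.05)
  expect_gte(res$p, 1 / 200)

  skip_if_not_installed("vegan")
  d2 <- as.matrix(dist(matrix(rnorm(12), 6, 2)))
  mine <- mantel_test(d, d2, n_perm = 999, seed = 2, tail = "greater")
  veg <- vegan::mantel(d, d2, permutations = 999)
  expect_equal(mine$r, unname(veg$statistic), tolerance = 1e-12)
})

test_that("Mantel p-values are roughly uniform under the null", {
  set.seed(99)
  ps <- replicate(150, {
    d1 <- as.matrix(dist(rnorm(8))); d2 <- as.matrix(dist(rnorm(8)))
    mantel_test(d1, d2, n_perm = 199, seed = sample.int(1e6, 1))$p
  })
  # sanity (not a sharp calibration): p spread across (0, 1]; the
  # permutation p grid is discrete, so ties are expected
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 1e-4)
})

test_that("Mantel rejects mismatched labels and degenerate inputs", {
  d <- as.matrix(dist(1:4)); rownames(d) <- colnames(d) <- letters[1:4]
  d2 <- d; rownames(d2) <- colnames(d2) <- letters[4:1]
  expect_error(mantel_test(d, d2), "labels")
  expect_error(mantel_test(d[1:2, 1:2], d[1:2, 1:2]), "at least 3")
  flat <- matrix(1, 4, 4) - diag(4)
  dimnames(flat) <- list(letters[1:4], letters[1:4])
  expect_error(mantel_test(flat, flat, n_perm = 19), "degenerate")
})
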