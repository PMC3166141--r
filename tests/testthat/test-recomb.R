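test_that("segregating-site extraction keeps biallelic columns only", {
  aln <- rbind(c("A", "A", "A", "C", "A"),
               c("A", "C", "A", "C", "-"),
               c("A", "C", "G", "C", "A"),
               c("A", "C", "T", "C", "A"))
  sm <- segregating_sites(aln)
  # col 1/4 monomorphic, col 3 triallelic, col 5 has a gap: only col 2 stays
  expect_equal(ncol(sm$matrix), 1L)
  expect_equal(sm$positions, 2L)
  expect_equal(sm$n_dropped_multi, 1L)
  expect_equal(sm$n_dropped_gap, 1L)
  # majority allele codes 0: column 2 has one A and three C
  expect_equal(sum(sm$matrix[, 1]), 1L)
  identical_aln <- matrix("G", 5, 8)
  expect_equal(ncol(segregating_sites(identical_aln)$matrix), 0L)
  # the documented example: one clean biallelic column kept, one 4-state dropped
  aln2 <- cbind(c("A", "A", "T", "T"), c("A", "C", "G", "T"))
  sm2 <- segregating_sites(aln2)
  expect_equal(ncol(sm2$matrix), 1L)
  expect_equal(sm2$positions, 1L)
  expect_equal(sm2$n_dropped_multi, 1L)
  expect_error(segregating_sites(c("ACGT", "ACG")), "ragged")
})

test_that("r-squared matches hand-derived haplotype configurations", {
  # two identical columns -> r2 = 1
  sm <- make_site_matrix(cbind(c(0, 0, 1, 1), c(0, 0, 1, 1)), c(1, 5))
  expect_equal(pairwise_r2(sm)$r2, 1)
  # all four haplotypes equally frequent -> D = 0 -> r2 = 0
  sm2 <- make_site_matrix(cbind(c(0, 0, 1, 1), c(0, 1, 0, 1)), c(1, 5))
  expect_equal(pairwise_r2(sm2)$r2, 0)
  # perfect repulsion is still perfect association
  sm3 <- make_site_matrix(cbind(c(0, 0, 1, 1), c(1, 1, 0, 0)), c(1, 5))
  expect_equal(pairwise_r2(sm3)$r2, 1)
  # r2 in [0,1] and invariant to 0/1 relabelling
  set.seed(31)
  for (i in 1:50) {
    sm4 <- random_sites(10, 6, 200)
    r <- pairwise_r2(sm4)$r2
    expect_true(all(r >= -1e-12 & r <= 1 + 1e-12))
    flip <- sample(6, 2)
    m2 <- sm4$matrix; m2[, flip] <- 1L - m2[, flip]
    sm5 <- make_site_matrix(m2, sm4$positions, sm4$L)
    expect_equal(pairwise_r2(sm5)$r2, r, tolerance = 1e-12)
  }
})

test_that("LD-distance correlation matches direct computation", {
  expect_equal(ld_distance_correlation(data.frame(distance = 1:3,
                                                  r2 = c(1, 0.5, 0))), -1)
  expect_equal(ld_distance_correlation(data.frame(distance = 1:3,
                                                  r2 = c(0.2, 0.2, 0.8))),
               0.866, tolerance = 5e-4)
  expect_true(is.na(ld_distance_correlation(data.frame(distance = 1:3,
                                                       r2 = c(0.4, 0.4, 0.4)))))
})

test_that("three columns are tested over the six exhaustive permutations", {
  sm <- make_site_matrix(cbind(c(0, 0, 1, 1, 1), c(0, 1, 1, 1, 0),
                               c(1, 1, 0, 0, 0)), c(2, 10, 40), 50)
  res <- permutation_test(sm, n_perm = 1000)
  expect_true(res$exhaustive)
  expect_equal(res$n_permutations, 6L)
  expect_true(res$p_value %in% ((1:6) / 6))
})

test_that("Monte-Carlo p converges to exhaustive enumeration for few columns", {
  set.seed(17)
  sm <- random_sites(12, 6, 300)
  ex <- permutation_test(sm, n_perm = 100000)     # 6! = 720 -> exhaustive
  expect_true(ex$exhaustive)
  for (np in c(400, 2000)) {
    # force Monte Carlo by reducing the budget below 720
    mc <- permutation_test(sm, n_perm = min(np, 719))
    expect_false(mc$exhaustive)
    expect_lt(abs(mc$p_value - ex$p_value), 2 / sqrt(mc$n_permutations))
  }
})

test_that("permutation p-values are super-uniform under exchangeability", {
  set.seed(23)
  pvals <- replicate(2000, {
    sm <- random_sites(8, 6, 327)
    permutation_test(sm, n_perm = 99)$p_value
  })
  # one-sided Kolmogorov bound at alpha = 0.01: ecdf must not exceed the
  # uniform by more than sqrt(log(1/alpha) / (2 m))
  ps <- sort(pvals)
  d_plus <- max(seq_along(ps) / length(ps) - ps)
  expect_lte(d_plus, sqrt(log(100) / (2 * length(ps))))
})

test_that("the test holds its level on simulated non-recombining samples", {
  set.seed(29)
  p <- sim_params(n_sample = 24, c = 0, theta_s = 0.1)
  rej <- replicate(400, detect_recombination(simulate_sample(p),
                                             n_perm = 200)$detected)
  rate <- mean(rej)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("moderate recombination in a neutral sample is detected", {
  # all-pseudogene neutral sample (f = 1) with an ancient duplication and a
  # per-link scaled recombination rate in the gradual-decay regime: r2 falls
  # off with distance and the test fires far above its level.  (At extreme
  # rates every pair of sites is already at linkage equilibrium, the r2 -
  # distance relation flattens, and this statistic loses power.)
  set.seed(37)
  p <- sim_params(n_sample = 24, c = 1, f = 1, t_d = 5, theta_s = 0.05,
                  r_over_mu = 2, theta_b = 0.05 / 2e6)
  rej <- replicate(60, detect_recombination(simulate_sample(p),
                                            n_perm = 200)$detected)
  expect_gt(mean(rej), 0.5)
})

test_that("degenerate alignments score not-detected with p = 1", {
  invariant <- matrix("A", 6, 50)
  res <- detect_recombination(invariant)
  expect_false(res$detected)
  expect_equal(res$p_value, 1)
  expect_true(res$degenerate)
  expect_error(permutation_test(make_site_matrix(cbind(c(0, 1, 0, 1)), 3L, 10L)),
               "insufficient")
  # determinism of the full pipeline
  s <- simulate_sample(sim_params(theta_s = 0.1, c = 0.5, r_over_mu = 20), seed = 5)
  r1 <- detect_recombination(s, n_perm = 200, seed = 11)
  r2 <- detect_recombination(s, n_perm = 200, seed = 11)
  expect_identical(r1, r2)
})

test_that("observed statistic and tail agree with vegan's Mantel formulation", {
  # the LD-distance permutation test is a Mantel test between the pairwise
  # r-squared matrix and the pairwise distance matrix of the site positions;
  # vegan provides an independent implementation (negated distances align
  # vegan's upper tail with this test's lower tail)
  set.seed(41)
  sm <- random_sites(12, 15, 327)
  res <- permutation_test(sm, n_perm = 999)
  r2m <- matrix(0, 15, 15)
  pr <- pairwise_r2(sm)
  for (k in seq_len(nrow(pr))) {
    r2m[pr$i[k], pr$j[k]] <- pr$r2[k]
    r2m[pr$j[k], pr$i[k]] <- pr$r2[k]
  }
  dm <- as.matrix(dist(sm$positions))
  mt <- vegan::mantel(as.dist(r2m), as.dist(-dm), permutations = 999)
  expect_equal(unname(mt$statistic), -res$observed_correlation, tolerance = 1e-12)
  expect_lt(abs(mt$signif - res$p_value), 2 / sqrt(999))
})
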