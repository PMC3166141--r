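test_that("parameter validation enforces the model invariants", {
  expect_error(sim_params(f = 0.5), "f >= 1")
  expect_error(sim_params(theta_s = 0), "theta_s > 0")
  expect_error(sim_params(c = 1.5), "c <= 1")
  expect_error(sim_params(t_d = 0), "t_d > 0")
  expect_error(sim_params(theta_b = 2, theta_s = 1), "theta_b <= theta_s")
  p <- sim_params(theta_s = 0.2, r_over_mu = 60)
  expect_equal(p$rho_site, 12)
  expect_equal(p$theta_p, 0.01)
})

test_that("the S class never recombines: one marginal tree when c = 0 or r = 0", {
  set.seed(101)
  for (i in 1:20) {
    tr <- simulate_arg(sim_params(n_sample = 6, c = 0, r_over_mu = 2000,
                                  theta_s = 1))
    expect_equal(nrow(tr$segments), 1L)
  }
  for (i in 1:20) {
    tr <- simulate_arg(sim_params(n_sample = 6, c = 0.5, r_over_mu = 0,
                                  theta_s = 1, t_d = 2))
    expect_equal(nrow(tr$segments), 1L)
  }
})

test_that("marginal segments partition the sequence and trees carry all tips", {
  set.seed(7)
  for (i in 1:10) {
    p <- sim_params(n_sample = 8, c = 0.75, r_over_mu = 200, theta_s = 0.5,
                    t_d = 0.5, L = 100)
    tr <- simulate_arg(p)
    segs <- tr$segments
    expect_equal(segs$start[1], 0L)
    expect_equal(segs$end[nrow(segs)], 100L)
    if (nrow(segs) > 1L) {
      expect_true(all(segs$start[-1] == segs$end[-nrow(segs)]))
      expect_true(all(diff(segs$start) > 0))
    }
    phys <- marginal_trees_phylo(tr)
    for (ph in phys) {
      expect_equal(ape::Ntip(ph), 8L)
      expect_true(ape::is.binary(ph))
      expect_true(ape::is.ultrametric(ph, tol = 1e-6))
    }
  }
})

test_that("pairwise coalescence times match the analytic rates", {
  # S-class pair: rate 1 -> E[T2] = 1, exponential
  set.seed(202)
  p <- sim_params(n_sample = 2, c = 0, theta_s = 0.1)
  t2 <- replicate(10000, tmrca(simulate_arg(p)))
  se <- sd(t2) / sqrt(length(t2))
  expect_lt(abs(mean(t2) - 1), 3 * se)
  ks <- suppressWarnings(ks.test(t2, "pexp", 1))
  expect_gt(ks$p.value, 0.01)

  # P-class pair: rate f -> E[T2] ~ 1/f when t_d is large
  p2 <- sim_params(n_sample = 2, c = 1, f = 20, t_d = 3, theta_s = 0.1)
  t2p <- replicate(10000, tmrca(simulate_arg(p2)))
  expect_lt(abs(mean(t2p) - 0.05), 3 * sd(t2p) / sqrt(length(t2p)))
  # P times stochastically smaller: median ratio ~ 1/f
  expect_lt(abs(median(t2p) / median(t2) - 1 / 20), 0.02)
})

test_that("neutral TMRCA distribution matches an independent coalescent oracle", {
  # msprime with ploidy 1 and population size 1 has pair-coalescence rate 1,
  # the same time units as the simulator's S class
  py <- paste(
    "import msprime",
    "out = []",
    "for s in range(1, 2001):",
    "    ts = msprime.sim_ancestry(samples=10, ploidy=1, population_size=1, random_seed=s)",
    "    t = ts.first()",
    "    out.append(t.time(t.root))",
    "print('\\n'.join(repr(x) for x in out))",
    sep = "\n")
  ref <- as.numeric(system2("python", c("-c", shQuote(py)), stdout = TRUE))
  expect_equal(length(ref), 2000L)
  set.seed(303)
  p <- sim_params(n_sample = 10, c = 0, theta_s = 0.1)
  mine <- replicate(2000, tmrca(simulate_arg(p)))
  ks <- suppressWarnings(ks.test(mine, ref))
  expect_gt(ks$p.value, 0.01)
})

test_that("sequence evolution follows Jukes-Cantor expectations", {
  # fixed two-tip tree with TMRCA 1: path length 2, d = theta_s per site;
  # expected p-distance 3/4 (1 - exp(-4 d / 3))
  tr <- structure(list(
    node_time = c(0, 0, 1), node_left = c(NA, NA, 1L), node_right = c(NA, NA, 2L),
    segments = data.frame(start = 0L, end = 10000L, root = 3L),
    source_labels = c("S", "S"), n_recomb = 0L,
    params = sim_params(n_sample = 2, c = 0, theta_s = 0.1, L = 10000L)),
    class = "marginal_trees")
  set.seed(404)
  pd <- replicate(20, {
    s <- evolve_sequences(tr)
    mean(s$alignment[1, ] != s$alignment[2, ])
  })
  # two branches of length 1 * theta_s / 2 each: total divergence d = 0.1
  expected <- 0.75 * (1 - exp(-4 * 0.1 / 3))
  se <- sd(pd) / sqrt(length(pd))
  expect_lt(abs(mean(pd) - expected), 3 * se)
})

test_that("mutation events and segregating sites match Watterson's expectation", {
  n <- 24L; L <- 327L
  a_n <- sum(1 / seq_len(n - 1))
  # substitution events: E = theta_s * L * a_n exactly (jump-process count)
  set.seed(505)
  p <- sim_params(n_sample = n, c = 0, theta_s = 0.1, L = L)
  ev <- replicate(2000, simulate_sample(p)$n_mut_events)
  se_ev <- sd(ev) / sqrt(length(ev))
  expect_lt(abs(mean(ev) - 0.1 * L * a_n), 3 * se_ev)
  # biallelic column count: finite-site bias is negligible at small theta
  set.seed(506)
  p2 <- sim_params(n_sample = n, c = 0, theta_s = 0.01, L = L)
  segs <- replicate(1500, ncol(segregating_sites(simulate_sample(p2))$matrix))
  se_s <- sd(segs) / sqrt(length(segs))
  expect_lt(abs(mean(segs) - 0.01 * L * a_n), 3 * se_s + 0.02 * 0.01 * L * a_n)
})

test_that("pairwise diversity between S-class tips equals theta_s", {
  set.seed(606)
  p <- sim_params(n_sample = 2, c = 0, theta_s = 0.05, L = 2000L)
  pis <- replicate(400, {
    s <- simulate_sample(p)
    mean(s$alignment[1, ] != s$alignment[2, ])
  })
  # finite-sites p-distance slightly below theta_s; JC-correct it back
  d <- -0.75 * log(1 - 4 * pis / 3)
  expect_lt(abs(mean(d) - 0.05), 3 * sd(d) / sqrt(length(d)))
})

test_that("samples are labelled and reproducible", {
  p <- sim_params(theta_s = 0.1, c = 0.5, n_sample = 24)
  s <- simulate_sample(p, seed = 7)
  expect_equal(sum(s$source_labels == "P"), 12L)
  expect_equal(sum(s$source_labels == "S"), 12L)
  expect_equal(dim(s$alignment), c(24L, 327L))
  s2 <- simulate_sample(p, seed = 7)
  expect_identical(s$alignment, s2$alignment)
  s3 <- simulate_sample(sim_params(theta_s = 0.1, c = 0, n_sample = 24), seed = 1)
  expect_true(all(s3$source_labels == "S"))
})

test_that("grid runner is deterministic per combination and validates inputs", {
  expect_error(run_grid(theta_s = 0.1, t_d = 1, r_over_mu = 0, c = 0, reps = 0),
               "reps")
  g1 <- run_grid(theta_s = 0.1, t_d = c(0.1, 1), r_over_mu = 20, c = 0.25,
                 reps = 5, n_perm = 50, seed = 9)
  g2 <- run_grid(theta_s = 0.1, t_d = c(0.1, 1), r_over_mu = 20, c = 0.25,
                 reps = 5, n_perm = 50, seed = 9)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 2L)
  expect_true(all(g1$proportion >= 0 & g1$proportion <= 1))
})
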