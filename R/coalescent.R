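#' Simulation parameters for the contaminated S-locus coalescent
#'
#' The allelic genealogy of S-alleles under long-term balancing selection
#' is approximated by a neutral coalescent with effective size inflated by
#' a scaling factor `f`, so the S-allele mutation parameter is
#' `theta_s = 4 f Ne mu` per site while a duplicated pseudogene, released
#' from balancing selection, evolves with `theta_p = theta_s / f`.  Time
#' is measured in units of `4 Ne f` generations throughout: an S-class
#' pair coalesces at rate 1 and a pseudogene-class pair at rate `f`.
#'
#' Looking backward, the pseudogene recombines (the functional S-allele
#' does not) until the duplication time `t_d`; a severe bottleneck of
#' duration `t_b` and mutation parameter `theta_b` (a proxy for the
#' bottleneck size: pairwise coalescence rate `theta_s / theta_b`) then
#' enforces the duplication's single origin, after which the surviving
#' pseudogene lineage joins the S-allele genealogy.
#'
#' @param f balancing-selection scaling factor (>= 1).
#' @param theta_s per-site population mutation rate of S-alleles.
#' @param t_d duplication time, units of 4 Ne f generations (> 0).
#' @param t_b bottleneck duration, same units (>= 0).
#' @param theta_b bottleneck mutation parameter (0 < theta_b <= theta_s);
#'   the default `theta_s / 2e6` makes coalescence to a single lineage
#'   during the bottleneck essentially certain.
#' @param r_over_mu ratio of the per-generation, per-adjacent-site
#'   recombination rate to the mutation rate; the scaled recombination
#'   rate per adjacent-site interval is `rho_site = theta_s * r_over_mu`.
#' @param c contamination proportion: the fraction of the sample drawn
#'   from the pseudogene (`round(c * n_sample)` sequences).
#' @param n_sample total sequences sampled.
#' @param L sites.
#' @return object of class `sim_params`.
#' @examples
#' sim_params(theta_s = 0.1, t_d = 1, r_over_mu = 200, c = 0.5)
#' @export
sim_params <- function(f = 20, theta_s = 0.1, t_d = 1, t_b = 0.005,
                       theta_b = theta_s / 2e6, r_over_mu = 0, c = 0,
                       n_sample = 24L, L = 327L) {
  stopifnot(f >= 1, theta_s > 0, t_d > 0, t_b >= 0, theta_b > 0,
            theta_b <= theta_s, r_over_mu >= 0, c >= 0, c <= 1,
            n_sample >= 1, L >= 1)
  n_p <- as.integer(round(c * n_sample))
  if (n_p < 0L || n_p > n_sample) stop("contaminant count outside sample")
  structure(list(f = f, theta_s = theta_s, theta_p = theta_s / f,
                 t_d = t_d, t_b = t_b, theta_b = theta_b,
                 r_over_mu = r_over_mu, rho_site = theta_s * r_over_mu,
                 c = c, n_sample = as.integer(n_sample), n_p = n_p,
                 L = as.integer(L)),
            class = "sim_params")
}

#' Simulate the ancestral recombination graph of a contaminated sample
#'
#' Runs the structured coalescent of [sim_params()] backward from a sample
#' of `n_sample` sequences, `round(c * n_sample)` of which descend from
#' the recombining pseudogene (class `"P"`) and the rest from the
#' non-recombining S-allele class (`"S"`).  Recombination occurs only on
#' P-class lineages and only more recently than `t_d`, at rate `rho_site`
#' per breakpoint spanned by a lineage's ancestral material, with the
#' breakpoint uniform over that span.  The process ends at the grand MRCA
#' of every site and returns the marginal genealogies.
#'
#' @param params a [sim_params()] object.
#' @param seed optional RNG seed (the R RNG drives all events, so
#'   `set.seed()` beforehand works equally).
#' @return object of class `marginal_trees`: a node table (`node_time`,
#'   `node_left`, `node_right`; tips are nodes `1..n_sample` at time 0),
#'   a `segments` data frame (half-open `[start, end)` 0-based site
#'   intervals, each with its root node), `source_labels`, the recombination
#'   event count `n_recomb`, and the originating `params`.
#' @examples
#' tr <- simulate_arg(sim_params(n_sample = 4, c = 0), seed = 1)
#' nrow(tr$segments)   # one tree: the S class never recombines
#' @export
simulate_arg <- function(params, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  res <- .arg_simulate_cpp(params$n_sample, params$n_p, params$f,
                           params$theta_s, params$t_d, params$t_b,
                           params$theta_b, params$rho_site, params$L)
  segs <- data.frame(start = res$seg_start, end = res$seg_end,
                     root = res$seg_root + 1L)
  structure(list(node_time = res$node_time,
                 node_left = res$node_left + 1L,
                 node_right = res$node_right + 1L,
                 segments = segs,
                 source_labels = rep(c("P", "S"),
                                     c(params$n_p, params$n_sample - params$n_p)),
                 n_recomb = res$n_recomb,
                 params = params),
            class = "marginal_trees")
}

#' @export
print.marginal_trees <- function(x, ...) {
  cat("Marginal genealogies for", x$params$n_sample, "sequences over",
      x$params$L, "sites\n")
  cat("  segments:", nrow(x$segments),
      " recombination events:", x$n_recomb, "\n")
  cat("  grand MRCA at", format(max(x$node_time), digits = 4),
      "coalescent time units\n")
  invisible(x)
}

#' Time to the grand most recent common ancestor
#'
#' @param trees a `marginal_trees` object.
#' @return the oldest node time, in coalescent units (4 Ne f generations).
#' @export
tmrca <- function(trees) max(trees$node_time)

#' Evolve Jukes-Cantor sequences along marginal genealogies
#'
#' Each site evolves along its segment's tree under the Jukes-Cantor
#' model with branch lengths of (coalescent time) x `theta_s / 2` expected
#' substitutions per site and a uniform root base.  Substitutions are
#' realised as an explicit jump process, so the object also reports the
#' number of mutation events, which follows the infinite-sites expectation
#' `theta_s * L * sum(1/i, i < n)` and is convenient for calibration
#' checks.
#'
#' @param trees a `marginal_trees` object from [simulate_arg()].
#' @param params parameters (defaults to those stored in `trees`).
#' @param seed optional RNG seed.
#' @return object of class `sequence_sample`: `alignment` (character
#'   matrix of A/C/G/T), `source_labels`, `n_mut_events`, `params`.
#' @export
evolve_sequences <- function(trees, params = trees$params, seed = NULL) {
  stopifnot(inherits(trees, "marginal_trees"))
  if (!is.null(seed)) set.seed(seed)
  segs <- trees$segments
  if (nrow(segs) == 0L || sum(segs$end - segs$start) != params$L)
    stop("segments do not cover the sequence")
  res <- .evolve_jc_cpp(trees$node_time, trees$node_left - 1L,
                        trees$node_right - 1L, segs$start, segs$end,
                        segs$root - 1L, params$theta_s,
                        params$n_sample, params$L)
  aln <- matrix(c("A", "C", "G", "T")[res$alignment + 1L],
                params$n_sample, params$L)
  rownames(aln) <- sprintf("%s%02d", tolower(trees$source_labels),
                           seq_len(params$n_sample))
  structure(list(alignment = aln,
                 source_labels = trees$source_labels,
                 n_mut_events = res$n_mut_events,
                 params = params),
            class = "sequence_sample")
}

#' @export
print.sequence_sample <- function(x, ...) {
  cat("Sequence sample:", nrow(x$alignment), "x", ncol(x$alignment),
      " (", sum(x$source_labels == "P"), "pseudogene,",
      sum(x$source_labels == "S"), "S-allele )\n")
  invisible(x)
}

#' Simulate a contaminated sequence sample
#'
#' Composition of [simulate_arg()] and [evolve_sequences()]; deterministic
#' given the seed.
#'
#' @inheritParams simulate_arg
#' @return a `sequence_sample`.
#' @examples
#' s <- simulate_sample(sim_params(theta_s = 0.1, c = 0.5, n_sample = 24), seed = 7)
#' table(s$source_labels)
#' @export
simulate_sample <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  evolve_sequences(simulate_arg(params))
}

#' Convert marginal genealogies to ape trees
#'
#' @param trees a `marginal_trees` object.
#' @return list of `ape::phylo` objects, one per segment, each with
#'   attributes `start`/`end` giving its 1-based inclusive site range.
#' @export
marginal_trees_phylo <- function(trees) {
  n <- trees$params$n_sample
  tips <- rownames_for_tips(trees)
  nwk_node <- function(id, parent_time) {
    bl <- parent_time - trees$node_time[id]
    if (id <= n) return(sprintf("%s:%.10g", tips[id], bl))
    sprintf("(%s,%s):%.10g",
            nwk_node(trees$node_left[id], trees$node_time[id]),
            nwk_node(trees$node_right[id], trees$node_time[id]), bl)
  }
  lapply(seq_len(nrow(trees$segments)), function(i) {
    root <- trees$segments$root[i]
    txt <- if (root <= n) sprintf("(%s:0);", tips[root]) else
      sprintf("(%s,%s);",
              nwk_node(trees$node_left[root], trees$node_time[root]),
              nwk_node(trees$node_right[root], trees$node_time[root]))
    ph <- ape::read.tree(text = txt)
    attr(ph, "start") <- trees$segments$start[i] + 1L
    attr(ph, "end") <- trees$segments$end[i]
    ph
  })
}

rownames_for_tips <- function(trees) {
  sprintf("%s%02d", tolower(trees$source_labels),
          seq_len(trees$params$n_sample))
}

#' Detection proportions over a factorial parameter grid
#'
#' For every combination of `theta_s`, `t_d`, `r_over_mu` and `c`, runs
#' `reps` simulate-then-test replicates ([simulate_sample()] followed by
#' [detect_recombination()]) and records the proportion detecting
#' recombination at level `alpha`, with its binomial standard error.  The
#' default parameter lists are the full factorial design used to gauge how
#' often pseudogene contamination alone produces a recombination signal;
#' `f = 20`, `t_b = 0.005` and `theta_b = theta_s / 2e6` are fixed by that
#' design.  Each combination uses a deterministic sub-seed derived from
#' `seed`, so rows are reproducible independently of grid order.
#'
#' @param theta_s,t_d,r_over_mu,c numeric vectors of grid values.
#' @param f,t_b scalar fixed parameters.
#' @param theta_b_fun function of `theta_s` giving `theta_b`.
#' @param n_sample,L sample size and sequence length.
#' @param reps simulation replicates per combination (>= 1).
#' @param alpha detection level.
#' @param n_perm permutations per test.
#' @param seed integer master seed.
#' @param verbose print one line per combination.
#' @return data frame: one row per combination with the parameters,
#'   `reps`, `detections`, `proportion` and `se`.
#' @export
run_grid <- function(theta_s = c(0.01, 0.1, 0.2, 0.3, 1, 2),
                     t_d = c(0.01, 0.1, 1, 2, 3),
                     r_over_mu = c(2, 20, 60, 100, 200, 2000),
                     c = c(0.25, 0.5, 0.75),
                     f = 20, t_b = 0.005,
                     theta_b_fun = function(ts) ts / 2e6,
                     n_sample = 24L, L = 327L,
                     reps = 1000L, alpha = 0.05, n_perm = 1000L,
                     seed = 1L, verbose = FALSE) {
  if (reps < 1L) stop("reps must be >= 1")
  grid <- expand.grid(theta_s = theta_s, t_d = t_d, r_over_mu = r_over_mu,
                      c = c, KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0L) stop("empty parameter grid")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    sub_seed <- (as.integer(seed) %% 100000L) * 20011L + i * 7919L
    set.seed(sub_seed %% 2147483647L)
    par <- sim_params(f = f, theta_s = g$theta_s, t_d = g$t_d, t_b = t_b,
                      theta_b = theta_b_fun(g$theta_s),
                      r_over_mu = g$r_over_mu, c = g$c,
                      n_sample = n_sample, L = L)
    det <- 0L
    for (r in seq_len(reps)) {
      s <- simulate_sample(par)
      res <- detect_recombination(s, alpha = alpha, n_perm = n_perm)
      det <- det + as.integer(res$detected)
    }
    prop <- det / reps
    if (verbose)
      message(sprintf("theta_s=%g t_d=%g r/mu=%g c=%g: %d/%d detected",
                      g$theta_s, g$t_d, g$r_over_mu, g$c, det, reps))
    data.frame(theta_s = g$theta_s, t_d = g$t_d, r_over_mu = g$r_over_mu,
               c = g$c, f = f, t_b = t_b, theta_b = theta_b_fun(g$theta_s),
               reps = reps, detections = det, proportion = prop,
               se = sqrt(prop * (1 - prop) / reps))
  })
  do.call(rbind, rows)
}
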