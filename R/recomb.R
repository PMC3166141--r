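#' Extract biallelic segregating sites from an alignment
#'
#' Columns with gaps, ambiguity codes or more than two states are dropped
#' (counts are kept on the result); remaining polymorphic columns are
#' coded 0 for the majority allele and 1 for the alternate, with ties
#' broken alphabetically.  The 0/1 labelling is immaterial to r-squared.
#'
#' @param x a `sequence_sample`, a character matrix of aligned sequences,
#'   or an `ape::DNAbin` matrix.
#' @return object of class `site_matrix`: binary `matrix` (sequences x
#'   sites), 1-based `positions` within the alignment, the alignment
#'   length `L`, and the dropped-column counts `n_dropped_gap` /
#'   `n_dropped_multi`.
#' @export
segregating_sites <- function(x) {
  aln <- as_alignment_matrix(x)
  n <- nrow(aln)
  if (n < 2L) stop("need at least 2 sequences")
  L <- ncol(aln)
  keep_pos <- integer(0)
  cols <- list()
  n_gap <- 0L; n_multi <- 0L
  for (j in seq_len(L)) {
    col <- aln[, j]
    if (!all(col %in% c("A", "C", "G", "T"))) { n_gap <- n_gap + 1L; next }
    states <- sort(unique(col))
    if (length(states) == 1L) next
    if (length(states) > 2L) { n_multi <- n_multi + 1L; next }
    counts <- c(sum(col == states[1]), sum(col == states[2]))
    major <- states[which.max(counts)]  # ties -> alphabetical first
    keep_pos <- c(keep_pos, j)
    cols[[length(cols) + 1L]] <- as.integer(col != major)
  }
  mat <- if (length(cols)) do.call(cbind, cols) else matrix(integer(0), n, 0L)
  structure(list(matrix = mat, positions = keep_pos, L = L,
                 n_dropped_gap = n_gap, n_dropped_multi = n_multi),
            class = "site_matrix")
}

# normalise the accepted alignment representations to an upper-case
# character matrix
as_alignment_matrix <- function(x) {
  if (inherits(x, "sequence_sample")) return(x$alignment)
  if (inherits(x, "DNAbin")) {
    if (!is.matrix(x)) stop("ragged alignment: sequences differ in length")
    return(toupper(as.character(x)))
  }
  if (is.matrix(x) && is.character(x)) return(toupper(x))
  if (is.character(x)) {
    lens <- nchar(x)
    if (length(unique(lens)) != 1L) stop("ragged alignment: sequences differ in length")
    return(toupper(do.call(rbind, strsplit(x, ""))))
  }
  stop("unsupported alignment type")
}

#' Linkage disequilibrium (r-squared) for all pairs of sites
#'
#' For each unordered pair of biallelic columns, `r2 = D^2 / (pA qA pB qB)`
#' with `D = freq(1,1) - pA pB`; the distance is the absolute difference
#' of the columns' alignment positions.
#'
#' @param sites a `site_matrix` with at least two columns.
#' @return data frame with one row per pair: `i`, `j` (column indices),
#'   `distance` (sites) and `r2`.
#' @export
pairwise_r2 <- function(sites) {
  stopifnot(inherits(sites, "site_matrix"))
  X <- sites$matrix
  S <- ncol(X)
  if (S < 2L) stop("need at least 2 segregating sites")
  n <- nrow(X)
  p <- colMeans(X)
  p11 <- crossprod(X) / n
  D <- p11 - outer(p, p)
  denom <- outer(p * (1 - p), p * (1 - p))
  r2m <- D^2 / denom
  idx <- which(upper.tri(r2m), arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2],
             distance = abs(sites$positions[idx[, 1]] - sites$positions[idx[, 2]]),
             r2 = r2m[idx])
}

# full symmetric r2 matrix (diag 0) for the permutation inner loop
r2_matrix <- function(sites) {
  X <- sites$matrix
  n <- nrow(X)
  p <- colMeans(X)
  D <- crossprod(X) / n - outer(p, p)
  r2m <- D^2 / outer(p * (1 - p), p * (1 - p))
  diag(r2m) <- 0
  r2m
}

#' Correlation between linkage disequilibrium and distance
#'
#' Pearson product-moment correlation of r-squared against inter-site
#' distance.  Recombination causes LD to decay with distance, i.e. a
#' negative correlation.
#'
#' @param pairs data frame from [pairwise_r2()] (columns `distance`, `r2`).
#' @return the correlation, or `NA_real_` when either coordinate has zero
#'   variance (not computable; the permutation test reports p = 1).
#' @export
ld_distance_correlation <- function(pairs) {
  stopifnot(all(c("distance", "r2") %in% names(pairs)), nrow(pairs) >= 2L)
  if (stats::sd(pairs$distance) == 0 || stats::sd(pairs$r2) == 0) return(NA_real_)
  stats::cor(pairs$distance, pairs$r2)
}

#' Permutation test of recombination from LD decay with distance
#'
#' The null distribution of the r2-distance correlation is built by
#' permuting the assignment of columns to positions: each column pair
#' keeps its r-squared but acquires the distance of its permuted
#' positions.  The test is one-tailed toward negative correlation and the
#' Monte Carlo p-value is `(1 + #{perm cor <= observed}) / (n_perm + 1)`.
#' With seven or fewer columns and a sufficient permutation budget all
#' permutations are enumerated and the p-value is the exact tail
#' proportion (the identity permutation included).
#'
#' @param sites a `site_matrix` with at least three columns.
#' @param n_perm number of permutations.
#' @param alpha detection level.
#' @param seed optional RNG seed.
#' @return object of class `ld_test`: `observed_correlation`, `p_value`,
#'   `n_sites`, `n_pairs`, `n_permutations`, `detected`, `exhaustive`,
#'   `alpha`.
#' @export
permutation_test <- function(sites, n_perm = 1000L, alpha = 0.05, seed = NULL) {
  stopifnot(inherits(sites, "site_matrix"))
  if (!is.null(seed)) set.seed(seed)
  S <- ncol(sites$matrix)
  if (S < 3L) stop("insufficient data: need >= 3 segregating sites")
  pairs <- pairwise_r2(sites)
  obs <- ld_distance_correlation(pairs)
  if (is.na(obs)) {
    return(structure(list(observed_correlation = NA_real_, p_value = 1,
                          n_sites = S, n_pairs = nrow(pairs),
                          n_permutations = 0L, detected = FALSE,
                          exhaustive = FALSE, degenerate = TRUE,
                          alpha = alpha), class = "ld_test"))
  }
  cnt <- .perm_count_cpp(r2_matrix(sites), as.numeric(sites$positions),
                         as.integer(n_perm))
  p <- if (cnt$exhaustive) cnt$count_le / cnt$total
       else (1 + cnt$count_le) / (cnt$total + 1)
  structure(list(observed_correlation = obs, p_value = p,
                 n_sites = S, n_pairs = nrow(pairs),
                 n_permutations = as.integer(cnt$total),
                 detected = p <= alpha,
                 exhaustive = isTRUE(cnt$exhaustive),
                 degenerate = FALSE, alpha = alpha),
            class = "ld_test")
}

#' @export
print.ld_test <- function(x, ...) {
  cat("LD-distance permutation test of recombination\n")
  cat(sprintf("  sites: %d  pairs: %d  permutations: %d%s\n", x$n_sites,
              x$n_pairs, x$n_permutations,
              if (x$exhaustive) " (exhaustive)" else ""))
  cat(sprintf("  observed correlation: %s  p = %.4g  -> %s at alpha = %g\n",
              format(x$observed_correlation, digits = 4), x$p_value,
              if (x$detected) "recombination detected" else "not detected",
              x$alpha))
  invisible(x)
}

#' Full recombination-detection pipeline
#'
#' [segregating_sites()] then [permutation_test()].  An alignment with
#' fewer than three usable biallelic columns cannot carry a signal and is
#' scored "not detected" with p = 1 (flagged `degenerate`) rather than
#' erroring, so that low-diversity simulation replicates still contribute
#' to detection proportions.
#'
#' @param x alignment input as in [segregating_sites()].
#' @inheritParams permutation_test
#' @return an `ld_test`.
#' @export
detect_recombination <- function(x, alpha = 0.05, n_perm = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sites <- segregating_sites(x)
  S <- ncol(sites$matrix)
  if (S < 3L) {
    return(structure(list(observed_correlation = NA_real_, p_value = 1,
                          n_sites = S, n_pairs = 0L, n_permutations = 0L,
                          detected = FALSE, exhaustive = FALSE,
                          degenerate = TRUE, alpha = alpha),
                     class = "ld_test"))
  }
  permutation_test(sites, n_perm = n_perm, alpha = alpha)
}
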