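# Independent brute-force oracles used to cross-check the package's
# statistics.  These deliberately share no code with the implementation.

# Pearson chi-square from first principles
chi2_oracle <- function(tab) {
  N <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / N
  sum((tab - E)^2 / E)
}

# two-sided Fisher p by full enumeration of the hypergeometric support;
# tables with probability <= observed * (1 + 1e-7) are summed (the relative
# tolerance matches the conventional handling of floating-point ties)
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  a_min <- max(0L, r1 + c1 - N); a_max <- min(r1, c1)
  support <- a_min:a_max
  probs <- dhyper(support, c1, N - c1, r1)
  p_obs <- dhyper(tab[1, 1], c1, N - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# genetic code for the Nei-Gojobori oracle, taken from Biostrings so the
# oracle's code table is independent of the implementation's (seqinr)
oracle_code <- local({
  code <- NULL
  function() {
    if (is.null(code)) code <<- Biostrings::GENETIC_CODE
    code
  }
})

# synonymous sites of one codon: fraction of one-step changes preserving
# the amino acid, changes to stop counted as non-synonymous
ng_sites_oracle <- function(codon) {
  code <- oracle_code()
  v <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) for (alt in setdiff(c("A", "C", "G", "T"), v[pos])) {
    w <- v; w[pos] <- alt
    m <- paste(w, collapse = "")
    if (code[[m]] != "*" && code[[m]] == code[[codon]]) s <- s + 1 / 3
  }
  s
}

# average syn/nonsyn differences over all mutational pathways between two
# codons, recursively enumerated; pathways through stop codons dropped
# (all pathways used if every one is blocked)
ng_diffs_oracle <- function(c1, c2) {
  code <- oracle_code()
  v2 <- strsplit(c2, "")[[1]]
  walk <- function(cur, allow_stop) {
    dp <- which(cur != v2)
    if (length(dp) == 0L) return(list(c(0, 0)))
    out <- list()
    for (pos in dp) {
      nxt <- cur; nxt[pos] <- v2[pos]
      aa_from <- code[[paste(cur, collapse = "")]]
      aa_to <- code[[paste(nxt, collapse = "")]]
      if (!allow_stop && aa_to == "*" && any(nxt != v2)) next
      step <- if (aa_to != "*" && aa_from != "*" && aa_from == aa_to)
        c(1, 0) else c(0, 1)
      for (tail in walk(nxt, allow_stop))
        out[[length(out) + 1L]] <- step + tail
    }
    out
  }
  res <- walk(strsplit(c1, "")[[1]], allow_stop = FALSE)
  if (length(res) == 0L) res <- walk(strsplit(c1, "")[[1]], allow_stop = TRUE)
  colMeans(do.call(rbind, res))
}

# column-wise nucleotide diversity for gapless alignments: mean over
# columns of the fraction of differing pairs
pi_column_oracle <- function(aln) {
  n <- nrow(aln)
  npairs <- n * (n - 1) / 2
  colsum <- apply(aln, 2, function(col) {
    tab <- table(col)
    (npairs - sum(tab * (tab - 1) / 2)) / npairs
  })
  mean(colsum)
}

# random full (two-unit) genotypes for property tests
random_genotype <- function(pool) paste(sample(pool, 2), collapse = "+")

# site matrix built directly from a binary matrix (helper for permutation
# tests that do not need sequence simulation)
make_site_matrix <- function(mat, positions, L = max(positions)) {
  stopifnot(ncol(mat) == length(positions))
  structure(list(matrix = mat, positions = positions, L = L,
                 n_dropped_gap = 0L, n_dropped_multi = 0L),
            class = "site_matrix")
}

# random polymorphic binary columns (iid across columns, hence position-
# exchangeable: the null of the permutation test holds by construction)
random_sites <- function(n, S, L) {
  cols <- replicate(S, {
    repeat {
      x <- rbinom(n, 1, runif(1, 0.2, 0.8))
      if (length(unique(x)) == 2L) return(x)
    }
  })
  make_site_matrix(cols, sort(sample.int(L, S)), L)
}
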