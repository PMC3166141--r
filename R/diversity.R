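# --- codon machinery ---------------------------------------------------------

.codon_env <- new.env(parent = emptyenv())

# standard genetic code keyed by upper-case codon; "*" marks stops
codon_table <- function() {
  if (!is.null(.codon_env$aa)) return(.codon_env$aa)
  b <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  codons <- sort(codons)
  aa <- vapply(codons, function(cd)
    seqinr::translate(strsplit(tolower(cd), "")[[1]]), character(1))
  .codon_env$aa <- aa
  aa
}

translate_codon <- function(codon) unname(codon_table()[codon])

# per-codon count of synonymous sites: at each position, the fraction of
# the three one-step changes that preserve the amino acid (changes to stop
# codons count as non-synonymous)
codon_syn_sites <- function(codon) {
  aa <- codon_table()
  a0 <- aa[codon]
  bases <- c("A", "C", "G", "T")
  s <- 0
  cv <- strsplit(codon, "")[[1]]
  for (pos in 1:3) {
    for (alt in setdiff(bases, cv[pos])) {
      mut <- cv; mut[pos] <- alt
      a1 <- aa[paste(mut, collapse = "")]
      if (a1 != "*" && a1 == a0) s <- s + 1 / 3
    }
  }
  s
}

# average synonymous / non-synonymous differences between two codons over
# all orderings of the single-base steps; pathways through stop codons are
# excluded (all pathways are used if every one is blocked)
codon_path_diffs <- function(c1, c2) {
  aa <- codon_table()
  v1 <- strsplit(c1, "")[[1]]
  v2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(v1 != v2)
  k <- length(diff_pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  paths <- if (k == 1L) list(diff_pos) else
    lapply(asplit(permutations_of(diff_pos), 1), as.integer)
  tally <- function(order_, allow_stop) {
    cur <- v1
    sd <- 0; nd <- 0
    for (pos in order_) {
      nxt <- cur; nxt[pos] <- v2[pos]
      a_from <- aa[paste(cur, collapse = "")]
      a_to <- aa[paste(nxt, collapse = "")]
      if (!allow_stop && a_to == "*" && !identical(nxt, v2)) return(NULL)
      if (a_to == "*" || a_from == "*") { nd <- nd + 1 }   # stop endpoints: nonsyn
      else if (a_from == a_to) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- Filter(Negate(is.null), lapply(paths, tally, allow_stop = FALSE))
  if (length(res) == 0L) res <- lapply(paths, tally, allow_stop = TRUE)
  colMeans(do.call(rbind, res))
}

permutations_of <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1L))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- permutations_of(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

# --- public operations -------------------------------------------------------

#' Nei-Gojobori synonymous / non-synonymous divergence for one pair
#'
#' Pathway-counting estimator: synonymous sites per codon are the
#' fraction of one-step changes at each position that preserve the amino
#' acid (averaged over the two sequences), and synonymous /
#' non-synonymous differences are averaged over all orderings of the
#' single-base steps between differing codons, excluding pathways through
#' stop codons.  Proportions `pS`, `pN` receive the Jukes-Cantor
#' correction `d = -(3/4) log(1 - 4p/3)`; a proportion at or beyond the
#' 3/4 ceiling is flagged saturated and its distance left `NA`.
#' Codons containing a gap, an ambiguity code or a stop in either
#' sequence are skipped.
#'
#' @param seq1,seq2 nucleotide strings or character vectors of equal
#'   length.
#' @param frame reading-frame offset 0, 1 or 2.
#' @return list with `Sd`, `Nd`, `S_sites`, `N_sites`, `pS`, `pN`, `dS`,
#'   `dN`, `saturated` (logical), `n_codons_used`, `n_codons_skipped`.
#' @examples
#' nei_gojobori_pair("AAAAAA", "AAGAAC")   # one syn + one nonsyn change
#' @export
nei_gojobori_pair <- function(seq1, seq2, frame = 0L) {
  s1 <- if (length(seq1) == 1L) strsplit(toupper(seq1), "")[[1]] else toupper(seq1)
  s2 <- if (length(seq2) == 1L) strsplit(toupper(seq2), "")[[1]] else toupper(seq2)
  if (length(s1) != length(s2)) stop("sequences differ in length")
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2")
  s1 <- s1[(frame + 1L):length(s1)]
  s2 <- s2[(frame + 1L):length(s2)]
  n_codons <- length(s1) %/% 3L
  aa <- codon_table()
  Sd <- 0; Nd <- 0; Ssites <- 0; Nsites <- 0
  used <- 0L; skipped <- 0L
  for (ci in seq_len(n_codons)) {
    idx <- (3L * (ci - 1L) + 1L):(3L * ci)
    c1 <- paste(s1[idx], collapse = "")
    c2 <- paste(s2[idx], collapse = "")
    ok <- all(c(s1[idx], s2[idx]) %in% c("A", "C", "G", "T")) &&
      aa[c1] != "*" && aa[c2] != "*"
    if (!ok) { skipped <- skipped + 1L; next }
    used <- used + 1L
    Ssites <- Ssites + (codon_syn_sites(c1) + codon_syn_sites(c2)) / 2
    d <- codon_path_diffs(c1, c2)
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  Nsites <- 3 * used - Ssites
  pS <- if (Ssites > 0) Sd / Ssites else NA_real_
  pN <- if (Nsites > 0) Nd / Nsites else NA_real_
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  saturated <- (!is.na(pS) && pS >= 0.75) || (!is.na(pN) && pN >= 0.75)
  list(Sd = unname(Sd), Nd = unname(Nd), S_sites = Ssites, N_sites = Nsites,
       pS = pS, pN = pN, dS = jc(pS), dN = jc(pN), saturated = saturated,
       n_codons_used = used, n_codons_skipped = skipped)
}

#' Average pairwise nucleotide diversity
#'
#' Mean over all unordered sequence pairs of (differences / compared
#' sites), with pairwise deletion: for each pair only columns where both
#' sequences carry an unambiguous base are compared.
#'
#' @param x alignment (`sequence_sample`, character matrix, `DNAbin`, or
#'   character vector of equal-length strings).
#' @param details return the per-pair table instead of the mean?
#' @return the per-site diversity (scalar), or with `details = TRUE` a
#'   data frame with one row per pair (`i`, `j`, `diffs`, `compared`,
#'   `p_dist`).
#' @export
pairwise_pi <- function(x, details = FALSE) {
  aln <- as_alignment_matrix(x)
  n <- nrow(aln)
  if (n < 2L) stop("need at least 2 sequences")
  valid <- matrix(aln %in% c("A", "C", "G", "T"), n)
  pr <- utils::combn(n, 2)
  rows <- lapply(seq_len(ncol(pr)), function(k) {
    i <- pr[1, k]; j <- pr[2, k]
    both <- valid[i, ] & valid[j, ]
    comp <- sum(both)
    diffs <- sum(aln[i, both] != aln[j, both])
    data.frame(i = i, j = j, diffs = diffs, compared = comp,
               p_dist = if (comp > 0) diffs / comp else NA_real_)
  })
  tab <- do.call(rbind, rows)
  if (details) return(tab)
  mean(tab$p_dist, na.rm = TRUE)
}

#' Average pairwise divergence of a codon alignment
#'
#' Applies [nei_gojobori_pair()] to every pair and averages, dropping
#' saturated pairs from the corrected means with a warning; total-site
#' diversity comes from [pairwise_pi()].
#'
#' @param x alignment as in [pairwise_pi()]; sequences are read in the
#'   given codon `frame`.
#' @param frame reading-frame offset 0, 1 or 2.
#' @return object of class `diversity_result`: `pi`, `pi_s` (mean dS),
#'   `pi_a` (mean dN), `pS_mean`, `pN_mean`, `mean_Sd`, `mean_Nd`,
#'   `mean_S_sites`, `mean_N_sites`, `n_pairs`, `n_saturated`.
#' @export
average_pairwise_divergence <- function(x, frame = 0L) {
  aln <- as_alignment_matrix(x)
  n <- nrow(aln)
  if (n < 2L) stop("need at least 2 sequences")
  pr <- utils::combn(n, 2)
  res <- lapply(seq_len(ncol(pr)), function(k)
    nei_gojobori_pair(aln[pr[1, k], ], aln[pr[2, k], ], frame = frame))
  sat <- vapply(res, `[[`, logical(1), "saturated")
  if (all(sat)) stop("all sequence pairs are saturated (p >= 3/4)")
  if (any(sat))
    warning(sum(sat), " saturated pair(s) dropped from corrected means")
  m <- function(f, use = !sat) mean(vapply(res[use], `[[`, numeric(1), f), na.rm = TRUE)
  structure(list(pi = pairwise_pi(aln),
                 pi_s = m("dS"), pi_a = m("dN"),
                 pS_mean = m("pS", use = TRUE), pN_mean = m("pN", use = TRUE),
                 mean_Sd = m("Sd", use = TRUE), mean_Nd = m("Nd", use = TRUE),
                 mean_S_sites = m("S_sites", use = TRUE),
                 mean_N_sites = m("N_sites", use = TRUE),
                 n_pairs = ncol(pr), n_saturated = sum(sat)),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat("Average pairwise divergence over", x$n_pairs, "pairs\n")
  cat(sprintf("  Pi_s = %.3f  Pi_a = %.3f  Pi = %.3f", x$pi_s, x$pi_a, x$pi))
  if (x$n_saturated > 0) cat("  (", x$n_saturated, "saturated pairs dropped )")
  cat("\n")
  invisible(x)
}

#' Sliding-window nucleotide diversity
#'
#' [pairwise_pi()] computed in windows along the alignment; used to
#' locate regions of elevated diversity such as the hypervariable 5'
#' stretch of stigmatic S-proteins.
#'
#' @param x alignment as in [pairwise_pi()].
#' @param window window width in sites (default 50).
#' @param step step between window starts (default 10).
#' @return data frame with `start`, `end` (1-based inclusive),
#'   `midpoint` and `pi` per window.
#' @export
sliding_window_pi <- function(x, window = 50L, step = 10L) {
  aln <- as_alignment_matrix(x)
  L <- ncol(aln)
  if (window < 1L) stop("window must be positive")
  if (step < 1L) stop("step must be positive")
  if (window > L) stop("window exceeds alignment length")
  starts <- seq(1L, L - window + 1L, by = step)
  out <- lapply(starts, function(s) {
    w <- aln[, s:(s + window - 1L), drop = FALSE]
    data.frame(start = s, end = s + window - 1L,
               midpoint = s + (window - 1L) / 2,
               pi = pairwise_pi(w))
  })
  do.call(rbind, out)
}

#' Silent-clock divergence time
#'
#' Divergence time as silent substitutions per site divided by the silent
#' substitution rate.  The verbatim quotient dates the total divergence
#' along both branches; `pairwise_halving = TRUE` divides by `2 * rate`
#' to date the split itself, the usual convention for a pairwise
#' distance.
#'
#' @param ds silent substitutions per site (>= 0).
#' @param rate silent substitution rate, substitutions per site per year
#'   (> 0).
#' @param pairwise_halving halve for the two lineages of a pairwise
#'   comparison?
#' @return time in years.
#' @examples
#' divergence_time(0.2, 5e-9)   # 4e7 years
#' @export
divergence_time <- function(ds, rate, pairwise_halving = FALSE) {
  if (rate <= 0) stop("rate must be positive")
  stopifnot(ds >= 0)
  ds / (if (pairwise_halving) 2 * rate else rate)
}
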