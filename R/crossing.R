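#' Parse and format S-locus genotypes
#'
#' A genotype is a set of one or two haplotype-unit labels.  Co-segregating
#' PCR products that are inherited as one unit (linked markers) must already
#' be collapsed into a single label; see [collapse_linked()].  A single-label
#' genotype marks a plant for which only one product could be amplified and
#' is treated as ambiguously genotyped downstream.
#'
#' @param x for `parse_genotype()`, a string of "+"-joined haplotype labels
#'   (e.g. `"S8a+S1c"`); for `format_genotype()`, a character vector of
#'   labels.
#' @return `parse_genotype()` returns a character vector of unique labels;
#'   `format_genotype()` the "+"-joined string.
#' @examples
#' parse_genotype("S8a+S1c")
#' format_genotype(c("S8a", "S1c"))
#' @export
parse_genotype <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  labs <- unique(strsplit(x, "+", fixed = TRUE)[[1]])
  labs <- labs[nzchar(labs)]
  if (length(labs) < 1L) stop("invalid genotype: no haplotype labels in ", sQuote(x))
  if (length(labs) > 2L) stop("invalid genotype: more than two haplotype units in ", sQuote(x))
  labs
}

#' @rdname parse_genotype
#' @export
format_genotype <- function(x) paste(unique(x), collapse = "+")

#' Collapse linked co-segregating products into haplotype units
#'
#' Products that always co-segregate (e.g. two PCR products amplified from
#' one inherited haplotype) are replaced by their group label so that
#' prediction and segregation analysis operate on inherited units.
#'
#' @param products character vector of product names observed in one plant.
#' @param groups named list mapping a group label to its member product
#'   names; groups must be disjoint.
#' @return character vector with each complete member set replaced by its
#'   group label.
#' @export
collapse_linked <- function(products, groups) {
  if (is.null(groups) || length(groups) == 0L) return(products)
  members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(members)) stop("linked groups must be disjoint")
  out <- products
  for (lab in names(groups)) {
    hit <- out %in% groups[[lab]]
    if (!any(hit)) next
    if (sum(hit) < length(groups[[lab]]))
      warning("linked group ", sQuote(lab), " only partially observed; collapsing anyway")
    out <- c(out[!hit], lab)
  }
  unique(out)
}

#' Predict the GSI phenotype of a cross from parental S-genotypes
#'
#' Under single-locus gametophytic self-incompatibility, haploid pollen is
#' rejected when its S-allele matches either allele of the maternal plant.
#' A cross between identical heterozygous genotypes is therefore predicted
#' incompatible, a cross sharing exactly one allele semi-compatible (half
#' the pollen succeeds, so fruit is expected), and a cross sharing none
#' fully compatible.  If either plant has only one recorded product the
#' missing allele could be anything, so the cross is classed `"ambiguous"`
#' rather than guessed.
#'
#' The prediction is symmetric in its arguments for full (two-unit)
#' genotypes: reciprocal crosses receive the same class.
#'
#' @param maternal,paternal genotypes: character vectors of 1-2 haplotype
#'   labels, or "+"-joined strings.
#' @return one of `"incompatible"`, `"semi_compatible"`, `"compatible"`,
#'   `"ambiguous"`.
#' @examples
#' predict_cross_phenotype("S8a+S1c", "S8a+S1c")   # incompatible
#' predict_cross_phenotype("S8a+S1c", "S8b+S1c")   # semi_compatible
#' @export
predict_cross_phenotype <- function(maternal, paternal) {
  norm <- function(g) {
    if (length(g) == 0L) stop("invalid genotype: empty")
    if (is.character(g) && length(g) == 1L) parse_genotype(g) else unique(as.character(g))
  }
  m <- norm(maternal)
  p <- norm(paternal)
  if (length(m) < 1L || length(p) < 1L) stop("invalid genotype: empty")
  if (length(m) > 2L || length(p) > 2L) stop("invalid genotype: more than two haplotype units")
  if (length(m) == 1L || length(p) == 1L) return("ambiguous")
  shared <- sum(p %in% m)
  if (shared == 2L) "incompatible"
  else if (shared == 1L) "semi_compatible"
  else "compatible"
}

#' Tabulate fruit set by predicted cross class
#'
#' Builds the 2x2 contingency table (rows = predicted class, columns =
#' fruit / no fruit) that underlies the genotype-phenotype concordance
#' tests.
#'
#' @param records data frame of cross records with columns `predicted`,
#'   `n_pollinations` and `n_fruit`.
#' @param classes the two predicted classes forming the table rows
#'   (default incompatible vs semi-compatible).
#' @return 2x2 integer matrix with `dimnames` rows = classes, columns =
#'   `c("fruit", "no_fruit")`.
#' @export
tabulate_fruit_set <- function(records,
                               classes = c("incompatible", "semi_compatible")) {
  stopifnot(length(classes) == 2L)
  tab <- matrix(0L, 2L, 2L, dimnames = list(classes, c("fruit", "no_fruit")))
  if (NROW(records) == 0L) return(tab)
  stopifnot(all(c("predicted", "n_pollinations", "n_fruit") %in% names(records)))
  if (any(records$n_fruit > records$n_pollinations))
    stop("record with n_fruit > n_pollinations")
  bad <- !(records$predicted %in% classes)
  if (any(bad))
    stop("classification error: record(s) with predicted class outside ",
         paste(classes, collapse = "/"), ": ",
         paste(unique(records$predicted[bad]), collapse = ", "))
  for (cl in classes) {
    r <- records[records$predicted == cl, , drop = FALSE]
    tab[cl, "fruit"]    <- sum(r$n_fruit)
    tab[cl, "no_fruit"] <- sum(r$n_pollinations - r$n_fruit)
  }
  tab
}

#' Pearson chi-square test on a 2x2 table
#'
#' Plain Pearson statistic `sum((O - E)^2 / E)` with 1 df and no continuity
#' correction, as conventionally reported for fruit-set concordance tables.
#'
#' @param table 2x2 matrix of nonnegative counts.
#' @return list with `statistic`, `df` (= 1) and `p_value`.
#' @export
pearson_chi_square <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) == 2L, ncol(table) == 2L, all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("undefined test: zero marginal total")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = 1L, p_value = unname(ct$p.value))
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric tail probability; the two-sided p-value sums all
#' tables with probability less than or equal to that observed.
#'
#' @param table 2x2 matrix of nonnegative counts.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return the p-value.
#' @export
fisher_exact <- function(table, alternative = "two.sided") {
  table <- as.matrix(table)
  stopifnot(nrow(table) == 2L, ncol(table) == 2L, all(table >= 0), sum(table) > 0)
  stats::fisher.test(table, alternative = alternative)$p.value
}

#' Goodness-of-fit test for genotype segregation
#'
#' Chi-square goodness of fit of observed offspring genotype-class counts
#' against an expected ratio, e.g. the 1:1:1:1 expected when two
#' heterozygous parents segregate two alleles each.
#'
#' @param observed nonnegative integer counts per genotype class (>= 2
#'   classes).
#' @param expected_ratio positive weights, recycled to the normalized
#'   expected proportions; defaults to an even ratio.
#' @return list with `statistic`, `df` (= classes - 1) and `p_value`.
#' @examples
#' segregation_gof(c(10, 6, 4, 4))   # against 1:1:1:1
#' @export
segregation_gof <- function(observed, expected_ratio = rep(1, length(observed))) {
  if (length(observed) != length(expected_ratio))
    stop("observed and expected_ratio lengths differ")
  stopifnot(length(observed) >= 2L, sum(observed) > 0, all(expected_ratio > 0))
  ct <- suppressWarnings(
    stats::chisq.test(observed, p = expected_ratio / sum(expected_ratio)))
  list(statistic = unname(ct$statistic),
       df = length(observed) - 1L,
       p_value = unname(ct$p.value))
}

#' Find reciprocally incompatible pairs in a diallel crossing array
#'
#' In a single-locus GSI system at most four mating types segregate among
#' full sibs, so any diallel among five sibs must contain at least one pair
#' with matching genotypes, i.e. a pair that sets no fruit in either
#' direction.  Entries are `"fruit"`, `"no_fruit"` or `"not_done"`; the
#' diagonal is ignored.  Pairs where only one direction was attempted and
#' failed are reported separately, since they are suggestive but not
#' confirmed.
#'
#' @param outcomes square character matrix of cross outcomes, rows =
#'   maternal plant, columns = paternal plant.
#' @return list with `n_pairs`, `pairs` (2-column index matrix of
#'   reciprocally incompatible pairs) and `one_way` (same for pairs tested
#'   in one direction only, with no fruit).
#' @export
diallel_incompatible_pairs <- function(outcomes) {
  outcomes <- as.matrix(outcomes)
  if (nrow(outcomes) != ncol(outcomes)) stop("diallel matrix must be square")
  ok <- outcomes %in% c("fruit", "no_fruit", "not_done")
  if (!all(ok)) stop("entries must be fruit/no_fruit/not_done")
  k <- nrow(outcomes)
  pairs <- matrix(integer(0), 0L, 2L)
  one_way <- matrix(integer(0), 0L, 2L)
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      a <- outcomes[i, j]; b <- outcomes[j, i]
      if (a == "no_fruit" && b == "no_fruit")
        pairs <- rbind(pairs, c(i, j))
      else if ((a == "no_fruit" && b == "not_done") ||
               (b == "no_fruit" && a == "not_done"))
        one_way <- rbind(one_way, c(i, j))
    }
  }
  list(n_pairs = nrow(pairs), pairs = pairs, one_way = one_way)
}

#' Probability that a diallel uncovers no incompatible pair
#'
#' For k full sibs drawn from a cross whose offspring fall into m equally
#' likely incompatibility classes, the probability that no two sibs share a
#' class (and hence that the diallel finds no reciprocally incompatible
#' pair) is `prod((m - i) / m, i = 0..k-1)`, zero when k > m.  Under
#' one-locus GSI with heterozygous parents m = 4, so five sibs always
#' contain an incompatible pair; under a two-locus identity model m = 16
#' and five sibs miss one about half the time.
#'
#' @param k number of sibs in the diallel (>= 2).
#' @param model `"one_locus_gsi"` (4 classes), `"two_locus_identity"`
#'   (16 classes), or a single positive integer giving the class count of a
#'   custom equally-likely model.
#' @param method `"exact"` (product formula) or `"monte_carlo"`.
#' @param mc_reps Monte Carlo replicates when `method = "monte_carlo"`.
#' @return list with `prob` and, for Monte Carlo, its standard error `se`
#'   (`se = 0` for exact results).
#' @examples
#' prob_no_incompatible_pair(5, "one_locus_gsi")       # 0: pigeonhole
#' prob_no_incompatible_pair(5, "two_locus_identity")  # ~0.4999
#' @export
prob_no_incompatible_pair <- function(k, model = "one_locus_gsi",
                                      method = c("exact", "monte_carlo"),
                                      mc_reps = 10000L) {
  stopifnot(k >= 2L)
  method <- match.arg(method)
  m <- if (is.numeric(model)) {
    stopifnot(length(model) == 1L, model >= 1, model == round(model))
    as.integer(model)
  } else switch(model,
    one_locus_gsi = 4L,
    two_locus_identity = 16L,
    stop("unknown model: ", model))
  if (method == "exact") {
    p <- if (k > m) 0 else prod((m - seq_len(k) + 1) / m)
    return(list(prob = p, se = 0))
  }
  hits <- vapply(seq_len(mc_reps), function(i) {
    cls <- sample.int(m, k, replace = TRUE)
    as.numeric(!anyDuplicated(cls))
  }, numeric(1))
  p <- mean(hits)
  list(prob = p, se = sqrt(p * (1 - p) / mc_reps))
}

#' Genotype-phenotype concordance from cross records
#'
#' Combines [tabulate_fruit_set()], [pearson_chi_square()] and
#' [fisher_exact()] into one report.  Records from ambiguously genotyped
#' plants (single recorded product) are excluded by default because most
#' unexpected fruit set traces to them; set `include_ambiguous = TRUE` to
#' reproduce published totals that pooled such crosses under their assumed
#' class.
#'
#' @param records data frame of cross records (see [table1_fixture()] for
#'   the column layout); an optional logical `ambiguous` column marks
#'   records with an incompletely genotyped parent.
#' @param classes two predicted classes to contrast.
#' @param include_ambiguous keep records flagged ambiguous?
#' @return list with the 2x2 `table`, `chi_square` (list from
#'   [pearson_chi_square()]), `fisher_p`, and the record counts used and
#'   excluded.
#' @export
crossing_concordance <- function(records,
                                 classes = c("incompatible", "semi_compatible"),
                                 include_ambiguous = FALSE) {
  amb <- if ("ambiguous" %in% names(records)) records$ambiguous else
    vapply(seq_len(NROW(records)), function(i) {
      length(parse_genotype(records$maternal_genotype[i])) < 2L ||
        length(parse_genotype(records$paternal_genotype[i])) < 2L
    }, logical(1))
  keep <- records$predicted %in% classes & (include_ambiguous | !amb)
  used <- records[keep, , drop = FALSE]
  tab <- tabulate_fruit_set(used, classes)
  list(table = tab,
       chi_square = pearson_chi_square(tab),
       fisher_p = fisher_exact(tab),
       n_records = nrow(used),
       n_excluded_ambiguous = sum(records$predicted %in% classes & amb & !include_ambiguous))
}
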