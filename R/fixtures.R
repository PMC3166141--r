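#' Packaged crossing-table fixtures
#'
#' `table1_fixture()` returns the full-sib fruit-set records for the
#' *Argemone munita* crossing families (8-1, parents `S8a S8b x S1c S1d`;
#' 25-4, parents `S25a S25b x S4a S4d`).  `table2_fixture()` returns the
#' *Platystemon californicus* records for families 1-3 and 1-2, in which
#' two PCR products per parental haplotype co-segregated as linked units
#' (`S3ab` = S3a+S3b, `S2de` = S2d+S2e) and one parental allele (`S2?`)
#' was never amplified.  Rows whose parents had only a single recorded
#' product are flagged `ambiguous`; their `predicted` class is the class
#' under which the published totals pooled them.
#'
#' @return data frame with columns `family`, `maternal_id`, `paternal_id`,
#'   `maternal_genotype`, `paternal_genotype`, `n_pollinations`, `n_fruit`,
#'   `predicted`, `ambiguous`.  Genotype fields join haplotype-unit labels
#'   with "+".
#' @examples
#' tabulate_fruit_set(table1_fixture())
#' @export
table1_fixture <- function() {
  rec <- function(family, mg, pg, n, f, cls, amb = FALSE)
    data.frame(family = family,
               maternal_id = paste0(family, ":", mg),
               paternal_id = paste0(family, ":", pg),
               maternal_genotype = mg, paternal_genotype = pg,
               n_pollinations = n, n_fruit = f,
               predicted = cls, ambiguous = amb,
               stringsAsFactors = FALSE)
  rbind(
    rec("8-1",  "S8a+S1c",  "S8a+S1c",  7L,  0L, "incompatible"),
    rec("8-1",  "S8b+S1d",  "S8b+S1d",  5L,  0L, "incompatible"),
    rec("8-1",  "S8b+S1c",  "S8b+S1c",  3L,  0L, "incompatible"),
    rec("25-4", "S25a+S4a", "S25a+S4a", 32L, 0L, "incompatible"),
    rec("25-4", "S25b+S4a", "S25b+S4a", 16L, 8L, "incompatible"),
    rec("25-4", "S25a+S4d", "S25a+S4d", 11L, 0L, "incompatible"),
    rec("25-4", "S25b+S4d", "S25b+S4d", 18L, 12L, "incompatible"),
    rec("8-1",  "S8a+S1c",  "S8b+S1c",  7L,  7L, "semi_compatible"),
    rec("8-1",  "S8a+S1d",  "S8b+S1d",  7L,  7L, "semi_compatible"),
    rec("25-4", "S4a+S25a", "S4d+S25a", 20L, 20L, "semi_compatible"),
    rec("25-4", "S4a+S25a", "S4a+S25b", 12L, 12L, "semi_compatible"),
    rec("25-4", "S4a+S25b", "S4d+S25b", 18L, 18L, "semi_compatible"))
}

#' @rdname table1_fixture
#' @export
table2_fixture <- function() {
  rec <- function(family, mg, pg, n, f, cls, amb = FALSE)
    data.frame(family = family,
               maternal_id = paste0(family, ":", mg),
               paternal_id = paste0(family, ":", pg),
               maternal_genotype = mg, paternal_genotype = pg,
               n_pollinations = n, n_fruit = f,
               predicted = cls, ambiguous = amb,
               stringsAsFactors = FALSE)
  rbind(
    rec("1-3", "S1a+S3ab", "S1a+S3ab", 33L,  0L, "incompatible"),
    rec("1-3", "S1b+S3ab", "S1b+S3ab", 17L,  0L, "incompatible"),
    rec("1-3", "S1a+S3c",  "S1a+S3c",   8L,  1L, "incompatible"),
    rec("1-3", "S1b",      "S1b",      23L, 10L, "incompatible", amb = TRUE),
    rec("1-2", "S1a+S2de", "S1a+S2de", 18L,  4L, "incompatible"),
    rec("1-2", "S1b+S2de", "S1b+S2de", 13L,  1L, "incompatible"),
    rec("1-2", "S1a+S1b",  "S1a+S1b",  17L,  0L, "incompatible"),
    rec("1-3", "S1a+S3ab", "S1a+S3c",  17L, 16L, "semi_compatible"),
    rec("1-3", "S1b+S3ab", "S1b+S3c",  20L, 18L, "semi_compatible"),
    rec("1-3", "S1a+S3ab", "S1b+S3ab",  7L,  7L, "semi_compatible"),
    rec("1-2", "S1b+S2de", "S1b+S2?",   5L,  5L, "semi_compatible"),
    rec("1-2", "S1a+S2de", "S1b+S2de", 11L, 10L, "semi_compatible"))
}

#' @rdname table1_fixture
#' @export
fixture_linked_groups <- function() {
  list(S3ab = c("S3a", "S3b"), S2de = c("S2d", "S2e"))
}

#' Simulate a full-sib family segregating at a heterozygous GSI locus
#'
#' Each offspring receives one haplotype unit from each parent, uniformly
#' and independently, so the four offspring genotypes are expected in a
#' 1:1:1:1 ratio.  Linked co-segregating products are represented by a
#' single unit label throughout and therefore transmit as one unit.
#'
#' @param maternal,paternal parental genotypes: two haplotype-unit labels
#'   each (character vector or "+"-joined string).
#' @param n_offspring number of offspring to draw.
#' @param seed optional RNG seed.
#' @return character vector of offspring genotype strings
#'   (`maternal_unit+paternal_unit`).
#' @examples
#' generate_family("S8a+S8b", "S1c+S1d", 8, seed = 1)
#' @export
generate_family <- function(maternal, paternal, n_offspring, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- if (length(maternal) == 1L) parse_genotype(maternal) else unique(maternal)
  p <- if (length(paternal) == 1L) parse_genotype(paternal) else unique(paternal)
  if (length(m) < 2L || length(p) < 2L)
    stop("family simulation needs heterozygous parents (two units each)")
  if (n_offspring == 0L) return(character(0))
  mi <- sample.int(2L, n_offspring, replace = TRUE)
  pi_ <- sample.int(2L, n_offspring, replace = TRUE)
  paste(m[mi], p[pi_], sep = "+")
}

#' Simulate fruit-set records for designed crosses among offspring
#'
#' Draws fruit counts binomially with a class-dependent success
#' probability: `p_fruit_semi` for predicted semi-compatible crosses,
#' `p_fruit_compat` for compatible ones, and for predicted-incompatible
#' crosses the `baseline_incompatible` rate unless the shared genotype
#' carries a "weak" allele listed in `leak`, in which case that allele's
#' leak rate applies (the maximum when several are present).  This is how
#' partially functional S-alleles enter the data model: prediction itself
#' stays purely genotypic.
#'
#' @param offspring character vector of offspring genotype strings.
#' @param model list with elements `p_fruit_semi`, `p_fruit_compat`,
#'   `baseline_incompatible` (probabilities) and `leak` (named numeric,
#'   possibly empty).
#' @param design data frame with columns `maternal`, `paternal` (indices
#'   into `offspring`) and `n_pollinations`.
#' @param seed optional RNG seed.
#' @return cross-record data frame as in [table1_fixture()].
#' @export
simulate_cross_records <- function(offspring, model, design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("maternal", "paternal", "n_pollinations") %in% names(design)))
  if (any(design$maternal < 1 | design$maternal > length(offspring)) ||
      any(design$paternal < 1 | design$paternal > length(offspring)))
    stop("design references offspring outside the family")
  leak <- model$leak
  out <- lapply(seq_len(nrow(design)), function(i) {
    mg <- offspring[design$maternal[i]]
    pg <- offspring[design$paternal[i]]
    cls <- predict_cross_phenotype(mg, pg)
    p <- switch(cls,
      semi_compatible = model$p_fruit_semi,
      compatible = model$p_fruit_compat,
      incompatible = {
        carried <- intersect(parse_genotype(mg), names(leak))
        if (length(carried)) max(model$baseline_incompatible, unlist(leak[carried]))
        else model$baseline_incompatible
      },
      ambiguous = NA_real_)
    n <- design$n_pollinations[i]
    nf <- if (is.na(p)) NA_integer_ else stats::rbinom(1L, n, p)
    data.frame(family = "sim",
               maternal_id = paste0("o", design$maternal[i]),
               paternal_id = paste0("o", design$paternal[i]),
               maternal_genotype = mg, paternal_genotype = pg,
               n_pollinations = n, n_fruit = nf,
               predicted = cls,
               ambiguous = cls == "ambiguous",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Alignment with a planted high-diversity region
#'
#' Generates an n x L nucleotide alignment whose per-column expected
#' pairwise diversity is `pi_in` inside `hot_region` and `pi_out`
#' elsewhere.  Each column draws its alternate-allele count from
#' Binomial(n, q) with `2 q (1 - q)` equal to the target, which makes the
#' expected column diversity exact; the realized global value fluctuates
#' around the target (within ~10% for L >= 300, n >= 10).  Used to
#' exercise sliding-window analyses with a known answer.
#'
#' @param n sequences; `L` sites; `hot_region` integer pair (1-based,
#'   inclusive) inside `[1, L]`.
#' @param pi_in,pi_out target per-site diversity inside/outside the
#'   region; both must lie in `[0, 0.5]` (0.5 is the two-allele maximum).
#' @param L alignment length.
#' @param seed optional RNG seed.
#' @return character matrix of A/C/G/T with rownames `seq1..seqn`.
#' @export
planted_diversity_alignment <- function(n, L, hot_region, pi_in, pi_out,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(hot_region) == 2L, hot_region[1] >= 1, hot_region[2] <= L,
            hot_region[1] <= hot_region[2])
  if (pi_in > 0.5 || pi_out > 0.5 || pi_in < 0 || pi_out < 0 || pi_out > pi_in)
    stop("impossible diversity target (need 0 <= pi_out <= pi_in <= 0.5)")
  bases <- c("A", "C", "G", "T")
  aln <- matrix("A", n, L, dimnames = list(paste0("seq", seq_len(n)), NULL))
  qs <- ifelse(seq_len(L) >= hot_region[1] & seq_len(L) <= hot_region[2],
               (1 - sqrt(1 - 2 * pi_in)) / 2,
               (1 - sqrt(1 - 2 * pi_out)) / 2)
  for (j in seq_len(L)) {
    ref <- sample(bases, 1L)
    aln[, j] <- ref
    k <- stats::rbinom(1L, n, qs[j])
    if (k > 0L) {
      alt <- sample(setdiff(bases, ref), 1L)
      aln[sample.int(n, k), j] <- alt
    }
  }
  aln
}
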