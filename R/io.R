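#' Read and write FASTA alignments
#'
#' Thin wrappers around ape's FASTA support that preserve sequence order
#' and description lines and, when an alignment is required, validate
#' equal lengths.  Simulated samples written with
#' `write_fasta_alignment()` carry their source class (`S` for the
#' balanced S-allele class, `P` for the pseudogene) as the last
#' whitespace-separated token of the description line;
#' `read_fasta_alignment()` recovers it into a `source_labels` attribute
#' when every description ends in `S` or `P`.
#'
#' @param path file path.
#' @param alignment require equal sequence lengths?
#' @return `read_fasta_alignment()`: upper-case character matrix with
#'   rownames from the description lines (and possibly a `source_labels`
#'   attribute); `write_fasta_alignment()`: the path, invisibly.
#' @export
read_fasta_alignment <- function(path, alignment = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("empty FASTA file: ", path)
  lens <- lengths(dna)
  if (alignment && length(unique(lens)) != 1L)
    stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
  mat <- toupper(do.call(rbind, as.character(dna)))
  rownames(mat) <- names(dna)
  toks <- vapply(strsplit(names(dna), "\\s+"), function(t) t[length(t)], character(1))
  if (all(toks %in% c("S", "P"))) attr(mat, "source_labels") <- toks
  mat
}

#' @param x a `sequence_sample` or character matrix of aligned sequences.
#' @rdname read_fasta_alignment
#' @export
write_fasta_alignment <- function(x, path) {
  if (inherits(x, "sequence_sample")) {
    mat <- x$alignment
    hdr <- paste(rownames(mat), x$source_labels)
  } else {
    mat <- as_alignment_matrix(x)
    hdr <- rownames(mat)
    if (is.null(hdr)) hdr <- paste0("seq", seq_len(nrow(mat)))
  }
  lines <- character(2L * nrow(mat))
  lines[c(TRUE, FALSE)] <- paste0(">", hdr)
  lines[c(FALSE, TRUE)] <- apply(mat, 1L, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Write and read ms-dialect haplotype blocks
#'
#' Emits the classic text dialect of coalescent simulators: a `//` line,
#' `segsites: k`, a `positions:` line of site-midpoint fractions of the
#' alignment length (6 decimals), and one 0/1 row per sequence.  The
#' reader inverts the writer; it needs the alignment length `L` to map
#' fractional positions back to 1-based site indices.
#'
#' @param x a `site_matrix` or anything [segregating_sites()] accepts.
#' @param path file path.
#' @return `write_ms()`: the path, invisibly; `read_ms()`: a
#'   `site_matrix`.
#' @export
write_ms <- function(x, path) {
  sites <- if (inherits(x, "site_matrix")) x else segregating_sites(x)
  k <- ncol(sites$matrix)
  lines <- c("//", paste0("segsites: ", k))
  if (k > 0L) {
    pos <- sprintf("%.6f", (sites$positions - 0.5) / sites$L)
    lines <- c(lines, paste("positions:", paste(pos, collapse = " ")),
               apply(sites$matrix, 1L, paste, collapse = ""))
  } else {
    lines <- c(lines, "positions:")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @param L alignment length used when the block was written.
#' @rdname write_ms
#' @export
read_ms <- function(path, L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  iseg <- grep("^segsites:", lines)[1]
  if (is.na(iseg)) stop("not an ms-dialect file: no segsites line")
  k <- as.integer(sub("^segsites:\\s*", "", lines[iseg]))
  ipos <- grep("^positions:", lines)[1]
  if (k == 0L) {
    return(structure(list(matrix = matrix(integer(0), 0L, 0L),
                          positions = integer(0), L = as.integer(L),
                          n_dropped_gap = 0L, n_dropped_multi = 0L),
                     class = "site_matrix"))
  }
  fracs <- as.numeric(strsplit(sub("^positions:\\s*", "", lines[ipos]), "\\s+")[[1]])
  if (length(fracs) != k) stop("positions line does not match segsites")
  rows <- lines[(ipos + 1L):length(lines)]
  rows <- rows[nzchar(rows)]
  mat <- do.call(rbind, lapply(strsplit(rows, ""), as.integer))
  if (ncol(mat) != k) stop("haplotype rows do not match segsites")
  structure(list(matrix = mat,
                 positions = as.integer(round(fracs * L + 0.5)),
                 L = as.integer(L),
                 n_dropped_gap = 0L, n_dropped_multi = 0L),
            class = "site_matrix")
}

#' Read and write cross-record tables
#'
#' Cross records travel as CSV with the columns `family`, `maternal_id`,
#' `paternal_id`, `maternal_genotype`, `paternal_genotype`,
#' `n_pollinations`, `n_fruit` (plus optional `predicted` and
#' `ambiguous`); genotype fields join haplotype-unit labels with "+".
#' Linked co-segregating products are declared in a YAML or JSON sidecar
#' mapping group label to member product names (see
#' [read_linked_groups()]); genotypes in the CSV are expected to use the
#' group labels already.  Missing `predicted`/`ambiguous` columns are
#' reconstructed with [predict_cross_phenotype()].
#'
#' @param path CSV file path.
#' @param records a cross-record data frame.
#' @return `read_cross_records()`: the validated data frame;
#'   `write_cross_records()`: the path, invisibly.
#' @export
read_cross_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("family", "maternal_id", "paternal_id", "maternal_genotype",
            "paternal_genotype", "n_pollinations", "n_fruit")
  miss <- setdiff(need, names(rec))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(rec$n_fruit > rec$n_pollinations))
    stop("record with n_fruit > n_pollinations")
  if (any(rec$n_fruit < 0 | rec$n_pollinations < 0))
    stop("negative count in cross records")
  if (!"predicted" %in% names(rec))
    rec$predicted <- vapply(seq_len(nrow(rec)), function(i)
      predict_cross_phenotype(rec$maternal_genotype[i], rec$paternal_genotype[i]),
      character(1))
  if (!"ambiguous" %in% names(rec))
    rec$ambiguous <- vapply(seq_len(nrow(rec)), function(i)
      length(parse_genotype(rec$maternal_genotype[i])) < 2L ||
        length(parse_genotype(rec$paternal_genotype[i])) < 2L, logical(1))
  rec
}

#' @rdname read_cross_records
#' @export
write_cross_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a linked-group sidecar
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file mapping group label to
#'   member product names.
#' @return named list of character vectors.
#' @export
read_linked_groups <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  groups <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  lapply(groups, as.character)
}

#' Write a detection or concordance report as JSON
#'
#' @param result an `ld_test`, a [crossing_concordance()] result, or any
#'   list of scalars/vectors.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_report_json <- function(result, path) {
  out <- unclass(result)
  if (!is.null(out$table)) out$table <- as.data.frame(out$table)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
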