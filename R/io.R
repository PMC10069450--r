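## Readers and writers for the package's plain-text formats.
## All genomic coordinates are 0-based half-open, noted in file headers.

READS_COLS <- c("chrom", "start", "end", "sequence", "count", "strand", "origin")
CALLS_COLS <- c("chrom", "pos", "strand", "context", "meth", "total")

#' Write and read aligned small RNA reads as TSV
#'
#' Seven-column TSV (`chrom`, `start`, `end`, `sequence`, `count`,
#' `strand`, `origin`); `origin` is optional on input. A `#`-prefixed
#' header documents the coordinate convention. Round-trips losslessly.
#'
#' @param reads Read tibble.
#' @param path File path.
#' @return `write_reads_tsv()` returns `path` invisibly;
#'   `read_reads_tsv()` returns a read tibble.
#' @export
write_reads_tsv <- function(reads, path) {
  stopifnot(all(setdiff(READS_COLS, "origin") %in% names(reads)))
  if (!"origin" %in% names(reads)) reads$origin <- NA_character_
  writeLines(
    "# small RNA reads: chrom, start, end (0-based half-open), sequence (RNA 5'->3'), count, strand, origin",
    path)
  readr::write_tsv(reads[, READS_COLS], path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_reads_tsv
#' @export
read_reads_tsv <- function(path) {
  out <- readr::read_tsv(
    path, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_integer(),
      end = readr::col_integer(), sequence = readr::col_character(),
      count = readr::col_integer(), strand = readr::col_character(),
      origin = readr::col_character()))
  validate_reads(out, path)
  out
}

validate_reads <- function(reads, where = "reads") {
  missing <- setdiff(setdiff(READS_COLS, "origin"), names(reads))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing columns %s", where, paste(missing, collapse = ", ")))
  }
  bad <- which(!(reads$strand %in% c("+", "-")))
  if (length(bad) > 0) {
    abort(sprintf("%s: malformed strand %s at record %d", where,
                  reads$strand[bad[1]], bad[1]))
  }
  bad <- which(reads$end <= reads$start)
  if (length(bad) > 0) {
    abort(sprintf("%s: end <= start at record %d", where, bad[1]))
  }
  has_seq <- !is.na(reads$sequence)
  bad <- which(has_seq & !grepl("^[ACGU]+$", reads$sequence))
  if (length(bad) > 0) {
    abort(sprintf("%s: non-RNA character in sequence at record %d", where, bad[1]))
  }
  bad <- which(has_seq & reads$end - reads$start != nchar(reads$sequence))
  if (length(bad) > 0) {
    abort(sprintf("%s: end - start != sequence length at record %d", where, bad[1]))
  }
  invisible(reads)
}

#' Write and read per-cytosine methylation calls as TSV
#'
#' Six-column TSV (`chrom`, `pos` 0-based, `strand`, `context`, `meth`,
#' `total`), with optional leading `genotype`/`replicate` columns when
#' present.
#'
#' @param calls Methylation call tibble.
#' @param path File path.
#' @return `write_methylation_tsv()` returns `path` invisibly;
#'   `read_methylation_tsv()` returns a call tibble.
#' @export
write_methylation_tsv <- function(calls, path) {
  stopifnot(all(CALLS_COLS %in% names(calls)))
  extra <- intersect(c("genotype", "replicate"), names(calls))
  writeLines(
    "# methylation calls: pos is 0-based; context CG/CHG/CHH; meth <= total",
    path)
  readr::write_tsv(calls[, c(extra, CALLS_COLS)], path,
                   append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_methylation_tsv
#' @export
read_methylation_tsv <- function(path) {
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  missing <- setdiff(CALLS_COLS, names(out))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing columns %s", path, paste(missing, collapse = ", ")))
  }
  if (any(out$meth > out$total)) {
    abort(sprintf("%s: meth > total at record %d", path,
                  which(out$meth > out$total)[1]))
  }
  if (!all(out$context %in% c("CG", "CHG", "CHH"))) {
    abort(sprintf("%s: unknown context value", path))
  }
  as_tibble(out)
}

#' Write and read locus intervals as BED
#'
#' BED3 plus an optional fourth column holding the expression weight
#' (written as the BED name field would be; read back as
#' `expression_weight`).
#'
#' @param loci Locus tibble (`chrom`, `start`, `end`, optionally
#'   `expression_weight`).
#' @param path File path.
#' @return `write_loci_bed()` returns `path` invisibly; `read_loci_bed()`
#'   returns a locus tibble with a generated `locus_id`.
#' @export
write_loci_bed <- function(loci, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(loci)))
  out <- loci[, c("chrom", "start", "end")]
  out$expression_weight <- if ("expression_weight" %in% names(loci)) {
    loci$expression_weight
  } else 1
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_loci_bed
#' @export
read_loci_bed <- function(path) {
  out <- readr::read_tsv(
    path, col_names = c("chrom", "start", "end", "expression_weight"),
    comment = "#", show_col_types = FALSE,
    col_types = "ciid")
  if (any(out$end <= out$start)) {
    abort(sprintf("%s: end <= start at record %d", path,
                  which(out$end <= out$start)[1]))
  }
  out %>%
    mutate(locus_id = sprintf("L%04d", row_number())) %>%
    select("locus_id", "chrom", "start", "end", "expression_weight")
}

#' Write and read a genome as FASTA
#'
#' Thin wrappers over [Biostrings::writeXStringSet()] /
#' [Biostrings::readDNAStringSet()].
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param path File path.
#' @return `write_genome_fasta()` returns `path` invisibly;
#'   `read_genome_fasta()` returns a `DNAStringSet` with bare names.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  out <- Biostrings::readDNAStringSet(path)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}
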