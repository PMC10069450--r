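## Pol V-like target transcription and AGO4 slicing of long RNAs.

#' Transcribe target RNAs and slice them with a guide pool
#'
#' Each locus yields one long noncoding transcript on the strand opposite
#' the guides (the genomic - strand, as Pol V scaffold transcripts oppose
#' the Pol IV-derived guides in this model). Every 24-nt guide in the pool
#' with a perfectly complementary site inside the transcript programs one
#' slicing event via [slice_target()] on the intact transcript (fragments
#' are not re-sliced); both cleavage fragments are retained and those of at
#' least `min_len` nt are emitted. The 3' fragment's position 10 pairs the
#' guide's 5' nucleotide, so a guide pool with a 5'-A bias leaves a uridine
#' signature at position 10 of the 3' fragments.
#'
#' With `slicing = FALSE` (a slicing-defective control) the same number of
#' cuts is placed uniformly at random within each transcript instead, so
#' fragment abundance is comparable but carries no slicing geometry.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param loci Locus tibble; loci must be longer than 100 bp (Pol V-like
#'   transcripts exceed 100 nt) -- shorter loci raise an error.
#' @param guides Read tibble; only + strand 24-mers are used as guides,
#'   weighted by their `count`.
#' @param min_len Minimum emitted fragment length (nt); default 30, the
#'   size cutoff used when profiling long AGO4-associated RNAs.
#' @param slicing If `FALSE`, cut uniformly at random (no guide geometry).
#' @param seed Integer seed (only consumed when `slicing = FALSE`).
#' @return Read tibble with the usual columns plus `side` (`"5p"`/`"3p"`
#'   for guided cuts, `NA` for random cuts); `origin` is `"target_frag"`.
#' @export
transcribe_and_slice_targets <- function(genome, loci, guides, min_len = 30,
                                         slicing = TRUE, seed = NULL) {
  chars <- genome_chars(genome)
  if (any(loci$end - loci$start <= 100)) {
    abort("target loci must be longer than 100 bp")
  }
  guides <- guides %>%
    filter(.data$strand == "+", nchar(.data$sequence) == 24L)
  gen <- function() {
    per_locus <- lapply(seq_len(nrow(loci)), function(i) {
      locus <- loci[i, ]
      a <- locus$start; b <- locus$end
      transcript <- rna_from_genome(chars[[locus$chrom]], a, b, "-")
      g <- guides %>%
        filter(.data$chrom == locus$chrom, .data$start >= a, .data$end <= b)
      if (nrow(g) == 0) return(NULL)
      rows <- lapply(seq_len(nrow(g)), function(j) {
        gs <- g$start[j]
        offset <- b - gs
        site <- substr(transcript, offset - 23L, offset)
        if (site != rna_revcomp(g$sequence[j])) return(NULL)
        if (slicing) {
          res <- slice_target(align_guide_target(g$sequence[j], transcript, offset))
          if (!res$sliced) return(NULL)
          cut <- res$cut_after_position      # target coordinate b - cut genomic
          frag5 <- res$frag5; frag3 <- res$frag3
          sides <- c("5p", "3p")
        } else {
          cut <- sample_from(seq(1L, nchar(transcript) - 1L))
          frag5 <- substr(transcript, 1L, cut)
          frag3 <- substr(transcript, cut + 1L, nchar(transcript))
          sides <- c(NA_character_, NA_character_)
        }
        gcut <- b - cut  # genomic coordinate of the scissile bond
        out <- list()
        if (nchar(frag5) >= min_len) {
          out <- c(out, list(tibble(
            chrom = locus$chrom, start = as.integer(gcut), end = as.integer(b),
            sequence = frag5, count = g$count[j], strand = "-",
            origin = "target_frag", side = sides[1])))
        }
        if (nchar(frag3) >= min_len) {
          out <- c(out, list(tibble(
            chrom = locus$chrom, start = as.integer(a), end = as.integer(gcut),
            sequence = frag3, count = g$count[j], strand = "-",
            origin = "target_frag", side = sides[2])))
        }
        if (length(out) == 0) NULL else bind_rows(out)
      })
      bind_rows(rows)
    })
    out <- bind_rows(per_locus)
    if (nrow(out) == 0) {
      return(mutate(empty_reads(), side = character()))
    }
    out
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
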