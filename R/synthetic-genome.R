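## Synthetic genomes and locus tables.

#' Simulate a random genome
#'
#' Generates chromosomes as i.i.d. DNA with a given GC content. The default
#' 36% GC matches a gene-poor plant genome.
#'
#' @param lengths Integer vector of chromosome lengths (bp); names become
#'   chromosome names (default `chr1`, `chr2`, ...).
#' @param gc GC fraction in `[0, 1]`.
#' @param seed Integer seed; the output is byte-identical for a fixed seed.
#' @return A [Biostrings::DNAStringSet] with one entry per chromosome.
#' @examples
#' gen <- simulate_genome(10000, seed = 7)
#' @export
simulate_genome <- function(lengths = 1e5, gc = 0.36, seed = NULL) {
  stopifnot(all(lengths >= 1), gc >= 0, gc <= 1)
  lengths <- as.integer(lengths)
  nm <- names(lengths)
  if (is.null(nm)) nm <- paste0("chr", seq_along(lengths))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  gen <- function() {
    seqs <- vapply(lengths, function(L) {
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
    }, character(1))
    Biostrings::DNAStringSet(setNames(seqs, nm))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate siRNA-producing loci
#'
#' Places exactly `n` non-overlapping intervals on a genome by dividing each
#' chromosome into equal slots and drawing one locus uniformly within each
#' slot. Each locus carries a nonnegative expression weight (gamma with mean
#' 1) controlling how many siRNA duplexes, and how much RdDM methylation
#' gain, it receives downstream.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param n Number of loci.
#' @param width Integer range of locus widths (bp).
#' @param weight_shape Shape of the mean-1 gamma distribution of expression
#'   weights; larger values give more even loci.
#' @param margin Minimum distance kept between a locus and a contig end.
#' @param seed Integer seed.
#' @return Tibble with columns `locus_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and `expression_weight`, sorted by position.
#' @export
simulate_loci <- function(genome, n = 200, width = c(260, 400),
                          weight_shape = 2, margin = 50, seed = NULL) {
  stopifnot(n >= 1, length(width) == 2, width[1] >= 30, width[2] >= width[1])
  lens <- setNames(Biostrings::width(genome), names(genome))
  ## loci per chromosome, proportional to length
  n_per <- floor(n * lens / sum(lens))
  rem <- n - sum(n_per)
  if (rem > 0) {
    idx <- order(lens, decreasing = TRUE)[seq_len(rem)]
    n_per[idx] <- n_per[idx] + 1L
  }
  gen <- function() {
    pieces <- lapply(names(lens)[n_per > 0], function(ch) {
      k <- n_per[[ch]]
      usable <- lens[[ch]] - 2 * margin
      slot <- usable / k
      if (slot < width[2] + 1) {
        abort(sprintf(
          "chromosome %s too short for %d loci of width <= %d", ch, k, width[2]))
      }
      w <- sample_from(seq(width[1], width[2]), k, replace = TRUE)
      slot_start <- margin + floor(slot * (seq_len(k) - 1))
      start <- slot_start + floor(runif(k, 0, slot - w))
      tibble(chrom = ch, start = as.integer(start),
             end = as.integer(start + w))
    })
    bind_rows(pieces) %>%
      mutate(expression_weight = stats::rgamma(n, shape = weight_shape,
                                               rate = weight_shape)) %>%
      arrange(.data$chrom, .data$start) %>%
      mutate(locus_id = sprintf("L%04d", row_number())) %>%
      select("locus_id", "chrom", "start", "end", "expression_weight")
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
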