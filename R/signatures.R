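## Slicing fingerprints: shared 5' ends of 12- and 23-nt RNAs, 12-mer 3'
## termini at the predicted cut, and the position-10 U signature of long
## sliced target fragments.

#' Co-5' analysis of 12-nt RNAs against 23-nt passengers and 24-nt guides
#'
#' Sliced passenger 5' fragments keep their parent's 5' end, so 12-mers in
#' a slicing-competent library should share 5' genomic coordinates with
#' 23-nt passenger strands (observable in a slicing-defective library),
#' and their 3' termini should sit at the bond opposite positions 10/11 of
#' an antisense 24-mer guide. Matching is exact by default; `slop` allows
#' +/- n nt for noisy alignments.
#'
#' @param reads12 Read tibble of 12-mers (other lengths are dropped).
#' @param reads23 Read tibble providing the 23-mer 5' ends (e.g. the
#'   slicing-defective library, or generator truth).
#' @param reads24 Read tibble providing antisense 24-mer guides.
#' @param slop Coordinate tolerance in nt; default 0.
#' @param passenger_lengths Lengths of the passenger reads whose 5' ends
#'   are matched; default 23 (set `c(23L, 24L)` to include intact 24-nt
#'   passengers of 24/24 duplexes, e.g. for a generator ground-truth
#'   check).
#' @return One-row tibble of class `co5_report`: `n_12mers`,
#'   `n_sharing_5p`, `fraction`, `n_3p_at_predicted_cut`,
#'   `fraction_at_cut` (count-weighted).
#' @export
co5prime <- function(reads12, reads23, reads24, slop = 0L,
                     passenger_lengths = 23L) {
  r12 <- filter(reads12, .data$end - .data$start == 12L)
  empty <- tibble(n_12mers = 0, n_sharing_5p = 0, fraction = NA_real_,
                  n_3p_at_predicted_cut = 0, fraction_at_cut = NA_real_)
  if (nrow(r12) == 0) {
    return(structure(empty, class = c("co5_report", class(empty))))
  }
  r23 <- filter(reads23, (.data$end - .data$start) %in% passenger_lengths)
  r24 <- filter(reads24, .data$end - .data$start == 24L)
  p5_23 <- r23 %>%
    mutate(p5 = five_prime_coord(.data$strand, .data$start, .data$end)) %>%
    distinct(.data$chrom, .data$strand, .data$p5)
  r12 <- mutate(r12,
                p5 = five_prime_coord(.data$strand, .data$start, .data$end),
                p3 = if_else(.data$strand == "+", .data$end - 1L, .data$start))
  match_with_slop <- function(x, keys, cols) {
    hit <- rep(FALSE, nrow(x))
    for (d in seq(-slop, slop)) {
      shifted <- mutate(x, !!cols[3] := .data[[cols[3]]] + as.integer(d))
      m <- !is.na(match(
        paste(shifted$chrom, shifted[[cols[2]]], shifted[[cols[3]]]),
        paste(keys$chrom, keys[[cols[2]]], keys[[cols[3]]])))
      hit <- hit | m
    }
    hit
  }
  shares <- match_with_slop(r12, p5_23, c("chrom", "strand", "p5"))
  ## predicted cut: for a - strand 12-mer (3' terminus at start), the
  ## antisense + strand 24-mer has its position-10/11 bond at start
  ## (guide positions 10, 11 at 0-based g+9, g+10): g = start - 10.
  ## For a + strand 12-mer (3' terminus at end-1): - strand guide start
  ## h = end - 14 (its positions 10/11 at h+14, h+13).
  g24_plus <- r24 %>% filter(.data$strand == "+") %>%
    distinct(.data$chrom, .data$start)
  g24_minus <- r24 %>% filter(.data$strand == "-") %>%
    distinct(.data$chrom, .data$start)
  at_cut <- rep(FALSE, nrow(r12))
  for (d in seq(-slop, slop)) {
    minus12 <- r12$strand == "-"
    want_plus <- r12$start - 10L + as.integer(d)
    want_minus <- r12$end - 14L + as.integer(d)
    at_cut <- at_cut |
      (minus12 & !is.na(match(paste(r12$chrom, want_plus),
                              paste(g24_plus$chrom, g24_plus$start)))) |
      (!minus12 & !is.na(match(paste(r12$chrom, want_minus),
                               paste(g24_minus$chrom, g24_minus$start))))
  }
  n12 <- sum(r12$count)
  out <- tibble(
    n_12mers = n12,
    n_sharing_5p = sum(r12$count[shares]),
    fraction = sum(r12$count[shares]) / n12,
    n_3p_at_predicted_cut = sum(r12$count[at_cut]),
    fraction_at_cut = sum(r12$count[at_cut]) / n12)
  structure(out, class = c("co5_report", class(out)))
}

#' Position-10 uridine signature of long RNAs
#'
#' Builds the count-weighted positional base-frequency matrix (5' anchor,
#' positions 1-30) of reads of at least `min_len` nt and locates the
#' position of maximal uridine enrichment. Slicing of targets by guides
#' with a 5'-terminal adenosine leaves U at position 10 of the 3'
#' cleavage fragments, so a slicing-competent pool peaks there while a
#' slicing-defective pool shows no excess.
#'
#' @param reads Read tibble with sequences.
#' @param min_len Minimum read length (nt); default 30.
#' @return A list of class `u10_report`: `matrix` (a
#'   [positional_matrix()] over positions 1-30), `peak_position` (argmax
#'   of U frequency), `peak_excess` (U frequency at the peak minus the
#'   mean U frequency at the other positions), `n_reads` (count-weighted).
#'   Empty input gives an empty report with `NA` peak fields.
#' @export
u10_signature <- function(reads, min_len = 30L) {
  long <- filter(reads, .data$end - .data$start >= min_len,
                 !is.na(.data$sequence))
  if (nrow(long) == 0) {
    pm <- positional_matrix(long, anchor = "5prime", max_positions = 30L)
    out <- list(matrix = pm, peak_position = NA_integer_,
                peak_excess = NA_real_, n_reads = 0)
    return(structure(out, class = "u10_report"))
  }
  pm <- positional_matrix(long, anchor = "5prime", max_positions = 30L)
  u <- pm$U
  peak <- which.max(u)
  out <- list(matrix = pm,
              peak_position = as.integer(pm$position[peak]),
              peak_excess = u[peak] - mean(u[-peak]),
              n_reads = sum(long$count))
  structure(out, class = "u10_report")
}

#' @export
print.u10_report <- function(x, ...) {
  cat("<u10_report>\n")
  if (x$n_reads == 0) {
    cat("  no qualifying reads\n")
  } else {
    cat(sprintf("  %s reads >= min length; peak U at position %d (excess %.3f)\n",
                format(x$n_reads, big.mark = ","), x$peak_position,
                x$peak_excess))
  }
  invisible(x)
}
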