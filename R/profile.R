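## Population-level descriptive statistics of small RNA libraries.
## All statistics are count-weighted: a record with count = 5 contributes 5.

#' Size distribution of a small RNA library
#'
#' @param reads Read tibble.
#' @param length_range Optional integer range `c(min, max)` restricting the
#'   lengths reported.
#' @return Tibble with `length`, `count` and `fraction` (fractions sum to 1
#'   over the represented lengths); zero rows for empty input.
#' @export
size_distribution <- function(reads, length_range = NULL) {
  if (nrow(reads) == 0) {
    return(tibble(length = integer(), count = integer(), fraction = double()))
  }
  out <- reads %>%
    mutate(length = .data$end - .data$start) %>%
    group_by(.data$length) %>%
    summarise(count = sum(.data$count), .groups = "drop")
  if (!is.null(length_range)) {
    out <- filter(out, .data$length >= length_range[1],
                  .data$length <= length_range[2])
  }
  mutate(out, fraction = .data$count / sum(.data$count)) %>%
    arrange(.data$length)
}

#' Positional nucleotide frequency matrix
#'
#' Count-weighted per-position base frequencies, anchored at the 5' or 3'
#' end (the numeric content behind a sequence logo). With a 3' anchor,
#' position 1 is the 3'-terminal nucleotide, counting inward.
#'
#' @param reads Read tibble with sequences.
#' @param size_filter Optional integer vector of read lengths to keep
#'   (recommended whenever reads of mixed length must align positionally).
#' @param anchor `"5prime"` or `"3prime"`.
#' @param max_positions Optional cap on the number of positions reported.
#' @return A tibble of class `positional_matrix` with columns `position`,
#'   `A`, `C`, `G`, `U`; each covered row sums to 1.
#' @export
positional_matrix <- function(reads, size_filter = NULL,
                              anchor = c("5prime", "3prime"),
                              max_positions = NULL) {
  anchor <- arg_match(anchor)
  if (!is.null(size_filter)) {
    reads <- filter(reads, (.data$end - .data$start) %in% size_filter)
  }
  reads <- filter(reads, !is.na(.data$sequence))
  empty <- tibble(position = integer(), A = double(), C = double(),
                  G = double(), U = double())
  if (nrow(reads) == 0) {
    return(structure(empty, anchor = anchor,
                     class = c("positional_matrix", class(empty))))
  }
  chars <- strsplit(reads$sequence, "")
  lens <- lengths(chars)
  long <- tibble(
    base = unlist(chars),
    j = unlist(lapply(lens, seq_len)),
    len = rep(lens, lens),
    weight = rep(reads$count, lens)) %>%
    mutate(position = if (anchor == "5prime") .data$j else .data$len - .data$j + 1L)
  if (!is.null(max_positions)) long <- filter(long, .data$position <= max_positions)
  out <- long %>%
    group_by(.data$position, .data$base) %>%
    summarise(w = sum(.data$weight), .groups = "drop_last") %>%
    mutate(freq = .data$w / sum(.data$w)) %>%
    ungroup() %>%
    select("position", "base", "freq") %>%
    tidyr::pivot_wider(names_from = "base", values_from = "freq",
                       values_fill = 0)
  for (b in RNA_BASES) if (!b %in% names(out)) out[[b]] <- 0
  out <- out[, c("position", RNA_BASES)] %>% arrange(.data$position)
  structure(out, anchor = anchor,
            class = c("positional_matrix", class(out)))
}

## 5' genomic coordinate of a read (0-based): start on +, end - 1 on -.
five_prime_coord <- function(strand, start, end) {
  if_else(strand == "+", start, end - 1L)
}

#' Classify 23-nt reads as passenger strands or truncated guides
#'
#' A 23-mer is *passenger-like* when it carries the penultimate 3' uridine
#' (position 22, the templated complement of the partner guide's 5'
#' adenosine) **and** overlaps an antisense 24-mer in the canonical DCL3
#' register (its 3' terminus one nucleotide past the 24-mer's 5'
#' terminus). It is *truncated-guide-like* when its sequence equals a
#' library 24-mer minus its 3'-terminal base, at the same 5' coordinate
#' and strand. Exact-sequence evidence beats positional evidence, so a
#' read matching both rules counts as truncated-guide-like.
#'
#' @param reads Read tibble; 23- and 24-mers are taken from it unless a
#'   separate `reads24` pool is supplied.
#' @param reads24 Optional read tibble providing the 24-mer set.
#' @return One-row tibble with count-weighted totals: `n_23mers`,
#'   `passenger_like`, `truncated_guide_like`, `unclassified`.
#' @export
classify_23mers <- function(reads, reads24 = NULL) {
  if (is.null(reads24)) reads24 <- reads
  r23 <- filter(reads, .data$end - .data$start == 23L)
  r24 <- filter(reads24, .data$end - .data$start == 24L) %>%
    mutate(p5 = five_prime_coord(.data$strand, .data$start, .data$end))
  if (nrow(r23) == 0) {
    return(tibble(n_23mers = 0L, passenger_like = 0L,
                  truncated_guide_like = 0L, unclassified = 0L))
  }
  r23 <- r23 %>%
    mutate(p5 = five_prime_coord(.data$strand, .data$start, .data$end),
           prefix23 = substr(.data$sequence, 1L, 23L),
           penult_u = substr(.data$sequence, 22L, 22L) == "U")
  ## truncated guide: same 5' coordinate/strand 24-mer whose first 23 nt match
  trunc_keys <- r24 %>%
    mutate(prefix23 = substr(.data$sequence, 1L, 23L)) %>%
    distinct(.data$chrom, .data$strand, .data$p5, .data$prefix23)
  r23 <- r23 %>%
    left_join(mutate(trunc_keys, is_trunc = TRUE),
              by = c("chrom", "strand", "p5", "prefix23")) %>%
    mutate(is_trunc = !is.na(.data$is_trunc))
  ## passenger: antisense 24-mer in canonical register.
  ## For a - strand 23-mer at [b, b+23): + strand 24-mer with start b + 1.
  ## For a + strand 23-mer at [c, c+23): - strand 24-mer with start c - 2.
  anti24_plus <- r24 %>% filter(.data$strand == "+") %>%
    distinct(.data$chrom, start24 = .data$start) %>% mutate(hit = TRUE)
  anti24_minus <- r24 %>% filter(.data$strand == "-") %>%
    distinct(.data$chrom, start24 = .data$start) %>% mutate(hit = TRUE)
  r23 <- r23 %>%
    mutate(want24 = if_else(.data$strand == "-", .data$start + 1L,
                            .data$start - 2L)) %>%
    left_join(rename(anti24_plus, hp = "hit"),
              by = c(chrom = "chrom", want24 = "start24")) %>%
    left_join(rename(anti24_minus, hm = "hit"),
              by = c(chrom = "chrom", want24 = "start24")) %>%
    mutate(
      anti = if_else(.data$strand == "-", !is.na(.data$hp), !is.na(.data$hm)),
      class = case_when(
        .data$is_trunc ~ "truncated_guide_like",
        .data$penult_u & .data$anti ~ "passenger_like",
        TRUE ~ "unclassified"))
  tibble(
    n_23mers = sum(r23$count),
    passenger_like = sum(r23$count[r23$class == "passenger_like"]),
    truncated_guide_like = sum(r23$count[r23$class == "truncated_guide_like"]),
    unclassified = sum(r23$count[r23$class == "unclassified"]))
}

#' Detect 3' uridylation of guide-length reads
#'
#' Finds reads of `base_len + 1` or `base_len + 2` nt whose first
#' `base_len` nucleotides equal a library `base_len`-mer at the same 5'
#' coordinate and strand and whose extra 3' nucleotides are all uridine.
#' The reported fraction is the count-weighted ratio of such U-tailed
#' reads to `base_len`-mers (uridylated forms are emitted in addition to
#' their source guides, so this ratio estimates the uridylation rate).
#'
#' @param reads Read tibble.
#' @param base_len Unextended guide length; default 24.
#' @return One-row tibble: `n_base`, `n_extended`, `n_u_tailed`,
#'   `fraction`.
#' @export
detect_uridylation <- function(reads, base_len = 24L) {
  reads <- mutate(reads, length = .data$end - .data$start)
  base <- filter(reads, .data$length == base_len)
  ext <- filter(reads, .data$length %in% (base_len + 1:2))
  n_base <- sum(base$count)
  if (nrow(ext) == 0 || n_base == 0) {
    return(tibble(n_base = n_base, n_extended = sum(ext$count),
                  n_u_tailed = 0L, fraction = 0))
  }
  base_keys <- base %>%
    mutate(p5 = five_prime_coord(.data$strand, .data$start, .data$end)) %>%
    distinct(.data$chrom, .data$strand, .data$p5, .data$sequence) %>%
    rename(base_seq = "sequence") %>%
    mutate(matched = TRUE)
  ext <- ext %>%
    mutate(p5 = five_prime_coord(.data$strand, .data$start, .data$end),
           base_seq = substr(.data$sequence, 1L, base_len),
           tail = substr(.data$sequence, base_len + 1L, .data$length),
           tail_u = grepl("^U+$", .data$tail)) %>%
    left_join(base_keys, by = c("chrom", "strand", "p5", "base_seq")) %>%
    mutate(u_tailed = .data$tail_u & !is.na(.data$matched))
  tibble(n_base = n_base,
         n_extended = sum(ext$count),
         n_u_tailed = sum(ext$count[ext$u_tailed]),
         fraction = sum(ext$count[ext$u_tailed]) / n_base)
}

## Assign reads to loci: a read belongs to a locus iff their overlap is at
## least `min_overlap_frac` of the read length; ties on overlap go to the
## lexicographically first locus_id. Returns `reads` plus a locus_id column
## (NA when unassigned).
assign_to_loci <- function(reads, loci, min_overlap_frac = 0.5) {
  if (nrow(reads) == 0) return(mutate(reads, locus_id = character()))
  rd <- data.table::data.table(
    chrom = reads$chrom, rstart = reads$start, rend = reads$end,
    rs = reads$start, re = reads$end, idx = seq_len(nrow(reads)))
  lc <- data.table::data.table(
    chrom = loci$chrom, start = loci$start, end = loci$end,
    ls = loci$start, le = loci$end, locus_id = loci$locus_id)
  hits <- lc[rd, on = .(chrom, start < rend, end > rstart),
             allow.cartesian = TRUE, nomatch = NULL]
  if (nrow(hits) > 0) {
    hits[, overlap := pmin(le, re) - pmax(ls, rs)]
    hits <- hits[overlap >= min_overlap_frac * (re - rs)]
    data.table::setorder(hits, idx, -overlap, locus_id)
    hits <- hits[!duplicated(idx)]
  }
  assignment <- rep(NA_character_, nrow(reads))
  if (nrow(hits) > 0) assignment[hits$idx] <- hits$locus_id
  mutate(reads, locus_id = assignment)
}

#' Per-locus small RNA abundance in RPM
#'
#' Assigns each read to the locus it overlaps by at least 50% of the read
#' length (larger overlap wins; ties go to the lexicographically first
#' locus) and reports count and RPM per locus and size class.
#' RPM = count x 10^6 / `library_total`.
#'
#' @param reads Read tibble.
#' @param loci Locus tibble (non-overlapping).
#' @param library_total Total mappable read count used for normalization;
#'   defaults to `sum(reads$count)`.
#' @param min_overlap_frac Minimum overlap as a fraction of read length.
#' @return Tibble of class `locus_abundance` with `locus_id` (including an
#'   `"unassigned"` bucket), `length`, `count`, `rpm`.
#' @export
locus_abundance <- function(reads, loci, library_total = NULL,
                            min_overlap_frac = 0.5) {
  if (is.null(library_total)) library_total <- sum(reads$count)
  out <- assign_to_loci(reads, loci, min_overlap_frac) %>%
    mutate(locus_id = if_else(is.na(.data$locus_id), "unassigned", .data$locus_id),
           length = .data$end - .data$start) %>%
    group_by(.data$locus_id, .data$length) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    mutate(rpm = .data$count * 1e6 / library_total)
  structure(out, library_total = library_total,
            class = c("locus_abundance", class(out)))
}

#' Loci dominated by a set of size classes
#'
#' Keeps the loci whose most abundant size class (by RPM) is among
#' `sizes`; ties involving a listed size count as dominated by it. The
#' `"unassigned"` bucket is never returned.
#'
#' @param abundance A [locus_abundance()] tibble.
#' @param sizes Integer vector of dominant size classes; default 23/24.
#' @return Character vector of locus ids.
#' @export
dominant_size_loci <- function(abundance, sizes = c(23L, 24L)) {
  abundance %>%
    filter(.data$locus_id != "unassigned") %>%
    group_by(.data$locus_id) %>%
    filter(.data$rpm == max(.data$rpm)) %>%
    summarise(dominated = any(.data$length %in% sizes)) %>%
    filter(.data$dominated) %>%
    pull("locus_id")
}
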