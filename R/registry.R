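## In silico duplex reconstitution: pairing-registry spectra between size
## classes on opposite genomic strands, with a randomized-start null.
##
## Sign convention: for a top read on the + strand and a bottom read on
## the - strand, the registry is r = g5(top) - g3(bottom), i.e. the
## 0-based start of the top read minus the 0-based start of the bottom
## read (the bottom read's 3' nucleotide sits at its lowest coordinate).
## Positive r means the bottom strand's 3' terminus overhangs past the
## top strand's 5' terminus: canonical DCL3 24/23 duplexes give r = +1
## (23-mer 3' end 1 nt past the 24-mer 5' end) and 24/24 duplexes r = +2.

#' Pairing registry of one antisense read pair
#'
#' @param top,bottom One-row read data frames on opposite strands of the
#'   same chromosome (`top` on `+`, `bottom` on `-`).
#' @return Integer registry, or `NA` when the reads do not overlap by at
#'   least 1 nt. Same-strand input is a usage error.
#' @examples
#' top <- tibble::tibble(chrom = "c", start = 100L, end = 124L, strand = "+")
#' bot <- tibble::tibble(chrom = "c", start = 99L, end = 122L, strand = "-")
#' registry(top, bot)  # +1, the canonical 24/23 placement
#' @export
registry <- function(top, bottom) {
  if (top$strand == bottom$strand) {
    abort("registry() requires reads on opposite strands")
  }
  if (top$strand == "-") { tmp <- top; top <- bottom; bottom <- tmp }
  if (top$chrom != bottom$chrom) return(NA_integer_)
  if (min(top$end, bottom$end) - max(top$start, bottom$start) < 1L) {
    return(NA_integer_)
  }
  as.integer(top$start - bottom$start)
}

#' Registry spectrum between two size classes
#'
#' Counts, for every overlapping antisense pair of a `sizes[1]`-nt + strand
#' read and a `sizes[2]`-nt - strand read with `|r| <= max_abs_registry`,
#' the pairing registry `r`. With `weighted = TRUE` (default) a pair
#' contributes `count_top * count_bottom`; otherwise each distinct record
#' pair contributes 1 (unique-sequence mode).
#'
#' @param reads Read tibble.
#' @param sizes Length-2 integer vector: top (+ strand) and bottom
#'   (- strand) read lengths, e.g. `c(24, 23)`.
#' @param max_abs_registry Window half-width bounding the pair search.
#' @param weighted Count-weighted (default) or unique-record pairs.
#' @return A tibble of class `registry_spectrum` with columns `registry`
#'   and `n_pairs`, plus attributes `sizes` and `n_total`.
#' @export
registry_spectrum <- function(reads, sizes = c(24L, 23L),
                              max_abs_registry = 30L, weighted = TRUE) {
  stopifnot(length(sizes) == 2)
  top <- filter(reads, .data$strand == "+",
                .data$end - .data$start == sizes[1])
  bottom <- filter(reads, .data$strand == "-",
                   .data$end - .data$start == sizes[2])
  empty <- tibble(registry = integer(), n_pairs = double())
  if (nrow(top) == 0 || nrow(bottom) == 0) {
    return(structure(empty, sizes = as.integer(sizes), n_total = 0,
                     class = c("registry_spectrum", class(empty))))
  }
  tt <- data.table::data.table(chrom = top$chrom, start = top$start,
                               ts = top$start, te = top$end,
                               tw = top$count)
  bb <- data.table::data.table(chrom = bottom$chrom,
                               lo = bottom$start - as.integer(max_abs_registry),
                               hi = bottom$start + as.integer(max_abs_registry),
                               bs = bottom$start, be = bottom$end,
                               bw = bottom$count)
  ## windowed pair search: candidate pairs have |r| <= max_abs_registry
  pairs <- bb[tt, on = .(chrom, lo <= start, hi >= start),
              allow.cartesian = TRUE, nomatch = NULL]
  spec <- empty
  n_total <- 0
  if (nrow(pairs) > 0) {
    pairs <- pairs[pmin(te, be) - pmax(ts, bs) >= 1L]
    if (nrow(pairs) > 0) {
      pairs[, registry := ts - bs]
      pairs[, w := if (weighted) as.double(tw) * bw else 1]
      agg <- pairs[, .(n_pairs = sum(w)), by = registry]
      data.table::setorder(agg, registry)
      spec <- as_tibble(agg)
      n_total <- sum(spec$n_pairs)
    }
  }
  structure(spec, sizes = as.integer(sizes), n_total = n_total,
            class = c("registry_spectrum", class(spec)))
}

#' Randomized-start null library
#'
#' Re-places every read uniformly at random within its locus, preserving
#' chromosome, locus, length, strand and count -- a simulated library with
#' the same abundance and sizes as the input, from the same loci, but
#' initiating at random positions. Sequences are set to `NA` (re-placed
#' reads are no longer genome-consistent; registry analysis is
#' coordinate-based).
#'
#' @param reads Read tibble; every read must be assignable to a locus and
#'   no read may be longer than its locus.
#' @param loci Locus tibble.
#' @param seed Integer seed.
#' @param min_overlap_frac Overlap fraction used to assign reads to loci.
#' @return Read tibble with randomized starts.
#' @export
simulate_null <- function(reads, loci, seed = NULL, min_overlap_frac = 0.5) {
  asg <- assign_to_loci(reads, loci, min_overlap_frac)
  if (any(is.na(asg$locus_id))) {
    abort(sprintf("%d read(s) not assignable to any locus",
                  sum(is.na(asg$locus_id))))
  }
  asg <- asg %>%
    left_join(select(loci, "locus_id", lstart = "start", lend = "end"),
              by = "locus_id") %>%
    mutate(length = .data$end - .data$start)
  if (any(asg$length > asg$lend - asg$lstart)) {
    abort("read longer than its locus; cannot randomize placement")
  }
  gen <- function() {
    new_start <- asg$lstart +
      floor(runif(nrow(asg)) * (asg$lend - asg$lstart - asg$length + 1L))
    asg %>%
      mutate(start = as.integer(new_start),
             end = as.integer(new_start + .data$length),
             sequence = NA_character_) %>%
      select(!!!syms(intersect(c(READS_COLS, "locus_id"), names(asg))))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Modal registry enrichment of a real spectrum over a null
#'
#' @param real,null [registry_spectrum()] objects for the experimental and
#'   randomized-start libraries.
#' @return One-row tibble: `modal_registry` (mode of the real spectrum;
#'   ties break toward the smallest `|r|`), `real_fraction`,
#'   `null_fraction` at the same registry, and `enrichment`
#'   (`real_fraction / null_fraction`; `Inf` when the null never realizes
#'   the modal registry).
#' @export
mode_enrichment <- function(real, null) {
  stopifnot(inherits(real, "registry_spectrum"),
            inherits(null, "registry_spectrum"))
  if (nrow(real) == 0) {
    return(tibble(modal_registry = NA_integer_, real_fraction = NA_real_,
                  null_fraction = NA_real_, enrichment = NA_real_))
  }
  cand <- real %>%
    filter(.data$n_pairs == max(.data$n_pairs)) %>%
    arrange(abs(.data$registry))
  mode_r <- cand$registry[1]
  real_frac <- cand$n_pairs[1] / sum(real$n_pairs)
  null_n <- null$n_pairs[match(mode_r, null$registry)]
  null_frac <- if (is.na(null_n) || sum(null$n_pairs) == 0) 0
               else null_n / sum(null$n_pairs)
  tibble(modal_registry = as.integer(mode_r),
         real_fraction = real_frac,
         null_fraction = null_frac,
         enrichment = if (null_frac > 0) real_frac / null_frac else Inf)
}
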