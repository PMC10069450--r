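## Pol IV / RDR2 / DCL3 / AGO4 biogenesis simulator.
##
## Genomic model: Pol IV transcribes the + strand of a locus, so its
## transcript equals the genomic sequence (T -> U) over [start, start+len).
## RDR2 copies it into the full complement and adds one untemplated 3'
## nucleotide, which genomically sits at start-1 and is carried by aligned
## reads as a single terminal mismatch (an aligner tolerating <= 2
## mismatches places the read anyway). DCL3 dices the precursor from its
## ends: the 24/23 duplex comes from the Pol IV 5' end (guide = Pol IV nt
## 1-24 on +; passenger = RDR2 3'-terminal 23-mer on -, registry +1), the
## 24/24 duplex from the other end (2-nt 3' overhangs, registry +2).

#' Biogenesis simulation parameters
#'
#' Bundles the tunable rates of the Pol IV/RDR2/DCL3/AGO4 generator. The
#' defaults reproduce the hallmarks of in vivo AGO4 small RNA pools:
#' Pol IV initiation biased to A and G, combined with DCL3's preference for
#' dsRNA ends with a 5' A (and against 5' G), gives an effective guide
#' 5'-A frequency near 0.8; 24/23 and 24/24 duplexes are produced in equal
#' proportion; guide 3' truncation and untemplated uridylation occur at
#' trace (5%) rates.
#'
#' @param precursor_len_range Integer range of Pol IV/RDR2 dsRNA precursor
#'   lengths (bp), default 25-40.
#' @param polIV_5p_bias,rdr2_5p_bias Named probability vectors over
#'   A, C, G, U for the 5'-terminal nucleotide of each polymerase's
#'   transcript (imposed by rejection sampling of start positions, so reads
#'   stay genome-consistent).
#' @param dcl3_5pA_weight,dcl3_5pG_weight Relative weights with which DCL3
#'   engages dsRNA ends whose 5' nucleotide is A or G (C and U have weight
#'   1).
#' @param p_24_24 Probability a dicing event yields the 24/24 duplex rather
#'   than the 24/23 duplex.
#' @param guide_trunc_prob Probability a loaded guide additionally yields a
#'   1-nt 3'-truncated 23-nt read.
#' @param guide_uridylation_prob Probability a loaded guide additionally
#'   yields a 3'-uridylated 25- or 26-nt read.
#' @param frag12_retention_prob Probability the sliced passenger's 12-nt
#'   5' fragment survives turnover and is observed in a wild-type library;
#'   the default keeps 12-mers a minor class relative to 24-nt guides, as
#'   in vivo.
#' @param keep_frag3 Retain the passenger 3' fragment (11-mer for 24/23) in
#'   wild-type libraries; off by default because in vivo pools show a 12-nt
#'   class but no 11-nt class.
#' @param max_tries Cap on rejection-sampling attempts per draw.
#' @return A list of class `biogenesis_params`.
#' @export
biogenesis_params <- function(precursor_len_range = c(25L, 40L),
                              polIV_5p_bias = c(A = 0.65, C = 0.05, G = 0.25, U = 0.05),
                              rdr2_5p_bias = c(A = 0.35, C = 0.15, G = 0.15, U = 0.35),
                              dcl3_5pA_weight = 1.5,
                              dcl3_5pG_weight = 0.5,
                              p_24_24 = 0.5,
                              guide_trunc_prob = 0.05,
                              guide_uridylation_prob = 0.05,
                              frag12_retention_prob = 0.4,
                              keep_frag3 = FALSE,
                              max_tries = 50L) {
  stopifnot(length(precursor_len_range) == 2,
            precursor_len_range[1] >= 25, precursor_len_range[2] >= precursor_len_range[1],
            p_24_24 >= 0, p_24_24 <= 1,
            guide_trunc_prob >= 0, guide_trunc_prob <= 1,
            guide_uridylation_prob >= 0, guide_uridylation_prob <= 1,
            frag12_retention_prob >= 0, frag12_retention_prob <= 1,
            dcl3_5pA_weight >= 0, dcl3_5pG_weight >= 0)
  for (v in list(polIV_5p_bias, rdr2_5p_bias)) {
    if (!setequal(names(v), RNA_BASES) || abs(sum(v) - 1) > 1e-8 || any(v < 0)) {
      abort("5' bias vectors must be probabilities named A, C, G, U summing to 1")
    }
  }
  structure(list(
    precursor_len_range = as.integer(precursor_len_range),
    polIV_5p_bias = polIV_5p_bias[RNA_BASES],
    rdr2_5p_bias = rdr2_5p_bias[RNA_BASES],
    dcl3_5pA_weight = dcl3_5pA_weight,
    dcl3_5pG_weight = dcl3_5pG_weight,
    p_24_24 = p_24_24,
    guide_trunc_prob = guide_trunc_prob,
    guide_uridylation_prob = guide_uridylation_prob,
    frag12_retention_prob = frag12_retention_prob,
    keep_frag3 = isTRUE(keep_frag3),
    max_tries = as.integer(max_tries)),
    class = "biogenesis_params")
}

## Named character vector of chromosome sequences from a DNAStringSet (or
## pass-through for an already-converted named character vector).
genome_chars <- function(genome) {
  if (is.character(genome)) return(genome)
  setNames(as.character(genome), names(genome))
}

#' Transcribe one Pol IV/RDR2 dsRNA precursor at a locus
#'
#' Draws a precursor start and length inside the locus by rejection
#' sampling so that the Pol IV 5' nucleotide follows `polIV_5p_bias` and
#' the RDR2 5' nucleotide (the complement of the Pol IV 3' base) follows
#' `rdr2_5p_bias`; after `max_tries` failed draws the last candidate is
#' accepted. The RDR2 strand is the full complement of the Pol IV strand
#' plus exactly one untemplated 3' nucleotide (drawn uniformly), giving a
#' 1-nt 3' overhang relative to the Pol IV strand.
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @param locus One-row data frame with `chrom`, `start`, `end`.
#' @param params A [biogenesis_params()] list.
#' @return A list of class `sirna_precursor` with `chrom`, `start` (0-based
#'   genomic position of the Pol IV 5' nucleotide), `len`, `pol_iv` and
#'   `rdr2` (RNA, 5'->3'; `nchar(rdr2) == len + 1`).
#' @export
transcribe_precursor <- function(genome, locus, params = biogenesis_params()) {
  chars <- genome_chars(genome)
  chrom_seq <- chars[[locus$chrom]]
  lo <- as.integer(locus$start)
  hi <- as.integer(locus$end)
  rng <- params$precursor_len_range
  if (hi - lo - 1L < rng[1]) {
    abort(sprintf("locus [%d,%d) too short for a %d-bp precursor", lo, hi, rng[1]))
  }
  want5 <- chartr("U", "T", sample(RNA_BASES, 1, prob = params$polIV_5p_bias))
  ## RDR2 5' base pairs the Pol IV 3' base: genomic base is its DNA complement
  want3 <- chartr("ACGU", "TGCA", sample(RNA_BASES, 1, prob = params$rdr2_5p_bias))
  s <- plen <- NA_integer_
  for (i in seq_len(params$max_tries)) {
    plen <- sample_from(seq(rng[1], min(rng[2], hi - lo - 1L)))
    s <- sample_from(seq(lo + 1L, hi - plen))
    if (substr(chrom_seq, s + 1L, s + 1L) == want5 &&
        substr(chrom_seq, s + plen, s + plen) == want3) break
  }
  pol_iv <- dna_to_rna(substr(chrom_seq, s + 1L, s + plen))
  rdr2 <- paste0(rna_revcomp(pol_iv), sample(RNA_BASES, 1))
  structure(list(chrom = locus$chrom, start = s, len = plen,
                 pol_iv = pol_iv, rdr2 = rdr2),
            class = "sirna_precursor")
}

#' Dice a precursor into an siRNA duplex
#'
#' With probability `1 - p_24_24` DCL3 cuts from the precursor end carrying
#' the Pol IV 5' terminus, yielding the 24/23 duplex: guide = Pol IV nt
#' 1-24, passenger = the RDR2 strand's 3'-terminal 23-mer whose terminal
#' nucleotide is untemplated and whose penultimate base is the templated
#' complement of the guide 5' base. Otherwise it cuts from the opposite
#' end, yielding a 24/24 duplex with 2-nt 3' overhangs at both ends.
#' Dicing events are accepted with probability proportional to the DCL3
#' end-preference weight of the candidate guide's 5' nucleotide
#' (`dcl3_5pA_weight` for A, `dcl3_5pG_weight` for G, 1 otherwise).
#'
#' @param precursor A [transcribe_precursor()] result.
#' @param params A [biogenesis_params()] list.
#' @return A validated [build_duplex()] object with genomic placement
#'   fields `chrom`, `guide_start`, `guide_end`, `guide_strand` (`"+"`),
#'   `passenger_start`, `passenger_end`, `passenger_strand` (`"-"`);
#'   class `c("placed_duplex", "sirna_duplex")`.
#' @export
dice <- function(precursor, params = biogenesis_params()) {
  stopifnot(inherits(precursor, "sirna_precursor"))
  plen <- precursor$len
  if (plen < 25L) abort("precursor shorter than 25 bp cannot be diced")
  w <- c(A = params$dcl3_5pA_weight, C = 1, G = params$dcl3_5pG_weight, U = 1)
  wmax <- max(w)
  branch24 <- FALSE
  for (i in seq_len(params$max_tries)) {
    branch24 <- runif(1) < params$p_24_24
    g5 <- if (branch24) substr(precursor$pol_iv, plen - 23L, plen - 23L)
          else substr(precursor$pol_iv, 1L, 1L)
    if (wmax == 0 || runif(1) <= w[[g5]] / wmax) break
  }
  s <- precursor$start
  e <- s + plen
  if (!branch24) {
    guide <- substr(precursor$pol_iv, 1L, 24L)
    passenger <- substr(precursor$rdr2, plen - 21L, plen + 1L)
    dup <- build_duplex(guide, passenger, "d24_23")
    dup$chrom <- precursor$chrom
    dup$guide_start <- s; dup$guide_end <- s + 24L
    dup$passenger_start <- s - 1L; dup$passenger_end <- s + 22L
  } else {
    guide <- substr(precursor$pol_iv, plen - 23L, plen)
    passenger <- substr(precursor$rdr2, 3L, 26L)
    dup <- build_duplex(guide, passenger, "d24_24")
    dup$chrom <- precursor$chrom
    dup$guide_start <- e - 24L; dup$guide_end <- e
    dup$passenger_start <- e - 26L; dup$passenger_end <- e - 2L
  }
  dup$guide_strand <- "+"
  dup$passenger_strand <- "-"
  class(dup) <- c("placed_duplex", class(dup))
  dup
}

empty_reads <- function() {
  tibble(chrom = character(), start = integer(), end = integer(),
         sequence = character(), count = integer(), strand = character(),
         origin = character())
}

read_row <- function(chrom, start, end, sequence, strand, origin) {
  tibble(chrom = chrom, start = as.integer(start), end = as.integer(end),
         sequence = sequence, count = 1L, strand = strand, origin = origin)
}

#' Load a duplex into AGO4 and mature the small RNA reads
#'
#' Emits the aligned small RNA reads one AGO4 loading event contributes to
#' a library. Slicing-defective AGO4 (`"SD"`) retains the duplex intact:
#' the guide and the intact passenger are emitted. Wild type (`"WT"`)
#' slices the passenger via [slice_passenger()]: the guide is emitted, the
#' 12-nt passenger 5' fragment is emitted with probability
#' `frag12_retention_prob`, and the 3' fragment is discarded (unless
#' `params$keep_frag3`, in which case it accompanies a retained 12-mer). With probability `guide_trunc_prob` a
#' 1-nt 3'-truncated guide (23 nt, 5' base preserved, no penultimate-U
#' signature) is additionally emitted, and with `guide_uridylation_prob` a
#' guide elongated by 1-2 untemplated 3' uridines, both in the wild-type
#' pool where siRNA turnover acts on the loaded guide.
#'
#' @param duplex A placed duplex from [dice()].
#' @param genotype `"WT"` or `"SD"`.
#' @param params A [biogenesis_params()] list.
#' @return Tibble of reads: `chrom`, `start`, `end` (0-based half-open),
#'   `sequence` (RNA, 5'->3'), `count`, `strand`, `origin`.
#' @export
load_and_mature <- function(duplex, genotype = c("WT", "SD"),
                            params = biogenesis_params()) {
  genotype <- arg_match(genotype)
  stopifnot(inherits(duplex, "placed_duplex"))
  out <- list(read_row(duplex$chrom, duplex$guide_start, duplex$guide_end,
                       duplex$guide, duplex$guide_strand, "guide24"))
  if (genotype == "SD") {
    tag <- if (nchar(duplex$passenger) == 23L) "passenger23" else "passenger24"
    out <- c(out, list(read_row(duplex$chrom, duplex$passenger_start,
                                duplex$passenger_end, duplex$passenger,
                                duplex$passenger_strand, tag)))
  } else {
    sl <- slice_passenger(duplex)
    retained <- sl$sliced &&
      (params$frag12_retention_prob >= 1 ||
         runif(1) < params$frag12_retention_prob)
    if (retained) {
      l5 <- nchar(sl$frag5)
      ## frag5 keeps the passenger 5' end: the high-coordinate side on -
      out <- c(out, list(read_row(
        duplex$chrom, duplex$passenger_end - l5, duplex$passenger_end,
        sl$frag5, duplex$passenger_strand, "frag12")))
      if (params$keep_frag3) {
        l3 <- nchar(sl$frag3)
        out <- c(out, list(read_row(
          duplex$chrom, duplex$passenger_start, duplex$passenger_start + l3,
          sl$frag3, duplex$passenger_strand, "frag11")))
      }
    }
    if (runif(1) < params$guide_trunc_prob) {
      out <- c(out, list(read_row(
        duplex$chrom, duplex$guide_start, duplex$guide_end - 1L,
        substr(duplex$guide, 1L, 23L), duplex$guide_strand, "trunc23")))
    }
    if (runif(1) < params$guide_uridylation_prob) {
      k <- sample(1:2, 1)
      out <- c(out, list(read_row(
        duplex$chrom, duplex$guide_start, duplex$guide_end + k,
        paste0(duplex$guide, strrep("U", k)), duplex$guide_strand,
        paste0("urid", 24L + k))))
    }
  }
  bind_rows(out)
}

#' Simulate a stream of placed siRNA duplexes over a set of loci
#'
#' Runs transcription and dicing for a Poisson number of dicing events per
#' locus (mean `duplexes_per_locus * expression_weight`). The duplex
#' stream depends only on the genome, loci, parameters and seed -- not on
#' the AGO4 genotype -- so wild-type and slicing-defective libraries built
#' from the same stream are paired at identical genomic positions, as in
#' vivo where biogenesis is upstream of AGO4 loading.
#'
#' @param genome A [Biostrings::DNAStringSet] (or named character vector).
#' @param loci Locus tibble from [simulate_loci()] (or with the same
#'   columns; missing `expression_weight` defaults to 1).
#' @param params A [biogenesis_params()] list.
#' @param duplexes_per_locus Mean number of dicing events per unit
#'   expression weight.
#' @param seed Integer seed.
#' @return List of placed duplexes (see [dice()]).
#' @export
simulate_duplexes <- function(genome, loci, params = biogenesis_params(),
                              duplexes_per_locus = 50, seed = NULL) {
  chars <- genome_chars(genome)
  if (!"expression_weight" %in% names(loci)) loci$expression_weight <- 1
  gen <- function() {
    unlist(lapply(seq_len(nrow(loci)), function(i) {
      locus <- loci[i, ]
      n_i <- rpois(1, duplexes_per_locus * locus$expression_weight)
      if (n_i == 0) return(NULL)
      lapply(seq_len(n_i), function(j) {
        dice(transcribe_precursor(chars, locus, params), params)
      })
    }), recursive = FALSE)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Mature a duplex stream into an aggregated read library
#'
#' Applies [load_and_mature()] to every duplex and aggregates identical
#' reads by summing counts.
#'
#' @param duplexes List of placed duplexes from [simulate_duplexes()].
#' @param genotype `"WT"` or `"SD"`.
#' @param params A [biogenesis_params()] list.
#' @param seed Integer seed for the maturation randomness
#'   (truncation/uridylation draws).
#' @return Tibble of aggregated reads (`chrom`, `start`, `end`,
#'   `sequence`, `count`, `strand`, `origin`), sorted by position.
#' @export
mature_library <- function(duplexes, genotype = c("WT", "SD"),
                           params = biogenesis_params(), seed = NULL) {
  genotype <- arg_match(genotype)
  n <- length(duplexes)
  if (n == 0) return(empty_reads())
  ## vectorized over the whole stream (equivalent to row-binding
  ## load_and_mature() over every duplex; the per-duplex operation remains
  ## the reference implementation)
  f_chr <- function(fld) vapply(duplexes, function(d) as.character(d[[fld]]), "")
  f_int <- function(fld) vapply(duplexes, function(d) as.integer(d[[fld]]), 1L)
  chrom <- f_chr("chrom")
  gs <- f_int("guide_start"); ge <- f_int("guide_end")
  gstr <- f_chr("guide_strand"); guide <- f_chr("guide")
  ps <- f_int("passenger_start"); pe <- f_int("passenger_end")
  pstr <- f_chr("passenger_strand"); pass <- f_chr("passenger")
  anchor <- f_int("guide_anchor")
  plen <- nchar(pass)
  gen <- function() {
    rows <- list(tibble(chrom = chrom, start = gs, end = ge, sequence = guide,
                        count = 1L, strand = gstr, origin = "guide24"))
    if (genotype == "SD") {
      rows <- c(rows, list(tibble(
        chrom = chrom, start = ps, end = pe, sequence = pass, count = 1L,
        strand = pstr,
        origin = if_else(plen == 23L, "passenger23", "passenger24"))))
    } else {
      cut <- anchor - slice_site_guide_positions()[2]
      ok <- cut >= 1L & cut < plen
      if (params$frag12_retention_prob < 1) {
        ok <- ok & runif(n) < params$frag12_retention_prob
      }
      frag5 <- substr(pass, 1L, cut)
      l5 <- nchar(frag5)
      rows <- c(rows, list(tibble(
        chrom = chrom[ok], start = pe[ok] - l5[ok], end = pe[ok],
        sequence = frag5[ok], count = 1L, strand = pstr[ok],
        origin = "frag12")))
      if (params$keep_frag3) {
        frag3 <- substr(pass, cut + 1L, plen)
        l3 <- nchar(frag3)
        rows <- c(rows, list(tibble(
          chrom = chrom[ok], start = ps[ok], end = ps[ok] + l3[ok],
          sequence = frag3[ok], count = 1L, strand = pstr[ok],
          origin = "frag11")))
      }
      tr <- runif(n) < params$guide_trunc_prob
      if (any(tr)) {
        rows <- c(rows, list(tibble(
          chrom = chrom[tr], start = gs[tr], end = ge[tr] - 1L,
          sequence = substr(guide[tr], 1L, 23L), count = 1L,
          strand = gstr[tr], origin = "trunc23")))
      }
      ur <- runif(n) < params$guide_uridylation_prob
      if (any(ur)) {
        k <- sample(1:2, sum(ur), replace = TRUE)
        rows <- c(rows, list(tibble(
          chrom = chrom[ur], start = gs[ur], end = ge[ur] + k,
          sequence = paste0(guide[ur], strrep("U", k)), count = 1L,
          strand = gstr[ur], origin = paste0("urid", 24L + k))))
      }
    }
    reads <- bind_rows(rows)
    if (nrow(reads) == 0) return(empty_reads())
    reads %>%
      group_by(.data$chrom, .data$start, .data$end, .data$sequence,
               .data$strand, .data$origin) %>%
      summarise(count = sum(.data$count), .groups = "drop") %>%
      select("chrom", "start", "end", "sequence", "count", "strand", "origin") %>%
      arrange(.data$chrom, .data$start, .data$end, .data$strand)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate a small RNA library over a set of loci
#'
#' Convenience wrapper chaining [simulate_duplexes()] and
#' [mature_library()]. Calling it with the same seed for different
#' genotypes yields libraries built from the identical duplex stream, so
#' genotype contrasts (12-mers in WT vs intact 23-mers in SD at the same
#' positions) are paired.
#'
#' @inheritParams simulate_duplexes
#' @inheritParams mature_library
#' @return Tibble of aggregated reads.
#' @examples
#' gen <- simulate_genome(50000, seed = 1)
#' loci <- simulate_loci(gen, n = 20, seed = 2)
#' sd_lib <- simulate_sirna_library(gen, loci, "SD", seed = 3,
#'                                  duplexes_per_locus = 10)
#' @export
simulate_sirna_library <- function(genome, loci, genotype = c("WT", "SD"),
                                   params = biogenesis_params(),
                                   duplexes_per_locus = 50, seed = NULL) {
  genotype <- arg_match(genotype)
  dup_seed <- if (is.null(seed)) NULL else seed
  mat_seed <- if (is.null(seed)) NULL else seed + 1000003L
  duplexes <- simulate_duplexes(genome, loci, params, duplexes_per_locus,
                                seed = dup_seed)
  mature_library(duplexes, genotype, params, seed = mat_seed)
}
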