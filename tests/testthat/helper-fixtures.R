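## Shared synthetic fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

## Medium-scale paired WT/SD libraries over one 200-kb chromosome.
fx <- function() {
  if (!exists("lib", envir = .fixtures)) {
    genome <- simulate_genome(2e5, seed = 101)
    loci <- simulate_loci(genome, n = 100, seed = 102)
    params <- biogenesis_params()
    duplexes <- simulate_duplexes(genome, loci, params, 20, seed = 103)
    wt <- mature_library(duplexes, "WT", params, seed = 104)
    sd <- mature_library(duplexes, "SD", params, seed = 104)
    guides <- dplyr::filter(wt, origin == "guide24")
    frags <- transcribe_and_slice_targets(genome, loci, guides)
    frags_ctrl <- transcribe_and_slice_targets(genome, loci, guides,
                                               slicing = FALSE, seed = 105)
    assign("lib", list(genome = genome, loci = loci, params = params,
                       duplexes = duplexes, wt = wt, sd = sd,
                       guides = guides, frags = frags,
                       frags_ctrl = frags_ctrl),
           envir = .fixtures)
  }
  get("lib", envir = .fixtures)
}

## Random valid duplex of a random geometry (paired region <= 30 nt).
random_duplex <- function() {
  geom <- sample(c("d24_23", "d24_24", "custom"), 1)
  if (geom == "custom") {
    o3 <- sample(0:4, 1)
    o5 <- sample(0:4, 1)
    glen <- sample((12 + o3):(30 + o3), 1)
    guide <- random_rna(glen)
    paired <- glen - o3
    pass <- paste0(
      rna_revcomp(substr(guide, glen - o3 - paired + 1, glen - o3)),
      random_rna(o5))
    build_duplex(guide, pass, "custom", overhang_5g = o5, overhang_3g = o3)
  } else {
    guide <- random_rna(24)
    pass <- paste0(rna_revcomp(substr(guide, 1, 22)),
                   random_rna(if (geom == "d24_23") 1 else 2))
    build_duplex(guide, pass, geom)
  }
}

random_rna <- function(n) {
  if (n == 0) return("")
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

## Brute-force oracle: scan the passenger for the unique bond whose
## flanking nucleotides are paired to guide positions 10 and 11.
oracle_cut_after <- function(duplex) {
  anchor <- duplex$guide_anchor
  plen <- nchar(duplex$passenger)
  partner <- function(p) {
    g <- anchor - p
    if (g >= anchor - duplex$paired_len && g <= anchor - 1 && g >= 1) g else NA
  }
  for (i in seq_len(plen - 1)) {
    gpair <- c(partner(i), partner(i + 1))
    if (!anyNA(gpair) && setequal(gpair, c(10, 11))) return(i)
  }
  NA_integer_
}

## Brute-force all-pairs registry spectrum via the scalar registry().
oracle_spectrum <- function(reads, sizes, max_abs = 30) {
  top <- dplyr::filter(reads, strand == "+", end - start == sizes[1])
  bottom <- dplyr::filter(reads, strand == "-", end - start == sizes[2])
  counts <- integer()
  if (nrow(top) > 0 && nrow(bottom) > 0) {
    for (i in seq_len(nrow(top))) {
      for (j in seq_len(nrow(bottom))) {
        r <- registry(top[i, ], bottom[j, ])
        if (!is.na(r) && abs(r) <= max_abs) {
          key <- as.character(r)
          counts[key] <- (if (key %in% names(counts)) counts[[key]] else 0L) +
            top$count[i] * bottom$count[j]
        }
      }
    }
  }
  tibble::tibble(registry = as.integer(names(counts)),
                 n_pairs = as.numeric(counts)) |>
    dplyr::arrange(registry)
}

## Bare read tibble builder for hand-constructed cases.
mk_reads <- function(chrom, start, len, strand, sequence = NA, count = 1L,
                     origin = NA_character_) {
  n <- max(lengths(list(chrom, start, len, strand)))
  tibble::tibble(
    chrom = rep_len(chrom, n), start = as.integer(rep_len(start, n)),
    end = as.integer(rep_len(start, n) + rep_len(len, n)),
    sequence = as.character(rep_len(sequence, n)),
    count = as.integer(rep_len(count, n)),
    strand = rep_len(strand, n), origin = rep_len(origin, n))
}
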