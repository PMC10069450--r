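## Bisulfite methylome simulation and cytosine context assignment.

#' Methylome simulation parameters
#'
#' @param base_rates Named vector of genome-wide background methylation
#'   rates per context (`CG`, `CHG`, `CHH`).
#' @param rdDM_gain Methylation rate added to CHG and CHH cytosines inside
#'   designated RdDM loci in the wild type.
#' @param mutant_retention Fraction of `rdDM_gain` retained in the
#'   AGO4-null mutant (genotype `"ago4"`).
#' @param sd_retention Fraction retained in the slicing-defective line
#'   (genotype `"SD"`); intermediate between mutant and wild type.
#' @param coverage_mean Mean sequencing coverage per cytosine (Poisson).
#' @param replicates Number of independent replicates per genotype.
#' @return A list of class `methylome_params`.
#' @export
methylome_params <- function(base_rates = c(CG = 0.20, CHG = 0.08, CHH = 0.03),
                             rdDM_gain = 0.25,
                             mutant_retention = 0.1,
                             sd_retention = 0.5,
                             coverage_mean = 20,
                             replicates = 2) {
  stopifnot(setequal(names(base_rates), c("CG", "CHG", "CHH")),
            all(base_rates >= 0), all(base_rates <= 1),
            rdDM_gain >= 0, rdDM_gain <= 1,
            mutant_retention >= 0, sd_retention >= mutant_retention,
            sd_retention <= 1, coverage_mean > 0, replicates >= 1)
  structure(list(base_rates = base_rates[c("CG", "CHG", "CHH")],
                 rdDM_gain = rdDM_gain,
                 mutant_retention = mutant_retention,
                 sd_retention = sd_retention,
                 coverage_mean = coverage_mean,
                 replicates = as.integer(replicates)),
            class = "methylome_params")
}

genotype_retention <- function(genotype, params) {
  switch(genotype,
         WT = 1,
         ago4 = params$mutant_retention,
         SD = params$sd_retention,
         abort(sprintf("unknown genotype '%s' (use WT, ago4 or SD)", genotype)))
}

## All cytosines of one chromosome (both strands) with context.
## Positions within 2 bp of a contig end are omitted (context undefined).
chrom_cytosines <- function(chrom_seq, chrom) {
  v <- strsplit(toupper(chrom_seq), "")[[1]]
  L <- length(v)
  if (L < 3L) return(NULL)
  ## + strand: C at 1-based i, needs i + 2 <= L
  ip <- which(v == "C")
  ip <- ip[ip >= 1L & ip <= L - 2L]
  ctx_p <- ifelse(v[ip + 1L] == "G", "CG",
                  ifelse(v[ip + 2L] == "G", "CHG", "CHH"))
  ## - strand: G on + strand; strand-aware downstream bases are i-1, i-2
  im <- which(v == "G")
  im <- im[im >= 3L]
  ctx_m <- ifelse(v[im - 1L] == "C", "CG",
                  ifelse(v[im - 2L] == "C", "CHG", "CHH"))
  tibble(chrom = chrom,
         pos = c(ip, im) - 1L,
         strand = rep(c("+", "-"), c(length(ip), length(im))),
         context = c(ctx_p, ctx_m)) %>%
    arrange(.data$pos, .data$strand)
}

#' Assign the methylation context of a cytosine
#'
#' Determines CG / CHG / CHH (H = any base except G) for a cytosine at a
#' 0-based position on either strand, reading strand-aware downstream
#' bases from the genome. Returns `NA` within 2 bp of a contig end, where
#' the trinucleotide is undefined.
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @param chrom Chromosome name.
#' @param pos 0-based position; must be a cytosine on `strand` (a G on the
#'   + strand for `strand = "-"`), otherwise an error.
#' @param strand `"+"` or `"-"`.
#' @return `"CG"`, `"CHG"`, `"CHH"`, or `NA_character_`.
#' @examples
#' gen <- Biostrings::DNAStringSet(c(chr1 = "ACGTT"))
#' assign_context(gen, "chr1", 1, "+")  # CG
#' @export
assign_context <- function(genome, chrom, pos, strand = "+") {
  chars <- genome_chars(genome)
  v <- chars[[chrom]]
  L <- nchar(v)
  i <- as.integer(pos) + 1L  # 1-based
  base <- substr(v, i, i)
  need <- if (strand == "+") "C" else "G"
  if (base != need) {
    abort(sprintf("position %d on %s strand is %s, not a cytosine",
                  pos, strand, base))
  }
  if (strand == "+") {
    if (i > L - 2L) return(NA_character_)
    n1 <- substr(v, i + 1L, i + 1L); n2 <- substr(v, i + 2L, i + 2L)
    if (n1 == "G") "CG" else if (n2 == "G") "CHG" else "CHH"
  } else {
    if (i < 3L) return(NA_character_)
    n1 <- substr(v, i - 1L, i - 1L); n2 <- substr(v, i - 2L, i - 2L)
    if (n1 == "C") "CG" else if (n2 == "C") "CHG" else "CHH"
  }
}

#' Simulate bisulfite methylomes for several genotypes
#'
#' Every cytosine of the genome (both strands) receives a Poisson read
#' total and a binomial methylated count whose rate is the per-context
#' background plus, for CHG/CHH cytosines inside the designated RdDM loci,
#' `rdDM_gain` scaled by the genotype's retention (1 for `"WT"`,
#' `mutant_retention` for `"ago4"`, `sd_retention` for `"SD"`).
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param loci Tibble of RdDM loci (`chrom`, `start`, `end`); may have zero
#'   rows for a locus-free null methylome. An optional `gain_scale` column
#'   scales `rdDM_gain` per locus (e.g. to couple methylation gain to
#'   siRNA expression weight).
#' @param genotypes Character vector drawn from `"WT"`, `"ago4"`, `"SD"`.
#' @param params A [methylome_params()] list.
#' @param seed Integer seed.
#' @return Tibble of per-cytosine calls: `genotype`, `replicate`, `chrom`,
#'   `pos` (0-based), `strand`, `context`, `meth`, `total`.
#' @export
simulate_methylome <- function(genome, loci, genotypes = c("WT", "ago4"),
                               params = methylome_params(), seed = NULL) {
  chars <- genome_chars(genome)
  cyt <- bind_rows(lapply(names(chars), function(ch) {
    chrom_cytosines(chars[[ch]], ch)
  }))
  ## locus membership (loci are non-overlapping within a chromosome)
  cyt$gain_scale <- 0
  if (!is.null(loci) && nrow(loci) > 0) {
    scale_col <- if ("gain_scale" %in% names(loci)) loci$gain_scale else
      rep(1, nrow(loci))
    for (ch in unique(loci$chrom)) {
      in_ch <- loci$chrom == ch
      lc <- loci[in_ch, ]
      sc <- scale_col[in_ch]
      o <- order(lc$start)
      lc <- lc[o, ]; sc <- sc[o]
      sel <- cyt$chrom == ch
      idx <- findInterval(cyt$pos[sel], lc$start)
      hit <- idx >= 1 & cyt$pos[sel] < lc$end[pmax(idx, 1)]
      val <- rep(0, sum(sel))
      val[hit] <- sc[idx[hit]]
      cyt$gain_scale[sel] <- val
    }
  }
  n <- nrow(cyt)
  base <- params$base_rates[cyt$context]
  gain_ctx <- (cyt$context %in% c("CHG", "CHH")) * cyt$gain_scale
  gen <- function() {
    combos <- expand.grid(replicate = seq_len(params$replicates),
                          genotype = genotypes, stringsAsFactors = FALSE)
    bind_rows(lapply(seq_len(nrow(combos)), function(k) {
      gt <- combos$genotype[k]
      rate <- pmin(1, base + params$rdDM_gain * genotype_retention(gt, params) * gain_ctx)
      total <- rpois(n, params$coverage_mean)
      meth <- rbinom(n, total, rate)
      tibble(genotype = gt, replicate = combos$replicate[k],
             chrom = cyt$chrom, pos = cyt$pos, strand = cyt$strand,
             context = cyt$context, meth = meth, total = total)
    }))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
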