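test_that("generator output is byte-identical for a fixed seed", {
  g1 <- simulate_genome(c(a = 5000, b = 3000), gc = 0.4, seed = 5)
  g2 <- simulate_genome(c(a = 5000, b = 3000), gc = 0.4, seed = 5)
  expect_identical(as.character(g1), as.character(g2))
  expect_true(all(strsplit(as.character(simulate_genome(2000, gc = 1,
                                                        seed = 1)), "")[[1]]
                  %in% c("G", "C")))

  loci <- simulate_loci(g1, n = 10, seed = 6)
  expect_identical(loci, simulate_loci(g1, n = 10, seed = 6))
  expect_equal(nrow(loci), 10L)
  expect_true(all(loci$start < loci$end))

  lib1 <- simulate_sirna_library(g1, loci, "SD", duplexes_per_locus = 5,
                                 seed = 7)
  lib2 <- simulate_sirna_library(g1, loci, "SD", duplexes_per_locus = 5,
                                 seed = 7)
  expect_identical(lib1, lib2)
})

test_that("RDR2 strand is the full complement plus one untemplated 3' nucleotide", {
  f <- fx()
  locus <- f$loci[1, ]
  withr::with_seed(31, {
    for (i in 1:20) {
      prec <- transcribe_precursor(f$genome, locus, f$params)
      expect_equal(nchar(prec$rdr2), prec$len + 1L)
      expect_equal(substr(prec$rdr2, 1, prec$len), rna_revcomp(prec$pol_iv))
      ## genome consistency of the Pol IV strand
      expect_equal(prec$pol_iv,
                   argoslice::dna_to_rna(substr(
                     as.character(f$genome[[locus$chrom]]),
                     prec$start + 1, prec$start + prec$len)))
    }
  })
})

test_that("Pol IV 5' nucleotide frequency tracks the sampling bias", {
  f <- fx()
  params <- biogenesis_params(
    polIV_5p_bias = c(A = 0.9, C = 0.04, G = 0.03, U = 0.03))
  withr::with_seed(37, {
    first <- vapply(1:400, function(i) {
      locus <- f$loci[sample.int(nrow(f$loci), 1), ]
      substr(transcribe_precursor(f$genome, locus, params)$pol_iv, 1, 1)
    }, character(1))
  })
  expect_gt(mean(first == "A"), 0.82)  # 0.9 within binomial error at n = 400
  expect_lt(mean(first == "A"), 0.97)
})

test_that("dicing geometry propagates the guide 5' base to the passenger penultimate position", {
  f <- fx()
  locus <- f$loci[2, ]
  p2423 <- biogenesis_params(p_24_24 = 0)
  withr::with_seed(41, {
    for (i in 1:20) {
      d <- dice(transcribe_precursor(f$genome, locus, p2423), p2423)
      expect_equal(d$geometry, "d24_23")
      expect_equal(d$overhang_5g, 1L)
      expect_equal(substr(d$passenger, 22, 22),
                   rna_complement(substr(d$guide, 1, 1)))
      ## registry of the placement matches the geometry
      expect_equal(d$guide_start - d$passenger_start, 1L)
    }
    p2424 <- biogenesis_params(p_24_24 = 1)
    for (i in 1:10) {
      d <- dice(transcribe_precursor(f$genome, locus, p2424), p2424)
      expect_equal(d$geometry, "d24_24")
      expect_equal(d$guide_start - d$passenger_start, 2L)
    }
  })
})

test_that("maturation reproduces the genotype contrast: 12-mers only in WT, intact passengers only in SD", {
  f <- fx()
  expect_equal(sum(f$wt$count[f$wt$origin %in% c("passenger23", "passenger24")]), 0L)
  expect_equal(sum(f$sd$count[f$sd$origin == "frag12"]), 0L)
  expect_gt(sum(f$wt$count[f$wt$origin == "frag12"]), 0L)
  expect_gt(sum(f$sd$count[f$sd$origin == "passenger23"]), 0L)

  ## with turnover off the length sets are exactly {12, 24} and {23, 24}
  p0 <- biogenesis_params(guide_trunc_prob = 0, guide_uridylation_prob = 0)
  wt0 <- mature_library(f$duplexes, "WT", p0)
  sd0 <- mature_library(f$duplexes, "SD", p0)
  expect_setequal(unique(wt0$end - wt0$start), c(12L, 24L))
  expect_setequal(unique(sd0$end - sd0$start), c(23L, 24L))
})

test_that("equal 24/23 and 24/24 loading without slicing gives a 3:1 strand ratio", {
  f <- fx()
  p0 <- biogenesis_params(guide_trunc_prob = 0, guide_uridylation_prob = 0)
  n <- 200
  withr::with_seed(43, {
    stream <- c(
      simulate_duplexes(f$genome, f$loci[1:20, ],
                        biogenesis_params(p_24_24 = 0), n / 20, seed = 1),
      simulate_duplexes(f$genome, f$loci[1:20, ],
                        biogenesis_params(p_24_24 = 1), n / 20, seed = 2))
  })
  sd <- mature_library(stream, "SD", p0)
  dist <- size_distribution(sd)
  n24 <- dist$count[dist$length == 24]
  n23 <- dist$count[dist$length == 23]
  ## each 24/23 contributes one 24- and one 23-mer; each 24/24 two 24-mers
  n2423 <- sum(vapply(stream, function(d) d$geometry == "d24_23", TRUE))
  n2424 <- length(stream) - n2423
  expect_equal(n24, n2423 + 2L * n2424)
  expect_equal(n23, n2423)
  ## at equal loading the ratio converges to 3:1
  sd_half <- mature_library(
    simulate_duplexes(f$genome, f$loci, biogenesis_params(p_24_24 = 0.5),
                      20, seed = 44),
    "SD", p0)
  dist_half <- size_distribution(sd_half)
  ratio <- dist_half$count[dist_half$length == 24] /
    dist_half$count[dist_half$length == 23]
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 3.6)
})

test_that("penultimate-U frequency among SD 23-mers matches the guide 5'-A frequency", {
  f <- fx()
  p23 <- dplyr::filter(f$sd, origin == "passenger23")
  g24 <- dplyr::filter(f$sd, origin == "guide24")
  ## restrict guides to 24/23 events (those with a paired passenger23)
  freq_u <- sum(p23$count[substr(p23$sequence, 22, 22) == "U"]) / sum(p23$count)
  g_of_23 <- dplyr::semi_join(
    g24, dplyr::mutate(p23, start = start + 1L),
    by = c("chrom", "start"))
  freq_a <- sum(g_of_23$count[substr(g_of_23$sequence, 1, 1) == "A"]) /
    sum(g_of_23$count)
  expect_equal(freq_u, freq_a, tolerance = 0.02)
  expect_gt(freq_u, 0.7)  # the effective guide 5'-A bias is ~0.8
})

test_that("sliced target fragments conserve length and carry the +10 complement of the guide 5' base", {
  f <- fx()
  frags <- f$frags
  expect_true(all(frags$origin == "target_frag"))
  expect_true(all(frags$end - frags$start >= 30))
  f3 <- dplyr::filter(frags, side == "3p")
  expect_gt(nrow(f3), 100)
  ## join each 3' fragment to the guide whose cut produced it:
  ## fragment end = guide start + 10
  g <- dplyr::mutate(f$guides, cut = start + 10L,
                     g5 = substr(sequence, 1, 1))
  j <- dplyr::inner_join(f3, dplyr::distinct(g, chrom, cut, g5),
                         by = c("chrom", end = "cut"))
  expect_equal(nrow(j), nrow(f3))
  expect_true(all(substr(j$sequence, 10, 10) == rna_complement(j$g5)))

  ## when both fragments of a cut pass the length filter they tile the
  ## locus-wide transcript exactly
  f5 <- dplyr::filter(frags, side == "5p")
  pairs <- dplyr::inner_join(
    dplyr::distinct(f5, chrom, gcut = start, b = end),
    dplyr::distinct(f3, chrom, a = start, gcut = end),
    by = c("chrom", "gcut"))
  expect_gt(nrow(pairs), 50)
  with_locus <- dplyr::semi_join(
    pairs, dplyr::select(f$loci, chrom, a = start, b = end),
    by = c("chrom", "a", "b"))
  expect_equal(nrow(with_locus), nrow(pairs))

  ## a guide with no complementary site yields nothing
  fake <- mk_reads("chr1", f$loci$start[1] + 50, 24, "+",
                   sequence = strrep("A", 24), origin = "guide24")
  expect_equal(nrow(transcribe_and_slice_targets(f$genome, f$loci, fake)), 0L)
})

test_that("methylome contexts are genome-consistent and rates follow genotype retention", {
  gen <- Biostrings::DNAStringSet(c(chr1 = "ACCGGTACGTACTTACGG"))
  ## + strand: pos1 C in CCG -> CHG; pos2 C in CGG -> CG; pos7 C in CGT -> CG
  expect_equal(assign_context(gen, "chr1", 1, "+"), "CHG")
  expect_equal(assign_context(gen, "chr1", 2, "+"), "CG")
  expect_equal(assign_context(gen, "chr1", 11, "+"), "CHH")  # C in CTT
  expect_error(assign_context(gen, "chr1", 0, "+"), "not a cytosine")
  ## - strand: G at pos 4 -> C on minus; downstream (leftward) G,C -> CG? no:
  ## pos4 G, upstream bases pos3 G, pos2 C -> comp reads C then G -> CHG
  expect_equal(assign_context(gen, "chr1", 4, "-"), "CHG")

  f <- fx()
  mp <- methylome_params()
  loci <- f$loci[1:10, ]
  calls <- simulate_methylome(f$genome, loci, c("WT", "ago4"), mp, seed = 51)
  expect_true(all(calls$meth <= calls$total))
  ## spot-check context against the scalar rule
  sub <- dplyr::slice_sample(dplyr::filter(calls, genotype == "WT",
                                           replicate == 1), n = 50)
  ctx <- mapply(function(ch, p, s) assign_context(f$genome, ch, p, s),
                sub$chrom, sub$pos, sub$strand)
  expect_equal(unname(ctx), sub$context)

  ## moment check: wild-type CHH rate inside loci ~ base + gain
  in_loci <- dplyr::inner_join(
    dplyr::filter(calls, genotype == "WT", context == "CHH"),
    dplyr::select(loci, chrom, ls = start, le = end),
    by = "chrom", relationship = "many-to-many") |>
    dplyr::filter(pos >= ls, pos < le)
  expect_gt(nrow(in_loci), 200)
  rate <- sum(in_loci$meth) / sum(in_loci$total)
  expect_equal(rate, unname(mp$base_rates["CHH"]) + mp$rdDM_gain,
               tolerance = 0.03)
  mut_chh <- dplyr::semi_join(
    dplyr::filter(calls, genotype == "ago4", context == "CHH"),
    in_loci, by = c("chrom", "pos", "strand"))
  mut_rate <- sum(mut_chh$meth) / sum(mut_chh$total)
  expect_equal(mut_rate,
               unname(mp$base_rates["CHH"]) + mp$rdDM_gain * mp$mutant_retention,
               tolerance = 0.03)

  ## full retention makes genotypes indistinguishable: no DMRs called
  mp1 <- methylome_params(mutant_retention = 1, sd_retention = 1)
  null_calls <- simulate_methylome(f$genome, loci, c("WT", "ago4"), mp1,
                                   seed = 52)
  expect_equal(nrow(call_dmrs(null_calls)), 0L)
})

test_that("read and methylation tables round-trip through TSV", {
  f <- fx()
  path <- withr::local_tempfile(fileext = ".tsv")
  reads <- head(f$sd, 1000)
  write_reads_tsv(reads, path)
  expect_equal(as.data.frame(read_reads_tsv(path)), as.data.frame(reads))

  ## empty table -> header-only file that reads back empty
  write_reads_tsv(f$sd[0, ], path)
  expect_equal(nrow(read_reads_tsv(path)), 0L)

  ## malformed strand is rejected with the record number
  bad <- reads
  bad$strand[3] <- "*"
  write_reads_tsv(bad, path)
  expect_error(read_reads_tsv(path), "malformed strand.*record 3")

  mpath <- withr::local_tempfile(fileext = ".tsv")
  calls <- head(simulate_methylome(
    simulate_genome(2000, seed = 1), f$loci[0, ], "WT",
    methylome_params(replicates = 1), seed = 2), 500)
  write_methylation_tsv(calls, mpath)
  back <- read_methylation_tsv(mpath)
  expect_equal(as.data.frame(back[, names(calls)]), as.data.frame(calls))

  bpath <- withr::local_tempfile(fileext = ".bed")
  write_loci_bed(f$loci, bpath)
  back_loci <- read_loci_bed(bpath)
  expect_equal(back_loci$start, f$loci$start)
  expect_equal(back_loci$expression_weight, f$loci$expression_weight)

  fpath <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(f$genome, fpath)
  expect_identical(as.character(read_genome_fasta(fpath)),
                   as.character(f$genome))
})
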