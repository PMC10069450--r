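test_that("size distribution is count-conserving and shows the genotype size classes", {
  f <- fx()
  d_wt <- size_distribution(f$wt)
  d_sd <- size_distribution(f$sd)
  expect_equal(sum(d_wt$count), sum(f$wt$count))
  expect_equal(sum(d_wt$fraction), 1)
  expect_equal(d_wt$length[which.max(d_wt$count)], 24L)
  expect_gt(d_sd$fraction[d_sd$length == 23], 0.1)
  expect_false(12L %in% d_sd$length)
  expect_true(12L %in% d_wt$length)

  single <- mk_reads("chr1", 10, 21, "+", sequence = random_rna(21))
  expect_equal(size_distribution(single)$fraction, 1)
  expect_equal(nrow(size_distribution(f$wt[0, ])), 0L)
})

test_that("positional matrices are probability rows with the expected anchors", {
  f <- fx()
  pm <- positional_matrix(f$sd, size_filter = 24L, anchor = "5prime")
  expect_true(all(abs(rowSums(pm[, c("A", "C", "G", "U")]) - 1) < 1e-9))
  ## pooled SD 24-mers are A-dominated at position 1; among guides of
  ## 24/23 duplexes (the Pol IV 5'-end strands) the bias reaches ~0.8
  expect_equal(names(which.max(pm[pm$position == 1, c("A", "C", "G", "U")])),
               "A")
  g2423 <- dplyr::semi_join(
    dplyr::filter(f$sd, origin == "guide24"),
    dplyr::mutate(dplyr::filter(f$sd, origin == "passenger23"),
                  start = start + 1L),
    by = c("chrom", "start"))
  pm_g <- positional_matrix(g2423, size_filter = 24L, anchor = "5prime")
  expect_gt(pm_g$A[pm_g$position == 1], 0.7)

  ## SD 23-mers: U at position 22 tracks the guide 5'-A frequency
  pm23 <- positional_matrix(f$sd, size_filter = 23L, anchor = "5prime")
  expect_gt(pm23$U[pm23$position == 22], 0.7)

  ## 3' anchor: position 1 is the terminal base
  r <- mk_reads("chr1", c(0, 100), c(5, 7), "+",
                sequence = c("AUGCA", "GGGGGGA"))
  pm3 <- positional_matrix(r, anchor = "3prime")
  expect_equal(pm3$A[pm3$position == 1], 1)

  withr::with_seed(61, {
    unif <- mk_reads("chr1", seq(0, 990, 10), 24, "+",
                     sequence = vapply(1:100, function(i) random_rna(24), ""))
  })
  pmu <- positional_matrix(unif, anchor = "5prime")
  expect_true(all(abs(as.matrix(pmu[, c("A", "C", "G", "U")]) - 0.25) < 0.2))
  expect_equal(nrow(positional_matrix(unif[0, ])), 0L)
})

test_that("23-mer classification separates passengers from truncated guides", {
  f <- fx()
  cls_sd <- classify_23mers(f$sd)
  cls_wt <- classify_23mers(f$wt)
  expect_gt(cls_sd$passenger_like / cls_sd$n_23mers, 0.5)
  expect_lt(cls_sd$truncated_guide_like / cls_sd$n_23mers, 0.1)
  expect_gt(cls_wt$truncated_guide_like / cls_wt$n_23mers, 0.9)
  expect_equal(cls_wt$passenger_like, 0L)

  ## precedence: a read matching both rules counts as truncated-guide-like
  g <- paste0("A", random_rna(20), "AUC")  # 24-mer with U at position 22
  r24 <- mk_reads("chr1", 100, 24, "+", sequence = g)
  ambiguous <- mk_reads("chr1", 100, 23, "+", sequence = substr(g, 1, 23))
  ## give it an antisense partner in canonical register too: start - 2 on -
  anti <- mk_reads("chr1", 98, 24, "-", sequence = random_rna(24))
  res <- classify_23mers(dplyr::bind_rows(r24, ambiguous, anti))
  expect_equal(res$truncated_guide_like, 1L)
  expect_equal(res$passenger_like, 0L)
})

test_that("uridylation detection recovers the simulated rate and ignores non-U tails", {
  f <- fx()
  ur <- detect_uridylation(f$wt)
  expect_equal(ur$fraction, 0.05, tolerance = 0.5)
  expect_gt(ur$n_u_tailed, 0)
  expect_equal(ur$n_u_tailed, ur$n_extended)  # all simulated tails are U

  p0 <- biogenesis_params(guide_uridylation_prob = 0)
  wt0 <- mature_library(f$duplexes, "WT", p0, seed = 1)
  expect_equal(detect_uridylation(wt0)$fraction, 0)

  g <- random_rna(24)
  base <- mk_reads("chr1", 50, 24, "+", sequence = g)
  ext_bad <- mk_reads("chr1", 50, 25, "+", sequence = paste0(g, "G"))
  res <- detect_uridylation(dplyr::bind_rows(base, ext_bad))
  expect_equal(res$n_u_tailed, 0L)
  expect_equal(res$n_extended, 1L)
})

test_that("locus abundance computes RPM with the 50% overlap rule", {
  loci <- tibble::tibble(locus_id = c("L0001", "L0002"),
                         chrom = "chr1", start = c(100L, 500L),
                         end = c(200L, 600L), expression_weight = 1)
  reads <- mk_reads("chr1", rep(120, 10), 24, "+", sequence = random_rna(24))
  ab <- locus_abundance(reads, loci, library_total = 1e6)
  expect_equal(ab$rpm[ab$locus_id == "L0001" & ab$length == 24], 10)

  ## read overlapping no locus lands in the unassigned bucket
  far <- mk_reads("chr1", 900, 24, "+", sequence = random_rna(24))
  ab2 <- locus_abundance(dplyr::bind_rows(reads, far), loci,
                         library_total = 1e6)
  expect_equal(ab2$count[ab2$locus_id == "unassigned"], 1L)

  ## a read straddling the boundary with < 50% inside is not assigned
  edge <- mk_reads("chr1", 188, 24, "+", sequence = random_rna(24))  # 12/24 in
  ab3 <- locus_abundance(edge, loci, library_total = 1e6)
  expect_equal(ab3$locus_id, "L0001")  # exactly 50% overlap qualifies
  edge2 <- mk_reads("chr1", 189, 24, "+", sequence = random_rna(24)) # 11/24 in
  ab4 <- locus_abundance(edge2, loci, library_total = 1e6)
  expect_equal(ab4$locus_id, "unassigned")

  ## doubling counts doubles RPM only at fixed library size
  doubled <- dplyr::mutate(reads, count = 2L)
  ab5 <- locus_abundance(doubled, loci, library_total = 1e6)
  expect_equal(ab5$rpm, 2 * ab$rpm)
  ab6 <- locus_abundance(doubled, loci)  # library_total re-derived
  expect_equal(ab6$rpm, locus_abundance(reads, loci)$rpm)
})

test_that("dominant-size filtering keeps 23/24-dominated loci and honors ties", {
  ab <- structure(tibble::tibble(
    locus_id = c("L1", "L1", "L2", "L2", "L3", "L3"),
    length = c(24L, 21L, 21L, 24L, 23L, 21L),
    count = 1L,
    rpm = c(10, 5, 10, 5, 7, 7)),
    class = c("locus_abundance", class(tibble::tibble())))
  expect_setequal(dominant_size_loci(ab), c("L1", "L3"))
  expect_setequal(dominant_size_loci(ab, sizes = 21L), c("L2", "L3"))
})
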