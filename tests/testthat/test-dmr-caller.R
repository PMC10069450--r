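test_that("window rates pool strands with half-open 100-nt tiles", {
  calls <- tibble::tibble(
    chrom = "chr1", pos = c(10L, 50L, 100L, 150L),
    strand = c("+", "-", "+", "+"), context = "CHH",
    meth = c(3L, 7L, 5L, 0L), total = c(10L, 10L, 10L, 10L))
  ws <- window_rates(calls)
  ## two CHH cytosines at 3/10 and 7/10 pool to rate 0.5
  expect_equal(ws$rate[ws$start == 0], 0.5)
  ## position 100 belongs to the second window (half-open convention)
  expect_equal(ws$n_cytosines[ws$start == 100], 2L)
  ## permuting record order changes nothing
  perm <- window_rates(calls[sample(4), ])
  expect_equal(dplyr::arrange(perm, start), dplyr::arrange(ws, start))
  ## cytosines below the coverage filter are excluded from the pool
  low <- dplyr::mutate(calls, total = c(10L, 3L, 10L, 10L))
  expect_equal(window_rates(low)$rate[1], 3 / 10)
})

test_that("bin qualification requires four cytosines each covered four-fold", {
  mk_stats <- function(n_cov, n_all = n_cov) {
    tibble::tibble(chrom = "chr1", start = 0L, end = 100L, context = "CHH",
                   n_cytosines = n_all, n_cytosines_cov = n_cov,
                   meth_sum = 10, total_sum = 40, rate = 0.25)
  }
  expect_equal(nrow(qualify_bins(mk_stats(4L))), 1L)       # boundary passes
  expect_equal(nrow(qualify_bins(mk_stats(3L, 4L))), 0L)   # one cytosine at cov 3
  expect_equal(nrow(qualify_bins(mk_stats(3L, 3L))), 0L)   # three cytosines
  expect_equal(nrow(qualify_bins(mk_stats(4L), context = "CHG")), 0L)
})

test_that("the differential rule compares every replicate pair at 10 points", {
  mk_rep <- function(rate) {
    tibble::tibble(chrom = "chr1", start = c(0L, 200L), end = c(100L, 300L),
                   context = "CHH", n_cytosines = 6L, n_cytosines_cov = 6L,
                   meth_sum = rate * 100, total_sum = 100, rate = rate)
  }
  wt <- list(mk_rep(c(0.30, 0.30)), mk_rep(c(0.28, 0.28)))
  ## (0.30, 0.28) vs (0.15, 0.12): every mutant rep <= every WT rep - 0.10
  mut_yes <- list(mk_rep(c(0.15, 0.15)), mk_rep(c(0.12, 0.12)))
  expect_equal(nrow(differential_bins(wt, mut_yes)), 2L)
  ## (0.25, 0.12): 0.25 > 0.28 - 0.10, not differential
  mut_no <- list(mk_rep(c(0.25, 0.25)), mk_rep(c(0.12, 0.12)))
  expect_equal(nrow(differential_bins(wt, mut_no)), 0L)
  ## identical genotypes are never differential
  expect_equal(nrow(differential_bins(wt, wt)), 0L)
  ## monotonicity: growing delta never adds bins
  deltas <- c(0.05, 0.10, 0.15, 0.20)
  n_bins <- vapply(deltas, function(d) {
    nrow(differential_bins(wt, mut_yes, delta = d))
  }, 1L)
  expect_true(all(diff(n_bins) <= 0))
  ## relative mode: at a 20% relative deficit 0.25 > 0.28 * 0.8 fails
  ## while 0.15 <= 0.224 passes
  expect_equal(nrow(differential_bins(wt, mut_no, delta = 0.20,
                                      relative = TRUE)), 0L)
  expect_equal(nrow(differential_bins(wt, mut_yes, delta = 0.20,
                                      relative = TRUE)), 2L)
})

test_that("differential bins merge by single linkage within 200 bp", {
  mk_bins <- function(starts) {
    tibble::tibble(chrom = "chr1", start = as.integer(starts),
                   end = as.integer(starts + 100), wt_mean = 0.3,
                   mut_mean = 0.1, wt_min = 0.3, mut_max = 0.1, delta = 0.2)
  }
  ## bins [0,100) and [200,300): gap 100 <= 200 -> one DMR [0,300)
  one <- merge_dmrs(mk_bins(c(0, 200)))
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$start, one$end), c(0L, 300L))
  ## gap 300 -> two DMRs
  two <- merge_dmrs(mk_bins(c(0, 400)))
  expect_equal(nrow(two), 2L)
  ## a single bin is its own DMR
  solo <- merge_dmrs(mk_bins(0))
  expect_equal(c(solo$start, solo$end, solo$n_bins), c(0L, 100L, 1L))
  ## chains merge transitively but never across chromosomes
  chain <- mk_bins(c(0, 200, 400))
  expect_equal(nrow(merge_dmrs(chain)), 1L)
  chain2 <- dplyr::mutate(chain, chrom = c("chr1", "chr1", "chr2"))
  expect_equal(nrow(merge_dmrs(chain2)), 2L)
})

test_that("seeded RdDM loci are recovered with high sensitivity and a clean null", {
  genome <- simulate_genome(50000, seed = 301)
  loci <- simulate_loci(genome, n = 10, width = c(300, 300), seed = 302)
  mp <- methylome_params()  # gain 0.25, retention 0.1, coverage 20, 2 reps
  calls <- simulate_methylome(genome, loci, c("WT", "ago4"), mp, seed = 303)
  dmrs <- call_dmrs(calls)
  hit <- vapply(seq_len(nrow(loci)), function(i) {
    any(dmrs$chrom == loci$chrom[i] & dmrs$start < loci$end[i] &
          dmrs$end > loci$start[i])
  }, TRUE)
  expect_gte(mean(hit), 0.9)
  ## DMRs stay at the seeded loci
  expect_true(all(vapply(seq_len(nrow(dmrs)), function(i) {
    any(loci$chrom == dmrs$chrom[i] & loci$start < dmrs$end[i] &
          loci$end > dmrs$start[i])
  }, TRUE)))
  ## the pooled DMR rates reflect the simulated gain and retention
  expect_equal(mean(dmrs$wt_rate), 0.28, tolerance = 0.1)
  expect_equal(mean(dmrs$mut_rate), 0.055, tolerance = 0.3)

  ## null control across several seeds: identical genotypes give no DMRs
  mp_null <- methylome_params(mutant_retention = 1, sd_retention = 1)
  for (s in 311:313) {
    null_calls <- simulate_methylome(genome, loci, c("WT", "ago4"), mp_null,
                                     seed = s)
    expect_equal(nrow(call_dmrs(null_calls)), 0L)
  }
})

test_that("DMR-siRNA association recovers the simulated coupling", {
  genome <- simulate_genome(80000, seed = 321)
  loci <- simulate_loci(genome, n = 16, width = c(300, 300), seed = 322)
  ## couple methylation gain to siRNA expression
  loci$expression_weight <- rep(c(0.2, 2), 8)
  loci$gain_scale <- loci$expression_weight / 2
  calls <- simulate_methylome(genome, loci, c("WT", "ago4"),
                              methylome_params(), seed = 323)
  reads <- simulate_sirna_library(genome, loci, "WT",
                                  duplexes_per_locus = 40, seed = 324)
  dmrs <- call_dmrs(calls)
  expect_gt(nrow(dmrs), 3)
  assoc <- dmr_sirna_association(dmrs, reads)
  expect_gt(assoc$estimate, 0.5)

  ## two points give |r| = 1; constant methylation is undefined
  two <- structure(tibble::tibble(
    chrom = "chr1", start = c(0L, 1000L), end = c(100L, 1100L),
    n_bins = 1L, wt_rate = c(0.1, 0.3), mut_rate = 0.05,
    mean_delta = c(0.05, 0.25)), class = c("dmr", class(tibble::tibble())))
  r2 <- mk_reads("chr1", c(10, 1010), 24, "+", count = c(1L, 50L))
  expect_equal(abs(dmr_sirna_association(two, r2)$estimate), 1)
  const <- dplyr::mutate(two, wt_rate = 0.3)
  class(const) <- class(two)
  expect_true(is.na(dmr_sirna_association(const, r2)$estimate))
})
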