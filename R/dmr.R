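## Windowed bisulfite differential methylation.
##
## Procedure: bin the genome into fixed non-sliding 100-nt windows from
## coordinate 0 (half-open), pool both strands, compute per-context rates
## as summed methylated reads over summed total reads; keep bins with at
## least `min_cytosines` cytosines each covered by >= `min_cov` reads in
## every library; a bin is differential when every mutant replicate is at
## least `delta` (10 percentage points) below every wild-type replicate;
## merge differential bins within `max_gap` (200 bp) by single linkage.

#' Per-window methylation rates
#'
#' Pools calls into fixed `window`-nt tiles (half-open, from coordinate
#' 0), both strands together, one row per window x context. The rate is
#' the coverage-weighted pool Σmeth / Σtotal over the window's cytosines
#' meeting the coverage filter.
#'
#' @param calls Methylation call tibble (`chrom`, `pos`, `strand`,
#'   `context`, `meth`, `total`).
#' @param window Window size in nt; default 100.
#' @param min_cov Per-cytosine coverage below which a cytosine is excluded
#'   from the pooled rate (and counted only in `n_cytosines`); default 4.
#' @return Tibble with `chrom`, `start`, `end`, `context`, `n_cytosines`,
#'   `n_cytosines_cov`, `meth_sum`, `total_sum`, `rate` (`NA` when no
#'   cytosine passes the filter).
#' @export
window_rates <- function(calls, window = 100L, min_cov = 4L) {
  calls %>%
    mutate(start = (.data$pos %/% window) * as.integer(window),
           covered = .data$total >= min_cov) %>%
    group_by(.data$chrom, .data$start, .data$context) %>%
    summarise(
      n_cytosines = n(),
      n_cytosines_cov = sum(.data$covered),
      meth_sum = sum(.data$meth[.data$covered]),
      total_sum = sum(.data$total[.data$covered]),
      .groups = "drop") %>%
    mutate(end = .data$start + as.integer(window),
           rate = if_else(.data$total_sum > 0,
                          .data$meth_sum / .data$total_sum, NA_real_)) %>%
    select("chrom", "start", "end", "context", "n_cytosines",
           "n_cytosines_cov", "meth_sum", "total_sum", "rate")
}

#' Coverage-qualified bins
#'
#' Keeps windows of the requested context having at least `min_cytosines`
#' cytosines each covered by at least the coverage filter applied in
#' [window_rates()].
#'
#' @param stats A [window_rates()] tibble.
#' @param min_cytosines Minimum number of sufficiently covered cytosines.
#' @param context Methylation context; default CHH.
#' @return Filtered window tibble.
#' @export
qualify_bins <- function(stats, min_cytosines = 4L, context = "CHH") {
  stats %>%
    filter(.data$context == !!context,
           .data$n_cytosines_cov >= min_cytosines)
}

#' Differential bins between genotypes
#'
#' A bin must qualify (per [qualify_bins()]) in every replicate of both
#' genotypes, and is differential when every mutant replicate's rate is at
#' least `delta` below every wild-type replicate's rate (all replicate
#' pairs; with `relative = TRUE` the deficit is `delta` as a fraction of
#' the wild-type rate instead of percentage points).
#'
#' @param wt_reps,mut_reps Lists of [window_rates()] tibbles, one per
#'   replicate (a single tibble is treated as one replicate).
#' @param delta Methylation deficit; default 0.10 (10 percentage points).
#' @param context Methylation context; default CHH.
#' @param min_cytosines Passed to [qualify_bins()].
#' @param relative Interpret `delta` as a relative deficit.
#' @return Tibble of differential bins: `chrom`, `start`, `end`,
#'   per-genotype mean rates (`wt_mean`, `mut_mean`), `wt_min`,
#'   `mut_max`, `delta` (wt_mean - mut_mean); the per-replicate rates are
#'   kept in the attribute `"detail"` (long tibble) for downstream
#'   pooling.
#' @export
differential_bins <- function(wt_reps, mut_reps, delta = 0.10,
                              context = "CHH", min_cytosines = 4L,
                              relative = FALSE) {
  as_rep_list <- function(x) if (is.data.frame(x)) list(x) else x
  wt_reps <- as_rep_list(wt_reps)
  mut_reps <- as_rep_list(mut_reps)
  prep <- function(reps, genotype) {
    bind_rows(lapply(seq_along(reps), function(i) {
      qualify_bins(reps[[i]], min_cytosines, context) %>%
        mutate(genotype = genotype, replicate = i)
    }))
  }
  all_reps <- bind_rows(prep(wt_reps, "WT"), prep(mut_reps, "mut"))
  n_lib <- length(wt_reps) + length(mut_reps)
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  wt_mean = double(), mut_mean = double(),
                  wt_min = double(), mut_max = double(), delta = double())
  if (nrow(all_reps) == 0) return(structure(empty, detail = all_reps))
  summ <- all_reps %>%
    group_by(.data$chrom, .data$start, .data$end) %>%
    filter(n() == n_lib) %>%  # bin qualifies in every library
    summarise(
      wt_mean = mean(.data$rate[.data$genotype == "WT"]),
      mut_mean = mean(.data$rate[.data$genotype == "mut"]),
      wt_min = min(.data$rate[.data$genotype == "WT"]),
      mut_max = max(.data$rate[.data$genotype == "mut"]),
      .groups = "drop") %>%
    mutate(delta = .data$wt_mean - .data$mut_mean)
  diff <- if (relative) {
    filter(summ, .data$mut_max <= .data$wt_min * (1 - !!delta))
  } else {
    filter(summ, .data$mut_max <= .data$wt_min - !!delta)
  }
  detail <- semi_join(all_reps, diff, by = c("chrom", "start", "end"))
  structure(arrange(diff, .data$chrom, .data$start), detail = detail)
}

#' Merge differential bins into DMRs
#'
#' Single-linkage merging of differential bins on the same chromosome
#' whose end-to-start gap is at most `max_gap` (default 200 bp). When the
#' bin table carries the `"detail"` attribute from [differential_bins()],
#' per-genotype rates are re-pooled over member bins from summed counts.
#'
#' @param bins A [differential_bins()] tibble.
#' @param max_gap Maximum genomic gap between merged bins (bp).
#' @return Tibble of class `dmr` with `chrom`, `start`, `end`, `n_bins`,
#'   `wt_rate`, `mut_rate`, `mean_delta`.
#' @export
merge_dmrs <- function(bins, max_gap = 200L) {
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  n_bins = integer(), wt_rate = double(),
                  mut_rate = double(), mean_delta = double())
  if (nrow(bins) == 0) {
    return(structure(empty, class = c("dmr", class(empty))))
  }
  detail <- attr(bins, "detail")
  bins <- arrange(bins, .data$chrom, .data$start)
  new_run <- c(TRUE, bins$chrom[-1] != bins$chrom[-nrow(bins)] |
                 bins$start[-1] - bins$end[-nrow(bins)] > max_gap)
  bins$dmr_id <- cumsum(new_run)
  dmrs <- bins %>%
    group_by(.data$dmr_id) %>%
    summarise(chrom = first(.data$chrom),
              start = min(.data$start), end = max(.data$end),
              n_bins = n(),
              wt_rate = mean(.data$wt_mean),
              mut_rate = mean(.data$mut_mean),
              mean_delta = mean(.data$delta),
              .groups = "drop")
  if (!is.null(detail) && nrow(detail) > 0) {
    pooled <- bins %>%
      select("dmr_id", "chrom", "start") %>%
      inner_join(detail, by = c("chrom", "start")) %>%
      group_by(.data$dmr_id, .data$genotype, .data$replicate) %>%
      summarise(rate = sum(.data$meth_sum) / sum(.data$total_sum),
                .groups = "drop") %>%
      group_by(.data$dmr_id, .data$genotype) %>%
      summarise(rate = mean(.data$rate), .groups = "drop") %>%
      tidyr::pivot_wider(names_from = "genotype", values_from = "rate")
    dmrs <- dmrs %>%
      left_join(pooled, by = "dmr_id") %>%
      mutate(wt_rate = .data$WT, mut_rate = .data$mut,
             mean_delta = .data$WT - .data$mut) %>%
      select(-"WT", -"mut")
  }
  out <- dmrs %>% select(-"dmr_id") %>% arrange(.data$chrom, .data$start)
  structure(out, class = c("dmr", class(out)))
}

#' Call DMRs from per-cytosine methylation calls
#'
#' End-to-end wrapper: [window_rates()] per genotype x replicate,
#' [differential_bins()] and [merge_dmrs()].
#'
#' @param calls Call tibble with `genotype` and `replicate` columns (as
#'   produced by [simulate_methylome()]).
#' @param wt,mut Genotype labels to compare.
#' @param window,min_cov,min_cytosines,delta,context,relative,merge_gap
#'   Parameters of the underlying steps.
#' @return A [merge_dmrs()] tibble.
#' @export
call_dmrs <- function(calls, wt = "WT", mut = "ago4", window = 100L,
                      min_cov = 4L, min_cytosines = 4L, delta = 0.10,
                      context = "CHH", relative = FALSE, merge_gap = 200L) {
  split_reps <- function(gt) {
    sub <- filter(calls, .data$genotype == gt)
    if (nrow(sub) == 0) abort(sprintf("no calls for genotype '%s'", gt))
    lapply(sort(unique(sub$replicate)), function(r) {
      window_rates(filter(sub, .data$replicate == r), window, min_cov)
    })
  }
  bins <- differential_bins(split_reps(wt), split_reps(mut), delta = delta,
                            context = context, min_cytosines = min_cytosines,
                            relative = relative)
  merge_dmrs(bins, max_gap = merge_gap)
}

#' Associate DMRs with siRNA abundance
#'
#' Pairs each DMR's wild-type CHH methylation rate with the RPM of
#' `size`-nt siRNAs overlapping it (via [locus_abundance()] using the
#' DMRs as loci) and reports the Pearson correlation over DMRs.
#'
#' @param dmrs A [merge_dmrs()] tibble.
#' @param reads Small RNA read tibble.
#' @param library_total Library size for RPM; defaults to
#'   `sum(reads$count)`.
#' @param size siRNA size class; default 24.
#' @return A list of class `dmr_association`: `table` (per-DMR rates and
#'   RPM), `estimate` (Pearson r; `NA` when undefined, e.g. constant
#'   methylation), `p_value`, `n`.
#' @export
dmr_sirna_association <- function(dmrs, reads, library_total = NULL,
                                  size = 24L) {
  stopifnot(inherits(dmrs, "dmr"))
  if (is.null(library_total)) library_total <- sum(reads$count)
  loci <- dmrs %>%
    mutate(locus_id = sprintf("DMR%04d", row_number())) %>%
    select("locus_id", "chrom", "start", "end", "wt_rate", "mut_rate")
  ab <- locus_abundance(reads, loci, library_total) %>%
    filter(.data$length == size, .data$locus_id != "unassigned") %>%
    select("locus_id", "rpm")
  table <- loci %>%
    left_join(ab, by = "locus_id") %>%
    mutate(rpm = if_else(is.na(.data$rpm), 0, .data$rpm))
  est <- NA_real_; pv <- NA_real_
  if (nrow(table) >= 3 &&
      stats::sd(table$wt_rate) > 0 && stats::sd(table$rpm) > 0) {
    ct <- cor.test(table$wt_rate, table$rpm, method = "pearson")
    est <- unname(ct$estimate); pv <- ct$p.value
  } else if (nrow(table) == 2 &&
             stats::sd(table$wt_rate) > 0 && stats::sd(table$rpm) > 0) {
    est <- unname(stats::cor(table$wt_rate, table$rpm))
  }
  structure(list(table = table, estimate = est, p_value = pv,
                 n = nrow(table)),
            class = "dmr_association")
}

#' @export
print.dmr_association <- function(x, ...) {
  cat(sprintf("<dmr_association> %d DMRs; Pearson r = %s\n", x$n,
              ifelse(is.na(x$estimate), "undefined",
                     sprintf("%.3f", x$estimate))))
  invisible(x)
}
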