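## End-to-end orchestration: simulate -> profile -> registry -> signatures
## -> DMRs -> summary. One seed controls all randomness; each stage uses a
## seed derived from it so stages can be rerun independently.

#' Build a validated pipeline configuration
#'
#' Assembles all knobs of [run_pipeline()] with defaults matching the
#' package's standard simulation scale (one 200-kb chromosome, 200 siRNA
#' loci of which 20 are RdDM methylation targets, ~50 duplexes per unit
#' expression weight). Unknown keys in any section are rejected.
#'
#' @param seed Master seed; every stage derives its own seed from it.
#' @param out_dir Run directory for outputs.
#' @param genome List: `length`, `gc`, or `path` to an existing FASTA
#'   (then `length`/`gc` are ignored).
#' @param loci List: `n`, `width` (range), `n_rddm` (how many loci get the
#'   methylation gain), or `path` to a BED file.
#' @param library List: `duplexes_per_locus` plus any [biogenesis_params()]
#'   overrides.
#' @param methylome Any [methylome_params()] overrides.
#' @param analysis List: `max_abs_registry`, `u10_min_len`, `dmr` (list of
#'   [call_dmrs()] overrides).
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = "argoslice-run",
                       genome = list(), loci = list(), library = list(),
                       methylome = list(), analysis = list()) {
  take <- function(given, defaults, section) {
    unknown <- setdiff(names(given), names(defaults))
    if (length(unknown) > 0) {
      abort(sprintf("unknown %s config key(s): %s", section,
                    paste(unknown, collapse = ", ")))
    }
    utils::modifyList(defaults, given)
  }
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    genome = take(genome, list(length = 2e5, gc = 0.36, path = NULL), "genome"),
    loci = take(loci, list(n = 200L, width = c(260L, 400L), n_rddm = 20L,
                           path = NULL), "loci"),
    library = take(library, c(list(duplexes_per_locus = 50),
                              unclass(biogenesis_params())), "library"),
    methylome = take(methylome, unclass(methylome_params()), "methylome"),
    analysis = take(analysis, list(max_abs_registry = 30L, u10_min_len = 30L,
                                   dmr = list()), "analysis"))
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match the arguments of
#'   [run_config()].
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  known <- c("seed", "out_dir", "genome", "loci", "library", "methylome",
             "analysis")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  exec(run_config, !!!raw)
}

#' Validate input files
#'
#' Parses each supplied file with the package readers and collects
#' diagnostics instead of stopping at the first problem.
#'
#' @param reads,methylation,loci,genome Optional file paths (reads TSV,
#'   methylation TSV, locus BED, genome FASTA).
#' @return Tibble with `file`, `kind`, `ok`, `message` (record-level
#'   errors name the offending record).
#' @export
validate_inputs <- function(reads = NULL, methylation = NULL, loci = NULL,
                            genome = NULL) {
  check_one <- function(path, kind, reader) {
    if (is.null(path)) return(NULL)
    msg <- "ok"; ok <- TRUE
    if (!file.exists(path)) {
      ok <- FALSE; msg <- "file not found"
    } else {
      res <- tryCatch({ reader(path); NULL }, error = function(e) conditionMessage(e))
      if (!is.null(res)) { ok <- FALSE; msg <- res }
    }
    tibble(file = path, kind = kind, ok = ok, message = msg)
  }
  out <- bind_rows(
    check_one(reads, "reads", read_reads_tsv),
    check_one(methylation, "methylation", read_methylation_tsv),
    check_one(loci, "loci", read_loci_bed),
    check_one(genome, "genome", read_genome_fasta))
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble(file = character(), kind = character(), ok = logical(),
                  message = character())
  }
  out
}

#' Run the full synthetic RdDM analysis pipeline
#'
#' Simulates a genome, siRNA loci, slicing-defective and wild-type AGO4
#' libraries, sliced target fragments and bisulfite methylomes, then runs
#' every analysis stage: size profiles, 23-mer classification,
#' uridylation, 24/23 and 24/24 registry spectra with the
#' randomized-start null, co-5' and position-10 U signatures, DMR calling
#' and DMR-siRNA association. All tables are written under
#' `config$out_dir` together with a checksum manifest and a JSON summary.
#'
#' @param config A [run_config()] list.
#' @return Invisibly, a list with the summary (also written as
#'   `summary.json`) and the in-memory result objects.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  stage <- function(msg) message(sprintf("[argoslice +%.1fs] %s",
                                         as.numeric(Sys.time() - t0, units = "secs"),
                                         msg))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  out <- function(name) file.path(config$out_dir, name)

  stage("genome")
  genome <- if (!is.null(config$genome$path)) {
    if (!file.exists(config$genome$path)) {
      abort(sprintf("genome path not found: %s", config$genome$path))
    }
    read_genome_fasta(config$genome$path)
  } else {
    simulate_genome(config$genome$length, config$genome$gc, seed = seed + 1L)
  }
  write_genome_fasta(genome, out("genome.fa"))

  stage("loci")
  loci <- if (!is.null(config$loci$path)) {
    read_loci_bed(config$loci$path)
  } else {
    simulate_loci(genome, n = config$loci$n, width = config$loci$width,
                  seed = seed + 2L)
  }
  write_loci_bed(loci, out("loci.bed"))

  stage("small RNA libraries")
  bp <- exec(biogenesis_params,
             !!!config$library[setdiff(names(config$library), "duplexes_per_locus")])
  dpl <- config$library$duplexes_per_locus
  duplexes <- simulate_duplexes(genome, loci, bp, dpl, seed = seed + 3L)
  sd_lib <- mature_library(duplexes, "SD", bp, seed = seed + 4L)
  wt_lib <- mature_library(duplexes, "WT", bp, seed = seed + 4L)
  write_reads_tsv(sd_lib, out("reads_SD.tsv"))
  write_reads_tsv(wt_lib, out("reads_WT.tsv"))

  stage("profiles")
  sizes_sd <- size_distribution(sd_lib)
  sizes_wt <- size_distribution(wt_lib)
  readr::write_tsv(mutate(sizes_sd, library = "SD") %>%
                     bind_rows(mutate(sizes_wt, library = "WT")),
                   out("size_distributions.tsv"))
  cls_sd <- classify_23mers(sd_lib)
  cls_wt <- classify_23mers(wt_lib)
  urid_wt <- detect_uridylation(wt_lib)
  abundance <- locus_abundance(wt_lib, loci)
  readr::write_tsv(abundance, out("locus_abundance_WT.tsv"))

  stage("registry spectra")
  mar <- config$analysis$max_abs_registry
  spec_2423 <- registry_spectrum(sd_lib, c(24L, 23L), mar)
  spec_2424 <- registry_spectrum(sd_lib, c(24L, 24L), mar)
  null_lib <- simulate_null(sd_lib, loci, seed = seed + 5L)
  null_2423 <- registry_spectrum(null_lib, c(24L, 23L), mar)
  enrich <- mode_enrichment(spec_2423, null_2423)
  readr::write_tsv(tidy(spec_2423), out("registry_24_23.tsv"))
  readr::write_tsv(tidy(spec_2424), out("registry_24_24.tsv"))
  readr::write_tsv(tidy(null_2423), out("registry_24_23_null.tsv"))

  stage("slicing signatures")
  co5 <- co5prime(wt_lib, sd_lib, wt_lib)
  guides <- filter(wt_lib, .data$origin == "guide24")
  frags_wt <- transcribe_and_slice_targets(genome, loci, guides,
                                           min_len = config$analysis$u10_min_len,
                                           slicing = TRUE)
  frags_sd <- transcribe_and_slice_targets(genome, loci, guides,
                                           min_len = config$analysis$u10_min_len,
                                           slicing = FALSE, seed = seed + 6L)
  u10_wt <- u10_signature(filter(frags_wt, .data$side == "3p"),
                          config$analysis$u10_min_len)
  u10_sd <- u10_signature(frags_sd, config$analysis$u10_min_len)
  readr::write_tsv(u10_wt$matrix, out("u10_matrix_WT.tsv"))
  readr::write_tsv(u10_sd$matrix, out("u10_matrix_SD.tsv"))

  stage("methylome and DMRs")
  mp <- exec(methylome_params, !!!config$methylome)
  n_rddm <- min(config$loci$n_rddm, nrow(loci))
  rddm_loci <- loci %>%
    slice_max(.data$expression_weight, n = n_rddm, with_ties = FALSE) %>%
    mutate(gain_scale = pmin(.data$expression_weight, 1.5))
  calls <- simulate_methylome(genome, rddm_loci, c("WT", "ago4"), mp,
                              seed = seed + 7L)
  write_methylation_tsv(calls, out("methylation_calls.tsv"))
  dmrs <- exec(call_dmrs, calls, !!!config$analysis$dmr)
  readr::write_tsv(dmrs, out("dmrs.tsv"))
  assoc <- dmr_sirna_association(dmrs, wt_lib)

  summary <- list(
    seed = seed,
    n_loci = nrow(loci),
    library_counts = list(SD = sum(sd_lib$count), WT = sum(wt_lib$count)),
    modal_registry_24_23 = if (nrow(spec_2423) > 0) {
      spec_2423$registry[which.max(spec_2423$n_pairs)]
    } else NA,
    modal_registry_24_24 = if (nrow(spec_2424) > 0) {
      spec_2424$registry[which.max(spec_2424$n_pairs)]
    } else NA,
    null_mode_enrichment = enrich$enrichment,
    co5_fraction = co5$fraction,
    co5_fraction_at_cut = co5$fraction_at_cut,
    u10_peak_position_WT = u10_wt$peak_position,
    u10_peak_excess_WT = u10_wt$peak_excess,
    u10_peak_excess_SD = u10_sd$peak_excess,
    classify_SD = as.list(cls_sd),
    classify_WT = as.list(cls_wt),
    uridylation_fraction_WT = urid_wt$fraction,
    n_dmrs = nrow(dmrs),
    dmr_sirna_pearson = assoc$estimate)
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")

  files <- setdiff(list.files(config$out_dir, full.names = TRUE),
                   out("manifest.json"))
  manifest <- tibble(file = basename(files),
                     md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, out("manifest.json"), pretty = TRUE)
  stage("done")

  invisible(list(summary = summary, genome = genome, loci = loci,
                 sd_lib = sd_lib, wt_lib = wt_lib,
                 spectra = list(r24_23 = spec_2423, r24_24 = spec_2424,
                                null_24_23 = null_2423),
                 co5 = co5, u10 = list(WT = u10_wt, SD = u10_sd),
                 dmrs = dmrs, association = assoc))
}
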