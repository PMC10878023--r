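# End-to-end screen: run every confound analysis from files on disk.

#' Run the full genetic-confound screen on a dataset directory
#'
#' Consumes the file layout written by [simulate_dataset()] (or any
#' directory with the same pieces): reference FASTA, joint two-clone VCF,
#' two coverage TSVs, CNV and SV call tables, a methylation sample sheet
#' and beta matrix. Runs hard filtering, clone-unique INDEL definition in
#' both directions, differential-genotype and allele-frequency drift
#' screens, the off-target scan and INDEL enrichment test, binned-depth
#' CNV screening with call concordance, translocation filtering, and
#' matched-pair methylation tests.
#'
#' @param paths Named list of file paths (`fasta`, `vcf`, `coverage_a`,
#'   `coverage_b`, `cnv_a`, `cnv_b`, `sv_a`, `sv_b`, `sample_sheet`,
#'   `beta`).
#' @param guide A [guide_spec()] for the off-target scan.
#' @param clone_a,clone_b Sample names in the VCF (edited clone first).
#' @param seed Integer seed for the enrichment resampling.
#' @param categories Off-target categories for the enrichment test.
#' @param region_pad Padding added around site footprints when counting
#'   INDELs in off-target regions (default 100 bp).
#' @param flag_threshold Bin percent-change flag threshold (default 50).
#' @param max_age_diff Methylation pairing age cutoff in days (default 60).
#' @return Nested list of results per analysis stage.
#' @export
confound_screen <- function(paths, guide, clone_a = "HR1ex",
                            clone_b = "WT", seed = 1L,
                            categories = offtarget_categories(
                              mismatches = 4:7, pam = c("NGG", "NRG"),
                              bulge = c("none", "bulge")),
                            region_pad = 100L, flag_threshold = 50,
                            max_age_diff = 60) {
  genome <- read_fasta(paths$fasta)
  raw_a <- read_vcf(paths$vcf, clone_a)
  raw_b <- read_vcf(paths$vcf, clone_b)
  filt_a <- apply_hard_filters(raw_a)
  filt_b <- apply_hard_filters(raw_b)
  cov_a <- read_coverage(paths$coverage_a)
  cov_b <- read_coverage(paths$coverage_b)

  unique_a <- clone_unique_indels(filt_a, filt_b, cov_b,
                                  callset_b_unfiltered = raw_b)
  unique_b <- clone_unique_indels(filt_b, filt_a, cov_a,
                                  callset_b_unfiltered = raw_a)
  diff_10 <- differential_biallelic_snvs(filt_a, filt_b, min_depth = 10L,
                                         coverage_a = cov_a,
                                         coverage_b = cov_b)
  diff_20 <- differential_biallelic_snvs(filt_a, filt_b, min_depth = 20L,
                                         coverage_a = cov_a,
                                         coverage_b = cov_b)
  drift <- allele_frequency_drift(filt_a, filt_b, min_depth = 20L,
                                  delta_threshold = 0.5)

  sites <- find_offtarget_sites(genome, guide)
  cats <- categorize_sites(sites, categories)
  wt_indels_df <- as.data.frame(filt_b)
  wt_indels <- clone_callset(
    wt_indels_df[wt_indels_df$vtype == "INDEL" &
                   has_alt_evidence(wt_indels_df), , drop = FALSE],
    clone_id(filt_b))
  enrichment <- run_enrichment(unique_a, wt_indels, cats, genome,
                               seed = seed, pad = region_pad)

  bins <- make_bins(genome)
  bins_a <- bin_mean_depth(bins, cov_a)
  bins_b <- bin_mean_depth(bins, cov_b)
  cmp <- compare_bins(bins_a, bins_b, flag_threshold = flag_threshold)
  flagged <- cmp[cmp$flagged, , drop = FALSE]
  chrom_summary <- chromosome_depth_summary(cov_a, genome)

  calls_a <- read_interval_table(paths$cnv_a, dialect = "cnv")
  calls_b <- read_interval_table(paths$cnv_b, dialect = "cnv")
  uniq_cnv_a <- unique_cnvs(calls_a, calls_b)
  concordance <- cnv_bin_concordance(flagged, uniq_cnv_a)
  sv_a <- read_interval_table(paths$sv_a, dialect = "sv")
  sv_b <- read_interval_table(paths$sv_b, dialect = "sv")
  sv_unique <- filter_translocations(sv_a, sv_b)

  meta <- read_sample_sheet(paths$sample_sheet)
  beta <- read_beta_matrix(paths$beta)
  pairs <- build_matched_pairs(meta, max_age_diff = max_age_diff)
  meth_tests <- per_tissue_tests(beta, pairs)

  list(
    callsets = list(raw_a = raw_a, raw_b = raw_b, filtered_a = filt_a,
                    filtered_b = filt_b),
    unique_indels = list(a = unique_a, b = unique_b),
    differential = list(depth10 = diff_10, depth20 = diff_20),
    drift = drift,
    offtargets = list(sites = sites, categories = cats),
    enrichment = enrichment,
    coverage = list(comparison = cmp, flagged = flagged,
                    chromosomes = chrom_summary),
    cnv = list(calls_a = calls_a, calls_b = calls_b,
               unique_a = uniq_cnv_a, concordance = concordance),
    sv = list(unique_supported = sv_unique),
    methylation = list(pairs = pairs, tests = meth_tests,
                       pair_summary = attr(pairs, "summary"))
  )
}

#' Simulate a dataset and screen it in one call
#'
#' @param dir Output directory for the simulated files.
#' @param seed Integer seed driving both simulation and analysis
#'   resampling.
#' @param params Simulation parameters ([default_sim_params()]).
#' @param ... Passed to [confound_screen()].
#' @return List with `dataset` (simulation objects) and `results`
#'   (screen output).
#' @export
run_pipeline <- function(dir, seed, params = default_sim_params(), ...) {
  ds <- simulate_dataset(dir, seed, params)
  res <- confound_screen(ds$paths, ds$guide, clone_a = params$clone_a,
                         clone_b = params$clone_b,
                         seed = sub_seed(seed, 99L),
                         region_pad = params$region_flank, ...)
  list(dataset = ds, results = res)
}
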