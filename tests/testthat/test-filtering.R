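test_that("hard filters apply the per-type thresholds strictly", {
  # SNV fails on FS > 60 while the same FS passes for an INDEL (cutoff 200)
  snv_fs <- callset_of(rec(pos = 10L, FS = 61.0, QD = 20, MQ = 55,
                           SOR = 1, MQRankSum = 0, ReadPosRankSum = 0))
  expect_identical(nrow(apply_hard_filters(snv_fs)), 0L)
  indel_fs <- callset_of(rec(pos = 10L, ref = "AT", alt = "A", FS = 61.0,
                             QD = 20, ReadPosRankSum = 0))
  expect_identical(nrow(apply_hard_filters(indel_fs)), 1L)
})

test_that("records with absent statistics pass those tests", {
  cs <- callset_of(rec(pos = 5L))         # all six statistics NA
  expect_identical(nrow(apply_hard_filters(cs)), 1L)
  # but a present violation still removes the record
  cs2 <- callset_of(rec(pos = 5L, MQ = 39.9))
  expect_identical(nrow(apply_hard_filters(cs2)), 0L)
})

test_that("an 8-record set with 3 single-threshold violations keeps 5", {
  cs <- callset_of(
    rec(pos = 10L, FS = 2, QD = 25, MQ = 58, SOR = 1, MQRankSum = 0,
        ReadPosRankSum = 0),                                   # pass SNV
    rec(pos = 20L, QD = 1.5, FS = 2, MQ = 58, SOR = 1, MQRankSum = 0,
        ReadPosRankSum = 0),                                   # fail QD
    rec(pos = 30L, ref = "G", alt = "GTT", FS = 10,
        ReadPosRankSum = -1),                                  # pass INDEL
    rec(pos = 40L, ref = "GAA", alt = "G", FS = 250,
        ReadPosRankSum = -1),                                  # fail FS
    rec(pos = 50L, SOR = 1, FS = 1, QD = 20, MQ = 50, MQRankSum = -2,
        ReadPosRankSum = -2),                                  # pass SNV
    rec(pos = 60L, qual = 10),                                 # fail QUAL
    rec(pos = 70L, ref = "T", alt = "TAC", ReadPosRankSum = -19.9), # pass
    rec(pos = 80L, MQ = 55, FS = 3, QD = 18, SOR = 2.9, MQRankSum = -12,
        ReadPosRankSum = -7.9))                                # pass SNV
  filt <- apply_hard_filters(cs)
  expect_identical(nrow(filt), 5L)
  expect_setequal(filt$pos, c(10L, 30L, 50L, 70L, 80L))
  expect_identical(attr(filt, "n_removed"), 3L)
})

test_that("records strictly inside all thresholds always pass", {
  set.seed(42)
  n <- 200L
  cs <- clone_callset(do.call(rbind, lapply(seq_len(n), function(i) {
    if (i %% 2L) {
      rec(pos = i * 10L, FS = runif(1, 0, 59.9), QD = runif(1, 2.1, 35),
          MQ = runif(1, 40.1, 60), SOR = runif(1, 0, 2.9),
          MQRankSum = runif(1, -12.4, 5),
          ReadPosRankSum = runif(1, -7.9, 5), qual = runif(1, 30.1, 3000))
    } else {
      rec(pos = i * 10L, ref = "AT", alt = "A", FS = runif(1, 0, 199),
          QD = runif(1, 2.1, 35), ReadPosRankSum = runif(1, -19.9, 5),
          qual = runif(1, 30.1, 3000))
    }
  })), "A")
  expect_identical(nrow(apply_hard_filters(cs)), n)
})

test_that("allele frequency is alt reads over depth", {
  cs <- callset_of(rec(pos = 1L, depth = 20L, alt_reads = 8L),
                   rec(pos = 2L, depth = 30L, alt_reads = 0L),
                   rec(pos = 3L, depth = 12L, alt_reads = 12L),
                   rec(pos = 4L, depth = 0L, alt_reads = 0L))
  expect_equal(allele_frequency(cs), c(0.4, 0, 1, NA))
})

test_that("INDEL left-alignment shifts representation-fragile alleles", {
  # c1: positions 1..12 = ACGTTTTTTGCA; a deletion of one T can be written
  # at any T; the canonical form anchors at the first T (pos 4)
  g <- genome_sequence(c(c1 = "ACGTTTTTTGCA"))
  cs <- callset_of(rec(pos = 8L, ref = "TT", alt = "T"))
  norm <- normalize_variants(cs, g)
  expect_identical(norm$pos, 3L)
  expect_identical(norm$ref, "GT")
  expect_identical(norm$alt, "G")
  # the same deletion written at another T collapses to the same form
  cs_alt <- callset_of(rec(pos = 5L, ref = "TT", alt = "T"))
  expect_identical(as.data.frame(normalize_variants(cs_alt, g)),
                   as.data.frame(norm))
  # shared leading bases beyond the anchor are trimmed
  cs2 <- callset_of(rec(pos = 1L, ref = "ACGT", alt = "ACG"))
  norm2 <- normalize_variants(cs2, g)
  expect_identical(norm2$pos, 3L)
  expect_identical(norm2$ref, "GT")
  expect_identical(norm2$alt, "G")
  # SNVs are untouched
  cs3 <- callset_of(rec(pos = 5L, ref = "T", alt = "A"))
  expect_identical(normalize_variants(cs3, g)$pos, 5L)
})

test_that("clone-unique INDELs honour overlap, coverage and alt evidence", {
  a <- callset_of(rec(pos = 100L, ref = "ATTT", alt = "A"),
                  rec(pos = 300L, ref = "G", alt = "GAC"),
                  rec(pos = 500L, ref = "CTT", alt = "C"),
                  rec(pos = 700L, ref = "T", alt = "TG"), clone = "A")
  # B has an overlapping INDEL at 101, an unfiltered SNV with alt reads at
  # 300, and nothing at 500/700
  b <- callset_of(rec(pos = 101L, ref = "TT", alt = "T"), clone = "B")
  b_unf <- callset_of(rec(pos = 101L, ref = "TT", alt = "T"),
                      rec(pos = 300L, ref = "G", alt = "C", gt = "0/0",
                          alt_reads = 2L), clone = "B")
  cov_b <- flat_coverage(c(c1 = 1000L), depth = 30L)
  cov_b$depth[cov_b$pos == 501L] <- 9L     # one low base inside 500..502
  u <- clone_unique_indels(a, b, cov_b, min_depth = 10L,
                           callset_b_unfiltered = b_unf)
  expect_identical(u$pos, 700L)
  expect_identical(attr(u, "n_overlap_b"), 1L)
  expect_identical(attr(u, "n_low_coverage"), 1L)

  # depth 10 across the span is sufficient (boundary 9 vs 10)
  cov_b10 <- flat_coverage(c(c1 = 1000L), depth = 10L)
  u10 <- clone_unique_indels(a, b, cov_b10, min_depth = 10L,
                             callset_b_unfiltered = b_unf)
  expect_setequal(u10$pos, c(500L, 700L))

  # positions absent from the coverage track are tallied, not crashed
  cov_trunc <- cov_b[cov_b$pos <= 600L, ]
  utr <- clone_unique_indels(a, b, cov_trunc, min_depth = 10L,
                             callset_b_unfiltered = b_unf)
  expect_identical(nrow(utr), 0L)
  expect_identical(attr(utr, "n_coverage_unavailable"), 1L)
})

test_that("unique INDELs partition against shared on synthetic callsets", {
  g <- make_genome(3, c(c1 = 150000L, c2 = 150000L))
  p <- default_sim_params(n_shared_snv = 100L, n_shared_indel = 50L,
                          n_unique_indel_a = 20L, n_unique_indel_b = 15L,
                          n_diff_geno = 0L, n_drift = 0L, fail_frac = 0,
                          enrichment_factor = 1.0)
  sim <- simulate_clone_callsets(g, NULL, seed = 11, params = p)
  cs <- sim_callsets(sim)
  cov <- flat_coverage(chrom_lengths(g), depth = 30L)
  ua <- clone_unique_indels(cs[[1]], cs[[2]], cov)
  ub <- clone_unique_indels(cs[[2]], cs[[1]], cov)
  expect_identical(nrow(ua), 20L)
  expect_identical(nrow(ub), 15L)
  expect_setequal(paste(ua$chrom, ua$pos),
                  paste(sim$truth$unique_a$chrom, sim$truth$unique_a$pos))
  # shared INDELs are exactly the rest of either clone's INDEL calls
  n_indels_a <- sum(cs[[1]]$vtype == "INDEL" &
                      cs[[1]]$gt != "0/0")
  expect_identical(n_indels_a - nrow(ua), 50L)
})

test_that("differential biallelic genotypes compare depth and genotype", {
  a <- callset_of(rec(pos = 100L, gt = "0/1", depth = 25L),
                  rec(pos = 200L, gt = "0/1", depth = 25L),
                  rec(pos = 300L, gt = "0/1", depth = 8L, alt_reads = 4L),
                  clone = "A")
  b <- callset_of(rec(pos = 100L, gt = "1/1", depth = 25L,
                      alt_reads = 25L),
                  rec(pos = 200L, gt = "0/1", depth = 25L),
                  rec(pos = 300L, gt = "1/1", depth = 30L,
                      alt_reads = 30L), clone = "B")
  d <- differential_biallelic_snvs(a, b, min_depth = 10L)
  expect_identical(d$pos, 100L)            # 200 same gt; 300 depth_a too low
  expect_identical(d$gt_a, "0/1")
  expect_identical(d$gt_b, "1/1")
})

test_that("one-sided sites use implied reference genotypes with coverage", {
  a <- callset_of(rec(pos = 150L, gt = "0/1", depth = 30L), clone = "A")
  b <- clone_callset(rec(pos = 999L, gt = "0/1", depth = 30L)[0, ], "B")
  cov_b <- flat_coverage(c(c1 = 1000L), depth = 25L)
  d <- differential_biallelic_snvs(a, b, min_depth = 10L,
                                   coverage_b = cov_b)
  expect_identical(nrow(d), 1L)
  expect_identical(d$gt_b, "0/0")
  expect_identical(d$depth_b, 25L)
  # excluded when the flag is off, or when coverage is below the cutoff
  expect_identical(nrow(differential_biallelic_snvs(
    a, b, min_depth = 10L, coverage_b = cov_b,
    include_implied_ref = FALSE)), 0L)
  expect_identical(nrow(differential_biallelic_snvs(
    a, b, min_depth = 30L, coverage_b = cov_b)), 0L)
})

test_that("planted differential genotypes are recovered exactly", {
  g <- make_genome(8, c(c1 = 200000L))
  p <- default_sim_params(n_shared_snv = 300L, n_shared_indel = 0L,
                          n_unique_indel_a = 0L, n_unique_indel_b = 0L,
                          n_diff_geno = 100L, n_drift = 20L, fail_frac = 0)
  sim <- simulate_clone_callsets(g, NULL, seed = 19, params = p)
  cs <- sim_callsets(sim)
  d20 <- differential_biallelic_snvs(cs[[1]], cs[[2]], min_depth = 20L)
  expect_identical(nrow(d20), 100L)
  d50 <- differential_biallelic_snvs(cs[[1]], cs[[2]], min_depth = 50L)
  expect_lt(nrow(d50), 100L)
  d10 <- differential_biallelic_snvs(cs[[1]], cs[[2]], min_depth = 10L)
  expect_gte(nrow(d10), nrow(d20))
})

test_that("allele-frequency drift screens by depth and absolute change", {
  a <- callset_of(rec(pos = 100L, depth = 40L, alt_reads = 38L),  # 0.95
                  rec(pos = 200L, depth = 40L, alt_reads = 24L),  # 0.60
                  clone = "A")
  b <- callset_of(rec(pos = 100L, depth = 40L, alt_reads = 2L),   # 0.05
                  rec(pos = 200L, depth = 40L, alt_reads = 16L),  # 0.40
                  clone = "B")
  dr <- allele_frequency_drift(a, b, min_depth = 20L,
                               delta_threshold = 0.5)
  expect_identical(dr$pos, 100L)
  expect_equal(dr$delta, 0.9)
  expect_equal(dr$af_a, 0.95)
  expect_equal(dr$af_b, 0.05)
  # delta invariant within numerical tolerance
  expect_equal(dr$delta, abs(dr$af_a - dr$af_b), tolerance = 1e-12)
})

test_that("planted drift sites are recovered exactly among stable ones", {
  g <- make_genome(4, c(c1 = 300000L))
  p <- default_sim_params(n_shared_snv = 2000L, n_shared_indel = 0L,
                          n_unique_indel_a = 0L, n_unique_indel_b = 0L,
                          n_diff_geno = 0L, n_drift = 30L, fail_frac = 0)
  sim <- simulate_clone_callsets(g, NULL, seed = 29, params = p)
  cs <- sim_callsets(sim)
  dr <- allele_frequency_drift(cs[[1]], cs[[2]], min_depth = 20L,
                               delta_threshold = 0.5)
  expect_identical(nrow(dr), 30L)
  expect_setequal(paste(dr$chrom, dr$pos),
                  paste(sim$truth$drift$chrom, sim$truth$drift$pos))
  # counts are non-increasing in both the depth and change thresholds
  expect_lte(nrow(allele_frequency_drift(cs[[1]], cs[[2]], 30L, 0.5)),
             nrow(dr))
  expect_lte(nrow(allele_frequency_drift(cs[[1]], cs[[2]], 20L, 0.7)),
             nrow(dr))
})

test_that("variant counts per gene set follow overlap semantics", {
  genes <- data.frame(chrom = "c1",
                      start = c(1000L, 3000L, 5000L, 7000L),
                      end = c(2000L, 4000L, 6000L, 8000L),
                      label = c("gA", "gB", "gC", "gD"))
  cs <- callset_of(
    rec(pos = 1500L), rec(pos = 1600L), rec(pos = 1999L),
    rec(pos = 998L, ref = "AGCT", alt = "A"),   # spans into gA by 1 bp
    rec(pos = 3500L), rec(pos = 3600L),
    rec(pos = 2500L), rec(pos = 2600L),         # outside all genes
    rec(pos = 5001L), rec(pos = 5500L), rec(pos = 6000L),
    rec(pos = 6500L))
  counts <- count_variants_in_genesets(cs, genes)
  expect_identical(counts[["gA"]], 4L)
  expect_identical(counts[["gB"]], 2L)
  # 0-based [5000,6000) covers 1-based 5001..6000
  expect_identical(counts[["gC"]], 3L)
  expect_identical(counts[["gD"]], 0L)
})
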