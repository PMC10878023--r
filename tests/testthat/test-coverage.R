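test_that("bins tile each chromosome with a truncated terminal bin", {
  g <- make_genome(3, c(cA = 120000L))
  b <- make_bins(g, bin_size = 50000L)
  expect_identical(b$start, c(0L, 50000L, 100000L))
  expect_identical(b$end, c(50000L, 100000L, 120000L))
  expect_false(any(b$masked))
})

test_that("N masking uses the strict >100 rule (100 vs 101 boundary)", {
  seqs <- c(cN = paste0(paste(rep("A", 100), collapse = ""),
                        paste(rep("N", 101), collapse = ""),
                        paste(rep("C", 99), collapse = ""),
                        paste(rep("N", 100), collapse = ""),
                        paste(rep("G", 200), collapse = "")))
  g <- genome_sequence(seqs)
  b <- make_bins(g, bin_size = 300L)
  expect_identical(b$n_bases, c(101L, 100L))
  expect_identical(b$masked, c(TRUE, FALSE))
})

test_that("bin means average over the full width with absent positions as 0", {
  g <- make_genome(5, c(c1 = 1000L))
  bins <- make_bins(g, bin_size = 500L)
  cov <- flat_coverage(c(c1 = 1000L), depth = 30L)
  full <- bin_mean_depth(bins, cov)
  expect_equal(full$mean_depth, c(30, 30))
  # depth 30 over the first half of bin 1 only
  half <- cov[cov$pos <= 250L, ]
  expect_equal(bin_mean_depth(bins, half)$mean_depth, c(15, 0))
})

test_that("coverage mass is conserved across bins per chromosome", {
  g <- make_genome(7, c(c1 = 120000L, c2 = 70000L))
  cov <- simulate_coverage(g, NULL, seed = 3, mean_depth = 20)
  bins <- bin_mean_depth(make_bins(g, 50000L), cov)
  for (ch in c("c1", "c2")) {
    mass_bins <- sum(bins$mean_depth[bins$chrom == ch] *
                       (bins$end - bins$start)[bins$chrom == ch])
    expect_equal(mass_bins, sum(cov$depth[cov$chrom == ch]))
  }
})

test_that("percent change reproduces the worked depth comparison", {
  g <- make_genome(5, c(c1 = 1000L))
  skel <- make_bins(g, bin_size = 1000L)
  a <- skel; a$mean_depth <- 13.1
  b <- skel; b$mean_depth <- 10.0
  cmp <- compare_bins(a, b, normalize = FALSE)
  expect_equal(cmp$pct_change, 31)
  expect_false(cmp$flagged)
  cmp2 <- compare_bins(a, a, normalize = FALSE)
  expect_equal(cmp2$pct_change, 0)
})

test_that("percent change is antisymmetric without normalization", {
  g <- make_genome(11, c(c1 = 200000L))
  cov_a <- simulate_coverage(g, data.frame(chrom = "c1", start = 50000L,
                                           end = 100000L, mult = 0.5),
                             seed = 4, mean_depth = 30)
  cov_b <- simulate_coverage(g, NULL, seed = 5, mean_depth = 30)
  bins <- make_bins(g, 50000L)
  ba <- bin_mean_depth(bins, cov_a)
  bb <- bin_mean_depth(bins, cov_b)
  ab <- compare_bins(ba, bb, normalize = FALSE)
  ba_ <- compare_bins(bb, ba, normalize = FALSE)
  expect_equal(sign(ab$pct_change), -sign(ba_$pct_change))
  # mismatched skeletons are an error
  g2 <- make_genome(11, c(c1 = 150000L))
  expect_error(compare_bins(ba, bin_mean_depth(make_bins(g2, 50000L),
                                               cov_b)),
               "skeletons differ")
})

test_that("a planted heterozygous deletion is flagged with ~-53% change", {
  g <- make_genome(13, c(c1 = 500000L))
  del <- data.frame(chrom = "c1", start = 100000L, end = 150000L,
                    mult = 0.47)
  cov_a <- simulate_coverage(g, del, seed = 21, mean_depth = 30)
  cov_b <- simulate_coverage(g, NULL, seed = 22, mean_depth = 30)
  bins <- make_bins(g, 50000L)
  cmp <- compare_bins(bin_mean_depth(bins, cov_a),
                      bin_mean_depth(bins, cov_b), flag_threshold = 50,
                      normalize = FALSE)
  hit <- cmp[cmp$start == 100000L, ]
  expect_true(hit$flagged)
  expect_equal(hit$pct_change, -53, tolerance = 0.05)
  expect_identical(sum(cmp$flagged), 1L)
  # the deleted bin's depth is ~0.47x baseline (within 2%)
  expect_equal(hit$depth_a / hit$depth_b, 0.47, tolerance = 0.02)
})

test_that("chromosome loss screening flags a 0.5x chromosome", {
  g <- make_genome(9, c(c1 = 100000L, c2 = 100000L, c3 = 100000L))
  cov <- simulate_coverage(g, data.frame(chrom = "c2", start = 0L,
                                         end = 100000L, mult = 0.5),
                           seed = 6, mean_depth = 30)
  s <- chromosome_depth_summary(cov, g)
  expect_identical(s$summary$flagged, c(FALSE, TRUE, FALSE))
  # equal depths: nothing flagged; cumulative profile ends at 1
  cov_eq <- simulate_coverage(g, NULL, seed = 7, mean_depth = 30)
  s_eq <- chromosome_depth_summary(cov_eq, g)
  expect_false(any(s_eq$summary$flagged))
  ends <- tapply(s_eq$profile$cum_frac, s_eq$profile$chrom, function(x) {
    x[length(x)]
  })
  expect_equal(as.numeric(ends), rep(1, 3))
  # empty coverage: warning, all flagged
  empty <- cov_eq[0, ]
  expect_warning(s0 <- chromosome_depth_summary(empty, g), "empty")
  expect_true(all(s0$summary$flagged))
})

test_that("unique CNVs require same-type reciprocal overlap", {
  a1 <- data.frame(chrom = "c1", start = 1000L, end = 2000L,
                   cnv_type = "deletion")
  expect_identical(nrow(unique_cnvs(a1, a1)), 0L)
  b_dup <- a1; b_dup$cnv_type <- "duplication"
  expect_identical(nrow(unique_cnvs(a1, b_dup)), 1L)
  # partial overlap below the reciprocal fraction does not match
  b_shift <- data.frame(chrom = "c1", start = 1800L, end = 2800L,
                        cnv_type = "deletion")
  expect_identical(nrow(unique_cnvs(a1, b_shift, 0.5)), 1L)
  expect_identical(nrow(unique_cnvs(a1, b_shift, 0.2)), 0L)
})

test_that("a 10-vs-8 call fixture with 3 engineered matches leaves 7 unique", {
  mk <- function(starts, types, chrom = "c1") {
    data.frame(chrom = chrom, start = starts, end = starts + 1000L,
               cnv_type = types)
  }
  calls_a <- mk(seq(0L, 90000L, by = 10000L),
                rep(c("deletion", "duplication"), 5))
  calls_b <- rbind(
    mk(c(0L, 20000L, 40000L),
       c("deletion", "deletion", "deletion")),      # matches a1, a3, a5
    mk(c(10200L, 60500L), c("deletion", "duplication")),  # wrong type vs a2/a7
    mk(c(35000L, 55000L, 75000L),
       c("duplication", "duplication", "duplication")))  # elsewhere
  u <- unique_cnvs(calls_a, calls_b, reciprocal_overlap = 0.5)
  expect_identical(nrow(u), 7L)
  expect_false(any(u$start %in% c(0L, 20000L, 40000L)))
})

test_that("flagged-bin concordance counts >=1 bp overlaps", {
  bin <- data.frame(chrom = "c1", start = 50000L, end = 100000L)
  del <- data.frame(chrom = "c1", start = 40000L, end = 120000L,
                    cnv_type = "deletion")
  expect_identical(cnv_bin_concordance(bin, del)[c("n_flagged",
                                                   "n_concordant")],
                   list(n_flagged = 1L, n_concordant = 1L))
  expect_identical(cnv_bin_concordance(bin, del[0, ])$n_concordant, 0L)
})

test_that("translocation filtering keeps supported clone-unique events", {
  sv_a <- data.frame(
    chrom_a = c("c1", "c1", "c2", "c2", "c3", "c3"),
    pos_a = c(10000L, 20000L, 30000L, 40000L, 50000L, 60000L),
    chrom_b = c("c2", "c3", "c1", "c3", "c1", "c2"),
    pos_b = c(15000L, 25000L, 35000L, 45000L, 55000L, 65000L),
    sv_type = "CTX",
    supporting_reads = c(3L, 2L, 5L, 3L, 8L, 4L))
  # candidate 4 is shared with the other clone (breakpoints within 1 kb);
  # candidate 5 appears with swapped breakpoint order
  sv_b <- data.frame(
    chrom_a = c("c2", "c1"), pos_a = c(40400L, 55200L),
    chrom_b = c("c3", "c3"), pos_b = c(45300L, 49800L),
    sv_type = "CTX", supporting_reads = c(6L, 7L))
  kept <- filter_translocations(sv_a, sv_b, min_reads = 2L)
  # candidate 2 has exactly 2 reads (strictly greater required) -> dropped
  expect_setequal(kept$pos_a, c(10000L, 30000L, 60000L))
})
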