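test_that("region counts follow overlap-once semantics and saturate", {
  vars <- callset_of(rec(pos = 100L), rec(pos = 5000L), rec(pos = 9000L))
  regions <- data.frame(chrom = "c1", start = c(50L, 80L),
                        end = c(150L, 120L))   # both cover the first variant
  expect_identical(count_in_regions(vars, regions), 1L)
  whole <- data.frame(chrom = "c1", start = 0L, end = 10000L)
  expect_identical(count_in_regions(vars, whole), 3L)
  expect_identical(count_in_regions(vars[0, ], whole), 0L)
})

test_that("random regions are deterministic, size-matched and in bounds", {
  g <- make_genome(17, c(c1 = 1000L))
  tmpl <- data.frame(chrom = "c1", start = 0L, end = 10L)
  r1 <- sample_random_regions(g, tmpl, seed = 5)
  r2 <- sample_random_regions(g, tmpl, seed = 5)
  expect_identical(r1, r2)
  expect_identical(r1$end - r1$start, 10L)
  expect_gte(r1$start, 0L)
  expect_lte(r1$end, 1000L)
  # width larger than every chromosome is an error
  expect_error(sample_random_regions(
    g, data.frame(chrom = "c1", start = 0L, end = 2000L), seed = 1),
    "wider than every chromosome")
})

test_that("random region starts are uniform across the genome", {
  g <- make_genome(23, c(c1 = 1000L))
  tmpl <- data.frame(chrom = "c1", start = 0L, end = 100L)
  starts <- vapply(1:1000, function(i) {
    sample_random_regions(g, tmpl, seed = i)$start
  }, integer(1))
  # 10 equal slices of the 901 eligible starts
  slice <- cut(starts, breaks = seq(0, 901, length.out = 11),
               include.lowest = TRUE)
  gof <- suppressWarnings(stats::chisq.test(table(slice)))
  expect_gt(gof$p.value, 0.01)
})

test_that("N-heavy draws are rejected and an all-N genome exhausts retries", {
  allN <- genome_sequence(c(c1 = paste(rep("N", 2000), collapse = "")))
  tmpl <- data.frame(chrom = "c1", start = 0L, end = 500L)
  expect_error(sample_random_regions(allN, tmpl, seed = 3, retry_cap = 50L),
               "after 50 attempts")
  # genome with one N-free area: all draws land there
  half <- genome_sequence(c(c1 = paste0(
    paste(rep("N", 1000), collapse = ""),
    paste(rep("A", 1000), collapse = ""))))
  r <- sample_random_regions(half, data.frame(chrom = "c1", start = 0L,
                                              end = c(300L, 300L, 300L)),
                             seed = 9)
  expect_true(all(r$start >= 900L))        # <=100 Ns tolerated per region
})

test_that("WT subsampling saturates at the full set and at zero", {
  wt <- callset_of(rec(pos = 100L), rec(pos = 200L), rec(pos = 5000L),
                   rec(pos = 6000L))
  regions <- data.frame(chrom = "c1", start = 0L, end = 1000L)
  full <- subsample_wt_null(wt, n = 4L, regions, seed = 1)
  expect_identical(full, rep(2L, 5))
  expect_identical(subsample_wt_null(wt, n = 0L, regions, seed = 1),
                   rep(0L, 5))
  expect_error(subsample_wt_null(wt, n = 5L, regions, seed = 1),
               "cannot sample")
})

test_that("WT subsample means track the in-region fraction binomially", {
  set.seed(99)
  n_wt <- 2000L
  pos <- sample.int(100000L, n_wt)
  wt <- clone_callset(do.call(rbind, lapply(pos, function(p) rec(pos = p))),
                      "WT")
  regions <- data.frame(chrom = "c1", start = 0L, end = 20000L)
  f <- mean(pos <= 20000L)
  draws <- subsample_wt_null(wt, n = 500L, regions, seed = 7, draws = 5L)
  expect_lt(abs(mean(draws) - 500 * f), 3 * sqrt(500 * f * (1 - f)))
})

test_that("one-sample t matches the closed form and flags degeneracy", {
  r <- one_sample_t(c(8, 9, 10, 11, 12), 10)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  dg <- one_sample_t(c(10, 10, 10, 10, 10), 10)
  expect_true(dg$degenerate)
  expect_true(is.na(dg$t))
  # hand computation: mean 2.8, sd over the five values, df 4
  nulls <- c(2, 3, 2, 4, 3)
  t_hand <- (mean(nulls) - 9) / (sqrt(sum((nulls - mean(nulls))^2) / 4) /
                                   sqrt(5))
  p_hand <- 2 * pt(-abs(t_hand), df = 4)
  r2 <- one_sample_t(nulls, 9)
  expect_equal(r2$t, t_hand)
  expect_equal(r2$p, p_hand)
  expect_identical(r2$df, 4L)
})

test_that("enrichment saturates when regions cover the whole genome", {
  g <- make_genome(31, c(c1 = 50000L))
  vars <- clone_callset(do.call(rbind, lapply(
    seq(100L, 40000L, by = 400L), function(p) rec(pos = p))), "A")
  wt <- clone_callset(do.call(rbind, lapply(
    seq(150L, 45000L, by = 300L), function(p) rec(pos = p))), "WT")
  cats <- data.frame(mismatches = 0L, pam = "NGG", bulge = "none")
  cats$regions <- list(data.frame(chrom = "c1", start = 0L, end = 50000L))
  res <- run_enrichment(vars, wt, cats, g, seed = 3)
  expect_identical(res$observed, nrow(vars))
  expect_identical(res$random_null[[1]], rep(nrow(vars), 5L))
  expect_identical(res$wt_null[[1]], rep(nrow(vars), 5L))
  expect_true(res$degenerate_random)
})

test_that("an empty category yields a flagged degenerate result", {
  g <- make_genome(31, c(c1 = 10000L))
  vars <- callset_of(rec(pos = 100L))
  cats <- data.frame(mismatches = 5L, pam = "NGG", bulge = "none")
  cats$regions <- list(data.frame(chrom = character(), start = integer(),
                                  end = integer()))
  res <- run_enrichment(vars, vars, cats, g, seed = 2)
  expect_identical(res$observed, 0L)
  expect_true(res$degenerate_random && res$degenerate_wt)
})

test_that("enrichment results are fully reproducible for a fixed seed", {
  g <- make_genome(37, c(c1 = 40000L))
  set.seed(41)
  vars <- clone_callset(do.call(rbind, lapply(
    sample.int(39000L, 50L), function(p) rec(pos = p))), "A")
  wt <- clone_callset(do.call(rbind, lapply(
    sample.int(39000L, 80L), function(p) rec(pos = p))), "WT")
  cats <- data.frame(mismatches = 4L, pam = "NGG", bulge = "none")
  cats$regions <- list(data.frame(chrom = "c1",
                                  start = c(1000L, 8000L, 20000L),
                                  end = c(1500L, 8500L, 20500L)))
  r1 <- run_enrichment(vars, wt, cats, g, seed = 11)
  r2 <- run_enrichment(vars, wt, cats, g, seed = 11)
  expect_identical(r1, r2)
  # null counts never exceed the sampled variant count; observed <= |vars|
  expect_lte(r1$observed, nrow(vars))
  expect_true(all(r1$random_null[[1]] <= nrow(vars)))
  expect_true(all(r1$wt_null[[1]] <= nrow(vars)))
})
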