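# Off-target INDEL enrichment: observed counts in predicted off-target
# regions versus (a) the same variants in random regions of equal number
# and size, and (b) subsampled wild-type variants in the same regions,
# each summarized by a one-sample t-test over a small number of draws.

#' Per-chromosome cumulative N counts for O(1) window N-counting
#'
#' @param genome A `genome_sequence`.
#' @return Named list of cumulative N-count vectors (length + 1 each).
#' @export
genome_n_index <- function(genome) {
  check_genome(genome)
  lapply(unclass(genome), function(s) {
    c(0L, cumsum(charToRaw(s) == charToRaw("N")))
  })
}

#' Count variants overlapping a region set
#'
#' Number of records whose REF span overlaps at least one region; a record
#' overlapping several regions counts once.
#'
#' @param variants A callset or variant record data frame.
#' @param regions Data frame of 0-based half-open intervals.
#' @return Integer count.
#' @export
count_in_regions <- function(variants, regions) {
  if (nrow(variants) == 0L || is.null(regions) || nrow(regions) == 0L) {
    return(0L)
  }
  ov <- GenomicRanges::findOverlaps(refspan_gr(as.data.frame(variants)),
                                    intervals_to_gr(regions))
  length(unique(S4Vectors::queryHits(ov)))
}

#' Sample random regions matched in number and size to a template
#'
#' Draws one interval per template interval, of identical length, uniformly
#' over all valid start positions genome-wide (chromosome chosen with
#' probability proportional to its number of eligible starts). Draws whose
#' window contains more than `max_n` Ns are rejected and redrawn (the same
#' rule that masks N-heavy coverage bins). Regions may overlap one another
#' unless `allow_overlap = FALSE`.
#'
#' @param genome A `genome_sequence`.
#' @param template_regions Data frame of 0-based half-open intervals.
#' @param seed Integer seed; fixed seed gives identical output.
#' @param max_n Maximum tolerated Ns per region (default 100).
#' @param allow_overlap Permit sampled regions to overlap (default TRUE).
#' @param retry_cap Redraw attempts per region before failing (default 1000).
#' @param n_index Precomputed [genome_n_index()] (computed on the fly when
#'   absent; pass it when drawing many region sets from one genome).
#' @return Data frame `chrom`, `start`, `end`.
#' @export
sample_random_regions <- function(genome, template_regions, seed,
                                  max_n = 100L, allow_overlap = TRUE,
                                  retry_cap = 1000L, n_index = NULL) {
  check_genome(genome)
  lens <- chrom_lengths(genome)
  widths <- template_regions$end - template_regions$start
  if (length(widths) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  if (max(widths) > max(lens)) {
    stop("template region wider than every chromosome", call. = FALSE)
  }
  ncums <- if (is.null(n_index)) genome_n_index(genome) else n_index
  with_seed(seed, {
    chroms <- character(length(widths))
    starts <- integer(length(widths))
    taken <- NULL
    for (i in seq_along(widths)) {
      w <- widths[i]
      eligible <- pmax(lens - w + 1L, 0L)
      if (sum(eligible) == 0L) {
        stop("no chromosome can host a region of width ", w, call. = FALSE)
      }
      ok <- FALSE
      for (try in seq_len(retry_cap)) {
        chrom <- sample(names(lens), 1L, prob = eligible)
        s0 <- sample.int(eligible[[chrom]], 1L) - 1L       # 0-based start
        nc <- ncums[[chrom]]
        n_in <- nc[s0 + w + 1L] - nc[s0 + 1L]
        if (n_in > max_n) next
        if (!allow_overlap && !is.null(taken)) {
          clash <- taken$chrom == chrom & taken$start < s0 + w &
            s0 < taken$end
          if (any(clash)) next
        }
        ok <- TRUE
        break
      }
      if (!ok) {
        stop("could not place region of width ", w, " after ", retry_cap,
             " attempts (genome too N-rich or crowded)", call. = FALSE)
      }
      chroms[i] <- chrom
      starts[i] <- s0
      taken <- rbind(taken, data.frame(chrom = chrom, start = s0,
                                       end = s0 + w))
    }
    data.frame(chrom = chroms, start = starts, end = starts + widths)
  })
}

#' Subsampled wild-type null counts
#'
#' Each draw samples `n` wild-type variants without replacement and counts
#' how many fall in `regions`.
#'
#' @param wt_variants Wild-type callset (all WT INDELs in the headline use).
#' @param n Number of variants per draw (the edited clone's unique count).
#' @param regions Off-target regions.
#' @param seed Integer seed.
#' @param draws Number of draws (default 5).
#' @return Integer vector of `draws` counts.
#' @export
subsample_wt_null <- function(wt_variants, n, regions, seed, draws = 5L) {
  wt <- as.data.frame(wt_variants)
  if (n > nrow(wt)) {
    stop("cannot sample ", n, " from ", nrow(wt), " WT variants",
         call. = FALSE)
  }
  with_seed(seed, {
    vapply(seq_len(draws), function(d) {
      idx <- sample.int(nrow(wt), n)
      count_in_regions(wt[idx, , drop = FALSE], regions)
    }, integer(1))
  })
}

#' Two-sided one-sample t-test of null counts against an observed count
#'
#' Tests the null draws against the observed value as hypothesized mean
#' (df = draws - 1). Zero variance in the nulls makes the statistic
#' undefined: the result carries `degenerate = TRUE` with `NA` t and p.
#'
#' @param null_counts Numeric vector (>= 2 values).
#' @param observed Observed count.
#' @param alternative "two.sided" (default), "less" or "greater".
#' @return List: `t`, `p`, `df`, `mean_null`, `sd_null`, `degenerate`.
#' @export
one_sample_t <- function(null_counts, observed,
                         alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(null_counts) >= 2L)
  m <- mean(null_counts)
  s <- stats::sd(null_counts)
  if (s == 0) {
    return(list(t = NA_real_, p = NA_real_, df = length(null_counts) - 1L,
                mean_null = m, sd_null = 0, degenerate = TRUE))
  }
  tt <- t.test(null_counts, mu = observed, alternative = alternative)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = as.integer(tt$parameter), mean_null = m, sd_null = s,
       degenerate = FALSE)
}

#' Off-target INDEL enrichment across site categories
#'
#' For each category of predicted off-target sites: counts the edited
#' clone's unique INDELs in the category's regions (observed); builds a
#' random-region null (the same INDELs counted in `draws` sets of equally
#' many, equally sized random regions) and a wild-type null (`draws`
#' subsamples of `|unique_a|` WT INDELs counted in the category's regions);
#' and compares each null against the observed count with a one-sample
#' t-test.
#'
#' @param unique_a The edited clone's unique INDELs (a callset).
#' @param wt_all All wild-type INDELs (a callset).
#' @param categories Output of [categorize_sites()] (needs a `regions`
#'   list-column).
#' @param genome The `genome_sequence` (for random-region placement).
#' @param seed Integer seed; every draw's sub-seed derives from it.
#' @param draws Randomizations per null (default 5).
#' @param pad Symmetric padding in bp added to each region before counting
#'   and before templating random regions (default 0: site footprints as
#'   emitted).
#' @param alternative Sidedness of the t-tests (default two-sided).
#' @return Data frame with one row per category: observed count, both null
#'   count vectors (list-columns `random_null`, `wt_null`), t/p for both
#'   comparisons, degeneracy flags and the seed.
#' @export
run_enrichment <- function(unique_a, wt_all, categories, genome, seed,
                           draws = 5L, pad = 0L,
                           alternative = "two.sided") {
  check_genome(genome)
  stopifnot("regions" %in% names(categories))
  lens <- chrom_lengths(genome)
  n_a <- nrow(unique_a)
  res <- categories[, setdiff(names(categories), "regions"), drop = FALSE]
  obs <- integer(nrow(categories))
  rnull <- vector("list", nrow(categories))
  wnull <- vector("list", nrow(categories))
  tr <- pr <- tw <- pw <- rep(NA_real_, nrow(categories))
  dg_r <- dg_w <- rep(TRUE, nrow(categories))
  nidx <- NULL
  for (k in seq_len(nrow(categories))) {
    regions <- categories$regions[[k]]
    if (!is.null(regions) && nrow(regions) && pad > 0L) {
      regions$start <- pmax(regions$start - pad, 0L)
      regions$end <- pmin(regions$end + pad, lens[regions$chrom])
    }
    obs[k] <- count_in_regions(unique_a, regions)
    if (is.null(regions) || nrow(regions) == 0L) {
      rnull[[k]] <- integer(draws)
      wnull[[k]] <- integer(draws)
      next                               # empty category: degenerate nulls
    }
    if (is.null(nidx)) nidx <- genome_n_index(genome)
    rnull[[k]] <- vapply(seq_len(draws), function(d) {
      rnd <- sample_random_regions(genome, regions,
                                   seed = sub_seed(seed, k * 1000L + d),
                                   n_index = nidx)
      count_in_regions(unique_a, rnd)
    }, integer(1))
    wnull[[k]] <- subsample_wt_null(wt_all, n_a, regions,
                                    seed = sub_seed(seed, k * 1000L + 500L),
                                    draws = draws)
    t_r <- one_sample_t(rnull[[k]], obs[k], alternative)
    t_w <- one_sample_t(wnull[[k]], obs[k], alternative)
    tr[k] <- t_r$t; pr[k] <- t_r$p; dg_r[k] <- t_r$degenerate
    tw[k] <- t_w$t; pw[k] <- t_w$p; dg_w[k] <- t_w$degenerate
  }
  res$observed <- obs
  res$random_null <- I(rnull)
  res$wt_null <- I(wnull)
  res$t_random <- tr; res$p_random <- pr; res$degenerate_random <- dg_r
  res$t_wt <- tw; res$p_wt <- pw; res$degenerate_wt <- dg_w
  res$seed <- seed
  res
}
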