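# Strain-matched methylation pairs and per-probe paired tests with FDR.

#' Build strain-matched sample pairs
#'
#' Within each (tissue, sex) stratum, pairs one sample of `strain_a` with
#' one of `strain_b`; each sample is used at most once and a pair is only
#' formed when the age difference is at most `max_age_diff` days
#' (inclusive).
#'
#' `method = "optimal"` (default) computes, per stratum, the
#' maximum-cardinality matching of minimal total age difference by exact
#' dynamic programming (deterministic, ties resolved by sample-id order).
#' `method = "greedy"` repeatedly takes the globally smallest remaining age
#' difference in the stratum (ties by sample-id order); it is faster but,
#' under an age cutoff, a locally closest pair can block two feasible pairs,
#' so greedy can pair fewer samples than the optimum.
#'
#' @param metadata Data frame: `sample_id`, `strain`, `tissue`, `sex`,
#'   `age_days`.
#' @param max_age_diff Maximum age difference in days, inclusive
#'   (default 60).
#' @param method "optimal" or "greedy".
#' @param strain_a,strain_b The two strains to pair (defaults "129Sv",
#'   "B6").
#' @return Data frame of pairs (`sample_129sv`, `sample_b6`, `tissue`,
#'   `sex`, `age_129sv`, `age_b6`, `age_diff_days`) with a `summary`
#'   attribute (pair count, per-sex counts, tissue count, median/max age
#'   difference).
#' @export
build_matched_pairs <- function(metadata, max_age_diff = 60,
                                method = c("optimal", "greedy"),
                                strain_a = "129Sv", strain_b = "B6") {
  method <- match.arg(method)
  needed <- c("sample_id", "strain", "tissue", "sex", "age_days")
  stopifnot(all(needed %in% names(metadata)))
  if (anyDuplicated(metadata$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  strata <- unique(metadata[, c("tissue", "sex")])
  pairs <- list()
  for (r in seq_len(nrow(strata))) {
    sub <- metadata[metadata$tissue == strata$tissue[r] &
                      metadata$sex == strata$sex[r], , drop = FALSE]
    a <- sub[sub$strain == strain_a, , drop = FALSE]
    b <- sub[sub$strain == strain_b, , drop = FALSE]
    a <- a[order(a$sample_id), , drop = FALSE]
    b <- b[order(b$sample_id), , drop = FALSE]
    if (nrow(a) == 0L || nrow(b) == 0L) next
    sel <- if (method == "greedy") {
      match_stratum_greedy(a$age_days, b$age_days, max_age_diff)
    } else {
      match_stratum_optimal(a$age_days, b$age_days, max_age_diff)
    }
    if (nrow(sel) == 0L) next
    pairs[[length(pairs) + 1L]] <- data.frame(
      sample_129sv = a$sample_id[sel$i], sample_b6 = b$sample_id[sel$j],
      tissue = strata$tissue[r], sex = strata$sex[r],
      age_129sv = a$age_days[sel$i], age_b6 = b$age_days[sel$j],
      age_diff_days = abs(a$age_days[sel$i] - b$age_days[sel$j]),
      stringsAsFactors = FALSE)
  }
  out <- if (length(pairs)) do.call(rbind, pairs) else data.frame(
    sample_129sv = character(), sample_b6 = character(),
    tissue = character(), sex = character(), age_129sv = numeric(),
    age_b6 = numeric(), age_diff_days = numeric(), stringsAsFactors = FALSE)
  out <- out[order(out$tissue, out$sex, out$sample_129sv), , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(!anyDuplicated(out$sample_129sv), !anyDuplicated(out$sample_b6),
            all(out$age_diff_days <= max_age_diff))
  attr(out, "summary") <- list(
    n_pairs = nrow(out),
    n_by_sex = table(out$sex),
    n_tissues = length(unique(out$tissue)),
    median_age_diff = if (nrow(out)) median(out$age_diff_days) else NA_real_,
    max_age_diff = if (nrow(out)) max(out$age_diff_days) else NA_real_)
  out
}

# greedy: repeatedly take the smallest remaining feasible age difference;
# ties resolved by (i, j) order, i.e. by sample id after the caller's sort
match_stratum_greedy <- function(age_a, age_b, max_diff) {
  cand <- expand.grid(i = seq_along(age_a), j = seq_along(age_b))
  cand$diff <- abs(age_a[cand$i] - age_b[cand$j])
  cand <- cand[cand$diff <= max_diff, , drop = FALSE]
  cand <- cand[order(cand$diff, cand$i, cand$j), , drop = FALSE]
  used_a <- logical(length(age_a)); used_b <- logical(length(age_b))
  res <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    res[[length(res) + 1L]] <- c(i = i, j = j)
  }
  if (!length(res)) return(data.frame(i = integer(), j = integer()))
  as.data.frame(do.call(rbind, res))
}

# exact DP over (next A index, bitmask of used B): maximize pair count,
# then minimize total age difference; deterministic reconstruction
match_stratum_optimal <- function(age_a, age_b, max_diff) {
  swapped <- FALSE
  if (length(age_b) > length(age_a)) {
    tmp <- age_a; age_a <- age_b; age_b <- tmp   # mask over the smaller side
    swapped <- TRUE
  }
  na <- length(age_a); nb <- length(age_b)
  if (nb > 16L) {
    stop("stratum too large for exact matching (", nb,
         " on the smaller side); use method = \"greedy\"", call. = FALSE)
  }
  feas <- outer(age_a, age_b, function(x, y) abs(x - y) <= max_diff)
  diffm <- abs(outer(age_a, age_b, "-"))
  memo_cnt <- array(NA_integer_, dim = c(na + 1L, 2L^nb))
  memo_tot <- array(NA_real_, dim = c(na + 1L, 2L^nb))
  solve <- function(i, mask) {
    if (i > na) return(c(0, 0))
    m1 <- mask + 1L
    if (!is.na(memo_cnt[i, m1])) return(c(memo_cnt[i, m1], memo_tot[i, m1]))
    best <- solve(i + 1L, mask)                      # skip a_i
    for (j in seq_len(nb)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (feas[i, j] && bitwAnd(mask, bit) == 0L) {
        v <- solve(i + 1L, bitwOr(mask, bit))
        v <- c(v[1] + 1, v[2] + diffm[i, j])
        if (v[1] > best[1] || (v[1] == best[1] && v[2] < best[2])) best <- v
      }
    }
    memo_cnt[i, m1] <<- as.integer(best[1])
    memo_tot[i, m1] <<- best[2]
    best
  }
  solve(1L, 0L)
  # reconstruct: at each A index prefer the smallest-id feasible B that
  # attains the optimum; otherwise skip
  res <- list()
  mask <- 0L
  for (i in seq_len(na)) {
    tgt <- c(memo_cnt[i, mask + 1L], memo_tot[i, mask + 1L])
    chosen <- 0L
    for (j in seq_len(nb)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (feas[i, j] && bitwAnd(mask, bit) == 0L) {
        v <- solve(i + 1L, bitwOr(mask, bit))
        if (v[1] + 1L == tgt[1] &&
            isTRUE(all.equal(v[2] + diffm[i, j], tgt[2]))) {
          chosen <- j
          break
        }
      }
    }
    if (chosen > 0L) {
      res[[length(res) + 1L]] <- c(i = i, j = chosen)
      mask <- bitwOr(mask, bitwShiftL(1L, chosen - 1L))
    }
  }
  out <- if (length(res)) as.data.frame(do.call(rbind, res)) else
    data.frame(i = integer(), j = integer())
  if (swapped) out <- data.frame(i = out$j, j = out$i)
  out
}

#' Paired test of strain methylation difference at one probe
#'
#' Two-sided paired t-test of the per-pair beta differences (B6 minus
#' 129Sv). Pairs missing a value at the probe are dropped; fewer than two
#' complete pairs yields an undefined result, and zero within-pair variance
#' a degenerate one.
#'
#' @param beta Numeric matrix, probes x samples (dimnames required).
#' @param pairs Output of [build_matched_pairs()].
#' @param probe Probe id (row of `beta`).
#' @return List: `mean_diff`, `t`, `p`, `n_pairs`, `degenerate`, `defined`.
#' @export
paired_probe_test <- function(beta, pairs, probe) {
  if (!probe %in% rownames(beta)) stop("unknown probe: ", probe,
                                       call. = FALSE)
  d <- beta[probe, pairs$sample_b6] - beta[probe, pairs$sample_129sv]
  d <- d[!is.na(d)]
  if (length(d) < 2L) {
    return(list(mean_diff = if (length(d)) mean(d) else NA_real_,
                t = NA_real_, p = NA_real_, n_pairs = length(d),
                degenerate = FALSE, defined = FALSE))
  }
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      # identical paired values: no evidence of any difference
      return(list(mean_diff = 0, t = 0, p = 1, n_pairs = length(d),
                  degenerate = FALSE, defined = TRUE))
    }
    return(list(mean_diff = mean(d), t = NA_real_, p = NA_real_,
                n_pairs = length(d), degenerate = TRUE, defined = FALSE))
  }
  tt <- tryCatch(t.test(d), error = function(e) NULL)
  if (is.null(tt)) {
    # numerically constant differences (floating-point residue only)
    return(list(mean_diff = mean(d), t = NA_real_, p = NA_real_,
                n_pairs = length(d), degenerate = TRUE, defined = FALSE))
  }
  list(mean_diff = mean(d), t = unname(tt$statistic), p = tt$p.value,
       n_pairs = length(d), degenerate = FALSE, defined = TRUE)
}

#' Per-tissue paired tests with FDR adjustment
#'
#' Runs [paired_probe_test()] for every (tissue, probe) combination and
#' adjusts p-values by Benjamini-Hochberg. Undefined tests (fewer than two
#' complete pairs, or zero within-pair variance) are excluded before
#' adjustment. The adjustment family is the whole emitted table by default;
#' `fdr_scope = "per_probe"` adjusts within each probe across tissues.
#'
#' @param beta Probes x samples beta matrix.
#' @param pairs Output of [build_matched_pairs()].
#' @param probes Probe ids to test (default: all rows of `beta`).
#' @param fdr_scope "global" (default) or "per_probe".
#' @return Data frame: `tissue`, `probe`, `n_pairs`, `mean_diff`, `t`, `p`,
#'   `q`.
#' @export
per_tissue_tests <- function(beta, pairs, probes = rownames(beta),
                             fdr_scope = c("global", "per_probe")) {
  fdr_scope <- match.arg(fdr_scope)
  tissues <- unique(pairs$tissue)
  grid <- expand.grid(tissue = tissues, probe = probes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    pr <- paired_probe_test(beta, pairs[pairs$tissue == grid$tissue[k], ,
                                        drop = FALSE], grid$probe[k])
    data.frame(tissue = grid$tissue[k], probe = grid$probe[k],
               n_pairs = pr$n_pairs, mean_diff = pr$mean_diff, t = pr$t,
               p = pr$p, defined = pr$defined, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$defined, setdiff(names(out), "defined"), drop = FALSE]
  if (nrow(out)) {
    out$q <- if (fdr_scope == "global") {
      p.adjust(out$p, method = "BH")
    } else {
      stats::ave(out$p, out$probe,
                 FUN = function(p) p.adjust(p, method = "BH"))
    }
  } else {
    out$q <- numeric()
  }
  rownames(out) <- NULL
  out
}
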