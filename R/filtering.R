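# Hard filtering of SNV/INDEL calls, clone-unique INDEL definition,
# allele frequencies, differential genotypes and allele-frequency drift.

#' GATK-style hard filter thresholds
#'
#' Defaults are the standard hard-filter cutoffs for joint-genotyped calls:
#' INDELs fail on FS > 200, ReadPosRankSum < -20, QUAL < 30 or QD < 2;
#' SNVs fail on QD < 2, QUAL < 30, SOR > 3, FS > 60, MQ < 40,
#' MQRankSum < -12.5 or ReadPosRankSum < -8.
#'
#' @param indel,snv Named lists overriding individual cutoffs.
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(indel = list(), snv = list()) {
  def_indel <- list(FS_max = 200.0, ReadPosRankSum_min = -20.0,
                    QUAL_min = 30.0, QD_min = 2.0)
  def_snv <- list(QD_min = 2.0, QUAL_min = 30.0, SOR_max = 3.0,
                  FS_max = 60.0, MQ_min = 40.0, MQRankSum_min = -12.5,
                  ReadPosRankSum_min = -8.0)
  structure(list(indel = modifyList(def_indel, indel),
                 snv = modifyList(def_snv, snv)),
            class = "filter_thresholds")
}

# violation test where a missing statistic passes (missing != failing)
viol_gt <- function(x, cutoff) !is.na(x) & x > cutoff
viol_lt <- function(x, cutoff) !is.na(x) & x < cutoff

#' Remove low-confidence calls by hard thresholds
#'
#' A record is removed iff any cutoff for its variant type is violated
#' (strict inequalities); records missing a statistic pass that statistic's
#' test.
#'
#' @param callset A [clone_callset()].
#' @param thresholds A [filter_thresholds()].
#' @return The filtered `clone_callset`, with attribute `n_removed`.
#' @export
apply_hard_filters <- function(callset, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  th_i <- thresholds$indel
  th_s <- thresholds$snv
  is_snv <- callset$vtype == "SNV"
  fail_indel <- viol_gt(callset$FS, th_i$FS_max) |
    viol_lt(callset$ReadPosRankSum, th_i$ReadPosRankSum_min) |
    viol_lt(callset$qual, th_i$QUAL_min) |
    viol_lt(callset$QD, th_i$QD_min)
  fail_snv <- viol_lt(callset$QD, th_s$QD_min) |
    viol_lt(callset$qual, th_s$QUAL_min) |
    viol_gt(callset$SOR, th_s$SOR_max) |
    viol_gt(callset$FS, th_s$FS_max) |
    viol_lt(callset$MQ, th_s$MQ_min) |
    viol_lt(callset$MQRankSum, th_s$MQRankSum_min) |
    viol_lt(callset$ReadPosRankSum, th_s$ReadPosRankSum_min)
  fail <- ifelse(is_snv, fail_snv, fail_indel)
  out <- clone_callset(as.data.frame(callset)[!fail, , drop = FALSE],
                       clone_id(callset))
  attr(out, "n_removed") <- sum(fail)
  out
}

#' Does a record carry alternate-allele evidence?
#' @noRd
has_alt_evidence <- function(records) {
  gt_alt <- !is.na(records$gt) & records$gt != "0/0" & records$gt != "0"
  ad_alt <- !is.na(records$alt_reads) & records$alt_reads > 0L
  gt_alt | ad_alt
}

#' Left-align and trim INDEL representations against the reference
#'
#' Shifts each INDEL to its leftmost equivalent representation (repeatedly
#' dropping a shared terminal base and prepending the preceding reference
#' base) and trims redundant shared leading bases, so that representation
#' differences between callers cannot defeat positional comparison. SNVs
#' pass through unchanged.
#'
#' @param callset A [clone_callset()].
#' @param genome The reference `genome_sequence`.
#' @return The normalized `clone_callset`.
#' @export
normalize_variants <- function(callset, genome) {
  check_genome(genome)
  df <- as.data.frame(callset)
  idx <- which(df$vtype == "INDEL" & df$chrom %in% names(genome))
  for (i in idx) {
    chrom_seq <- unclass(genome)[[df$chrom[i]]]
    r <- df$ref[i]; a <- df$alt[i]; p <- df$pos[i]
    repeat {
      # drop shared terminal base, borrowing leftward when one allele empties
      while (nchar(r) > 0L && nchar(a) > 0L &&
             substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
        if (nchar(r) == 1L || nchar(a) == 1L) {
          if (p == 1L) break
          prev <- substr(chrom_seq, p - 1L, p - 1L)
          r <- paste0(prev, substr(r, 1L, nchar(r) - 1L))
          a <- paste0(prev, substr(a, 1L, nchar(a) - 1L))
          p <- p - 1L
        } else {
          r <- substr(r, 1L, nchar(r) - 1L)
          a <- substr(a, 1L, nchar(a) - 1L)
        }
      }
      # trim redundant shared leading bases (keep one anchor base)
      moved <- FALSE
      while (nchar(r) > 1L && nchar(a) > 1L &&
             substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
        r <- substr(r, 2L, nchar(r)); a <- substr(a, 2L, nchar(a))
        p <- p + 1L
        moved <- TRUE
      }
      if (!moved) break
    }
    df$ref[i] <- r; df$alt[i] <- a; df$pos[i] <- p
  }
  df$vtype <- ifelse(nchar(df$ref) == 1L & nchar(df$alt) == 1L,
                     "SNV", "INDEL")
  clone_callset(df, clone_id(callset))
}

#' Define INDELs unique to one clone
#'
#' An INDEL call of clone A (with alternate-allele support) is unique iff
#' (i) no INDEL of clone B overlaps its REF span, (ii) every base of the REF
#' span has depth >= `min_depth` in B's coverage track, and (iii) no record
#' of any type with alternate-allele evidence in B's unfiltered callset
#' overlaps the span — i.e. B shows no read support for any alternate allele
#' there. Records whose span has positions absent from the coverage track
#' are excluded and tallied separately.
#'
#' Callsets should be hard-filtered and, if produced by different caller
#' runs, normalized with [normalize_variants()] first.
#'
#' @param callset_a Clone A's hard-filtered callset.
#' @param callset_b Clone B's hard-filtered callset.
#' @param coverage_b Clone B per-base coverage (`chrom`, `pos`, `depth`).
#' @param min_depth Minimum B depth across the REF span (default 10).
#' @param callset_b_unfiltered Clone B's callset before hard filtering
#'   (defaults to `callset_b`).
#' @return `clone_callset` of A-unique INDELs with attributes
#'   `n_candidates`, `n_overlap_b`, `n_low_coverage`, `n_b_alt_evidence`
#'   and `n_coverage_unavailable`.
#' @export
clone_unique_indels <- function(callset_a, callset_b, coverage_b,
                                min_depth = 10L,
                                callset_b_unfiltered = callset_b) {
  cand <- as.data.frame(callset_a)
  cand <- cand[cand$vtype == "INDEL" & has_alt_evidence(cand), , drop = FALSE]
  n_cand <- nrow(cand)
  if (n_cand == 0L) {
    out <- clone_callset(cand, clone_id(callset_a))
    attr(out, "n_candidates") <- 0L
    attr(out, "n_overlap_b") <- 0L
    attr(out, "n_low_coverage") <- 0L
    attr(out, "n_b_alt_evidence") <- 0L
    attr(out, "n_coverage_unavailable") <- 0L
    return(out)
  }
  gr_a <- refspan_gr(cand)

  b_ind <- as.data.frame(callset_b)
  b_ind <- b_ind[b_ind$vtype == "INDEL" & has_alt_evidence(b_ind), ,
                 drop = FALSE]
  hit_i <- if (nrow(b_ind)) {
    S4Vectors::queryHits(GenomicRanges::findOverlaps(gr_a, refspan_gr(b_ind)))
  } else integer()

  b_any <- as.data.frame(callset_b_unfiltered)
  b_any <- b_any[has_alt_evidence(b_any), , drop = FALSE]
  hit_iii <- if (nrow(b_any)) {
    S4Vectors::queryHits(GenomicRanges::findOverlaps(gr_a, refspan_gr(b_any)))
  } else integer()

  # minimum B depth over each REF span via a keyed per-position join
  cov <- data.table::as.data.table(coverage_b[, c("chrom", "pos", "depth")])
  data.table::setkey(cov, chrom, pos)
  span_w <- nchar(cand$ref)
  want <- data.table::data.table(
    rec = rep.int(seq_len(n_cand), span_w),
    chrom = rep.int(cand$chrom, span_w),
    pos = unlist(lapply(seq_len(n_cand), function(i) {
      seq.int(cand$pos[i], cand$pos[i] + span_w[i] - 1L)
    }))
  )
  want[, depth := cov[want, on = c("chrom", "pos"), x.depth]]
  per_rec <- want[, .(any_na = anyNA(depth),
                      min_depth = as.double(
                        suppressWarnings(min(depth, na.rm = TRUE)))),
                  by = "rec"]
  unavailable <- per_rec$rec[per_rec$any_na]
  low_cov <- per_rec$rec[!per_rec$any_na & per_rec$min_depth < min_depth]

  fail_overlap <- unique(c(hit_i, hit_iii))
  keep <- setdiff(seq_len(n_cand), c(fail_overlap, unavailable, low_cov))
  out <- clone_callset(cand[keep, , drop = FALSE], clone_id(callset_a))
  attr(out, "n_candidates") <- n_cand
  attr(out, "n_overlap_b") <- length(unique(hit_i))
  attr(out, "n_low_coverage") <- length(setdiff(low_cov, fail_overlap))
  attr(out, "n_b_alt_evidence") <- length(unique(hit_iii))
  attr(out, "n_coverage_unavailable") <- length(unavailable)
  out
}

#' Within-sample alternate allele frequency
#'
#' Alternate-supporting reads divided by read depth at the position.
#' Records with zero or missing depth yield `NA` and are skipped by callers.
#'
#' @param records A callset or variant record data frame.
#' @return Numeric vector of frequencies in \[0, 1\] (or `NA`).
#' @export
allele_frequency <- function(records) {
  af <- ifelse(is.na(records$depth) | records$depth == 0L,
               NA_real_, records$alt_reads / records$depth)
  af
}

#' Differentially genotyped biallelic SNVs between two clones
#'
#' Returns SNV positions where both clones have depth >= `min_depth`, the
#' site is biallelic (one ALT allele) and the genotypes differ. Sites with
#' a call in only one clone are included (as an implied homozygous-reference
#' genotype in the other clone) when the other clone's depth at the position
#' — from its callset record or, failing that, its coverage track — meets
#' `min_depth`; disable with `include_implied_ref = FALSE`.
#'
#' @param callset_a,callset_b Hard-filtered callsets.
#' @param min_depth Minimum depth in both clones.
#' @param coverage_a,coverage_b Optional per-base coverage tracks used to
#'   establish depth for implied-reference sites absent from a callset.
#' @param include_implied_ref Include one-sided sites as 0/0 in the other
#'   clone (default TRUE).
#' @return Data frame: `chrom`, `pos`, `ref`, `alt_a`, `alt_b`, `gt_a`,
#'   `gt_b`, `depth_a`, `depth_b`.
#' @export
differential_biallelic_snvs <- function(callset_a, callset_b,
                                        min_depth = 10L,
                                        coverage_a = NULL, coverage_b = NULL,
                                        include_implied_ref = TRUE) {
  pick <- function(cs) {
    df <- as.data.frame(cs)
    df <- df[df$vtype == "SNV" & df$n_alt == 1L & !is.na(df$gt) &
               !is.na(df$depth), , drop = FALSE]
    df$key <- paste(df$chrom, df$pos, sep = ":")
    df[!duplicated(df$key), , drop = FALSE]
  }
  a <- pick(callset_a)
  b <- pick(callset_b)
  m <- merge(a, b, by = "key", suffixes = c("_a", "_b"))
  both <- m[m$depth_a >= min_depth & m$depth_b >= min_depth &
              (m$gt_a != m$gt_b | m$alt_a != m$alt_b), , drop = FALSE]
  res <- data.frame(chrom = both$chrom_a, pos = both$pos_a, ref = both$ref_a,
                    alt_a = both$alt_a, alt_b = both$alt_b,
                    gt_a = both$gt_a, gt_b = both$gt_b,
                    depth_a = both$depth_a, depth_b = both$depth_b,
                    stringsAsFactors = FALSE)

  if (include_implied_ref) {
    one_sided <- function(x, other_cov, flip) {
      x <- x[has_alt_evidence(x) & x$depth >= min_depth, , drop = FALSE]
      if (nrow(x) == 0L || is.null(other_cov)) return(NULL)
      cov <- data.table::as.data.table(
        other_cov[, c("chrom", "pos", "depth")])
      data.table::setkey(cov, chrom, pos)
      d_other <- cov[data.table::data.table(chrom = x$chrom, pos = x$pos),
                     on = c("chrom", "pos"), x.depth]
      sel <- !is.na(d_other) & d_other >= min_depth
      if (!any(sel)) return(NULL)
      x <- x[sel, , drop = FALSE]
      d_other <- d_other[sel]
      if (flip) {
        data.frame(chrom = x$chrom, pos = x$pos, ref = x$ref,
                   alt_a = NA_character_, alt_b = x$alt,
                   gt_a = "0/0", gt_b = x$gt,
                   depth_a = d_other, depth_b = x$depth,
                   stringsAsFactors = FALSE)
      } else {
        data.frame(chrom = x$chrom, pos = x$pos, ref = x$ref,
                   alt_a = x$alt, alt_b = NA_character_,
                   gt_a = x$gt, gt_b = "0/0",
                   depth_a = x$depth, depth_b = d_other,
                   stringsAsFactors = FALSE)
      }
    }
    a_only <- a[!a$key %in% b$key, , drop = FALSE]
    b_only <- b[!b$key %in% a$key, , drop = FALSE]
    res <- rbind(res,
                 one_sided(a_only, coverage_b, flip = FALSE),
                 one_sided(b_only, coverage_a, flip = TRUE))
  }
  res <- res[order(res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Allele-frequency drift between two clones
#'
#' Matches hard-filtered biallelic SNVs by (chrom, pos, ref, alt) and
#' reports those with depth >= `min_depth` in both clones and an allele
#' frequency change above `delta_threshold`. The default reading of a
#' ">50% change" is an absolute difference of more than 0.5 frequency
#' points; `mode = "relative"` instead uses |af_a - af_b| / af_b.
#' Positions biallelic in both clones but with different ALT alleles are
#' excluded and counted in attribute `n_discordant_alt`.
#'
#' @param callset_a,callset_b Hard-filtered callsets.
#' @param min_depth Minimum depth in both clones (default 20).
#' @param delta_threshold Change threshold (default 0.5).
#' @param mode "absolute" (default) or "relative".
#' @return Data frame of drift records: `chrom`, `pos`, `ref`, `alt`,
#'   `af_a`, `af_b`, `delta`.
#' @export
allele_frequency_drift <- function(callset_a, callset_b, min_depth = 20L,
                                   delta_threshold = 0.5,
                                   mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  pick <- function(cs) {
    df <- as.data.frame(cs)
    df <- df[df$vtype == "SNV" & df$n_alt == 1L & !is.na(df$depth) &
               df$depth > 0L & !is.na(df$alt_reads), , drop = FALSE]
    df$poskey <- paste(df$chrom, df$pos, df$ref, sep = ":")
    df$key <- paste(df$poskey, df$alt, sep = ":")
    df[!duplicated(df$key), , drop = FALSE]
  }
  a <- pick(callset_a)
  b <- pick(callset_b)
  m <- merge(a, b, by = "key", suffixes = c("_a", "_b"))
  # same position+ref in both, but no shared alt allele
  pos_shared <- intersect(a$poskey, b$poskey)
  n_discordant <- length(setdiff(pos_shared,
                                 sub(":[^:]*$", "", unique(m$key))))
  m <- m[m$depth_a >= min_depth & m$depth_b >= min_depth, , drop = FALSE]
  af_a <- m$alt_reads_a / m$depth_a
  af_b <- m$alt_reads_b / m$depth_b
  delta <- if (mode == "absolute") {
    abs(af_a - af_b)
  } else {
    ifelse(af_b > 0, abs(af_a - af_b) / af_b, NA_real_)
  }
  sel <- !is.na(delta) & delta > delta_threshold
  out <- data.frame(chrom = m$chrom_a[sel], pos = m$pos_a[sel],
                    ref = m$ref_a[sel], alt = m$alt_a[sel],
                    af_a = af_a[sel], af_b = af_b[sel], delta = delta[sel],
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_discordant_alt") <- n_discordant
  out
}

#' Count variants falling in labeled gene sets
#'
#' Per-label count of records whose REF span overlaps any interval carrying
#' that label; a record overlapping intervals of two labels counts once per
#' label, and multiple overlaps within a label count once.
#'
#' @param callset A callset.
#' @param gene_intervals Data frame with `chrom`, `start`, `end` (0-based
#'   half-open) and `label`.
#' @return Named integer vector, one entry per distinct label.
#' @export
count_variants_in_genesets <- function(callset, gene_intervals) {
  stopifnot(all(c("chrom", "start", "end", "label") %in%
                  names(gene_intervals)))
  labels <- unique(gene_intervals$label)
  counts <- setNames(integer(length(labels)), labels)
  if (nrow(callset) == 0L || nrow(gene_intervals) == 0L) return(counts)
  ov <- GenomicRanges::findOverlaps(refspan_gr(as.data.frame(callset)),
                                    intervals_to_gr(gene_intervals))
  hit_lab <- gene_intervals$label[S4Vectors::subjectHits(ov)]
  hit_rec <- S4Vectors::queryHits(ov)
  tab <- table(unique(data.frame(rec = hit_rec, lab = hit_lab))$lab)
  counts[names(tab)] <- as.integer(tab)
  counts
}
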