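# Binned read-depth screening: fixed-width genome bins with N-masking,
# between-clone percent-change flagging, chromosome-loss screening, and
# concordance with external CNV calls and translocation candidates.

#' Tile a genome into fixed-width coverage bins
#'
#' Bins tile each chromosome from 0; the terminal bin is truncated. A bin is
#' masked when it contains more than `max_n` undefined bases (Ns).
#'
#' @param genome A `genome_sequence`.
#' @param bin_size Bin width in bp (default 50000).
#' @param max_n Masking threshold on N count per bin (default 100).
#' @return Data frame `chrom`, `start`, `end` (0-based half-open),
#'   `n_bases`, `masked`; attribute `bin_size`.
#' @export
make_bins <- function(genome, bin_size = 50000L, max_n = 100L) {
  check_genome(genome)
  stopifnot(bin_size > 0L)
  out <- lapply(names(genome), function(chrom) {
    len <- nchar(unclass(genome)[[chrom]])
    starts <- seq.int(0L, len - 1L, by = bin_size)
    ends <- pmin(starts + bin_size, len)
    ncum <- c(0L, cumsum(charToRaw(unclass(genome)[[chrom]]) ==
                           charToRaw("N")))
    nb <- ncum[ends + 1L] - ncum[starts + 1L]
    data.frame(chrom = chrom, start = starts, end = ends,
               n_bases = as.integer(nb), stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, out)
  bins$masked <- bins$n_bases > max_n
  attr(bins, "bin_size") <- as.integer(bin_size)
  bins
}

#' Per-bin mean read depth
#'
#' Mean depth over every position of the bin; positions absent from the
#' coverage track count as depth 0, and the denominator is the full bin
#' width (N bases included — N-heavy bins are masked anyway).
#'
#' @param bins Output of [make_bins()].
#' @param coverage Per-base coverage (`chrom`, `pos` 1-based, `depth`).
#' @return `bins` with a `mean_depth` column.
#' @export
bin_mean_depth <- function(bins, coverage) {
  bin_size <- attr(bins, "bin_size")
  if (is.null(bin_size)) bin_size <- max(bins$end - bins$start)
  cov <- data.table::as.data.table(coverage[, c("chrom", "pos", "depth")])
  sums <- cov[, .(mass = sum(as.double(depth))),
              by = .(chrom, start = ((pos - 1L) %/% bin_size) * bin_size)]
  key <- paste(bins$chrom, bins$start)
  m <- sums$mass[match(key, paste(sums$chrom, sums$start))]
  m[is.na(m)] <- 0
  bins$mean_depth <- m / (bins$end - bins$start)
  attr(bins, "bin_size") <- bin_size
  bins
}

#' Compare binned depths between two clones
#'
#' Requires identical bin skeletons. Masked bins are excluded; bins with
#' zero depth in clone B are excluded and tallied. By default clone A's
#' depths are rescaled by the library-size ratio (total depth mass of B over
#' A across unmasked bins) before the signed percent change
#' `(a - b) / b * 100` is computed; `normalize = FALSE` compares raw depths.
#' A bin is flagged when |percent change| exceeds `flag_threshold`.
#'
#' @param bins_a,bins_b Outputs of [bin_mean_depth()] on the same skeleton.
#' @param flag_threshold Percent-change magnitude for flagging (default 50).
#' @param normalize Apply library-size normalization (default TRUE).
#' @return Data frame `chrom`, `start`, `end`, `depth_a`, `depth_b`,
#'   `pct_change`, `flagged`; attributes `n_zero_b`, `scale_a`.
#' @export
compare_bins <- function(bins_a, bins_b, flag_threshold = 50,
                         normalize = TRUE) {
  same <- identical(bins_a[, c("chrom", "start", "end")],
                    bins_b[, c("chrom", "start", "end")]) &&
    identical(bins_a$masked, bins_b$masked)
  if (!same) stop("bin skeletons differ between clones", call. = FALSE)
  keep <- !bins_a$masked
  a <- bins_a[keep, , drop = FALSE]
  b <- bins_b[keep, , drop = FALSE]
  w <- a$end - a$start
  scale_a <- 1
  if (normalize) {
    mass_a <- sum(a$mean_depth * w)
    mass_b <- sum(b$mean_depth * w)
    if (mass_a > 0) scale_a <- mass_b / mass_a
  }
  depth_a <- a$mean_depth * scale_a
  zero_b <- b$mean_depth == 0
  out <- data.frame(chrom = a$chrom, start = a$start, end = a$end,
                    depth_a = depth_a, depth_b = b$mean_depth,
                    stringsAsFactors = FALSE)[!zero_b, , drop = FALSE]
  out$pct_change <- (out$depth_a - out$depth_b) / out$depth_b * 100
  out$flagged <- abs(out$pct_change) > flag_threshold
  rownames(out) <- NULL
  attr(out, "n_zero_b") <- sum(zero_b)
  attr(out, "scale_a") <- scale_a
  out
}

#' Per-chromosome depth summary and loss screen
#'
#' Mean depth per chromosome (absent positions count 0); chromosomes below
#' `loss_frac` of the genome-wide median per-chromosome mean are flagged as
#' candidate losses. A cumulative depth-fraction profile along each
#' chromosome (for arm-truncation screening plots) is returned alongside.
#'
#' @param coverage Per-base coverage track.
#' @param genome A `genome_sequence`.
#' @param loss_frac Loss cutoff as a fraction of the median (default 0.6).
#' @param profile_bin Bin width of the cumulative profile (default 50000).
#' @return List with `summary` (`chrom`, `length`, `mean_depth`, `flagged`)
#'   and `profile` (`chrom`, `end`, `cum_frac`).
#' @export
chromosome_depth_summary <- function(coverage, genome, loss_frac = 0.6,
                                     profile_bin = 50000L) {
  check_genome(genome)
  lens <- chrom_lengths(genome)
  cov <- data.table::as.data.table(coverage[, c("chrom", "pos", "depth")])
  totals <- cov[, .(mass = sum(as.double(depth))), by = chrom]
  mass <- setNames(rep(0, length(lens)), names(lens))
  mass[totals$chrom] <- totals$mass
  mean_depth <- mass / lens
  med <- median(mean_depth)
  flagged <- mean_depth < loss_frac * med | med == 0
  if (all(mass == 0)) {
    warning("coverage track is empty: all chromosomes flagged")
    flagged[] <- TRUE
  }
  prof <- cov[, .(mass = sum(as.double(depth))),
              by = .(chrom, bin = (pos - 1L) %/% profile_bin)]
  profile <- do.call(rbind, lapply(names(lens), function(ch) {
    nb <- ceiling(lens[[ch]] / profile_bin)
    m <- rep(0, nb)
    sel <- prof$chrom == ch
    m[prof$bin[sel] + 1L] <- prof$mass[sel]
    data.frame(chrom = ch,
               end = pmin(seq_len(nb) * profile_bin, lens[[ch]]),
               cum_frac = if (sum(m) > 0) cumsum(m) / sum(m) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(summary = data.frame(chrom = names(lens), length = unname(lens),
                            mean_depth = unname(mean_depth),
                            flagged = unname(flagged),
                            stringsAsFactors = FALSE),
       profile = profile)
}

#' CNV calls unique to one clone
#'
#' A call in A is matched when a B call of the same type reciprocally
#' overlaps it by at least `reciprocal_overlap` of both intervals; unmatched
#' calls are unique.
#'
#' @param calls_a,calls_b Data frames `chrom`, `start`, `end` (0-based
#'   half-open), `cnv_type`.
#' @param reciprocal_overlap Required reciprocal overlap fraction
#'   (default 0.5).
#' @return The unique subset of `calls_a`.
#' @export
unique_cnvs <- function(calls_a, calls_b, reciprocal_overlap = 0.5) {
  stopifnot(reciprocal_overlap >= 0, reciprocal_overlap <= 1)
  if (nrow(calls_a) == 0L) return(calls_a)
  if (nrow(calls_b) == 0L) return(calls_a)
  gr_a <- intervals_to_gr(calls_a)
  gr_b <- intervals_to_gr(calls_b)
  ov <- GenomicRanges::findOverlaps(gr_a, gr_b)
  q <- S4Vectors::queryHits(ov)
  s <- S4Vectors::subjectHits(ov)
  w_ov <- GenomicRanges::width(GenomicRanges::pintersect(gr_a[q], gr_b[s]))
  matched <- calls_a$cnv_type[q] == calls_b$cnv_type[s] &
    w_ov >= reciprocal_overlap * GenomicRanges::width(gr_a)[q] &
    w_ov >= reciprocal_overlap * GenomicRanges::width(gr_b)[s]
  out <- calls_a[setdiff(seq_len(nrow(calls_a)), unique(q[matched])), ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Concordance of depth-flagged bins with unique CNV calls
#'
#' A flagged bin is concordant when it overlaps at least one unique CNV
#' call by one or more bases.
#'
#' @param flagged_bins Flagged rows of [compare_bins()] output (or any
#'   interval data frame).
#' @param unique_calls Output of [unique_cnvs()].
#' @return List: `n_flagged`, `n_concordant`, `concordant` (the concordant
#'   bins).
#' @export
cnv_bin_concordance <- function(flagged_bins, unique_calls) {
  n_flagged <- nrow(flagged_bins)
  if (n_flagged == 0L || is.null(unique_calls) || nrow(unique_calls) == 0L) {
    return(list(n_flagged = n_flagged, n_concordant = 0L,
                concordant = flagged_bins[integer(), , drop = FALSE]))
  }
  ov <- GenomicRanges::findOverlaps(intervals_to_gr(flagged_bins),
                                    intervals_to_gr(unique_calls))
  hit <- sort(unique(S4Vectors::queryHits(ov)))
  list(n_flagged = n_flagged, n_concordant = length(hit),
       concordant = flagged_bins[hit, , drop = FALSE])
}

#' Filter translocation candidates to clone-unique, well-supported events
#'
#' Keeps candidates with strictly more than `min_reads` supporting reads and
#' no candidate of the same type in the other clone whose two breakpoints
#' both lie within `breakpoint_tol` bp (either breakpoint orientation).
#'
#' @param sv_a Candidate table (`chrom_a`, `pos_a`, `chrom_b`, `pos_b`,
#'   `sv_type`, `supporting_reads`).
#' @param sv_b The other clone's candidate table.
#' @param min_reads Support threshold; kept iff `supporting_reads >
#'   min_reads` (default 2).
#' @param breakpoint_tol Breakpoint matching tolerance in bp (default 1000).
#' @return The unique, supported subset of `sv_a`.
#' @export
filter_translocations <- function(sv_a, sv_b, min_reads = 2L,
                                  breakpoint_tol = 1000L) {
  keep <- sv_a[sv_a$supporting_reads > min_reads, , drop = FALSE]
  if (nrow(keep) == 0L || is.null(sv_b) || nrow(sv_b) == 0L) {
    rownames(keep) <- NULL
    return(keep)
  }
  near <- function(c1, p1, c2, p2) {
    c1 == c2 & abs(p1 - p2) <= breakpoint_tol
  }
  shared <- vapply(seq_len(nrow(keep)), function(i) {
    same_type <- sv_b$sv_type == keep$sv_type[i]
    fwd <- near(keep$chrom_a[i], keep$pos_a[i], sv_b$chrom_a, sv_b$pos_a) &
      near(keep$chrom_b[i], keep$pos_b[i], sv_b$chrom_b, sv_b$pos_b)
    rev <- near(keep$chrom_a[i], keep$pos_a[i], sv_b$chrom_b, sv_b$pos_b) &
      near(keep$chrom_b[i], keep$pos_b[i], sv_b$chrom_a, sv_b$pos_a)
    any(same_type & (fwd | rev))
  }, logical(1))
  out <- keep[!shared, , drop = FALSE]
  rownames(out) <- NULL
  out
}
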