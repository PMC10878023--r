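# Off-target landscape scanning: enumerate genomic near-matches of a guide
# under mismatch, PAM-degeneracy and single 1-bp bulge allowances.
#
# Site identity is PAM-anchored: the candidate alignments (no bulge, RNA
# bulge, DNA bulge) that share one PAM position and strand are explanations
# of the same physical site, and the minimal-mismatch explanation is
# reported (ties: none > rna > dna). Bulge placements are interior to the
# protospacer. Windows containing N are never reported.

#' Specify a guide RNA for off-target search
#'
#' @param protospacer Protospacer sequence over A/C/G/T, written 5'->3' with
#'   the PAM-proximal end last (Cas9 convention; PAM lies 3' of it).
#' @param pam_pattern IUPAC PAM pattern, e.g. "NGG", "NAG" or "NRG".
#' @param max_mismatches Maximum protospacer mismatches, 0-7.
#' @param bulge_size 0 (no bulges) or 1 (allow one 1-bp RNA or DNA bulge).
#' @return A `guide_spec` list.
#' @export
guide_spec <- function(protospacer, pam_pattern = "NGG",
                       max_mismatches = 4L, bulge_size = 0L) {
  protospacer <- toupper(protospacer)
  pam_pattern <- toupper(pam_pattern)
  if (grepl("[^ACGT]", protospacer) || nchar(protospacer) < 10L) {
    stop("protospacer must be >= 10 nt over A/C/G/T", call. = FALSE)
  }
  if (grepl(sprintf("[^%s]", paste(names(Biostrings::IUPAC_CODE_MAP),
                                   collapse = "")), pam_pattern)) {
    stop("pam_pattern must be IUPAC nucleotide codes", call. = FALSE)
  }
  if (!max_mismatches %in% 0:7) {
    stop("max_mismatches must be in 0..7", call. = FALSE)
  }
  if (!bulge_size %in% 0:1) stop("bulge_size must be 0 or 1", call. = FALSE)
  structure(list(protospacer = protospacer, pam_pattern = pam_pattern,
                 max_mismatches = as.integer(max_mismatches),
                 bulge_size = as.integer(bulge_size)),
            class = "guide_spec")
}

iupac_chars <- function(code) {
  strsplit(Biostrings::IUPAC_CODE_MAP[[code]], "")[[1]]
}

#' Does each observed PAM match an IUPAC pattern?
#' @noRd
pam_matches <- function(observed, pattern) {
  pat <- strsplit(pattern, "")[[1]]
  ok <- nchar(observed) == length(pat)
  obs <- strsplit(toupper(observed), "")
  for (j in seq_along(pat)) {
    allowed <- iupac_chars(pat[j])
    ok <- ok & vapply(obs, function(o) {
      length(o) >= j && o[j] %in% allowed
    }, logical(1))
  }
  ok
}

# Scan one strand-oriented sequence. Returns candidates in scan-space
# 0-based half-open coordinates. Column-sweep implementation: mismatch
# counts for all window starts at once; bulge placements folded in via
# prefix/suffix mismatch sums.
scan_strand <- function(seq_char, guide) {
  g <- nchar(guide$protospacer)
  pam <- strsplit(guide$pam_pattern, "")[[1]]
  p <- length(pam)
  L <- nchar(seq_char)
  none <- data.frame(q = integer(), mm = integer(), bulge = character())
  if (L < g + p) return(none)

  sraw <- charToRaw(seq_char)
  graw <- charToRaw(guide$protospacer)
  rawN <- charToRaw("N")
  ncum <- c(0L, cumsum(sraw == rawN))
  has_n <- function(a1, b1) (ncum[b1 + 1L] - ncum[a1]) > 0L

  # PAM match indicator over 1-based PAM starts 1..L-p+1
  Lp <- L - p + 1L
  pam_ok <- rep(TRUE, Lp)
  for (j in seq_len(p)) {
    allowed <- charToRaw(paste(iupac_chars(pam[j]), collapse = ""))
    sl <- sraw[seq.int(j, j + Lp - 1L)]
    okj <- sl == allowed[1]
    for (ch in allowed[-1]) okj <- okj | (sl == ch)
    pam_ok <- pam_ok & okj
  }

  sweep_mm <- function(width, pattern_at) {
    # pattern_at(i) gives the guide raw byte compared at window offset i
    K <- L - p - width + 1L
    if (K < 1L) return(NULL)
    ms <- vector("list", width)
    for (i in seq_len(width)) {
      ms[[i]] <- as.integer(sraw[seq.int(i, i + K - 1L)] != pattern_at(i))
    }
    ms
  }

  cand <- list()

  # --- no bulge ---
  K0 <- L - p - g + 1L
  if (K0 >= 1L) {
    mm0 <- integer(K0)
    for (i in seq_len(g)) {
      mm0 <- mm0 + (sraw[seq.int(i, i + K0 - 1L)] != graw[i])
    }
    q1 <- seq_len(K0) + g          # 1-based PAM start
    keep <- pam_ok[q1] & mm0 <= guide$max_mismatches
    w1 <- which(keep)
    if (length(w1)) {
      # footprint incl. PAM: [w, w + g + p - 1]
      w1 <- w1[!vapply(w1, function(o) has_n(o, o + g + p - 1L), logical(1))]
    }
    if (length(w1)) {
      cand$none <- data.frame(q = q1[w1], mm = mm0[w1], bulge = "none")
    }
  }

  if (guide$bulge_size >= 1L && g >= 4L) {
    # --- RNA bulge: one guide base (interior, positions 2..g-1) unpaired;
    #     genomic window one base shorter than the guide ---
    Kr <- L - p - (g - 1L) + 1L
    if (Kr >= 1L) {
      A <- sweep_mm(g - 1L, function(i) graw[i])        # guide prefix aligned
      B <- sweep_mm(g - 1L, function(i) graw[i + 1L])   # guide suffix aligned
      prefA <- vector("list", g)        # prefA[[k+1]] = sum_{i<=k} A_i
      prefA[[1]] <- integer(Kr)
      for (k in seq_len(g - 1L)) prefA[[k + 1L]] <- prefA[[k]] + A[[k]]
      sufB <- vector("list", g + 1L)    # sufB[[k]] = sum_{i>=k} B_i
      sufB[[g]] <- integer(Kr)
      for (k in rev(seq_len(g - 1L))) sufB[[k]] <- sufB[[k + 1L]] + B[[k]]
      mmr <- NULL
      for (d in 2:(g - 1L)) {          # deleted guide index, interior only
        md <- prefA[[d]] + sufB[[d]]
        mmr <- if (is.null(mmr)) md else pmin(mmr, md)
      }
      q1 <- seq_len(Kr) + (g - 1L)
      keep <- pam_ok[q1] & mmr <= guide$max_mismatches
      w1 <- which(keep)
      if (length(w1)) {
        w1 <- w1[!vapply(w1, function(o) has_n(o, o + g - 1L + p - 1L),
                         logical(1))]
      }
      if (length(w1)) {
        cand$rna <- data.frame(q = q1[w1], mm = mmr[w1], bulge = "rna")
      }
    }

    # --- DNA bulge: one genomic base (interior of the g+1 window) unpaired ---
    Kd <- L - p - (g + 1L) + 1L
    if (Kd >= 1L) {
      C <- sweep_mm(g + 1L, function(i) if (i <= g) graw[i] else graw[g])
      # C_i compares window offset i to guide i (left-aligned), i = 1..g
      D <- vector("list", g)
      for (i in seq_len(g)) {
        D[[i]] <- as.integer(sraw[seq.int(i + 1L, i + Kd)] != graw[i])
      }
      prefC <- vector("list", g + 1L)
      prefC[[1]] <- integer(Kd)
      for (k in seq_len(g)) prefC[[k + 1L]] <- prefC[[k]] + C[[k]]
      sufD <- vector("list", g + 2L)
      sufD[[g + 1L]] <- integer(Kd)
      for (k in rev(seq_len(g))) sufD[[k]] <- sufD[[k + 1L]] + D[[k]]
      mmd <- NULL
      for (t in 2:g) {                 # bulged window position, interior
        mt <- prefC[[t]] + sufD[[t]]
        mmd <- if (is.null(mmd)) mt else pmin(mmd, mt)
      }
      q1 <- seq_len(Kd) + (g + 1L)
      keep <- pam_ok[q1] & mmd <= guide$max_mismatches
      w1 <- which(keep)
      if (length(w1)) {
        w1 <- w1[!vapply(w1, function(o) has_n(o, o + g + 1L + p - 1L),
                         logical(1))]
      }
      if (length(w1)) {
        cand$dna <- data.frame(q = q1[w1], mm = mmd[w1], bulge = "dna")
      }
    }
  }

  if (length(cand) == 0L) return(none)
  all_c <- do.call(rbind, cand)
  # PAM-anchored dedup with precedence none > rna > dna at equal mismatches
  prec <- match(all_c$bulge, c("none", "rna", "dna"))
  ord <- order(all_c$q, all_c$mm, prec)
  all_c <- all_c[ord, , drop = FALSE]
  all_c <- all_c[!duplicated(all_c$q), , drop = FALSE]

  flen <- g + c(none = 0L, rna = -1L, dna = 1L)[all_c$bulge]
  data.frame(
    q = all_c$q,
    mm = all_c$mm,
    bulge = all_c$bulge,
    fstart0 = all_c$q - flen - 1L,          # 0-based footprint start
    fend0 = all_c$q + p - 1L,               # 0-based half-open footprint end
    proto_seq = substring(seq_char, all_c$q - flen, all_c$q - 1L),
    pam_seq = substring(seq_char, all_c$q, all_c$q + p - 1L),
    stringsAsFactors = FALSE
  )
}

#' Enumerate genomic off-target sites of a guide
#'
#' Scans both strands of every chromosome for sites within the guide's
#' mismatch allowance whose PAM matches the IUPAC pattern exactly (zero PAM
#' mismatches); mismatches are counted over the protospacer only. With
#' `bulge_size = 1`, sites reachable with one interior 1-bp bulge (RNA bulge:
#' genomic site one base shorter; DNA bulge: one base longer) are also
#' reported with their minimal mismatch count; a site explicable without a
#' bulge is reported as `bulge = "none"`. Minus-strand hits are reported in
#' plus-strand coordinates. Any footprint containing an N is excluded.
#'
#' @param genome A `genome_sequence`.
#' @param guide A [guide_spec()].
#' @param exclude Optional data frame of 0-based half-open intervals
#'   (`chrom`, `start`, `end`); overlapping sites (e.g. the on-target locus)
#'   are removed.
#' @return Data frame sorted by (chrom, start, strand) with columns `chrom`,
#'   `start`, `end` (0-based half-open footprint incl. PAM), `strand`,
#'   `mismatches`, `bulge` ("none"/"rna"/"dna"), `site_sequence`
#'   (protospacer-aligned genomic sequence in guide orientation) and
#'   `pam_observed`.
#' @export
find_offtarget_sites <- function(genome, guide, exclude = NULL) {
  check_genome(genome)
  stopifnot(inherits(guide, "guide_spec"))
  out <- list()
  for (chrom in names(genome)) {
    fwd <- unclass(genome)[[chrom]]
    L <- nchar(fwd)
    hits_f <- scan_strand(fwd, guide)
    if (nrow(hits_f)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = hits_f$fstart0, end = hits_f$fend0,
        strand = "+", mismatches = hits_f$mm, bulge = hits_f$bulge,
        site_sequence = hits_f$proto_seq, pam_observed = hits_f$pam_seq,
        stringsAsFactors = FALSE)
    }
    rev <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
    hits_r <- scan_strand(rev, guide)
    if (nrow(hits_r)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = L - hits_r$fend0, end = L - hits_r$fstart0,
        strand = "-", mismatches = hits_r$mm, bulge = hits_r$bulge,
        site_sequence = hits_r$proto_seq, pam_observed = hits_r$pam_seq,
        stringsAsFactors = FALSE)
    }
  }
  sites <- if (length(out)) do.call(rbind, out) else data.frame(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), mismatches = integer(), bulge = character(),
    site_sequence = character(), pam_observed = character(),
    stringsAsFactors = FALSE)
  if (!is.null(exclude) && nrow(sites) && nrow(exclude)) {
    ov <- GenomicRanges::findOverlaps(intervals_to_gr(sites),
                                      intervals_to_gr(exclude))
    drop <- unique(S4Vectors::queryHits(ov))
    if (length(drop)) sites <- sites[-drop, , drop = FALSE]
  }
  sites <- sites[order(sites$chrom, sites$start, sites$strand), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Default off-target category grid
#'
#' Exact-mismatch categories crossed with NGG/NRG PAM and with/without a
#' 1-bp bulge, mirroring the per-panel categories of an off-target INDEL
#' enrichment figure.
#'
#' @param mismatches Integer vector of exact mismatch counts.
#' @param pam Character vector of IUPAC PAM patterns.
#' @param bulge Character vector over "none"/"rna"/"dna"/"bulge"/"any"
#'   ("bulge" = any 1-bp bulge).
#' @return Data frame with one row per category.
#' @export
offtarget_categories <- function(mismatches = 0:7, pam = c("NGG", "NRG"),
                                 bulge = c("none", "bulge")) {
  expand.grid(mismatches = as.integer(mismatches), pam = pam, bulge = bulge,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Assign off-target sites to (mismatch, PAM, bulge) categories
#'
#' A site belongs to a category when its mismatch count equals the category's
#' exactly, its observed PAM matches the category's IUPAC pattern (so NRG
#' categories are the union of NGG and NAG matches) and its bulge status
#' matches ("bulge" accepts either bulge direction, "any" accepts all).
#'
#' @param sites Output of [find_offtarget_sites()].
#' @param categories Data frame as from [offtarget_categories()].
#' @return `categories` with added `n_sites` and a `regions` list-column of
#'   0-based half-open interval data frames.
#' @export
categorize_sites <- function(sites, categories = offtarget_categories()) {
  stopifnot(all(c("mismatches", "pam", "bulge") %in% names(categories)))
  regions <- vector("list", nrow(categories))
  n_sites <- integer(nrow(categories))
  for (k in seq_len(nrow(categories))) {
    sel <- sites$mismatches == categories$mismatches[k] &
      pam_matches(sites$pam_observed, categories$pam[k]) &
      switch(categories$bulge[k],
             none = sites$bulge == "none",
             rna = sites$bulge == "rna",
             dna = sites$bulge == "dna",
             bulge = sites$bulge %in% c("rna", "dna"),
             any = rep(TRUE, nrow(sites)),
             stop("unknown bulge category: ", categories$bulge[k]))
    sub <- sites[sel, c("chrom", "start", "end"), drop = FALSE]
    rownames(sub) <- NULL
    regions[[k]] <- sub
    n_sites[k] <- nrow(sub)
  }
  categories$n_sites <- n_sites
  categories$regions <- regions
  categories
}
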