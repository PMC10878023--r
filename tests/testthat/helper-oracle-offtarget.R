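# Independent brute-force oracle for the off-target scanner: at every PAM
# position and strand, explicitly tries the bulge-free alignment and every
# interior 1-bp bulge placement by string surgery, and keeps the
# minimal-mismatch explanation (ties: none > rna > dna). Shares only the
# site definition with the package implementation, not its algorithm.

oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_scan_one <- function(chars, guide_chars, pam_chars, max_mm,
                            bulge_size) {
  g <- length(guide_chars)
  p <- length(pam_chars)
  L <- length(chars)
  out <- list()
  for (q in seq_len(L - p + 1L)) {
    pam_obs <- chars[q:(q + p - 1L)]
    if (any(pam_obs == "N")) next
    pam_hit <- all(vapply(seq_len(p), function(j) {
      pam_obs[j] %in% oracle_iupac[[pam_chars[j]]]
    }, logical(1)))
    if (!pam_hit) next
    best_mm <- Inf
    best_bulge <- NA_character_
    consider <- function(mm, bulge) {
      prec <- match(bulge, c("none", "rna", "dna"))
      best_prec <- match(best_bulge, c("none", "rna", "dna"))
      if (mm < best_mm || (mm == best_mm && prec < best_prec)) {
        best_mm <<- mm
        best_bulge <<- bulge
      }
    }
    if (q - g >= 1L) {
      w <- chars[(q - g):(q - 1L)]
      if (!any(w == "N")) consider(sum(w != guide_chars), "none")
    }
    if (bulge_size >= 1L && g >= 4L) {
      if (q - (g - 1L) >= 1L) {
        w <- chars[(q - g + 1L):(q - 1L)]
        if (!any(w == "N")) {
          for (d in 2:(g - 1L)) {
            consider(sum(w != guide_chars[-d]), "rna")
          }
        }
      }
      if (q - (g + 1L) >= 1L) {
        w <- chars[(q - g - 1L):(q - 1L)]
        if (!any(w == "N")) {
          for (t in 2:g) {
            consider(sum(w[-t] != guide_chars), "dna")
          }
        }
      }
    }
    if (is.finite(best_mm) && best_mm <= max_mm) {
      flen <- g + c(none = 0L, rna = -1L, dna = 1L)[[best_bulge]]
      out[[length(out) + 1L]] <- data.frame(
        fstart0 = q - flen - 1L, fend0 = q + p - 1L,
        mismatches = best_mm, bulge = best_bulge,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(fstart0 = integer(), fend0 = integer(),
                      mismatches = integer(), bulge = character()))
  }
  do.call(rbind, out)
}

oracle_offtarget_sites <- function(genome, guide) {
  guide_chars <- strsplit(guide$protospacer, "")[[1]]
  pam_chars <- strsplit(guide$pam_pattern, "")[[1]]
  res <- list()
  for (chrom in names(genome)) {
    fwd <- unclass(genome)[[chrom]]
    L <- nchar(fwd)
    hf <- oracle_scan_one(strsplit(fwd, "")[[1]], guide_chars, pam_chars,
                          guide$max_mismatches, guide$bulge_size)
    if (nrow(hf)) {
      res[[length(res) + 1L]] <- data.frame(
        chrom = chrom, start = hf$fstart0, end = hf$fend0, strand = "+",
        mismatches = hf$mismatches, bulge = hf$bulge,
        stringsAsFactors = FALSE)
    }
    rev <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
    hr <- oracle_scan_one(strsplit(rev, "")[[1]], guide_chars, pam_chars,
                          guide$max_mismatches, guide$bulge_size)
    if (nrow(hr)) {
      res[[length(res) + 1L]] <- data.frame(
        chrom = chrom, start = L - hr$fend0, end = L - hr$fstart0,
        strand = "-", mismatches = hr$mismatches, bulge = hr$bulge,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else data.frame(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), mismatches = integer(), bulge = character(),
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

site_key <- function(sites) {
  sprintf("%s:%d-%d:%s:mm%d:%s", sites$chrom, sites$start, sites$end,
          sites$strand, sites$mismatches, sites$bulge)
}
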