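# VCF input (via vcfR) and a minimal VCF text writer for simulated callsets.

INFO_STATS <- c("FS", "QD", "MQ", "SOR", "MQRankSum", "ReadPosRankSum")

#' Construct a clone callset
#'
#' A callset is a data frame of per-ALT variant records for one clone, sorted
#' by (chrom, pos). Columns: `chrom`, `pos` (1-based first REF base), `ref`,
#' `alt`, `vtype` ("SNV"/"INDEL"), `qual`, the six GATK site statistics
#' (`FS`, `QD`, `MQ`, `SOR`, `MQRankSum`, `ReadPosRankSum`; `NA` = absent),
#' `gt` (normalized unphased genotype string, e.g. "0/1"), `depth`,
#' `alt_reads` and `n_alt` (number of ALT alleles at the source site).
#'
#' @param records Data frame with the columns above.
#' @param clone_id Non-empty clone identifier.
#' @return A `clone_callset` (data frame with attribute `clone_id`).
#' @export
clone_callset <- function(records, clone_id) {
  stopifnot(is.character(clone_id), length(clone_id) == 1L, nzchar(clone_id))
  needed <- c("chrom", "pos", "ref", "alt", "vtype", "qual", INFO_STATS,
              "gt", "depth", "alt_reads", "n_alt")
  miss <- setdiff(needed, names(records))
  if (length(miss)) {
    stop("callset is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(records$pos < 1L)) stop("pos must be >= 1", call. = FALSE)
  bad <- !is.na(records$depth) & !is.na(records$alt_reads) &
    records$alt_reads > records$depth
  if (any(bad)) stop("alt_reads > depth at ", sum(bad), " record(s)",
                     call. = FALSE)
  snv <- nchar(records$ref) == 1L & nchar(records$alt) == 1L
  if (any(records$vtype != ifelse(snv, "SNV", "INDEL"))) {
    stop("vtype inconsistent with REF/ALT lengths", call. = FALSE)
  }
  ord <- order(records$chrom, records$pos, records$ref, records$alt)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  structure(records, clone_id = clone_id,
            class = c("clone_callset", "data.frame"))
}

#' Clone identifier of a callset
#' @param callset A `clone_callset`.
#' @return Character scalar.
#' @export
clone_id <- function(callset) attr(callset, "clone_id")

#' Normalize a genotype string
#'
#' Phasing is dropped and allele indices sorted, so "1|0" becomes "0/1".
#' Missing genotypes ("./.", ".") return `NA`.
#' @noRd
normalize_gt <- function(gt) {
  gt <- sub(":.*$", "", gt)
  out <- rep(NA_character_, length(gt))
  ok <- !is.na(gt) & !grepl("\\.", gt) & nzchar(gt)
  if (any(ok)) {
    parts <- strsplit(gt[ok], "[/|]")
    out[ok] <- vapply(parts, function(p) {
      paste(sort(as.integer(p)), collapse = "/")
    }, character(1))
  }
  out
}

#' Read one sample's callset from a VCF
#'
#' Multi-allelic records are decomposed into one record per ALT allele, each
#' inheriting the site-level statistics. Symbolic ALTs (`<DEL>` etc.) and
#' spanning-deletion alleles (`*`) are dropped and counted. Site statistics
#' absent from INFO stay `NA` (absent, not zero). Depth comes from the
#' per-sample `DP` field and `alt_reads` from the ALT component of `AD`.
#'
#' @param path VCF 4.x file (plain text or bgzipped).
#' @param sample Sample name present in the VCF.
#' @return A [clone_callset()] with attribute `n_dropped_symbolic` counting
#'   dropped symbolic/spanning alleles.
#' @export
read_vcf <- function(path, sample) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (!sample %in% samples) {
    stop("sample '", sample, "' not in VCF (has: ",
         paste(samples, collapse = ", "), ")", call. = FALSE)
  }
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0L) {
    empty <- data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        vtype = character(), qual = double())
    for (s in INFO_STATS) empty[[s]] <- double()
    empty$gt <- character(); empty$depth <- integer()
    empty$alt_reads <- integer(); empty$n_alt <- integer()
    return(clone_callset(empty, sample))
  }

  info <- lapply(INFO_STATS, function(s) {
    suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = s)))
  })
  names(info) <- INFO_STATS
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")[, sample]
  dp_raw <- suppressWarnings(
    as.integer(vcfR::extract.gt(vcf, element = "DP")[, sample]))
  ad_raw <- vcfR::extract.gt(vcf, element = "AD")[, sample]

  alt_list <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",",
                       fixed = TRUE)
  n_alt_site <- lengths(alt_list)
  ad_list <- strsplit(ifelse(is.na(ad_raw), "", ad_raw), ",", fixed = TRUE)

  rec <- vector("list", n)
  n_symbolic <- 0L
  for (i in seq_len(n)) {
    alts <- alt_list[[i]]
    if (length(alts) == 0L) next
    symbolic <- grepl("[<>*]", alts) | grepl("[^ACGTNacgtn]", alts)
    n_symbolic <- n_symbolic + sum(symbolic)
    keep <- which(!symbolic)
    if (length(keep) == 0L) next
    ad <- suppressWarnings(as.integer(ad_list[[i]]))
    rec[[i]] <- data.frame(
      chrom = unname(fix[i, "CHROM"]),
      pos = as.integer(unname(fix[i, "POS"])),
      ref = toupper(unname(fix[i, "REF"])),
      alt = unname(toupper(alts[keep])),
      qual = suppressWarnings(as.numeric(unname(fix[i, "QUAL"]))),
      gt = normalize_gt(unname(gt_raw[i])),
      depth = unname(dp_raw[i]),
      alt_reads = if (length(ad) >= 2L) ad[keep + 1L] else NA_integer_,
      n_alt = unname(n_alt_site[i]),
      idx = i,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rec[!vapply(rec, is.null, logical(1))])
  if (is.null(out)) {
    return(read_vcf_empty(sample, n_symbolic))
  }
  for (s in INFO_STATS) out[[s]] <- info[[s]][out$idx]
  out$idx <- NULL
  out$vtype <- ifelse(nchar(out$ref) == 1L & nchar(out$alt) == 1L,
                      "SNV", "INDEL")
  # clamp impossible AD/DP combinations rather than failing the whole file
  bad <- !is.na(out$depth) & !is.na(out$alt_reads) & out$alt_reads > out$depth
  if (any(bad)) {
    warning(sum(bad), " record(s) with AD > DP; depth raised to AD")
    out$depth[bad] <- out$alt_reads[bad]
  }
  cs <- clone_callset(out, sample)
  attr(cs, "n_dropped_symbolic") <- n_symbolic
  cs
}

read_vcf_empty <- function(sample, n_symbolic) {
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), vtype = character(), qual = double())
  for (s in INFO_STATS) empty[[s]] <- double()
  empty$gt <- character(); empty$depth <- integer()
  empty$alt_reads <- integer(); empty$n_alt <- integer()
  cs <- clone_callset(empty, sample)
  attr(cs, "n_dropped_symbolic") <- n_symbolic
  cs
}

#' Write a joint multi-sample VCF (4.2 text)
#'
#' Emits the simulated sites of several clones as one jointly-genotyped VCF,
#' the shape produced by cohort genotyping. `sites` holds one row per site
#' (`chrom`, `pos`, `ref`, `alt`, `qual` and any of the six site statistics);
#' `sample_data` is a named list with one data frame per sample holding `gt`,
#' `depth` and `alt_reads` aligned row-by-row with `sites`.
#'
#' @param sites Site-level data frame.
#' @param sample_data Named list of per-sample data frames.
#' @param path Output path.
#' @param contigs Named integer vector of chromosome lengths for the header.
#' @return `path`, invisibly.
#' @export
write_joint_vcf <- function(sites, sample_data, path, contigs = NULL) {
  stopifnot(length(names(sample_data)) == length(sample_data))
  ord <- order(sites$chrom, sites$pos, sites$ref, sites$alt)
  sites <- sites[ord, , drop = FALSE]
  sample_data <- lapply(sample_data, function(d) d[ord, , drop = FALSE])

  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=cloneconfound-simulator",
    if (!is.null(contigs)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contigs),
              as.integer(contigs))
    },
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
            INFO_STATS, INFO_STATS),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", names(sample_data)), collapse = "\t")
  )

  info_cols <- intersect(INFO_STATS, names(sites))
  fmt <- vapply(info_cols, function(s) {
    v <- sites[[s]]
    ifelse(is.na(v), NA_character_,
           sprintf("%s=%s", s, formatC(v, format = "g", digits = 6)))
  }, character(nrow(sites)))
  if (is.null(dim(fmt))) fmt <- matrix(fmt, nrow = nrow(sites))
  info <- apply(fmt, 1L, function(r) {
    r <- r[!is.na(r)]
    if (!length(r)) "." else paste(r, collapse = ";")
  })

  fields <- lapply(sample_data, function(d) {
    ad <- paste(d$depth - d$alt_reads, d$alt_reads, sep = ",")
    sprintf("%s:%s:%d", d$gt, ad, d$depth)
  })
  body <- do.call(paste, c(
    list(sites$chrom, sites$pos, ".", sites$ref, sites$alt,
         formatC(sites$qual, format = "f", digits = 2), "PASS", info,
         "GT:AD:DP"),
    fields, sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}
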