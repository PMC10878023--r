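# Coverage tracks and interval tables (BED / CNV / SV dialects).
#
# Internal convention: intervals are 0-based half-open; coverage positions
# are stored 1-based (the default output of per-base genome-coverage tools).

#' Read a per-base coverage track
#'
#' Three tab-separated columns: chrom, position, integer depth — the layout
#' written by `bedtools genomecov -d` (1-based positions) or `-dz` (0-based).
#'
#' @param path Coverage TSV; may be empty.
#' @param coord_dialect "1-based" (default, `-d`) or "0-based" (`-dz`);
#'   0-based input positions are shifted to the internal 1-based convention.
#' @param strip_chr Drop a leading "chr" from chromosome names.
#' @return Data frame with columns `chrom`, `pos` (1-based), `depth`.
#' @export
read_coverage <- function(path, coord_dialect = c("1-based", "0-based"),
                          strip_chr = FALSE) {
  coord_dialect <- match.arg(coord_dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      depth = integer()))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1),
                          showProgress = FALSE)
  if (ncol(dt) != 3L) {
    stop("coverage file must have 3 columns, found ", ncol(dt), call. = FALSE)
  }
  data.table::setnames(dt, c("chrom", "pos", "depth"))
  if (!is.numeric(dt$pos) || !is.numeric(dt$depth) ||
      any(dt$depth != as.integer(dt$depth)) || any(dt$depth < 0)) {
    stop("coverage depth must be a non-negative integer", call. = FALSE)
  }
  if (coord_dialect == "0-based") dt[, pos := pos + 1L]
  if (strip_chr) dt[, chrom := sub("^chr", "", chrom)]
  out <- as.data.frame(dt)
  out$pos <- as.integer(out$pos)
  out$depth <- as.integer(out$depth)
  out
}

#' Write a coverage track (1-based positions, TSV)
#'
#' @param coverage Data frame with `chrom`, `pos`, `depth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(coverage, path) {
  data.table::fwrite(coverage[, c("chrom", "pos", "depth")], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read an interval table (BED, CNV-call or SV-candidate dialect)
#'
#' BED input is already 0-based half-open; the `cnv` and `sv` dialects are
#' 1-based inclusive and are converted to the internal 0-based half-open
#' convention on read.
#'
#' Columns by dialect:
#' * `bed`: chrom, start, end, (name ...)
#' * `cnv`: chrom, start, end, type (deletion/duplication)
#' * `sv`: chromA, posA, chromB, posB, type, supporting_reads
#'
#' @param path Tab-separated file.
#' @param dialect One of "bed", "cnv", "sv".
#' @param strip_chr Drop a leading "chr" from chromosome names.
#' @return For `bed`/`cnv`: a data frame `chrom`, `start`, `end` (0-based
#'   half-open) plus `label` (BED name) or `cnv_type`. For `sv`: a data frame
#'   `chrom_a`, `pos_a`, `chrom_b`, `pos_b` (1-based breakpoints), `sv_type`,
#'   `supporting_reads`.
#' @export
read_interval_table <- function(path, dialect = c("bed", "cnv", "sv"),
                                strip_chr = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    return(switch(dialect,
      bed = empty_intervals(),
      cnv = data.frame(chrom = character(), start = integer(),
                       end = integer(), cnv_type = character()),
      sv = data.frame(chrom_a = character(), pos_a = integer(),
                      chrom_b = character(), pos_b = integer(),
                      sv_type = character(), supporting_reads = integer())))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          showProgress = FALSE)
  if (dialect == "sv") {
    if (ncol(dt) < 6L) stop("sv dialect needs 6 columns", call. = FALSE)
    out <- data.frame(chrom_a = as.character(dt[[1]]),
                      pos_a = as.integer(dt[[2]]),
                      chrom_b = as.character(dt[[3]]),
                      pos_b = as.integer(dt[[4]]),
                      sv_type = as.character(dt[[5]]),
                      supporting_reads = as.integer(dt[[6]]))
    if (strip_chr) {
      out$chrom_a <- sub("^chr", "", out$chrom_a)
      out$chrom_b <- sub("^chr", "", out$chrom_b)
    }
    return(out)
  }
  if (ncol(dt) < 3L) stop(dialect, " dialect needs >= 3 columns",
                          call. = FALSE)
  start <- as.integer(dt[[2]])
  end <- as.integer(dt[[3]])
  if (dialect == "cnv") {
    # 1-based inclusive -> 0-based half-open
    start <- start - 1L
  }
  bad <- which(start >= end | start < 0L)
  if (length(bad)) {
    stop("invalid interval (start >= end after conversion) at line ",
         bad[1], call. = FALSE)
  }
  chrom <- as.character(dt[[1]])
  if (strip_chr) chrom <- sub("^chr", "", chrom)
  if (dialect == "bed") {
    out <- data.frame(chrom = chrom, start = start, end = end,
                      label = if (ncol(dt) >= 4L) as.character(dt[[4]])
                              else NA_character_)
  } else {
    type <- tolower(as.character(dt[[4]]))
    if (!all(type %in% c("deletion", "duplication"))) {
      stop("cnv type must be deletion/duplication", call. = FALSE)
    }
    out <- data.frame(chrom = chrom, start = start, end = end,
                      cnv_type = type)
  }
  out
}

#' Write intervals as BED3+name
#'
#' @param intervals Data frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- intervals[, c("chrom", "start", "end")]
  if (!is.null(intervals$label)) cols$label <- intervals$label
  data.table::fwrite(cols, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
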