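# Internal helpers: seeded RNG scoping, interval conversion, input checks.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores (or removes) the global `.Random.seed` afterwards so that seeded
#' package functions never perturb the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  code
}

#' Derive a reproducible sub-seed from a parent seed
#'
#' Keeps derived seeds inside the 32-bit integer range.
#' @noRd
sub_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + 1103 * as.double(i)) %% 2147483629)
}

#' Convert 0-based half-open interval data frame to GRanges
#'
#' Internal intervals are 0-based half-open; GRanges is 1-based closed.
#' @noRd
intervals_to_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

#' GRanges for the REF span of variant records (1-based pos, width nchar(ref))
#' @noRd
refspan_gr <- function(records) {
  GenomicRanges::GRanges(
    seqnames = records$chrom,
    ranges = IRanges::IRanges(
      start = records$pos,
      end = records$pos + nchar(records$ref) - 1L
    )
  )
}

#' Validate a genome_sequence object
#' @noRd
check_genome <- function(genome) {
  if (!inherits(genome, "genome_sequence")) {
    stop("expected a 'genome_sequence' (see read_fasta()/make_genome())",
         call. = FALSE)
  }
  invisible(genome)
}

empty_intervals <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             label = character(), stringsAsFactors = FALSE)
}
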