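#' Genome sequence container
#'
#' A genome is stored as a named character vector of uppercase chromosome
#' sequences over the alphabet A/C/G/T/N, with class `genome_sequence`.
#' Chromosome order is the order of the input; names must be unique and
#' every chromosome must be non-empty.
#'
#' @param sequences Named character vector of nucleotide sequences.
#' @return A `genome_sequence` object.
#' @export
genome_sequence <- function(sequences) {
  if (length(sequences) == 0L) stop("genome has no chromosomes", call. = FALSE)
  nm <- names(sequences)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("every chromosome needs a name", call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  sequences <- toupper(sequences)
  if (any(nchar(sequences) == 0L)) {
    stop("zero-length chromosome(s): ",
         paste(nm[nchar(sequences) == 0L], collapse = ", "), call. = FALSE)
  }
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    stop("non-ACGTN characters in chromosome(s): ",
         paste(nm[bad], collapse = ", "), call. = FALSE)
  }
  structure(as.character(sequences), names = nm, class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat("genome_sequence with", length(x), "chromosome(s)\n")
  print(data.frame(chrom = names(x), length = nchar(unclass(x)),
                   row.names = NULL))
  invisible(x)
}

#' Chromosome lengths of a genome
#'
#' @param genome A `genome_sequence`.
#' @return Named integer vector of chromosome lengths in bases.
#' @export
chrom_lengths <- function(genome) {
  check_genome(genome)
  setNames(nchar(unclass(genome)), names(genome))
}

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased (soft-masking is discarded); Ns are retained.
#'
#' @param path Path to a FASTA file.
#' @return A `genome_sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  # headers may carry descriptions after the first whitespace
  nm <- sub("\\s.*$", "", names(set))
  genome_sequence(setNames(as.character(set), nm))
}

#' Write a genome to FASTA
#'
#' Fixed 70-column wrapping so identical genomes produce byte-identical files.
#'
#' @param genome A `genome_sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  check_genome(genome)
  set <- Biostrings::DNAStringSet(unclass(genome))
  names(set) <- names(genome)
  Biostrings::writeXStringSet(set, filepath = path, width = 70L)
  invisible(path)
}
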