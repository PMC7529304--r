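# Reference genome loading and flank extraction.
#
# Coordinates are 1-based inclusive throughout (VCF convention). Flank
# requests running past a contig end are truncated, never padded, so
# genome-edge events remain scorable with microhomology capped by the
# available flank.

#' Load a reference genome from FASTA
#'
#' Reads a (plain or gzip) multi-record FASTA file. Sequences are
#' upper-cased and any character outside A,C,G,T,N is mapped to N, so
#' soft-masked references behave identically to unmasked ones and IUPAC
#' ambiguity codes can never produce spurious microhomology.
#'
#' @param path Path to a FASTA file.
#' @return A \code{\linkS4class{GenomeSequence}}.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' contigLengths(loadGenome(fa))
#' @export
loadGenome <- function(path) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path)
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e)
                     stop("failed to parse FASTA '", path, "': ",
                          conditionMessage(e), call. = FALSE))
  if (length(seqs) == 0L)
    stop("FASTA file contains no records: ", path)
  # FASTA headers may carry descriptions; the contig name is the first word
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm))
    stop("duplicate contig name(s) in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  ctg <- toupper(as.character(seqs))
  ctg <- gsub("[^ACGTN]", "N", ctg)
  names(ctg) <- nm
  new("GenomeSequence", contigs = ctg)
}

#' Construct a GenomeSequence from in-memory sequences
#'
#' @param contigs Named character vector of nucleotide sequences. The same
#'   cleanup as \code{\link{loadGenome}} is applied (upper-case, non-ACGTN
#'   to N).
#' @return A \code{\linkS4class{GenomeSequence}}.
#' @export
genomeSequence <- function(contigs) {
  ctg <- gsub("[^ACGTN]", "N", toupper(contigs))
  names(ctg) <- names(contigs)
  new("GenomeSequence", contigs = ctg)
}

#' Extract a flanking sequence from the reference
#'
#' Returns up to \code{length} reference bases adjacent to a position,
#' always reported 5'->3' on the reference strand. \code{downstream} gives
#' the window starting at \code{start} and running right;
#' \code{upstream} gives the window ending at \code{start} and running
#' left. Windows are truncated (never padded) at contig ends.
#'
#' @param genome A \code{\linkS4class{GenomeSequence}}.
#' @param contig Contig name.
#' @param start 1-based inclusive position anchoring the window.
#' @param length Maximum number of bases to return (positive integer).
#' @param direction \code{"downstream"} (window = \code{[start,
#'   start+length-1]}) or \code{"upstream"} (window = \code{[start-length+1,
#'   start]}).
#' @return A nucleotide string of at most \code{length} characters.
#' @examples
#' g <- genomeSequence(c(c1 = "AAACGTTT"))
#' extractFlank(g, "c1", 4, 3, "downstream")  # "CGT"
#' extractFlank(g, "c1", 3, 2, "upstream")    # "AA"
#' @export
extractFlank <- function(genome, contig, start, length,
                         direction = c("downstream", "upstream")) {
  direction <- match.arg(direction)
  seq <- getContig(genome, contig)
  n <- nchar(seq)
  if (length < 1L) stop("flank length must be positive")
  if (start < 1L || start > n)
    stop("position ", start, " out of range for contig ", contig,
         " (length ", n, ")")
  if (direction == "downstream") {
    substr(seq, start, min(start + length - 1, n))
  } else {
    substr(seq, max(1, start - length + 1), start)
  }
}

#' Write a GenomeSequence to FASTA
#'
#' @param genome A \code{\linkS4class{GenomeSequence}}.
#' @param path Output FASTA path.
#' @return \code{path}, invisibly.
#' @export
writeGenomeFasta <- function(genome, path) {
  dna <- Biostrings::DNAStringSet(genome@contigs)
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}
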