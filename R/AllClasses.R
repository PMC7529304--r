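# S4 containers for the MMEJ signature pipeline.

#' GenomeSequence: a reference genome held in memory
#'
#' Named upper-case nucleotide sequences (alphabet A,C,G,T,N), one element
#' per contig. Built by \code{\link{loadGenome}} or
#' \code{\link{simulateReference}}; queried with \code{\link{extractFlank}}.
#'
#' @slot contigs Named character vector, one sequence per contig.
#' @seealso \code{\link{loadGenome}}, \code{\link{extractFlank}}
#' @exportClass GenomeSequence
setClass("GenomeSequence", representation(contigs = "character"))

setValidity("GenomeSequence", function(object) {
  ctg <- object@contigs
  if (length(ctg) == 0L)
    return("genome must contain at least one contig")
  nm <- names(ctg)
  if (is.null(nm) || any(!nzchar(nm)))
    return("all contigs must be named")
  if (anyDuplicated(nm))
    return("duplicate contig names")
  if (any(nchar(ctg) == 0L))
    return("empty contig sequence")
  if (any(grepl("[^ACGTN]", ctg)))
    return("contig sequences may contain only A,C,G,T,N")
  TRUE
})

#' IndelSet: normalized indel calls for one sample
#'
#' A collection of insertion/deletion calls in anchor-base representation:
#' exactly one of REF/ALT is a single base (the anchor), and \code{event_seq}
#' is the inserted or deleted nucleotides with the anchor excluded. Records
#' are keyed by \code{contig:pos:ref:alt}; keys are unique within a set.
#'
#' @slot records data.frame with columns \code{contig}, \code{pos} (1-based
#'   anchor position), \code{ref}, \code{alt}, \code{qual}, \code{kind}
#'   ("insertion"/"deletion"), \code{event_seq}, \code{event_len}, \code{key}.
#' @slot sampleLabel Free-text sample label.
#' @seealso \code{\link{readIndels}}, \code{\link{indelRecords}}
#' @exportClass IndelSet
setClass("IndelSet",
         representation(records = "data.frame", sampleLabel = "character"))

.INDEL_COLS <- c("contig", "pos", "ref", "alt", "qual", "kind",
                 "event_seq", "event_len", "key")

.emptyIndelFrame <- function() {
  data.frame(contig = character(), pos = integer(), ref = character(),
             alt = character(), qual = numeric(), kind = character(),
             event_seq = character(), event_len = integer(),
             key = character(), stringsAsFactors = FALSE)
}

setValidity("IndelSet", function(object) {
  rec <- object@records
  if (!all(.INDEL_COLS %in% names(rec)))
    return(paste("records must have columns:",
                 paste(.INDEL_COLS, collapse = ", ")))
  if (nrow(rec) == 0L) return(TRUE)
  if (anyDuplicated(rec$key))
    return("duplicate indel keys within a set")
  if (any(nchar(rec$ref) == nchar(rec$alt)))
    return("SNV/MNV records are not allowed in an IndelSet")
  oneSide <- xor(nchar(rec$ref) == 1L, nchar(rec$alt) == 1L)
  if (!all(oneSide))
    return("records must be in anchor-base representation")
  if (any(rec$event_len < 1L))
    return("event_len must be >= 1")
  delOk <- rec$kind == "deletion" & nchar(rec$ref) > nchar(rec$alt) |
    rec$kind == "insertion" & nchar(rec$alt) > nchar(rec$ref)
  if (!all(delOk))
    return("kind inconsistent with allele lengths")
  TRUE
})

#' IndelPartition: pre-existing vs newly arisen indels for one subject
#'
#' The partition of one subject's post-transformation ("LCL") call set into
#' the intersection with the matched pre-transformation ("B-cell") set
#' (pre-existing indels, assumed to predate transformation) and the
#' post-unique remainder (newly arisen indels).
#'
#' @slot preexisting \code{IndelSet}: intersection of the two samples.
#' @slot new \code{IndelSet}: calls unique to the post sample.
#' @slot subjectLabel Free-text subject label.
#' @seealso \code{\link{partitionPreNew}}
#' @exportClass IndelPartition
setClass("IndelPartition",
         representation(preexisting = "IndelSet", new = "IndelSet",
                        subjectLabel = "character"))

setValidity("IndelPartition", function(object) {
  shared <- intersect(object@preexisting@records$key,
                      object@new@records$key)
  if (length(shared) > 0L)
    return("preexisting and new sets must be disjoint")
  TRUE
})

## ---- accessors ----

#' @describeIn GenomeSequence-class contig names
#' @param genome A \code{GenomeSequence}.
#' @export
contigNames <- function(genome) names(genome@contigs)

#' @describeIn GenomeSequence-class named vector of contig lengths
#' @export
contigLengths <- function(genome) {
  stats::setNames(nchar(genome@contigs), names(genome@contigs))
}

#' @describeIn GenomeSequence-class retrieve one contig sequence as a string
#' @param contig Contig name.
#' @export
getContig <- function(genome, contig) {
  if (!contig %in% names(genome@contigs))
    stop("unknown contig: ", contig)
  unname(genome@contigs[contig])
}

#' Access the record table of an IndelSet
#'
#' @param x An \code{IndelSet}.
#' @return data.frame of indel records (see \code{\linkS4class{IndelSet}}).
#' @export
indelRecords <- function(x) x@records

#' Record keys of an IndelSet
#'
#' @param x An \code{IndelSet}.
#' @return Character vector \code{contig:pos:ref:alt}.
#' @export
indelKeys <- function(x) x@records$key

#' Sample label of an IndelSet
#'
#' @param x An \code{IndelSet}.
#' @export
sampleLabel <- function(x) x@sampleLabel

#' @describeIn IndelPartition-class the pre-existing (intersection) set
#' @param x An \code{IndelPartition}.
#' @export
preexistingSet <- function(x) x@preexisting

#' @describeIn IndelPartition-class the newly arisen (post-unique) set
#' @export
newSet <- function(x) x@new

#' Number of records in an IndelSet
#' @param x An \code{IndelSet}.
#' @export
setMethod("length", "IndelSet", function(x) nrow(x@records))

.newIndelSet <- function(records, sampleLabel = "") {
  rownames(records) <- NULL
  new("IndelSet", records = records, sampleLabel = sampleLabel)
}

setMethod("show", "GenomeSequence", function(object) {
  len <- contigLengths(object)
  cat("GenomeSequence with", length(len), "contig(s),",
      format(sum(as.numeric(len)), big.mark = ","), "bp total\n")
  shown <- utils::head(len, 5)
  for (i in seq_along(shown))
    cat("  ", names(shown)[i], ": ", shown[i], " bp\n", sep = "")
  if (length(len) > 5) cat("  ...\n")
})

setMethod("show", "IndelSet", function(object) {
  rec <- object@records
  cat("IndelSet '", object@sampleLabel, "': ", nrow(rec), " record(s) (",
      sum(rec$kind == "deletion"), " deletions, ",
      sum(rec$kind == "insertion"), " insertions)\n", sep = "")
})

setMethod("show", "IndelPartition", function(object) {
  cat("IndelPartition '", object@subjectLabel, "': ",
      length(object@preexisting), " pre-existing, ",
      length(object@new), " new\n", sep = "")
})
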