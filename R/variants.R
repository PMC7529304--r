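# VCF indel ingestion, quality filtering, normalization, exclusion.

# Reduce one (pos, ref, alt) to anchor-base-minimal representation:
# trim the shared suffix, then the shared prefix (keeping one anchor base).
# Returns NULL for records that are not simple anchor-base indels
# (complex substitution+indel alleles).
.minimalIndel <- function(pos, ref, alt) {
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  if (xor(nchar(ref) == 1L, nchar(alt) == 1L) &&
      substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    list(pos = pos, ref = ref, alt = alt)
  } else {
    NULL
  }
}

.indelKey <- function(contig, pos, ref, alt) {
  paste(contig, pos, ref, alt, sep = ":")
}

.finishIndelFrame <- function(rec) {
  rec$pos <- as.integer(rec$pos)
  isDel <- nchar(rec$ref) > nchar(rec$alt)
  rec$kind <- ifelse(isDel, "deletion", "insertion")
  long <- ifelse(isDel, rec$ref, rec$alt)
  rec$event_seq <- substr(long, 2L, nchar(long))
  rec$event_len <- nchar(rec$event_seq)
  rec$key <- .indelKey(rec$contig, rec$pos, rec$ref, rec$alt)
  rec[, .INDEL_COLS]
}

#' Read indel calls from a VCF file
#'
#' Parses a VCF (v4.x, plain or bgzip), splits multi-allelic rows into one
#' record per ALT, keeps only simple indels, and applies the variant-level
#' quality filter: records with \code{QUAL < qualMin} are removed, as are
#' records with missing QUAL (\code{"."}) unless \code{keepMissingQual} is
#' set (useful for known-variant exclusion files, which typically carry no
#' QUAL). Symbolic alleles (\code{<DEL>}-style) and breakend notation are
#' skipped with a logged count, as are complex substitution+indel alleles
#' that have no anchor-base representation. Alleles are reduced to
#' anchor-base-minimal form at read time; call
#' \code{\link{normalizeIndels}} afterwards to left-align against the
#' reference.
#'
#' @param path Path to a VCF file.
#' @param qualMin Minimum QUAL retained (default 40).
#' @param keepMissingQual Keep records whose QUAL is missing (default
#'   FALSE: absence of a quality score cannot certify quality).
#' @param sampleLabel Label stored on the returned set (default: file name).
#' @return An \code{\linkS4class{IndelSet}} (possibly empty).
#' @export
readIndels <- function(path, qualMin = 40, keepMissingQual = FALSE,
                       sampleLabel = basename(path)) {
  if (!file.exists(path))
    stop("VCF file not found: ", path)
  stopifnot(qualMin >= 0)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown")),
    error = function(e)
      stop("failed to parse VCF '", path, "': ", conditionMessage(e),
           call. = FALSE))
  nRead <- nrow(vcf)
  if (nRead == 0L)
    return(.newIndelSet(.emptyIndelFrame(), sampleLabel))
  evcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(evcf)
  rec <- data.frame(
    contig = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(evcf)),
    alt = as.character(VariantAnnotation::alt(evcf)),
    qual = VariantAnnotation::qual(evcf),
    stringsAsFactors = FALSE)
  nSplit <- nrow(rec) - nRead

  # symbolic (<DEL>-style) and breakend ([ or ] notation) alleles
  symbolic <- grepl("[][<>]", rec$alt) | rec$alt == "*"
  nSymbolic <- sum(symbolic)
  rec <- rec[!symbolic & nzchar(rec$alt) & nzchar(rec$ref), , drop = FALSE]

  # only indels: allele lengths differ (drops SNVs and MNVs)
  rec <- rec[nchar(rec$ref) != nchar(rec$alt), , drop = FALSE]

  missingQual <- is.na(rec$qual)
  nNoQual <- if (keepMissingQual) 0L else sum(missingQual)
  keep <- if (keepMissingQual) missingQual | rec$qual >= qualMin
          else !missingQual & rec$qual >= qualMin
  nQualFail <- sum(!keep) - nNoQual
  rec <- rec[keep, , drop = FALSE]

  nComplex <- 0L
  if (nrow(rec) > 0L) {
    mins <- vector("list", nrow(rec))
    for (i in seq_len(nrow(rec)))
      mins[[i]] <- .minimalIndel(rec$pos[i], rec$ref[i], rec$alt[i])
    ok <- !vapply(mins, is.null, logical(1))
    nComplex <- sum(!ok)
    rec <- rec[ok, , drop = FALSE]
    if (nrow(rec) > 0L) {
      rec$pos <- vapply(mins[ok], `[[`, numeric(1), "pos")
      rec$ref <- vapply(mins[ok], `[[`, character(1), "ref")
      rec$alt <- vapply(mins[ok], `[[`, character(1), "alt")
    }
  }

  if (nrow(rec) > 0L) {
    rec <- .finishIndelFrame(rec)
    dup <- duplicated(rec$key)
    if (any(dup)) rec <- rec[!dup, , drop = FALSE]
  } else {
    rec <- .emptyIndelFrame()
  }
  message(sprintf(
    "readIndels [%s]: %d rows read, %d added by multi-allelic split, %d symbolic skipped, %d complex skipped, %d QUAL-filtered, %d missing-QUAL removed, %d indels kept",
    sampleLabel, nRead, max(nSplit, 0L), nSymbolic, nComplex,
    max(nQualFail, 0L), nNoQual, nrow(rec)))
  .newIndelSet(rec, sampleLabel)
}

# Left-align one anchor-base event: shift left while the base preceding the
# event equals the last base of the event sequence. Works identically for
# insertions and deletions (rotation of the event string).
.leftAlignOne <- function(contigSeq, pos, eventSeq) {
  L <- nchar(eventSeq)
  while (pos > 1L &&
         substr(contigSeq, pos, pos) == substr(eventSeq, L, L)) {
    eventSeq <- paste0(substr(contigSeq, pos, pos),
                       substr(eventSeq, 1L, L - 1L))
    pos <- pos - 1L
  }
  list(pos = pos, event_seq = eventSeq)
}

#' Left-align indel records against the reference
#'
#' Shifts each record to its leftmost equivalent representation (the event
#' sequence is rotated while the base preceding the event equals its last
#' base) and re-derives the anchor-base alleles from the reference. The
#' operation is idempotent; equivalent calls written at different positions
#' normalize to identical records. Records whose REF allele does not match
#' the reference raise a consistency error.
#'
#' @param x An \code{\linkS4class{IndelSet}}.
#' @param genome A \code{\linkS4class{GenomeSequence}}.
#' @return A normalized \code{IndelSet}.
#' @export
normalizeIndels <- function(x, genome) {
  rec <- x@records
  if (nrow(rec) == 0L) return(x)
  for (i in seq_len(nrow(rec))) {
    seq <- getContig(genome, rec$contig[i])
    refObs <- substr(seq, rec$pos[i], rec$pos[i] + nchar(rec$ref[i]) - 1L)
    if (refObs != rec$ref[i])
      stop("REF mismatch vs reference at ", rec$key[i],
           " (reference has '", refObs, "')")
    shifted <- .leftAlignOne(seq, rec$pos[i], rec$event_seq[i])
    rec$pos[i] <- shifted$pos
    rec$event_seq[i] <- shifted$event_seq
    anchor <- substr(seq, shifted$pos, shifted$pos)
    if (rec$kind[i] == "deletion") {
      rec$ref[i] <- paste0(anchor, shifted$event_seq)
      rec$alt[i] <- anchor
    } else {
      rec$ref[i] <- anchor
      rec$alt[i] <- paste0(anchor, shifted$event_seq)
    }
  }
  rec$key <- .indelKey(rec$contig, rec$pos, rec$ref, rec$alt)
  dup <- duplicated(rec$key)
  if (any(dup)) {
    message("normalizeIndels: ", sum(dup),
            " record(s) collapsed onto an equivalent representation")
    rec <- rec[!dup, , drop = FALSE]
  }
  .newIndelSet(rec, x@sampleLabel)
}

#' Remove known variants from an indel set
#'
#' Removes records of \code{target} that appear in any of the exclusion
#' sets (e.g. population catalogues of previously described indels). By
#' default matching is by exact normalized key
#' (\code{contig:pos:ref:alt}); \code{matchBy = "position"} relaxes this to
#' contig and position only.
#'
#' @param target An \code{\linkS4class{IndelSet}}.
#' @param exclusions A single \code{IndelSet} or a list of them (empty list
#'   = identity).
#' @param matchBy \code{"key"} (default) or \code{"position"}.
#' @return The filtered \code{IndelSet}; input order is preserved.
#' @export
excludeKnown <- function(target, exclusions = list(),
                         matchBy = c("key", "position")) {
  matchBy <- match.arg(matchBy)
  if (is(exclusions, "IndelSet")) exclusions <- list(exclusions)
  if (length(exclusions) == 0L) return(target)
  rec <- target@records
  if (nrow(rec) == 0L) return(target)
  idOf <- function(df) {
    if (matchBy == "key") df$key else paste(df$contig, df$pos, sep = ":")
  }
  bad <- unique(unlist(lapply(exclusions,
                              function(e) idOf(e@records))))
  keep <- !(idOf(rec) %in% bad)
  message("excludeKnown [", target@sampleLabel, "]: removed ",
          sum(!keep), " of ", nrow(rec), " records")
  .newIndelSet(rec[keep, , drop = FALSE], target@sampleLabel)
}

#' Write an IndelSet as VCF v4.2
#'
#' Emits a sites-only VCF with anchor-base alleles, sorted by contig (in
#' reference order) then position. Records must be reference-consistent;
#' an inconsistency raises an error naming the record. The output
#' round-trips through \code{\link{readIndels}}.
#'
#' @param x An \code{\linkS4class{IndelSet}} (normalized).
#' @param genome A \code{\linkS4class{GenomeSequence}} (used for the contig
#'   header lines and a reference-consistency check).
#' @param path Output path.
#' @param qual QUAL value written when a record has none (default 60).
#' @return \code{path}, invisibly.
#' @export
writeIndelVCF <- function(x, genome, path, qual = 60) {
  rec <- x@records
  lens <- contigLengths(genome)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(lens), lens),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
  if (nrow(rec) > 0L) {
    for (i in seq_len(nrow(rec))) {
      seq <- getContig(genome, rec$contig[i])
      refObs <- substr(seq, rec$pos[i], rec$pos[i] + nchar(rec$ref[i]) - 1L)
      if (refObs != rec$ref[i])
        stop("record ", rec$key[i], " is not reference-consistent")
    }
    ord <- order(match(rec$contig, names(lens)), rec$pos, rec$ref, rec$alt)
    rec <- rec[ord, , drop = FALSE]
    q <- ifelse(is.na(rec$qual), qual, rec$qual)
    body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t.",
                    rec$contig, rec$pos, rec$ref, rec$alt,
                    format(q, trim = TRUE, scientific = FALSE))
  } else {
    body <- character()
  }
  writeLines(c(header, body), path)
  invisible(path)
}
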