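# Deletion junction-microhomology scoring and the threshold-stratified
# report tables.

.SMALL_DEL_RANGE <- c(2L, 29L)
.LONG_DEL_RANGE <- c(30L, 500L)
.MH_CAP <- 20L

#' Junction microhomology length of a deletion
#'
#' Length of the contiguous match between the deleted sequence and the
#' adjacent (downstream) reference sequence, counted from the beginning of
#' each: the longest common prefix of the two strings. N never matches any
#' base (including N), so ambiguity cannot create spurious microhomology.
#' The result is capped at \code{cap} (20 bp by default; no larger
#' threshold is ever applied downstream).
#'
#' Vectorized over pairs.
#'
#' @param deletionSeq Deleted nucleotide sequence(s) (non-empty).
#' @param adjacentSeq Downstream flanking sequence(s); may be shorter than
#'   the deletion (contig edge), which caps the attainable score.
#' @param cap Maximum reported length (default 20).
#' @return Integer vector of microhomology lengths.
#' @examples
#' microhomologyLength("ACGT", "ACGA")  # 3
#' microhomologyLength("TTTT", "GAAA")  # 0
#' @export
microhomologyLength <- function(deletionSeq, adjacentSeq, cap = .MH_CAP) {
  n <- max(length(deletionSeq), length(adjacentSeq))
  deletionSeq <- rep_len(toupper(deletionSeq), n)
  adjacentSeq <- rep_len(toupper(adjacentSeq), n)
  if (any(nchar(deletionSeq) == 0L))
    stop("deletion sequence must be non-empty")
  mh <- integer(n)
  alive <- rep(TRUE, n)
  for (i in seq_len(cap)) {
    a <- substr(deletionSeq, i, i)
    b <- substr(adjacentSeq, i, i)
    hit <- alive & a != "" & b != "" & a == b & a != "N"
    if (!any(hit)) break
    mh[hit] <- i
    alive <- hit
  }
  mh
}

#' Score deletions for junction microhomology
#'
#' For every deletion of 2-500 bp in the set, extracts the downstream (3')
#' reference flank beginning at the first base after the deleted interval
#' — of length \code{min(event_len, cap)}, truncated at the contig end —
#' and records the junction microhomology length
#' (\code{\link{microhomologyLength}} of event sequence vs flank) and the
#' size class (\code{small} = 2-29 bp, \code{long} = 30-500 bp). Deletions
#' outside 2-500 bp (and non-deletions) are skipped with a logged count.
#'
#' With \code{orientation = "both"}, the score is the maximum of the
#' default 3'-prefix comparison and the mirrored 5' comparison (suffix of
#' the deletion vs suffix of the upstream flank); the default and all
#' reported analyses use \code{"threeprime"}.
#'
#' @param x An \code{\linkS4class{IndelSet}} (normalized).
#' @param genome A \code{\linkS4class{GenomeSequence}}.
#' @param cap Microhomology cap (default 20).
#' @param orientation \code{"threeprime"} (default) or \code{"both"}.
#' @return data.frame with columns \code{key}, \code{contig}, \code{pos},
#'   \code{event_len}, \code{mh_len}, \code{size_class}.
#' @export
scoreDeletions <- function(x, genome, cap = .MH_CAP,
                           orientation = c("threeprime", "both")) {
  orientation <- match.arg(orientation)
  rec <- x@records
  del <- rec[rec$kind == "deletion", , drop = FALSE]
  eligible <- del$event_len >= .SMALL_DEL_RANGE[1] &
    del$event_len <= .LONG_DEL_RANGE[2]
  if (any(!eligible))
    message("scoreDeletions [", x@sampleLabel, "]: ", sum(!eligible),
            " deletion(s) outside 2-500 bp not scored")
  del <- del[eligible, , drop = FALSE]
  if (nrow(del) == 0L) {
    return(data.frame(key = character(), contig = character(),
                      pos = integer(), event_len = integer(),
                      mh_len = integer(), size_class = character(),
                      stringsAsFactors = FALSE))
  }
  if (any(!del$contig %in% names(genome@contigs)))
    stop("unknown contig in deletion set")
  ctgSeq <- genome@contigs[del$contig]
  ctgLen <- unname(contigLengths(genome)[del$contig])
  flankStart <- del$pos + del$event_len + 1L
  flankLen <- pmin(del$event_len, cap)
  flankStop <- pmin(flankStart + flankLen - 1L, ctgLen)
  flank <- ifelse(flankStart > ctgLen, "",
                  substr(ctgSeq, flankStart, flankStop))
  mh <- microhomologyLength(del$event_seq, flank, cap = cap)
  if (orientation == "both") {
    upStop <- del$pos
    upStart <- pmax(1L, upStop - flankLen + 1L)
    upFlank <- substr(ctgSeq, upStart, upStop)
    revstr <- function(s) vapply(strsplit(s, ""), function(ch)
      paste(rev(ch), collapse = ""), character(1))
    mh5 <- microhomologyLength(revstr(del$event_seq), revstr(upFlank),
                               cap = cap)
    mh <- pmax(mh, mh5)
  }
  data.frame(key = del$key, contig = del$contig, pos = del$pos,
             event_len = del$event_len, mh_len = mh,
             size_class = ifelse(del$event_len <= .SMALL_DEL_RANGE[2],
                                 "small", "long"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Threshold-stratified deletion microhomology table
#'
#' For each minimum-microhomology threshold T (default 2..20) and one size
#' class, counts the deletions considered (those in the class with
#' \code{event_len >= T}; shorter deletions could not possibly carry a
#' T bp match and are excluded from the row) and those with
#' \code{mh_len >= T}, separately for the pre-existing and new sets, and
#' tests the two proportions with \code{\link{proportionChisq}}. Fractions
#' are kept at full precision; \code{p} is the display label
#' (\code{\link{formatP}}) and \code{p_raw} the raw value. Rows with an
#' empty considered set on either side get \code{p = "NA"}.
#'
#' @param partition An \code{\linkS4class{IndelPartition}}.
#' @param genome A \code{\linkS4class{GenomeSequence}}.
#' @param sizeClass \code{"small"} (2-29 bp) or \code{"long"} (30-500 bp).
#' @param thresholds Integer thresholds (default 2:20).
#' @param correct Continuity correction flag for the test (default TRUE).
#' @param nsAlpha Display threshold for "NS" (default 0.05).
#' @param scored Optional precomputed list with elements \code{pre} and
#'   \code{new} as returned by \code{\link{scoreDeletions}} (avoids
#'   re-scoring when both size classes are tabulated).
#' @return data.frame with columns \code{minimum_mh},
#'   \code{pre_existing_deletions}, \code{pre_with_mh},
#'   \code{pre_fraction}, \code{new_deletions}, \code{new_with_mh},
#'   \code{new_fraction}, \code{p}, \code{p_raw}.
#' @export
buildDeletionTable <- function(partition, genome,
                               sizeClass = c("small", "long"),
                               thresholds = 2:20, correct = TRUE,
                               nsAlpha = 0.05, scored = NULL) {
  sizeClass <- match.arg(sizeClass)
  if (is.null(scored)) {
    scored <- list(pre = scoreDeletions(partition@preexisting, genome),
                   new = scoreDeletions(partition@new, genome))
  }
  pre <- scored$pre[scored$pre$size_class == sizeClass, , drop = FALSE]
  nw <- scored$new[scored$new$size_class == sizeClass, , drop = FALSE]
  rows <- lapply(thresholds, function(T) {
    pKeep <- pre$event_len >= T
    nKeep <- nw$event_len >= T
    nPre <- sum(pKeep); nNew <- sum(nKeep)
    mhPre <- sum(pKeep & pre$mh_len >= T)
    mhNew <- sum(nKeep & nw$mh_len >= T)
    degenerate <- mhPre + mhNew == 0L ||
      (nPre - mhPre) + (nNew - mhNew) == 0L
    if (nPre > 0L && nNew > 0L && !degenerate) {
      ts <- proportionChisq(mhPre, nPre, mhNew, nNew, correct = correct)
      pRaw <- ts$p.value
    } else {
      pRaw <- NA_real_
    }
    data.frame(minimum_mh = T,
               pre_existing_deletions = nPre, pre_with_mh = mhPre,
               pre_fraction = if (nPre > 0L) mhPre / nPre else NA_real_,
               new_deletions = nNew, new_with_mh = mhNew,
               new_fraction = if (nNew > 0L) mhNew / nNew else NA_real_,
               p = formatP(pRaw, alpha = nsAlpha), p_raw = pRaw,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # structural sanity: considered and matching counts shrink as T grows
  stopifnot(!is.unsorted(rev(out$pre_existing_deletions)),
            !is.unsorted(rev(out$new_deletions)),
            !is.unsorted(rev(out$pre_with_mh)),
            !is.unsorted(rev(out$new_with_mh)))
  out
}

#' Write a threshold table as TSV in display formatting
#'
#' Fractions are rounded to two decimals for display; the raw p-value
#' column is retained at full precision.
#'
#' @param tab data.frame from \code{\link{buildDeletionTable}}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeThresholdTable <- function(tab, path) {
  disp <- tab
  disp$pre_fraction <- sprintf("%.2f", disp$pre_fraction)
  disp$new_fraction <- sprintf("%.2f", disp$new_fraction)
  disp$p_raw <- ifelse(is.na(tab$p_raw), "NA",
                       sprintf("%.6g", tab$p_raw))
  utils::write.table(disp, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
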