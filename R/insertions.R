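# Insertion classification: templated-in-trans small insertions and
# snapback-synthesis large insertions.

.SMALL_INS_MAX <- 3L
.REPEAT_MIN <- 7L
.SEP_MIN <- 4L
.CONTEXT_WIDTH <- 15L

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse complement of a nucleotide string
#'
#' Strict A-T / C-G complementation; any other character (including N)
#' becomes N.
#'
#' @param x Nucleotide string(s).
#' @return Reverse-complemented string(s).
#' @export
reverseComplement <- function(x) {
  vapply(x, function(s) {
    ch <- rev(strsplit(toupper(s), "")[[1]])
    comp <- .COMPLEMENT[ch]
    comp[is.na(comp)] <- "N"
    paste(comp, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Search a junction context for a templated-insertion word
#'
#' Core matcher for synthesis-dependent ("in trans") small insertions. Let
#' L be the reference bases immediately 5' of the insertion point and R
#' those immediately 3'. The call is positive iff there exist flank match
#' lengths k >= \code{flankMin} and m >= \code{flankMin} such that the
#' junction word \code{suffix_k(L) + insertion + prefix_m(R)} occurs
#' elsewhere in the context \code{L + R}, with at least \code{gapMin}
#' bases between the occurrence's footprint and the junction bases that
#' contribute the flanks. The template copy may straddle the insertion
#' point. Words containing N never match.
#'
#' Among positive candidates the one with maximal total flank match
#' \code{k + m} is reported (ties: upstream template first, then smallest
#' gap, then largest k, then leftmost occurrence).
#'
#' @param insertion Inserted nucleotides.
#' @param upstream Reference sequence 5' of the insertion point (5'->3').
#' @param downstream Reference sequence 3' of the insertion point.
#' @param flankMin Minimum flank match on each side (default 2).
#' @param gapMin Minimum separation between template copy and junction
#'   flank bases (default 1).
#' @return \code{NULL} (negative) or a list with \code{side}
#'   ("upstream"/"downstream": location of the template copy's midpoint),
#'   \code{p2_len} (= k), \code{mh2_len} (= m), \code{template_offset}
#'   (gap in bp) and \code{template_start} (1-based start of the
#'   occurrence within \code{L + R}).
#' @examples
#' # the canonical worked junction: repeated word AGA|g|AAA upstream
#' templatedInsertionMatch("G",
#'   upstream = "TCAGAGAAATCCAGA", downstream = "AAACTGTTTGCATGC")
#' @export
templatedInsertionMatch <- function(insertion, upstream, downstream,
                                    flankMin = 2L, gapMin = 1L) {
  I <- toupper(insertion)
  L <- toupper(upstream); R <- toupper(downstream)
  nl <- nchar(L); nr <- nchar(R)
  if (nl < flankMin || nr < flankMin) return(NULL)
  C <- paste0(L, R)
  nC <- nl + nr
  jStart <- function(k) nl - k + 1L   # junction footprint start in C
  jEnd <- function(m) nl + m          # junction footprint end in C
  best <- NULL
  for (k in seq(flankMin, nl)) {
    for (m in seq(flankMin, nr)) {
      word <- paste0(substr(L, nl - k + 1L, nl), I, substr(R, 1L, m))
      if (grepl("N", word, fixed = TRUE)) next
      wl <- nchar(word)
      if (wl > nC) next
      hits <- gregexpr(paste0("(?=", word, ")"), C, perl = TRUE)[[1]]
      if (hits[1] == -1L) next
      for (s in as.integer(hits)) {
        occEnd <- s + wl - 1L
        leftOk <- occEnd <= jStart(k) - 1L - gapMin
        rightOk <- s >= jEnd(m) + 1L + gapMin
        if (!leftOk && !rightOk) next
        mid <- s + (wl - 1) / 2
        side <- if (mid <= nl + 0.5) "upstream" else "downstream"
        offset <- if (leftOk) jStart(k) - occEnd - 1L
                  else s - jEnd(m) - 1L
        cand <- list(side = side, p2_len = k, mh2_len = m,
                     template_offset = as.integer(offset),
                     template_start = s)
        if (is.null(best) ||
            (k + m) > (best$p2_len + best$mh2_len) ||
            ((k + m) == (best$p2_len + best$mh2_len) &&
             .candBeats(cand, best)))
          best <- cand
      }
    }
  }
  best
}

# tie-break between candidates with equal total flank match
.candBeats <- function(cand, best) {
  sideRank <- function(x) if (x$side == "upstream") 0L else 1L
  if (sideRank(cand) != sideRank(best)) return(sideRank(cand) < sideRank(best))
  if (cand$template_offset != best$template_offset)
    return(cand$template_offset < best$template_offset)
  if (cand$p2_len != best$p2_len) return(cand$p2_len > best$p2_len)
  cand$template_start < best$template_start
}

#' Classify a small insertion as templated-in-trans or not
#'
#' Extracts the +/- \code{contextWidth} nt reference context around the
#' insertion point and runs \code{\link{templatedInsertionMatch}}. Only
#' insertions of at most 3 bp are eligible; longer records are rejected
#' with a logged reason. An insertion too close to a contig edge to
#' provide \code{flankMin} bases on each side is negative (the flank
#' minimums cannot be met).
#'
#' @param record One-row data.frame (or list) with fields \code{contig},
#'   \code{pos} (anchor position: insertion lies between \code{pos} and
#'   \code{pos + 1}), \code{kind}, \code{event_seq}, \code{event_len}.
#' @param genome A \code{\linkS4class{GenomeSequence}}.
#' @param contextWidth Context half-width in nt (default 15).
#' @param flankMin,gapMin See \code{\link{templatedInsertionMatch}}.
#' @return List with \code{eligible} (logical), \code{positive} (logical)
#'   and \code{match} (list or NULL).
#' @export
classifySmallInsertion <- function(record, genome,
                                   contextWidth = .CONTEXT_WIDTH,
                                   flankMin = 2L, gapMin = 1L) {
  if (record$kind != "insertion")
    stop("record is not an insertion")
  if (record$event_len > .SMALL_INS_MAX) {
    message("classifySmallInsertion: ", record$key %||% "",
            " insertion of ", record$event_len,
            " bp exceeds 3 bp; not evaluated")
    return(list(eligible = FALSE, positive = FALSE, match = NULL))
  }
  n <- contigLengths(genome)[[record$contig]]
  upstream <- if (record$pos >= 1L)
    extractFlank(genome, record$contig, record$pos, contextWidth,
                 "upstream") else ""
  downstream <- if (record$pos + 1L <= n)
    extractFlank(genome, record$contig, record$pos + 1L, contextWidth,
                 "downstream") else ""
  m <- templatedInsertionMatch(record$event_seq, upstream, downstream,
                               flankMin = flankMin, gapMin = gapMin)
  list(eligible = TRUE, positive = !is.null(m), match = m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Find the best internal inverted repeat of an insertion
#'
#' Core matcher for snapback-synthesis large insertions: the inserted
#' sequence is compared with its own reverse complement. A positive call
#' requires a substring of at least \code{repeatMin} nt whose reverse
#' complement also occurs in the insertion, with non-overlapping footprints
#' separated by at least \code{sepMin} nt. Substrings containing N are
#' disqualified. Among valid pairs the maximal repeat length is reported
#' (ties: smallest first start, then smallest second start).
#'
#' @param insertion Inserted nucleotide sequence.
#' @param repeatMin Minimum repeat length in nt (default 7).
#' @param sepMin Minimum gap between the two footprints in nt (default 4).
#' @return \code{NULL} (negative) or a list with \code{repeat_len},
#'   \code{first_start}, \code{second_start} (1-based within the
#'   insertion) and \code{separation} (gap in nt).
#' @examples
#' snapbackMatch(paste0("ATCGATC", "TTTT", "GATCGAT"))
#' @export
snapbackMatch <- function(insertion, repeatMin = .REPEAT_MIN,
                          sepMin = .SEP_MIN) {
  x <- strsplit(toupper(insertion), "")[[1]]
  n <- length(x)
  if (n < 2L * repeatMin + sepMin) return(NULL)
  rc <- rev(unname(.COMPLEMENT[x]))  # NA where not A/C/G/T
  # M[a+1, b+1] = length of the longest common suffix of x[1..a], rc[1..b]
  M <- matrix(0L, n + 1L, n + 1L)
  for (a in seq_len(n)) {
    eq <- !is.na(rc) & rc == x[a]
    M[a + 1L, which(eq) + 1L] <- M[a, which(eq)] + 1L
  }
  idx <- which(M >= repeatMin, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  Lm <- M[idx]
  a <- idx[, 1L] - 1L
  b <- idx[, 2L] - 1L
  # x[a-L+1..a] == rc[b-L+1..b]; the rc segment is the reverse complement
  # of x[(n-b+1)..(n-b+L)], giving an inverted-repeat pair within x.
  p1 <- a - Lm + 1L
  p2 <- n - b + 1L
  s1 <- pmin(p1, p2); s2 <- pmax(p1, p2)
  gap <- s2 - s1 - Lm
  # trimming t bases at the inner junction shortens the repeat by t and
  # widens the gap by 2t, so an overlapping/close pair can still yield a
  # valid shorter repeat
  t <- pmax(0L, as.integer(ceiling((sepMin - gap) / 2)))
  r <- Lm - t
  ok <- r >= repeatMin & (s1 != s2 | t > 0L)
  ok <- ok & (s2 + t + r - 1L) <= n & s1 >= 1L
  if (!any(ok)) return(NULL)
  r <- r[ok]; s1 <- s1[ok]; s2 <- (s2 + t)[ok]
  ord <- order(-r, s1, s2)
  i <- ord[1L]
  list(repeat_len = as.integer(r[i]), first_start = as.integer(s1[i]),
       second_start = as.integer(s2[i]),
       separation = as.integer(s2[i] - s1[i] - r[i]))
}

#' Classify a large insertion as snapback-like or not
#'
#' Insertions shorter than \code{2 * repeatMin + sepMin} nt (18 nt at the
#' defaults) cannot contain two separated repeat copies and are rejected
#' with a logged reason rather than being counted as negative.
#'
#' @param record One-row data.frame (or list) with fields \code{kind},
#'   \code{event_seq}, \code{event_len} (and optionally \code{key}).
#' @param repeatMin,sepMin See \code{\link{snapbackMatch}}.
#' @return List with \code{eligible}, \code{positive}, \code{match}.
#' @export
classifySnapbackInsertion <- function(record, repeatMin = .REPEAT_MIN,
                                      sepMin = .SEP_MIN) {
  if (record$kind != "insertion")
    stop("record is not an insertion")
  minLen <- 2L * repeatMin + sepMin
  if (record$event_len < minLen) {
    message("classifySnapbackInsertion: ", record$key %||% "",
            " insertion of ", record$event_len, " bp is below the ",
            minLen, " bp evaluation minimum; not evaluated")
    return(list(eligible = FALSE, positive = FALSE, match = NULL))
  }
  m <- snapbackMatch(record$event_seq, repeatMin = repeatMin,
                     sepMin = sepMin)
  list(eligible = TRUE, positive = !is.null(m), match = m)
}

#' Per-insertion classification table for one set
#'
#' Buckets every insertion of a set (small = 1-3 bp, large >= 18 bp,
#' unclassified = 4-17 bp) and runs the matching classifier. Every
#' insertion lands in exactly one bucket.
#'
#' @param x An \code{\linkS4class{IndelSet}}.
#' @param genome A \code{\linkS4class{GenomeSequence}}.
#' @param contextWidth,flankMin,gapMin Small-insertion parameters.
#' @param repeatMin,sepMin Snapback parameters.
#' @return data.frame with one row per insertion: \code{key},
#'   \code{event_len}, \code{bucket}, \code{positive}, \code{p2_len},
#'   \code{mh2_len}, \code{template_offset}, \code{side},
#'   \code{repeat_len}, \code{separation}.
#' @export
classifyInsertions <- function(x, genome, contextWidth = .CONTEXT_WIDTH,
                               flankMin = 2L, gapMin = 1L,
                               repeatMin = .REPEAT_MIN, sepMin = .SEP_MIN) {
  rec <- x@records
  ins <- rec[rec$kind == "insertion", , drop = FALSE]
  if (nrow(ins) == 0L) {
    return(data.frame(key = character(), event_len = integer(),
                      bucket = character(), positive = logical(),
                      p2_len = integer(), mh2_len = integer(),
                      template_offset = integer(), side = character(),
                      repeat_len = integer(), separation = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(
    key = ins$key, event_len = ins$event_len,
    bucket = ifelse(ins$event_len <= .SMALL_INS_MAX, "small",
                    ifelse(ins$event_len >= 2L * repeatMin + sepMin,
                           "large", "unclassified")),
    positive = FALSE, p2_len = NA_integer_, mh2_len = NA_integer_,
    template_offset = NA_integer_, side = NA_character_,
    repeat_len = NA_integer_, separation = NA_integer_,
    stringsAsFactors = FALSE, row.names = NULL)
  for (i in seq_len(nrow(ins))) {
    if (out$bucket[i] == "small") {
      cl <- classifySmallInsertion(ins[i, ], genome,
                                   contextWidth = contextWidth,
                                   flankMin = flankMin, gapMin = gapMin)
      out$positive[i] <- cl$positive
      if (cl$positive) {
        out$p2_len[i] <- cl$match$p2_len
        out$mh2_len[i] <- cl$match$mh2_len
        out$template_offset[i] <- cl$match$template_offset
        out$side[i] <- cl$match$side
      }
    } else if (out$bucket[i] == "large") {
      cl <- classifySnapbackInsertion(ins[i, ], repeatMin = repeatMin,
                                      sepMin = sepMin)
      out$positive[i] <- cl$positive
      if (cl$positive) {
        out$repeat_len[i] <- cl$match$repeat_len
        out$separation[i] <- cl$match$separation
      }
    }
  }
  nUncl <- sum(out$bucket == "unclassified")
  if (nUncl > 0L)
    message("classifyInsertions [", x@sampleLabel, "]: ", nUncl,
            " insertion(s) of 4-17 bp in the unclassified bucket")
  out
}

#' Insertion signature summaries for a partition
#'
#' Builds the two contingency summaries comparing the pre-existing and new
#' sets: templated small insertions (1-3 bp) and snapback large insertions
#' (>= 18 nt at the defaults). Mean insertion lengths per eligible set are
#' reported alongside the proportion test.
#'
#' @param partition An \code{\linkS4class{IndelPartition}}.
#' @param genome A \code{\linkS4class{GenomeSequence}}.
#' @param correct Continuity correction flag (default TRUE).
#' @param nsAlpha Display threshold for "NS" (default 0.05).
#' @param ... Passed to \code{\link{classifyInsertions}}.
#' @return List with elements \code{small} and \code{snapback}, each a
#'   one-row data.frame with \code{n_pre}, \code{pos_pre}, \code{frac_pre},
#'   \code{n_new}, \code{pos_new}, \code{frac_new}, \code{mean_len_pre},
#'   \code{mean_len_new}, \code{p}, \code{p_raw}; plus
#'   \code{per_event_pre} and \code{per_event_new} classification tables.
#' @export
buildInsertionTables <- function(partition, genome, correct = TRUE,
                                 nsAlpha = 0.05, ...) {
  clPre <- classifyInsertions(partition@preexisting, genome, ...)
  clNew <- classifyInsertions(partition@new, genome, ...)
  summarize <- function(bucket) {
    p <- clPre[clPre$bucket == bucket, , drop = FALSE]
    n <- clNew[clNew$bucket == bucket, , drop = FALSE]
    pRaw <- if (nrow(p) > 0L && nrow(n) > 0L)
      proportionChisq(sum(p$positive), nrow(p), sum(n$positive), nrow(n),
                      correct = correct)$p.value
    else NA_real_
    data.frame(
      n_pre = nrow(p), pos_pre = sum(p$positive),
      frac_pre = if (nrow(p) > 0L) mean(p$positive) else NA_real_,
      n_new = nrow(n), pos_new = sum(n$positive),
      frac_new = if (nrow(n) > 0L) mean(n$positive) else NA_real_,
      mean_len_pre = if (nrow(p) > 0L) mean(p$event_len) else NA_real_,
      mean_len_new = if (nrow(n) > 0L) mean(n$event_len) else NA_real_,
      p = formatP(pRaw, alpha = nsAlpha), p_raw = pRaw,
      stringsAsFactors = FALSE)
  }
  list(small = summarize("small"), snapback = summarize("large"),
       per_event_pre = clPre, per_event_new = clNew)
}
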