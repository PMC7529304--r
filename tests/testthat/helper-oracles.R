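# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the implementation's code paths:
# character-by-character scans and exhaustive enumeration only.

BASES <- c("A", "C", "G", "T")

randSeq <- function(n) paste(sample(BASES, n, replace = TRUE),
                             collapse = "")

# longest common prefix by position-by-position scan; N matches nothing
oraclePrefix <- function(a, b, cap = 20L) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  k <- 0L
  for (i in seq_len(min(length(ca), length(cb), cap))) {
    if (ca[i] == cb[i] && ca[i] != "N") k <- i else break
  }
  k
}

# exhaustive (k, m, window) enumeration for the templated-insertion rule;
# returns the maximal k+m over valid candidates, or NULL if negative
oracleTemplated <- function(I, L, R, flankMin = 2L, gapMin = 1L) {
  nl <- nchar(L); nr <- nchar(R)
  if (nl < flankMin || nr < flankMin) return(NULL)
  C <- paste0(L, R); nC <- nl + nr
  best <- NULL
  for (k in flankMin:nl) {
    for (m in flankMin:nr) {
      word <- paste0(substr(L, nl - k + 1L, nl), I, substr(R, 1L, m))
      if (grepl("N", word, fixed = TRUE)) next
      wl <- nchar(word)
      if (wl > nC) next
      js <- nl - k + 1L; je <- nl + m
      for (s in seq_len(nC - wl + 1L)) {
        if (substr(C, s, s + wl - 1L) != word) next
        if ((s + wl - 1L) <= js - 1L - gapMin || s >= je + 1L + gapMin) {
          if (is.null(best) || k + m > best) best <- k + m
        }
      }
    }
  }
  best
}

# exhaustive (r, i, j) scan for the snapback rule; returns the maximal
# valid repeat length, or 0 if negative
oracleSnapback <- function(seq, rmin = 7L, smin = 4L) {
  x <- strsplit(seq, "")[[1]]
  n <- length(x)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  maxr <- floor((n - smin) / 2)
  if (maxr < rmin) return(0L)
  for (r in maxr:rmin) {
    for (i in seq_len(n - r + 1L)) {
      s1 <- x[i:(i + r - 1L)]
      if (any(!s1 %in% names(comp))) next
      rc1 <- rev(unname(comp[s1]))
      jmin <- i + r + smin
      if (jmin > n - r + 1L) next
      for (j in jmin:(n - r + 1L)) {
        if (all(x[j:(j + r - 1L)] == rc1)) return(r)
      }
    }
  }
  0L
}

# build an IndelSet directly from allele columns (bypasses VCF reading)
makeIndelSet <- function(df, label = "test") {
  rec <- data.frame(contig = df$contig, pos = as.integer(df$pos),
                    ref = df$ref, alt = df$alt,
                    qual = if ("qual" %in% names(df)) df$qual else 60,
                    stringsAsFactors = FALSE)
  rec <- mmejscan:::.finishIndelFrame(rec)
  mmejscan:::.newIndelSet(rec, label)
}

# write raw VCF text independently of writeIndelVCF
writeVcfText <- function(path, bodyLines,
                         contigs = c(chr1 = 1000L)) {
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                      contigs),
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", sep = "\t"))
  writeLines(c(header, bodyLines), path)
  path
}

# leftmost equivalent representation of a deletion/insertion by exhaustive
# shift enumeration: apply the edit, then find the smallest anchor whose
# edit reproduces the same result
oracleLeftmostDeletion <- function(contigSeq, pos, L) {
  n <- nchar(contigSeq)
  applyDel <- function(p) paste0(substr(contigSeq, 1, p),
                                 substr(contigSeq, p + L + 1L, n))
  target <- applyDel(pos)
  for (p in seq_len(pos)) {
    if (p + L <= n && applyDel(p) == target)
      return(list(pos = p,
                  event_seq = substr(contigSeq, p + 1L, p + L)))
  }
  stop("unreachable")
}

smallSimConfig <- function(seed = 1L, ...) {
  simulationConfig(genomeLength = 120000L,
                   nPreDeletionsSmall = 200L, nNewDeletionsSmall = 200L,
                   nPreDeletionsLong = 30L, nNewDeletionsLong = 30L,
                   nPreSmallInsertions = 40L, nNewSmallInsertions = 40L,
                   nPreLargeInsertions = 15L, nNewLargeInsertions = 25L,
                   seed = seed, ...)
}
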