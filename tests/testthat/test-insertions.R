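test_that("the canonical AGA|g|AAA junction is recognized with both flanks of 3", {
  # upstream context carries the template copy AGAGAAA; the junction reads
  # P2 = AGA, inserted G, mh2 = AAA
  up <- "CCAGAGAAATTTAGA"
  dn <- "AAACCTTCCTTCCTT"
  m <- templatedInsertionMatch("G", up, dn)
  expect_false(is.null(m))
  expect_equal(m$side, "upstream")
  expect_equal(m$p2_len, 3L)
  expect_equal(m$mh2_len, 3L)
  expect_gte(m$template_offset, 1L)

  g <- genomeSequence(c(c1 = paste0(up, dn)))
  rec <- makeIndelSet(data.frame(contig = "c1", pos = 15, ref = "A",
                                 alt = "AG"))
  cl <- classifySmallInsertion(indelRecords(rec)[1, ], g)
  expect_true(cl$eligible)
  expect_true(cl$positive)
  expect_equal(cl$match$p2_len, 3L)
})

test_that("contexts without a repeated junction word are negative", {
  expect_null(templatedInsertionMatch("G", strrep("T", 15), strrep("C", 15)))
  # junction word containing N never matches
  expect_null(templatedInsertionMatch("G", "AANAGAGAAATTAGA",
                                      "NNNNNNNNNNNNNNN"))
})

test_that("small-insertion eligibility and edge handling follow the rules", {
  g <- genomeSequence(c(c1 = "ACGTACGTACGTACGTACGT"))
  long <- list(contig = "c1", pos = 10, kind = "insertion",
               event_seq = "ACGT", event_len = 4L, key = "k")
  cl <- suppressMessages(classifySmallInsertion(long, g))
  expect_false(cl$eligible)
  edge <- list(contig = "c1", pos = 1, kind = "insertion",
               event_seq = "G", event_len = 1L, key = "k")
  cl <- classifySmallInsertion(edge, g)   # |L| = 1 < 2: negative
  expect_true(cl$eligible)
  expect_false(cl$positive)
})

test_that("small-insertion classification agrees with exhaustive enumeration", {
  set.seed(41)
  for (rep in 1:120) {
    I <- randSeq(sample(1:3, 1))
    if (rep %% 3 == 0) {
      # plant a template copy so positives are well represented
      word <- paste0(randSeq(2), I, randSeq(2))
      L <- paste0(randSeq(3), word, randSeq(10 - nchar(word)),
                  substr(word, 1, 2))
      R <- paste0(substr(word, nchar(word) - 1, nchar(word)), randSeq(13))
    } else {
      L <- randSeq(15); R <- randSeq(15)
    }
    got <- templatedInsertionMatch(I, L, R)
    want <- oracleTemplated(I, L, R)
    expect_equal(is.null(got), is.null(want),
                 info = paste(I, L, R, sep = " / "))
    if (!is.null(got))
      expect_equal(got$p2_len + got$mh2_len, want,
                   info = paste(I, L, R, sep = " / "))
  }
})

test_that("constructed inverted repeats are called snapback with the planted geometry", {
  m <- snapbackMatch(paste0("ATCGATC", "TTTT", "GATCGAT"))
  expect_false(is.null(m))
  expect_equal(m$repeat_len, 7L)
  expect_equal(m$separation, 4L)
  expect_null(snapbackMatch(strrep("A", 20)))
  # an 18 nt perfect palindrome contains a 7 nt repeat with 4 nt gap
  half <- "ACGGTCAGT"
  expect_false(is.null(snapbackMatch(paste0(half, reverseComplement(half)))))
})

test_that("large-insertion eligibility enforces the 2x7+4 minimum", {
  short <- list(kind = "insertion", event_seq = randSeq(17),
                event_len = 17L, key = "k")
  cl <- suppressMessages(classifySnapbackInsertion(short))
  expect_false(cl$eligible)
  ok <- list(kind = "insertion",
             event_seq = paste0("ATCGATC", "TTTT", "GATCGAT"),
             event_len = 18L, key = "k")
  cl <- classifySnapbackInsertion(ok)
  expect_true(cl$eligible)
  expect_true(cl$positive)
})

test_that("snapback classification agrees with exhaustive substring scanning", {
  set.seed(43)
  for (rep in 1:120) {
    if (rep %% 2 == 0) {
      r <- sample(7:11, 1); sp <- sample(4:8, 1)
      A <- randSeq(r)
      x <- paste0(randSeq(sample(0:6, 1)), A, randSeq(sp),
                  reverseComplement(A), randSeq(sample(0:6, 1)))
    } else {
      x <- randSeq(sample(18:40, 1))
    }
    got <- snapbackMatch(x)
    want <- oracleSnapback(x)
    expect_equal(!is.null(got), want > 0L, info = x)
    if (!is.null(got)) {
      expect_equal(got$repeat_len, want, info = x)
      # reported footprints really are reverse complements with the gap
      first <- substr(x, got$first_start,
                      got$first_start + got$repeat_len - 1L)
      second <- substr(x, got$second_start,
                       got$second_start + got$repeat_len - 1L)
      expect_equal(second, reverseComplement(first), info = x)
      expect_equal(got$second_start - got$first_start - got$repeat_len,
                   got$separation, info = x)
      expect_gte(got$separation, 4L)
    }
  }
})

test_that("snapback calls are strand-symmetric and stable under extension", {
  set.seed(47)
  for (rep in 1:60) {
    x <- if (rep %% 2 == 0) {
      A <- randSeq(8)
      paste0(randSeq(3), A, randSeq(5), reverseComplement(A), randSeq(3))
    } else randSeq(sample(18:35, 1))
    call1 <- !is.null(snapbackMatch(x))
    expect_equal(!is.null(snapbackMatch(reverseComplement(x))), call1)
    if (call1)
      expect_false(is.null(snapbackMatch(paste0(randSeq(5), x,
                                                randSeq(5)))))
  }
})

test_that("every insertion lands in exactly one analysis bucket", {
  g <- genomeSequence(c(c1 = randSeq(200)))
  anchors <- c(50, 90, 130)
  lens <- c(2L, 10L, 20L)
  seqs <- vapply(lens, function(L) randSeq(L), character(1))
  s <- makeIndelSet(data.frame(
    contig = "c1", pos = anchors,
    ref = substr(getContig(g, "c1"), anchors, anchors),
    alt = paste0(substr(getContig(g, "c1"), anchors, anchors), seqs)))
  cl <- suppressMessages(classifyInsertions(s, g))
  expect_equal(sort(cl$bucket), sort(c("small", "unclassified", "large")))
  expect_equal(nrow(cl), 3L)
})

test_that("insertion summaries recover the planted classification exactly", {
  cfg <- smallSimConfig(seed = 51)
  sim <- suppressMessages(simulateMMEJCohort(cfg))
  part <- suppressMessages(partitionPreNew(sim$bcell, sim$lcl, "s"))
  tabs <- suppressMessages(buildInsertionTables(part, sim$genome))
  tr <- sim$truth
  cnt <- function(set, cls) sum(tr$set == set & tr$class == cls)
  expect_equal(tabs$small$pos_pre, cnt("preexisting", "templated_small_ins"))
  expect_equal(tabs$small$pos_new, cnt("new", "templated_small_ins"))
  expect_equal(tabs$small$n_pre,
               cnt("preexisting", "templated_small_ins") +
                 cnt("preexisting", "plain_small_ins"))
  expect_equal(tabs$snapback$pos_pre, cnt("preexisting", "snapback_ins"))
  expect_equal(tabs$snapback$pos_new, cnt("new", "snapback_ins"))
  expect_equal(tabs$snapback$n_new,
               cnt("new", "snapback_ins") + cnt("new", "plain_large_ins"))
})

test_that("empty eligible sets give NA summaries", {
  empty <- mmejscan:::.newIndelSet(mmejscan:::.emptyIndelFrame())
  part <- new("IndelPartition", preexisting = empty, new = empty,
              subjectLabel = "t")
  g <- genomeSequence(c(c1 = "ACGTACGTAC"))
  tabs <- buildInsertionTables(part, g)
  expect_equal(tabs$small$n_pre, 0L)
  expect_equal(tabs$small$p, "NA")
  expect_equal(tabs$snapback$p, "NA")
})
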