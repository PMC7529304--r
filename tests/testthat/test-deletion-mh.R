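test_that("microhomology length is the N-aware common prefix, capped at 20", {
  expect_equal(microhomologyLength("ACGT", "ACGA"), 3L)
  expect_equal(microhomologyLength("TTTT", "GAAA"), 0L)
  expect_equal(microhomologyLength("NAAA", "NAAA"), 0L)  # N matches nothing
  expect_equal(microhomologyLength("AANA", "AANA"), 2L)
  expect_equal(microhomologyLength(strrep("A", 30), strrep("A", 30)), 20L)
  expect_equal(microhomologyLength("ACG", "AC"), 2L)     # short flank caps
  expect_error(microhomologyLength("", "ACGT"), "non-empty")

  set.seed(31)
  for (rep in 1:200) {
    a <- randSeq(sample(1:40, 1))
    b <- randSeq(sample(0:40, 1))
    if (nchar(b) == 0) b <- ""
    expect_equal(microhomologyLength(a, b), oraclePrefix(a, b))
  }
})

test_that("deletion scoring extracts the downstream flank and caps at the contig edge", {
  # ...G | ACG | ACGTT...  -> deletion ACG, flank ACGTT, mh = 3
  g <- genomeSequence(c(c1 = "TTGACGACGTTCC"))
  del <- makeIndelSet(data.frame(contig = "c1", pos = 3, ref = "GACG",
                                 alt = "G"))
  sc <- scoreDeletions(del, g)
  expect_equal(sc$mh_len, 3L)
  expect_equal(sc$size_class, "small")

  # deletion AT followed by GG -> no microhomology
  g <- genomeSequence(c(c1 = "CCATGGCC"))
  del <- makeIndelSet(data.frame(contig = "c1", pos = 2, ref = "CAT",
                                 alt = "C"))
  expect_equal(scoreDeletions(del, g)$mh_len, 0L)

  # deletion at the contig end: flank shorter than the event, still scored
  g <- genomeSequence(c(c1 = "AACGTCG"))
  del <- makeIndelSet(data.frame(contig = "c1", pos = 2, ref = "ACGT",
                                 alt = "A"))
  sc <- scoreDeletions(del, g)
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$mh_len, oraclePrefix("CGT", "CG"))
})

test_that("deletions outside 2-500 bp and non-deletions are not scored", {
  g <- genomeSequence(c(c1 = paste(rep("ACGT", 300), collapse = "")))
  recs <- data.frame(
    contig = "c1",
    pos = c(1, 10, 300),
    ref = c(substr(getContig(g, "c1"), 1, 2),        # 1 bp deletion
            substr(getContig(g, "c1"), 10, 10),      # insertion
            substr(getContig(g, "c1"), 300, 300 + 501)),  # 501 bp deletion
    alt = c(substr(getContig(g, "c1"), 1, 1), "AT",
            substr(getContig(g, "c1"), 300, 300)))
  s <- makeIndelSet(recs)
  expect_equal(nrow(suppressMessages(scoreDeletions(s, g))), 0L)
})

test_that("planted junction microhomology is recovered exactly", {
  cfg <- smallSimConfig(seed = 12, mhFractionPre = 1, mhFractionNew = 1)
  sim <- suppressMessages(simulateMMEJCohort(cfg))
  part <- suppressMessages(partitionPreNew(sim$bcell, sim$lcl, "s"))
  for (set in list(preexistingSet(part), newSet(part))) {
    sc <- scoreDeletions(set, sim$genome)
    tr <- sim$truth[match(sc$key, sim$truth$key), ]
    expect_true(all(!is.na(tr$mh_len)))
    expect_equal(sc$mh_len, tr$mh_len)
    expect_true(all(tr$mh_len >= 2))
  }
})

test_that("threshold rows drop deletions shorter than T", {
  # one pre deletion of length 3 with full homology; at T = 4 the row
  # must consider (and count) nothing
  g <- genomeSequence(c(c1 = "TTGACTACTCCAAGGTTACGTACGATTA"))
  pre <- makeIndelSet(data.frame(contig = "c1", pos = 3, ref = "GACT",
                                 alt = "G"))
  nw <- makeIndelSet(data.frame(contig = "c1", pos = 16, ref = "TACG",
                                alt = "T"))
  part <- new("IndelPartition", preexisting = pre, new = nw,
              subjectLabel = "t")
  tab <- buildDeletionTable(part, g, "small", thresholds = 2:5)
  expect_equal(tab$pre_existing_deletions, c(1L, 1L, 0L, 0L))
  expect_equal(tab$new_deletions, c(1L, 1L, 0L, 0L))
  expect_equal(tab$p[tab$minimum_mh == 4], "NA")
})

test_that("an empty partition yields all-zero rows labelled NA", {
  empty <- mmejscan:::.newIndelSet(mmejscan:::.emptyIndelFrame())
  part <- new("IndelPartition", preexisting = empty, new = empty,
              subjectLabel = "t")
  g <- genomeSequence(c(c1 = "ACGTACGTAC"))
  tab <- buildDeletionTable(part, g, "small")
  expect_equal(nrow(tab), 19L)
  expect_true(all(tab$pre_existing_deletions == 0))
  expect_true(all(tab$p == "NA"))
  expect_true(all(is.na(tab$p_raw)))
})

test_that("threshold counts match brute force and behave monotonically", {
  cfg <- smallSimConfig(seed = 21)
  sim <- suppressMessages(simulateMMEJCohort(cfg))
  part <- suppressMessages(partitionPreNew(sim$bcell, sim$lcl, "s"))
  scored <- list(pre = scoreDeletions(preexistingSet(part), sim$genome),
                 new = scoreDeletions(newSet(part), sim$genome))
  for (cls in c("small", "long")) {
    tab <- buildDeletionTable(part, sim$genome, cls, scored = scored)
    p <- scored$pre[scored$pre$size_class == cls, ]
    n <- scored$new[scored$new$size_class == cls, ]
    for (i in seq_len(nrow(tab))) {
      T <- tab$minimum_mh[i]
      expect_equal(tab$pre_existing_deletions[i], sum(p$event_len >= T))
      expect_equal(tab$pre_with_mh[i],
                   sum(p$event_len >= T & p$mh_len >= T))
      expect_equal(tab$new_with_mh[i],
                   sum(n$event_len >= T & n$mh_len >= T))
    }
    expect_true(all(diff(tab$pre_existing_deletions) <= 0))
    expect_true(all(diff(tab$new_with_mh) <= 0))
    if (cls == "long") {
      # every long deletion is >= 30 bp > 20, so totals never shrink
      expect_equal(length(unique(tab$pre_existing_deletions)), 1L)
      expect_equal(length(unique(tab$new_deletions)), 1L)
    }
  }
})

test_that("planted enriched fractions are recovered with a decisive test", {
  cfg <- simulationConfig(genomeLength = 60000L,
                          nPreDeletionsSmall = 200L,
                          nNewDeletionsSmall = 200L,
                          nPreDeletionsLong = 0L, nNewDeletionsLong = 0L,
                          nPreSmallInsertions = 0L,
                          nNewSmallInsertions = 0L,
                          nPreLargeInsertions = 0L,
                          nNewLargeInsertions = 0L,
                          mhFractionPre = 0.3, mhFractionNew = 0.6,
                          seed = 4)
  sim <- suppressMessages(simulateMMEJCohort(cfg))
  part <- suppressMessages(partitionPreNew(sim$bcell, sim$lcl, "s"))
  tab <- buildDeletionTable(part, sim$genome, "small")
  r <- tab[tab$minimum_mh == 2, ]
  tr <- sim$truth
  expect_equal(r$pre_with_mh,
               sum(tr$set == "preexisting" & tr$class == "mh_deletion"))
  expect_equal(r$new_with_mh,
               sum(tr$set == "new" & tr$class == "mh_deletion"))
  expect_lt(abs(r$pre_fraction - 0.3), 3 * sqrt(0.3 * 0.7 / 200))
  expect_lt(abs(r$new_fraction - 0.6), 3 * sqrt(0.6 * 0.4 / 200))
  expect_lt(r$p_raw, 1e-6)
})

test_that("identical inputs give byte-identical report tables", {
  cfg <- smallSimConfig(seed = 33)
  sim <- suppressMessages(simulateMMEJCohort(cfg))
  part <- suppressMessages(partitionPreNew(sim$bcell, sim$lcl, "s"))
  t1 <- buildDeletionTable(part, sim$genome, "small")
  t2 <- buildDeletionTable(part, sim$genome, "small")
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeThresholdTable(t1, f1); writeThresholdTable(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
})
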