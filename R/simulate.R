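# Synthetic cohort generator: a toy reference plus paired pre/post indel
# call sets with planted MMEJ signatures and a ground-truth manifest.
#
# Placement uses disjoint variable-width slots (a random permutation of
# events laid out end-to-end with per-event spans plus slack), so planted
# events can never collide and generation is fully vectorizable for the
# deletion bulk. Every planted signature is forced into the reference by
# construction (flank prefix copied for mh-deletions, junction word copied
# for templated insertions, inverted repeat synthesized for snapbacks);
# signature-free events are guarded (forced first-base mismatch) or
# rejection-sampled against the classifiers so truth labels are exact.

.BASES <- c("A", "C", "G", "T")

# Seed whitening: consecutive integer seeds initialize correlated
# Mersenne-Twister states whose structure survives thousands of draws and
# inflates between-replicate dependence; drawing one integer from the
# freshly seeded stream acts as a hash and decorrelates nearby seeds.
.whitenSeed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  h <- sample.int(2147483647L, 1L)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  h
}

#' Configuration for the synthetic MMEJ cohort simulator
#'
#' All counts are per set (pre-existing / new). Signature assignment per
#' event is Bernoulli at the configured fraction, so recovered fractions
#' carry binomial sampling noise around the target — which is what a
#' calibration of the downstream proportion test needs.
#'
#' @param genomeLength Bases per contig (default 300000).
#' @param nContigs Number of contigs (default 1).
#' @param gcContent GC fraction of the i.i.d. background (default 0.41,
#'   human-like).
#' @param nPreDeletionsSmall,nNewDeletionsSmall Small (2-29 bp) deletions
#'   per set.
#' @param nPreDeletionsLong,nNewDeletionsLong Long (30-500 bp) deletions
#'   per set.
#' @param mhFractionPre,mhFractionNew Fraction of deletions planted with
#'   junction microhomology of at least 2 bp.
#' @param mhLengthWeights Unnormalized weights over microhomology lengths
#'   2..20 for signature-positive deletions (default: geometric decay with
#'   ratio 0.65, echoing the roughly geometric decline of observed
#'   junction-homology lengths).
#' @param nPreSmallInsertions,nNewSmallInsertions 1-3 bp insertions per set.
#' @param templatedFractionPre,templatedFractionNew Fraction of small
#'   insertions planted with a nearby template copy.
#' @param nPreLargeInsertions,nNewLargeInsertions >= 18 nt insertions per
#'   set.
#' @param snapbackFractionPre,snapbackFractionNew Fraction of large
#'   insertions planted with an internal inverted repeat.
#' @param largeInsLenRange Length range of large insertions (default
#'   c(18, 60)).
#' @param qual QUAL written for simulated calls (default 60).
#' @param seed Integer seed; fixes all outputs.
#' @return A list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(genomeLength = 300000L, nContigs = 1L,
                             gcContent = 0.41,
                             nPreDeletionsSmall = 800L,
                             nNewDeletionsSmall = 800L,
                             nPreDeletionsLong = 80L,
                             nNewDeletionsLong = 80L,
                             mhFractionPre = 0.77, mhFractionNew = 0.84,
                             mhLengthWeights = 0.65^(0:18),
                             nPreSmallInsertions = 120L,
                             nNewSmallInsertions = 120L,
                             templatedFractionPre = 0.3,
                             templatedFractionNew = 0.3,
                             nPreLargeInsertions = 40L,
                             nNewLargeInsertions = 80L,
                             snapbackFractionPre = 0.4,
                             snapbackFractionNew = 0.6,
                             largeInsLenRange = c(18L, 60L),
                             qual = 60, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(genomeLength > 0, nContigs >= 1,
            gcContent >= 0, gcContent <= 1,
            length(mhLengthWeights) == 19L, all(mhLengthWeights >= 0))
  fracs <- c(mhFractionPre, mhFractionNew, templatedFractionPre,
             templatedFractionNew, snapbackFractionPre,
             snapbackFractionNew)
  stopifnot(all(fracs >= 0), all(fracs <= 1))
  counts <- c(nPreDeletionsSmall, nNewDeletionsSmall, nPreDeletionsLong,
              nNewDeletionsLong, nPreSmallInsertions, nNewSmallInsertions,
              nPreLargeInsertions, nNewLargeInsertions)
  stopifnot(all(counts >= 0))
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate a random reference genome
#'
#' I.i.d. bases at the configured GC content; deterministic given
#' \code{config$seed}.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @return A \code{\linkS4class{GenomeSequence}}.
#' @export
simulateReference <- function(config) {
  set.seed(.whitenSeed(config$seed))
  pr <- c((1 - config$gcContent) / 2, config$gcContent / 2,
          config$gcContent / 2, (1 - config$gcContent) / 2)
  ctg <- vapply(seq_len(config$nContigs), function(i)
    paste(sample(.BASES, config$genomeLength, replace = TRUE, prob = pr),
          collapse = ""), character(1))
  names(ctg) <- paste0("ctg", seq_len(config$nContigs))
  new("GenomeSequence", contigs = ctg)
}

# draw a base different from each element of `cur` (vectorized)
.otherBase <- function(cur) {
  altTab <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                  G = c("A", "C", "T"), T = c("A", "C", "G"))
  altTab[cbind(match(cur, .BASES), sample.int(3L, length(cur),
                                              replace = TRUE))]
}

#' Plant MMEJ events into a reference and emit paired call sets
#'
#' Builds the event roster from the configuration, places events in
#' disjoint slots (capacity error if the genome is too small), forces the
#' intended signature of each event into the reference sequence, and
#' returns the edited genome together with the two call sets (pre-existing
#' events appear in both; new events only in the post set) and the
#' ground-truth manifest. All records are left-aligned and
#' anchor-base-minimal by construction (a guard base prevents any
#' alternative alignment).
#'
#' @param genome A \code{\linkS4class{GenomeSequence}} from
#'   \code{\link{simulateReference}} (pure ACGT).
#' @param config The same \code{\link{simulationConfig}}.
#' @return List with \code{genome} (edited reference), \code{bcell},
#'   \code{lcl} (\code{\linkS4class{IndelSet}}s) and \code{truth}
#'   (data.frame: key, class, set, contig, pos, event_len, mh_len,
#'   template_offset, repeat_len, separation).
#' @export
plantEvents <- function(genome, config) {
  set.seed(.whitenSeed(config$seed + 1L))
  mhLens <- 2:20
  wts <- config$mhLengthWeights / sum(config$mhLengthWeights)

  mk <- function(n, set, type) {
    if (n == 0L) return(NULL)
    data.frame(set = rep(set, n), type = rep(type, n),
               stringsAsFactors = FALSE)
  }
  ev <- rbind(
    mk(config$nPreDeletionsSmall, "preexisting", "del_small"),
    mk(config$nNewDeletionsSmall, "new", "del_small"),
    mk(config$nPreDeletionsLong, "preexisting", "del_long"),
    mk(config$nNewDeletionsLong, "new", "del_long"),
    mk(config$nPreSmallInsertions, "preexisting", "ins_small"),
    mk(config$nNewSmallInsertions, "new", "ins_small"),
    mk(config$nPreLargeInsertions, "preexisting", "ins_large"),
    mk(config$nNewLargeInsertions, "new", "ins_large"))
  if (is.null(ev) || nrow(ev) == 0L) {
    empty <- .newIndelSet(.emptyIndelFrame())
    return(list(genome = genome, bcell = empty, lcl = empty,
                truth = data.frame()))
  }
  nEv <- nrow(ev)
  isDel <- ev$type %in% c("del_small", "del_long")
  isPre <- ev$set == "preexisting"

  # ---- per-event attributes (one stream, event-major order) ----
  ev$L <- 0L; ev$mh <- NA_integer_; ev$signature <- FALSE
  ev$repeat_len <- NA_integer_; ev$sep <- NA_integer_
  sm <- ev$type == "del_small"; lg <- ev$type == "del_long"
  ev$L[sm] <- sample(.SMALL_DEL_RANGE[1]:.SMALL_DEL_RANGE[2], sum(sm),
                     replace = TRUE)
  ev$L[lg] <- sample(.LONG_DEL_RANGE[1]:.LONG_DEL_RANGE[2], sum(lg),
                     replace = TRUE)
  frac <- ifelse(isPre, config$mhFractionPre, config$mhFractionNew)
  ev$signature[isDel] <- stats::rbinom(sum(isDel), 1L,
                                       frac[isDel]) == 1L
  ev$mh[isDel] <- 0L
  nSig <- sum(isDel & ev$signature)
  ev$mh[isDel & ev$signature] <- sample(mhLens, nSig, replace = TRUE,
                                        prob = wts)
  # a small deletion cannot carry more homology than its own length
  fix <- isDel & ev$signature & ev$mh > ev$L
  ev$L[fix] <- ev$mh[fix]

  si <- ev$type == "ins_small"
  ev$L[si] <- sample(1:3, sum(si), replace = TRUE)
  tfrac <- ifelse(isPre, config$templatedFractionPre,
                  config$templatedFractionNew)
  ev$signature[si] <- stats::rbinom(sum(si), 1L, tfrac[si]) == 1L

  li <- ev$type == "ins_large"
  ev$L[li] <- sample(config$largeInsLenRange[1]:config$largeInsLenRange[2],
                     sum(li), replace = TRUE)
  sfrac <- ifelse(isPre, config$snapbackFractionPre,
                  config$snapbackFractionNew)
  ev$signature[li] <- stats::rbinom(sum(li), 1L, sfrac[li]) == 1L
  liSig <- li & ev$signature
  ev$repeat_len[liSig] <- sample(7:12, sum(liSig), replace = TRUE)
  ev$sep[liSig] <- sample(4:8, sum(liSig), replace = TRUE)
  need <- 2L * ev$repeat_len[liSig] + ev$sep[liSig]
  ev$L[liSig] <- pmax(ev$L[liSig], need)

  # ---- slot placement ----
  span <- ifelse(isDel, ev$L, 0L)
  width <- span + 70L
  ord <- sample.int(nEv)
  margin <- 50L
  avail <- config$genomeLength - 2L * margin
  startRel <- integer(nEv); contigIdx <- integer(nEv)
  cum <- 0L; ctg <- 1L
  for (r in seq_len(nEv)) {
    i <- ord[r]
    if (cum + width[i] > avail) {
      ctg <- ctg + 1L
      cum <- 0L
      if (ctg > config$nContigs) {
        need <- sum(width)
        stop("genome too small for requested events: need ~", need,
             " bp of slot space, have ", config$nContigs * avail, " bp")
      }
    }
    contigIdx[i] <- ctg
    startRel[i] <- cum
    cum <- cum + width[i]
  }
  ev$contig <- paste0("ctg", contigIdx)
  ev$pos <- margin + startRel + 25L   # anchor position, 1-based

  Gl <- lapply(genome@contigs, function(s) strsplit(s, "")[[1]])

  # ---- deletions: vectorized reference edits per contig ----
  for (ci in unique(contigIdx[isDel])) {
    G <- Gl[[ci]]
    d <- which(isDel & contigIdx == ci)
    p <- ev$pos[d]; L <- ev$L[d]; k <- ev$mh[d]
    # force flank prefix equal to deletion prefix for the first k bases
    hasK <- k > 0L
    if (any(hasK)) {
      src <- unlist(mapply(function(pp, kk) (pp + 1L):(pp + kk),
                           p[hasK], k[hasK], SIMPLIFY = FALSE))
      off <- unlist(mapply(function(kk, ll) rep(ll, kk),
                           k[hasK], L[hasK], SIMPLIFY = FALSE))
      G[src + off] <- G[src]
    }
    # force a mismatch right after the homology tract (caps mh at k);
    # for k = 0 this is the first flank base (signature-free junction)
    capped <- k < pmin(L, .MH_CAP)
    mmPos <- p + L + k + 1L
    dPos <- p + k + 1L
    if (any(capped)) {
      cur <- G[dPos[capped]]
      hit <- G[mmPos[capped]] == cur
      if (any(hit))
        G[mmPos[capped][hit]] <- .otherBase(cur[hit])
    }
    # guard against left-shift: anchor base must differ from the last
    # deleted base, which also keeps the record anchor-minimal
    lastDel <- G[p + L]
    shift <- G[p] == lastDel
    if (any(shift)) G[p[shift]] <- .otherBase(lastDel[shift])
    Gl[[ci]] <- G
  }

  # ---- insertions: per-event construction ----
  ev$insSeq <- NA_character_
  ev$template_offset <- NA_integer_
  insIdx <- which(!isDel)
  for (i in insIdx) {
    ci <- contigIdx[i]
    G <- Gl[[ci]]
    p <- ev$pos[i]
    if (ev$type[i] == "ins_small") {
      for (try in seq_len(200L)) {
        I <- paste(sample(.BASES, ev$L[i], replace = TRUE), collapse = "")
        if (substr(I, ev$L[i], ev$L[i]) == G[p]) next
        if (ev$signature[i]) {
          word <- c(G[(p - 1L):p], strsplit(I, "")[[1]], G[(p + 1L):(p + 2L)])
          wl <- length(word)
          G[(p - 14L):(p - 14L + wl - 1L)] <- word
          ev$template_offset[i] <- (15L - 2L + 1L) - wl - 1L  # gap in context
          ev$insSeq[i] <- I
          break
        } else {
          up <- paste(G[(p - 14L):p], collapse = "")
          dn <- paste(G[(p + 1L):(p + 15L)], collapse = "")
          if (is.null(templatedInsertionMatch(I, up, dn))) {
            ev$insSeq[i] <- I
            break
          }
          if (try %% 25L == 0L)  # stubborn repetitive context: refresh it
            G[(p - 14L):(p - 3L)] <- sample(.BASES, 12L, replace = TRUE)
        }
      }
      if (is.na(ev$insSeq[i]))
        stop("failed to construct a signature-free small insertion")
    } else {
      for (try in seq_len(200L)) {
        if (ev$signature[i]) {
          r <- ev$repeat_len[i]; sp <- ev$sep[i]
          core <- 2L * r + sp
          pad <- ev$L[i] - core
          padPre <- if (pad > 0L) sample(0:pad, 1L) else 0L
          padPost <- pad - padPre
          A <- paste(sample(.BASES, r, replace = TRUE), collapse = "")
          I <- paste0(
            paste(sample(.BASES, padPre, replace = TRUE), collapse = ""),
            A,
            paste(sample(.BASES, sp, replace = TRUE), collapse = ""),
            reverseComplement(A),
            paste(sample(.BASES, padPost, replace = TRUE), collapse = ""))
          if (substr(I, ev$L[i], ev$L[i]) == G[p]) next
          ev$insSeq[i] <- I
          break
        } else {
          I <- paste(sample(.BASES, ev$L[i], replace = TRUE), collapse = "")
          if (substr(I, ev$L[i], ev$L[i]) == G[p]) next
          if (is.null(snapbackMatch(I))) {
            ev$insSeq[i] <- I
            break
          }
        }
      }
      if (is.na(ev$insSeq[i]))
        stop("failed to construct a large insertion")
    }
    Gl[[ci]] <- G
  }

  contigs <- vapply(Gl, paste, character(1), collapse = "")
  names(contigs) <- names(genome@contigs)
  outGenome <- new("GenomeSequence", contigs = contigs)

  # ---- build records from the edited reference ----
  ctgStr <- contigs[ev$contig]
  anchor <- substr(ctgStr, ev$pos, ev$pos)
  eventSeq <- ifelse(isDel,
                     substr(ctgStr, ev$pos + 1L, ev$pos + ev$L),
                     ev$insSeq)
  refAll <- ifelse(isDel, paste0(anchor, eventSeq), anchor)
  altAll <- ifelse(isDel, anchor, paste0(anchor, eventSeq))
  rec <- data.frame(contig = ev$contig, pos = ev$pos, ref = refAll,
                    alt = altAll, qual = config$qual,
                    stringsAsFactors = FALSE)
  rec <- .finishIndelFrame(rec)

  classOf <- ifelse(ev$type %in% c("del_small", "del_long"),
                    ifelse(ev$signature, "mh_deletion", "plain_deletion"),
             ifelse(ev$type == "ins_small",
                    ifelse(ev$signature, "templated_small_ins",
                           "plain_small_ins"),
                    ifelse(ev$signature, "snapback_ins",
                           "plain_large_ins")))
  truth <- data.frame(key = rec$key, class = classOf, set = ev$set,
                      contig = ev$contig, pos = ev$pos,
                      event_len = rec$event_len,
                      mh_len = ev$mh, template_offset = ev$template_offset,
                      repeat_len = ev$repeat_len, separation = ev$sep,
                      stringsAsFactors = FALSE)

  bcell <- .newIndelSet(rec[isPre, , drop = FALSE], "sim.bcell")
  lcl <- .newIndelSet(rec, "sim.lcl")
  list(genome = outGenome, bcell = bcell, lcl = lcl, truth = truth)
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper: \code{\link{simulateReference}} then
#' \code{\link{plantEvents}}; optionally writes the FASTA reference, the
#' two VCFs and the truth manifest (JSON) to a directory.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @param dir Optional output directory (created if needed).
#' @return The \code{\link{plantEvents}} list, plus \code{paths} when
#'   \code{dir} is given.
#' @export
simulateMMEJCohort <- function(config, dir = NULL) {
  genome <- simulateReference(config)
  out <- plantEvents(genome, config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(fasta = file.path(dir, "reference.fa"),
                  bcell = file.path(dir, "bcell.vcf"),
                  lcl = file.path(dir, "lcl.vcf"),
                  truth = file.path(dir, "truth.json"))
    writeGenomeFasta(out$genome, paths$fasta)
    writeIndelVCF(out$bcell, out$genome, paths$bcell, qual = config$qual)
    writeIndelVCF(out$lcl, out$genome, paths$lcl, qual = config$qual)
    jsonlite::write_json(out$truth, paths$truth, dataframe = "rows",
                         na = "null", digits = NA)
    out$paths <- paths
  }
  out
}
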