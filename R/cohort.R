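# Cohort set algebra: cross-subject decontamination and the
# pre-existing / newly-arisen partition.

#' Remove indels shared between subjects
#'
#' An indel key observed in two or more different subjects (in any of their
#' samples) is most plausibly a common polymorphism or a systematic calling
#' artefact rather than an independent somatic event, and is removed from
#' every set. With a single subject the input is returned unchanged with a
#' warning (no cross-subject evidence is available).
#'
#' @param subjects Named list of subjects; each subject is a list with
#'   elements \code{bcell} and \code{lcl}, both
#'   \code{\linkS4class{IndelSet}}s (normalized).
#' @return The same structure with cross-subject-shared records removed.
#' @export
removeCrossSubjectShared <- function(subjects) {
  stopifnot(is.list(subjects), length(subjects) >= 1L)
  if (length(subjects) == 1L) {
    warning("single subject: cross-subject shared-indel removal skipped")
    return(subjects)
  }
  keysPerSubject <- lapply(subjects, function(s)
    unique(c(indelKeys(s$bcell), indelKeys(s$lcl))))
  tab <- table(unlist(keysPerSubject))
  shared <- names(tab)[tab >= 2L]
  message("removeCrossSubjectShared: ", length(shared),
          " key(s) shared between subjects removed")
  dropShared <- function(set) {
    rec <- set@records
    .newIndelSet(rec[!(rec$key %in% shared), , drop = FALSE],
                 set@sampleLabel)
  }
  lapply(subjects, function(s) {
    s$bcell <- dropShared(s$bcell)
    s$lcl <- dropShared(s$lcl)
    s
  })
}

#' Partition a subject's calls into pre-existing and newly arisen sets
#'
#' The intersection of the pre-transformation ("B-cell") and
#' post-transformation ("LCL") call sets is taken to predate transformation
#' (pre-existing); calls unique to the post sample are taken to have arisen
#' afterwards (new). Calls unique to the pre sample are discarded from the
#' analysis and reported in the log.
#'
#' @param bcell Pre-transformation \code{\linkS4class{IndelSet}}.
#' @param lcl Post-transformation \code{\linkS4class{IndelSet}}.
#' @param subjectLabel Free-text subject label.
#' @return An \code{\linkS4class{IndelPartition}}. The partition is exact:
#'   \code{length(preexisting) + length(new) == length(lcl)}.
#' @export
partitionPreNew <- function(bcell, lcl, subjectLabel = "") {
  bKeys <- indelKeys(bcell)
  lrec <- lcl@records
  inB <- lrec$key %in% bKeys
  pre <- .newIndelSet(lrec[inB, , drop = FALSE],
                      paste0(subjectLabel, ".preexisting"))
  nw <- .newIndelSet(lrec[!inB, , drop = FALSE],
                     paste0(subjectLabel, ".new"))
  nBOnly <- sum(!(bKeys %in% lrec$key))
  message("partitionPreNew [", subjectLabel, "]: ", length(pre),
          " pre-existing, ", length(nw), " new; ", nBOnly,
          " pre-sample-unique call(s) discarded")
  new("IndelPartition", preexisting = pre, new = nw,
      subjectLabel = subjectLabel)
}
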