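# End-to-end orchestration: filter -> exclude -> cross-subject clean ->
# partition -> score -> test, with deterministic TSV/JSON outputs.

#' Configuration for a full pipeline run
#'
#' Collects every tunable constant of the analysis. The defaults are the
#' canonical ones: QUAL >= 40, thresholds 2..20, small deletions 2-29 bp,
#' long deletions 30-500 bp, small insertions <= 3 bp, snapback repeat
#' >= 7 nt with >= 4 nt separation (hence a \code{2*7 + 4 = 18} nt
#' evaluation minimum), +/-15 nt small-insertion context, Yates-corrected
#' tests, "NS" at p >= 0.05.
#'
#' @param reference Path to the reference FASTA.
#' @param subjects Named list; each element a list with \code{bcell} and
#'   \code{lcl} VCF paths.
#' @param exclusions Character vector of known-variant VCF paths (may be
#'   empty).
#' @param qualMin Minimum QUAL (default 40).
#' @param thresholds Minimum-microhomology thresholds (default 2:20).
#' @param smallDelRange,longDelRange Deletion size classes in bp.
#' @param smallInsMax Maximum small-insertion length in bp (default 3).
#' @param repeatMin Minimum snapback repeat length in nt (default 7).
#' @param sepMin Minimum snapback separation in nt (default 4).
#' @param snapbackMin Minimum evaluated large-insertion length; computed
#'   as \code{2*repeatMin + sepMin} when NULL.
#' @param contextWidth Small-insertion context half-width in nt (default 15).
#' @param correct Continuity correction flag (default TRUE).
#' @param nsAlpha "NS" display threshold (default 0.05).
#' @param outputDir Output directory.
#' @param matchBy Exclusion matching: \code{"key"} or \code{"position"}.
#' @return A list of class \code{RunConfig}.
#' @export
runConfig <- function(reference, subjects, exclusions = character(),
                      qualMin = 40, thresholds = 2:20,
                      smallDelRange = c(2L, 29L),
                      longDelRange = c(30L, 500L), smallInsMax = 3L,
                      repeatMin = 7L, sepMin = 4L, snapbackMin = NULL,
                      contextWidth = 15L, correct = TRUE, nsAlpha = 0.05,
                      outputDir = "mmejscan-out",
                      matchBy = c("key", "position")) {
  matchBy <- match.arg(matchBy)
  if (is.null(snapbackMin)) snapbackMin <- 2L * repeatMin + sepMin
  if (snapbackMin < 2L * repeatMin + sepMin)
    warning("snapbackMin below 2*repeatMin + sepMin: insertions shorter ",
            "than ", 2L * repeatMin + sepMin,
            " nt cannot contain two separated repeat copies")
  stopifnot(smallDelRange[1] <= smallDelRange[2],
            longDelRange[1] <= longDelRange[2],
            smallDelRange[2] < longDelRange[1],
            smallInsMax >= 1L, repeatMin >= 1L, sepMin >= 0L,
            contextWidth >= 2L, qualMin >= 0)
  cfg <- as.list(environment())
  class(cfg) <- "RunConfig"
  cfg
}

#' Run the full MMEJ signature analysis
#'
#' Executes the complete pipeline for every subject: read indels (QUAL
#' filter), remove known variants, left-align, remove cross-subject-shared
#' calls, partition into pre-existing/new sets, build the small- and
#' long-deletion threshold tables and the two insertion summaries, and
#' write all reports plus a run manifest to \code{config$outputDir}.
#' Outputs are deterministic: identical inputs give byte-identical files.
#'
#' @param config A \code{\link{runConfig}}.
#' @return Invisibly, a named list per subject with elements
#'   \code{partition}, \code{small_deletions}, \code{long_deletions},
#'   \code{insertions}.
#' @export
runFullAnalysis <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  for (s in names(config$subjects)) {
    for (role in c("bcell", "lcl")) {
      p <- config$subjects[[s]][[role]]
      if (is.null(p) || !file.exists(p))
        stop("subject '", s, "': missing ", role, " VCF: ",
             if (is.null(p)) "<unset>" else p)
    }
  }
  genome <- loadGenome(config$reference)
  exclSets <- lapply(config$exclusions, function(p) {
    e <- readIndels(p, qualMin = 0, keepMissingQual = TRUE)
    normalizeIndels(e, genome)
  })
  subjects <- lapply(config$subjects, function(s) {
    list(bcell = normalizeIndels(
           excludeKnown(readIndels(s$bcell, qualMin = config$qualMin),
                        exclSets, matchBy = config$matchBy), genome),
         lcl = normalizeIndels(
           excludeKnown(readIndels(s$lcl, qualMin = config$qualMin),
                        exclSets, matchBy = config$matchBy), genome))
  })
  if (length(subjects) >= 2L)
    subjects <- removeCrossSubjectShared(subjects)

  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  for (s in names(subjects)) {
    part <- partitionPreNew(subjects[[s]]$bcell, subjects[[s]]$lcl,
                            subjectLabel = s)
    scored <- list(pre = scoreDeletions(part@preexisting, genome),
                   new = scoreDeletions(part@new, genome))
    tabS <- buildDeletionTable(part, genome, "small",
                               thresholds = config$thresholds,
                               correct = config$correct,
                               nsAlpha = config$nsAlpha, scored = scored)
    tabL <- buildDeletionTable(part, genome, "long",
                               thresholds = config$thresholds,
                               correct = config$correct,
                               nsAlpha = config$nsAlpha, scored = scored)
    ins <- buildInsertionTables(part, genome, correct = config$correct,
                                nsAlpha = config$nsAlpha,
                                contextWidth = config$contextWidth,
                                repeatMin = config$repeatMin,
                                sepMin = config$sepMin)
    pfx <- file.path(config$outputDir, s)
    writeThresholdTable(tabS, paste0(pfx, ".deletions_small.tsv"))
    writeThresholdTable(tabL, paste0(pfx, ".deletions_long.tsv"))
    utils::write.table(ins$small, paste0(pfx, ".insertions_small.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ins$snapback, paste0(pfx, ".insertions_snapback.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    perDel <- rbind(cbind(scored$pre, set = "preexisting"),
                    cbind(scored$new, set = "new"))
    utils::write.table(perDel, paste0(pfx, ".deletions_events.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    perIns <- rbind(cbind(ins$per_event_pre, set = "preexisting"),
                    cbind(ins$per_event_new, set = "new"))
    utils::write.table(perIns, paste0(pfx, ".insertions_events.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results[[s]] <- list(partition = part, small_deletions = tabS,
                         long_deletions = tabL, insertions = ins)
  }

  inputs <- c(reference = config$reference,
              unlist(lapply(config$subjects, unlist)),
              if (length(config$exclusions))
                stats::setNames(config$exclusions,
                                paste0("exclusion", seq_along(config$exclusions))))
  manifest <- list(
    package = "mmejscan",
    version = as.character(utils::packageVersion("mmejscan")),
    config = config[setdiff(names(config), "subjects")],
    subjects = config$subjects,
    input_md5 = as.list(tools::md5sum(unname(inputs))),
    counts = lapply(results, function(r)
      list(preexisting = length(r$partition@preexisting),
           new = length(r$partition@new))))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, null = "null"),
             file.path(config$outputDir, "manifest.json"))
  invisible(results)
}
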