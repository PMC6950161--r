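#' Read peptide chains from FASTA
#'
#' Sequences are read as amino acids; a `*` token in the description
#' line marks C-terminal amidation (the asterisk never appears in the
#' sequence itself).
#'
#' @param path FASTA file.
#' @return Named list of [PeptideChain-class] objects.
#' @export
readPeptideFasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (!length(aa)) stop(sprintf("no sequences in '%s'", path))
  headers <- names(aa)
  amid <- grepl("(^|\\s)\\*(\\s|$)", headers)
  ids <- vapply(strsplit(headers, "\\s+"), `[[`, character(1L), 1L)
  stats::setNames(
    lapply(seq_along(aa), function(i)
      peptideChain(as.character(aa[[i]]), amidated = amid[i])),
    ids)
}

#' Write peptide chains to FASTA
#'
#' @param chains Named list of [PeptideChain-class] objects.
#' @param path Output file. Sequences are wrapped at 60 columns;
#'   amidated chains get a trailing `*` token in the description line.
#' @export
writePeptideFasta <- function(chains, path) {
  stopifnot(is.list(chains), length(chains) >= 1L)
  nm <- .chainNames(chains)
  seqs <- Biostrings::AAStringSet(vapply(chains, chainSequence,
                                         character(1L)))
  names(seqs) <- ifelse(vapply(chains, isAmidated, logical(1L)),
                        paste(nm, "*"), nm)
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read LC-MS mass observations from CSV
#'
#' Expects columns `mass` and `condition`
#' (native/reduced/alkylated); `retention_time`, `peak_area` and
#' `label` are optional.
#'
#' @param path CSV file.
#' @param condition Optionally subset to one condition.
#' @return `data.frame` of observations.
#' @export
readMassObservations <- function(path, condition = NULL) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("mass", "condition") %in% names(x)))
    stop(sprintf("'%s' needs columns 'mass' and 'condition'", path))
  bad <- setdiff(unique(x$condition), c("native", "reduced", "alkylated"))
  if (length(bad))
    stop(sprintf("unknown condition '%s' in '%s'", bad[1L], path))
  if (any(!is.finite(x$mass) | x$mass <= 0))
    stop(sprintf("non-positive mass in '%s'", path))
  if (!is.null(condition)) x <- x[x$condition == condition, , drop = FALSE]
  x
}

#' Read per-contig aligned-read counts from TSV
#'
#' @param path Two-column TSV (`contig`, `count`), with or without a
#'   header line.
#' @return `data.frame` with columns `contig` and `count`.
#' @export
readContigCounts <- function(path) {
  first <- utils::read.delim(path, nrows = 1L, header = FALSE,
                             stringsAsFactors = FALSE)
  hasHeader <- is.character(first[[2L]]) &&
    is.na(suppressWarnings(as.numeric(first[[2L]])))
  x <- utils::read.delim(path, header = hasHeader,
                         stringsAsFactors = FALSE)
  names(x)[1:2] <- c("contig", "count")
  if (any(!is.finite(x$count) | x$count < 0))
    stop(sprintf("negative or missing count in '%s'", path))
  x
}

#' Read de novo sequence tags from CSV
#'
#' @param path CSV with columns `sequence` and `alc`.
#' @return `data.frame` of tags.
#' @export
readSequenceTags <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sequence", "alc") %in% names(x)))
    stop(sprintf("'%s' needs columns 'sequence' and 'alc'", path))
  x
}

#' Write a MatchReport as JSON and/or TSV
#'
#' @param report A `MatchReport` from [matchMasses()].
#' @param jsonPath,tsvPath Output paths (either may be `NULL`).
#' @export
writeMatchReport <- function(report, jsonPath = NULL, tsvPath = NULL) {
  stopifnot(inherits(report, "MatchReport"))
  if (!is.null(jsonPath))
    jsonlite::write_json(
      list(assignments = report$assignments,
           matches = report$matches,
           unexplained = report$unexplained,
           unmatchedHypotheses = report$unmatchedHypotheses,
           tolerance = report$tolerance),
      jsonPath, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(tsvPath))
    utils::write.table(report$assignments, tsvPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(report)
}

#' Run the full peptidome characterization pipeline
#'
#' Chains the stages end to end, as the original study does: six-frame
#' translation and ORF extraction of every contig, ALC-filtered tag
#' matching to locate precursor ORFs, anchored signal/prepro/mature
#' segmentation (with the glycine amidation-donor heuristic), RPM
#' quantification over the contigs supporting each precursor, relative
#' peak-area abundance of the native observations, dimer scanning with
#' reduction/alkylation verification, and a physicochemical annotation
#' table.
#'
#' @param contigs Named character vector of contig sequences (or a
#'   FASTA path).
#' @param counts `data.frame` with `contig`/`count` (or a TSV path).
#' @param tags Tag `data.frame` (`sequence`, `alc`) or CSV path.
#' @param native,reduced,alkylated Mass observations (data frames,
#'   numeric vectors, CSV paths, or `NULL`).
#' @param matureAnchors Named character vector of mature sequences used
#'   as segmentation anchors (names become peptide names). Each anchor
#'   is searched in the tag-supported ORFs.
#' @param minOrfLength Minimum ORF length in residues (default 60;
#'   venom precursors are short).
#' @param alcThreshold ALC filter for tags (default 60).
#' @param tolerance Mass-matching tolerance in Da (default 0.5).
#' @param totalReads Total aligned reads (default: sum of `counts`).
#' @return A list with `precursors` (list of [PrecursorModel-class]),
#'   `chains`, `rpm`, `abundance`, `scan` (from [dimerScan()]) and
#'   `properties` (from [peptideProperties()]).
#' @export
runPipeline <- function(contigs, counts, tags, native,
                        reduced = NULL, alkylated = NULL,
                        matureAnchors, minOrfLength = 60L,
                        alcThreshold = 60, tolerance = 0.5,
                        totalReads = NULL) {
  if (is.character(contigs) && length(contigs) == 1L && file.exists(contigs)) {
    x <- Biostrings::readDNAStringSet(contigs)
    contigs <- stats::setNames(as.character(x),
                               vapply(strsplit(names(x), "\\s+"),
                                      `[[`, character(1L), 1L))
  }
  if (is.character(counts)) counts <- readContigCounts(counts)
  if (is.character(tags) && length(tags) == 1L && file.exists(tags))
    tags <- readSequenceTags(tags)
  if (is.character(native) && length(native) == 1L && file.exists(native))
    native <- readMassObservations(native, "native")
  if (is.character(reduced) && length(reduced) == 1L && file.exists(reduced))
    reduced <- readMassObservations(reduced, "reduced")
  if (is.character(alkylated) && length(alkylated) == 1L &&
      file.exists(alkylated))
    alkylated <- readMassObservations(alkylated, "alkylated")
  stopifnot(!is.null(names(contigs)), !is.null(names(matureAnchors)))
  if (is.null(totalReads)) totalReads <- sum(counts$count)

  # translate every contig, pool ORFs with their source contig
  orfRows <- list()
  for (ctg in names(contigs)) {
    o <- extractOrfs(sixFrameTranslate(contigs[[ctg]]), minOrfLength)
    if (nrow(o)) { o$contig <- ctg; orfRows[[length(orfRows) + 1L]] <- o }
  }
  orfs <- if (length(orfRows)) do.call(rbind, orfRows) else
    data.frame(orf = character(), frame = character(),
               start = integer(), end = integer(), contig = character())

  hits <- matchTags(tags, orfs, alcThreshold = alcThreshold)
  supported <- sort(unique(hits$orf))

  precursors <- list()
  chains <- list()
  pepToContigs <- list()
  for (p in names(matureAnchors)) {
    anchor <- matureAnchors[[p]]
    inOrf <- supported[vapply(supported, function(j)
      grepl(anchor, orfs$orf[j], fixed = TRUE), logical(1L))]
    if (!length(inOrf)) next
    model <- segmentPrecursor(orfs$orf[inOrf[1L]], matureAnchor = anchor,
                              contigs = unique(orfs$contig[inOrf]))
    precursors[[p]] <- model
    chains[[p]] <- maturePeptide(model)
    pepToContigs[[p]] <- unique(orfs$contig[inOrf])
  }
  if (!length(chains))
    stop("no mature anchor was recovered from the tag-supported ORFs")

  rpm <- readsPerMillion(counts, totalReads, pepToContigs)
  abundance <- NULL
  if (is.data.frame(native) && "peak_area" %in% names(native)) {
    lbl <- if ("label" %in% names(native)) native$label
           else sprintf("obs_%g", round(native$mass, 2L))
    abundance <- relativeAbundance(stats::setNames(native$peak_area, lbl))
  }
  scan <- dimerScan(chains, native, reduced, alkylated,
                    tolerance = tolerance, includeMonomers = TRUE)
  props <- peptideProperties(chains, rpm = rpm)
  list(precursors = precursors, chains = chains, rpm = rpm,
       abundance = abundance, scan = scan, properties = props)
}
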