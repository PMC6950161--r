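#' Six-frame translation of a nucleotide contig
#'
#' Translates the three forward frames and the three frames of the
#' reverse complement under the standard genetic code. Stop codons are
#' rendered as `"*"`; codons containing `N` translate to the unknown
#' sentinel `"X"`; trailing partial codons are dropped.
#'
#' @param contig A nucleotide sequence: a string or a
#'   [Biostrings::DNAString]. Alphabet restricted to A/C/G/T/N.
#' @return Named character vector of six amino-acid strings
#'   (`F1`,`F2`,`F3`,`R1`,`R2`,`R3`).
#' @examples
#' sixFrameTranslate("ATGGCT")[["F1"]]   # "MA"
#' @export
sixFrameTranslate <- function(contig) {
  if (is(contig, "DNAString")) contig <- as.character(contig)
  stopifnot(is.character(contig), length(contig) == 1L)
  contig <- toupper(contig)
  bad <- regmatches(contig, regexpr("[^ACGTN]", contig))
  if (length(bad) && nzchar(bad))
    stop(sprintf("non-IUPAC nucleotide '%s' in contig", bad))
  dna <- Biostrings::DNAString(contig)
  rc <- Biostrings::reverseComplement(dna)
  oneFrame <- function(x, off) {
    n <- length(x) - off
    n <- n - n %% 3L
    if (n < 3L) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(x, off + 1L, off + n),
      if.fuzzy.codon = "solve", no.init.codon = TRUE))
  }
  out <- c(
    F1 = oneFrame(dna, 0L), F2 = oneFrame(dna, 1L), F3 = oneFrame(dna, 2L),
    R1 = oneFrame(rc, 0L), R2 = oneFrame(rc, 1L), R3 = oneFrame(rc, 2L)
  )
  out
}

#' Extract open reading frames from translated frames
#'
#' ORFs are maximal stop-free stretches (stop-to-stop extraction; no
#' start-codon requirement, since peptide precursors may lie mid-contig
#' in overextended assemblies). Stretches shorter than `minLength`
#' residues are dropped.
#'
#' @param frames Named character vector of translated frames, e.g. from
#'   [sixFrameTranslate()], or a single amino-acid string.
#' @param minLength Minimum ORF length in residues (default 100, the
#'   usual threshold for annotating full protein ORFs; use a smaller
#'   value when mining short peptide precursors).
#' @return A `data.frame` with columns `orf` (sequence), `frame`,
#'   `start` and `end` (1-based residue coordinates within the frame).
#' @export
extractOrfs <- function(frames, minLength = 100L) {
  stopifnot(is.character(frames), minLength >= 1L)
  if (is.null(names(frames)))
    names(frames) <- paste0("frame", seq_along(frames))
  rows <- list()
  for (f in names(frames)) {
    pieces <- strsplit(frames[[f]], "*", fixed = TRUE)[[1L]]
    pos <- 1L
    for (p in pieces) {
      if (nchar(p) >= minLength)
        rows[[length(rows) + 1L]] <- data.frame(
          orf = p, frame = f, start = pos, end = pos + nchar(p) - 1L,
          stringsAsFactors = FALSE)
      pos <- pos + nchar(p) + 1L
    }
  }
  if (!length(rows))
    return(data.frame(orf = character(), frame = character(),
                      start = integer(), end = integer()))
  do.call(rbind, rows)
}

.canonIL <- function(x) gsub("L", "I", x, fixed = TRUE)

# all 1-based offsets where `tag` occurs in `subject` with at most
# `maxMismatch` substitutions
.tagOffsets <- function(tag, subject, maxMismatch = 0L) {
  nt <- nchar(tag); ns <- nchar(subject)
  if (nt > ns) return(integer(0L))
  if (maxMismatch == 0L) {
    hits <- gregexpr(tag, subject, fixed = TRUE)[[1L]]
    return(if (hits[1L] == -1L) integer(0L) else as.integer(hits))
  }
  tchars <- strsplit(tag, "")[[1L]]
  schars <- strsplit(subject, "")[[1L]]
  offs <- integer(0L)
  for (s in seq_len(ns - nt + 1L)) {
    if (sum(schars[s:(s + nt - 1L)] != tchars) <= maxMismatch)
      offs <- c(offs, s)
  }
  offs
}

#' Match de novo sequence tags against translated ORFs
#'
#' Tags below the ALC (Average Local Confidence) threshold are
#' discarded; the rest are searched in every ORF. A tag matches at an
#' offset when every position agrees, with isoleucine and leucine
#' treated as interchangeable when `ilEquivalent = TRUE` (they are
#' isobaric, so de novo MS sequencing cannot tell them apart). A scored
#' mismatch mode is available through `maxMismatch`.
#'
#' @param tags A `data.frame` with columns `sequence` and `alc`
#'   (percent, 0-100), or a character vector (ALC then taken as 100).
#' @param orfs A `data.frame` with an `orf` column (e.g. from
#'   [extractOrfs()]) or a character vector of amino-acid strings.
#' @param alcThreshold Minimum ALC score kept (default 60).
#' @param ilEquivalent Treat I and L as equivalent (default `TRUE`).
#' @param maxMismatch Maximum substitutions tolerated (default 0).
#' @return A `data.frame` with columns `tag`, `alc`, `orf` (index into
#'   the input), `offset` (1-based position of the match).
#' @export
matchTags <- function(tags, orfs, alcThreshold = 60,
                      ilEquivalent = TRUE, maxMismatch = 0L) {
  if (is.character(tags))
    tags <- data.frame(sequence = tags, alc = 100, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(tags),
            all(c("sequence", "alc") %in% names(tags)),
            alcThreshold >= 0, alcThreshold <= 100)
  if (any(tags$alc < 0 | tags$alc > 100))
    stop("ALC scores must lie in [0, 100]")
  orfSeqs <- if (is.data.frame(orfs)) orfs$orf else orfs
  keep <- tags[tags$alc >= alcThreshold, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(keep))) {
    tg <- toupper(keep$sequence[i])
    tgc <- if (ilEquivalent) .canonIL(tg) else tg
    for (j in seq_along(orfSeqs)) {
      sub <- if (ilEquivalent) .canonIL(orfSeqs[j]) else orfSeqs[j]
      for (off in .tagOffsets(tgc, sub, maxMismatch))
        rows[[length(rows) + 1L]] <- data.frame(
          tag = tg, alc = keep$alc[i], orf = j, offset = off,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(tag = character(), alc = numeric(),
                      orf = integer(), offset = integer()))
  do.call(rbind, rows)
}

#' Segment a precursor ORF into signal, prepro and mature regions
#'
#' The cleavage rule is one of:
#' \describe{
#'   \item{`matureAnchor`}{cut immediately before the first occurrence
#'     of a supplied mature sequence; the mature span equals the anchor
#'     occurrence. If the residue immediately after the mature span is a
#'     glycine, the mature peptide is flagged as C-terminally amidated
#'     (glycine is the standard amidation donor; heuristic, disable with
#'     `amidationDonor = FALSE`).}
#'   \item{`cutPosition`}{explicit cut: the mature region starts at
#'     `cutPosition + 1` and runs to the end of the ORF.}
#'   \item{`motif`}{a regular expression; the cut falls right after its
#'     first match.}
#' }
#' The prepro region must be non-empty; an optional `signalLength`
#' splits a signal peptide off its front.
#'
#' @param orf Amino-acid sequence of the ORF.
#' @param matureAnchor,cutPosition,motif The cleavage rule (exactly one).
#' @param signalLength Length of the signal region (default 0 = not
#'   annotated).
#' @param amidationDonor Apply the glycine-donor amidation heuristic
#'   (anchored mode only)?
#' @param contigs Optional source contig identifiers.
#' @return A [PrecursorModel-class].
#' @examples
#' orf <- paste0("MKLSYLVLGLA", "EADALAESLP", "DWKNTAKEWGKKVGEALLDCAKQKM", "G")
#' pm <- segmentPrecursor(orf, matureAnchor = "DWKNTAKEWGKKVGEALLDCAKQKM",
#'                        signalLength = 11)
#' maturePeptide(pm)
#' @export
segmentPrecursor <- function(orf, matureAnchor = NULL, cutPosition = NULL,
                             motif = NULL, signalLength = 0L,
                             amidationDonor = TRUE, contigs = character()) {
  stopifnot(is.character(orf), length(orf) == 1L)
  orf <- toupper(orf)
  n <- nchar(orf)
  rules <- c(!is.null(matureAnchor), !is.null(cutPosition), !is.null(motif))
  if (sum(rules) != 1L)
    stop("supply exactly one of 'matureAnchor', 'cutPosition', 'motif'")
  amidated <- FALSE
  if (!is.null(matureAnchor)) {
    matureAnchor <- toupper(matureAnchor)
    at <- regexpr(matureAnchor, orf, fixed = TRUE)
    if (at == -1L)
      stop("mature anchor not found in ORF")
    matureStart <- as.integer(at)
    matureEnd <- matureStart + nchar(matureAnchor) - 1L
    if (amidationDonor && matureEnd < n &&
        substr(orf, matureEnd + 1L, matureEnd + 1L) == "G")
      amidated <- TRUE
  } else if (!is.null(cutPosition)) {
    cutPosition <- as.integer(cutPosition)
    if (cutPosition < 1L || cutPosition >= n)
      stop("'cutPosition' must leave a non-empty prepro and mature region")
    matureStart <- cutPosition + 1L
    matureEnd <- n
  } else {
    at <- regexpr(motif, orf)
    if (at == -1L)
      stop("cleavage motif not found in ORF")
    matureStart <- as.integer(at) + attr(at, "match.length")
    if (matureStart > n)
      stop("cleavage motif leaves an empty mature region")
    matureEnd <- n
  }
  new("PrecursorModel", orf = orf, signalEnd = as.integer(signalLength),
      matureStart = matureStart, matureEnd = matureEnd,
      amidated = amidated, contigs = contigs)
}

#' Column-wise consensus of an aligned block
#'
#' For each alignment column, emits the residue supported by more than
#' `majorityThreshold` of the non-gap rows, and `"X"` otherwise.
#' Columns where gaps are the majority are dropped.
#'
#' @param block Character vector of equal-length aligned sequences
#'   (gap = `"-"`).
#' @param majorityThreshold Fraction in (0.5, 1]; default 0.5 means a
#'   strict majority.
#' @return The consensus string.
#' @examples
#' consensusSequence(c("MKLS", "MKIS", "MKLS"))
#' @export
consensusSequence <- function(block, majorityThreshold = 0.5) {
  stopifnot(is.character(block), length(block) >= 1L)
  if (majorityThreshold <= 0.5 - 1e-12 && majorityThreshold != 0.5 ||
      majorityThreshold > 1)
    stop("'majorityThreshold' must lie in [0.5, 1]")
  if (length(unique(nchar(block))) != 1L)
    stop("all rows must have the same length")
  mat <- do.call(rbind, strsplit(toupper(block), ""))
  cols <- character(0L)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    gaps <- sum(col == "-")
    if (gaps > length(col) / 2) next       # gap-majority column dropped
    res <- col[col != "-"]
    tab <- sort(table(res), decreasing = TRUE)
    frac <- tab[1L] / length(res)
    cols <- c(cols, if (frac > majorityThreshold) names(tab)[1L] else "X")
  }
  paste(cols, collapse = "")
}
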