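#' @import methods
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' PeptideChain: a single peptide chain
#'
#' An amino-acid sequence together with its terminal state (free acid or
#' C-terminally amidated) and any site-localized modifications. This is
#' the unit of all mass arithmetic.
#'
#' @slot sequence Uppercase one-letter amino-acid string (20 standard
#'   codes only).
#' @slot amidated Logical; `TRUE` when the C-terminal hydroxyl is
#'   replaced by an amine (-0.984 Da).
#' @slot modifications A `data.frame` with columns `position` (integer,
#'   1-based) and `name` (a key of [modificationDeltas()]), or `NULL`.
#'
#' @seealso [peptideChain()], [chainMass()], [cysteineCount()]
#' @export
setClass("PeptideChain",
  representation(
    sequence = "character",
    amidated = "logical",
    modifications = "data.frameOrNULL"
  ),
  prototype(amidated = FALSE, modifications = NULL)
)

setValidity("PeptideChain", function(object) {
  s <- object@sequence
  if (length(s) != 1L || is.na(s) || !nzchar(s))
    return("'sequence' must be a single non-empty string")
  aa <- strsplit(s, "")[[1]]
  bad <- which(!aa %in% .STANDARD_AA)
  if (length(bad))
    return(sprintf("unknown residue code '%s' at position %d",
                   aa[bad[1L]], bad[1L]))
  if (length(object@amidated) != 1L || is.na(object@amidated))
    return("'amidated' must be TRUE or FALSE")
  m <- object@modifications
  if (!is.null(m) && nrow(m)) {
    if (!all(c("position", "name") %in% names(m)))
      return("'modifications' needs columns 'position' and 'name'")
    if (any(m$position < 1L | m$position > nchar(s)))
      return("modification position outside sequence bounds")
    unknown <- setdiff(m$name, names(.MOD_DELTAS))
    if (length(unknown))
      return(sprintf("unknown modification '%s'", unknown[1L]))
    want <- .SITE_MODS[m$name]
    here <- aa[m$position]
    off <- which(!is.na(want) & want != here)
    if (length(off))
      return(sprintf("modification '%s' at position %d sits on '%s', expected '%s'",
                     m$name[off[1L]], m$position[off[1L]],
                     here[off[1L]], want[off[1L]]))
  }
  TRUE
})

#' Construct a PeptideChain
#'
#' @param sequence Amino-acid sequence (one-letter codes; coerced to
#'   uppercase).
#' @param amidated Is the C-terminus amidated? Default `FALSE` (free
#'   acid).
#' @param modifications Optional `data.frame` with columns `position`
#'   and `name` naming site-localized modifications (see
#'   [modificationDeltas()]).
#' @return A [PeptideChain-class] object.
#' @examples
#' peptideChain("TLTNMSLREILEKLGIKIPPGLNI")
#' peptideChain("DWKNTAKEWGKKVGEALLDCAKQKM", amidated = TRUE)
#' @export
peptideChain <- function(sequence, amidated = FALSE, modifications = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  new("PeptideChain",
      sequence = toupper(sequence),
      amidated = isTRUE(amidated),
      modifications = modifications)
}

#' @describeIn peptideChain Sequence accessor.
#' @param x A `PeptideChain`.
#' @export
chainSequence <- function(x) {
  stopifnot(is(x, "PeptideChain"))
  x@sequence
}

#' @describeIn peptideChain Is the chain C-terminally amidated?
#' @export
isAmidated <- function(x) {
  stopifnot(is(x, "PeptideChain"))
  x@amidated
}

#' @describeIn peptideChain Number of cysteines in the chain.
#' @export
cysteineCount <- function(x) {
  stopifnot(is(x, "PeptideChain"))
  lengths(regmatches(x@sequence, gregexpr("C", x@sequence, fixed = TRUE)))
}

setMethod("show", "PeptideChain", function(object) {
  cat(sprintf("PeptideChain (%d aa%s): %s\n",
              nchar(object@sequence),
              if (object@amidated) ", amidated" else "",
              object@sequence))
  if (!is.null(object@modifications) && nrow(object@modifications))
    cat("  modifications:",
        paste(sprintf("%s@%d", object@modifications$name,
                      object@modifications$position), collapse = ", "),
        "\n")
  invisible(NULL)
})

#' PeptideAssembly: a monomer or disulfide-linked dimer
#'
#' One or two [PeptideChain-class] chains with a disulfide-bond count and
#' a mass convention. Models the monomer, homodimer and heterodimer
#' species of a venom peptidome.
#'
#' Two mass conventions are supported because published dimer masses mix
#' them: `"chemical"` subtracts two hydrogens (2.0157 Da) per disulfide
#' bond; `"additive"` is the plain sum of the chain masses, ignoring
#' bonds.
#'
#' @slot chains List of one or two `PeptideChain` objects.
#' @slot interchainBonds,intrachainBonds Non-negative integers; a
#'   one-chain assembly has `interchainBonds = 0`.
#' @slot convention `"chemical"` or `"additive"`.
#'
#' @seealso [peptideAssembly()], [assemblyMass()], [reducedChainMasses()]
#' @export
setClass("PeptideAssembly",
  representation(
    chains = "list",
    interchainBonds = "integer",
    intrachainBonds = "integer",
    convention = "character"
  ),
  prototype(interchainBonds = 0L, intrachainBonds = 0L,
            convention = "chemical")
)

setValidity("PeptideAssembly", function(object) {
  n <- length(object@chains)
  if (n < 1L || n > 2L)
    return("an assembly has one or two chains")
  if (!all(vapply(object@chains, is, logical(1L), "PeptideChain")))
    return("'chains' must contain PeptideChain objects")
  if (object@interchainBonds < 0L || object@intrachainBonds < 0L)
    return("bond counts must be non-negative")
  if (n == 1L && object@interchainBonds > 0L)
    return("a one-chain assembly cannot have interchain bonds")
  nCys <- sum(vapply(object@chains, cysteineCount, integer(1L)))
  if (2L * (object@interchainBonds + object@intrachainBonds) > nCys)
    return(sprintf(
      "%d disulfide bond(s) need %d cysteines but the chains have %d",
      object@interchainBonds + object@intrachainBonds,
      2L * (object@interchainBonds + object@intrachainBonds), nCys))
  if (!object@convention %in% c("chemical", "additive"))
    return("'convention' must be \"chemical\" or \"additive\"")
  TRUE
})

#' Construct a PeptideAssembly
#'
#' @param chains A `PeptideChain`, or a list of one or two of them.
#' @param interchainBonds,intrachainBonds Disulfide bond counts.
#' @param convention Dimer mass convention, `"chemical"` (default;
#'   -2 H per bond) or `"additive"`.
#' @return A [PeptideAssembly-class] object.
#' @examples
#' ch <- peptideChain("DWTDTAKEWGRKVGGALLDCAKQKM", amidated = TRUE)
#' homo <- peptideAssembly(list(ch, ch), interchainBonds = 1)
#' assemblyMass(homo)
#' @export
peptideAssembly <- function(chains, interchainBonds = 0L,
                            intrachainBonds = 0L,
                            convention = c("chemical", "additive")) {
  if (is(chains, "PeptideChain")) chains <- list(chains)
  new("PeptideAssembly",
      chains = chains,
      interchainBonds = as.integer(interchainBonds),
      intrachainBonds = as.integer(intrachainBonds),
      convention = match.arg(convention))
}

#' @describeIn peptideAssembly List of constituent chains.
#' @param x A `PeptideAssembly`.
#' @export
assemblyChains <- function(x) {
  stopifnot(is(x, "PeptideAssembly"))
  x@chains
}

#' @describeIn peptideAssembly Total disulfide bond count
#'   (interchain + intrachain).
#' @export
disulfideBonds <- function(x) {
  stopifnot(is(x, "PeptideAssembly"))
  x@interchainBonds + x@intrachainBonds
}

#' @describeIn peptideAssembly `TRUE` for a single-chain assembly.
#' @export
isMonomer <- function(x) {
  stopifnot(is(x, "PeptideAssembly"))
  length(x@chains) == 1L
}

setMethod("show", "PeptideAssembly", function(object) {
  kind <- if (isMonomer(object)) "Monomer"
    else if (chainSequence(object@chains[[1L]]) ==
             chainSequence(object@chains[[2L]])) "Homodimer"
    else "Heterodimer"
  cat(sprintf("PeptideAssembly: %s, %d S-S (%d inter / %d intra), %s convention\n",
              kind, disulfideBonds(object), object@interchainBonds,
              object@intrachainBonds, object@convention))
  for (ch in object@chains)
    cat("  ", chainSequence(ch), if (isAmidated(ch)) "*" else "", "\n",
        sep = "")
  invisible(NULL)
})

#' PrecursorModel: signal / prepro / mature segmentation of an ORF
#'
#' A translated open reading frame partitioned into a (possibly empty)
#' signal region, a non-empty prepro region and a non-empty mature
#' region, in that order and without gaps. The mature region is the
#' secreted peptide; when the residue immediately following it is a
#' glycine, the chain is flagged as C-terminally amidated (glycine is the
#' standard amidation donor).
#'
#' @slot orf Full amino-acid sequence of the ORF.
#' @slot signalEnd Last position of the signal region (0 = no signal
#'   annotated).
#' @slot matureStart,matureEnd 1-based span of the mature peptide.
#' @slot amidated Whether the mature peptide is amidated.
#' @slot contigs Identifiers of the source contig(s).
#'
#' @seealso [segmentPrecursor()], [maturePeptide()]
#' @export
setClass("PrecursorModel",
  representation(
    orf = "character",
    signalEnd = "integer",
    matureStart = "integer",
    matureEnd = "integer",
    amidated = "logical",
    contigs = "character"
  ),
  prototype(signalEnd = 0L, amidated = FALSE, contigs = character())
)

setValidity("PrecursorModel", function(object) {
  n <- nchar(object@orf)
  if (length(object@orf) != 1L || n < 2L)
    return("'orf' must be a single sequence of at least two residues")
  if (object@signalEnd < 0L || object@signalEnd >= object@matureStart - 1L)
    return("regions must satisfy signal < prepro < mature with a non-empty prepro")
  if (object@matureStart < 2L)
    return("prepro region must be non-empty (mature cannot start at position 1)")
  if (object@matureEnd < object@matureStart || object@matureEnd > n)
    return("mature span must be non-empty and inside the ORF")
  TRUE
})

#' @describeIn segmentPrecursor Signal-region sequence (may be "").
#' @export
signalRegion <- function(x) {
  stopifnot(is(x, "PrecursorModel"))
  if (x@signalEnd == 0L) "" else substr(x@orf, 1L, x@signalEnd)
}

#' @describeIn segmentPrecursor Prepro-region sequence (signal excluded).
#' @export
preproRegion <- function(x) {
  stopifnot(is(x, "PrecursorModel"))
  substr(x@orf, x@signalEnd + 1L, x@matureStart - 1L)
}

#' @describeIn segmentPrecursor Mature-region sequence.
#' @export
matureRegion <- function(x) {
  stopifnot(is(x, "PrecursorModel"))
  substr(x@orf, x@matureStart, x@matureEnd)
}

#' @describeIn segmentPrecursor The mature peptide as a [PeptideChain-class],
#'   carrying the amidation flag.
#' @export
maturePeptide <- function(x) {
  stopifnot(is(x, "PrecursorModel"))
  peptideChain(matureRegion(x), amidated = x@amidated)
}

setMethod("show", "PrecursorModel", function(object) {
  cat(sprintf("PrecursorModel (%d aa ORF)\n", nchar(object@orf)))
  cat(sprintf("  signal : %s\n", signalRegion(object)))
  cat(sprintf("  prepro : %s\n", preproRegion(object)))
  cat(sprintf("  mature : %s%s\n", matureRegion(object),
              if (object@amidated) " (amidated)" else ""))
  if (length(object@contigs))
    cat("  contigs:", paste(object@contigs, collapse = ", "), "\n")
  invisible(NULL)
})
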