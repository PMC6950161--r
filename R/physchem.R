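#' Percentage of hydrophobic residues
#'
#' Fraction of the chain drawn from a hydrophobic residue set, as a
#' percentage rounded to 2 decimal places. The default set
#' \{A, C, F, I, L, M, V, W, Y\} is the one that reproduces the
#' hydrophobicity annotations of published venom peptide tables.
#'
#' @param chain A [PeptideChain-class] or a sequence string.
#' @param hydrophobicSet Character vector of one-letter codes counted as
#'   hydrophobic.
#' @return Percentage in `[0, 100]`.
#' @examples
#' hydrophobicFraction("FWGLILQGIWAVVKWAGPIIVDIAADYVIEYV")  # 71.88
#' @export
hydrophobicFraction <- function(chain, hydrophobicSet = .HYDROPHOBIC_SET) {
  if (is.character(chain)) chain <- peptideChain(chain)
  stopifnot(is(chain, "PeptideChain"))
  aa <- strsplit(chain@sequence, "")[[1L]]
  round(100 * sum(aa %in% hydrophobicSet) / length(aa), 2L)
}

# Henderson-Hasselbalch charge of a pooled set of ionizable groups.
# `groups` is a named integer vector over names(pka).
.groupCharge <- function(groups, pH, pka) {
  pos <- c("Nterm", "K", "R", "H")
  neg <- c("Cterm", "C", "D", "E", "Y")
  cp <- sum(groups[pos] / (1 + 10^(pH - pka[pos])))
  cn <- sum(groups[neg] / (1 + 10^(pka[neg] - pH)))
  unname(cp - cn)
}

.chainGroups <- function(chain, pka) {
  aa <- strsplit(chain@sequence, "")[[1L]]
  g <- stats::setNames(integer(length(pka)), names(pka))
  g["Nterm"] <- 1L
  g["Cterm"] <- if (chain@amidated) 0L else 1L
  for (r in c("C", "D", "E", "H", "K", "R", "Y")) g[r] <- sum(aa == r)
  g
}

.ionizableGroups <- function(x, pka, ionizeBondedCys = TRUE) {
  if (is.character(x)) x <- peptideChain(x)
  if (is(x, "PeptideChain")) return(.chainGroups(x, pka))
  stopifnot(is(x, "PeptideAssembly"))
  g <- Reduce(`+`, lapply(x@chains, .chainGroups, pka = pka))
  if (!ionizeBondedCys)
    g["C"] <- max(g[["C"]] - 2L * disulfideBonds(x), 0L)
  g
}

#' Net charge at a given pH
#'
#' Henderson-Hasselbalch sum over the N-terminus, the C-terminus
#' (suppressed when amidated) and the ionizable side chains
#' D, E, C, Y, H, K, R. For an assembly the charge is the sum over both
#' chains' groups, which makes a homodimer's charge exactly twice its
#' monomer's; set `ionizeBondedCys = FALSE` to remove disulfide-bonded
#' cysteines from the ionizable pool instead.
#'
#' Net charge is strictly decreasing in pH, which guarantees a unique
#' isoelectric point.
#'
#' @param x A [PeptideChain-class], [PeptideAssembly-class] or sequence
#'   string.
#' @param pH pH at which to evaluate (default 7).
#' @param pkaSet Name of a pKa table ([pkaSet()]) or a named numeric
#'   vector with entries `Nterm`, `Cterm`, `C`, `D`, `E`, `H`, `K`,
#'   `R`, `Y`.
#' @param ionizeBondedCys Keep disulfide-bonded cysteines ionizable in
#'   assemblies (default `TRUE`)?
#' @return Net charge in elementary charges (float; round to 1 dp for
#'   presentation).
#' @examples
#' netCharge(peptideChain("DWKNTAKEWGKKVGEALLDCAKQKM", amidated = TRUE))
#' @export
netCharge <- function(x, pH = 7, pkaSet = "emboss",
                      ionizeBondedCys = TRUE) {
  if (is.character(pkaSet)) pkaSet <- pkaSet(pkaSet)
  if (any(pH <= 0 | pH >= 14)) stop("'pH' must lie in (0, 14)")
  g <- .ionizableGroups(x, pkaSet, ionizeBondedCys)
  vapply(pH, function(p) .groupCharge(g, p, pkaSet), numeric(1L))
}

#' Isoelectric point
#'
#' The pH at which the Henderson-Hasselbalch net charge vanishes, found
#' by bisection on (0, 14) to |charge| < 1e-4. The default pKa table is
#' the Bjellqvist-style set used by the common web pI calculators;
#' published pI values are reproducible only to a few tenths of a pH
#' unit because every calculator ships its own pKa table.
#'
#' @inheritParams netCharge
#' @return pI in pH units (round to 2 dp for presentation).
#' @examples
#' isoelectricPoint("GILGVIARWIWKLIQILAPTAAVEVATRLGLPQ")  # ~10.8
#' @export
isoelectricPoint <- function(x, pkaSet = "bjellqvist",
                             ionizeBondedCys = TRUE) {
  if (is.character(pkaSet)) pkaSet <- pkaSet(pkaSet)
  g <- .ionizableGroups(x, pkaSet, ionizeBondedCys)
  if (sum(g) == 0L) stop("no ionizable group; pI undefined")
  lo <- 1e-6; hi <- 14 - 1e-6
  cLo <- .groupCharge(g, lo, pkaSet)
  cHi <- .groupCharge(g, hi, pkaSet)
  if (cLo < 0 || cHi > 0)
    stop("net charge has no zero in (0, 14); pI undefined")
  repeat {
    mid <- (lo + hi) / 2
    cm <- .groupCharge(g, mid, pkaSet)
    if (abs(cm) < 1e-4 && (hi - lo) < 1e-6) return(mid)
    if (cm > 0) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-12) return(mid)
  }
}

#' Pairwise and average sequence identity
#'
#' Equal-length sequences are scored positionally
#' (matches / length x 100). Unequal-length pairs are globally aligned
#' (match +1, mismatch 0, affine gaps) and identity is matches over
#' alignment length.
#'
#' @param a,b Amino-acid sequences (strings, [PeptideChain-class]s, or
#'   anything [chainSequence()] accepts).
#' @return Percentage identity.
#' @examples
#' percentIdentity("DWKNTAKEWGKKVGEALLDCAKQKM",
#'                 "DWTDTAKEWGRKVGGALLDCAKQKM")   # 84
#' @export
percentIdentity <- function(a, b) {
  a <- if (is(a, "PeptideChain")) chainSequence(a) else toupper(a)
  b <- if (is(b, "PeptideChain")) chainSequence(b) else toupper(b)
  stopifnot(nzchar(a), nzchar(b))
  if (nchar(a) == nchar(b)) {
    av <- strsplit(a, "")[[1L]]
    bv <- strsplit(b, "")[[1L]]
    return(100 * sum(av == bv) / length(av))
  }
  alpha <- Biostrings::AA_STANDARD
  m <- matrix(0, length(alpha), length(alpha),
              dimnames = list(alpha, alpha))
  diag(m) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = m, gapOpening = 5, gapExtension = 1,
    type = "global")
  alnLen <- nchar(as.character(Biostrings::alignedPattern(aln)))
  100 * Biostrings::nmatch(aln) / alnLen
}

#' @describeIn percentIdentity Mean of all pairwise identities of a set
#'   of sequences.
#' @param sequences Character vector (or list of chains) of length >= 2.
#' @export
averageIdentity <- function(sequences) {
  seqs <- vapply(sequences, function(s)
    if (is(s, "PeptideChain")) chainSequence(s) else toupper(s),
    character(1L))
  stopifnot(length(seqs) >= 2L)
  pairs <- utils::combn(length(seqs), 2L)
  mean(apply(pairs, 2L, function(p)
    percentIdentity(seqs[p[1L]], seqs[p[2L]])))
}

#' Physicochemical annotation table for a set of peptides
#'
#' Builds a venom-table-style summary: name, neutral mass, sequence,
#' assembly features, net charge, hydrophobic percentage and pI for
#' each chain or assembly supplied.
#'
#' @param peptides Named list of [PeptideChain-class] and/or
#'   [PeptideAssembly-class] objects.
#' @param rpm Optional named numeric of RPM values (matched by name).
#' @param massType,pH,chargePkaSet,piPkaSet Calculation parameters.
#' @return A `data.frame` with columns `name`, `mass`, `rpm`,
#'   `sequence`, `features`, `netCharge`, `hydrophobicPct`, `pI`.
#' @export
peptideProperties <- function(peptides, rpm = NULL,
                              massType = "monoisotopic", pH = 7,
                              chargePkaSet = "emboss",
                              piPkaSet = "bjellqvist") {
  stopifnot(is.list(peptides), length(peptides) >= 1L)
  nm <- .chainNames(peptides)
  rows <- lapply(seq_along(peptides), function(i) {
    p <- peptides[[i]]
    if (is(p, "PeptideChain")) {
      mass <- chainMass(p, massType)
      seqs <- paste0(chainSequence(p), if (isAmidated(p)) " *" else "")
      feat <- "Monomer"
    } else {
      mass <- assemblyMass(p, massType)
      seqs <- paste(vapply(assemblyChains(p), function(ch)
        paste0(chainSequence(ch), if (isAmidated(ch)) " *" else ""),
        character(1L)), collapse = " / ")
      kind <- if (isMonomer(p)) "Monomer"
        else if (chainSequence(p@chains[[1L]]) ==
                 chainSequence(p@chains[[2L]])) "Homodimer"
        else "Heterodimer"
      feat <- if (disulfideBonds(p) > 0L && kind != "Monomer")
        sprintf("%d S-S %s", disulfideBonds(p), kind) else kind
    }
    data.frame(
      name = nm[i], mass = round(mass, 2L),
      rpm = if (!is.null(rpm) && nm[i] %in% names(rpm))
        unname(rpm[[nm[i]]]) else NA_real_,
      sequence = seqs, features = feat,
      netCharge = round(netCharge(p, pH, chargePkaSet), 1L),
      hydrophobicPct = if (is(p, "PeptideChain")) hydrophobicFraction(p)
        else hydrophobicFraction(p@chains[[1L]]),
      pI = tryCatch(round(isoelectricPoint(p, piPkaSet), 2L),
                    error = function(e) NA_real_),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
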