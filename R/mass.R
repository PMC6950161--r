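#' Neutral mass of a peptide chain
#'
#' Sums residue masses plus one water, then applies the amidation delta
#' (if the chain is flagged amidated) and any site-localized modification
#' deltas. Cysteines are counted as free thiols; disulfide arithmetic
#' lives at the assembly level ([assemblyMass()]).
#'
#' Masses are kept unrounded internally; round only at presentation.
#'
#' @param chain A [PeptideChain-class] (or a bare sequence string, taken
#'   as an unmodified free acid).
#' @param massType `"monoisotopic"` (default) or `"average"`.
#' @return Neutral mass in Da.
#' @examples
#' chainMass(peptideChain("TLTNMSLREILEKLGIKIPPGLNI"))      # 2662.55
#' chainMass("G")                                           # 75.03202
#' @export
chainMass <- function(chain, massType = c("monoisotopic", "average")) {
  massType <- match.arg(massType)
  if (is.character(chain)) chain <- peptideChain(chain)
  stopifnot(is(chain, "PeptideChain"))
  validObject(chain)
  tab <- residueMasses(massType)
  aa <- strsplit(chain@sequence, "")[[1L]]
  m <- sum(tab[aa]) + .WATER[[massType]]
  if (chain@amidated) m <- m + .MOD_DELTAS[["c_terminal_amidation"]]
  mods <- chain@modifications
  if (!is.null(mods) && nrow(mods)) m <- m + sum(.MOD_DELTAS[mods$name])
  unname(m)
}

#' Neutral mass of a peptide assembly
#'
#' Under the `"chemical"` convention each disulfide bond removes two
#' hydrogens (2.0157 Da) from the summed chain masses; under the
#' `"additive"` convention bond counts are ignored and the chain masses
#' are simply summed. Published dimer masses mix both conventions, so the
#' convention travels with the assembly and can be overridden here.
#'
#' @param assembly A [PeptideAssembly-class].
#' @param massType `"monoisotopic"` or `"average"`.
#' @param convention Optional override of the assembly's own convention.
#' @return Neutral mass in Da.
#' @examples
#' ch <- peptideChain("DWKGGAKDCAKKGAQCVLECVQQKM", amidated = TRUE)
#' dim3 <- peptideAssembly(list(ch, ch), interchainBonds = 1,
#'                         intrachainBonds = 2)
#' assemblyMass(dim3)                         # 5438.59 (chemical)
#' assemblyMass(dim3, convention = "additive")
#' @export
assemblyMass <- function(assembly, massType = c("monoisotopic", "average"),
                         convention = NULL) {
  massType <- match.arg(massType)
  stopifnot(is(assembly, "PeptideAssembly"))
  validObject(assembly)
  conv <- if (is.null(convention)) assembly@convention
          else match.arg(convention, c("chemical", "additive"))
  m <- sum(vapply(assembly@chains, chainMass, numeric(1L),
                  massType = massType))
  if (conv == "chemical")
    m <- m + .MOD_DELTAS[["disulfide_per_bond"]] * disulfideBonds(assembly)
  unname(m)
}

#' Masses of the fully reduced constituent chains
#'
#' Returns the free-thiol (fully reduced) neutral mass of each chain of
#' an assembly: the masses expected to appear in an LC-MS run after DTT
#' reduction splits the interchain bonds. For a homodimer the two values
#' are equal; for a monomer the single value is its own [chainMass()].
#'
#' @inheritParams assemblyMass
#' @return Numeric vector, one mass per chain.
#' @export
reducedChainMasses <- function(assembly,
                               massType = c("monoisotopic", "average")) {
  massType <- match.arg(massType)
  stopifnot(is(assembly, "PeptideAssembly"))
  vapply(assembly@chains, chainMass, numeric(1L), massType = massType)
}

#' Mass of a reduced chain after iodoacetamide alkylation
#'
#' Adds one carbamidomethyl group (+57.0215 Da) per cysteine to the
#' free-thiol chain mass. The shift relative to the reduced chain counts
#' the chain's cysteines, which is how disulfide bonds are inferred from
#' reduction/alkylation experiments.
#'
#' @inheritParams chainMass
#' @return Neutral mass in Da.
#' @examples
#' ch <- peptideChain("DWKNTAKEWGKKVGEALLDCAKQKM", amidated = TRUE)
#' alkylatedMass(ch) - chainMass(ch)   # 57.02146, one cysteine
#' @export
alkylatedMass <- function(chain, massType = c("monoisotopic", "average")) {
  massType <- match.arg(massType)
  if (is.character(chain)) chain <- peptideChain(chain)
  chainMass(chain, massType) +
    .MOD_DELTAS[["carbamidomethyl_per_cys"]] * cysteineCount(chain)
}
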