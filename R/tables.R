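#' Amino acid residue mass tables
#'
#' Monoisotopic and average residue masses (Da) for the 20 standard amino
#' acids, as used by [chainMass()]. Residue masses are the mass of the
#' amino acid minus one water; a peptide's neutral mass is the sum of its
#' residue masses plus one water.
#'
#' Isoleucine and leucine are isobaric but kept as distinct codes; no
#' mass-based merging happens at this layer.
#'
#' @param massType `"monoisotopic"` or `"average"`.
#' @return Named numeric vector of residue masses in Da, one entry per
#'   one-letter code.
#' @examples
#' residueMasses()[["G"]]           # 57.02146
#' residueMasses("average")[["W"]]
#' @export
residueMasses <- function(massType = c("monoisotopic", "average")) {
  massType <- match.arg(massType)
  if (massType == "monoisotopic") .MONO_RESIDUES else .AVG_RESIDUES
}

.MONO_RESIDUES <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
  V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.AVG_RESIDUES <- c(
  G =  57.0519, A =  71.0788, S =  87.0782, P =  97.1167,
  V =  99.1326, T = 101.1051, C = 103.1388, L = 113.1594,
  I = 113.1594, N = 114.1038, D = 115.0886, Q = 128.1307,
  K = 128.1741, E = 129.1155, M = 131.1926, H = 137.1411,
  F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

.WATER <- c(monoisotopic = 18.010565, average = 18.01528)
.HYDROGEN <- 1.007825

#' Chemical and post-translational modification mass deltas
#'
#' Named neutral mass deltas (Da) applied on top of residue summation:
#' \describe{
#'   \item{c_terminal_amidation}{replacement of the C-terminal hydroxyl by
#'     an amine, -0.98402 Da.}
#'   \item{carbamidomethyl_per_cys}{iodoacetamide capping of a free thiol,
#'     +57.02146 Da per cysteine (the "57 Da" shift used to count
#'     cysteines after reduction/alkylation).}
#'   \item{met_oxidation}{+15.99491 Da.}
#'   \item{pyroglutamate_from_glu}{water loss on N-terminal Glu
#'     cyclization, -18.01056 Da.}
#'   \item{disulfide_per_bond}{loss of two hydrogens per cystine bridge,
#'     -2.01565 Da.}
#' }
#'
#' @return Named numeric vector of mass deltas in Da.
#' @examples
#' modificationDeltas()[["carbamidomethyl_per_cys"]]
#' @export
modificationDeltas <- function() .MOD_DELTAS

.MOD_DELTAS <- c(
  c_terminal_amidation     =  -0.984016,
  carbamidomethyl_per_cys  =  57.021464,
  met_oxidation            =  15.994915,
  pyroglutamate_from_glu   = -18.010565,
  disulfide_per_bond       =  -2.015650
)

# site-localized modifications that peptideChain() accepts, with the
# residue each one may sit on (NA = any)
.SITE_MODS <- c(
  carbamidomethyl_per_cys = "C",
  met_oxidation           = "M",
  pyroglutamate_from_glu  = "E"
)

#' Ionizable-group pKa sets
#'
#' Two named pKa tables for Henderson-Hasselbalch net-charge and
#' isoelectric-point calculations: an EMBOSS-style set and a
#' Bjellqvist-style set (the table behind ExPASy's compute pI tool).
#' Entries cover the N- and C-termini and the ionizable side chains
#' C, D, E, H, K, R, Y.
#'
#' @param name `"emboss"` or `"bjellqvist"`.
#' @return Named numeric vector of pKa values.
#' @examples
#' pkaSet("emboss")
#' @export
pkaSet <- function(name = c("emboss", "bjellqvist")) {
  name <- match.arg(name)
  .PKA_SETS[[name]]
}

.PKA_SETS <- list(
  emboss = c(
    Nterm = 8.6, Cterm = 3.6,
    C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1
  ),
  bjellqvist = c(
    Nterm = 7.5, Cterm = 3.55,
    C = 9.0, D = 4.05, E = 4.45, H = 5.98, K = 10.0, R = 12.0, Y = 10.0
  )
)

.STANDARD_AA <- names(.MONO_RESIDUES)

# Default hydrophobic residue set; reproduces all hydrophobic-percentage
# annotations used for venom peptide tables.
.HYDROPHOBIC_SET <- c("A", "C", "F", "I", "L", "M", "V", "W", "Y")
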