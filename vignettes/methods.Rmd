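---
title: "Methods: venom peptidome characterization and dimer inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: venom peptidome characterization and dimer inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptidomer)
```

# The problem

A venom peptidome is characterized by reconciling three independent
data streams: venom-gland transcriptome contigs (which encode peptide
precursors), de novo MS/MS sequence tags (short, high-confidence
fragments of the mature peptides), and LC–MS neutral-mass lists of the
venom in three chemical states — native, DTT-reduced, and
iodoacetamide-alkylated. None of the three alone identifies a peptide:
transcripts prove only that a precursor is expressed, tags are too
short to define termini, and a mass is anonymous. The package's job is
the arithmetic and the bookkeeping that tie them together, including
the special case that motivates most of the machinery: peptides that
circulate as disulfide-linked homo- or heterodimers.

# Mass model

A chain's neutral mass is the sum of its residue masses plus one water,
with modification deltas applied on top:

$$M(\text{chain}) = \sum_i m_{r_i} + m_{H_2O} + \delta_{\text{amid}} +
  \sum_k \delta_k$$

where $\delta_{\text{amid}} = -0.98402$ Da replaces the C-terminal
hydroxyl by an amine when the chain is amidated. Cysteines are always
counted as free thiols at the chain level; disulfide arithmetic lives
at the assembly level. Residue tables are standard monoisotopic and
average values; the test suite cross-checks the monoisotopic table
against an independently coded elemental-composition oracle to
$10^{-4}$ Da.

**Dimer conventions.** Chemically, forming a disulfide bond removes two
hydrogens, so a dimer's mass is
$M_1 + M_2 - 2.0157 \cdot n_{SS}$ ("chemical" convention). Published
dimer tables, however, are not always consistent: in the reference
venom table one homodimer and the heterodimer are printed as the plain
sum of the chain masses ("additive"), while the other two homodimers
follow the chemical convention. Rather than deciding which the authors
intended, every assembly carries a convention and `assemblyMass()` can
override it, so both values are always computable and the 2.0157 Da/bond
gap is reported instead of silently absorbed. The package default is
`chemical`, the physically correct choice.

**Reduction and alkylation.** Reduction splits interchain bonds: a true
dimer's native mass must disappear from the reduced list while both
free-chain masses appear. A monomer without intrachain bonds must
persist unchanged. Alkylation then caps each free thiol with a
carbamidomethyl group (+57.0215 Da), so the shift of each reduced chain
divided by 57.0215 and rounded must equal its sequence cysteine count.
Verification status moves only forward (`unverified` →
`reduction_consistent` → `fully_verified`) or terminates in
`contradicted`; an empty observation list never contradicts.

# Dimer hypothesis space

Chains with an odd number of cysteines cannot pair all thiols
intramolecularly; they are the dimer candidates. For $n$ candidates the
package enumerates $n$ homodimers and $n(n-1)/2$ heterodimers (plus,
optionally, the free monomers — a chain can be present in both forms,
as the reference venom's minor free subunit shows). Each hypothesis is
assigned the maximum pairable cysteine count,
$\lfloor (c_1 + c_2)/2 \rfloor$ bonds, with at least one bond
interchain; for a 3+3-cysteine homodimer this gives three bonds whose
interchain/intrachain split is genuinely unresolvable from masses
alone, and the hypothesis is flagged `topologyAmbiguous` rather than
given an invented topology.

# Tolerances

Matching tolerances are instrument properties, not free parameters:

| context | default | rationale |
|---|---|---|
| calculated vs calculated | 0.05 Da | printed-table precision (2 dp) |
| Orbitrap-grade observations | 0.02 Da | high-resolution survey |
| ion-trap-grade observations | 3.5 Da | observed native-vs-theoretical gaps reach ~3.2 Da |

All are overridable per call. Ties in matching are broken
deterministically: smallest absolute error, then lower theoretical
mass. The alkylation integer-shift check uses
`max(0.25, tolerance)` Da: 0.25 Da is ample at Orbitrap resolution, and
at ion-trap resolution a tighter bound than the matching tolerance
would contradict hypotheses on noise alone.

# Transcript mining

Translation covers all six frames under the standard genetic code with
no initiator-codon special-casing (mid-contig ORFs are the norm in
overextended assemblies), stops rendered as `*` and fuzzy codons as
`X`. ORF extraction is stop-to-stop with no start-codon requirement,
for the same reason; the length filter defaults to 100 residues for
whole-protein annotation but the pipeline uses 60 when mining short
peptide precursors.

Tag matching treats isoleucine and leucine as interchangeable by
default: they are isobaric and indistinguishable to de novo MS/MS. The
published workflow aligned tags with a short-sequence BLAST (PAM30);
here exact/I-L-tolerant substring matching replaces it, because
high-confidence tags are short enough that gapped alignment adds
nothing testable — a scored-mismatch mode (`maxMismatch`) is provided
for noisier tags. The ALC filter keeps tags at or above the threshold
(default 60%).

Precursor segmentation requires an explicit rule — an anchor (the
mature sequence, typically assembled from tags and mass matching), a
cut position, or a cleavage motif. Signal-peptide prediction is not
reimplemented: there is no testable description of it in this setting,
and an anchored cut is what the downstream arithmetic actually needs.
C-terminal amidation is flagged when the residue following the mature
span is glycine, the canonical amidation donor; this is a heuristic and
can be disabled.

The consensus operation emits, per column, the residue supported by
more than the majority threshold of non-gap rows, else `X`, dropping
gap-majority columns. The published consensus string cannot be
reproduced verbatim because the underlying full precursor sequences are
available only as a figure; the operation is therefore validated
synthetically (mutating a template at known columns must yield `X`
exactly there).

# Quantification

RPM is deliberately not length-normalized: assemblies of short venom
peptide transcripts are often overextended, so TPM-style length
correction would systematically underestimate exactly the transcripts
of interest. Counts are used as provided (whether the aligner counted
reads or read pairs is upstream of the package and documented as such).
RPM is invariant under splitting a precursor's reads across several
contigs, which the synthetic generator exercises explicitly. Relative
abundance normalizes integrated peak areas to 100%, with trace-level
peptides carrying `NA` and excluded from the normalization, mirroring
how trace peaks are handled in published tables.

# Physicochemical annotation

Net charge and pI are Henderson–Hasselbalch sums over the termini and
the D, E, C, Y, H, K, R side chains; the charge curve is strictly
decreasing in pH, so the pI is found by bisection to
$|z| < 10^{-4}$. Two pKa tables ship: an EMBOSS-style set (default for
`netCharge`) and a Bjellqvist-style set (default for
`isoelectricPoint`, the table behind the common web pI calculators).
The split default mirrors the reference study itself, which used
different web tools for the two columns; both functions accept either
set.

Reproduction of published columns is tolerance-based (±0.3 charge,
±0.4 pH) because web calculators neither state their pKa tables nor
handle modifications. Two conventions matter when reproducing them:

- The web calculators score the **bare sequence** — no amidation, and
  dimers pasted as a single concatenated sequence (one N-terminus, one
  C-terminus, all cysteines ionizable). Under that convention the
  published pI column is reproduced essentially exactly; the package's
  own chemistry-aware route (amidation suppressing the C-terminus,
  assemblies pooling both chains' groups) is the default for new data.
- Assembly charge defaults to the plain sum of the chain charges
  (`ionizeBondedCys = TRUE`), which makes a homodimer's charge exactly
  twice its monomer's — the arithmetic the published table uses. The
  chemically stricter alternative, removing two cysteines from the
  ionizable pool per disulfide bond, is available via
  `ionizeBondedCys = FALSE`; at pH 7 the difference is ~0.03 charge
  units per cysteine and does not move any value outside the
  tolerances above.
- One published net-charge value (+1.0 for the lone acidic peptide,
  pI ≈ 4) can only be a magnitude: no Henderson–Hasselbalch sum gives a
  positive charge at pH 7 for that sequence. The package reports the
  signed value (≈ −1.0).

The hydrophobic residue set \{A, C, F, I, L, M, V, W, Y\} reproduces
all six distinct published hydrophobicity percentages simultaneously.
Identity percentages are positional for equal-length pairs and
global-alignment-based (match +1, mismatch 0, affine gaps, identity =
matches / alignment length) otherwise.

# The synthetic-data generator

`generateTranscriptome()` emulates the statistical structure of a
venom-gland study: a conserved signal+prepro template mutated at
random columns (per-column rate 0.08, matching the ~50% family-level
prepro identity regime), variable cationic mature regions of 24–33
residues (the size range of the reference peptidome), a glycine
amidation donor on ~70% of peptides, precursors embedded mid-contig in
random UTRs on a random strand, one peptide encoded by two contigs (to
exercise RPM summation), one dominant species (venom peptidomes are
often dominated by a single linear peptide), and multinomial read
counts. The first three precursors carry 1, 3 and 1 cysteines; two
homodimers and one heterodimer are planted, leaving the remaining
odd-cysteine pairings as decoy hypotheses the data must not support.

`generateMassLists()` adds Gaussian noise (σ default 0.1 Da; ~0.02 is
Orbitrap-like, ~1.5 ion-trap-like) to the theoretical masses and builds
the three condition lists with the planted dimers disappearing on
reduction. Decoy native masses model unrelated co-eluting compounds:
they are sampled uniformly over the mass range but rejected within 2 Da
of any enumerable hypothesis mass — a decoy that coincided with a
peptide hypothesis would not be a decoy but an (unintended) planted
truth, so the rejection radius encodes the generator's ground-truth
semantics, not a tuning of the test.

What the generator does **not** emulate: isotope envelopes and charge
states (masses are already deproteinated neutrals), chromatographic
peak shape, assembly errors beyond overextension, sequencing errors in
tags, and incomplete reduction. Passing the synthetic round trip
therefore shows the logic is correct under the stated noise model, not
that the pipeline is robust to raw-instrument artifacts.

Test problem sizes are kept small by design — 4–6 precursors,
$10^4$–$2\times10^5$ reads, 20 seeds for the recovery properties —
which is enough to exercise every code path; the statistics of the
method do not change with scale because every operation is linear in
its inputs.

# Numerical and degenerate-input choices

- Masses are kept unrounded internally and rounded only at
  presentation (2 dp, the printed-table precision).
- Unknown residues are rejected naming the offending character and
  position; bond counts exceeding cysteine capacity, empty candidate
  lists, non-native observations in native matching, zero/negative
  tolerances, all-zero peak areas, unknown contigs in the RPM mapping,
  and absent anchors all fail loudly rather than guessing.
- A peptide whose charge curve has no zero in (0, 14) (e.g. an
  amidated chain with no acidic group) has no pI; `isoelectricPoint()`
  errors and the batch annotation table records `NA`.
- All report coordinates are 1-based inclusive, the R convention.

# Known limitations

- Disulfide connectivity (which cysteine pairs with which) is out of
  scope; only bond counts are inferred, and 3-bond homodimer topology
  is reported as ambiguous.
- Native observations that no hypothesis explains are reported as
  unexplained rather than force-assigned; in the reference venom three
  masses remain unexplained and may be peptides without transcript
  support or artifacts.
- Exact reproduction of web-calculator pI/charge values is impossible
  in principle (unstated pKa tables); agreement is tolerance-based.
- The amidation-donor heuristic (trailing glycine) can misfire on
  precursors whose mature peptide genuinely ends before a
  non-donor glycine; it is overridable per call.
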