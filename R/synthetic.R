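## Ground-truthed synthetic study generator.
##
## Emulates the input structure of a venom peptidome study: precursor
## transcripts with a conserved signal+prepro template and variable
## cationic mature regions, per-contig aligned-read counts, de novo
## sequence tags, and native/reduced/alkylated LC-MS mass lists with
## planted dimers and decoy masses.

.SIGNAL_TEMPLATE <- "MKLSYLVLGLAVLFVLAIVFAPAMA"
.PREPRO_TEMPLATE <- "QSVGMADAEADALAESLANALADALP"

# cationic-biased residue weights for mature regions (no C; cysteines
# are planted explicitly to control dimer candidacy)
.MATURE_WEIGHTS <- c(
  K = 3, R = 2, G = 2, A = 3, L = 3, I = 2, V = 2, E = 1.5, D = 1,
  W = 1, T = 1, Q = 1, N = 1, S = 1, M = 0.5, F = 1, P = 0.5
)

.CODONS <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  aa <- vapply(codons, function(cd)
    as.character(Biostrings::translate(Biostrings::DNAString(cd),
                                       no.init.codon = TRUE)),
    character(1L))
  split(codons, aa)
})

.randomSeq <- function(n, weights) {
  paste(sample(names(weights), n, replace = TRUE,
               prob = weights / sum(weights)), collapse = "")
}

.mutate <- function(seq, positions) {
  aa <- strsplit(seq, "")[[1L]]
  for (p in positions) {
    aa[p] <- sample(setdiff(.STANDARD_AA, aa[p]), 1L)
  }
  paste(aa, collapse = "")
}

.reverseTranslate <- function(protein) {
  aa <- strsplit(protein, "")[[1L]]
  paste(vapply(aa, function(a) sample(.CODONS[[a]], 1L), character(1L)),
        collapse = "")
}

#' Generate a synthetic venom-gland transcriptome with ground truth
#'
#' Builds `nPrecursors` peptide precursors sharing a mutated
#' signal+prepro template (conserved prepro, variable mature region, as
#' venom precursor families show), embeds their coding sequences in
#' contigs with random UTRs on a random strand, and draws per-contig
#' aligned-read counts multinomially from true expression frequencies.
#' One peptide is encoded by two contigs to exercise RPM summation, and
#' one peptide dominates expression. The first three precursors carry an
#' odd number of cysteines (1, 3, 1) and are the planted dimer subunits:
#' two homodimers and one heterodimer are planted; the remaining
#' odd-cysteine pairings are decoy hypotheses that the data must not
#' support.
#'
#' Same seed, same output: the generator is fully deterministic.
#'
#' @param nPrecursors Number of precursors (>= 4; default 6).
#' @param totalReads Total aligned reads to distribute (default 1e6).
#' @param seed Random seed.
#' @param mutationRate Per-column mutation probability applied to the
#'   signal+prepro template (default 0.08).
#' @param dir Optional directory; when given, writes `contigs.fasta`,
#'   `counts.tsv` and `manifest.json` there.
#' @return A list with `contigs` (named character vector of nucleotide
#'   sequences), `counts` (`data.frame` contig/count) and `manifest`
#'   (ground truth: precursor table, planted chains and assemblies,
#'   true RPMs, peptide-to-contig map, template and mutated columns).
#' @export
generateTranscriptome <- function(nPrecursors = 6L, totalReads = 1e6,
                                  seed = 1L, mutationRate = 0.08,
                                  dir = NULL) {
  stopifnot(nPrecursors >= 4L, totalReads >= 1L)
  set.seed(seed)
  template <- paste0(.SIGNAL_TEMPLATE, .PREPRO_TEMPLATE)
  sigLen <- nchar(.SIGNAL_TEMPLATE)
  tplLen <- nchar(template)
  # planted cysteine plan: precursors 1-3 are dimer subunits
  cysPlan <- c(1L, 3L, 1L, rep_len(c(0L, 2L, 0L), nPrecursors - 3L))
  names <- sprintf("pep%02d", seq_len(nPrecursors))

  prepro <- character(nPrecursors)
  mutatedCols <- vector("list", nPrecursors)
  mature <- character(nPrecursors)
  amidated <- logical(nPrecursors)
  for (i in seq_len(nPrecursors)) {
    cols <- which(stats::runif(tplLen) < mutationRate)
    cols <- setdiff(cols, 1L)              # keep the initiator Met
    mutatedCols[[i]] <- cols
    prepro[i] <- .mutate(template, cols)
    len <- sample(24:33, 1L)
    m <- .randomSeq(len, .MATURE_WEIGHTS)
    if (cysPlan[i] > 0L) {
      at <- sample(seq_len(len), cysPlan[i])
      aa <- strsplit(m, "")[[1L]]
      aa[at] <- "C"
      m <- paste(aa, collapse = "")
    }
    mature[i] <- m
    amidated[i] <- stats::runif(1L) < 0.7
  }

  # contigs: peptide 1 is split over two contigs; random strand/UTRs
  contigSeqs <- character(0L)
  pepToContig <- stats::setNames(vector("list", nPrecursors), names)
  for (i in seq_len(nPrecursors)) {
    orf <- paste0(prepro[i], mature[i], if (amidated[i]) "G" else "")
    nCopies <- if (i == 1L) 2L else 1L
    for (k in seq_len(nCopies)) {
      cds <- paste0(.reverseTranslate(orf), sample(c("TAA", "TGA", "TAG"), 1L))
      utr5 <- .randomSeq(sample(30:80, 1L),
                         c(A = 1, C = 1, G = 1, T = 1))
      utr3 <- .randomSeq(sample(30:80, 1L),
                         c(A = 1, C = 1, G = 1, T = 1))
      ctg <- paste0(utr5, cds, utr3)
      if (stats::runif(1L) < 0.5)
        ctg <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(ctg)))
      id <- sprintf("contig_%s_%d", names[i], k)
      contigSeqs[id] <- ctg
      pepToContig[[names[i]]] <- c(pepToContig[[names[i]]], id)
    }
  }

  # expression: gamma weights, peptide 4 dominant (the main linear toxin)
  w <- stats::rgamma(nPrecursors, shape = 1.2)
  w[4L] <- w[4L] + 8 * sum(w)
  perContig <- unlist(lapply(seq_len(nPrecursors), function(i) {
    ctgs <- pepToContig[[names[i]]]
    share <- if (length(ctgs) == 1L) 1 else as.vector(stats::rbeta(1L, 2, 2))
    stats::setNames(w[i] * (if (length(ctgs) == 1L) 1
                            else c(share, 1 - share)), ctgs)
  }))
  counts <- stats::rmultinom(1L, size = totalReads,
                             prob = perContig / sum(perContig))[, 1L]
  countsDf <- data.frame(contig = names(perContig),
                         count = as.integer(counts),
                         stringsAsFactors = FALSE)
  trueRpm <- vapply(names, function(p)
    sum(counts[pepToContig[[p]]]) / (totalReads / 1e6), numeric(1L))

  chains <- stats::setNames(lapply(seq_len(nPrecursors), function(i)
    peptideChain(mature[i], amidated = amidated[i])), names)
  planted <- list(
    homodimerA = peptideAssembly(list(chains[[1L]], chains[[1L]]),
                                 interchainBonds = 1L),
    homodimerB = peptideAssembly(list(chains[[2L]], chains[[2L]]),
                                 interchainBonds = 1L,
                                 intrachainBonds = 2L),
    heterodimerAC = peptideAssembly(list(chains[[1L]], chains[[3L]]),
                                    interchainBonds = 1L)
  )

  manifest <- list(
    seed = seed,
    totalReads = totalReads,
    template = template,
    signalLength = sigLen,
    mutatedColumns = mutatedCols,
    precursors = data.frame(
      name = names, prepro = prepro, mature = mature,
      amidated = amidated, nCys = cysPlan, stringsAsFactors = FALSE),
    chains = chains,
    plantedAssemblies = planted,
    dimerChainNames = names[1:3],
    trueRpm = trueRpm,
    peptideToContigs = pepToContig
  )

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(contigSeqs),
      file.path(dir, "contigs.fasta"), width = 60L)
    utils::write.table(countsDf, file.path(dir, "counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    json <- manifest
    json$chains <- lapply(manifest$chains, function(ch)
      list(sequence = chainSequence(ch), amidated = isAmidated(ch)))
    json$plantedAssemblies <- lapply(manifest$plantedAssemblies,
      function(a) list(
        chains = vapply(assemblyChains(a), chainSequence, character(1L)),
        interchainBonds = a@interchainBonds,
        intrachainBonds = a@intrachainBonds))
    jsonlite::write_json(json, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(contigs = contigSeqs, counts = countsDf, manifest = manifest)
}

#' Generate de novo sequence tags for a synthetic study
#'
#' Samples short substrings of each planted mature peptide with high ALC
#' scores, plus low-confidence junk tags (random sequences below the
#' usual 60% ALC filter), mirroring the output of de novo MS/MS
#' sequencing.
#'
#' @param manifest Manifest from [generateTranscriptome()].
#' @param perPeptide Confident tags per mature peptide (default 4).
#' @param nJunk Number of junk tags (default 10).
#' @param seed Random seed.
#' @return `data.frame` with columns `sequence` and `alc`.
#' @export
generateSequenceTags <- function(manifest, perPeptide = 4L, nJunk = 10L,
                                 seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(manifest$precursors))) {
    m <- manifest$precursors$mature[i]
    for (k in seq_len(perPeptide)) {
      len <- sample(7:12, 1L)
      start <- sample(seq_len(nchar(m) - len + 1L), 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = substr(m, start, start + len - 1L),
        alc = round(stats::runif(1L, 62, 99), 1L),
        stringsAsFactors = FALSE)
    }
  }
  for (k in seq_len(nJunk))
    rows[[length(rows) + 1L]] <- data.frame(
      sequence = .randomSeq(sample(7:12, 1L), .MATURE_WEIGHTS),
      alc = round(stats::runif(1L, 20, 59), 1L),
      stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Generate native / reduced / alkylated mass lists with planted truth
#'
#' The native list holds the monomer masses of the non-dimer chains,
#' the planted assembly masses (chemical convention) and `nDecoys`
#' decoy masses; the reduced list holds every free chain mass with the
#' interchain-linked dimer masses gone; the alkylated list shifts every
#' cysteine-bearing chain by +57.0215 Da per cysteine. Gaussian noise
#' of standard deviation `sigma` is added to every observed mass.
#' Peak areas are Dirichlet-distributed with one dominant species.
#' Decoy masses model unrelated co-eluting compounds: they are sampled
#' uniformly over the observed mass range but rejected within 2 Da of
#' any enumerable hypothesis mass, so they can never be explained by a
#' peptide hypothesis.
#'
#' @param manifest Manifest from [generateTranscriptome()].
#' @param sigma Mass noise standard deviation in Da (default 0.1;
#'   ~0.02 is Orbitrap-like, ~1.5 ion-trap-like).
#' @param seed Random seed.
#' @param nDecoys Decoy masses added to the native list (default 3).
#' @param dir Optional directory; writes `native.csv`, `reduced.csv`,
#'   `alkylated.csv`.
#' @return List of three `data.frame`s (`native`, `reduced`,
#'   `alkylated`) with columns `mass`, `retention_time`, `peak_area`,
#'   `condition`, `label`, plus `trueAbundance` (named percentages over
#'   the native species).
#' @export
generateMassLists <- function(manifest, sigma = 0.1, seed = 1L,
                              nDecoys = 3L, dir = NULL) {
  stopifnot(sigma >= 0)
  set.seed(seed + 1L)
  chains <- manifest$chains
  nm <- names(chains)
  dimerNames <- manifest$dimerChainNames
  planted <- manifest$plantedAssemblies

  # native species: free monomers of the non-dimer chains, the first
  # dimer subunit also free at low level, and the planted assemblies
  monomerNames <- c(setdiff(nm, dimerNames), dimerNames[1L])
  species <- c(
    stats::setNames(lapply(monomerNames, function(p)
      chainMass(chains[[p]])), monomerNames),
    stats::setNames(lapply(planted, assemblyMass), names(planted))
  )
  masses <- unlist(species)

  # peak areas: dominant species = the dominant transcript (pep04)
  a <- stats::rgamma(length(masses), shape = 0.8)
  dom <- which(names(masses) == nm[4L])
  a[dom] <- a[dom] + 6 * sum(a)
  trueAbundance <- 100 * a / sum(a)

  # decoys: rejection-sampled away from every enumerable hypothesis
  hypMasses <- unlist(lapply(c("chemical", "additive"), function(conv)
    enumerateAssemblies(chains[dimerNames], conventions = conv,
                        includeMonomers = TRUE)$mass))
  decoys <- numeric(0L)
  while (length(decoys) < nDecoys) {
    cand <- stats::runif(1L, min(masses) - 200, max(masses) + 200)
    if (all(abs(cand - c(hypMasses, masses)) > 2)) decoys <- c(decoys, cand)
  }

  noisy <- function(x) x + stats::rnorm(length(x), 0, sigma)
  native <- data.frame(
    mass = noisy(c(masses, decoys)),
    retention_time = round(sort(stats::runif(length(masses) + nDecoys,
                                             14, 51)), 2L),
    peak_area = c(round(1e5 * a), round(stats::rgamma(nDecoys, 0.5) * 1e4)),
    condition = "native",
    label = c(names(masses), sprintf("decoy%d", seq_len(nDecoys))),
    stringsAsFactors = FALSE)

  redMasses <- vapply(chains, chainMass, numeric(1L))
  reduced <- data.frame(
    mass = noisy(unname(redMasses)),
    retention_time = round(sort(stats::runif(length(redMasses), 14, 51)), 2L),
    peak_area = round(stats::rgamma(length(redMasses), 1) * 1e5),
    condition = "reduced", label = names(redMasses),
    stringsAsFactors = FALSE)

  alkMasses <- vapply(chains, alkylatedMass, numeric(1L))
  alkylated <- data.frame(
    mass = noisy(unname(alkMasses)),
    retention_time = round(sort(stats::runif(length(alkMasses), 14, 51)), 2L),
    peak_area = round(stats::rgamma(length(alkMasses), 1) * 1e5),
    condition = "alkylated", label = names(alkMasses),
    stringsAsFactors = FALSE)

  out <- list(native = native, reduced = reduced, alkylated = alkylated,
              trueAbundance = stats::setNames(trueAbundance, names(masses)))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (cond in c("native", "reduced", "alkylated"))
      utils::write.csv(out[[cond]], file.path(dir, paste0(cond, ".csv")),
                       row.names = FALSE, quote = FALSE)
  }
  out
}
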