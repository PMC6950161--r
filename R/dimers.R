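#' Select chains that cannot fully pair their cysteines alone
#'
#' Chains bearing an odd number of cysteines cannot close all their
#' thiols intramolecularly and are therefore candidates for interchain
#' disulfide bonding (dimerization). Input order is preserved.
#'
#' @param chains A list of [PeptideChain-class] objects (optionally
#'   named).
#' @return The subset of `chains` with an odd cysteine count.
#' @export
selectDimerCandidates <- function(chains) {
  if (is(chains, "PeptideChain")) chains <- list(chains)
  stopifnot(is.list(chains))
  odd <- vapply(chains, function(ch) cysteineCount(ch) %% 2L == 1L,
                logical(1L))
  chains[odd]
}

.chainNames <- function(chains) {
  nm <- names(chains)
  if (is.null(nm)) nm <- rep("", length(chains))
  blank <- !nzchar(nm)
  nm[blank] <- paste0("chain", seq_along(chains))[blank]
  nm
}

# total bonds = all pairable cysteines across the two chains, with at
# least one bond interchain; topology beyond that is unresolved.
.dimerBonds <- function(cysA, cysB) {
  total <- (cysA + cysB) %/% 2L
  list(inter = if (total >= 1L) 1L else 0L,
       intra = max(total - 1L, 0L),
       ambiguous = total > 1L)
}

#' Enumerate monomer/homodimer/heterodimer mass hypotheses
#'
#' For `n` candidate chains emits `n` homodimers and `n(n-1)/2`
#' heterodimers per requested convention (plus, optionally, the `n` free
#' monomers, since a chain can be present both free and dimerized). Each
#' hypothesis is assigned the maximum number of pairable cysteines as
#' its disulfide-bond count, with at least one bond interchain; when
#' more than one bond is possible the interchain/intrachain split is
#' flagged as topologically ambiguous.
#'
#' @param candidates List of [PeptideChain-class] objects, typically
#'   from [selectDimerCandidates()]. Names are used as chain labels.
#' @param conventions Character vector drawn from
#'   `c("chemical", "additive")`; one set of hypotheses is emitted per
#'   convention.
#' @param includeMonomers Also emit each chain as a free monomer
#'   hypothesis (default `FALSE`).
#' @param massType Passed to [assemblyMass()].
#' @return A `data.frame` with one row per hypothesis: `id`, `kind`,
#'   `chainA`, `chainB`, `interchainBonds`, `intrachainBonds`, `bonds`,
#'   `topologyAmbiguous`, `convention`, `mass`, and a list column
#'   `assembly` holding the [PeptideAssembly-class] objects.
#' @examples
#' a <- peptideChain("DWKNTAKEWGKKVGEALLDCAKQKM", amidated = TRUE)
#' c <- peptideChain("DWTDTAKEWGRKVGGALLDCAKQKM", amidated = TRUE)
#' enumerateAssemblies(list(Ta1a = a, Ta1c = c))
#' @export
enumerateAssemblies <- function(candidates,
                                conventions = "chemical",
                                includeMonomers = FALSE,
                                massType = "monoisotopic") {
  if (is(candidates, "PeptideChain")) candidates <- list(candidates)
  if (!length(candidates))
    stop("no candidate chains to enumerate")
  conventions <- match.arg(conventions, c("chemical", "additive"),
                           several.ok = TRUE)
  nm <- .chainNames(candidates)
  names(candidates) <- nm
  cys <- vapply(candidates, cysteineCount, integer(1L))
  rows <- list()
  for (conv in conventions) {
    if (includeMonomers) {
      for (i in seq_along(candidates)) {
        asm <- peptideAssembly(candidates[[i]],
                               intrachainBonds = cys[i] %/% 2L,
                               convention = conv)
        rows[[length(rows) + 1L]] <- list(
          id = sprintf("%s|monomer|%s", nm[i], conv),
          kind = "monomer", chainA = nm[i], chainB = NA_character_,
          interchainBonds = 0L, intrachainBonds = cys[[i]] %/% 2L,
          topologyAmbiguous = FALSE, convention = conv,
          mass = assemblyMass(asm, massType), assembly = asm)
      }
    }
    pairs <- cbind(seq_along(candidates), seq_along(candidates))
    if (length(candidates) > 1L)
      pairs <- rbind(pairs, t(utils::combn(seq_along(candidates), 2L)))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      b <- .dimerBonds(cys[[i]], cys[[j]])
      asm <- peptideAssembly(list(candidates[[i]], candidates[[j]]),
                             interchainBonds = b$inter,
                             intrachainBonds = b$intra,
                             convention = conv)
      rows[[length(rows) + 1L]] <- list(
        id = sprintf("%s+%s|%s", nm[i], nm[j], conv),
        kind = if (i == j) "homodimer" else "heterodimer",
        chainA = nm[i], chainB = nm[j],
        interchainBonds = b$inter, intrachainBonds = b$intra,
        topologyAmbiguous = b$ambiguous, convention = conv,
        mass = assemblyMass(asm, massType), assembly = asm)
    }
  }
  out <- data.frame(
    id = vapply(rows, `[[`, character(1L), "id"),
    kind = vapply(rows, `[[`, character(1L), "kind"),
    chainA = vapply(rows, `[[`, character(1L), "chainA"),
    chainB = vapply(rows, `[[`, character(1L), "chainB"),
    interchainBonds = vapply(rows, `[[`, integer(1L), "interchainBonds"),
    intrachainBonds = vapply(rows, `[[`, integer(1L), "intrachainBonds"),
    topologyAmbiguous = vapply(rows, `[[`, logical(1L), "topologyAmbiguous"),
    convention = vapply(rows, `[[`, character(1L), "convention"),
    mass = vapply(rows, `[[`, numeric(1L), "mass"),
    stringsAsFactors = FALSE)
  out$bonds <- out$interchainBonds + out$intrachainBonds
  out$assembly <- lapply(rows, `[[`, "assembly")
  out
}

# normalize a mass-observation input (numeric vector or data.frame) and
# check its experimental condition
.observationFrame <- function(x, condition) {
  if (is.numeric(x)) {
    x <- data.frame(mass = as.numeric(x),
                    condition = rep(condition, length(x)),
                    label = sprintf("obs_%g", round(as.numeric(x), 2)),
                    stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x), "mass" %in% names(x))
  if (!"condition" %in% names(x)) x$condition <- condition
  if (!"label" %in% names(x)) x$label <- sprintf("obs_%g", round(x$mass, 2))
  if (any(x$condition != condition))
    stop(sprintf("expected only '%s' observations, found '%s'",
                 condition, setdiff(unique(x$condition), condition)[1L]))
  if (any(!is.finite(x$mass) | x$mass <= 0))
    stop("observation masses must be positive")
  x
}

#' Match mass hypotheses to native LC-MS observations
#'
#' A hypothesis matches an observation when the absolute difference
#' between theoretical and observed mass is at most `tolerance`. Every
#' native observation appears exactly once in the result: assigned to
#' its best-matching hypothesis (smallest absolute error, ties broken by
#' lower theoretical mass) or listed as unexplained. All within-tolerance
#' pairs are additionally reported in `matches`.
#'
#' @param hypotheses A `data.frame` from [enumerateAssemblies()] (needs
#'   columns `id` and `mass`).
#' @param observations Native-condition observations: a numeric vector
#'   of masses or a `data.frame` with columns `mass`, `condition` and
#'   optionally `label`, `retention_time`, `peak_area`.
#' @param tolerance Matching tolerance in Da. Defaults to 3.5 Da,
#'   appropriate for ion-trap survey data; use ~0.02 Da for
#'   Orbitrap-grade observations.
#' @return An object of class `MatchReport`: a list with elements
#'   `assignments` (one row per observation), `matches` (all pairs
#'   within tolerance, with signed error, observed minus theoretical,
#'   in Da and ppm), `unexplained`
#'   (observations no hypothesis reaches) and `unmatchedHypotheses`.
#' @export
matchMasses <- function(hypotheses, observations, tolerance = 3.5) {
  stopifnot(is.data.frame(hypotheses),
            all(c("id", "mass") %in% names(hypotheses)))
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance <= 0)
    stop("'tolerance' must be a single positive number")
  obs <- .observationFrame(observations, "native")
  pairs <- list()
  assign <- data.frame(label = obs$label, observed = obs$mass,
                       hypothesis = NA_character_,
                       theoretical = NA_real_, error = NA_real_,
                       ppm = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(obs))) {
    err <- obs$mass[k] - hypotheses$mass
    hit <- which(abs(err) <= tolerance)
    if (!length(hit)) next
    for (h in hit)
      pairs[[length(pairs) + 1L]] <- data.frame(
        label = obs$label[k], observed = obs$mass[k],
        hypothesis = hypotheses$id[h], theoretical = hypotheses$mass[h],
        error = err[h], ppm = 1e6 * err[h] / obs$mass[k],
        stringsAsFactors = FALSE)
    best <- hit[order(abs(err[hit]), hypotheses$mass[hit])][1L]
    assign$hypothesis[k] <- hypotheses$id[best]
    assign$theoretical[k] <- hypotheses$mass[best]
    assign$error[k] <- err[best]
    assign$ppm[k] <- 1e6 * err[best] / obs$mass[k]
  }
  matches <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(label = character(), observed = numeric(),
               hypothesis = character(), theoretical = numeric(),
               error = numeric(), ppm = numeric())
  structure(list(
    assignments = assign,
    matches = matches,
    unexplained = assign[is.na(assign$hypothesis),
                         c("label", "observed")],
    unmatchedHypotheses = setdiff(hypotheses$id, matches$hypothesis),
    tolerance = tolerance
  ), class = "MatchReport")
}

#' @export
print.MatchReport <- function(x, ...) {
  cat(sprintf("MatchReport: %d observation(s), tolerance %.3g Da\n",
              nrow(x$assignments), x$tolerance))
  cat(sprintf("  matched: %d, unexplained: %d, unmatched hypotheses: %d\n",
              sum(!is.na(x$assignments$hypothesis)),
              nrow(x$unexplained), length(x$unmatchedHypotheses)))
  invisible(x)
}

.massMatched <- function(target, masses, tolerance)
  any(abs(masses - target) <= tolerance)

#' Verify a matched hypothesis against the reduced mass list
#'
#' After DTT reduction, an interchain-linked dimer must split: each
#' constituent free-thiol chain mass must appear in the reduced list and
#' the native (dimer) mass must disappear. A monomer without intrachain
#' bonds must instead persist unchanged. A native mass that persists for
#' a dimer hypothesis contradicts it; an empty reduced list leaves the
#' hypothesis unverified.
#'
#' @param assembly A [PeptideAssembly-class] (the matched hypothesis).
#' @param reduced Reduced-condition observations (numeric vector or
#'   `data.frame` as in [matchMasses()]).
#' @param tolerance Matching tolerance in Da.
#' @param nativeMass The observed/theoretical native mass of the
#'   hypothesis; defaults to [assemblyMass()] of `assembly`.
#' @param massType Passed to the mass calculations.
#' @return One of `"unverified"`, `"reduction_consistent"`,
#'   `"contradicted"`.
#' @export
verifyByReduction <- function(assembly, reduced, tolerance = 3.5,
                              nativeMass = NULL,
                              massType = "monoisotopic") {
  stopifnot(is(assembly, "PeptideAssembly"))
  obs <- .observationFrame(reduced, "reduced")
  if (!nrow(obs)) return("unverified")
  if (is.null(nativeMass)) nativeMass <- assemblyMass(assembly, massType)
  nativePersists <- .massMatched(nativeMass, obs$mass, tolerance)
  if (isMonomer(assembly) && disulfideBonds(assembly) == 0L)
    return(if (nativePersists) "reduction_consistent" else "contradicted")
  if (nativePersists) return("contradicted")
  chainsSeen <- vapply(reducedChainMasses(assembly, massType),
                       .massMatched, logical(1L),
                       masses = obs$mass, tolerance = tolerance)
  if (all(chainsSeen)) "reduction_consistent" else "unverified"
}

#' Verify a reduction-consistent hypothesis against the alkylated list
#'
#' Each reduced chain must reappear shifted by one carbamidomethyl group
#' (+57.0215 Da) per cysteine. The observed shift, divided by 57.0215
#' and rounded, must equal the chain's cysteine count; a shift that is
#' not consistent with an integer number of carbamidomethyl groups, or
#' that implies the wrong cysteine count, contradicts the hypothesis.
#'
#' @param assembly A [PeptideAssembly-class] whose status is
#'   `reduction_consistent`.
#' @param alkylated Alkylated-condition observations.
#' @param tolerance Matching tolerance in Da.
#' @param shiftTolerance How far the observed shift may sit from an
#'   integer multiple of 57.0215 Da; never below 0.25 Da, raised to
#'   `tolerance` for low-resolution data.
#' @param massType Passed to the mass calculations.
#' @return One of `"fully_verified"`, `"reduction_consistent"` (cannot
#'   confirm), `"contradicted"`.
#' @export
verifyByAlkylation <- function(assembly, alkylated, tolerance = 3.5,
                               shiftTolerance = max(0.25, tolerance),
                               massType = "monoisotopic") {
  stopifnot(is(assembly, "PeptideAssembly"))
  obs <- .observationFrame(alkylated, "alkylated")
  if (!nrow(obs)) return("reduction_consistent")
  cam <- .MOD_DELTAS[["carbamidomethyl_per_cys"]]
  status <- "fully_verified"
  for (ch in assemblyChains(assembly)) {
    m0 <- chainMass(ch, massType)
    nCys <- cysteineCount(ch)
    expect <- m0 + cam * nCys
    if (.massMatched(expect, obs$mass, tolerance)) next
    # no observation at the expected mass: look for the chain at some
    # other shift inside the plausible alkylation window
    window <- obs$mass >= m0 - tolerance &
              obs$mass <= m0 + cam * (nCys + 1L) + tolerance
    if (!any(window)) { status <- "reduction_consistent"; next }
    cand <- obs$mass[window]
    shift <- cand[which.min(abs(cand - expect))] - m0
    k <- round(shift / cam)
    if (abs(shift - k * cam) > shiftTolerance || k != nCys)
      return("contradicted")
    status <- "reduction_consistent"
  }
  status
}

#' Full dimer scan: enumerate, match, verify
#'
#' Runs the complete dimer-inference workflow: select odd-cysteine
#' candidate chains, enumerate monomer/homodimer/heterodimer hypotheses,
#' match them to the native mass list, then push every matched
#' hypothesis through reduction and alkylation verification.
#' Verification status only moves forward
#' (`unverified` -> `reduction_consistent` -> `fully_verified`), or to
#' `contradicted`.
#'
#' @param chains List of [PeptideChain-class] objects (all chains; the
#'   odd-cysteine filter is applied internally unless
#'   `filterCandidates = FALSE`).
#' @param native,reduced,alkylated Mass observations for each
#'   experimental condition (numeric vector or `data.frame`); `reduced`
#'   and `alkylated` may be `NULL`.
#' @param tolerance Matching tolerance in Da (default 3.5, ion-trap
#'   grade).
#' @param conventions,includeMonomers,massType Passed to
#'   [enumerateAssemblies()].
#' @param filterCandidates Apply [selectDimerCandidates()] first?
#' @return A list with `hypotheses` (the enumeration table plus a
#'   `status` column and per-hypothesis match info) and `report` (the
#'   [matchMasses()] `MatchReport`).
#' @export
dimerScan <- function(chains, native, reduced = NULL, alkylated = NULL,
                      tolerance = 3.5, conventions = "chemical",
                      includeMonomers = TRUE, massType = "monoisotopic",
                      filterCandidates = TRUE) {
  if (filterCandidates) chains <- selectDimerCandidates(chains)
  hyp <- enumerateAssemblies(chains, conventions = conventions,
                             includeMonomers = includeMonomers,
                             massType = massType)
  report <- matchMasses(hyp, native, tolerance)
  hyp$matchedObservation <- NA_character_
  hyp$observedMass <- NA_real_
  hyp$status <- "unverified"
  a <- report$assignments
  for (i in seq_len(nrow(hyp))) {
    k <- which(a$hypothesis == hyp$id[i])
    if (!length(k)) next
    k <- k[which.min(abs(a$error[k]))]
    hyp$matchedObservation[i] <- a$label[k]
    hyp$observedMass[i] <- a$observed[k]
    st <- "unverified"
    if (!is.null(reduced)) {
      st <- verifyByReduction(hyp$assembly[[i]], reduced, tolerance,
                              massType = massType)
      if (st == "reduction_consistent" && !is.null(alkylated))
        st <- verifyByAlkylation(hyp$assembly[[i]], alkylated, tolerance,
                                 massType = massType)
    }
    hyp$status[i] <- st
  }
  list(hypotheses = hyp, report = report)
}
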