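#' Reads-per-million transcript quantification
#'
#' RPM of a peptide is the sum, over all contigs encoding its precursor,
#' of that contig's aligned-read count divided by the total number of
#' aligned reads in millions. There is deliberately no length
#' normalization (this is RPM, not TPM): assemblies of short peptide
#' transcripts are often overextended, and length normalization would
#' underestimate their expression.
#'
#' @param contigCounts Named numeric vector of aligned-read counts per
#'   contig, or a `data.frame` with columns `contig` and `count`.
#' @param totalAlignedReads Total aligned reads for the sample (> 0).
#' @param peptideToContigs Named list mapping each peptide identifier to
#'   the contig identifier(s) encoding it.
#' @return Named numeric vector of RPM values, one per peptide.
#' @examples
#' readsPerMillion(c(c1 = 300, c2 = 200), 1e6,
#'                 list(pep = c("c1", "c2")))   # 500
#' @export
readsPerMillion <- function(contigCounts, totalAlignedReads,
                            peptideToContigs) {
  if (is.data.frame(contigCounts)) {
    stopifnot(all(c("contig", "count") %in% names(contigCounts)))
    contigCounts <- stats::setNames(contigCounts$count,
                                    contigCounts$contig)
  }
  stopifnot(is.numeric(contigCounts), !is.null(names(contigCounts)),
            is.list(peptideToContigs))
  if (!is.numeric(totalAlignedReads) || totalAlignedReads <= 0)
    stop("'totalAlignedReads' must be positive")
  if (any(contigCounts < 0)) stop("read counts must be non-negative")
  vapply(peptideToContigs, function(ctgs) {
    unknown <- setdiff(ctgs, names(contigCounts))
    if (length(unknown))
      stop(sprintf("mapping references unknown contig '%s'", unknown[1L]))
    sum(contigCounts[ctgs]) / (totalAlignedReads / 1e6)
  }, numeric(1L))
}

#' Relative peak-area abundance
#'
#' Each peptide's contribution to the summed integrated peak areas,
#' expressed as a percentage. Peptides flagged as trace-level carry an
#' `NA` abundance and are excluded from the normalization, so the
#' remaining abundances still sum to 100.
#'
#' @param peakAreas Named numeric vector of integrated peak areas
#'   (>= 0), or a `data.frame` with columns `peptide` and `area`.
#' @param trace Character vector of peptide names observed only at
#'   trace levels.
#' @return Named numeric vector of percentages (NA for trace peptides).
#' @examples
#' relativeAbundance(c(a = 2, b = 1, c = 1))
#' @export
relativeAbundance <- function(peakAreas, trace = character()) {
  if (is.data.frame(peakAreas)) {
    stopifnot(all(c("peptide", "area") %in% names(peakAreas)))
    peakAreas <- stats::setNames(peakAreas$area, peakAreas$peptide)
  }
  stopifnot(is.numeric(peakAreas))
  if (any(peakAreas < 0, na.rm = TRUE))
    stop("peak areas must be non-negative")
  quant <- !(names(peakAreas) %in% trace)
  total <- sum(peakAreas[quant])
  if (!is.finite(total) || total <= 0)
    stop("at least one non-trace peak area must be positive")
  out <- rep(NA_real_, length(peakAreas))
  names(out) <- names(peakAreas)
  out[quant] <- 100 * peakAreas[quant] / total
  out
}
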