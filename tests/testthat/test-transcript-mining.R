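randomContig <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("six-frame translation follows the standard code", {
  fr <- sixFrameTranslate("ATGGCT")
  expect_equal(fr[["F1"]], "MA")
  expect_named(fr, c("F1", "F2", "F3", "R1", "R2", "R3"))
  # trailing partial codons dropped
  expect_equal(sixFrameTranslate("ATGGCTA")[["F1"]], "MA")
  # N codons translate to the unknown sentinel
  expect_equal(sixFrameTranslate("ATGNNN")[["F1"]], "MX")
  expect_error(sixFrameTranslate("ATGQ"), "non-IUPAC")
})

test_that("reverse frames equal forward frames of the reverse complement", {
  set.seed(31)
  for (i in 1:10) {
    ctg <- randomContig(sample(30:120, 1))
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(ctg)))
    fr <- sixFrameTranslate(ctg)
    frc <- sixFrameTranslate(rc)
    expect_equal(unname(fr[c("R1", "R2", "R3")]),
                 unname(frc[c("F1", "F2", "F3")]))
  }
})

test_that("ORF extraction is stop-to-stop with a length filter", {
  fr <- c(F1 = "MAGLKWATRR")     # no stop: whole frame is one ORF
  expect_equal(extractOrfs(fr, 1)$orf, "MAGLKWATRR")
  fr2 <- c(F1 = paste0(strrep("A", 99), "*", strrep("K", 100)))
  got <- extractOrfs(fr2, 100)
  expect_equal(nrow(got), 1)                       # 99-mer excluded
  expect_equal(got$start, 101)
  expect_equal(got$end, 200)
  # minLength 1: one ORF per stop-delimited segment
  expect_equal(nrow(extractOrfs(c(F1 = "AAA*GG*CCCC"), 1)), 3)
})

test_that("a planted precursor CDS appears in exactly one frame", {
  set.seed(17)
  for (i in 1:5) {
    sim <- generateTranscriptome(nPrecursors = 4, totalReads = 1e4,
                                 seed = i)
    pre <- sim$manifest$precursors[2, ]             # single-contig peptide
    ctg <- sim$contigs[[sim$manifest$peptideToContigs[[pre$name]]]]
    frames <- sixFrameTranslate(ctg)
    hits <- sum(vapply(frames, function(f)
      grepl(pre$mature, f, fixed = TRUE), logical(1)))
    expect_equal(hits, 1)
  }
})

test_that("tag matching filters on ALC and respects I/L equivalence", {
  orf <- "XTLTNMSLREILEKLGIKIPPGLNIX"
  hits <- matchTags(data.frame(sequence = "GIKIPPGLN", alc = 90), orf)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$offset, 16)
  # I/L toggled tag matches only under equivalence
  expect_equal(nrow(matchTags(data.frame(sequence = "GLKLPPGLN", alc = 90),
                              orf, ilEquivalent = TRUE)), 1)
  expect_equal(nrow(matchTags(data.frame(sequence = "GLKLPPGLN", alc = 90),
                              orf, ilEquivalent = FALSE)), 0)
  # below-threshold tag discarded
  expect_equal(nrow(matchTags(data.frame(sequence = "GIKIPPGLN", alc = 59),
                              orf, alcThreshold = 60)), 0)
  expect_error(matchTags(data.frame(sequence = "AAA", alc = 150), orf),
               "ALC")
})

test_that("strict matches are a subset of I/L-equivalent matches", {
  set.seed(23)
  for (i in 1:10) {
    orf <- randomPeptide(60)
    tags <- data.frame(
      sequence = vapply(1:8, function(k) randomPeptide(4), ""),
      alc = 90)
    strict <- matchTags(tags, orf, ilEquivalent = FALSE)
    loose <- matchTags(tags, orf, ilEquivalent = TRUE)
    strictKeys <- paste(strict$tag, strict$orf, strict$offset)
    looseKeys <- paste(loose$tag, loose$orf, loose$offset)
    expect_true(all(strictKeys %in% looseKeys))
  }
})

test_that("one mismatch is tolerated only in scored-mismatch mode", {
  orf <- "MAGLKWATRR"
  tags <- data.frame(sequence = "GLKWATRK", alc = 95)  # last residue off
  expect_equal(nrow(matchTags(tags, orf)), 0)
  expect_equal(nrow(matchTags(tags, orf, maxMismatch = 1)), 1)
})

test_that("anchored segmentation recovers the mature span and amidation", {
  mature <- "DWKNTAKEWGKKVGEALLDCAKQKM"
  orf <- paste0("MKLSYLVLGLAEADALAESLP", mature, "G")
  pm <- segmentPrecursor(orf, matureAnchor = mature, signalLength = 11)
  expect_equal(matureRegion(pm), mature)
  expect_true(isAmidated(maturePeptide(pm)))
  expect_equal(signalRegion(pm), "MKLSYLVLGLA")
  expect_equal(preproRegion(pm), "EADALAESLP")
  # no glycine donor: free acid
  orf2 <- paste0("MKLSYLVLGLAEADALAESLP", mature)
  expect_false(isAmidated(maturePeptide(
    segmentPrecursor(orf2, matureAnchor = mature))))
  expect_error(segmentPrecursor(orf, matureAnchor = "WWWWWW"), "anchor")
  expect_error(segmentPrecursor(orf, cutPosition = 0), "prepro")
  # motif rule cuts right after the match
  pm3 <- segmentPrecursor(orf, motif = "AESLP")
  expect_equal(matureRegion(pm3), paste0(mature, "G"))
})

test_that("consensus emits majority residues and X at variable columns", {
  expect_equal(consensusSequence(c("MKLS", "MKLS", "MKLS")), "MKLS")
  expect_equal(consensusSequence(c("AB", "AB", "GB"),
                                 majorityThreshold = 0.6), "AB")
  expect_equal(consensusSequence(c("AB", "AB", "GB"),
                                 majorityThreshold = 0.7), "XB")
  expect_error(consensusSequence(c("AB", "ABC")), "length")
  # gap-majority columns are dropped
  expect_equal(consensusSequence(c("A-K", "A-K", "AGK")), "AK")
})

test_that("mutating a template at known columns yields X exactly there", {
  set.seed(41)
  template <- randomPeptide(40)
  cols <- sort(sample(40, 6))
  rows <- vapply(1:6, function(r) {
    aa <- strsplit(template, "")[[1]]
    # give every row a distinct residue at each planted column so no
    # residue reaches a majority there
    aa[cols] <- vapply(aa[cols], function(orig)
      setdiff(names(residueMasses()), orig)[r], "")
    paste(aa, collapse = "")
  }, "")
  cons <- consensusSequence(rows)
  got <- which(strsplit(cons, "")[[1]] == "X")
  expect_equal(got, cols)
})

test_that("planted mature peptides are recovered by tags plus segmentation", {
  for (seed in 1:20) {
    sim <- generateTranscriptome(nPrecursors = 4, totalReads = 1e4,
                                 seed = seed)
    tags <- generateSequenceTags(sim$manifest, seed = seed)
    man <- sim$manifest$precursors
    # pool ORFs from all contigs
    orfs <- do.call(rbind, Filter(nrow, lapply(names(sim$contigs),
      function(ctg) {
        o <- extractOrfs(sixFrameTranslate(sim$contigs[[ctg]]), 40)
        if (nrow(o)) o$contig <- ctg
        o
      })))
    hits <- matchTags(tags, orfs, alcThreshold = 60)
    supported <- unique(hits$orf)
    for (i in seq_len(nrow(man))) {
      inOrf <- supported[vapply(supported, function(j)
        grepl(man$mature[i], orfs$orf[j], fixed = TRUE), logical(1))]
      expect_gte(length(inOrf), 1)
      pm <- segmentPrecursor(orfs$orf[inOrf[1]],
                             matureAnchor = man$mature[i])
      expect_equal(matureRegion(pm), man$mature[i])
      expect_equal(isAmidated(maturePeptide(pm)), man$amidated[i])
    }
  }
})
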