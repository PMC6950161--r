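# Reference pseudomyrmecitoxin chains (published venom peptide table)
# and an independent mass oracle built from elemental compositions.

toxinSequences <- function() {
  list(
    U1  = list(seq = "TLTNMSLREILEKLGIKIPPGLNI", amidated = FALSE),
    U2a = list(seq = "DWKNTAKEWGKKVGEALLDCAKQKM", amidated = TRUE),
    U2b = list(seq = "DWKGGAKDCAKKGAQCVLECVQQKM", amidated = TRUE),
    U2c = list(seq = "DWTDTAKEWGRKVGGALLDCAKQKM", amidated = TRUE),
    U3  = list(seq = "KKKRKWVTKAIKEVGKTIGEALVEEAVSAALSAATEGGEKEE",
               amidated = FALSE),
    U4  = list(seq = "GILGVIARWIWKLIQILAPTAAVEVATRLGLPQ", amidated = FALSE),
    U5  = list(seq = "FWGLILQGIWAVVKWAGPIIVDIAADYVIEYV", amidated = TRUE)
  )
}

toxinChains <- function() {
  lapply(toxinSequences(), function(x)
    peptideChain(x$seq, amidated = x$amidated))
}

# Independent residue-summation oracle: residue masses derived from
# elemental compositions and isotope masses, a different source than
# the package's residue table.
oracleChainMass <- function(sequence, amidated = FALSE) {
  iso <- c(H = 1.0078250319, C = 12, N = 14.0030740052,
           O = 15.9949146221, S = 31.97207069)
  # residue formulas as c(C, H, N, O, S)
  f <- list(
    G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0)
  )
  aa <- strsplit(sequence, "")[[1]]
  comp <- Reduce(`+`, f[aa]) + c(0, 2, 0, 1, 0)       # + H2O
  if (amidated) comp <- comp + c(0, 1, 1, -1, 0)      # -OH +NH2
  sum(comp * iso[c("C", "H", "N", "O", "S")])
}

randomPeptide <- function(n, alphabet = names(residueMasses())) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
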