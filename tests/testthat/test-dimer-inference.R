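test_that("odd-cysteine chains are selected as dimer candidates, in order", {
  chains <- toxinChains()
  cand <- selectDimerCandidates(chains[c("U2a", "U2b", "U2c")])
  expect_named(cand, c("U2a", "U2b", "U2c"))   # 1, 3, 1 cysteines
  expect_length(selectDimerCandidates(list(peptideChain("GAKLM"))), 0)
  expect_length(selectDimerCandidates(list(peptideChain("CGAKCLM"))), 0)
})

test_that("enumeration yields n homodimers plus n(n-1)/2 heterodimers", {
  chains <- toxinChains()[c("U2a", "U2b", "U2c")]
  hyp <- enumerateAssemblies(chains)
  expect_equal(nrow(hyp), 6)
  expect_equal(sum(hyp$kind == "homodimer"), 3)
  expect_equal(sum(hyp$kind == "heterodimer"), 3)
  one <- enumerateAssemblies(chains[1])
  expect_equal(nrow(one), 1)
  expect_equal(one$kind, "homodimer")
  withMono <- enumerateAssemblies(chains, includeMonomers = TRUE)
  expect_equal(nrow(withMono), 9)
  expect_error(enumerateAssemblies(list()), "no candidate")
})

test_that("enumeration includes the published homodimer masses", {
  chains <- toxinChains()[c("U2a", "U2b", "U2c")]
  hyp <- enumerateAssemblies(chains, conventions = "chemical")
  homoB <- hyp$mass[hyp$chainA == "U2b" & hyp$kind == "homodimer"]
  homoC <- hyp$mass[hyp$chainA == "U2c" & hyp$kind == "homodimer"]
  expect_lt(abs(homoB - 5438.60), 0.05)
  expect_lt(abs(homoC - 5608.78), 0.05)
  # 3+3 cysteines pair into 3 bonds with ambiguous topology
  bRow <- hyp[hyp$chainA == "U2b" & hyp$kind == "homodimer", ]
  expect_equal(bRow$bonds, 3L)
  expect_true(bRow$topologyAmbiguous)
  # 1+1 cysteines: a single unambiguous interchain bond
  aRow <- hyp[hyp$chainA == "U2a" & hyp$kind == "homodimer", ]
  expect_equal(aRow$interchainBonds, 1L)
  expect_false(aRow$topologyAmbiguous)
})

test_that("mass matching honors tolerance, sign and tie-breaking", {
  hyp <- data.frame(id = c("h1", "h2"), mass = c(5438.588, 6000))
  rep1 <- matchMasses(hyp, 5441.80, tolerance = 3.5)
  expect_equal(rep1$assignments$hypothesis, "h1")
  expect_equal(rep1$assignments$error, 3.212, tolerance = 1e-3)
  rep2 <- matchMasses(hyp, 5441.80, tolerance = 0.5)
  expect_true(is.na(rep2$assignments$hypothesis))
  expect_equal(nrow(rep2$unexplained), 1)
  rep3 <- matchMasses(hyp, 5438.588, tolerance = 0.5)
  expect_equal(rep3$assignments$error, 0)
  # tie: equal |error| resolved toward lower theoretical mass
  tie <- data.frame(id = c("lo", "hi"), mass = c(999.5, 1000.5))
  expect_equal(matchMasses(tie, 1000, 1)$assignments$hypothesis, "lo")
  expect_error(matchMasses(hyp, data.frame(mass = 100, condition = "reduced")),
               "native")
  expect_error(matchMasses(hyp, 1000, tolerance = 0), "positive")
})

test_that("every native observation appears exactly once in a report", {
  set.seed(21)
  for (i in 1:10) {
    hyp <- data.frame(id = paste0("h", 1:8),
                      mass = runif(8, 2000, 6000))
    obs <- runif(12, 2000, 6000)
    rep <- matchMasses(hyp, obs, tolerance = runif(1, 1, 200))
    expect_equal(nrow(rep$assignments), 12)
    expect_equal(sum(!is.na(rep$assignments$hypothesis)) +
                   nrow(rep$unexplained), 12)
  }
})

test_that("enlarging the tolerance never removes a match", {
  set.seed(13)
  hyp <- data.frame(id = paste0("h", 1:6), mass = runif(6, 2000, 6000))
  obs <- runif(10, 2000, 6000)
  matched <- function(tol)
    which(!is.na(matchMasses(hyp, obs, tol)$assignments$hypothesis))
  tols <- c(0.5, 2, 10, 50, 300)
  for (k in seq_len(length(tols) - 1))
    expect_true(all(matched(tols[k]) %in% matched(tols[k + 1])))
})

test_that("enumeration plus matching agrees with a brute-force oracle", {
  set.seed(99)
  for (rep in 1:5) {
    n <- sample(2:6, 1)
    chains <- lapply(seq_len(n), function(i) {
      nc <- sample(c(1L, 3L), 1)    # odd so all are candidates
      peptideChain(paste0(randomPeptide(sample(8:20, 1),
                                        setdiff(names(residueMasses()), "C")),
                          strrep("C", nc)))
    })
    names(chains) <- paste0("c", seq_len(n))
    obs <- runif(8, 1500, 7000)
    tol <- 40
    hyp <- enumerateAssemblies(chains, includeMonomers = FALSE)
    got <- matchMasses(hyp, obs, tol)$matches
    # oracle: loop over all ordered-unique pairs and feasible bond counts
    brute <- list()
    for (i in seq_len(n)) for (j in i:n) {
      nb <- (cysteineCount(chains[[i]]) + cysteineCount(chains[[j]])) %/% 2
      m <- chainMass(chains[[i]]) + chainMass(chains[[j]]) - 2.01565 * nb
      for (o in obs)
        if (abs(o - m) <= tol)
          brute[[length(brute) + 1]] <- c(i, j, round(o, 6))
    }
    expect_equal(nrow(got), length(brute))
    if (nrow(got)) {
      gotKeys <- sort(paste(got$hypothesis, round(got$observed, 6)))
      bruteKeys <- sort(vapply(brute, function(b)
        paste(sprintf("c%d+c%d|chemical", b[1], b[2]), b[3]), ""))
      expect_equal(gotKeys, bruteKeys)
    }
  }
})

test_that("reduction verification follows the disappear-and-split logic", {
  chains <- toxinChains()
  het <- peptideAssembly(list(chains$U2a, chains$U2c), interchainBonds = 1)
  # printed reduced masses appear, native mass gone -> consistent
  expect_equal(
    verifyByReduction(het, c(2875.47, 2805.39), tolerance = 0.05,
                      nativeMass = 5680.86),
    "reduction_consistent")
  # native mass persisting contradicts a dimer hypothesis
  expect_equal(
    verifyByReduction(het, c(2875.47, 2805.39, 5680.86), tolerance = 0.05,
                      nativeMass = 5680.86),
    "contradicted")
  # chains absent: cannot verify either way
  expect_equal(
    verifyByReduction(het, c(4000), tolerance = 0.05, nativeMass = 5680.86),
    "unverified")
  # empty reduced list leaves the hypothesis unverified
  expect_equal(
    verifyByReduction(het, numeric(0), tolerance = 0.05),
    "unverified")
  # a bond-free monomer must persist unchanged
  mono <- peptideAssembly(chains$U1)
  expect_equal(verifyByReduction(mono, chainMass(chains$U1) + 0.01,
                                 tolerance = 0.05),
               "reduction_consistent")
  expect_equal(verifyByReduction(mono, c(1234.5), tolerance = 0.05),
               "contradicted")
})

test_that("alkylation verification counts cysteines from the 57 Da shift", {
  chains <- toxinChains()
  het <- peptideAssembly(list(chains$U2a, chains$U2c), interchainBonds = 1)
  okA <- chainMass(chains$U2a) + 57.0215
  okC <- chainMass(chains$U2c) + 57.0215
  expect_equal(verifyByAlkylation(het, c(okA, okC), tolerance = 0.05),
               "fully_verified")
  # a +85 Da shift is not an integer number of carbamidomethyl groups
  bad <- chainMass(chains$U2a) + 85
  expect_equal(verifyByAlkylation(het, c(bad, okC), tolerance = 0.05),
               "contradicted")
  # three cysteines shift by 3 x 57.02146
  homoB <- peptideAssembly(list(chains$U2b, chains$U2b),
                           interchainBonds = 1, intrachainBonds = 2)
  alkB <- chainMass(chains$U2b) + 3 * 57.021464
  expect_equal(verifyByAlkylation(homoB, alkB, tolerance = 0.05),
               "fully_verified")
  # nothing near the chain: cannot confirm, not contradicted
  expect_equal(verifyByAlkylation(het, 9999, tolerance = 0.05),
               "reduction_consistent")
})

test_that("dimerScan ties the stages together on the published mass lists", {
  chains <- toxinChains()[c("U2a", "U2b", "U2c")]
  native <- data.frame(
    mass = c(2877.72, 5441.80, 5753.64, 5683.60, 5610.63),
    condition = "native",
    label = c("Ta-2875", "Ta-5438", "Ta-5750", "Ta-5680", "Ta-5608"))
  # reduced venom: the three free chains, dimer masses gone
  reduced <- vapply(chains, chainMass, numeric(1))
  alkylated <- reduced + 57.021464 * vapply(chains, cysteineCount, integer(1))
  scan <- dimerScan(chains, native, reduced, alkylated,
                    tolerance = 3.5, conventions = "chemical")
  hyp <- scan$hypotheses
  expect_equal(hyp$status[hyp$id == "U2b+U2b|chemical"], "fully_verified")
  expect_equal(hyp$status[hyp$id == "U2c+U2c|chemical"], "fully_verified")
  expect_equal(hyp$status[hyp$id == "U2a|monomer|chemical"], "fully_verified")
})
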