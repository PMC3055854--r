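identAln <- function(n = 100) {
  set.seed(1)
  cods <- sample(.oSense, n, replace = TRUE)
  new("CodonAlignment", geneId = "ident", codonsA = cods, codonsB = cods)
}

test_that("all counting methods return Ka = Ks = 0 on identical sequences", {
  aln <- identAln()
  for (m in c("NG", "LWL", "MLWL", "LPB", "MLPB")) {
    est <- suppressWarnings(estimateCounting(aln, m))  # MLWL kappa warning
    expect_equal(est$ka, 0, info = m)
    expect_equal(est$ks, 0, info = m)
    expect_true(est$omega_na, info = m)
  }
})

test_that("a single synonymous transition gives Ka = 0, Ks > 0", {
  set.seed(2)
  cods <- sample(setdiff(.oSense, c("TTT", "TTC")), 99, replace = TRUE)
  a <- c(cods, "TTT")
  b <- c(cods, "TTC")                     # Phe<->Phe, transition, 2-fold
  aln <- new("CodonAlignment", geneId = "syn1", codonsA = a, codonsB = b)
  for (m in c("NG", "LWL")) {
    est <- estimateCounting(aln, m)
    expect_equal(est$ka, 0, info = m)
    expect_gt(est$ks, 0)
    expect_false(est$omega_na)            # Ks > 0, Ka = 0 -> omega = 0
    expect_equal(est$omega, 0)
  }
})

test_that("NG equals the brute-force pathway + JC oracle", {
  set.seed(301)
  for (i in 1:60) {
    aln <- randomCodonAlignment(30)
    est <- estimateCounting(aln, "NG")
    orc <- oracleNG(aln@codonsA, aln@codonsB)
    expect_equal(est$ka, unname(orc[["ka"]]), tolerance = 1e-9)
    expect_equal(est$ks, unname(orc[["ks"]]), tolerance = 1e-9)
  }
})

test_that("Ka and Ks are invariant under swapping the sequences", {
  set.seed(303)
  for (i in 1:10) {
    aln <- randomCodonAlignment(40)
    swp <- new("CodonAlignment", geneId = "swap",
               codonsA = aln@codonsB, codonsB = aln@codonsA)
    for (m in c("NG", "LWL", "MLWL", "LPB", "MLPB")) {
      e1 <- estimateCounting(aln, m)
      e2 <- estimateCounting(swp, m)
      expect_equal(e1$ka, e2$ka, tolerance = 1e-12, info = m)
      expect_equal(e1$ks, e2$ks, tolerance = 1e-12, info = m)
    }
  }
})

test_that("adding a nonsynonymous difference never decreases NG Ka", {
  set.seed(304)
  for (i in 1:10) {
    cods <- sample(.oSense, 50, replace = TRUE)
    aln <- randomCodonAlignment(50)
    base <- estimateCounting(aln, "NG")$ka
    # append one codon column with a single nonsynonymous change
    ext <- new("CodonAlignment", geneId = "ext",
               codonsA = c(aln@codonsA, "AAA"),
               codonsB = c(aln@codonsB, "GAA"))   # Lys -> Glu, nonsyn
    expect_gte(estimateCounting(ext, "NG")$ka, base * 50 / 51 * 0.999)
    # replacing an identical column by a nonsynonymous one strictly grows Ka
    idx <- which(aln@codonsA == aln@codonsB)[1]
    if (!is.na(idx)) {
      mod <- aln
      mod@codonsA[idx] <- "AAA"; mod@codonsB[idx] <- "GAA"
      expect_gt(estimateCounting(mod, "NG")$ka, base)
    }
  }
})

test_that("LWL and LPB converge when there is no transition bias", {
  # the two methods differ only in the two-fold-site treatment: LWL fixes
  # the synonymous weight at 1/3 (exact when transversions run at twice
  # the transition rate, i.e. kappa = 1), LPB infers it from the A/B
  # decomposition; at kappa = 1 they must agree up to sampling noise
  diffs <- sapply(1:8, function(i) {
    p <- simParams(800, t = 0.4, kappa = 1, omega = 0.3, seed = 5000 + i)
    aln <- simulatePair(p)
    lwl <- estimateCounting(aln, "LWL")
    lpb <- estimateCounting(aln, "LPB")
    c(ka = (lwl$ka - lpb$ka) / lpb$ka, ks = (lwl$ks - lpb$ks) / lpb$ks)
  })
  expect_lt(abs(median(diffs["ka", ])), 0.05)
  expect_lt(abs(median(diffs["ks", ])), 0.05)
})

test_that("saturated alignments set NA flags instead of raising errors", {
  # maximally divergent pair: every codon differs at all three positions
  a <- rep("AAA", 50); b <- rep("CCC", 50)
  aln <- new("CodonAlignment", geneId = "sat", codonsA = a, codonsB = b)
  for (m in c("NG", "LWL", "MLWL", "LPB", "MLPB")) {
    est <- expect_silent(suppressWarnings(estimateCounting(aln, m)))
    expect_true(est$ka_na || est$ks_na || (est$ka >= 0), info = m)
  }
  ng <- suppressWarnings(estimateCounting(aln, "NG"))
  expect_true(ng$ks_na)                  # ps = 1 is beyond the JC domain
})

test_that("MLWL reports a kappa estimate and inherits LWL at kappa = 1", {
  set.seed(306)
  aln <- randomCodonAlignment(200, mutateProb = 0.3)
  ml <- estimateCounting(aln, "MLWL")
  expect_true(is.finite(ml$kappa))
  expect_gt(ml$kappa, 0)
})
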