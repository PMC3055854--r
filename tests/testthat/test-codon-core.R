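test_that("codon filtering drops gap, N and stop columns whole", {
  a <- buildCodonAlignment(SequencePair("g", "ATG---AAA", "ATGGCGAAA"))
  expect_equal(nCodons(a), 2)
  expect_equal(a@codonsA, c("ATG", "AAA"))

  s <- buildCodonAlignment(SequencePair("g", "ATGTAA", "ATGCAA"))
  expect_equal(nCodons(s), 1)

  n <- buildCodonAlignment(SequencePair("g", "ATNAAA", "ATGAAA"))
  expect_equal(nCodons(n), 1)

  expect_error(buildCodonAlignment(SequencePair("g", "ATGA", "ATGC")),
               "divisible by 3")
  expect_error(buildCodonAlignment(SequencePair("g", "TAA", "TAA")),
               "no codon columns")
})

test_that("degeneracy matches enumeration of all nine single-base changes", {
  expect_equal(degeneracy("GGG"), c(0L, 0L, 4L))
  expect_equal(degeneracy("TTT"), c(0L, 0L, 2L))
  # isoleucine 3-fold third position folds into the two-fold class
  expect_equal(degeneracy("ATT")[3], 2L)
  expect_error(degeneracy("TAA"), "stop")

  # against an independent enumeration for every sense codon
  for (cod in .oSense) {
    b <- strsplit(cod, "")[[1]]
    expected <- integer(3)
    for (p in 1:3) {
      ns <- 0
      for (nt in setdiff(.oBases, b[p])) {
        m <- b; m[p] <- nt
        if (.oc[[paste(m, collapse = "")]] == .oc[[cod]]) ns <- ns + 1
      }
      expected[p] <- if (ns == 3) 4L else if (ns == 0) 0L else 2L
    }
    expect_equal(degeneracy(cod), expected, info = cod)
  }
})

test_that("arginine two-fold first positions host synonymous transversions", {
  # CGA<->AGA and CGG<->AGG are synonymous first-position transversions,
  # the irregularity the modified LWL/LPB methods reassign
  gc <- Biostrings::GENETIC_CODE
  expect_equal(gc[["CGA"]], gc[["AGA"]])
  expect_equal(degeneracy("CGA")[1], 2L)
  expect_equal(degeneracy("AGA")[1], 2L)
  inv <- KaKsEval:::.kk$invTwofold
  expect_true(all(inv[c("AGA", "AGG", "CGA", "CGG"), 1]))
  # the isoleucine ATA third position shares the irregularity: its
  # synonymous alternatives (T, C) are transversions, the transition (G)
  # gives methionine
  expect_true(inv["ATA", 3])
  expect_equal(sum(inv), 5)
})

test_that("NG site counts follow the per-codon enumeration", {
  one <- function(cod) {
    aln <- new("CodonAlignment", geneId = "x", codonsA = cod, codonsB = cod)
    countSitesNG(aln)
  }
  expect_equal(one("TTT")[["S"]], 1 / 3, tolerance = 1e-12)
  expect_equal(one("CCC")[["S"]], 1, tolerance = 1e-12)
  expect_equal(one("CCC")[["N"]], 2, tolerance = 1e-12)

  set.seed(42)
  for (i in 1:20) {
    aln <- randomCodonAlignment(15)
    ns <- countSitesNG(aln)
    expect_equal(ns[["N"]] + ns[["S"]], 3 * nCodons(aln), tolerance = 1e-9)
    sOracle <- (sum(vapply(aln@codonsA, oracleSynSites, 1)) +
                  sum(vapply(aln@codonsB, oracleSynSites, 1))) / 2
    expect_equal(ns[["S"]], sOracle, tolerance = 1e-12)
  }
})

test_that("pathway enumeration matches the independent oracle", {
  p <- enumeratePathways("TTT", "GTA")
  expect_length(p, 2)
  d <- KaKsEval:::.pairDiffSummary("TTT", "GTA")
  expect_equal(d[["sd"]], 0.5)
  expect_equal(d[["nd"]], 1.5)

  expect_length(enumeratePathways("AAA", "AAA"), 0)

  set.seed(77)
  for (i in 1:150) {
    ca <- sample(.oSense, 1); cb <- sample(.oSense, 1)
    mine <- KaKsEval:::.pairDiffSummary(ca, cb)
    orc <- oraclePairDiffs(ca, cb)
    expect_equal(mine[["sd"]], orc[["sd"]], tolerance = 1e-12,
                 info = paste(ca, cb))
    expect_equal(mine[["nd"]], orc[["nd"]], tolerance = 1e-12,
                 info = paste(ca, cb))
    ndiff <- sum(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
    expect_lte(length(enumeratePathways(ca, cb)), factorial(ndiff))
  }
})

test_that("distance corrections hit closed-form values and saturate to NA", {
  expect_equal(distanceJC(0), 0)
  expect_equal(distanceJC(0.3), 0.3831192, tolerance = 1e-6)
  expect_true(is.na(distanceJC(0.75)))

  k0 <- distanceK2P(0, 0)
  expect_equal(k0[["d"]], 0)
  k <- distanceK2P(0.2, 0.1)
  expect_equal(k[["d"]], 0.5 * log(2) + 0.25 * log(1.25), tolerance = 1e-12)
  expect_equal(k[["tv"]], 0.5 * log(1.25), tolerance = 1e-12)
  # K2P equals JC only when the P:Q pattern is 1:2
  p <- 0.3
  expect_equal(distanceK2P(p / 3, 2 * p / 3)[["d"]], distanceJC(p),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(k[["d"]], distanceJC(0.3))))
  expect_true(is.na(distanceK2P(0.5, 0)[["d"]]))
})

test_that("corrections are monotone and never below the raw proportion", {
  ps <- seq(0.01, 0.7, by = 0.05)
  ds <- vapply(ps, distanceJC, 1)
  expect_true(all(diff(ds) > 0))
  expect_true(all(ds >= ps))
  k2 <- vapply(ps / 2, function(x) distanceK2P(x, x)[["d"]], 1)
  expect_true(all(diff(k2) > 0))
  expect_true(all(k2 >= ps))
})

test_that("TN93 decomposition collapses to K2P under uniform frequencies", {
  uf <- c(A = 1, C = 1, G = 1, T = 1)
  P <- 0.10; Q <- 0.06
  tn <- distanceTN93(P / 2, P / 2, Q, uf)
  k2 <- distanceK2P(P, Q)
  expect_equal(tn[["d"]], k2[["d"]], tolerance = 1e-9)
  expect_equal(tn[["tv"]], k2[["tv"]], tolerance = 1e-9)
  expect_equal(tn[["kappaR"]], k2[["kappaHat"]], tolerance = 1e-9)
  expect_equal(tn[["kappaY"]], k2[["kappaHat"]], tolerance = 1e-9)
  expect_true(is.na(distanceTN93(0.4, 0.4, 0.5, uf)[["d"]]))
})
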