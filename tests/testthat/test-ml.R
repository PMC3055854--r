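test_that("F3x4 frequencies normalize and respect composition limits", {
  set.seed(10)
  aln <- randomCodonAlignment(60)
  pi <- f3x4Frequencies(aln)
  expect_length(pi, 61)
  expect_equal(sum(pi), 1, tolerance = 1e-12)
  expect_true(all(pi > 0))

  # uniform base composition renormalizes to the uniform sense-codon law
  piU <- KaKsEval:::.f3x4FromPositional(
    matrix(0.25, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL)))
  expect_equal(unname(piU), rep(1 / 61, 61), tolerance = 1e-12)

  # degenerate all-A input keeps mass concentrated at AAA after smoothing
  allA <- new("CodonAlignment", geneId = "a",
              codonsA = rep("AAA", 30), codonsB = rep("AAA", 30))
  piA <- f3x4Frequencies(allA)
  expect_gt(piA[["AAA"]], 0.9)
})

test_that("the codon generator has generator structure and correct limits", {
  pi <- rep(1 / 61, 61)
  names(pi) <- KaKsEval:::.kk$codons
  m <- buildRateMatrix(pi, kappa = 2, omega = 0.5)
  expect_equal(max(abs(rowSums(m$Q))), 0, tolerance = 1e-12)
  expect_equal(m$rhoN + m$rhoS, 1, tolerance = 1e-12)
  # scaling: mean rate one substitution per codon per unit t
  expect_equal(-sum(pi * diag(m$Q)), 1, tolerance = 1e-12)

  # omega = 0 removes all nonsynonymous flux
  m0 <- buildRateMatrix(pi, kappa = 2, omega = 0)
  expect_equal(m0$rhoN, 0)

  # omega = kappa = 1 collapses to a pi-weighted symmetric exchange
  m1 <- buildRateMatrix(pi, kappa = 1, omega = 1)
  B <- diag(pi) %*% m1$Q
  expect_equal(max(abs(B - t(B))), 0, tolerance = 1e-12)

  # detailed balance holds for generic parameters too
  B2 <- diag(pi) %*% m$Q
  expect_equal(max(abs(B2 - t(B2))), 0, tolerance = 1e-12)
})

test_that("matrix exponential is the identity at t = 0 and stochastic", {
  pi <- rep(1 / 61, 61); names(pi) <- KaKsEval:::.kk$codons
  m <- buildRateMatrix(pi, kappa = 3, omega = 0.2)
  P0 <- KaKsEval:::.expmReversible(m$Q, pi, 0)
  expect_equal(max(abs(P0 - diag(61))), 0, tolerance = 1e-9)
  P <- KaKsEval:::.expmReversible(m$Q, pi, 0.7)
  expect_equal(max(abs(rowSums(P) - 1)), 0, tolerance = 1e-9)
  expect_true(all(P > 0))
  # stationarity of pi
  expect_equal(as.numeric(pi %*% P), unname(pi), tolerance = 1e-9)
})

test_that("GY returns zeros on identical sequences and is swap-invariant", {
  set.seed(20)
  cods <- sample(.oSense, 80, replace = TRUE)
  ident <- new("CodonAlignment", geneId = "i", codonsA = cods,
               codonsB = cods)
  e <- estimateGY(ident)
  expect_equal(e$ka, 0); expect_equal(e$ks, 0); expect_equal(e$t, 0)
  expect_true(e$omega_na)

  p <- simParams(300, t = 0.4, kappa = 2, omega = 0.3, seed = 21)
  aln <- simulatePair(p)
  swp <- new("CodonAlignment", geneId = "s", codonsA = aln@codonsB,
             codonsB = aln@codonsA)
  e1 <- estimateGY(aln); e2 <- estimateGY(swp)
  expect_equal(e1$ka, e2$ka, tolerance = 1e-4)
  expect_equal(e1$ks, e2$ks, tolerance = 1e-4)
})

test_that("GY log-likelihood at the MLE dominates the truth", {
  for (i in 1:5) {
    p <- simParams(300, t = 0.3, kappa = 2, omega = 0.25, seed = 30 + i)
    aln <- simulatePair(p)
    fit <- estimateGY(aln)
    llMLE <- attr(fit, "logLik")
    llTrue <- codonLogLik(aln, t = 0.3, kappa = 2, omega = 0.25)
    expect_gte(llMLE + 1e-6, llTrue)
  }
})

test_that("GY omega bias shrinks with alignment length", {
  relerr <- function(n, seeds) {
    median(sapply(seeds, function(s) {
      p <- simParams(n, t = 0.4, kappa = 2, omega = 0.25, seed = s)
      estimateGY(simulatePair(p))$omega
    })) / 0.25 - 1
  }
  seeds <- 1:12
  eShort <- relerr(100, 100 + seeds)
  eLong <- relerr(1000, 200 + seeds)
  expect_lt(abs(eLong), max(abs(eShort), 0.06))
})

test_that("YN and MYN return zeros on identical sequences", {
  set.seed(40)
  cods <- sample(.oSense, 80, replace = TRUE)
  ident <- new("CodonAlignment", geneId = "i", codonsA = cods,
               codonsB = cods)
  for (v in c("YN", "MYN")) {
    e <- estimateYN(ident, v)
    expect_equal(e$ka, 0, info = v)
    expect_equal(e$ks, 0, info = v)
    expect_true(e$omega_na, info = v)
  }
})

test_that("YN and MYN agree when the two transition classes collapse", {
  diffs <- sapply(1:10, function(i) {
    p <- simParams(400, t = 0.4, kappa = 2, omega = 0.3, seed = 600 + i)
    aln <- simulatePair(p)
    estimateYN(aln, "YN")$omega - estimateYN(aln, "MYN")$omega
  })
  # paired omega difference centered near zero at kappa_R = kappa_Y
  expect_lt(abs(median(diffs)), 0.02)
})

test_that("MYN separates purine and pyrimidine transition rates", {
  res <- sapply(1:12, function(i) {
    p <- simParams(500, t = 0.3, kappaR = 4, kappaY = 1, omega = 0.25,
                   seed = 700 + i)
    e <- estimateYN(simulatePair(p), "MYN")
    c(e$kappa_R, e$kappa_Y)
  })
  expect_gt(mean(res[1, ] > res[2, ]), 0.9)
  expect_gt(median(res[1, ]), median(res[2, ]))
})
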