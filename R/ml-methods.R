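# Model-based estimators: GY (maximum likelihood on a 61-state codon
# model) and the iterative approximate YN / MYN procedures. The codon
# rate-matrix machinery here is shared with the simulator module.

# --- static single-difference structure over the 61 sense codons --------

.codonModelTables <- function() {
  .codeTables()
  if (!is.null(.kk$singleDiff)) return(invisible(NULL))
  cods <- .kk$codons
  n <- length(cods)
  sp <- do.call(rbind, strsplit(cods, ""))
  diffcount <- matrix(0L, n, n)
  for (p in 1:3) diffcount <- diffcount + outer(sp[, p], sp[, p], "!=")
  single <- diffcount == 1L
  pos <- matrix(0L, n, n)
  for (p in 1:3) pos[single & outer(sp[, p], sp[, p], "!=")] <- p
  fromB <- toB <- matrix("", n, n)
  for (p in 1:3) {
    sel <- single & pos == p
    fromB[sel] <- matrix(sp[, p], n, n)[sel]
    toB[sel] <- matrix(sp[, p], n, n, byrow = TRUE)[sel]
  }
  isTs <- matrix(FALSE, n, n)
  isTs[single] <- .isTransition(fromB[single], toB[single])
  isTsR <- single & isTs & fromB %in% .PURINES
  isTsY <- single & isTs & fromB %in% .PYRIMIDINES
  isSyn <- outer(.kk$aa, .kk$aa, "==") & single
  .kk$singleDiff <- single
  .kk$sdPos <- pos
  .kk$sdToBase <- toB
  .kk$sdTs <- isTs
  .kk$sdTsR <- isTsR
  .kk$sdTsY <- isTsY
  .kk$sdSyn <- isSyn
  # flat index vectors for fast generator construction
  sel <- which(single)
  .kk$qSel <- sel
  .kk$qRow <- ((sel - 1L) %% n) + 1L
  .kk$qCol <- ((sel - 1L) %/% n) + 1L
  .kk$qTsR <- isTsR[sel]
  .kk$qTsY <- isTsY[sel]
  .kk$qSyn <- isSyn[sel]
  invisible(NULL)
}

#' F3x4 codon equilibrium frequencies from an alignment
#'
#' Position-specific nucleotide frequencies are estimated from both
#' sequences pooled; each codon frequency is the product of its three
#' positional frequencies, renormalized over the 61 sense codons. Zero
#' positional frequencies are smoothed by a small epsilon so that every
#' sense codon keeps positive mass.
#'
#' @param aln a \linkS4class{CodonAlignment}.
#' @param epsilon smoothing constant added to positional counts of absent
#'   bases (default 0.5, a half-count).
#' @return named numeric(61) summing to 1.
#' @export
f3x4Frequencies <- function(aln, epsilon = 0.5) {
  .codonModelTables()
  if (!nCodons(aln)) stop("empty codon alignment")
  cods <- c(aln@codonsA, aln@codonsB)
  mat <- do.call(rbind, strsplit(cods, ""))
  posFreq <- sapply(1:3, function(p) {
    cnt <- table(factor(mat[, p], levels = c("A", "C", "G", "T")))
    cnt <- as.numeric(cnt)
    if (any(cnt == 0)) cnt <- cnt + epsilon
    cnt / sum(cnt)
  })
  rownames(posFreq) <- c("A", "C", "G", "T")
  .f3x4FromPositional(posFreq)
}

# positional 4x3 matrix -> normalized codon frequencies over sense codons
.f3x4FromPositional <- function(posFreq) {
  .codonModelTables()
  sp <- do.call(rbind, strsplit(.kk$codons, ""))
  pi <- posFreq[sp[, 1], 1] * posFreq[sp[, 2], 2] * posFreq[sp[, 3], 3]
  pi <- pi / sum(pi)
  names(pi) <- .kk$codons
  pi
}

#' Build a scaled codon substitution rate matrix
#'
#' Off-diagonal rate i -> j is zero for multi-base changes and otherwise
#' pi_j times 1 (synonymous transversion), kappa (synonymous transition),
#' omega (nonsynonymous transversion) or omega x kappa (nonsynonymous
#' transition). With kappaR/kappaY given, the transition factor splits into
#' a purine (A<->G) and a pyrimidine (C<->T) component. The diagonal makes
#' rows sum to zero and the matrix is scaled so the mean rate is one, i.e.
#' divergence t is measured in substitutions per codon.
#'
#' @param pi named numeric(61) codon frequencies.
#' @param kappa transition/transversion rate ratio (ignored when kappaR and
#'   kappaY are supplied).
#' @param omega nonsynonymous/synonymous rate ratio.
#' @param kappaR,kappaY optional separate purine/pyrimidine transition
#'   ratios.
#' @return list with Q (61x61 generator, scaled), rhoN and rhoS (the
#'   expected nonsynonymous and synonymous flux fractions, summing to 1),
#'   and pi.
#' @export
buildRateMatrix <- function(pi, kappa = 2, omega = 1,
                            kappaR = NULL, kappaY = NULL) {
  .codonModelTables()
  stopifnot(length(pi) == 61L, abs(sum(pi) - 1) < 1e-6)
  pi <- pi[.kk$codons]
  if (is.null(kappaR)) { kappaR <- kappa; kappaY <- kappa }
  rate <- pi[.kk$qCol]
  rate[.kk$qTsR] <- rate[.kk$qTsR] * kappaR
  rate[.kk$qTsY] <- rate[.kk$qTsY] * kappaY
  rate[!.kk$qSyn] <- rate[!.kk$qSyn] * omega
  R <- matrix(0, 61, 61, dimnames = list(.kk$codons, .kk$codons))
  R[.kk$qSel] <- rate
  diag(R) <- -rowSums(R)
  mu <- -sum(pi * diag(R))
  if (mu <= 0) stop("degenerate rate matrix (zero total rate)")
  Q <- R / mu
  flux <- pi[.kk$qRow] * rate / mu
  rhoS <- sum(flux[.kk$qSyn])
  rhoN <- sum(flux[!.kk$qSyn])
  list(Q = Q, rhoN = rhoN, rhoS = rhoS, pi = pi)
}

# Transition probabilities exp(Qt) through the symmetrized eigensystem of
# the reversible generator (exact and much faster than a generic matrix
# exponential when many t values share one Q).
.expmReversible <- function(Q, pi, t) {
  sq <- sqrt(pi)
  S <- Q * outer(sq, 1 / sq)
  S <- (S + t(S)) / 2                 # symmetrize away rounding noise
  e <- eigen(S, symmetric = TRUE)
  P <- outer(1 / sq, sq) * (e$vectors %*% (t(e$vectors) * exp(e$values * t)))
  P[P < 1e-300] <- 1e-300
  P
}

# eigensystem reusable across t (for optim inner loop)
.eigenReversible <- function(Q, pi) {
  sq <- sqrt(pi)
  S <- Q * outer(sq, 1 / sq)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(U = e$vectors, lambda = e$values, sq = sq)
}

.probFromEigen <- function(es, t) {
  P <- outer(1 / es$sq, es$sq) *
    (es$U %*% (t(es$U) * exp(es$lambda * t)))
  P[P < 1e-300] <- 1e-300
  P
}

# convert (t, rhoN, rhoS) to Ka/Ks under the mutational-opportunity site
# convention: site fractions come from the omega = 1 generator with the
# same kappa(s) and pi.
.ratesFromModel <- function(t, fit, neutral) {
  ka <- t * fit$rhoN / (3 * neutral$rhoN)
  ks <- t * fit$rhoS / (3 * neutral$rhoS)
  c(ka = ka, ks = ks)
}

# --- GY maximum likelihood ---------------------------------------------

#' Goldman-Yang style pairwise maximum-likelihood estimate
#'
#' Maximizes the pairwise log-likelihood sum over codon sites of
#' log(pi_i P(t)_{ij}) under the codon model of [buildRateMatrix()] with
#' F3x4 frequencies, over (t, kappa, omega) on the log scale (bounded
#' quasi-Newton, three fixed starting points). The MLE is converted to Ka
#' and Ks with mutational-opportunity site fractions (omega excluded from
#' the site definition) so that cross-method comparison with the counting
#' methods is meaningful.
#'
#' @param aln a \linkS4class{CodonAlignment}.
#' @return one-row estimate data.frame (see [estimateCounting()]) with t
#'   (substitutions per codon) and kappa filled in.
#' @export
estimateGY <- function(aln) {
  .codonModelTables()
  if (!nCodons(aln)) stop("empty codon alignment")
  est <- .emptyEstimate(geneId(aln), "GY")
  if (all(aln@codonsA == aln@codonsB)) {
    est$ka <- 0; est$ks <- 0; est$t <- 0
    return(.finishEstimate(est))
  }
  pi <- f3x4Frequencies(aln)
  ia <- match(aln@codonsA, .kk$codons)
  ib <- match(aln@codonsB, .kk$codons)
  pat <- table(paste(ia, ib))
  cnt <- as.numeric(pat)
  idx <- do.call(rbind, lapply(strsplit(names(pat), " "), as.integer))
  logpi <- log(pi)

  negll <- function(par) {
    t <- exp(par[1]); kappa <- exp(par[2]); omega <- exp(par[3])
    m <- buildRateMatrix(pi, kappa = kappa, omega = omega)
    P <- .expmReversible(m$Q, pi, t)
    -sum(cnt * (logpi[idx[, 1]] + log(P[idx])))
  }

  pdiff <- mean(aln@codonsA != aln@codonsB)
  t0 <- max(1.2 * pdiff, 0.02)
  starts <- list(log(c(t0, 2, 0.3)), log(c(2 * t0, 1, 1)),
                 log(c(max(t0 / 2, 0.01), 4, 0.1)))
  lower <- log(c(1e-4, 0.05, 1e-4))
  upper <- log(c(20, 50, 20))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, negll, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(factr = 1e7)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) return(est)     # optimizer failure -> NA flags
  t <- exp(best$par[1]); kappa <- exp(best$par[2]); omega <- exp(best$par[3])
  m <- buildRateMatrix(pi, kappa = kappa, omega = omega)
  neutral <- buildRateMatrix(pi, kappa = kappa, omega = 1)
  r <- .ratesFromModel(t, m, neutral)
  est$ka <- r[["ka"]]; est$ks <- r[["ks"]]
  est$kappa <- kappa; est$t <- t
  attr(est, "logLik") <- -best$value
  .finishEstimate(est)
}

#' Pairwise codon-model log-likelihood at fixed parameters
#'
#' Utility for optimality checks: the log-likelihood of an alignment under
#' the [buildRateMatrix()] model at given (t, kappa, omega) with F3x4
#' frequencies estimated from the alignment.
#'
#' @param aln a CodonAlignment.
#' @param t divergence in substitutions per codon.
#' @param kappa,omega model parameters.
#' @return numeric(1) log-likelihood.
#' @export
codonLogLik <- function(aln, t, kappa, omega) {
  .codonModelTables()
  pi <- f3x4Frequencies(aln)
  m <- buildRateMatrix(pi, kappa = kappa, omega = omega)
  P <- .expmReversible(m$Q, pi, t)
  ia <- match(aln@codonsA, .kk$codons)
  ib <- match(aln@codonsB, .kk$codons)
  sum(log(pi[ia]) + log(P[cbind(ia, ib)]))
}

# --- YN / MYN iterative approximate methods ----------------------------

# kappa(s) from nucleotide distances at positions whose fold class agrees
# between the two sequences and is 0 or 4 (degeneracy-stratified sites).
.kappaFromConservedSites <- function(aln, variant) {
  .codeTables()
  fa <- .kk$fold[aln@codonsA, , drop = FALSE]
  fb <- .kk$fold[aln@codonsB, , drop = FALSE]
  ba <- do.call(rbind, strsplit(aln@codonsA, ""))
  bb <- do.call(rbind, strsplit(aln@codonsB, ""))
  sel <- (fa == fb) & (fa == 0L | fa == 4L)
  x <- ba[sel]; y <- bb[sel]
  n <- length(x)
  fallback <- list(kappa = 2, kappaR = 2, kappaY = 2, ok = FALSE)
  if (n < 10L) return(fallback)
  diff <- x != y
  ts <- diff & .isTransition(x, y)
  tsR <- ts & x %in% .PURINES
  tv <- diff & !ts
  if (variant == "YN") {
    k <- distanceK2P(sum(ts) / n, sum(tv) / n)
    kap <- k[["kappaHat"]]
    if (!is.finite(kap) || kap <= 0) return(fallback)
    list(kappa = kap, kappaR = kap, kappaY = kap, ok = TRUE)
  } else {
    bf <- table(factor(c(x, y), levels = c("A", "C", "G", "T")))
    k <- distanceTN93(sum(tsR) / n, sum(ts & !tsR) / n, sum(tv) / n,
                      as.numeric(bf) |> stats::setNames(c("A", "C", "G", "T")))
    if (!is.finite(k[["kappaR"]]) || !is.finite(k[["kappaY"]]) ||
        k[["kappaR"]] <= 0 || k[["kappaY"]] <= 0) return(fallback)
    list(kappa = NA_real_, kappaR = k[["kappaR"]], kappaY = k[["kappaY"]],
         ok = TRUE)
  }
}

# mutation-opportunity weighted site counts: per codon, the synonymous
# site count is 3 x (sum of mutation weights over synonymous single-base
# changes) / (sum over all non-stop changes), with weight = positional
# target-base frequency x transition factor.
.weightedSites <- function(aln, posFreq, kappaR, kappaY) {
  .codonModelTables()
  w <- matrix(0, 61, 61)
  sel <- .kk$singleDiff
  tb <- match(.kk$sdToBase[sel], c("A", "C", "G", "T"))
  pp <- .kk$sdPos[sel]
  w[sel] <- posFreq[cbind(tb, pp)] *
    ifelse(.kk$sdTsR[sel], kappaR, ifelse(.kk$sdTsY[sel], kappaY, 1))
  synW <- rowSums(w * .kk$sdSyn)
  totW <- rowSums(w)
  sPerCodon <- ifelse(totW > 0, 3 * synW / totW, 0)
  names(sPerCodon) <- .kk$codons
  S <- (sum(sPerCodon[aln@codonsA]) + sum(sPerCodon[aln@codonsB])) / 2
  c(N = 3 * nCodons(aln) - S, S = S)
}

# Compact per-pair pathway descriptors for omega-weighted difference
# counting: for each pathway, the per-class step counts (the 6-vector
# syn/nonsyn x tsR/tsY/tv), the kappa exponent counts, the number of
# nonsynonymous steps, and the (position, target-base) indices needed for
# the positional-frequency product. Cached per codon pair; the pathway
# weight then factorizes as freqprod x kappaR^nR x kappaY^nY x omega^nd,
# so omega iterations only rescale precomputed constants.
.pathDescriptors <- function(codonA, codonB) {
  key <- paste0("D:", codonA, ">", codonB)
  hit <- .kk$pathCache[[key]]
  if (!is.null(hit)) return(hit)
  paths <- .pathwaysFor(codonA, codonB)
  np <- length(paths)
  lab6 <- c("syn_tsR", "syn_tsY", "syn_tv", "non_tsR", "non_tsY", "non_tv")
  summ <- matrix(0, 6, np, dimnames = list(lab6, NULL))
  nR <- nY <- nd <- integer(np)
  freqIdx <- vector("list", np)
  for (i in seq_len(np)) {
    pth <- paths[[i]]
    kind <- ifelse(pth$ts, ifelse(pth$tsR, "tsR", "tsY"), "tv")
    lab <- paste0(ifelse(pth$syn, "syn_", "non_"), kind)
    for (l in lab6) summ[l, i] <- sum(lab == l)
    nR[i] <- sum(pth$tsR); nY[i] <- sum(pth$tsY); nd[i] <- sum(!pth$syn)
    freqIdx[[i]] <- cbind(match(pth$to, c("A", "C", "G", "T")), pth$pos)
  }
  out <- list(summ = summ, nR = nR, nY = nY, nd = nd, freqIdx = freqIdx,
              np = np)
  .kk$pathCache[[key]] <- out
  out
}

#' Iterative approximate estimate (YN and MYN variants)
#'
#' The procedure: (1) the transition/transversion ratio kappa (YN) or the
#' separate purine/pyrimidine ratios kappaR, kappaY (MYN) are estimated
#' from nucleotide differences at positions whose degeneracy class agrees
#' between the sequences and is 0- or 4-fold, via K2P (YN) or TN93 (MYN);
#' (2) synonymous/nonsynonymous sites are counted with positional-frequency
#' and kappa weighting of mutational opportunities; (3) differences are
#' counted by pathway enumeration with omega-dependent pathway weighting;
#' (4) the synonymous and nonsynonymous difference classes are corrected
#' with K2P (YN) or TN93 (MYN, two transition classes); (5) omega is
#' iterated to convergence (relative change < 1e-8, at most 100
#' iterations). Undefined corrections or non-convergence set NA flags.
#'
#' @param aln a \linkS4class{CodonAlignment}.
#' @param variant "YN" or "MYN".
#' @return one-row estimate data.frame (see [estimateCounting()]); MYN
#'   fills kappa_R and kappa_Y, YN fills kappa.
#' @export
estimateYN <- function(aln, variant = c("YN", "MYN")) {
  variant <- match.arg(variant)
  .codonModelTables()
  if (!nCodons(aln)) stop("empty codon alignment")
  est <- .emptyEstimate(geneId(aln), variant)
  kap <- .kappaFromConservedSites(aln, variant)
  if (variant == "YN") est$kappa <- kap$kappa
  else { est$kappa_R <- kap$kappaR; est$kappa_Y <- kap$kappaY }
  if (all(aln@codonsA == aln@codonsB)) {
    est$ka <- 0; est$ks <- 0
    return(.finishEstimate(est))
  }
  cods <- c(aln@codonsA, aln@codonsB)
  mat <- do.call(rbind, strsplit(cods, ""))
  posFreq <- sapply(1:3, function(p) {
    cnt <- as.numeric(table(factor(mat[, p], levels = c("A", "C", "G", "T"))))
    if (any(cnt == 0)) cnt <- cnt + 0.5
    cnt / sum(cnt)
  })
  rownames(posFreq) <- c("A", "C", "G", "T")
  baseFreq <- rowMeans(posFreq)
  ns <- .weightedSites(aln, posFreq, kap$kappaR, kap$kappaY)
  if (ns[["S"]] <= 0 || ns[["N"]] <= 0) return(.finishEstimate(est))

  keys <- paste(aln@codonsA, aln@codonsB)
  tab <- table(keys[aln@codonsA != aln@codonsB])
  pairCods <- strsplit(names(tab), " ")
  cntTab <- as.numeric(tab)
  # per unique pair: pathway descriptors plus the omega-free weight
  # constant of each pathway under this alignment's positional frequencies
  descs <- lapply(pairCods, function(pc) {
    d <- .pathDescriptors(pc[1], pc[2])
    d$const <- vapply(seq_len(d$np), function(i)
      prod(posFreq[d$freqIdx[[i]]]) * kap$kappaR^d$nR[i] *
        kap$kappaY^d$nY[i], numeric(1))
    d
  })

  correct <- function(counts, sites) {
    if (variant == "YN") {
      k <- distanceK2P((counts[["tsR"]] + counts[["tsY"]]) / sites,
                       counts[["tv"]] / sites)
      k[["d"]]
    } else {
      k <- distanceTN93(counts[["tsR"]] / sites, counts[["tsY"]] / sites,
                        counts[["tv"]] / sites, baseFreq)
      k[["d"]]
    }
  }

  omega <- 0.5
  ka <- ks <- NA_real_
  converged <- FALSE
  for (iter in 1:100) {
    om <- max(omega, 1e-6)
    d <- c(syn_tsR = 0, syn_tsY = 0, syn_tv = 0,
           non_tsR = 0, non_tsY = 0, non_tv = 0)
    for (j in seq_along(descs)) {
      dj <- descs[[j]]
      if (!dj$np) next
      pw <- dj$const * om^dj$nd
      if (sum(pw) <= 0) pw <- rep(1, dj$np)
      pw <- pw / sum(pw)
      d <- d + cntTab[j] * as.numeric(dj$summ %*% pw)
    }
    ks <- correct(c(tsR = d[["syn_tsR"]], tsY = d[["syn_tsY"]],
                    tv = d[["syn_tv"]]), ns[["S"]])
    ka <- correct(c(tsR = d[["non_tsR"]], tsY = d[["non_tsY"]],
                    tv = d[["non_tv"]]), ns[["N"]])
    if (is.na(ka) || is.na(ks)) break
    omegaNew <- if (ks > 0) ka / ks else omega
    if (abs(omegaNew - omega) < 1e-8 * max(1, abs(omega))) {
      omega <- omegaNew; converged <- TRUE; break
    }
    omega <- omegaNew
  }
  if (!is.na(ka) && !is.na(ks) && !converged && ks > 0) {
    # ran out of iterations without meeting the tolerance: NA flags
    ka <- ks <- NA_real_
  }
  est$ka <- ka; est$ks <- ks
  .finishEstimate(est)
}
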