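# Independent oracles, written against the standard genetic code with no
# shared code paths with the package internals. Used to freeze expected
# values for the estimators and the exact statistics.

.oc <- as.list(Biostrings::GENETIC_CODE)
.oBases <- c("A", "C", "G", "T")
.oSense <- names(.oc)[unlist(.oc) != "*"]

# brute-force synonymous site count of one codon (NG convention: each
# position contributes (#synonymous changes)/3; stops are nonsynonymous)
oracleSynSites <- function(codon) {
  b <- strsplit(codon, "")[[1]]
  s <- 0
  for (p in 1:3) for (nt in setdiff(.oBases, b[p])) {
    m <- b; m[p] <- nt
    if (.oc[[paste(m, collapse = "")]] == .oc[[codon]]) s <- s + 1 / 3
  }
  s
}

# all orderings of a vector, plain recursion
oraclePerms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  res <- list()
  for (i in seq_along(v))
    for (tl in oraclePerms(v[-i])) res[[length(res) + 1L]] <- c(v[i], tl)
  res
}

# pathway-averaged (sd, nd) for one codon pair; stop-crossing orderings
# dropped, with an all-orderings fallback mirroring the documented rule
oraclePairDiffs <- function(ca, cb) {
  a <- strsplit(ca, "")[[1]]; b <- strsplit(cb, "")[[1]]
  pos <- which(a != b)
  if (!length(pos)) return(c(sd = 0, nd = 0))
  walk <- function(ord, allowStop) {
    cur <- a; sd <- nd <- 0
    for (i in seq_along(ord)) {
      nxt <- cur; nxt[ord[i]] <- b[ord[i]]
      fromAA <- .oc[[paste(cur, collapse = "")]]
      toAA <- .oc[[paste(nxt, collapse = "")]]
      if (toAA == "*" && !allowStop) return(NULL)
      if (toAA == "*" && i < length(ord)) nd <- nd + 1
      else if (fromAA == toAA) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  perms <- oraclePerms(pos)
  res <- Filter(Negate(is.null), lapply(perms, walk, allowStop = FALSE))
  if (!length(res)) res <- lapply(perms, walk, allowStop = TRUE)
  colMeans(do.call(rbind, res))
}

# full NG estimate by brute force: enumeration + Jukes-Cantor
oracleNG <- function(codonsA, codonsB) {
  S <- (sum(vapply(codonsA, oracleSynSites, 1)) +
          sum(vapply(codonsB, oracleSynSites, 1))) / 2
  N <- 3 * length(codonsA) - S
  counts <- rowSums(vapply(seq_along(codonsA), function(i)
    oraclePairDiffs(codonsA[i], codonsB[i]), c(sd = 0, nd = 0)))
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  c(ka = jc(counts[["nd"]] / N), ks = jc(counts[["sd"]] / S))
}

# two-sided Fisher p by exhaustive hypergeometric enumeration
oracleFisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m + n == 0 || k == 0 || k == m + n || m == 0 || n == 0) return(1)
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  pObs <- dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Holm step-down by hand
oracleHolm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m); out[o] <- adj
  out
}

# random sense codon; optionally a mutated partner that stays sense
oracleRandomCodon <- function() sample(.oSense, 1)

randomCodonAlignment <- function(nCodons, mutateProb = 0.4,
                                 geneId = "rand") {
  a <- character(nCodons); b <- character(nCodons)
  for (i in seq_len(nCodons)) {
    a[i] <- oracleRandomCodon()
    if (runif(1) < mutateProb) {
      repeat {
        m <- strsplit(a[i], "")[[1]]
        for (p in sample(1:3, sample(1:2, 1)))
          m[p] <- sample(.oBases, 1)
        cand <- paste(m, collapse = "")
        if (.oc[[cand]] != "*") { b[i] <- cand; break }
      }
    } else b[i] <- a[i]
  }
  new("CodonAlignment", geneId = geneId, codonsA = a, codonsB = b)
}
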