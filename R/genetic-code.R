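# Genetic-code services shared by all estimators: degeneracy classes,
# mutation-pathway enumeration, site counting, distance corrections.
# All tables refer to the standard nuclear code and are built once per
# session into the package cache environment.

.kk <- new.env(parent = emptyenv())

.PURINES <- c("A", "G")
.PYRIMIDINES <- c("C", "T")

.isTransition <- function(b1, b2) {
  (b1 %in% .PURINES & b2 %in% .PURINES & b1 != b2) |
    (b1 %in% .PYRIMIDINES & b2 %in% .PYRIMIDINES & b1 != b2)
}

.codeTables <- function() {
  if (!is.null(.kk$codons)) return(invisible(NULL))
  gc <- Biostrings::GENETIC_CODE
  all64 <- names(gc)
  .kk$aa64 <- gc
  .kk$codons <- all64[gc != "*"]          # 61 sense codons
  .kk$stops <- all64[gc == "*"]
  .kk$aa <- gc[.kk$codons]
  # per-codon, per-position: number of synonymous single-base alternatives,
  # fold class, and whether the synonymous alternatives are all transversions
  # (the arginine irregularity at AGA/AGG/CGA/CGG first positions).
  nsyn <- matrix(0L, 61, 3, dimnames = list(.kk$codons, NULL))
  fold <- matrix(0L, 61, 3, dimnames = list(.kk$codons, NULL))
  invTwofold <- matrix(FALSE, 61, 3, dimnames = list(.kk$codons, NULL))
  for (ci in seq_along(.kk$codons)) {
    cod <- .kk$codons[ci]
    sp <- strsplit(cod, "")[[1]]
    for (p in 1:3) {
      alts <- setdiff(c("A", "C", "G", "T"), sp[p])
      synAlt <- logical(3); tsAlt <- logical(3)
      for (k in 1:3) {
        mut <- sp; mut[p] <- alts[k]
        mutc <- paste(mut, collapse = "")
        synAlt[k] <- gc[[mutc]] == gc[[cod]]     # change to stop is nonsyn
        tsAlt[k] <- .isTransition(sp[p], alts[k])
      }
      ns <- sum(synAlt)
      nsyn[ci, p] <- ns
      fold[ci, p] <- if (ns == 3L) 4L else if (ns == 0L) 0L else 2L
      # two-fold position whose synonymous change(s) are transversions only
      invTwofold[ci, p] <- fold[ci, p] == 2L && !any(synAlt & tsAlt)
    }
  }
  .kk$nsyn <- nsyn
  .kk$fold <- fold
  .kk$invTwofold <- invTwofold
  .kk$sitesNG <- rowSums(nsyn) / 3          # synonymous sites per codon (NG)
  .kk$pathCache <- new.env(parent = emptyenv())
  invisible(NULL)
}

.aaOf <- function(codons) {
  .codeTables()
  unname(.kk$aa64[codons])
}

#' Per-position degeneracy classes of a sense codon
#'
#' A codon position is four-fold degenerate if all three alternative bases
#' are synonymous, non-degenerate (0) if none is, and two-fold otherwise;
#' the isoleucine three-fold position is folded into the two-fold class
#' (LWL convention). Changes to stop codons count as nonsynonymous.
#'
#' @param codon a 3-letter sense codon (character).
#' @return integer(3) with values in {0, 2, 4}.
#' @examples
#' degeneracy("GGG")  # c(0, 0, 4)
#' degeneracy("TTT")  # c(0, 0, 2)
#' @export
degeneracy <- function(codon) {
  .codeTables()
  codon <- toupper(codon)
  if (!codon %in% .kk$codons) {
    if (codon %in% .kk$stops) stop("degeneracy() is undefined for stop codon ", codon)
    stop("not a valid codon: ", codon)
  }
  as.integer(.kk$fold[codon, ])
}

#' Enumerate mutation pathways between two sense codons
#'
#' All orderings of the differing positions are listed (k differences give
#' k! pathways); pathways passing through a stop codon are discarded. Each
#' step is labeled synonymous or nonsynonymous by comparing the encoded
#' residues before and after the step. If every ordering crosses a stop
#' codon, all orderings are retained as a fallback so that differences are
#' never silently dropped (flagged in the "stopFallback" attribute).
#'
#' @param codonA,codonB sense codons.
#' @return list of pathways; each pathway is a data.frame with one row per
#'   step (columns pos, from, to, syn, ts, tsR, tsY and the source/target
#'   codon of the step). Identical codons give an empty list.
#' @examples
#' length(enumeratePathways("TTT", "GTA"))  # 2
#' @export
enumeratePathways <- function(codonA, codonB) {
  .codeTables()
  codonA <- toupper(codonA); codonB <- toupper(codonB)
  stopifnot(codonA %in% .kk$codons, codonB %in% .kk$codons)
  .pathwaysFor(codonA, codonB)
}

# cached pathway enumeration; key "XXX>YYY"
.pathwaysFor <- function(codonA, codonB) {
  key <- paste0(codonA, ">", codonB)
  hit <- .kk$pathCache[[key]]
  if (!is.null(hit)) return(hit)
  a <- strsplit(codonA, "")[[1]]
  b <- strsplit(codonB, "")[[1]]
  diffPos <- which(a != b)
  if (!length(diffPos)) {
    res <- list()
    attr(res, "stopFallback") <- FALSE
    .kk$pathCache[[key]] <- res
    return(res)
  }
  perms <- .permutations(diffPos)
  buildPath <- function(ord, allowStop) {
    cur <- a
    steps <- vector("list", length(ord))
    for (i in seq_along(ord)) {
      p <- ord[i]
      nxt <- cur; nxt[p] <- b[p]
      fromCod <- paste(cur, collapse = ""); toCod <- paste(nxt, collapse = "")
      if (!allowStop && .kk$aa64[[toCod]] == "*") return(NULL)
      if (allowStop && .kk$aa64[[toCod]] == "*" && i < length(ord)) {
        # stop intermediate tolerated only in the fallback; label step by
        # whether the final-residue identity is preserved across it
        syn <- FALSE
      } else {
        syn <- .kk$aa64[[fromCod]] == .kk$aa64[[toCod]]
      }
      ts <- .isTransition(cur[p], b[p])
      steps[[i]] <- data.frame(
        pos = p, from = cur[p], to = b[p], syn = syn, ts = ts,
        tsR = ts && cur[p] %in% .PURINES,
        tsY = ts && cur[p] %in% .PYRIMIDINES,
        fromCodon = fromCod, toCodon = toCod,
        stringsAsFactors = FALSE)
      cur <- nxt
    }
    do.call(rbind, steps)
  }
  paths <- lapply(perms, buildPath, allowStop = FALSE)
  paths <- paths[!vapply(paths, is.null, logical(1))]
  fb <- FALSE
  if (!length(paths)) {          # all orderings blocked by a stop codon
    paths <- lapply(perms, buildPath, allowStop = TRUE)
    fb <- TRUE
  }
  attr(paths, "stopFallback") <- fb
  .kk$pathCache[[key]] <- paths
  paths
}

.permutations <- function(x) {
  n <- length(x)
  if (n == 1L) return(list(x))
  out <- list()
  for (i in seq_len(n))
    for (rest in .permutations(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

#' Nei-Gojobori synonymous/nonsynonymous site counts
#'
#' Per codon, the synonymous site count is the number of synonymous
#' single-base changes divided by 3, summed over the three positions
#' (changes to stop codons count as nonsynonymous); totals are averaged
#' between the two sequences, so N + S = 3 x number of codons exactly.
#'
#' @param aln a \linkS4class{CodonAlignment}.
#' @return named numeric c(N, S).
#' @export
countSitesNG <- function(aln) {
  .codeTables()
  sA <- sum(.kk$sitesNG[aln@codonsA])
  sB <- sum(.kk$sitesNG[aln@codonsB])
  S <- (sA + sB) / 2
  c(N = 3 * nCodons(aln) - S, S = S)
}

#' Build a CodonAlignment from an aligned sequence pair
#'
#' Codon columns containing any gap or N in either sequence are dropped as
#' whole codons, as are columns where either codon is a stop. The pair
#' length must be divisible by 3 (in frame).
#'
#' @param pair a \linkS4class{SequencePair}.
#' @return a \linkS4class{CodonAlignment}.
#' @export
buildCodonAlignment <- function(pair) {
  .codeTables()
  len <- nchar(pair@seqA)
  if (len %% 3L != 0L)
    stop("alignment length ", len, " of '", pair@geneId,
         "' is not divisible by 3")
  splitCodons <- function(s)
    substring(s, seq(1L, len, 3L), seq(3L, len, 3L))
  ca <- splitCodons(pair@seqA)
  cb <- splitCodons(pair@seqB)
  clean <- !grepl("[-N]", ca) & !grepl("[-N]", cb)
  keep <- clean
  keep[clean] <- .kk$aa64[ca[clean]] != "*" & .kk$aa64[cb[clean]] != "*"
  if (!any(keep))
    stop("no codon columns remain for '", pair@geneId,
         "' after gap/N/stop filtering")
  new("CodonAlignment", geneId = pair@geneId,
      codonsA = ca[keep], codonsB = cb[keep])
}

#' Jukes-Cantor distance
#'
#' d = -(3/4) log(1 - 4p/3). Saturated inputs (p >= 3/4) return NA rather
#' than raising a condition, so estimators can propagate NA flags.
#'
#' @param p raw proportion of difference in [0, 1].
#' @return corrected distance, or NA_real_ when undefined.
#' @export
distanceJC <- function(p) {
  stopifnot(p >= 0, p <= 1)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Kimura two-parameter distance with transition/transversion parts
#'
#' a = 1/(1 - 2P - Q), b = 1/(1 - 2Q); total d = log(a)/2 + log(b)/4; the
#' transversion part is log(b)/2 and the transition part is d minus it.
#' kappaHat = 2A/B is the implied transition/transversion rate ratio
#' (NA when B = 0).
#'
#' @param P,Q transition and transversion difference proportions.
#' @return named numeric c(d, ts, tv, kappaHat); all NA when a log argument
#'   is nonpositive (saturation).
#' @export
distanceK2P <- function(P, Q) {
  stopifnot(P >= 0, Q >= 0)
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0)
    return(c(d = NA_real_, ts = NA_real_, tv = NA_real_, kappaHat = NA_real_))
  d <- -log(a1) / 2 - log(a2) / 4
  tv <- -log(a2) / 2
  ts <- d - tv
  kap <- if (tv > 0) 2 * ts / tv else NA_real_
  c(d = d, ts = ts, tv = tv, kappaHat = kap)
}

#' Tamura-Nei (TN93) distance with separate purine/pyrimidine transitions
#'
#' Decomposes the corrected distance into purine-transition (A<->G),
#' pyrimidine-transition (C<->T) and transversion parts, and reports the
#' implied rate ratios kappaR = alphaR/beta and kappaY = alphaY/beta.
#'
#' @param P1,P2,Q proportions of A<->G, C<->T and transversion differences.
#' @param baseFreq named numeric frequencies of A, C, G, T (need not be
#'   normalized).
#' @return named numeric c(d, tsR, tsY, tv, kappaR, kappaY); NA-filled when
#'   a log argument is nonpositive or a frequency product vanishes.
#' @export
distanceTN93 <- function(P1, P2, Q, baseFreq) {
  stopifnot(P1 >= 0, P2 >= 0, Q >= 0)
  f <- baseFreq[c("A", "C", "G", "T")] / sum(baseFreq)
  piA <- f[["A"]]; piC <- f[["C"]]; piG <- f[["G"]]; piT <- f[["T"]]
  piR <- piA + piG; piY <- piC + piT
  bad <- c(d = NA_real_, tsR = NA_real_, tsY = NA_real_, tv = NA_real_,
           kappaR = NA_real_, kappaY = NA_real_)
  if (piA * piG <= 0 || piC * piT <= 0 || piR * piY <= 0) return(bad)
  k1 <- 2 * piA * piG / piR
  k2 <- 2 * piT * piC / piY
  w1 <- 1 - P1 / k1 - Q / (2 * piR)
  w2 <- 1 - P2 / k2 - Q / (2 * piY)
  w3 <- 1 - Q / (2 * piR * piY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) return(bad)
  tsR <- -k1 * log(w1) + k1 * piY * log(w3)
  tsY <- -k2 * log(w2) + k2 * piR * log(w3)
  tv <- -2 * piR * piY * log(w3)
  kR <- if (tv > 0) tsR * piR * piY / (tv * piA * piG) else NA_real_
  kY <- if (tv > 0) tsY * piR * piY / (tv * piT * piC) else NA_real_
  c(d = tsR + tsY + tv, tsR = tsR, tsY = tsY, tv = tv,
    kappaR = kR, kappaY = kY)
}

# Pathway-averaged difference summary for one codon pair: equal weight per
# surviving pathway. Returns sd/nd plus transition/transversion splits and
# per-fold-class allocations used by the LWL family (each step contributes
# half to the fold class of its position in the step's source codon and half
# to that in its target codon; inverted two-fold positions tracked apart).
.pairDiffSummary <- function(codonA, codonB) {
  key <- paste0("S:", codonA, ">", codonB)
  hit <- .kk$pathCache[[key]]
  if (!is.null(hit)) return(hit)
  paths <- .pathwaysFor(codonA, codonB)
  zero <- c(sd = 0, nd = 0, ts = 0, tv = 0, tsR = 0, tsY = 0,
            syn_tsR = 0, syn_tsY = 0, syn_tv = 0,
            non_tsR = 0, non_tsY = 0, non_tv = 0,
            ts0 = 0, ts2n = 0, ts2v = 0, ts4 = 0,
            tv0 = 0, tv2n = 0, tv2v = 0, tv4 = 0)
  if (!length(paths)) { .kk$pathCache[[key]] <- zero; return(zero) }
  acc <- zero
  w <- 1 / length(paths)
  for (pth in paths) {
    for (i in seq_len(nrow(pth))) {
      st <- pth[i, ]
      acc["sd"] <- acc["sd"] + w * st$syn
      acc["nd"] <- acc["nd"] + w * !st$syn
      acc["ts"] <- acc["ts"] + w * st$ts
      acc["tv"] <- acc["tv"] + w * !st$ts
      acc["tsR"] <- acc["tsR"] + w * st$tsR
      acc["tsY"] <- acc["tsY"] + w * st$tsY
      kind <- if (st$ts) { if (st$tsR) "tsR" else "tsY" } else "tv"
      lab <- paste0(if (st$syn) "syn_" else "non_", kind)
      acc[lab] <- acc[lab] + w
      # fold-class allocation (skip stop codons reachable only in fallback)
      for (codSide in c(st$fromCodon, st$toCodon)) {
        if (.kk$aa64[[codSide]] == "*") next
        fc <- .kk$fold[codSide, st$pos]
        cls <- if (fc == 2L) {
          if (.kk$invTwofold[codSide, st$pos]) "2v" else "2n"
        } else as.character(fc)
        lab2 <- paste0(if (st$ts) "ts" else "tv", cls)
        acc[lab2] <- acc[lab2] + w * 0.5
      }
    }
  }
  .kk$pathCache[[key]] <- acc
  acc
}

# Aggregate pathway-averaged difference counts over an alignment.
.alignmentDiffs <- function(aln) {
  .codeTables()
  keys <- paste(aln@codonsA, aln@codonsB)
  tab <- table(keys[aln@codonsA != aln@codonsB])
  acc <- NULL
  for (k in names(tab)) {
    cods <- strsplit(k, " ")[[1]]
    s <- .pairDiffSummary(cods[1], cods[2]) * as.integer(tab[[k]])
    acc <- if (is.null(acc)) s else acc + s
  }
  if (is.null(acc)) acc <- .pairDiffSummary("AAA", "AAA")  # zero vector
  acc
}

# Fold-class site totals averaged between the two sequences, with the
# inverted (arginine) two-fold positions reported separately.
.foldSiteCounts <- function(aln) {
  .codeTables()
  countOne <- function(cods) {
    f <- .kk$fold[cods, , drop = FALSE]
    inv <- .kk$invTwofold[cods, , drop = FALSE]
    c(L0 = sum(f == 0L), L2n = sum(f == 2L & !inv),
      L2v = sum(f == 2L & inv), L4 = sum(f == 4L))
  }
  (countOne(aln@codonsA) + countOne(aln@codonsB)) / 2
}

#' Write per-codon site-count debug table
#'
#' Dumps per-codon NG synonymous-site counts and fold classes of an
#' alignment to a TSV for inspection.
#'
#' @param aln a CodonAlignment.
#' @param path output TSV path.
#' @return invisibly, the data.frame written.
#' @export
dumpSiteCounts <- function(aln, path) {
  .codeTables()
  df <- data.frame(
    codon_index = seq_len(nCodons(aln)),
    codon_a = aln@codonsA, codon_b = aln@codonsB,
    syn_sites_a = .kk$sitesNG[aln@codonsA],
    syn_sites_b = .kk$sitesNG[aln@codonsB],
    fold_a = apply(.kk$fold[aln@codonsA, , drop = FALSE], 1, paste,
                   collapse = ","),
    fold_b = apply(.kk$fold[aln@codonsB, , drop = FALSE], 1, paste,
                   collapse = ","))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
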