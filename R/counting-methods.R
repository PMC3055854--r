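# The five approximate (counting) Ka/Ks methods.
#
# NG:   equal-weight mutation pathways, Jukes-Cantor correction of the
#       synonymous and nonsynonymous difference proportions.
# LWL:  sites split into non-degenerate (L0), two-fold (L2) and four-fold
#       (L4) classes, Kimura two-parameter correction per class, fixed
#       1/3 : 2/3 synonymous/nonsynonymous weighting of two-fold sites.
# LPB:  same site classes, but two-fold sites handled through the flexible
#       transition/transversion decomposition (Ks = avg(A2, A4) + B4,
#       Ka = avg(B0, B2) + A0).
# MLWL/MLPB: parent formulas with the arginine irregularity corrected.
#       Reassignment table: the inverted two-fold class is every sense
#       codon position whose synonymous alternatives are all
#       *transversions* - the first positions of AGA, AGG, CGA, CGG
#       (AGA<->CGA, AGG<->CGG are synonymous transversions) and the third
#       position of ATA (ATA<->ATT/ATC synonymous transversions, while
#       the transition ATA->ATG changes Ile to Met). These positions form
#       an "inverted" two-fold class in
#       which transversions feed the synonymous pool and transitions the
#       nonsynonymous pool, the mirror image of the normal two-fold rule.
#       MLWL additionally weights two-fold sites by an estimated
#       transition/transversion rate ratio kappa: the synonymous
#       opportunity of a normal two-fold site is kappa/(kappa+2) (1/3 at
#       kappa = 1, the LWL value) and 2/(kappa+2) at inverted sites.

.emptyEstimate <- function(geneId, method) {
  data.frame(gene_id = geneId, method = method,
             ka = NA_real_, ks = NA_real_, omega = NA_real_,
             kappa = NA_real_, kappa_R = NA_real_, kappa_Y = NA_real_,
             t = NA_real_,
             ka_na = TRUE, ks_na = TRUE, omega_na = TRUE,
             stringsAsFactors = FALSE)
}

.finishEstimate <- function(est) {
  est$ka_na <- is.na(est$ka)
  est$ks_na <- is.na(est$ks)
  est$omega <- ifelse(!est$ka_na & !est$ks_na & est$ks > 0,
                      est$ka / est$ks, NA_real_)
  est$omega_na <- is.na(est$omega)
  est
}

#' Estimate Ka and Ks with one of the five counting methods
#'
#' @param aln a \linkS4class{CodonAlignment}.
#' @param method one of "NG", "LWL", "MLWL", "LPB", "MLPB".
#' @return one-row data.frame with gene_id, method, ka, ks, omega, kappa
#'   (methods that estimate it), kappa_R, kappa_Y, t (NA for counting
#'   methods) and the NA flags ka_na, ks_na, omega_na. Saturation and zero
#'   denominators set NA flags and never raise conditions.
#' @export
estimateCounting <- function(aln, method = c("NG", "LWL", "MLWL", "LPB",
                                             "MLPB")) {
  method <- match.arg(method)
  if (!nCodons(aln)) stop("empty codon alignment")
  switch(method,
         NG = .estimateNG(aln),
         LWL = .estimateLWLFamily(aln, "LWL"),
         LPB = .estimateLWLFamily(aln, "LPB"),
         MLWL = .estimateLWLFamily(aln, "MLWL"),
         MLPB = .estimateLWLFamily(aln, "MLPB"))
}

.estimateNG <- function(aln) {
  ns <- countSitesNG(aln)
  d <- .alignmentDiffs(aln)
  est <- .emptyEstimate(geneId(aln), "NG")
  pn <- d[["nd"]] / ns[["N"]]
  ps <- d[["sd"]] / ns[["S"]]
  est$ka <- if (pn <= 1) distanceJC(min(pn, 1)) else NA_real_
  est$ks <- if (ps <= 1) distanceJC(min(ps, 1)) else NA_real_
  .finishEstimate(est)
}

# Shared engine for LWL, LPB, MLWL, MLPB. The M variants separate the
# inverted (arginine) two-fold class; the parents merge it into L2.
.estimateLWLFamily <- function(aln, method) {
  L <- .foldSiteCounts(aln)          # L0, L2n, L2v, L4 (averaged)
  d <- .alignmentDiffs(aln)
  modified <- method %in% c("MLWL", "MLPB")
  est <- .emptyEstimate(geneId(aln), method)

  # per-class K2P components; classes with zero sites contribute nothing
  comp <- function(ts, tv, L) {
    if (L <= 0) return(c(A = 0, B = 0, ok = 1))
    k <- distanceK2P(ts / L, tv / L)
    if (is.na(k[["d"]])) return(c(A = NA_real_, B = NA_real_, ok = 0))
    c(A = k[["ts"]], B = k[["tv"]], ok = 1)
  }
  if (modified) {
    L0 <- L[["L0"]]; L2n <- L[["L2n"]]; L2v <- L[["L2v"]]; L4 <- L[["L4"]]
    c0 <- comp(d[["ts0"]], d[["tv0"]], L0)
    c2n <- comp(d[["ts2n"]], d[["tv2n"]], L2n)
    c2v <- comp(d[["ts2v"]], d[["tv2v"]], L2v)
    c4 <- comp(d[["ts4"]], d[["tv4"]], L4)
  } else {
    L0 <- L[["L0"]]; L2n <- L[["L2n"]] + L[["L2v"]]; L2v <- 0
    L4 <- L[["L4"]]
    c0 <- comp(d[["ts0"]], d[["tv0"]], L0)
    c2n <- comp(d[["ts2n"]] + d[["ts2v"]], d[["tv2n"]] + d[["tv2v"]], L2n)
    c2v <- c(A = 0, B = 0, ok = TRUE)
    c4 <- comp(d[["ts4"]], d[["tv4"]], L4)
  }
  if (any(c(c0[["ok"]], c2n[["ok"]], c2v[["ok"]], c4[["ok"]]) == 0))
    return(.finishEstimate(est))     # saturation in some class -> NA

  A0 <- c0[["A"]]; B0 <- c0[["B"]]
  A2n <- c2n[["A"]]; B2n <- c2n[["B"]]
  A2v <- c2v[["A"]]; B2v <- c2v[["B"]]
  A4 <- c4[["A"]]; B4 <- c4[["B"]]

  if (method %in% c("LWL", "MLWL")) {
    kappa <- 1
    if (method == "MLWL") {
      # kappa from K2P-corrected transition/transversion distances pooled
      # over all site classes; fall back to 2 when undefined
      tot <- 3 * nCodons(aln)
      kk <- distanceK2P(d[["ts"]] / tot, d[["tv"]] / tot)
      kappa <- kk[["kappaHat"]]
      if (!is.finite(kappa) || kappa <= 0) {
        warning("MLWL kappa estimate undefined for '", geneId(aln),
                "'; falling back to kappa = 2")
        kappa <- 2
      }
      est$kappa <- kappa
    }
    w2 <- kappa / (kappa + 2)        # synonymous opportunity, normal 2-fold
    sSites <- L2n * w2 + L2v * (1 - w2) + L4
    nSites <- L0 + L2n * (1 - w2) + L2v * w2
    est$ks <- if (sSites > 0)
      (L2n * A2n + L2v * B2v + L4 * (A4 + B4)) / sSites else NA_real_
    est$ka <- if (nSites > 0)
      (L2n * B2n + L2v * A2v + L0 * (A0 + B0)) / nSites else NA_real_
  } else {                           # LPB / MLPB
    denS <- L2n + L2v + L4
    denN <- L0 + L2n + L2v
    est$ks <- if (denS > 0)
      (L2n * A2n + L2v * B2v + L4 * A4) / denS + B4 else NA_real_
    est$ka <- if (denN > 0)
      (L0 * B0 + L2n * B2n + L2v * A2v) / denN + A0 else NA_real_
  }
  .finishEstimate(est)
}
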