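# Markov codon-model simulator: ortholog-pair alignments with known
# divergence, transition/transversion ratios, omega and codon frequencies,
# plus the exactly computable expected Ka and Ks implied by the generator.

#' Simulation parameters
#'
#' Bundles the generative codon-model parameters. Codon frequencies default
#' to F3x4 built from a uniform base composition, which renormalizes to the
#' uniform distribution over the 61 sense codons.
#'
#' @param nCodons number of codons per sequence.
#' @param t divergence in expected substitutions per codon (whole pair).
#' @param kappa transition/transversion rate ratio (used when kappaR and
#'   kappaY are NULL).
#' @param omega nonsynonymous/synonymous rate ratio.
#' @param kappaR,kappaY optional separate purine/pyrimidine transition
#'   ratios.
#' @param pi optional named numeric(61) codon frequencies; default uniform
#'   F3x4.
#' @param baseFreq optional named c(A=,C=,G=,T=) base composition used for
#'   all three codon positions when pi is NULL.
#' @param seed integer seed, mandatory for reproducibility.
#' @return list of class "SimParams".
#' @export
simParams <- function(nCodons, t, kappa = 2, omega = 0.25,
                      kappaR = NULL, kappaY = NULL, pi = NULL,
                      baseFreq = NULL, seed) {
  stopifnot(nCodons >= 1, t >= 0, omega >= 0)
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  if (is.null(pi)) {
    if (is.null(baseFreq)) baseFreq <- c(A = .25, C = .25, G = .25, T = .25)
    bf <- baseFreq[c("A", "C", "G", "T")] / sum(baseFreq)
    pi <- .f3x4FromPositional(matrix(bf, 4, 3,
                                     dimnames = list(c("A", "C", "G", "T"),
                                                     NULL)))
  }
  structure(list(nCodons = as.integer(nCodons), t = t, kappa = kappa,
                 omega = omega, kappaR = kappaR, kappaY = kappaY,
                 pi = pi, seed = as.integer(seed)),
            class = "SimParams")
}

.simGenerator <- function(params, omega = params$omega) {
  buildRateMatrix(params$pi, kappa = params$kappa, omega = omega,
                  kappaR = params$kappaR, kappaY = params$kappaY)
}

#' Simulate one ortholog codon-pair alignment
#'
#' Ancestral codons are drawn i.i.d. from pi; the two lineages evolve
#' independently for t/2 each under the scaled generator (symmetric
#' two-lineage design, equivalent to one lineage of length t by
#' reversibility). Deterministic given the seed.
#'
#' @param params a [simParams()] object.
#' @param geneId label for the simulated pair.
#' @return a \linkS4class{CodonAlignment}.
#' @export
simulatePair <- function(params, geneId = "sim") {
  .codonModelTables()
  set.seed(params$seed)
  m <- .simGenerator(params)
  anc <- sample.int(61L, params$nCodons, replace = TRUE, prob = params$pi)
  if (params$t == 0) {
    cods <- .kk$codons[anc]
    return(new("CodonAlignment", geneId = geneId, codonsA = cods,
               codonsB = cods))
  }
  P <- .expmReversible(m$Q, params$pi, params$t / 2)
  evolve <- function(anc) {
    out <- integer(length(anc))
    for (i in unique(anc)) {
      sel <- anc == i
      out[sel] <- sample.int(61L, sum(sel), replace = TRUE, prob = P[i, ])
    }
    out
  }
  new("CodonAlignment", geneId = geneId,
      codonsA = .kk$codons[evolve(anc)],
      codonsB = .kk$codons[evolve(anc)])
}

#' Model-implied true Ka and Ks
#'
#' From the scaled generator: expected synonymous flux rhoS = sum of
#' pi_i q_ij over synonymous single-base pairs, nonsynonymous flux rhoN
#' likewise; site fractions come from the omega = 1 (mutational
#' opportunity) generator with the same kappa(s) and pi. Then
#' ka_true = t rhoN / (3 fracN) and ks_true = t rhoS / (3 fracS).
#'
#' @param params a [simParams()] object.
#' @return data.frame with ka_true, ks_true, omega_implied.
#' @export
expectedRates <- function(params) {
  fit <- .simGenerator(params)
  neutral <- .simGenerator(params, omega = 1)
  r <- .ratesFromModel(params$t, fit, neutral)
  data.frame(ka_true = r[["ka"]], ks_true = r[["ks"]],
             omega_implied = if (r[["ks"]] > 0) r[["ka"]] / r[["ks"]]
                             else NA_real_)
}

#' Run all (or selected) estimators on one alignment
#'
#' @param aln a \linkS4class{CodonAlignment}.
#' @param methods subset of the eight method tags.
#' @return data.frame with one row per method.
#' @export
estimateKaKs <- function(aln, methods = KAKS_METHODS) {
  methods <- match.arg(methods, KAKS_METHODS, several.ok = TRUE)
  rows <- lapply(methods, function(m) {
    switch(m,
           GY = estimateGY(aln),
           YN = estimateYN(aln, "YN"),
           MYN = estimateYN(aln, "MYN"),
           estimateCounting(aln, m))
  })
  do.call(rbind, rows)
}

#' Simulate a full genes x methods table with ground truth
#'
#' Per-gene omega is drawn from the configured distribution (default
#' uniform on [0.05, 0.5], reflecting predominantly purifying selection in
#' ortholog pairs); every gene gets a child seed derived from the root seed
#' by a fixed splitting rule, so per-gene results do not depend on
#' iteration order. Estimator NA values are retained in the table so that
#' downstream NA-handling paths are exercised.
#'
#' @param nGenes number of gene pairs.
#' @param nCodons codons per gene (default 300).
#' @param t divergence in substitutions per codon (default 0.5).
#' @param kappa transition/transversion ratio (default 2).
#' @param kappaR,kappaY optional separate transition ratios.
#' @param omegaRange range of the per-gene uniform omega draw.
#' @param seed root seed.
#' @param methods estimators to run (default all eight).
#' @return list with elements \code{table} (a \linkS4class{MethodTable}),
#'   \code{estimates} (long data.frame), \code{truth} (per-gene data.frame
#'   with gene_id, omega, t, kappa, ka_true, ks_true, seed) and
#'   \code{alignments} (list of CodonAlignment).
#' @export
simulateMethodTable <- function(nGenes, nCodons = 300, t = 0.5, kappa = 2,
                                kappaR = NULL, kappaY = NULL,
                                omegaRange = c(0.05, 0.5), seed,
                                methods = KAKS_METHODS) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  if (nGenes == 0L)
    return(list(table = MethodTable(data.frame(gene_id = character(),
                                               method = character(),
                                               ka = numeric(), ks = numeric(),
                                               omega = numeric())),
                estimates = NULL, truth = NULL, alignments = list()))
  set.seed(seed)
  childSeeds <- sample.int(.Machine$integer.max - 1L, nGenes)
  omegas <- stats::runif(nGenes, omegaRange[1], omegaRange[2])
  alns <- vector("list", nGenes)
  truth <- vector("list", nGenes)
  ests <- vector("list", nGenes)
  for (g in seq_len(nGenes)) {
    gid <- sprintf("gene%04d", g)
    p <- simParams(nCodons, t, kappa = kappa, omega = omegas[g],
                   kappaR = kappaR, kappaY = kappaY, seed = childSeeds[g])
    alns[[g]] <- simulatePair(p, geneId = gid)
    tr <- expectedRates(p)
    truth[[g]] <- data.frame(gene_id = gid, omega = omegas[g], t = t,
                             kappa = kappa, ka_true = tr$ka_true,
                             ks_true = tr$ks_true, seed = childSeeds[g])
    ests[[g]] <- estimateKaKs(alns[[g]], methods)
  }
  estimates <- do.call(rbind, ests)
  list(table = MethodTable(estimates), estimates = estimates,
       truth = do.call(rbind, truth), alignments = alns)
}

#' Export simulated alignments and truth table
#'
#' Writes the simulated pairs as AXT (and optionally paired FASTA), both
#' consumable by [readPairwiseAlignments()], plus the per-gene truth TSV.
#'
#' @param sim result of [simulateMethodTable()].
#' @param dir output directory (created if needed).
#' @param fasta also write paired FASTA.
#' @return invisibly, the directory.
#' @export
writeSimulation <- function(sim, dir, fasta = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pairs <- lapply(sim$alignments, function(a)
    SequencePair(geneId(a), paste(a@codonsA, collapse = ""),
                 paste(a@codonsB, collapse = "")))
  writePairwiseAlignments(pairs, file.path(dir, "pairs.axt"), "axt")
  if (fasta)
    writePairwiseAlignments(pairs, file.path(dir, "pairs.fasta"),
                            "fasta_pairs")
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
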