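# Workflow entry points wiring the modules together. Each writes plain
# TSV (with commented header lines carrying the configuration and seed)
# so every number is auditable; the inst/scripts/kaks.R front-end exposes
# them as shell subcommands.

.writeTsv <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readTsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run estimators over an alignment file
#'
#' Reads pairwise coding alignments, builds codon alignments (dropping
#' gap/N/stop codon columns) and writes one TSV row per (gene, method).
#'
#' @param input alignment file path.
#' @param output output TSV path.
#' @param format "axt" or "fasta_pairs".
#' @param methods method tags to run (default all eight).
#' @return invisibly, the estimates data.frame.
#' @export
cmdKaks <- function(input, output, format = c("axt", "fasta_pairs"),
                    methods = KAKS_METHODS) {
  format <- match.arg(format)
  pairs <- readPairwiseAlignments(input, format)
  if (!length(pairs)) stop("no alignment pairs in ", input)
  est <- do.call(rbind, lapply(pairs, function(p)
    estimateKaKs(buildCodonAlignment(p), methods)))
  .writeTsv(est, output,
            c(paste("kaks input:", input, "format:", format),
              paste("methods:", paste(methods, collapse = ","))))
  invisible(est)
}

#' Consistency analysis of a per-(gene, method) estimate table
#'
#' Filters NA-complete genes, writes per-gene divergence indexes, the
#' reference-vs-others shared-gene percentage matrix at the canonical
#' cut-offs, and a JSON summary with the Ka-vs-Ks rank-sum tests.
#'
#' @param estimates data.frame as written by [cmdKaks()] (or the file path
#'   to one).
#' @param outputDir directory for divergence.tsv, shared.tsv, summary.json.
#' @param reference reference method (default "GY").
#' @param cutoffs cut-off fractions (default the six canonical ones).
#' @return invisibly, a list with the three result objects.
#' @export
cmdConsistency <- function(estimates, outputDir, reference = "GY",
                           cutoffs = c(0.05, 0.10, 0.20, 0.30, 0.40, 0.50)) {
  if (is.character(estimates)) estimates <- .readTsv(estimates)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  tab <- filterCompleteGenes(MethodTable(estimates))
  div <- divergenceTable(tab)
  shared <- sharedGeneMatrix(tab, reference = reference, cutoffs = cutoffs)
  tests <- list(sd = compareDivergence(div, "sd"),
                range = compareDivergence(div, "range"))
  .writeTsv(div, file.path(outputDir, "divergence.tsv"),
            paste("reference:", reference))
  .writeTsv(shared, file.path(outputDir, "shared.tsv"),
            paste("cutoffs:", paste(cutoffs, collapse = ",")))
  jsonlite::write_json(tests, file.path(outputDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(divergence = div, shared = shared, tests = tests))
}

#' Classify genes by Ka from an estimate table
#'
#' @param estimates data.frame or TSV path from [cmdKaks()].
#' @param output output TSV path.
#' @param method which method's Ka to rank by (default "GY").
#' @param cutoff class-size fraction (default 0.10).
#' @param speciesId label for the species column.
#' @return invisibly, the classification data.frame.
#' @export
cmdClassify <- function(estimates, output, method = "GY", cutoff = 0.10,
                        speciesId = NA_character_) {
  if (is.character(estimates)) estimates <- .readTsv(estimates)
  sub <- estimates[estimates$method == method, c("gene_id", "ka")]
  cls <- classifyByKa(sub, cutoff = cutoff, speciesId = speciesId)
  .writeTsv(cls, output, paste("classify method:", method, "cutoff:", cutoff))
  invisible(cls)
}

#' Species network from per-species classification tables
#'
#' @param classFiles named character vector of classification TSV paths
#'   (names = species ids) or a named list of classification data.frames.
#' @param output edge-list TSV path.
#' @param retention see [buildSpeciesNetwork()].
#' @return invisibly, the edge data.frame.
#' @export
cmdNetwork <- function(classFiles, output, retention = "per_species") {
  tables <- if (is.character(classFiles)) lapply(classFiles, .readTsv)
            else classFiles
  edges <- buildSpeciesNetwork(tables, retention = retention)
  writeNetworkEdges(edges, output)
  invisible(edges)
}

#' Enrichment of a classified gene set
#'
#' @param classes classification data.frame or TSV path.
#' @param annotation annotation data.frame or TSV path (gene_id, level,
#'   category_id, category_name).
#' @param output output TSV path.
#' @param class which class to test ("fast" or "slow").
#' @param threshold enrichment cut-off (default 0.1).
#' @return invisibly, the enrichment data.frame.
#' @export
cmdEnrich <- function(classes, annotation, output, class = "fast",
                      threshold = 0.1) {
  if (is.character(classes)) classes <- .readTsv(classes)
  if (is.character(annotation)) annotation <- .readTsv(annotation)
  res <- enrich(classes$gene_id[classes$class == class], classes$gene_id,
                annotation, threshold = threshold)
  .writeTsv(res, output, paste("enrich class:", class, "threshold:",
                               threshold))
  invisible(res)
}

#' Expression-by-class comparison
#'
#' @param classes classification data.frame or TSV path.
#' @param tpm expression data.frame or TSV path (gene_id, tpm).
#' @param output output TSV path for the test table.
#' @return invisibly, the [compareExpressionByClass()] result.
#' @export
cmdExpression <- function(classes, tpm, output) {
  if (is.character(classes)) classes <- .readTsv(classes)
  if (is.character(tpm)) tpm <- .readTsv(tpm)
  res <- compareExpressionByClass(classes, tpm)
  .writeTsv(res$tests, output,
            c("expression rank-sum tests",
              paste(utils::capture.output(print(res$summary)),
                    collapse = " | ")))
  invisible(res)
}

#' Simulate alignments and truth table to disk
#'
#' @param outputDir directory for pairs.axt (+ pairs.fasta) and truth.tsv.
#' @param nGenes,nCodons,t,kappa,omegaRange,seed see
#'   [simulateMethodTable()].
#' @param fasta also write paired FASTA.
#' @param methods estimators to run on the simulated pairs while building
#'   the truth table; "NG" suffices when only the alignments are wanted.
#' @return invisibly, the simulation list.
#' @export
cmdSimulate <- function(outputDir, nGenes = 100, nCodons = 300, t = 0.5,
                        kappa = 2, omegaRange = c(0.05, 0.5), seed = 1,
                        fasta = FALSE, methods = "NG") {
  sim <- simulateMethodTable(nGenes, nCodons = nCodons, t = t, kappa = kappa,
                             omegaRange = omegaRange, seed = seed,
                             methods = methods)
  writeSimulation(sim, outputDir, fasta = fasta)
  invisible(sim)
}
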