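# Ka-percentile classification of genes into slow / intermediate / fast
# evolutionary classes, cross-species shared-class counts, and the
# species network built from shared-class coefficients.

#' Classify genes by Ka percentile
#'
#' Genes are sorted ascending by Ka (stable tie-break by gene id); with
#' k = floor(cutoff x n), ranks 1..k are slow-evolving, ranks n-k+1..n are
#' fast-evolving, and the k genes centered on the median rank (window
#' starting at ceiling((n-k)/2)) are intermediately-evolving; everything
#' else is unclassified. NA Ka values are treated as 0 before sorting
#' (NA values typically arise from 100% identical pairs), so NA genes sort
#' to the slow end. This NA -> 0 rule applies here only, never in the
#' consistency analyses, which instead eliminate NA genes.
#'
#' @param genes data.frame with columns gene_id and ka (NA allowed).
#' @param cutoff class-size fraction (default 0.10).
#' @param speciesId optional label stored in the species_id column.
#' @return data.frame: species_id, gene_id, ka (NA replaced by 0), rank,
#'   class (factor slow/intermediate/fast/unclassified), in rank order.
#' @export
classifyByKa <- function(genes, cutoff = 0.10, speciesId = NA_character_) {
  stopifnot(all(c("gene_id", "ka") %in% names(genes)))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene ids in classification input")
  n <- nrow(genes)
  k <- floor(cutoff * n)
  if (k < 1L)
    stop("too few genes (", n, ") for cutoff ", cutoff,
         ": floor(cutoff * n) must be >= 1")
  ka <- ifelse(is.na(genes$ka), 0, genes$ka)
  o <- order(ka, genes$gene_id)
  rank <- integer(n); rank[o] <- seq_len(n)
  cls <- rep("unclassified", n)
  cls[rank <= k] <- "slow"
  cls[rank > n - k] <- "fast"
  start <- ceiling((n - k) / 2)
  mid <- rank > start & rank <= start + k & cls == "unclassified"
  cls[mid] <- "intermediate"
  out <- data.frame(species_id = speciesId, gene_id = genes$gene_id,
                    ka = ka, rank = rank,
                    class = factor(cls, levels = c("slow", "intermediate",
                                                   "fast", "unclassified")))
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.classSet <- function(tbl, class) tbl$gene_id[tbl$class == class]

#' Count genes of a class shared by every listed species
#'
#' @param tables named list of [classifyByKa()] tables, one per species.
#' @param class "fast" or "slow".
#' @param speciesSubset species names to intersect (default all).
#' @return integer count of genes in the class in every listed species.
#' @export
sharedClassCounts <- function(tables, class = c("fast", "slow"),
                              speciesSubset = names(tables)) {
  class <- match.arg(class)
  unknown <- setdiff(speciesSubset, names(tables))
  if (length(unknown))
    stop("unknown species label(s): ", paste(unknown, collapse = ", "))
  sets <- lapply(tables[speciesSubset], .classSet, class = class)
  length(Reduce(intersect, sets))
}

#' Build the shared-class species network
#'
#' For every unordered species pair the coefficient of a class is the
#' number of shared genes of that class divided by the total number of
#' genes shared between the pair; the "both" class sums the fast and slow
#' coefficients. Edge retention keeps, per species (default) or per pair,
#' the largest two coefficients; an edge is retained when either endpoint
#' ranks it in its top two. Pairs sharing no genes yield NA coefficients
#' and are excluded.
#'
#' @param tables named list of per-species classification tables (at least
#'   3 species).
#' @param retention "per_species" (top-2 per species, the default reading
#'   of the rule) or "per_pair" (keep the best class per pair).
#' @return data.frame: species_a, species_b, class (fast/slow/both),
#'   coefficient, retained.
#' @export
buildSpeciesNetwork <- function(tables, retention = c("per_species",
                                                      "per_pair")) {
  retention <- match.arg(retention)
  sp <- names(tables)
  if (length(sp) < 3L) stop("need at least 3 species")
  combs <- utils::combn(sp, 2)
  rows <- list()
  for (j in seq_len(ncol(combs))) {
    a <- combs[1, j]; b <- combs[2, j]
    sharedAll <- intersect(tables[[a]]$gene_id, tables[[b]]$gene_id)
    if (!length(sharedAll)) next
    cf <- length(intersect(.classSet(tables[[a]], "fast"),
                           .classSet(tables[[b]], "fast"))) / length(sharedAll)
    cs <- length(intersect(.classSet(tables[[a]], "slow"),
                           .classSet(tables[[b]], "slow"))) / length(sharedAll)
    rows[[length(rows) + 1L]] <- data.frame(
      species_a = a, species_b = b,
      class = c("fast", "slow", "both"),
      coefficient = c(cf, cs, cf + cs))
  }
  edges <- do.call(rbind, rows)
  if (is.null(edges)) stop("no species pair shares any gene")
  edges$retained <- FALSE
  for (cl in unique(edges$class)) {
    sub <- edges$class == cl
    if (retention == "per_species") {
      for (s in sp) {
        inc <- which(sub & (edges$species_a == s | edges$species_b == s))
        if (!length(inc)) next
        # stable deterministic tie-break by the partner labels
        o <- order(-edges$coefficient[inc], edges$species_a[inc],
                   edges$species_b[inc])
        edges$retained[inc[o][seq_len(min(2L, length(inc)))]] <- TRUE
      }
    }
  }
  if (retention == "per_pair") {
    # alternative reading of the rule: keep, per species pair, the single
    # best class edge (fast vs slow); combined edges are informational
    edges$retained <- FALSE
    for (j in seq_len(ncol(combs))) {
      inc <- which(edges$class %in% c("fast", "slow") &
                     edges$species_a == combs[1, j] &
                     edges$species_b == combs[2, j])
      if (!length(inc)) next
      edges$retained[inc[which.max(edges$coefficient[inc])]] <- TRUE
    }
  }
  rownames(edges) <- NULL
  edges
}

#' Write a network edge list
#'
#' Plain TSV edge list (species_a, species_b, class, coefficient,
#' retained) consumable by common network viewers.
#'
#' @param edges output of [buildSpeciesNetwork()].
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
writeNetworkEdges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
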