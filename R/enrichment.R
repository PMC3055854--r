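# Functional-category enrichment of an evolutionary-rate gene class
# against a background (Fisher's exact test with Holm step-down
# correction, cut-off 0.1), and the expression-by-class comparison.

#' Two-sided Fisher exact p for a 2x2 table
#'
#' The two-sided p-value sums the hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed the
#' observed table's (up to a small relative tolerance for ties); this is
#' the convention of \code{stats::fisher.test}, which performs the
#' computation. Degenerate margins give p = 1.
#'
#' @param a,b,c,d nonnegative integer cell counts: a = class genes in the
#'   category, b = class genes outside it, c = background-only genes in the
#'   category, d = the rest.
#' @return p-value in (0, 1].
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  if (sum(cells) == 0 || (a + b == 0) || (c + d == 0) ||
      (a + c == 0) || (b + d == 0)) return(1)
  stats::fisher.test(matrix(cells, 2, 2, byrow = TRUE))$p.value
}

#' Holm (Bonferroni step-down) adjustment
#'
#' Sorted ascending, adjusted_i = max over j <= i of (m - j + 1) p_(j),
#' capped at 1, mapped back to input order. Delegates to
#' \code{stats::p.adjust(method = "holm")}.
#'
#' @param pvals numeric vector in [0, 1].
#' @return adjusted p-values in input order.
#' @export
holmAdjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1 | is.na(pvals)))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(pvals, method = "holm")
}

#' Category enrichment of a gene class against a background
#'
#' One 2x2 Fisher test per category with at least one class gene; Holm
#' correction is applied within each annotation level (the correction
#' family). A category is called enriched when the (adjusted, by default)
#' p-value is below the threshold and the observed class count exceeds its
#' expectation under independence (direction filter), so depleted
#' categories are never reported as enriched.
#'
#' @param classGenes character vector of class gene ids (subset of
#'   background).
#' @param background character vector of all background gene ids
#'   (typically every gene with an estimated Ka).
#' @param annotation data.frame with columns gene_id, level, category_id,
#'   category_name; genes may carry multiple categories and unannotated
#'   genes count in the b/d cells.
#' @param threshold enrichment cut-off (default 0.1).
#' @param useAdjusted apply the threshold to the Holm-adjusted p (default)
#'   or to the raw p.
#' @return data.frame of EnrichmentResult rows: level, category_id,
#'   category_name, a, b, c, d, p_raw, p_adj, enriched.
#' @export
enrich <- function(classGenes, background, annotation, threshold = 0.1,
                   useAdjusted = TRUE) {
  if (!length(classGenes)) stop("empty gene class")
  stopifnot(all(c("gene_id", "level", "category_id", "category_name") %in%
                names(annotation)))
  if (!all(classGenes %in% background))
    stop("class genes must be a subset of the background")
  classGenes <- unique(classGenes)
  background <- unique(background)
  nClass <- length(classGenes)
  nBgOnly <- length(background) - nClass
  ann <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  out <- list()
  for (lev in unique(ann$level)) {
    al <- ann[ann$level == lev, , drop = FALSE]
    cats <- unique(al$category_id[al$gene_id %in% classGenes])
    if (!length(cats)) next
    rows <- lapply(cats, function(cid) {
      members <- unique(al$gene_id[al$category_id == cid])
      a <- length(intersect(members, classGenes))
      b <- nClass - a
      cc <- length(members) - a
      d <- nBgOnly - cc
      data.frame(level = lev, category_id = cid,
                 category_name = al$category_name[al$category_id ==
                                                    cid][1],
                 a = a, b = b, c = cc, d = d,
                 p_raw = fisherExact2x2(a, b, cc, d))
    })
    df <- do.call(rbind, rows)
    df$p_adj <- holmAdjust(df$p_raw)
    expected <- nClass * (df$a + df$c) / length(background)
    pUsed <- if (useAdjusted) df$p_adj else df$p_raw
    df$enriched <- pUsed < threshold & df$a > expected
    out[[lev]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Expression levels by evolutionary class
#'
#' Two-sided Wilcoxon rank-sum tests for slow vs fast, intermediate vs
#' fast and slow vs intermediate, on transcripts-per-million (TPM)
#' expression values, plus per-class means and medians. Genes without an
#' expression value are dropped (count reported).
#'
#' @param classes a [classifyByKa()] table.
#' @param tpm data.frame with columns gene_id and tpm.
#' @return list with \code{tests} (comparison, statistic, p.value),
#'   \code{summary} (class, n, mean, median) and \code{n_dropped}.
#' @export
compareExpressionByClass <- function(classes, tpm) {
  stopifnot(all(c("gene_id", "tpm") %in% names(tpm)))
  merged <- merge(classes, tpm, by = "gene_id")
  nDropped <- nrow(classes) - nrow(merged)
  if (nDropped > 0)
    message(nDropped, " genes without expression values dropped")
  byClass <- split(merged$tpm, merged$class)
  pairs <- list(c("slow", "fast"), c("intermediate", "fast"),
                c("slow", "intermediate"))
  tests <- lapply(pairs, function(p) {
    x <- byClass[[p[1]]]; y <- byClass[[p[2]]]
    if (length(x) < 2L || length(y) < 2L)
      stop("need >= 2 genes with expression in classes ",
           p[1], " and ", p[2])
    wt <- stats::wilcox.test(x, y)
    data.frame(comparison = paste(p, collapse = "_vs_"),
               statistic = unname(wt$statistic), p.value = wt$p.value)
  })
  cls <- c("slow", "intermediate", "fast")
  summary <- data.frame(
    class = cls,
    n = vapply(byClass[cls], length, integer(1)),
    mean = vapply(byClass[cls], mean, numeric(1)),
    median = vapply(byClass[cls], stats::median, numeric(1)),
    row.names = NULL)
  list(tests = do.call(rbind, tests), summary = summary,
       n_dropped = nDropped)
}
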