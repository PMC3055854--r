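# Cross-method consistency statistics: NA-complete filtering, divergence
# indexes (sd/mean and range/mean over the methods), the Wilcoxon rank-sum
# comparison of Ka vs Ks divergence, and shared-gene percentages at ranked
# cut-offs.

#' Keep only genes with complete Ka and Ks across all methods
#'
#' Mirrors the elimination rule used before computing divergence indexes:
#' a gene is dropped when any method returned NA (not applicable or
#' infinite) for Ka or Ks. Gene order is preserved.
#'
#' @param table a \linkS4class{MethodTable}.
#' @return a filtered MethodTable (empty, with a warning, if no gene is
#'   complete).
#' @export
filterCompleteGenes <- function(table) {
  keep <- stats::complete.cases(table@ka) & stats::complete.cases(table@ks)
  if (!any(keep)) warning("no genes with complete Ka and Ks; empty table")
  new("MethodTable", genes = table@genes[keep], methods = table@methods,
      ka = table@ka[keep, , drop = FALSE],
      ks = table@ks[keep, , drop = FALSE],
      omega = table@omega[keep, , drop = FALSE])
}

#' Cross-method divergence index of one gene's estimates
#'
#' Mode "sd_over_mean": sample standard deviation (n-1 denominator)
#' divided by the mean. Mode "range_over_mean": (max - min)/mean. Both are
#' scale-invariant; a zero mean gives NA.
#'
#' @param values numeric vector (one value per method, all defined).
#' @param mode "sd_over_mean" or "range_over_mean".
#' @return numeric(1), NA_real_ when the mean is zero.
#' @export
divergenceIndex <- function(values, mode = c("sd_over_mean",
                                             "range_over_mean")) {
  mode <- match.arg(mode)
  stopifnot(!anyNA(values))
  m <- mean(values)
  if (m == 0) return(NA_real_)
  if (mode == "sd_over_mean") stats::sd(values) / m
  else (max(values) - min(values)) / m
}

#' Per-gene divergence records for a MethodTable
#'
#' @param table a \linkS4class{MethodTable}, normally NA-complete (see
#'   [filterCompleteGenes()]).
#' @return data.frame: gene_id, d_sd_ka, d_sd_ks, d_range_ka, d_range_ks.
#' @export
divergenceTable <- function(table) {
  idx <- function(m, mode) apply(m, 1, function(v)
    if (anyNA(v)) NA_real_ else divergenceIndex(v, mode))
  data.frame(gene_id = table@genes,
             d_sd_ka = idx(table@ka, "sd_over_mean"),
             d_sd_ks = idx(table@ks, "sd_over_mean"),
             d_range_ka = idx(table@ka, "range_over_mean"),
             d_range_ks = idx(table@ks, "range_over_mean"),
             row.names = NULL)
}

#' Rank-sum comparison of Ka vs Ks divergence indexes
#'
#' Two-sided Wilcoxon rank-sum test of the per-gene Ka divergence indexes
#' against the Ks ones (exact for small samples without ties, normal
#' approximation with tie correction otherwise).
#'
#' @param records output of [divergenceTable()].
#' @param mode which index pair to compare.
#' @return list with statistic, p.value, median_ka, median_ks.
#' @export
compareDivergence <- function(records, mode = c("sd", "range")) {
  mode <- match.arg(mode)
  ka <- records[[paste0("d_", mode, "_ka")]]
  ks <- records[[paste0("d_", mode, "_ks")]]
  ok <- !is.na(ka) & !is.na(ks)
  ka <- ka[ok]; ks <- ks[ok]
  if (length(ka) < 2L) stop("need at least 2 genes with defined indexes")
  wt <- stats::wilcox.test(ka, ks)
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       median_ka = stats::median(ka), median_ks = stats::median(ks))
}

#' Shared-gene percentage between two methods at a ranked cut-off
#'
#' Genes are ranked by the chosen statistic under each method (stable
#' tie-break by gene id); the top (fast) or bottom (slow) floor(cutoff x n)
#' genes per method are intersected and the overlap reported as a
#' percentage of the set size.
#'
#' @param table a \linkS4class{MethodTable} without NA in the chosen
#'   statistic (genes with NA are dropped with a warning).
#' @param statistic "ka", "ks" or "omega".
#' @param reference,other method tags.
#' @param cutoff fraction of genes per set; the canonical values are 0.05,
#'   0.10, 0.20, 0.30, 0.40, 0.50 (others are permitted but flagged with a
#'   message).
#' @param tail "fast" (largest values) or "slow" (smallest).
#' @return percentage in [0, 100].
#' @export
sharedGenePercentage <- function(table, statistic = c("ka", "ks", "omega"),
                                 reference = "GY", other, cutoff = 0.10,
                                 tail = c("fast", "slow")) {
  statistic <- match.arg(statistic)
  tail <- match.arg(tail)
  stopifnot(reference %in% table@methods, other %in% table@methods)
  if (!isTRUE(all.equal(cutoff, round(cutoff, 2))) ||
      !(round(cutoff, 2) %in% c(0.05, 0.10, 0.20, 0.30, 0.40, 0.50)))
    message("non-canonical cut-off ", cutoff)
  m <- slot(table, statistic)
  ok <- !is.na(m[, reference]) & !is.na(m[, other])
  if (!all(ok)) {
    warning(sum(!ok), " genes with NA ", statistic, " dropped")
    m <- m[ok, , drop = FALSE]
  }
  n <- nrow(m)
  k <- floor(cutoff * n)
  if (k < 1L) stop("floor(cutoff * n) is zero (n = ", n, ")")
  genes <- rownames(m)
  pick <- function(v) {
    o <- if (tail == "fast") order(-v, genes) else order(v, genes)
    genes[o[seq_len(k)]]
  }
  100 * length(intersect(pick(m[, reference]), pick(m[, other]))) / k
}

#' Shared-gene percentage matrix over cut-offs and methods
#'
#' Convenience wrapper computing the GY-vs-others (or any reference)
#' shared-gene percentages for every cut-off, statistic and comparison
#' method.
#'
#' @param table a \linkS4class{MethodTable}.
#' @param reference reference method (default "GY").
#' @param cutoffs fractions (default the six canonical ones).
#' @param statistics which statistics to tabulate.
#' @param tail "fast" or "slow".
#' @return long data.frame: statistic, cutoff, reference, other, tail,
#'   shared_pct.
#' @export
sharedGeneMatrix <- function(table, reference = "GY",
                             cutoffs = c(0.05, 0.10, 0.20, 0.30, 0.40, 0.50),
                             statistics = c("ka", "ks", "omega"),
                             tail = "fast") {
  others <- setdiff(table@methods, reference)
  grid <- expand.grid(statistic = statistics, cutoff = cutoffs,
                      other = others, stringsAsFactors = FALSE)
  grid$reference <- reference
  grid$tail <- tail
  grid$shared_pct <- mapply(function(s, co, ot)
    sharedGenePercentage(table, s, reference, ot, co, tail),
    grid$statistic, grid$cutoff, grid$other)
  grid[c("statistic", "cutoff", "reference", "other", "tail", "shared_pct")]
}
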