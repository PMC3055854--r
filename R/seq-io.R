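# Reading/writing pairwise coding alignments (AXT blocks, paired FASTA),
# back-translation of protein alignments, and per-pair / per-dataset
# quality statistics.

#' Read pairwise coding alignments
#'
#' Two dialects are supported. \code{"axt"}: blocks of a header line plus
#' two aligned sequence lines, blocks separated by blank lines; the pair
#' identifier is the second whitespace-separated header field when present
#' (alignment coordinates in the header are ignored). \code{"fasta_pairs"}:
#' consecutive records are paired (1st with 2nd, 3rd with 4th, ...); the
#' identifier of the first record of each pair labels the pair.
#'
#' @param source path to the alignment file.
#' @param format "axt" or "fasta_pairs".
#' @return list of \linkS4class{SequencePair} objects in file order.
#' @export
readPairwiseAlignments <- function(source, format = c("axt", "fasta_pairs")) {
  format <- match.arg(format)
  if (!file.exists(source)) stop("no such file: ", source)
  if (format == "axt") .readAxt(source) else .readFastaPairs(source)
}

.readAxt <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  # split into blocks at blank lines
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(blank)
  pairs <- list()
  for (g in split(lines[!blank], grp[!blank])) {
    if (!length(g)) next
    if (length(g) != 3L)
      stop("malformed AXT block (expected header + 2 sequence lines, got ",
           length(g), " lines): ", g[1])
    toks <- strsplit(trimws(g[1]), "\\s+")[[1]]
    id <- if (length(toks) >= 2L) toks[2] else toks[1]
    if (nchar(g[2]) != nchar(g[3]))
      stop("malformed pair '", id, "': aligned lengths ", nchar(g[2]),
           " and ", nchar(g[3]))
    pairs[[length(pairs) + 1L]] <- SequencePair(id, g[2], g[3])
  }
  pairs
}

.readFastaPairs <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) %% 2L != 0L)
    stop("FASTA pairing error: odd number of records (", length(recs), ")")
  pairs <- vector("list", length(recs) %/% 2L)
  for (i in seq_along(pairs)) {
    a <- recs[[2L * i - 1L]]; b <- recs[[2L * i]]
    idA <- names(recs)[2L * i - 1L]
    if (length(a) != length(b))
      stop("malformed pair '", idA, "': aligned lengths ", length(a),
           " and ", length(b))
    pairs[[i]] <- SequencePair(idA, as.character(a), as.character(b))
  }
  pairs
}

#' Write pairwise alignments
#'
#' Inverse of [readPairwiseAlignments()]; AXT blocks are written as
#' "index geneId" headers plus the two sequences, FASTA as consecutive
#' paired records (geneId and geneId_2).
#'
#' @param pairs list of SequencePair objects.
#' @param path output path.
#' @param format "axt" or "fasta_pairs".
#' @return invisibly, \code{path}.
#' @export
writePairwiseAlignments <- function(pairs, path,
                                    format = c("axt", "fasta_pairs")) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "axt") {
    for (i in seq_along(pairs)) {
      p <- pairs[[i]]
      writeLines(c(paste(i - 1L, p@geneId), p@seqA, p@seqB, ""), con)
    }
  } else {
    for (p in pairs)
      writeLines(c(paste0(">", p@geneId), p@seqA,
                   paste0(">", p@geneId, "_2"), p@seqB), con)
  }
  invisible(path)
}

#' Back-translate a pair of aligned protein sequences to codon alignments
#'
#' Each residue in the protein alignment is replaced by its source codon
#' from the corresponding (unaligned) CDS, and each residue gap by "---".
#' Terminal stop codons in the CDS are stripped beforehand. Every CDS codon
#' must translate to its aligned residue under the standard code.
#'
#' @param protAlnA,protAlnB aligned amino-acid strings (gaps "-").
#' @param cdsA,cdsB ungapped coding sequences.
#' @param geneId label for the resulting pair.
#' @return a \linkS4class{SequencePair} of codon-aligned nucleotides.
#' @examples
#' backtranslate("M-K", "MAK", "ATGAAA", "ATGGCGAAA")
#' @export
backtranslate <- function(protAlnA, protAlnB, cdsA, cdsB, geneId = "pair") {
  one <- function(prot, cds, tag) {
    prot <- toupper(prot)
    cds <- toupper(chartr("Uu", "Tt", cds))
    res <- strsplit(prot, "")[[1]]
    nres <- sum(res != "-")
    # strip one terminal stop codon if present
    if (nchar(cds) >= 3L) {
      last <- substr(cds, nchar(cds) - 2L, nchar(cds))
      if (.aaOf(last) == "*") cds <- substr(cds, 1L, nchar(cds) - 3L)
    }
    if (nchar(cds) != 3L * nres)
      stop("frame error in ", tag, " ('", geneId, "'): ", nres,
           " residues but ", nchar(cds), " nt of CDS")
    out <- character(length(res))
    ci <- 0L
    for (i in seq_along(res)) {
      if (res[i] == "-") { out[i] <- "---"; next }
      ci <- ci + 1L
      cod <- substr(cds, 3L * ci - 2L, 3L * ci)
      if (.aaOf(cod) != res[i])
        stop("back-translation mismatch in ", tag, " ('", geneId,
             "') at residue ", ci, ": codon ", cod, " encodes ",
             .aaOf(cod), ", alignment has ", res[i])
      out[i] <- cod
    }
    paste(out, collapse = "")
  }
  if (nchar(protAlnA) != nchar(protAlnB))
    stop("protein alignment length mismatch for '", geneId, "'")
  SequencePair(geneId, one(protAlnA, cdsA, "sequence A"),
               one(protAlnB, cdsB, "sequence B"))
}

#' Per-pair alignment quality statistics
#'
#' Identity is computed over columns where neither sequence has a gap; the
#' gap percentage denominator is all columns; the N fraction is the count
#' of N characters over the count of
#' nucleotide (non-gap) characters in both sequences.
#'
#' @param pair a \linkS4class{SequencePair}.
#' @return one-row data.frame: gene_id, pct_identity (NA if no non-gap
#'   columns), pct_gap, n_fraction, has_n.
#' @export
qcPair <- function(pair) {
  a <- strsplit(pair@seqA, "")[[1]]
  b <- strsplit(pair@seqB, "")[[1]]
  gapCol <- a == "-" | b == "-"
  nongap <- !gapCol
  ident <- if (any(nongap))
    100 * sum(a[nongap] == b[nongap]) / sum(nongap)
  else NA_real_
  nNt <- sum(a != "-") + sum(b != "-")
  nN <- sum(a == "N") + sum(b == "N")
  data.frame(gene_id = pair@geneId,
             pct_identity = ident,
             pct_gap = 100 * mean(gapCol),
             n_fraction = if (nNt > 0) nN / nNt else 0,
             has_n = nN > 0L)
}

#' Dataset-level quality summary
#'
#' @param records data.frame of [qcPair()] rows.
#' @return one-row data.frame: mean/sd of the N fraction, percentage of
#'   pairs containing any N, and mean identity over pairs with defined
#'   identity.
#' @export
qcDataset <- function(records) {
  if (!nrow(records)) stop("empty QC record set")
  data.frame(
    n_pairs = nrow(records),
    mean_n_fraction = mean(records$n_fraction),
    sd_n_fraction = stats::sd(records$n_fraction),
    pct_pairs_with_n = 100 * mean(records$has_n),
    mean_identity = mean(records$pct_identity, na.rm = TRUE))
}
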