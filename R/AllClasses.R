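#' @import methods
NULL

#' SequencePair: one pairwise-aligned coding sequence pair
#'
#' Holds a pair of aligned nucleotide sequences (one one-to-one ortholog
#' pair), normalized to uppercase ACGTN- with U mapped to T. Both sequences
#' must have equal length.
#'
#' @slot geneId character(1) gene/pair label.
#' @slot seqA,seqB aligned nucleotide strings (may contain N and gap "-").
#' @exportClass SequencePair
setClass("SequencePair",
  representation(geneId = "character", seqA = "character", seqB = "character"))

setValidity("SequencePair", function(object) {
  msg <- NULL
  if (length(object@geneId) != 1L) msg <- c(msg, "geneId must be length 1")
  if (length(object@seqA) != 1L || length(object@seqB) != 1L)
    msg <- c(msg, "seqA and seqB must be single strings")
  if (nchar(object@seqA) != nchar(object@seqB))
    msg <- c(msg, sprintf("unequal aligned lengths for '%s': %d vs %d",
                          object@geneId, nchar(object@seqA), nchar(object@seqB)))
  bad <- gsub("[ACGTN-]", "", paste0(object@seqA, object@seqB))
  if (nzchar(bad))
    msg <- c(msg, sprintf("illegal characters in '%s': %s", object@geneId,
                          paste(unique(strsplit(bad, "")[[1]]), collapse = "")))
  if (is.null(msg)) TRUE else msg
})

#' Construct a SequencePair
#'
#' Input is case-normalized to uppercase and U is mapped to T before
#' validation against the ACGTN- alphabet.
#'
#' @param geneId pair label.
#' @param seqA,seqB aligned nucleotide strings of equal length.
#' @return A \linkS4class{SequencePair}.
#' @examples
#' SequencePair("g1", "ATGAAA", "ATGAAG")
#' @export
SequencePair <- function(geneId, seqA, seqB) {
  norm <- function(x) chartr("u", "t", tolower(x)) |> toupper()
  new("SequencePair", geneId = as.character(geneId),
      seqA = norm(seqA), seqB = norm(seqB))
}

setMethod("show", "SequencePair", function(object) {
  cat("SequencePair '", object@geneId, "': ", nchar(object@seqA),
      " aligned columns\n", sep = "")
})

#' CodonAlignment: a gap- and ambiguity-filtered in-frame codon pair
#'
#' The universal substrate of all eight Ka/Ks estimators: two equal-length
#' vectors of sense codons (no gaps, no N, no stop codons).
#'
#' @slot geneId character(1) label.
#' @slot codonsA,codonsB character vectors of 3-letter sense codons.
#' @exportClass CodonAlignment
setClass("CodonAlignment",
  representation(geneId = "character", codonsA = "character",
                 codonsB = "character"))

setValidity("CodonAlignment", function(object) {
  msg <- NULL
  if (length(object@codonsA) != length(object@codonsB))
    msg <- c(msg, "codonsA and codonsB must have equal length")
  cods <- c(object@codonsA, object@codonsB)
  if (length(cods)) {
    if (any(nchar(cods) != 3L) || any(grepl("[^ACGT]", cods)))
      msg <- c(msg, "codons must be 3 unambiguous ACGT bases")
    else if (any(.aaOf(cods) == "*"))
      msg <- c(msg, "internal stop codon in alignment")
  }
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "CodonAlignment", function(object) {
  nd <- sum(object@codonsA != object@codonsB)
  cat("CodonAlignment '", object@geneId, "': ", length(object@codonsA),
      " codons, ", nd, " differing\n", sep = "")
})

#' @describeIn CodonAlignment-class number of codon columns
#' @param x,object a CodonAlignment.
#' @export
setGeneric("nCodons", function(x) standardGeneric("nCodons"))

#' @rdname CodonAlignment-class
#' @export
setMethod("nCodons", "CodonAlignment", function(x) length(x@codonsA))

#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' Gene identifier accessor
#' @param x a SequencePair or CodonAlignment.
#' @return character(1) label.
#' @rdname geneId
#' @export
setMethod("geneId", "SequencePair", function(x) x@geneId)

#' @rdname geneId
#' @export
setMethod("geneId", "CodonAlignment", function(x) x@geneId)

#' The eight estimation method tags
#' @export
KAKS_METHODS <- c("NG", "LWL", "MLWL", "LPB", "MLPB", "YN", "MYN", "GY")

#' MethodTable: genes x methods matrices of Ka, Ks and Ka/Ks
#'
#' Rectangular container for the per-gene, per-method estimates on which all
#' cross-method consistency statistics operate. NA entries mark estimates
#' that were not applicable (saturation, zero denominators) and are
#' distinguishable from true zeros.
#'
#' @slot genes ordered gene labels (rownames of the matrices).
#' @slot methods ordered method tags (colnames).
#' @slot ka,ks,omega numeric matrices genes x methods, NA allowed.
#' @exportClass MethodTable
setClass("MethodTable",
  representation(genes = "character", methods = "character",
                 ka = "matrix", ks = "matrix", omega = "matrix"))

setValidity("MethodTable", function(object) {
  msg <- NULL
  dims <- c(length(object@genes), length(object@methods))
  for (s in c("ka", "ks", "omega")) {
    m <- slot(object, s)
    if (!all(dim(m) == dims))
      msg <- c(msg, sprintf("slot %s has dimensions %dx%d, expected %dx%d",
                            s, nrow(m), ncol(m), dims[1], dims[2]))
  }
  if (anyDuplicated(object@genes)) msg <- c(msg, "duplicate gene ids")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "MethodTable", function(object) {
  cat("MethodTable: ", length(object@genes), " genes x ",
      length(object@methods), " methods (",
      paste(object@methods, collapse = ", "), ")\n", sep = "")
  cat("  NA entries: ka ", sum(is.na(object@ka)), ", ks ",
      sum(is.na(object@ks)), ", omega ", sum(is.na(object@omega)), "\n",
      sep = "")
})

#' Assemble a MethodTable from per-(gene, method) estimates
#'
#' @param estimates data.frame with columns gene_id, method, ka, ks, omega
#'   (the format produced by [estimateKaKs()]).
#' @return A \linkS4class{MethodTable} with genes in first-appearance order
#'   and methods in canonical order.
#' @export
MethodTable <- function(estimates) {
  stopifnot(all(c("gene_id", "method", "ka", "ks", "omega") %in%
                names(estimates)))
  genes <- unique(estimates$gene_id)
  methods <- intersect(KAKS_METHODS, unique(estimates$method))
  mk <- function(col) {
    m <- matrix(NA_real_, length(genes), length(methods),
                dimnames = list(genes, methods))
    m[cbind(match(estimates$gene_id, genes),
            match(estimates$method, methods))] <- estimates[[col]]
    m
  }
  new("MethodTable", genes = genes, methods = methods,
      ka = mk("ka"), ks = mk("ks"), omega = mk("omega"))
}

#' @export
setGeneric("kaMatrix", function(x) standardGeneric("kaMatrix"))
#' @export
setGeneric("ksMatrix", function(x) standardGeneric("ksMatrix"))
#' @export
setGeneric("omegaMatrix", function(x) standardGeneric("omegaMatrix"))

#' Matrix accessors for MethodTable
#' @param x a MethodTable.
#' @return numeric genes x methods matrix.
#' @rdname kaMatrix
#' @export
setMethod("kaMatrix", "MethodTable", function(x) x@ka)
#' @rdname kaMatrix
#' @export
setMethod("ksMatrix", "MethodTable", function(x) x@ks)
#' @rdname kaMatrix
#' @export
setMethod("omegaMatrix", "MethodTable", function(x) x@omega)

#' @export
setGeneric("methodNames", function(x) standardGeneric("methodNames"))
#' Method tags present in a MethodTable
#' @param x a MethodTable.
#' @rdname methodNames
#' @export
setMethod("methodNames", "MethodTable", function(x) x@methods)

#' @rdname geneId
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname geneId
#' @export
setMethod("geneIds", "MethodTable", function(x) x@genes)
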