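#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom Biostrings DNAStringSet
NULL

#' BarcodeLibrary: strain barcodes for a pooled deletion collection
#'
#' Maps fixed-length DNA barcode sequences to deletion-mutant identifiers
#' and gene names. Barcodes are stored as a \link[Biostrings]{DNAStringSet}
#' named by mutant id.
#'
#' @slot barcodes A \code{DNAStringSet}, one barcode per mutant, names are
#'   mutant ids.
#' @slot genes Character vector of gene names, parallel to \code{barcodes}.
#'
#' @details Barcodes are expected to be unique and of equal length over the
#'   alphabet \code{A,C,G,T,N}. Duplicated barcodes are tolerated by the
#'   validity method (they can arise in real libraries) but the constructor
#'   warns, because reads matching a duplicated barcode can never be
#'   assigned unambiguously.
#'
#' @seealso [barcodeLibrary()], [matchBarcode()], [countBarcodes()]
#' @export
setClass("BarcodeLibrary",
  representation(barcodes = "DNAStringSet", genes = "character"))

setValidity("BarcodeLibrary", function(object) {
  msg <- NULL
  if (length(object@barcodes) != length(object@genes))
    msg <- c(msg, "'barcodes' and 'genes' must have equal length")
  if (length(object@barcodes) > 0L) {
    if (is.null(names(object@barcodes)) || anyNA(names(object@barcodes)) ||
        any(names(object@barcodes) == ""))
      msg <- c(msg, "barcodes must be named by mutant id")
    else if (anyDuplicated(names(object@barcodes)))
      msg <- c(msg, "mutant ids must be unique")
    w <- Biostrings::width(object@barcodes)
    if (length(unique(w)) > 1L)
      msg <- c(msg, "all barcodes must have the same length")
    letters_used <- Biostrings::uniqueLetters(object@barcodes)
    if (!all(letters_used %in% c("A", "C", "G", "T", "N")))
      msg <- c(msg, "barcode alphabet restricted to A,C,G,T,N")
  }
  if (is.null(msg)) TRUE else msg
})

#' CountTable: per-mutant barcode counts for one sample
#'
#' Holds the non-negative integer barcode tally of a single sequencing
#' sample, together with its condition label and the number of reads that
#' could not be assigned to any library barcode.
#'
#' @slot counts Named integer vector, one tally per mutant id.
#' @slot genes Character vector of gene names parallel to \code{counts}.
#' @slot sample_id Length-one character.
#' @slot condition Length-one character, \code{"control"} or
#'   \code{"treatment"}.
#' @slot unassigned Length-one integer, reads not assigned to any mutant.
#' @slot total_reads Length-one integer; must equal
#'   \code{sum(counts) + unassigned}.
#'
#' @seealso [countBarcodes()], [bindScreens()], [giTable()]
#' @export
setClass("CountTable",
  representation(counts = "integer", genes = "character",
    sample_id = "character", condition = "character",
    unassigned = "integer", total_reads = "integer"))

setValidity("CountTable", function(object) {
  msg <- NULL
  if (length(object@counts) != length(object@genes))
    msg <- c(msg, "'counts' and 'genes' must have equal length")
  if (is.null(names(object@counts)) && length(object@counts) > 0L)
    msg <- c(msg, "'counts' must be named by mutant id")
  if (anyNA(object@counts) || any(object@counts < 0L))
    msg <- c(msg, "counts must be non-negative and non-missing")
  if (length(object@condition) != 1L ||
      !object@condition %in% c("control", "treatment"))
    msg <- c(msg, "'condition' must be \"control\" or \"treatment\"")
  if (length(object@unassigned) != 1L || object@unassigned < 0L)
    msg <- c(msg, "'unassigned' must be a single non-negative integer")
  if (length(object@total_reads) != 1L ||
      object@total_reads != sum(object@counts) + object@unassigned)
    msg <- c(msg, "'total_reads' must equal sum(counts) + unassigned")
  if (is.null(msg)) TRUE else msg
})

#' AnnotationSet: term-to-gene annotations over a gene universe
#'
#' A collection of gene sets (e.g. GO biological processes or phenotype
#' ontology terms) together with the background universe against which
#' over-representation is tested.
#'
#' @slot terms Named list of character vectors; each element is the set of
#'   genes annotated to one term.
#' @slot background Character vector, the gene universe (size N).
#'
#' @details Every term gene must belong to the background and every term
#'   must contain at least one gene; both are enforced by the validity
#'   method, because p-values are meaningless otherwise.
#'
#' @seealso [annotationSet()], [readGMT()], [enrichTerms()]
#' @export
setClass("AnnotationSet",
  representation(terms = "list", background = "character"))

setValidity("AnnotationSet", function(object) {
  msg <- NULL
  if (length(object@terms) > 0L) {
    if (is.null(names(object@terms)) || anyDuplicated(names(object@terms)))
      msg <- c(msg, "terms must be uniquely named")
    sizes <- lengths(object@terms)
    if (any(sizes < 1L))
      msg <- c(msg, "every term must contain at least one gene")
    all_genes <- unique(unlist(object@terms, use.names = FALSE))
    if (!all(all_genes %in% object@background))
      msg <- c(msg, "every term gene must belong to the background")
  }
  if (anyDuplicated(object@background))
    msg <- c(msg, "background genes must be unique")
  if (is.null(msg)) TRUE else msg
})

#' CompetitionResult: normalized competitive-growth outcome
#'
#' Result of one flow-cytometry growth competition: mutant and reference
#' GFP- fractions with and without toxicant, their GFP-loss-corrected
#' ratios, and the final growth ratio. See [growthRatio()] for the
#' formulas.
#'
#' @slot w_m,w_m_star Mutant fraction without / with toxicant,
#'   \code{M-GFP- / (M-GFP- + WT-GFP+)}.
#' @slot w_r,w_r_star Reference fraction without / with toxicant,
#'   \code{WT-GFP- / (WT-GFP- + WT-GFP+)}.
#' @slot w_n,w_n_star GFP-loss-corrected ratios \code{w_m/w_r} and
#'   \code{w_m_star/w_r_star}.
#' @slot growth_ratio \code{w_n_star / w_n}.
#' @slot w_big_n Named numeric of length 2, the raw mutant/wild-type count
#'   ratios \code{W_M/W_R} without and with toxicant.
#' @slot below_detection Logical; \code{TRUE} when the treated
#'   \code{W_M/W_R} falls below the assay's detection floor (0.03 by
#'   default). Flagged, never clamped.
#'
#' @export
setClass("CompetitionResult",
  representation(w_m = "numeric", w_r = "numeric",
    w_m_star = "numeric", w_r_star = "numeric",
    w_n = "numeric", w_n_star = "numeric",
    growth_ratio = "numeric", w_big_n = "numeric",
    below_detection = "logical"))

setValidity("CompetitionResult", function(object) {
  fr <- c(object@w_m, object@w_r, object@w_m_star, object@w_r_star)
  msg <- NULL
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    msg <- c(msg, "fractions must be finite and in [0, 1]")
  if (!is.finite(object@growth_ratio) || object@growth_ratio < 0)
    msg <- c(msg, "growth_ratio must be finite and >= 0")
  if (is.null(msg)) TRUE else msg
})
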