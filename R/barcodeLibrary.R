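#' Construct a BarcodeLibrary
#'
#' @param barcodes Character vector or \code{DNAStringSet} of equal-length
#'   DNA barcodes (alphabet A,C,G,T,N).
#' @param mutant_ids Character vector of unique mutant identifiers. If
#'   \code{barcodes} is already named, the names are used when
#'   \code{mutant_ids} is missing.
#' @param genes Character vector of gene names; defaults to the mutant ids.
#'
#' @return A [BarcodeLibrary-class] object.
#'
#' @details Duplicated barcode sequences trigger a warning: reads carrying
#'   such a barcode can never be uniquely assigned and are counted as
#'   unassigned by [matchBarcode()].
#'
#' @examples
#' lib <- barcodeLibrary(c(m1 = "ACGTACGTACGTACGTACGT",
#'                         m2 = "TTTTACGTACGTACGTACGT"))
#' mutantIds(lib)
#' @export
barcodeLibrary <- function(barcodes, mutant_ids = NULL, genes = NULL) {
  if (!methods::is(barcodes, "DNAStringSet"))
    barcodes <- Biostrings::DNAStringSet(barcodes)
  if (!is.null(mutant_ids))
    names(barcodes) <- mutant_ids
  if (is.null(names(barcodes)))
    stop("supply 'mutant_ids' or a named 'barcodes' vector")
  if (is.null(genes))
    genes <- names(barcodes)
  obj <- methods::new("BarcodeLibrary", barcodes = barcodes,
    genes = as.character(genes))
  if (anyDuplicated(as.character(barcodes)))
    warning("duplicated barcode sequences: affected reads will be unassigned")
  obj
}

#' @rdname BarcodeLibrary-class
#' @export
setMethod("mutantIds", "BarcodeLibrary", function(x) names(x@barcodes))

#' @rdname BarcodeLibrary-class
#' @export
setMethod("barcodes", "BarcodeLibrary", function(x) x@barcodes)

#' @rdname BarcodeLibrary-class
#' @export
setMethod("geneNames", "BarcodeLibrary",
  function(x) stats::setNames(x@genes, names(x@barcodes)))

#' @rdname BarcodeLibrary-class
#' @export
setMethod("length", "BarcodeLibrary", function(x) length(x@barcodes))

#' @rdname BarcodeLibrary-class
#' @param i Index for subsetting.
#' @export
setMethod("[", "BarcodeLibrary", function(x, i) {
  methods::new("BarcodeLibrary", barcodes = x@barcodes[i],
    genes = x@genes[i])
})

#' @rdname BarcodeLibrary-class
#' @export
setMethod("show", "BarcodeLibrary", function(object) {
  cat("BarcodeLibrary with", length(object), "mutants;",
      if (length(object)) Biostrings::width(object@barcodes)[1] else 0,
      "nt barcodes\n")
  if (length(object) > 0) {
    n <- min(3L, length(object))
    for (k in seq_len(n))
      cat(" ", names(object@barcodes)[k],
          as.character(object@barcodes[[k]]), object@genes[k], "\n")
    if (length(object) > n) cat("  ...\n")
  }
})

#' Read or write a barcode library as TSV
#'
#' Plain three-column tab-separated text: \code{mutant_id}, \code{barcode},
#' \code{gene}, with a header line.
#'
#' @param path File path.
#' @param library A [BarcodeLibrary-class] (for writing).
#' @return \code{readBarcodeLibrary} returns a \code{BarcodeLibrary};
#'   \code{writeBarcodeLibrary} returns \code{path} invisibly.
#' @export
readBarcodeLibrary <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
    colClasses = "character")
  stopifnot(all(c("mutant_id", "barcode", "gene") %in% names(df)))
  barcodeLibrary(df$barcode, mutant_ids = df$mutant_id, genes = df$gene)
}

#' @rdname readBarcodeLibrary
#' @export
writeBarcodeLibrary <- function(library, path) {
  df <- data.frame(mutant_id = mutantIds(library),
    barcode = as.character(barcodes(library)),
    gene = unname(geneNames(library)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
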