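#' @rdname BarcodeLibrary-class
#' @param x,object A \code{BarcodeLibrary}.
#' @export
setGeneric("mutantIds", function(x) standardGeneric("mutantIds"))

#' @rdname BarcodeLibrary-class
#' @export
setGeneric("barcodes", function(x) standardGeneric("barcodes"))

#' @rdname BarcodeLibrary-class
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' @rdname CountTable-class
#' @param x,object A \code{CountTable}.
#' @export
setGeneric("mutantCounts", function(x) standardGeneric("mutantCounts"))

#' @rdname CountTable-class
#' @export
setGeneric("unassignedReads", function(x) standardGeneric("unassignedReads"))

#' @rdname AnnotationSet-class
#' @param x,object An \code{AnnotationSet}.
#' @export
setGeneric("termGenes", function(x) standardGeneric("termGenes"))

#' @rdname AnnotationSet-class
#' @export
setGeneric("backgroundGenes", function(x) standardGeneric("backgroundGenes"))
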