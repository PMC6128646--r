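#' Construct an AnnotationSet
#'
#' @param terms Named list of character vectors (term id -> genes).
#' @param background Character vector, the gene universe. Defaults to the
#'   union of all term genes.
#' @return An [AnnotationSet-class].
#' @export
annotationSet <- function(terms, background = NULL) {
  terms <- lapply(terms, function(g) unique(as.character(g)))
  if (is.null(background))
    background <- unique(unlist(terms, use.names = FALSE))
  methods::new("AnnotationSet", terms = terms,
               background = unique(as.character(background)))
}

#' @rdname AnnotationSet-class
#' @export
setMethod("termGenes", "AnnotationSet", function(x) x@terms)

#' @rdname AnnotationSet-class
#' @export
setMethod("backgroundGenes", "AnnotationSet", function(x) x@background)

#' @rdname AnnotationSet-class
#' @export
setMethod("length", "AnnotationSet", function(x) length(x@terms))

#' @rdname AnnotationSet-class
#' @export
setMethod("show", "AnnotationSet", function(object) {
  cat("AnnotationSet:", length(object@terms), "terms over",
      length(object@background), "background genes\n")
  if (length(object@terms) > 0) {
    sz <- lengths(object@terms)
    cat("  term sizes:", min(sz), "-", max(sz), "\n")
  }
})

#' Read or write GMT gene-set files
#'
#' GMT is tab-separated, one term per line:
#' \code{term <tab> description <tab> gene1 <tab> gene2 ...}.
#'
#' @param path File path.
#' @param background Optional gene universe for the returned
#'   [AnnotationSet-class]; defaults to the union of term genes.
#' @param annotations An \code{AnnotationSet} (for writing).
#' @param descriptions Optional character vector of term descriptions.
#' @return \code{readGMT} returns an \code{AnnotationSet}; \code{writeGMT}
#'   returns \code{path} invisibly.
#' @export
readGMT <- function(path, background = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad))
    stop("malformed GMT: lines without genes: ",
         paste(which(bad), collapse = ", "))
  terms <- lapply(fields, function(f) f[-(1:2)])
  names(terms) <- vapply(fields, `[`, character(1), 1L)
  annotationSet(terms, background = background)
}

#' @rdname readGMT
#' @export
writeGMT <- function(annotations, path, descriptions = NULL) {
  stopifnot(methods::is(annotations, "AnnotationSet"))
  tg <- termGenes(annotations)
  if (is.null(descriptions)) descriptions <- rep("na", length(tg))
  lines <- mapply(function(id, desc, genes)
    paste(c(id, desc, genes), collapse = "\t"),
    names(tg), descriptions, tg)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Hypergeometric over-representation tail probability
#'
#' Probability of observing \code{k} or more genes of a size-\code{K} term
#' in a size-\code{n} list drawn without replacement from a background of
#' \code{N} genes: \code{P(X >= k)} with
#' \code{X ~ Hypergeometric(N, K, n)}. Computed in log space via
#' \code{stats::phyper}, so extreme tails (e.g. 1e-20) are exact to
#' double precision.
#'
#' @param k Observed overlap between list and term (vectorized).
#' @param n List size.
#' @param K Term size.
#' @param N Background size.
#' @return Raw upper-tail p-value(s) in \code{(0, 1]}.
#'
#' @examples
#' hypergeomTail(2, n = 5, K = 3, N = 10)   # 0.5
#' hypergeomTail(8, n = 68, K = 9, N = 2901)
#' @export
hypergeomTail <- function(k, n, K, N) {
  if (any(!is.finite(c(k, n, K, N))))
    stop("all arguments must be finite")
  if (any(c(k, n, K, N) < 0) || any(n > N) || any(K > N) ||
      any(k > pmin(n, K)))
    stop("inconsistent counts: need k <= min(n, K) and n, K <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term over-representation with Bonferroni correction
#'
#' Tests every term of an annotation set for over-representation in a gene
#' list by the hypergeometric upper tail, then applies Bonferroni
#' correction over the number of terms tested. Only enrichment (the upper
#' tail) is tested; the screen logic is one-sided.
#'
#' @param gene_list Character vector of genes of interest. Genes absent
#'   from the background are dropped with a warning.
#' @param annotations An [AnnotationSet-class].
#' @param alpha Significance cutoff on the corrected p-value (default 0.01).
#' @param min_term_size,max_term_size Terms outside these size bounds are
#'   excluded before testing (and before the Bonferroni divisor m is
#'   fixed).
#' @return A \link[S4Vectors]{DataFrame} sorted by corrected p-value with
#'   columns \code{term}, \code{k}, \code{n}, \code{K}, \code{N},
#'   \code{list_frequency}, \code{background_frequency}, \code{p_raw},
#'   \code{p_corrected}, \code{significant}, \code{genes}; the Bonferroni
#'   divisor is stored in \code{metadata()$m_tested}.
#'
#' @examples
#' ann <- annotationSet(list(t1 = c("a", "b", "c"), t2 = c("d", "e")),
#'                      background = letters[1:10])
#' enrichTerms(c("a", "b", "d"), ann)
#' @export
enrichTerms <- function(gene_list, annotations, alpha = 0.01,
                        min_term_size = 1, max_term_size = Inf) {
  stopifnot(methods::is(annotations, "AnnotationSet"))
  gene_list <- unique(as.character(gene_list))
  bg <- backgroundGenes(annotations)
  if (length(gene_list) == 0)
    stop("empty gene list")
  if (length(annotations) == 0)
    stop("empty annotation set")
  outside <- setdiff(gene_list, bg)
  if (length(outside) > 0) {
    warning(length(outside), " gene(s) not in background dropped: ",
            paste(utils::head(outside, 5), collapse = ", "))
    gene_list <- intersect(gene_list, bg)
    if (length(gene_list) == 0)
      stop("no gene of the list belongs to the background")
  }
  tg <- termGenes(annotations)
  sizes <- lengths(tg)
  tg <- tg[sizes >= min_term_size & sizes <= max_term_size]
  m <- length(tg)
  if (m == 0)
    stop("no term within the configured size bounds")
  N <- length(bg)
  n <- length(gene_list)
  K <- lengths(tg)
  hits <- lapply(tg, intersect, gene_list)
  k <- lengths(hits)
  p_raw <- hypergeomTail(k, n, K, N)
  res <- S4Vectors::DataFrame(
    term = names(tg), k = unname(k), n = n, K = unname(K), N = N,
    list_frequency = k / n,
    background_frequency = unname(K) / N,
    p_raw = unname(p_raw),
    p_corrected = unname(pmin(1, m * p_raw)),
    genes = unname(vapply(hits, paste, character(1), collapse = ",")),
    row.names = NULL)
  res$significant <- res$p_corrected <= alpha
  res <- res[order(res$p_corrected, res$p_raw, res$term), ]
  S4Vectors::metadata(res)$m_tested <- m
  res
}

#' Write an enrichment table as TSV
#'
#' @param result The \code{DataFrame} returned by [enrichTerms()].
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writeEnrichment <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
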