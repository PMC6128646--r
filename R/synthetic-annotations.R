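#' Simulate a term annotation set, optionally with a planted enrichment
#'
#' Generates random term-to-gene memberships over a background universe.
#' When \code{planted_term} is supplied, one designated term is built to
#' overlap a given gene list by exactly the requested number of genes, so
#' downstream over-representation statistics have a known signal.
#'
#' @param genes Character vector: the background gene universe.
#' @param n_terms Number of random terms to generate.
#' @param term_size_range Integer vector of length 2: minimum and maximum
#'   term size (inclusive); sizes drawn uniformly.
#' @param planted_term \code{NULL}, or a list with elements
#'   \describe{
#'     \item{name}{term identifier (default \code{"planted"}),}
#'     \item{list_genes}{the gene list to be enriched,}
#'     \item{term_size}{total size K of the planted term,}
#'     \item{overlap}{number k of \code{list_genes} placed in the term.}
#'   }
#' @param seed Integer seed.
#' @return An [AnnotationSet-class] containing \code{n_terms} random terms
#'   plus the planted term when requested.
#'
#' @examples
#' ann <- simulateAnnotations(sprintf("g%03d", 1:100), n_terms = 5,
#'   term_size_range = c(3, 10), seed = 1)
#' lengths(termGenes(ann))
#' @export
simulateAnnotations <- function(genes, n_terms, term_size_range = c(5, 50),
                                planted_term = NULL, seed = NULL) {
  genes <- unique(as.character(genes))
  N <- length(genes)
  assertScalarNumber(n_terms, "n_terms", lower = 0)
  if (length(term_size_range) != 2L || any(term_size_range < 1) ||
      term_size_range[1] > term_size_range[2])
    stop("'term_size_range' must be an ordered pair of sizes >= 1")
  if (term_size_range[2] > N)
    stop("term sizes cannot exceed the background size (", N, ")")
  withSeed(seed, {
    sizes <- if (n_terms > 0)
      sample(seq(term_size_range[1], term_size_range[2]), n_terms,
             replace = TRUE) else integer(0)
    terms <- lapply(sizes, function(k) sample(genes, k))
    names(terms) <- sprintf("term%03d", seq_len(n_terms))
    if (!is.null(planted_term)) {
      pt <- planted_term
      if (is.null(pt$name)) pt$name <- "planted"
      lg <- unique(as.character(pt$list_genes))
      if (!all(lg %in% genes))
        stop("planted 'list_genes' must belong to the background")
      K <- pt$term_size; k <- pt$overlap
      assertScalarNumber(K, "term_size", lower = 1, upper = N)
      assertScalarNumber(k, "overlap", lower = 0)
      if (k > K || k > length(lg))
        stop("planted overlap larger than the term or the gene list")
      if (K - k > N - length(lg))
        stop("not enough background genes outside the list for the term")
      inside <- sample(lg, k)
      outside <- sample(setdiff(genes, lg), K - k)
      terms[[pt$name]] <- c(inside, outside)
    }
    annotationSet(terms, background = genes)
  })
}
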