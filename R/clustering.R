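#' Uncentered correlation (cosine similarity)
#'
#' Similarity between two profiles without mean-centering:
#' \deqn{r = \sum_i x_i y_i / \sqrt{\sum_i x_i^2 \; \sum_i y_i^2}.}
#' Positions where either vector is missing are dropped pairwise before
#' computing (Cluster 3.0 behavior). Because profiles are not centered, a
#' mutant with uniformly strong GI scores across toxins and one with
#' uniformly weak scores still correlate highly if their shapes agree in
#' sign, which is the intended semantics for toxicogenomic profiles where
#' 0 means "unaffected".
#'
#' @param x,y Equal-length numeric vectors.
#' @return Similarity in \code{[-1, 1]}.
#'
#' @examples
#' uncenteredCorr(c(1, 1), c(1, 0))   # 1/sqrt(2)
#' @export
uncenteredCorr <- function(x, y) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 1)
    stop("no shared finite entries")
  nx <- sum(x^2); ny <- sum(y^2)
  if (nx == 0 || ny == 0)
    stop("undefined similarity: a vector has zero norm after ",
         "missing-data removal")
  r <- sum(x * y) / sqrt(nx * ny)
  min(1, max(-1, r))
}

# Pairwise uncentered-correlation similarity matrix over rows of m,
# with pairwise deletion and a minimum-overlap requirement.
uncenteredSimilarity <- function(m, min_overlap = 2) {
  n <- nrow(m)
  s <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- is.finite(m[i, ]) & is.finite(m[j, ])
      if (sum(ok) < min_overlap)
        stop("rows ", i, " and ", j, " share fewer than ", min_overlap,
             " finite entries")
      s[i, j] <- s[j, i] <- uncenteredCorr(m[i, ok], m[j, ok])
    }
  }
  rownames(s) <- colnames(s) <- rownames(m)
  s
}

#' Pairwise average-linkage clustering with uncentered correlation
#'
#' Agglomerative (UPGMA) clustering of the rows or columns of a GI-score
#' matrix on the distance \code{d = 1 - r}, where r is the uncentered
#' correlation with pairwise deletion of missing values. Inter-cluster
#' distance is the unweighted mean of all pairwise leaf distances
#' (realized by the Lance-Williams average update). Ties in the minimum
#' distance are broken by the lexicographically smallest pair of smallest
#' original leaf indices, so the tree is deterministic.
#'
#' @param m Numeric matrix of GI scores (mutants x screens); at least 2
#'   rows and 2 columns. Missing values allowed subject to
#'   \code{min_overlap}.
#' @param axis \code{"rows"} (default) or \code{"columns"}.
#' @param min_overlap Minimum shared finite entries per profile pair
#'   (default 2).
#' @return An object of class \code{hclust} (merge, height, order, labels)
#'   with \code{method = "average"} and
#'   \code{dist.method = "1 - uncentered correlation"}.
#'
#' @examples
#' m <- rbind(a = c(1, 0), b = c(2, 0), c = c(0, 1), d = c(0, 3))
#' averageLinkage(m)$merge
#' @export
averageLinkage <- function(m, axis = c("rows", "columns"),
                           min_overlap = 2) {
  axis <- match.arg(axis)
  m <- as.matrix(m)
  if (axis == "columns") m <- t(m)
  n <- nrow(m)
  if (n < 2)
    stop("need at least 2 profiles to cluster")
  d <- 1 - uncenteredSimilarity(m, min_overlap = min_overlap)
  labels <- rownames(m)

  active <- seq_len(n)              # current cluster ids
  node_of <- -seq_len(n)            # hclust merge code per cluster
  size <- rep(1L, n)
  rep_leaf <- seq_len(n)            # smallest original leaf index
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  dm <- d
  diag(dm) <- Inf

  for (step in seq_len(n - 1)) {
    k <- length(active)
    # find minimum distance; tie-break on smallest (rep_i, rep_j)
    best <- NULL
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        ia <- active[a]; ib <- active[b]
        dd <- dm[ia, ib]
        ra <- min(rep_leaf[ia], rep_leaf[ib])
        rb <- max(rep_leaf[ia], rep_leaf[ib])
        if (is.null(best) || dd < best$d - 1e-12 ||
            (abs(dd - best$d) <= 1e-12 &&
             (ra < best$ra || (ra == best$ra && rb < best$rb)))) {
          best <- list(d = dd, a = ia, b = ib, ra = ra, rb = rb)
        }
      }
    }
    i <- best$a; j <- best$b
    merge[step, ] <- sort(c(node_of[i], node_of[j]))
    height[step] <- best$d
    # Lance-Williams average update into slot i
    others <- setdiff(active, c(i, j))
    if (length(others) > 0) {
      upd <- (size[i] * dm[i, others] + size[j] * dm[j, others]) /
        (size[i] + size[j])
      dm[i, others] <- upd
      dm[others, i] <- upd
    }
    size[i] <- size[i] + size[j]
    rep_leaf[i] <- min(rep_leaf[i], rep_leaf[j])
    node_of[i] <- step
    active <- setdiff(active, j)
  }

  out <- list(merge = merge, height = height,
              order = leafOrder(merge), labels = labels,
              method = "average",
              dist.method = "1 - uncentered correlation",
              call = match.call())
  class(out) <- "hclust"
  out
}

# Left-first leaf order from an hclust merge matrix.
leafOrder <- function(merge) {
  n <- nrow(merge) + 1
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

#' Two-dimensional hierarchical clustering of a GI matrix
#'
#' Clusters rows (mutants) and columns (screens/toxins) independently with
#' [averageLinkage()] and reorders both axes by leaf order.
#'
#' @param m Numeric GI matrix, at least 2 x 2 for both trees; with a
#'   single column (or row) the corresponding tree is omitted and only the
#'   other axis is clustered.
#' @param min_overlap Passed to [averageLinkage()].
#' @return A list of class \code{BiclusterResult}: \code{matrix} (input
#'   reordered), \code{row_tree}, \code{col_tree} (\code{hclust} or
#'   \code{NULL}).
#' @export
clusterBidimensional <- function(m, min_overlap = 2) {
  m <- as.matrix(m)
  row_tree <- if (nrow(m) >= 2)
    averageLinkage(m, "rows", min_overlap) else NULL
  col_tree <- if (ncol(m) >= 2)
    averageLinkage(m, "columns", min_overlap) else NULL
  ro <- if (is.null(row_tree)) seq_len(nrow(m)) else row_tree$order
  co <- if (is.null(col_tree)) seq_len(ncol(m)) else col_tree$order
  structure(list(matrix = m[ro, co, drop = FALSE],
                 row_tree = row_tree, col_tree = col_tree),
            class = "BiclusterResult")
}

#' @export
print.BiclusterResult <- function(x, ...) {
  cat("BiclusterResult:", nrow(x$matrix), "x", ncol(x$matrix),
      "GI matrix\n  row tree:",
      if (is.null(x$row_tree)) "none" else "average linkage",
      "\n  col tree:",
      if (is.null(x$col_tree)) "none" else "average linkage", "\n")
  invisible(x)
}

#' Export a clustering in Cluster 3.0 / Java TreeView formats
#'
#' Writes \code{<prefix>.cdt} (the reordered matrix), \code{<prefix>.gtr}
#' (row tree) and \code{<prefix>.atr} (column tree), tab-delimited with
#' NODE/GENE/ARRY identifiers and merge similarities (\code{1 - height}),
#' so Java TreeView can open the result. Newick copies of both trees are
#' written as \code{<prefix>.rows.nwk} / \code{<prefix>.cols.nwk} via
#' \pkg{ape}.
#'
#' @param x A \code{BiclusterResult} from [clusterBidimensional()].
#' @param prefix Output path prefix.
#' @return Character vector of the files written, invisibly.
#' @export
writeClusterFiles <- function(x, prefix) {
  stopifnot(inherits(x, "BiclusterResult"))
  written <- character(0)
  m <- x$matrix
  rid <- rownames(m) %||% sprintf("row%d", seq_len(nrow(m)))
  cid <- colnames(m) %||% sprintf("col%d", seq_len(ncol(m)))

  tre_lines <- function(tree, tag) {
    # leaf ids refer to positions in the ORIGINAL label order
    nid <- function(code) {
      if (code < 0) sprintf("%s%dX", tag, -code) else sprintf("NODE%dX", code)
    }
    vapply(seq_along(tree$height), function(s) paste(
      sprintf("NODE%dX", s), nid(tree$merge[s, 1]), nid(tree$merge[s, 2]),
      format(1 - tree$height[s], digits = 8), sep = "\t"), character(1))
  }
  if (!is.null(x$row_tree)) {
    gtr <- paste0(prefix, ".gtr")
    writeLines(tre_lines(x$row_tree, "GENE"), gtr)
    nwk <- paste0(prefix, ".rows.nwk")
    ape::write.tree(ape::as.phylo(x$row_tree), nwk)
    written <- c(written, gtr, nwk)
  }
  if (!is.null(x$col_tree)) {
    atr <- paste0(prefix, ".atr")
    writeLines(tre_lines(x$col_tree, "ARRY"), atr)
    nwk <- paste0(prefix, ".cols.nwk")
    ape::write.tree(ape::as.phylo(x$col_tree), nwk)
    written <- c(written, atr, nwk)
  }

  # CDT rows/cols are in leaf order; GENE/ARRY ids index original order
  ro <- if (is.null(x$row_tree)) seq_len(nrow(m)) else x$row_tree$order
  co <- if (is.null(x$col_tree)) seq_len(ncol(m)) else x$col_tree$order
  cdt <- paste0(prefix, ".cdt")
  head1 <- paste(c("GID", "UNIQID", "NAME", "GWEIGHT", cid),
                 collapse = "\t")
  head2 <- paste(c("AID", "", "", "", sprintf("ARRY%dX", co)),
                 collapse = "\t")
  head3 <- paste(c("EWEIGHT", "", "", "", rep("1", ncol(m))),
                 collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(r) paste(
    c(sprintf("GENE%dX", ro[r]), rid[r], rid[r], "1",
      format(m[r, ], digits = 8)), collapse = "\t"), character(1))
  writeLines(c(head1, head2, head3, body), cdt)
  invisible(c(written, cdt))
}
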