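# Independent oracles used across the suite. Each one recomputes the
# quantity under test by a different route than the package code.

# Hypergeometric upper tail by exhaustive enumeration of all C(N, n)
# draws: the term is taken as the first K background elements.
hyperTailEnum <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)
  mean(overlap >= k)
}

# Hamming distance between two equal-length strings.
hammingDist <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# UPGMA agglomerator that recomputes every inter-cluster distance from
# scratch as the mean of all pairwise leaf distances (no Lance-Williams
# update), with the same smallest-leaf-pair tie rule.
naiveUPGMA <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- NULL
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        dd <- mean(D[clusters[[a]], clusters[[b]]])
        ra <- min(min(clusters[[a]]), min(clusters[[b]]))
        rb <- max(min(clusters[[a]]), min(clusters[[b]]))
        if (is.null(best) || dd < best$d - 1e-12 ||
            (abs(dd - best$d) <= 1e-12 &&
             (ra < best$ra || (ra == best$ra && rb < best$rb))))
          best <- list(d = dd, a = a, b = b, ra = ra, rb = rb)
      }
    }
    heights <- c(heights, best$d)
    merged <- sort(c(clusters[[best$a]], clusters[[best$b]]))
    clusters <- c(clusters[-c(best$a, best$b)], list(merged))
    partitions <- c(partitions, list(merged))
  }
  list(heights = heights, partitions = partitions)
}

# Merged leaf sets, in merge order, from an hclust object.
hclustPartitions <- function(hc) {
  n <- nrow(hc$merge) + 1
  members <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    grab <- function(code) if (code < 0) -code else members[[code]]
    members[[s]] <- sort(c(grab(hc$merge[s, 1]), grab(hc$merge[s, 2])))
  }
  members
}

# Gate predicates recomputed directly from a config, for order-
# independence checks.
gateMasks <- function(events, config) {
  list(
    live = events$DAPI <= config$dapi_max,
    box = events$FSC_A >= config$fsc_range[1] &
          events$FSC_A <= config$fsc_range[2] &
          events$SSC >= config$ssc_range[1] &
          events$SSC <= config$ssc_range[2],
    singlet = {
      r <- events$FSC_A / events$FSC_H
      r >= config$doublet_band[1] & r <= config$doublet_band[2]
    })
}
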