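test_that("uncentered correlation is cosine similarity without centering", {
  expect_equal(uncenteredCorr(c(3, 1, 4), c(3, 1, 4)), 1)
  expect_equal(uncenteredCorr(c(1, 0), c(0, 1)), 0)
  expect_equal(uncenteredCorr(c(1, 1), c(1, 0)), 1 / sqrt(2))
  # missing values removed pairwise
  expect_equal(uncenteredCorr(c(1, NA, 1), c(1, 5, 0)), 1 / sqrt(2))
  expect_error(uncenteredCorr(c(0, 0, NA), c(1, 2, 3)), "zero norm")
  expect_error(uncenteredCorr(1:3, 1:4), "equal length")
})

test_that("uncentered correlation has positive-scale sign invariance", {
  set.seed(201)
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(6); a <- runif(1, 0.1, 10) * sample(c(-1, 1), 1)
    expect_equal(uncenteredCorr(a * x, y),
                 sign(a) * uncenteredCorr(x, y), tolerance = 1e-12)
  }
})

test_that("identical and proportional rows merge first", {
  m <- rbind(a = c(1, 2, 3), b = c(2, 1, 0), c = c(1, 2, 3))
  hc <- averageLinkage(m)
  expect_identical(sort(hc$merge[1, ]), c(-3L, -1L))
  expect_equal(hc$height[1], 0)

  # proportional pairs have r = 1 (scale invariance of the similarity)
  m2 <- rbind(r1 = c(1, 0), r2 = c(2, 0), r3 = c(0, 1), r4 = c(0, 3))
  hc2 <- averageLinkage(m2)
  first_two <- list(sort(hc2$merge[1, ]), sort(hc2$merge[2, ]))
  expect_true(identical(first_two[[1]], c(-2L, -1L)))
  expect_true(identical(first_two[[2]], c(-4L, -3L)))
  expect_equal(hc2$height[1:2], c(0, 0))
})

test_that("3-leaf trees match exhaustive topology scoring", {
  set.seed(211)
  for (i in 1:15) {
    m <- matrix(rnorm(9), 3, 3)
    d <- 1 - outer(1:3, 1:3, Vectorize(function(a, b)
      uncenteredCorr(m[a, ], m[b, ])))
    # best first merge is the smallest pairwise distance
    pairs <- list(c(1, 2), c(1, 3), c(2, 3))
    dd <- sapply(pairs, function(p) d[p[1], p[2]])
    hc <- averageLinkage(m)
    expect_identical(sort(hc$merge[1, ]),
                     as.integer(sort(-pairs[[which.min(dd)]])))
    # final height is the average distance of the remaining leaf to the pair
    p <- pairs[[which.min(dd)]]
    rest <- setdiff(1:3, p)
    expect_equal(hc$height[2], mean(d[rest, p]), tolerance = 1e-12)
  }
})

test_that("UPGMA agrees with a from-scratch agglomerator and with hclust", {
  set.seed(221)
  for (i in 1:12) {
    n <- sample(4:8, 1)
    m <- matrix(rnorm(n * 4), n, 4)
    d <- 1 - outer(seq_len(n), seq_len(n), Vectorize(function(a, b)
      uncenteredCorr(m[a, ], m[b, ])))
    diag(d) <- 0
    hc <- averageLinkage(m)
    # merge distances are monotone non-decreasing (no inversions)
    expect_true(all(diff(hc$height) >= -1e-12))
    # identical merge sequence and heights as the naive O(n^3) oracle
    naive <- naiveUPGMA(d)
    expect_equal(hc$height, naive$heights, tolerance = 1e-10)
    expect_identical(hclustPartitions(hc), naive$partitions)
    # same heights as stats::hclust average linkage
    ref <- stats::hclust(stats::as.dist(d), method = "average")
    expect_equal(sort(hc$height), sort(ref$height), tolerance = 1e-10)
  }
})

test_that("bidimensional clustering reorders both axes consistently", {
  set.seed(231)
  # planted 2x2 block structure
  m <- rbind(
    matrix(rnorm(5 * 6, mean = rep(c(3, 0), each = 3 * 5), sd = 0.2), 5, 6),
    matrix(rnorm(5 * 6, mean = rep(c(0, 3), each = 3 * 5), sd = 0.2), 5, 6))
  rownames(m) <- sprintf("r%02d", 1:10)
  colnames(m) <- sprintf("c%d", 1:6)
  bc <- clusterBidimensional(m)
  expect_identical(sort(rownames(bc$matrix)), sort(rownames(m)))
  # planted row groups separate in leaf order
  grp <- as.integer(substring(rownames(bc$matrix), 2)) <= 5
  expect_identical(length(rle(grp)$lengths), 2L)
  cgrp <- as.integer(substring(colnames(bc$matrix), 2)) <= 3
  expect_identical(length(rle(cgrp)$lengths), 2L)

  # clustering the transpose swaps the trees
  bt <- clusterBidimensional(t(m))
  expect_equal(bt$row_tree$height, bc$col_tree$height)
  expect_equal(bt$col_tree$height, bc$row_tree$height)
  expect_identical(bt$row_tree$order, bc$col_tree$order)

  # single column: no column tree, rows still clustered
  one <- clusterBidimensional(m[, 1, drop = FALSE], min_overlap = 1)
  expect_null(one$col_tree)
  expect_false(is.null(one$row_tree))
})

test_that("missing cells use pairwise deletion with a minimum overlap", {
  m <- rbind(a = c(1, 2, NA, 4), b = c(1, 2, 3, 4), c = c(NA, 2, 3, 4))
  hc <- averageLinkage(m, min_overlap = 2)
  expect_s3_class(hc, "hclust")
  m2 <- rbind(a = c(1, NA, NA, NA), b = c(NA, 2, 3, 4), c = c(1, 2, 3, 4))
  expect_error(averageLinkage(m2, min_overlap = 2), "fewer than 2")
})

test_that("cluster exports are TreeView-compatible and Newick-parseable", {
  set.seed(241)
  m <- matrix(rnorm(24), 6, 4,
              dimnames = list(sprintf("mut%d", 1:6), sprintf("tox%d", 1:4)))
  bc <- clusterBidimensional(m)
  prefix <- file.path(tempdir(), "clust_test")
  files <- writeClusterFiles(bc, prefix)
  expect_true(all(file.exists(files)))

  gtr <- read.delim(paste0(prefix, ".gtr"), header = FALSE)
  expect_identical(nrow(gtr), 5L)  # n - 1 internal nodes
  # merge similarities non-increasing from first merge to last
  expect_true(all(diff(gtr$V4) <= 1e-12))

  cdt <- read.delim(paste0(prefix, ".cdt"), header = TRUE,
                    check.names = FALSE)
  expect_identical(nrow(cdt), 6L + 2L)  # AID + EWEIGHT + 6 rows

  tre <- ape::read.tree(paste0(prefix, ".rows.nwk"))
  expect_identical(sort(tre$tip.label), sort(rownames(m)))
})
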