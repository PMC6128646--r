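test_that("pool abundances are normalized, deterministic and noise-free", {
  cfg <- poolSimConfig(50, rho = runif(50), rho_jitter_sd = 0)
  ab <- simulatePool(cfg)
  expect_equal(sum(ab$control), 1, tolerance = 1e-12)
  expect_equal(sum(ab$treatment), 1, tolerance = 1e-12)
  expect_identical(simulatePool(cfg), simulatePool(cfg))

  # all-neutral pool: treatment composition equals control composition
  neutral <- simulatePool(poolSimConfig(10, rho = rep(1, 10)))
  expect_equal(neutral$control, neutral$treatment)

  # non-uniform inoculum is renormalized
  cfg2 <- poolSimConfig(4, initial_abundances = c(4, 3, 2, 1))
  expect_equal(sum(cfg2$initial_abundances), 1)
})

test_that("GI of a trace-abundance mutant equals 1 - rho in the noise-free model", {
  # closed form: for a mutant at negligible abundance the pool
  # renormalization cancels and GI -> 1 - rho
  for (rho_i in c(0, 0.2, 0.5, 0.8)) {
    rho <- rep(1, 1000)
    rho[1] <- rho_i
    a0 <- rep(1, 1000)
    a0[1] <- 1  # 0.001 of the pool after normalization
    cfg <- poolSimConfig(1000, initial_abundances = a0, rho = rho,
                         doublings = 5, rho_jitter_sd = 0)
    ab <- simulatePool(cfg)
    gi <- giScores(ab$control, ab$treatment, doublings = 5)
    expect_equal(gi[1], 1 - rho_i, tolerance = 0.005)
  }
})

test_that("pool config rejects invalid growth rates and abundances", {
  expect_error(poolSimConfig(3, rho = c(0.5, 1.2, 1)), "rho")
  expect_error(poolSimConfig(3, rho = c(-0.1, 1, 1)), "rho")
  expect_error(poolSimConfig(3, initial_abundances = c(1, 0, 1)),
               "initial_abundances")
  expect_error(simulatePool(poolSimConfig(2, doublings = 2000)),
               "non-finite")
})

test_that("read simulation reproduces the multinomial draw at error rate 0", {
  lib <- simulateBarcodeLibrary(20, seed = 11)
  sim <- simulateReads(rep(1, 20), lib, readSimConfig(2000, 0, seed = 12))
  expect_identical(sum(sim$true_counts), 2000L)
  ct <- suppressMessages(countBarcodes(sim$reads, lib, max_mismatch = 0))
  expect_identical(mutantCounts(ct), sim$true_counts)
  expect_identical(unassignedReads(ct), 0L)

  # bit-reproducible under a fixed seed
  sim2 <- simulateReads(rep(1, 20), lib, readSimConfig(2000, 0, seed = 12))
  expect_identical(as.character(sim$reads), as.character(sim2$reads))
})

test_that("empirical read frequencies converge to abundances (LLN)", {
  lib <- simulateBarcodeLibrary(20, seed = 21)
  ab <- (1:20) / sum(1:20)
  depth <- 50000
  dev_se <- unlist(lapply(1:20, function(s) {
    sim <- simulateReads(ab, lib, readSimConfig(depth, 0, seed = 20 + s))
    (sim$true_counts / depth - ab) / sqrt(ab * (1 - ab) / depth)
  }))
  # deviations behave like standard binomial noise: unbiased, unit scale,
  # and the 3 SE band holds at its nominal coverage
  expect_lt(abs(mean(dev_se)), 0.2)
  expect_equal(sd(dev_se), 1, tolerance = 0.15)
  expect_gte(mean(abs(dev_se) <= 3), 0.98)
  expect_true(all(abs(dev_se) <= 5))
})

test_that("duplicate barcodes in the library trigger a warning", {
  expect_warning(
    lib <- barcodeLibrary(c(m1 = "ACGTACGTAC", m2 = "ACGTACGTAC")),
    "duplicated")
  expect_warning(
    simulateReads(c(1, 1), lib, readSimConfig(10, 0, seed = 1)),
    "identical barcodes")
})

test_that("annotation simulation plants a known overlap and rejects bad sizes", {
  genes <- sprintf("g%04d", 1:2901)
  listg <- genes[1:68]
  ann <- simulateAnnotations(genes, n_terms = 10,
    term_size_range = c(5, 30),
    planted_term = list(list_genes = listg, term_size = 9, overlap = 8),
    seed = 31)
  planted <- termGenes(ann)$planted
  expect_length(planted, 9)
  expect_identical(length(intersect(planted, listg)), 8L)

  # downstream raw p for the planted term reaches the study-scale tail
  res <- enrichTerms(listg, ann, alpha = 0.01)
  p_planted <- res$p_raw[res$term == "planted"]
  expect_lte(p_planted, 2.69e-10)

  expect_error(simulateAnnotations(genes, 5, term_size_range = c(0, 10)),
               "term_size_range")
  expect_error(simulateAnnotations(genes, 0, planted_term = list(
    list_genes = listg, term_size = 0, overlap = 0)), "term_size")
  expect_error(simulateAnnotations(genes, 0, planted_term = list(
    list_genes = listg[1:3], term_size = 2, overlap = 3)), "overlap")
})

test_that("without a planted term, enrichment is null-calibrated", {
  genes <- sprintf("g%04d", 1:2901)
  listg <- genes[seq(7, 2901, by = 42)][1:68]
  n_sig <- 0L
  n_seeds <- 200
  for (s in seq_len(n_seeds)) {
    ann <- simulateAnnotations(genes, n_terms = 50,
                               term_size_range = c(5, 50), seed = s)
    res <- suppressWarnings(enrichTerms(listg, ann, alpha = 0.01))
    if (min(res$p_corrected) < 0.01) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig / n_seeds, 0.1)
})

test_that("flow event mixture carries the declared structure", {
  cfg <- flowSimConfig(20000,
    fractions = c(gfp_pos = 0.4, gfp_neg = 0.55, dead = 0.05,
                  doublet = 0, debris = 0),
    gfp_loss_rate = 0, seed = 41)
  ev <- simulateFlowEvents(cfg)
  expect_identical(nrow(ev), 20000L)

  # known composition recovered within 3 multinomial SEs after gating
  gated <- applyGates(ev)$events
  cls <- classifyGFP(gated)
  n <- cls$gfp_pos + cls$gfp_neg
  for (pr in list(c(cls$gfp_pos, 0.4 / 0.95), c(cls$gfp_neg, 0.55 / 0.95))) {
    se <- sqrt(pr[2] * (1 - pr[2]) / n)
    expect_lt(abs(pr[1] / n - pr[2]), 3 * se + 0.004)
  }

  # doublets pulse about twice the area per height
  cfg2 <- flowSimConfig(5000, fractions = c(gfp_pos = 0.5, gfp_neg = 0.3,
    dead = 0, doublet = 0.2, debris = 0), seed = 42)
  ev2 <- simulateFlowEvents(cfg2)
  dbl <- ev2[ev2$label == "doublet", ]
  expect_equal(median(dbl$FSC_A / dbl$FSC_H), 2, tolerance = 0.05)

  # dead cells sit above the DAPI threshold
  cfg3 <- flowSimConfig(5000, fractions = c(gfp_pos = 0.5, gfp_neg = 0.3,
    dead = 0.2, doublet = 0, debris = 0), seed = 43)
  ev3 <- simulateFlowEvents(cfg3)
  dead <- ev3[ev3$label == "dead", ]
  expect_gt(mean(dead$DAPI > gateConfig()$dapi_max), 0.99)

  # perfectly separated clusters and no GFP loss: zero classification error
  live <- ev[ev$label %in% c("gfp_pos", "gfp_neg"), ]
  pos <- live$FITC > gateConfig()$gfp_positive_min
  expect_identical(sum(pos & live$label == "gfp_neg"), 0L)
  neg <- live$FITC < gateConfig()$gfp_ambiguous[1]
  expect_identical(sum(neg & live$label == "gfp_pos"), 0L)

  # reproducible under seed
  expect_identical(simulateFlowEvents(cfg), simulateFlowEvents(cfg))
})

test_that("flow config enforces fraction and separation invariants", {
  expect_error(flowSimConfig(100, fractions = c(gfp_pos = 0.9,
    gfp_neg = 0.9, dead = 0, doublet = 0, debris = 0)), "sum <= 1")
  expect_error(flowSimConfig(100, fitc_cluster_params = list(
    pos = c(2.0, 0.2), neg = c(1.5, 0.2))), "separated")
})
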