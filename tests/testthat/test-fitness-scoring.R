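test_that("relative abundances are pseudocounted frequencies", {
  expect_equal(unname(relativeAbundance(c(10, 10, 20), 0)),
               c(0.25, 0.25, 0.5))
  expect_equal(unname(relativeAbundance(c(0, 10), 0.5)),
               c(0.5 / 11, 10.5 / 11))
  expect_equal(unname(relativeAbundance(rep(7, 5), 0.5)), rep(0.2, 5))
  expect_equal(sum(relativeAbundance(rpois(20, 50))), 1)
  expect_error(relativeAbundance(c(0, 0), 0), "pseudocount")
})

test_that("GI scores follow the per-doubling log2 depletion formula", {
  expect_equal(giScores(0.001, 0.001, 5), 0)
  expect_equal(giScores(0.001, 0.000125, 5), log2(8) / 5)
  expect_equal(giScores(0.001, 0.000125, 5), 0.6)
  expect_error(giScores(0.1, 0, 5), "pseudocount")
  expect_error(giScores(c(0.5, 0.5), 0.5, 5), "matched")
})

test_that("GI is antisymmetric and rescales exactly with doublings", {
  set.seed(141)
  cf <- relativeAbundance(rpois(100, 200))
  tf <- relativeAbundance(rpois(100, 150))
  gi <- giScores(cf, tf, 5)
  expect_equal(giScores(tf, cf, 5), -gi)
  expect_equal(giScores(cf, tf, 10), gi / 2)
})

test_that("robust Z standardizes by median and NIQR", {
  x <- c(1, 2, 3, 4, 5)
  z <- robustZ(x)
  expect_equal(z[3], 0)
  expect_equal(z[5], stats::qnorm(0.75) - stats::qnorm(0.25),
               tolerance = 1e-10)  # 1.349
  # affine invariance
  set.seed(151)
  g <- rnorm(200)
  expect_equal(robustZ(3 * g + 7), robustZ(g))
  expect_error(robustZ(c(1, 2, 3)), "at least 4")
  expect_error(robustZ(rep(2, 10)), "IQR")
})

test_that("tail-area FDR matches the BH envelope on one-sided normal p", {
  # one strong z among 100 nulls
  z <- c(4, rep(0, 99))
  q <- tailFDR(z)
  expect_equal(q[1], 100 * stats::pnorm(4, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(q[1], 3.17e-3, tolerance = 1e-2)
  # most-negative z has p ~ 1 -> q = pi0
  z2 <- c(-5, rnorm(50))
  expect_equal(max(tailFDR(z2, pi0 = 0.8)), 0.8, tolerance = 1e-6)

  # equivalence with stats::p.adjust BH for random inputs up to size 50
  set.seed(161)
  for (i in 1:40) {
    zz <- rnorm(sample(4:50, 1), sd = sample(c(0.5, 1, 2), 1))
    p <- stats::pnorm(zz, lower.tail = FALSE)
    expect_equal(tailFDR(zz), stats::p.adjust(p, "BH"), tolerance = 1e-12)
  }

  # q is monotone non-decreasing in p
  zz <- rnorm(200)
  q <- tailFDR(zz)
  o <- order(stats::pnorm(zz, lower.tail = FALSE))
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_error(tailFDR(numeric(0)), "empty")
  expect_error(tailFDR(c(1, Inf)), "finite")
})

test_that("sensitivity calls apply the two-screen concordance rule", {
  q <- rbind(a = c(0.05, 0.08), b = c(0.05, 0.5), c = c(0.5, 0.9),
             d = c(0.02, NA), e = c(NA, 0.3))
  calls <- callSensitive(q, cutoff = 0.1)
  expect_identical(calls["a", "call"], "sensitive_both")
  expect_identical(calls["b", "call"], "sensitive_one")
  expect_identical(calls["c", "call"], "not_sensitive")
  # single-screen coverage can at best be sensitive_one
  expect_identical(calls["d", "call"], "sensitive_one")
  expect_identical(calls["e", "call"], "not_sensitive")
  expect_identical(calls$sensitive, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  any_rule <- callSensitive(q, cutoff = 0.1, rule = "any")
  expect_identical(any_rule$sensitive, c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_error(callSensitive(rbind(c(NA, NA))), "at least one screen")
})

test_that("expressivity labels follow the GI cut points", {
  calls <- c("sensitive_both", "sensitive_both", "sensitive_one",
             "not_sensitive")
  gi <- c(0.9, 0.5, 0.2, 0.8)
  lab <- classifyExpressivity(calls, gi, thresholds = c(0.3, 0.7))
  expect_identical(lab, c("high", "medium", "low", NA))
  expect_error(classifyExpressivity(calls, gi, thresholds = c(0.7, 0.3)),
               "ascending")
  # default tertiles split called mutants into three non-empty groups
  calls2 <- rep("sensitive_both", 9)
  lab2 <- classifyExpressivity(calls2, seq(0.1, 0.9, by = 0.1))
  counts2 <- table(lab2)
  expect_true(all(counts2[c("low", "medium", "high")] >= 3L))
})

test_that("planted sensitive mutants are recovered across two screens", {
  rho <- c(rep(0.5, 30), rep(1, 1970))
  cfg <- poolSimConfig(2000, rho = rho)
  screens <- simulateScreenCounts(cfg, depth = 2e6, n_screens = 2,
                                  seed = 171)
  scores <- lapply(screens, function(s)
    scoreScreen(s$control, s$treatment, doublings = 5))
  q <- do.call(cbind, lapply(scores, `[[`, "q"))
  rownames(q) <- scores[[1]]$mutant
  calls <- callSensitive(q, cutoff = 0.1)
  planted <- seq_len(30)
  expect_gte(mean(calls$call[planted] == "sensitive_both"), 0.9)
  expect_identical(sum(calls$call[-planted] == "sensitive_both"), 0L)
  # planted GI lands near 1 - rho = 0.5
  gi_planted <- rowMeans(do.call(cbind, lapply(scores, `[[`, "gi")))[planted]
  expect_equal(mean(gi_planted), 0.5, tolerance = 0.05)
})

test_that("scoreScreen output is coherent end to end", {
  cfg <- poolSimConfig(100, rho_jitter_sd = 0)
  scr <- simulateScreenCounts(cfg, depth = 1e5, n_screens = 1, seed = 181)
  sc <- scoreScreen(scr[[1]]$control, scr[[1]]$treatment)
  expect_identical(nrow(sc), 100L)
  expect_true(all(is.finite(sc$gi)))
  expect_equal(median(sc$z), 0, tolerance = 0.2)
  expect_true(all(sc$q >= 0 & sc$q <= 1))
})
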