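liveConfig <- function(n, seed) flowSimConfig(n,
  fractions = c(gfp_pos = 0.5, gfp_neg = 0.5, dead = 0, doublet = 0,
                debris = 0),
  gfp_loss_rate = 0, seed = seed)

test_that("all-live singlet samples pass the gates almost untouched", {
  ev <- simulateFlowEvents(liveConfig(20000, 251))
  g <- applyGates(ev)
  total <- g$attrition[g$attrition$gate == "total", ]
  expect_lt(total$fraction_removed, 0.005)
})

test_that("gating retains live singlets and removes the rest", {
  cfg <- flowSimConfig(40000,
    fractions = c(gfp_pos = 0.46, gfp_neg = 0.46, dead = 0.04,
                  doublet = 0.02, debris = 0.02), seed = 261)
  ev <- simulateFlowEvents(cfg)
  g <- applyGates(ev)
  # >= 99% of retained events are truly live singlets
  expect_gte(mean(g$events$label %in% c("gfp_pos", "gfp_neg")), 0.99)
  # attrition report is internally consistent
  att <- g$attrition
  expect_identical(att$before - att$removed, att$after)
  expect_identical(att$after[3], nrow(g$events))
  # everything gone -> uninterpretable
  dead_only <- flowSimConfig(100, fractions = c(gfp_pos = 0, gfp_neg = 0,
    dead = 1, doublet = 0, debris = 0), seed = 262)
  expect_error(applyGates(simulateFlowEvents(dead_only)), "all events")
})

test_that("the three hard gates are order-independent (intersection)", {
  cfg <- flowSimConfig(10000,
    fractions = c(gfp_pos = 0.45, gfp_neg = 0.45, dead = 0.04,
                  doublet = 0.03, debris = 0.03), seed = 271)
  ev <- simulateFlowEvents(cfg)
  gc <- gateConfig()
  keep_pkg <- rownames(applyGates(ev, gc)$events)
  masks <- gateMasks(ev, gc)
  for (ord in list(c(1, 2, 3), c(3, 2, 1), c(2, 3, 1))) {
    kept <- ev
    for (gate in ord)
      kept <- kept[masks[[gate]][as.integer(rownames(kept))], , drop = FALSE]
    expect_identical(rownames(kept), keep_pkg)
  }
})

test_that("GFP classification respects the ambiguous band", {
  ev <- data.frame(FSC_A = 300, FSC_H = 300, SSC = 100, DAPI = 10,
                   FITC = c(1e4, 50, 5e2, 99.9, 1000), PE = 30)
  cls <- classifyGFP(ev)
  expect_identical(cls$gfp_pos, 1L)       # 1e4
  expect_identical(cls$gfp_neg, 2L)       # 50 and 99.9
  expect_identical(cls$ambiguous_excluded, 2L)  # 5e2 and 1000 (boundary)

  # simulated 50:50 mixture recovered within 3 multinomial SEs
  sim <- simulateFlowEvents(liveConfig(20000, 281))
  g <- classifyGFP(applyGates(sim)$events)
  n <- g$gfp_pos + g$gfp_neg
  se <- sqrt(0.25 / n)
  expect_lt(abs(g$gfp_pos / n - 0.5), 3 * se + 0.004)
})

test_that("growth ratio formulas match hand arithmetic", {
  s <- function(pos, neg) list(gfp_pos = pos, gfp_neg = neg)
  # W_m = 0.5
  r0 <- growthRatio(s(5000, 5000), s(5000, 5000), s(5000, 5000),
                    s(5000, 5000))
  expect_equal(r0@w_m, 0.5)
  expect_equal(r0@growth_ratio, 1)  # identical samples -> ratio 1

  # W_m = .5, W_r = .5, W_m* = .1, W_r* = .5 -> W_n 1, W_n* 0.2, ratio 0.2
  r1 <- growthRatio(s(5000, 5000), s(9000, 1000), s(5000, 5000),
                    s(5000, 5000))
  expect_equal(r1@w_n, 1)
  expect_equal(r1@w_n_star, 0.2)
  expect_equal(r1@growth_ratio, 0.2)
  expect_false(r1@below_detection)

  # below the detection floor: flagged, not clamped
  r2 <- growthRatio(s(5000, 5000), s(9900, 100), s(5000, 5000),
                    s(5000, 5000))
  expect_true(r2@below_detection)
  expect_gt(r2@growth_ratio, 0)

  expect_error(growthRatio(s(0, 5000), s(1, 1), s(1, 1), s(1, 1)),
               "zero GFP\\+")
})

test_that("swapping mutant and reference runs inverts W_n", {
  s <- function(pos, neg) list(gfp_pos = pos, gfp_neg = neg)
  a <- s(6000, 4000); b <- s(5000, 5000)
  r <- growthRatio(a, a, b, b)
  rsw <- growthRatio(b, b, a, a)
  expect_equal(rsw@w_n, 1 / r@w_n, tolerance = 1e-12)
})

test_that("replicate t-test reproduces the pooled Student form", {
  r <- replicateTest(c(0.9, 1.0, 1.1), c(0.4, 0.5, 0.6))
  expect_equal(r$t, 6.123724, tolerance = 1e-6)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * stats::pt(-6.123724, 4), tolerance = 1e-6)

  same <- replicateTest(c(1, 1, 1), c(1, 1, 1))
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)
  expect_error(replicateTest(1, c(1, 2)), "at least 2")
  # Welch flag reaches the unequal-variance form
  w <- replicateTest(c(0.9, 1.0, 1.1), c(0.1, 0.5, 0.9), welch = TRUE)
  expect_lt(w$df, 4)
})

test_that("growth ratio is stable under 50% event subsampling", {
  comp <- simulateCompetition(0.6, n_events = 40000, seed = 291)
  cg <- function(e) classifyGFP(applyGates(e)$events)
  full <- growthRatio(cg(comp$mutant_untreated), cg(comp$mutant_treated),
                      cg(comp$ref_untreated), cg(comp$ref_treated))
  set.seed(292)
  sub_ratios <- replicate(30, {
    half <- lapply(comp[1:4], function(e)
      e[sample(nrow(e), nrow(e) %/% 2), ])
    growthRatio(cg(half[[1]]), cg(half[[2]]), cg(half[[3]]),
                cg(half[[4]]))@growth_ratio
  })
  expect_lt(abs(mean(sub_ratios) / full@growth_ratio - 1), 0.02)
})

test_that("flow CSV round trip validates the schema", {
  ev <- simulateFlowEvents(liveConfig(50, 301))
  csv <- tempfile(fileext = ".csv")
  writeFlowCSV(ev, csv)
  back <- readFlowCSV(csv)
  expect_equal(back$FITC, ev$FITC, tolerance = 1e-6)
  bad <- ev
  names(bad)[1] <- "FSC"
  expect_error(writeFlowCSV(bad, csv), "needs columns")
})
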