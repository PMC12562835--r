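test_that("study-scale configuration mirrors the study design", {
  cfg <- studyLikeConfig(seed = 1)
  expect_equal(cfg@nPairs, 183L)
  m <- as.integer(names(cfg@meiosesProb))
  expect_equal(range(m), c(4L, 16L))
  expect_equal(sum(cfg@meiosesProb), 1)
  # expected meioses total over 183 pairs is the study's 1576
  expect_equal(183 * sum(m * cfg@meiosesProb), 1576, tolerance = 1e-9)
  expect_equal(unname(mutationRates(cfg@panel)["DYS627"]), 21 / 1576)
})

test_that("simulation is deterministic under a fixed seed", {
  s1 <- simulatePairs(studyLikeConfig(seed = 5))
  s2 <- simulatePairs(studyLikeConfig(seed = 5))
  expect_identical(s1$haplotypes@calls, s2$haplotypes@calls)
  expect_identical(s1$truth, s2$truth)
  expect_identical(as.data.frame(s1$pairs), as.data.frame(s2$pairs))
  s3 <- simulatePairs(studyLikeConfig(seed = 6))
  expect_false(identical(s1$truth, s3$truth))
})

test_that("a mutation-free panel yields identical pairs", {
  cfg <- simConfig(yfilerPlusPanel("zero"), nPairs = 40,
                   meiosesProb = stats::setNames(rep(1 / 13, 13), 4:16),
                   seed = 2)
  sim <- simulatePairs(cfg)
  expect_equal(nrow(sim$truth), 0L)
  cmp <- comparePairs(sim$haplotypes, sim$pairs)
  expect_equal(sum(pairSummary(cmp)$n_events), 0L)
  expect_equal(differentiationRate(cmp, perMeiosis = FALSE)$rate, 0)
})

test_that("per-meiosis mutation probability is honoured (binomial check)", {
  # single locus, mu = 0.5, m = 1: the mutated fraction is Binomial(n, 1/2)
  panel <- YstrPanel("L1", copies = 1L, mu = 0.5,
                     min_allele = 10, max_allele = 30)
  n <- 2000L
  cfg <- simConfig(panel, nPairs = n, meiosesProb = c("1" = 1), seed = 11)
  sim <- simulatePairs(cfg)
  mutated <- length(unique(sim$truth$family_id))
  se <- sqrt(n * 0.25)
  expect_lt(abs(mutated - n * 0.5), 3 * se)
})

test_that("inferred events never exceed simulated truth without dup/del", {
  cfg <- studyLikeConfig(seed = 13)
  cfg@pDupDel <- 0            # truth-vs-inference bound needs pure steps
  sim <- simulatePairs(cfg)
  cmp <- comparePairs(sim$haplotypes, sim$pairs)
  ev <- mutationEvents(cmp)
  for (key in unique(paste(sim$truth$family_id, sim$truth$locus))) {
    fam <- sub(" .*", "", key); loc <- sub(".* ", "", key)
    trueN <- sum(sim$truth$family_id == fam & sim$truth$locus == loc)
    infN <- sum(ev$family_id == fam & ev$locus == loc)
    expect_lte(infN, trueN)
  }
  # and no event is inferred where none was simulated
  simKeys <- unique(paste(sim$truth$family_id, sim$truth$locus))
  expect_true(all(paste(ev$family_id, ev$locus) %in% simKeys))
})

test_that("simulated differentiation tracks the analytic expectation", {
  # closed form ignoring collisions: P(diff) <= 1 - E_m[prod_l (1-mu_l)^m],
  # and parsimony collisions only push the observed rate below it
  cfg <- studyLikeConfig(seed = 17)
  cfg@nPairs <- 1000L
  cfg@pDupDel <- 0
  sim <- simulatePairs(cfg)
  cmp <- comparePairs(sim$haplotypes, sim$pairs)
  obs <- differentiationRate(cmp, perMeiosis = FALSE)$rate
  mu <- mutationRates(cfg@panel)
  mVals <- as.integer(names(cfg@meiosesProb))
  q <- prod(1 - mu)
  analytic <- 1 - sum(cfg@meiosesProb * q^mVals)
  se <- sqrt(analytic * (1 - analytic) / cfg@nPairs)
  expect_lte(obs, analytic + 3 * se)
  expect_gte(obs, analytic - 0.03 - 3 * se)   # collision loss is small
})

test_that("expected differentiation is non-decreasing in meioses", {
  panel <- yfilerPlusPanel("study")
  rates <- vapply(c(4L, 9L, 16L), function(m) {
    cfg <- simConfig(panel, nPairs = 400,
                     meiosesProb = stats::setNames(1, m),
                     pDupDel = 0, seed = 19 + m)
    sim <- simulatePairs(cfg)
    cmp <- comparePairs(sim$haplotypes, sim$pairs)
    differentiationRate(cmp, perMeiosis = FALSE)$rate
  }, numeric(1))
  mcTol <- 3 * sqrt(0.25 / 400)
  expect_gte(rates[2], rates[1] - mcTol)
  expect_gte(rates[3], rates[2] - mcTol)
  expect_gt(rates[3], rates[1])   # clear separation between 4 and 16
})

test_that("discordance histogram matches the truth log after parsimony", {
  cfg <- studyLikeConfig(seed = 23)
  cfg@pDupDel <- 0
  sim <- simulatePairs(cfg)
  cmp <- comparePairs(sim$haplotypes, sim$pairs)
  dist <- discordanceDistribution(cmp)
  expect_equal(sum(dist$counts), 183L)
  # every pair's inferred count is bounded by its simulated count
  trueByFam <- table(sim$truth$family_id)
  pp <- pairSummary(cmp)
  for (i in seq_len(nrow(pp))) {
    trueN <- if (pp$family_id[i] %in% names(trueByFam))
      as.integer(trueByFam[[pp$family_id[i]]]) else 0L
    expect_lte(pp$n_events[i], trueN)
  }
  # total inferred mutations conserved across summaries
  expect_equal(sum(pp$n_events), nrow(mutationEvents(cmp)))
  expect_equal(sum(as.integer(names(dist$counts)) * dist$counts),
               nrow(mutationEvents(cmp)))
})

test_that("degenerate configurations are rejected", {
  panel <- toyPanel()
  expect_error(simConfig(panel, 0, c("4" = 1)), "nPairs")
  expect_error(simConfig(panel, 5, c(0.5, 0.5)), "named")
  bad <- simConfig(panel, 5, c("4" = 1))
  expect_error({bad@pDupDel <- 1.5; validObject(bad)}, "probabilities")
})
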