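test_that("rate estimation sums events and meioses across pairs", {
  # two pairs: one with 2 events at DYS627, one clean; meioses 8 + 6
  panel <- toyPanel()
  haps <- YstrHaplotypes(
    list(A = list(DYS390 = 24, DYS627 = 20, DYS448 = 20, DYS385 = c(11, 14)),
         B = list(DYS390 = 24, DYS627 = 22, DYS448 = 20, DYS385 = c(11, 14)),
         C = list(DYS390 = 23, DYS627 = 19, DYS448 = 21, DYS385 = c(12, 13)),
         D = list(DYS390 = 23, DYS627 = 19, DYS448 = 21, DYS385 = c(12, 13))),
    panel)
  cmp <- comparePairs(haps, PedigreePairs(c("F1", "F2"), c("A", "C"),
                                          c("B", "D"), c(8L, 6L)))
  r <- estimateRates(cmp)
  expect_equal(r$meioses, rep(14L, 4))
  expect_equal(r$mutations[r$locus == "DYS627"], 2L)
  expect_equal(r$rate[r$locus == "DYS627"], 2 / 14)
  expect_equal(r$mutations[r$locus != "DYS627"], rep(0L, 3))
  # interval invariants: 0 <= lower <= rate <= upper <= 1
  expect_true(all(r$ci_lower >= 0 & r$ci_lower <= r$rate &
                    r$rate <= r$ci_upper & r$ci_upper <= 1))
})

test_that("counts-only rates reproduce the published point estimates", {
  r <- ratesFromCounts(studyCounts())
  expect_equal(roundHalfUp(r$rate[r$locus == "DYS627"], 3), 0.013)  # 21/1576
  expect_equal(r$rate[r$locus == "DYS19"], 0)
  expect_equal(sum(r$mutations), 161L)
  expect_error(ratesFromCounts(data.frame(locus = "L", mutations = 1,
                                          meioses = 0)), "meioses")
  # x = N boundary
  b <- ratesFromCounts(data.frame(locus = "L", mutations = 5, meioses = 5))
  expect_equal(b$rate, 1)
  expect_equal(b$ci_upper, 1)
})

test_that("Clopper-Pearson intervals are exact beta-quantile bounds", {
  ci <- ciClopperPearson(0, 1576)
  expect_equal(ci$lower, 0)
  expect_equal(ci$upper, 1 - 0.025^(1 / 1576))   # closed form at x = 0
  expect_equal(roundHalfUp(ci$upper, 3), 0.002)
  ci <- ciClopperPearson(20, 1576)
  expect_equal(roundHalfUp(ci$lower, 3), 0.008)
  expect_equal(roundHalfUp(ci$upper, 3), 0.020)
  expect_equal(ciClopperPearson(5, 5)$upper, 1)
  # agrees with the exact binomial test's interval
  for (x in c(1, 7, 40)) {
    bt <- stats::binom.test(x, 100)$conf.int
    ci <- ciClopperPearson(x, 100)
    expect_equal(c(ci$lower, ci$upper), as.numeric(bt))
  }
  expect_error(ciClopperPearson(6, 5), "x must")
  expect_error(ciClopperPearson(1, 5, alpha = 1.2), "alpha")
})

test_that("Wilson intervals have the score-interval shape", {
  expect_equal(ciWilson(0, 10)$lower, 0)          # x = 0 forces lower = 0
  expect_equal(ciWilson(10, 10)$upper, 1)
  # symmetric about 0.5 at x = N/2
  ci <- ciWilson(50, 100)
  expect_equal(ci$lower + ci$upper, 1)
  # contains x/N, stays in [0, 1]
  for (x in c(1, 13, 99)) {
    ci <- ciWilson(x, 100)
    expect_true(ci$lower <= x / 100 && x / 100 <= ci$upper)
    expect_true(ci$lower >= 0 && ci$upper <= 1)
  }
  # narrower than Clopper-Pearson at the study's scale
  w <- ciWilson(13, 1576); cp <- ciClopperPearson(13, 1576)
  expect_lt(w$upper - w$lower, cp$upper - cp$lower)
  expect_true(w$lower <= 13 / 1576 && 13 / 1576 <= w$upper)
})

test_that("Wilson widths do not exceed Clopper-Pearson widths on a grid", {
  for (n in c(30, 100, 1576))
    for (x in unique(pmin(n - 1, c(1, 2, 5, 10, n %/% 4, n %/% 2, n - 1)))) {
      w <- ciWilson(x, n); cp <- ciClopperPearson(x, n)
      expect_lte(w$upper - w$lower, cp$upper - cp$lower)
    }
})

test_that("Clopper-Pearson coverage at study scale is at least nominal", {
  set.seed(101)
  nRep <- 2000; n <- 1576; p <- 0.008
  x <- rbinom(nRep, n, p)
  ci <- ciClopperPearson(x, n)
  covered <- mean(ci$lower <= p & p <= ci$upper)
  mcTol <- 3 * sqrt(0.95 * 0.05 / nRep)
  expect_gte(covered, 0.95 - mcTol)
})

test_that("Fisher's exact p matches enumeration and the reference test", {
  # identical rates, same N: no association
  expect_equal(compareRates(5, 50, 5, 50)$p_value, 1.0)
  # extreme 2x2 table equals full enumeration
  expect_equal(compareRates(0, 10, 10, 10)$p_value,
               unname(oracleFisherAll(10, 10, 10)["0"]))
  # row swap invariance and range
  set.seed(3)
  for (i in 1:50) {
    n1 <- sample(1:40, 1); n2 <- sample(1:40, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    p12 <- compareRates(x1, n1, x2, n2)$p_value
    p21 <- compareRates(x2, n2, x1, n1)$p_value
    expect_equal(p12, p21)
    expect_true(p12 > 0 && p12 <= 1)
    # agreement with the standard implementation
    ft <- stats::fisher.test(matrix(c(x1, n1 - x1, x2, n2 - x2), 2,
                                    byrow = TRUE))$p.value
    expect_equal(p12, min(ft, 1), tolerance = 1e-12)
  }
})

test_that("reference counts reconstructed from rates are flagged", {
  expect_warning(x2 <- reconstructCounts(0.010, 1000), "approximate")
  expect_equal(x2, 10L)
  # sensitivity: reconstructed-count p-values move with x2 +- 1
  ps <- vapply(9:11, function(x) compareRates(1, 1575, x, 1000)$p_value,
               numeric(1))
  expect_true(all(diff(ps) < 0))   # more reference events, smaller p here
})
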