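test_that("single-copy parsimony counting follows the stepwise rules", {
  # a 2-repeat shift is two single-step mutations
  ev <- countSingleCopy(10, 12, "DYS390")
  expect_equal(ev$kind, c("single_step", "single_step"))
  expect_equal(ev$steps, c(1L, 1L))
  # identity
  expect_equal(nrow(countSingleCopy(13, 13, "DYS392")), 0L)
  # null vs called allele is one deletion; shared nulls are inherited state
  expect_equal(countSingleCopy(20, NA, "DYS448")$kind, "deletion")
  expect_equal(nrow(countSingleCopy(NA, NA, "DYS448")), 0L)
  # microvariant mismatch is one irreducible complex event, symmetric
  expect_equal(countSingleCopy(16, 16.2, "DYS458")$kind, "complex")
  expect_equal(countSingleCopy(16.2, 16, "DYS458"),
               countSingleCopy(16, 16.2, "DYS458"))
  # same microvariant class steps normally: 20.2 vs 22.2 is two steps
  expect_equal(countSingleCopy(20.2, 22.2, "DYS627")$kind,
               rep("single_step", 2))
})

test_that("multi-copy counting matches the spec'd interpretations", {
  # inherited duplication: identical multisets, no event
  expect_equal(nrow(countMultiCopy(c(15, 17), c(15, 17), "DYS19", 1L)), 0L)
  # one-step difference in one copy
  expect_equal(countMultiCopy(c(36, 38), c(36, 39), "DYF387S1")$kind,
               "single_step")
  # copy-number gain beyond the expected count is one duplication
  expect_equal(countMultiCopy(15, c(15, 16), "DYS19", 1L)$kind, "duplication")
  # identity-shift matching beats crossed matching: 2 steps, not 4
  ev <- countMultiCopy(c(35, 37), c(36, 38), "DYF387S1")
  expect_equal(ev$kind, rep("single_step", 2))
  # single peak vs homoallelic pair: tie resolved to no event
  expect_equal(nrow(countMultiCopy(14, c(14, 14), "DYS385")), 0L)
  # single peak at a 2-copy locus vs two distinct alleles: missing copy
  expect_equal(countMultiCopy(36, c(36, 38), "DYF387S1")$kind, "deletion")
  # locus-wide null against alleles is a single deletion
  expect_equal(countMultiCopy(NA_real_, c(14, 15), "DYS385")$kind, "deletion")
  expect_error(countMultiCopy(c(1, 2, 3, 4, 5), 14, "DYS385"), "4 copies")
})

test_that("multi-copy counting equals the exhaustive enumeration oracle", {
  sets <- oracleMultisets(10:13, sizes = 1:3)
  for (A in sets) for (B in sets) {
    got <- nrow(countMultiCopy(A, B, "L", 2L))
    want <- oracleMinEvents(A, B, 2L)
    if (got != want)
      fail(sprintf("mismatch at {%s} vs {%s}: %d != %d",
                   paste(A, collapse = ","), paste(B, collapse = ","),
                   got, want))
  }
  succeed()
  # microvariant corner: oracle agreement with fractional alleles
  mv <- list(16, 16.2, c(16, 16.2), c(16.2, 17.2), c(15, 16.2, 17))
  for (A in mv) for (B in mv)
    expect_equal(nrow(countMultiCopy(A, B, "L", 2L)),
                 oracleMinEvents(A, B, 2L),
                 info = paste(paste(A, collapse = ","), "vs",
                              paste(B, collapse = ",")))
})

test_that("pair comparison is symmetric and zero on identical haplotypes", {
  cmp0 <- toyPairSet()
  expect_equal(pairSummary(cmp0)$n_events, 0L)
  expect_equal(pairSummary(cmp0)$n_loci_discordant, 0L)

  cmp1 <- toyPairSet(list(DYS627 = 21))
  expect_equal(mutationEvents(cmp1)$locus, "DYS627")
  expect_equal(pairSummary(cmp1)$n_events, 1L)

  # symmetry under swapping the two haplotypes, across random haplotypes
  set.seed(42)
  panel <- toyPanel()
  for (i in 1:25) {
    mk <- function() list(DYS390 = sample(20:26, 1),
                          DYS627 = sample(c(18:22, 20.2), 1),
                          DYS448 = sample(c(18:21, NA), 1),
                          DYS385 = sort(sample(10:14, sample(1:3, 1),
                                               replace = TRUE)))
    c1 <- mk(); c2 <- mk()
    e12 <- comparePair(c1, c2, panel, "p")
    e21 <- comparePair(c2, c1, panel, "p")
    expect_equal(e12[order(e12$locus, e12$kind), c("locus", "kind")],
                 e21[order(e21$locus, e21$kind), c("locus", "kind")],
                 ignore_attr = TRUE)
  }
})

test_that("event-type accounting is conserved", {
  cmp <- toyPairSet(list(DYS390 = 27, DYS627 = 20.2, DYS448 = NA_real_,
                         DYS385 = c(11, 14, 15)))
  ev <- mutationEvents(cmp)
  expect_equal(nrow(ev), sum(ev$kind == "single_step") +
                 sum(ev$kind == "duplication") + sum(ev$kind == "deletion") +
                 sum(ev$kind == "complex"))
  expect_equal(pairSummary(cmp)$n_events, nrow(ev))
  expect_setequal(unique(ev$locus),
                  c("DYS390", "DYS627", "DYS448", "DYS385"))
})

test_that("pairs with more than the mutation threshold are excluded", {
  # 16 events: 3 steps at DYS390 + 13 at DYS627
  many <- toyPairSet(list(DYS390 = 27, DYS627 = 7))
  expect_equal(pairSummary(many)$n_events, 16L)
  expect_message(f <- filterPairs(many, 15L), "excluding 1 pair")
  expect_equal(length(f$kept), 0L)
  expect_equal(length(f$excluded), 1L)

  # exactly 15 events is kept ("more than 15" excludes)
  fifteen <- toyPairSet(list(DYS390 = 27, DYS627 = 8))
  expect_equal(pairSummary(fifteen)$n_events, 15L)
  f <- filterPairs(fifteen, 15L)
  expect_equal(length(f$kept), 1L)
  # and a zero-event pair is kept
  f0 <- filterPairs(toyPairSet(), 15L)
  expect_equal(length(f0$kept), 1L)
})

test_that("parsimony never overcounts net single-copy drift", {
  # on simulated single-copy walks, inferred events <= true event count
  set.seed(7)
  for (rep in 1:200) {
    k <- rpois(1, 2)                       # true number of step events
    steps <- sample(c(-1L, 1L), k, replace = TRUE)
    a <- 20L
    b <- a + sum(steps)
    ev <- countSingleCopy(a, b, "L")
    expect_lte(nrow(ev), k)
    expect_equal(nrow(ev), abs(sum(steps)))   # parsimony = |net drift|
  }
})
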