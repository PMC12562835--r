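## ---- event construction ---------------------------------------------------

.noEvents <- function() {
  data.frame(locus = character(), kind = character(), steps = integer(),
             stringsAsFactors = FALSE)
}

.events <- function(locus, kind, n = 1L) {
  if (n == 0L) return(.noEvents())
  data.frame(locus = locus, kind = rep(kind, n), steps = rep(1L, n),
             stringsAsFactors = FALSE)
}

## events explaining one matched copy pair (both alleles non-null).
## Same microvariant class: |difference| single-step units, decomposed into
## that many single_step events. Different fractional part: one irreducible
## "complex" event (a partial-repeat change is never decomposed into steps).
.copyPairEvents <- function(a, b, locus) {
  da <- .deci(a); db <- .deci(b)
  if (da == db) return(.noEvents())
  if (da %% 10L != db %% 10L) return(.events(locus, "complex"))
  .events(locus, "single_step", abs(da - db) %/% 10L)
}

.nEventsOf <- function(ev) nrow(ev)

## event count of one matched copy pair without materialising the table
.copyPairCost <- function(a, b) {
  da <- .deci(a); db <- .deci(b)
  if (da == db) 0L
  else if (da %% 10L != db %% 10L) 1L
  else abs(da - db) %/% 10L
}

## ---- single-copy counting -------------------------------------------------

#' Minimum-mutation events between two single-copy alleles
#'
#' Applies the parsimony rules for a single-copy marker: equal alleles give
#' no event; a k-repeat difference between alleles of the same microvariant
#' class is decomposed into k `single_step` events (a multi-step difference
#' between non-adjacent relatives is interpreted as multiple single-step
#' mutations distributed along the lineage); a microvariant (fractional-part)
#' mismatch is one `complex` event; a null against a called allele is one
#' `deletion` event; two nulls are a shared inherited state (no event).
#'
#' @param a,b numeric alleles (`NA` = null call).
#' @param locus marker name used in the returned event table.
#' @return a `data.frame` of events with columns `locus`, `kind`, `steps`
#'   (zero rows if the alleles agree).
#' @examples
#' countSingleCopy(10, 12, "DYS390")      # two single_step events
#' countSingleCopy(20, NA, "DYS448")      # one deletion
#' countSingleCopy(16, 16.2, "DYS458")    # one complex event
#' @export
countSingleCopy <- function(a, b, locus = "locus") {
  if (is.na(a) && is.na(b)) return(.noEvents())
  if (is.na(a) || is.na(b)) return(.events(locus, "deletion"))
  .copyPairEvents(a, b, locus)
}

## ---- multi-copy counting --------------------------------------------------

## all permutations of 1..n (n <= 4 in panel biology)
.perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .perms(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  out
}

## minimum-cost bijection between two equal-size allele vectors; returns the
## event list of the cheapest matching (ties broken by permutation order on
## the sorted inputs, which is deterministic)
.matchEqual <- function(A, B, locus) {
  n <- length(A)
  P <- .perms(n)
  bestPerm <- NULL
  bestCost <- Inf
  for (r in seq_len(nrow(P))) {
    cost <- 0L
    for (i in seq_len(n)) cost <- cost + .copyPairCost(A[i], B[P[r, i]])
    if (cost < bestCost) {
      bestCost <- cost
      bestPerm <- P[r, ]
    }
  }
  if (bestCost == 0L) return(.noEvents())
  do.call(rbind, lapply(seq_len(n), function(i)
    .copyPairEvents(A[i], B[bestPerm[i]], locus)))
}

## copy-number-change scenario: match a size-|small| subset of the larger
## multiset against the smaller one; each unmatched copy of the larger set is
## one duplication/deletion event. The gained/lost copies are chosen to
## minimise the residual step cost, then to be the smallest alleles.
.matchUnequal <- function(A, B, locus, expectedCopies) {
  swap <- length(A) > length(B)
  small <- if (swap) B else A
  large <- if (swap) A else B
  kind <- if (max(length(A), length(B)) > expectedCopies)
    "duplication" else "deletion"
  d <- length(large) - length(small)
  sel <- utils::combn(seq_along(large), length(small))
  bestIdx <- NULL
  bestKey <- c(Inf, Inf)
  for (j in seq_len(ncol(sel))) {
    idx <- sel[, j]
    resid <- .matchEqual(small, large[idx], locus)
    extra <- sum(large[-idx])          # prefer the smaller gained/lost allele
    key <- c(.nEventsOf(resid), extra)
    if (key[1] < bestKey[1] || (key[1] == bestKey[1] && key[2] < bestKey[2])) {
      bestKey <- key
      bestIdx <- idx
    }
  }
  rbind(.events(locus, kind, d), .matchEqual(small, large[bestIdx], locus))
}

#' Minimum-mutation events between two allele multisets
#'
#' Parsimony counting at a (potentially) multi-copy marker. Equal multisets
#' give no event (covers inherited duplications/deletions). Equal-size
#' multisets are matched by the minimum-total-step bijection, with
#' differences decomposed into `single_step` events (and `complex` events for
#' microvariant mismatches). A copy-number difference costs exactly one
#' `duplication` or `deletion` event per gained/lost copy, choosing the
#' changed copy so that the residual matching cost is minimal (ties broken
#' toward the smaller allele); the event is a `duplication` when the larger
#' multiset exceeds the marker's expected copy number, otherwise a
#' `deletion`.
#'
#' A single displayed allele at an expected two-copy marker is ambiguous: a
#' one-copy state (deletion candidate) or a homoallelic pair whose two copies
#' share one electrophoretic peak. Both interpretations are scored and the
#' cheaper wins; ties go to the homoallelic reading (no copy-number event).
#'
#' A locus-wide null (`NA`) against called alleles is one `deletion` event;
#' two nulls are a shared state (no event).
#'
#' @param A,B numeric allele multisets (each `NA` alone = null call); at most
#'   4 copies (larger multisets are outside panel biology and error).
#' @param locus marker name for the event table.
#' @param expectedCopies expected copy number of the marker (1 or 2).
#' @return a `data.frame` of events (columns `locus`, `kind`, `steps`).
#' @examples
#' countMultiCopy(c(36, 38), c(36, 39), "DYF387S1")   # one single_step
#' countMultiCopy(15, c(15, 16), "DYS19", expectedCopies = 1)  # duplication
#' countMultiCopy(c(15, 17), c(15, 17), "DYS19", expectedCopies = 1)  # none
#' @export
countMultiCopy <- function(A, B, locus = "locus", expectedCopies = 2L) {
  if (length(A) > 4L || length(B) > 4L)
    stop("more than 4 copies at ", locus, ": outside panel biology",
         call. = FALSE)
  if (length(A) < 1L || length(B) < 1L)
    stop("empty allele multiset at ", locus, call. = FALSE)
  if (anyNA(A) && anyNA(B)) return(.noEvents())
  if (anyNA(A) || anyNA(B)) return(.events(locus, "deletion"))
  A <- sort(A); B <- sort(B)
  ## fast path: identical multisets (incl. inherited dup/del) have no event
  if (length(A) == length(B) && all(.deci(A) == .deci(B)))
    return(.noEvents())

  ## candidate readings of each side: as observed, plus the homoallelic
  ## expansion of a single peak at an expected two-copy marker
  expand <- function(X) {
    out <- list(list(alleles = X, expanded = FALSE))
    if (length(X) == 1L && expectedCopies == 2L)
      out <- c(out, list(list(alleles = rep(X, 2L), expanded = TRUE)))
    out
  }
  best <- NULL
  bestKey <- c(Inf, Inf)
  for (ai in expand(A)) for (bi in expand(B)) {
    Ai <- ai$alleles; Bi <- bi$alleles
    ev <- if (length(Ai) == length(Bi)) .matchEqual(Ai, Bi, locus)
          else .matchUnequal(Ai, Bi, locus, expectedCopies)
    nCopyEv <- sum(ev$kind %in% c("duplication", "deletion"))
    key <- c(.nEventsOf(ev), nCopyEv)   # tie -> homoallelic (no copy event)
    if (key[1] < bestKey[1] || (key[1] == bestKey[1] && key[2] < bestKey[2])) {
      bestKey <- key
      best <- ev
    }
  }
  best
}

## ---- pair-level comparison ------------------------------------------------

#' Compare one pedigree pair locus by locus
#'
#' Runs parsimony mutation counting ([countMultiCopy()]) at every panel
#' marker and concatenates the per-locus event lists. Deterministic given its
#' inputs; symmetric in the two haplotypes.
#'
#' @param calls1,calls2 named per-locus call lists for the two males (as
#'   returned by [alleleCalls()]).
#' @param panel a [YstrPanel-class].
#' @param family_id pedigree identifier attached to the events.
#' @return a `data.frame` of events with columns `family_id`, `locus`,
#'   `kind`, `steps`.
#' @seealso [comparePairs()] for whole-manifest comparison.
#' @export
comparePair <- function(calls1, calls2, panel, family_id = "pair") {
  specs <- panel@specs
  evs <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    l <- specs$locus[i]
    ev <- tryCatch(
      countMultiCopy(calls1[[l]], calls2[[l]], l, specs$copies[i]),
      error = function(e) stop(sprintf("pair %s, locus %s: %s", family_id, l,
                                       conditionMessage(e)), call. = FALSE))
    evs[[i]] <- ev
  }
  ev <- do.call(rbind, evs)
  if (is.null(ev) || !nrow(ev)) {
    ev <- .noEvents()
    ev$family_id <- character()
  } else ev$family_id <- family_id
  ev[c("family_id", "locus", "kind", "steps")]
}

#' Compare all pairs of a manifest against a haplotype table
#'
#' Joins each pedigree pair to its two haplotypes (a sample id absent from
#' the haplotype table is an error at this point) and infers the
#' minimum-mutation explanation of every pair's differences.
#'
#' @param haplotypes a [YstrHaplotypes-class].
#' @param pairs a [PedigreePairs-class].
#' @return a [PairComparisonSet-class].
#' @examples
#' cfg <- studyLikeConfig(seed = 7)
#' sim <- simulatePairs(cfg)
#' cmp <- comparePairs(sim$haplotypes, sim$pairs)
#' cmp
#' @export
comparePairs <- function(haplotypes, pairs) {
  p <- pairs@pairs
  panel <- haplotypes@panel
  evs <- vector("list", nrow(p))
  nEv <- integer(nrow(p))
  nLoci <- integer(nrow(p))
  for (i in seq_len(nrow(p))) {
    for (s in c(p$sample1[i], p$sample2[i]))
      if (!s %in% haplotypes@sampleIds)
        stop(sprintf("sample %s (pair %s) not present in haplotype table",
                     s, p$family_id[i]), call. = FALSE)
    ev <- comparePair(haplotypes@calls[[p$sample1[i]]],
                      haplotypes@calls[[p$sample2[i]]],
                      panel, p$family_id[i])
    evs[[i]] <- ev
    nEv[i] <- nrow(ev)
    nLoci[i] <- length(unique(ev$locus))
  }
  events <- do.call(rbind, evs)
  if (is.null(events)) {
    events <- .noEvents()
    events$family_id <- character()
    events <- events[c("family_id", "locus", "kind", "steps")]
  }
  rownames(events) <- NULL
  perPair <- data.frame(family_id = p$family_id, meioses = p$meioses,
                        n_events = nEv, n_loci_discordant = nLoci,
                        stringsAsFactors = FALSE)
  new("PairComparisonSet", events = events, perPair = perPair, panel = panel)
}

#' Exclude pairs with too many mutations to be plausibly related
#'
#' Pairs showing more than `maxMutations` inferred mutations are unlikely to
#' be truly patrilineally related (mis-recorded genealogy or non-paternity)
#' and are excluded from rate estimation; the study-like threshold is 15
#' (strictly more than 15 excludes, exactly 15 is kept).
#'
#' @param comparisons a [PairComparisonSet-class].
#' @param maxMutations exclusion threshold (pairs with total events
#'   strictly greater are dropped).
#' @return a list with [PairComparisonSet-class] elements `kept` and
#'   `excluded`.
#' @export
filterPairs <- function(comparisons, maxMutations = 15L) {
  pp <- comparisons@perPair
  drop <- pp$n_events > maxMutations
  if (any(drop))
    message(sprintf("excluding %d pair(s) with > %d mutations: %s",
                    sum(drop), maxMutations,
                    paste(sprintf("%s (%d)", pp$family_id[drop],
                                  pp$n_events[drop]), collapse = ", ")))
  subsetOf <- function(keep) {
    ids <- pp$family_id[keep]
    new("PairComparisonSet",
        events = comparisons@events[comparisons@events$family_id %in% ids, ,
                                    drop = FALSE],
        perPair = pp[keep, , drop = FALSE],
        panel = comparisons@panel)
  }
  list(kept = subsetOf(!drop), excluded = subsetOf(drop))
}

#' @rdname PairComparisonSet-class
#' @aliases mutationEvents,PairComparisonSet-method
setMethod("mutationEvents", "PairComparisonSet", function(x) x@events)

#' @rdname PairComparisonSet-class
#' @aliases pairSummary,PairComparisonSet-method
setMethod("pairSummary", "PairComparisonSet", function(x) x@perPair)

setMethod("length", "PairComparisonSet", function(x) nrow(x@perPair))

setMethod("show", "PairComparisonSet", function(object) {
  pp <- object@perPair
  ev <- object@events
  cat(sprintf("PairComparisonSet: %d pairs, %d meioses, %d mutations\n",
              nrow(pp), sum(pp$meioses), nrow(ev)))
  if (nrow(ev)) {
    tb <- table(ev$kind)
    cat("  events:", paste(sprintf("%s=%d", names(tb), as.integer(tb)),
                           collapse = ", "), "\n")
  }
  cat(sprintf("  differentiated pairs: %d (%.1f%%)\n",
              sum(pp$n_events > 0),
              100 * mean(pp$n_events > 0)))
})
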