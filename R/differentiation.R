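#' Male relative differentiation rates by meioses stratum
#'
#' A pair is differentiated when its two haplotypes show at least one allelic
#' difference, i.e. at least one inferred mutation event of any kind
#' (single-step, duplication/deletion, or complex). The differentiation rate
#' of a stratum is the proportion of its pairs that are differentiated, with
#' an exact Clopper-Pearson confidence interval.
#'
#' @param comparisons a [PairComparisonSet-class].
#' @param perMeiosis also report one stratum per observed meioses value.
#' @param ranges optional list of length-2 integer vectors giving inclusive
#'   meioses ranges to report (e.g. `list(c(4, 13))`). A range matching no
#'   pair yields an `n_pairs = 0` row with `NA` rate, flagged by `empty`.
#' @param alpha significance level for the Clopper-Pearson interval.
#' @return `data.frame` with columns `stratum`, `n_pairs`,
#'   `n_differentiated`, `rate`, `ci_lower`, `ci_upper`, `empty`; the first
#'   row is the `"all"` stratum.
#' @examples
#' sim <- simulatePairs(studyLikeConfig(seed = 11))
#' cmp <- comparePairs(sim$haplotypes, sim$pairs)
#' differentiationRate(cmp, ranges = list(c(4, 13)))[1:3, ]
#' @export
differentiationRate <- function(comparisons, perMeiosis = TRUE,
                                ranges = list(), alpha = 0.05) {
  pp <- comparisons@perPair
  if (!nrow(pp)) stop("no pairs to summarise", call. = FALSE)
  diffd <- pp$n_events > 0L
  strata <- list(list(name = "all", sel = rep(TRUE, nrow(pp))))
  if (perMeiosis)
    for (m in sort(unique(pp$meioses)))
      strata <- c(strata, list(list(name = as.character(m),
                                    sel = pp$meioses == m)))
  for (r in ranges)
    strata <- c(strata, list(list(name = paste0(r[1], "-", r[2]),
                                  sel = pp$meioses >= r[1] &
                                        pp$meioses <= r[2])))
  rows <- lapply(strata, function(st) {
    n <- sum(st$sel)
    d <- sum(diffd[st$sel])
    if (n == 0L)
      return(data.frame(stratum = st$name, n_pairs = 0L,
                        n_differentiated = 0L, rate = NA_real_,
                        ci_lower = NA_real_, ci_upper = NA_real_,
                        empty = TRUE, stringsAsFactors = FALSE))
    ci <- ciClopperPearson(d, n, alpha)
    data.frame(stratum = st$name, n_pairs = n, n_differentiated = d,
               rate = d / n, ci_lower = ci$lower, ci_upper = ci$upper,
               empty = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Distribution of per-pair mutation counts and discordant loci
#'
#' Histogram of the number of inferred mutations per pair (including the
#' zero bin, so the counts sum to the number of pairs) and, per marker, the
#' number of pairs showing at least one event at that marker.
#'
#' @param comparisons a [PairComparisonSet-class].
#' @return a list with elements `counts` (named integer vector over
#'   k = 0, 1, 2, ...), `per_locus` (named integer vector over panel
#'   markers), and `n_pairs`.
#' @export
discordanceDistribution <- function(comparisons) {
  pp <- comparisons@perPair
  ev <- comparisons@events
  kmax <- if (nrow(pp)) max(pp$n_events) else 0L
  counts <- vapply(0:kmax, function(k) sum(pp$n_events == k), integer(1))
  names(counts) <- 0:kmax
  loci <- panelLoci(comparisons@panel)
  perLocus <- vapply(loci, function(l)
    length(unique(ev$family_id[ev$locus == l])), integer(1))
  list(counts = counts, per_locus = perLocus, n_pairs = nrow(pp))
}

#' Number of unique full-panel haplotypes
#'
#' Counts distinct haplotypes under per-locus multiset equality (alleles are
#' stored canonically sorted, nulls included). With one man per pedigree this
#' measures the panel's haplotype discrimination capacity among unrelated
#' males.
#'
#' @param haplotypes a [YstrHaplotypes-class].
#' @return integer count of distinct haplotypes.
#' @export
uniqueHaplotypeCount <- function(haplotypes) {
  keys <- vapply(haplotypes@sampleIds, function(s) {
    cl <- haplotypes@calls[[s]]
    paste(vapply(names(cl), function(l)
      paste0(l, "=", paste(formatAllele(cl[[l]]), collapse = ",")),
      character(1)), collapse = ";")
  }, character(1))
  length(unique(keys))
}
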