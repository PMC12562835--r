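#' Round half away from zero
#'
#' Fixed-precision decimal rounding with halves rounded up (0.0005 -> 0.001),
#' the convention used by the report layer; base `round()` rounds halves to
#' even.
#'
#' @param x numeric vector (non-negative in all report uses).
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' roundHalfUp(c(0.0025, 0.0135), 3)
#' @export
roundHalfUp <- function(x, digits = 3L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval from beta quantiles:
#' lower = `qbeta(alpha/2, x, n - x + 1)` (0 when x = 0),
#' upper = `qbeta(1 - alpha/2, x + 1, n - x)` (1 when x = n).
#'
#' @param x successes (mutation count), vectorised.
#' @param n trials (total meioses).
#' @param alpha two-sided significance level (default 0.05 for 95% CI).
#' @return `data.frame` with columns `lower` and `upper`.
#' @examples
#' ciClopperPearson(0, 1576)    # upper ~ 0.0023
#' ciClopperPearson(20, 1576)
#' @export
ciClopperPearson <- function(x, n, alpha = 0.05) {
  .checkBinomArgs(x, n, alpha)
  lower <- ifelse(x == 0, 0, stats::qbeta(alpha / 2, x, n - x + 1))
  upper <- ifelse(x == n, 1, stats::qbeta(1 - alpha / 2, x + 1, n - x))
  data.frame(lower = lower, upper = upper)
}

#' Wilson score binomial confidence interval
#'
#' Closed-form score interval; always contained in \[0, 1\] and containing
#' x/n. The lower bound is exactly 0 at x = 0 and the upper exactly 1 at
#' x = n.
#'
#' @inheritParams ciClopperPearson
#' @return `data.frame` with columns `lower` and `upper`.
#' @export
ciWilson <- function(x, n, alpha = 0.05) {
  .checkBinomArgs(x, n, alpha)
  z <- stats::qnorm(1 - alpha / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  lower <- pmax(0, centre - half)
  upper <- pmin(1, centre + half)
  lower[x == 0] <- 0
  upper[x == n] <- 1
  data.frame(lower = lower, upper = upper)
}

.checkBinomArgs <- function(x, n, alpha) {
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  if (any(x < 0 | x > n)) stop("x must satisfy 0 <= x <= n", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)",
                                     call. = FALSE)
}

.ciFun <- function(method) {
  switch(method, clopper_pearson = ciClopperPearson, wilson = ciWilson)
}

#' Per-locus mutation-rate estimates from pair comparisons
#'
#' Estimates each marker's per-meiosis mutation rate as mu = x / N, where x
#' is the total number of inferred mutations at the marker over all pairs
#' (each decomposed single-step unit and each duplication/deletion/complex
#' event counts as one mutation) and N is the total number of meioses summed
#' over pairs (identical across markers absent locus dropout). Confidence
#' intervals use the exact Clopper-Pearson method by default; the Wilson
#' score interval is available as an alternative.
#'
#' @param comparisons a [PairComparisonSet-class], typically the `kept`
#'   element of [filterPairs()].
#' @param method `"clopper_pearson"` or `"wilson"`.
#' @param alpha two-sided significance level.
#' @return `data.frame` with columns `locus`, `meioses`, `mutations`, `rate`,
#'   `ci_lower`, `ci_upper`, `method`, `alpha`.
#' @seealso [ratesFromCounts()] for the counts-only path.
#' @export
estimateRates <- function(comparisons, method = c("clopper_pearson", "wilson"),
                          alpha = 0.05) {
  method <- match.arg(method)
  N <- sum(comparisons@perPair$meioses)
  if (N == 0) stop("total meioses is zero", call. = FALSE)
  loci <- panelLoci(comparisons@panel)
  x <- vapply(loci, function(l)
    sum(comparisons@events$locus == l), integer(1))
  ratesFromCounts(data.frame(locus = loci, mutations = x, meioses = N,
                             stringsAsFactors = FALSE),
                  method = method, alpha = alpha)
}

#' Per-locus mutation-rate estimates from printed counts
#'
#' Counts-only mode: computes mu = x / N and binomial confidence intervals
#' directly from per-marker (mutations, meioses) totals, without haplotypes.
#' This reproduces a published rate table's statistical columns when the raw
#' genotypes are unavailable.
#'
#' @param counts `data.frame` with columns `locus`, `mutations`, `meioses`
#'   (e.g. [studyCounts()]).
#' @inheritParams estimateRates
#' @return `data.frame` as in [estimateRates()].
#' @examples
#' r <- ratesFromCounts(studyCounts())
#' subset(r, locus == "DYS627")
#' @export
ratesFromCounts <- function(counts, method = c("clopper_pearson", "wilson"),
                            alpha = 0.05) {
  method <- match.arg(method)
  if (!all(c("locus", "mutations", "meioses") %in% names(counts)))
    stop("counts needs columns locus, mutations, meioses", call. = FALSE)
  if (any(counts$meioses < 1)) stop("meioses must be >= 1", call. = FALSE)
  ci <- .ciFun(method)(counts$mutations, counts$meioses, alpha)
  data.frame(locus = counts$locus, meioses = counts$meioses,
             mutations = counts$mutations,
             rate = counts$mutations / counts$meioses,
             ci_lower = ci$lower, ci_upper = ci$upper,
             method = method, alpha = alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

## two-sided Fisher exact p for the 2x2 table [[x1, n1-x1], [x2, n2-x2]]:
## sum of hypergeometric probabilities not exceeding the observed table's
## probability (with the customary 1 + 1e-7 relative guard against
## floating-point ties)
.fisherP <- function(x1, n1, x2, n2) {
  k <- x1 + x2
  supp <- max(0L, k - n2):min(k, n1)
  pr <- stats::dhyper(supp, n1, n2, k)
  p <- sum(pr[pr <= pr[supp == x1] * (1 + 1e-7)])
  min(p, 1)
}

#' Fisher's exact comparison of two mutation rates
#'
#' Two-sided Fisher's exact test of the 2x2 table
#' \[\[x1, N1 - x1\], \[x2, N2 - x2\]\] (this study's mutations/meioses
#' against a reference study's), using the standard
#' "probability less than or equal to the observed table" convention.
#' Vectorised over loci.
#'
#' @param x1,n1 mutation count and meioses of this study.
#' @param x2,n2 mutation count and meioses of the reference study.
#' @param locus optional marker labels.
#' @return `data.frame` with columns `locus`, `x1`, `n1`, `x2`, `n2`,
#'   `rate1`, `rate2`, `p_value`.
#' @seealso [reconstructCounts()] when the reference publishes only rates.
#' @examples
#' compareRates(21, 1576, 15, 1000)
#' @export
compareRates <- function(x1, n1, x2, n2, locus = NA_character_) {
  if (any(c(x1, x2) < 0) || any(c(n1, n2) < 1) || any(x1 > n1) ||
      any(x2 > n2))
    stop("invalid counts", call. = FALSE)
  p <- mapply(.fisherP, x1, n1, x2, n2)
  data.frame(locus = locus, x1 = x1, n1 = n1, x2 = x2, n2 = n2,
             rate1 = x1 / n1, rate2 = x2 / n2, p_value = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Reconstruct integer counts from a published rate
#'
#' Many reference tables print only per-locus rates, not counts. This helper
#' recovers x = round(rate * N) for a given meioses total so that
#' [compareRates()] can be applied, and warns that p-values computed from
#' reconstructed counts are approximate (the true count may differ by
#' rounding of the printed rate).
#'
#' @param rate published per-meiosis rate(s).
#' @param meioses the reference study's meioses total(s).
#' @return integer vector of reconstructed mutation counts.
#' @export
reconstructCounts <- function(rate, meioses) {
  if (any(rate < 0 | rate > 1) || any(meioses < 1))
    stop("invalid rate or meioses", call. = FALSE)
  warning("counts reconstructed from rounded published rates; ",
          "downstream p-values are approximate", call. = FALSE)
  as.integer(round(rate * meioses))
}
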