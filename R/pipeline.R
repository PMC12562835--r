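.roundCols <- function(df, cols, rounding, digits = 3L) {
  if (rounding == "half_up_3dp")
    for (cl in cols) df[[cl]] <- roundHalfUp(df[[cl]], digits)
  df
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Rate-table report in the published layout
#'
#' Counts-only reporting: formats per-marker totals as a rate table with
#' columns Marker, Total Meioses, Mutations, Mutation Rate and the 95%
#' confidence bounds, optionally appending Fisher's-exact p-values against
#' reference study counts, and optionally writing the table to a TSV file.
#'
#' @param counts `data.frame` with columns `locus`, `mutations`, `meioses`
#'   (default: the bundled study totals, [studyCounts()]).
#' @param refCounts optional named list of reference studies; each element a
#'   `data.frame` with columns `locus`, `mutations`, `meioses`. A p-value
#'   column `p_<name>` is added per reference via [compareRates()].
#' @param method,alpha confidence-interval method and level.
#' @param rounding `"half_up_3dp"` rounds rate and CI columns half-up to 3
#'   decimals (the published precision); `"full_precision"` leaves them
#'   untouched.
#' @param path optional output TSV path.
#' @return the report `data.frame`, invisibly if `path` is given.
#' @examples
#' head(countsReport(), 3)
#' @export
countsReport <- function(counts = studyCounts(), refCounts = list(),
                         method = c("clopper_pearson", "wilson"),
                         alpha = 0.05,
                         rounding = c("half_up_3dp", "full_precision"),
                         path = NULL) {
  method <- match.arg(method)
  rounding <- match.arg(rounding)
  r <- ratesFromCounts(counts, method = method, alpha = alpha)
  out <- data.frame(marker = r$locus, total_meioses = r$meioses,
                    mutations = r$mutations, mutation_rate = r$rate,
                    ci_lower = r$ci_lower, ci_upper = r$ci_upper,
                    stringsAsFactors = FALSE)
  for (nm in names(refCounts)) {
    rc <- refCounts[[nm]]
    idx <- match(out$marker, rc$locus)
    cmp <- compareRates(out$mutations, out$total_meioses,
                        rc$mutations[idx], rc$meioses[idx])
    out[[paste0("p_", nm)]] <- cmp$p_value
  }
  out <- .roundCols(out, c("mutation_rate", "ci_lower", "ci_upper"), rounding)
  if (!is.null(path)) {
    .writeTsv(out, path)
    return(invisible(out))
  }
  out
}

#' Run the full pedigree rate-estimation pipeline
#'
#' End-to-end orchestration: parsimony comparison of every pair, exclusion
#' of pairs exceeding the mutation threshold, per-marker rate estimation
#' with confidence intervals, differentiation-rate summaries, and the
#' discordance distribution. When `outDir` is given, writes `events.tsv`
#' (family_id, locus, kind, steps), `rates.tsv` (published-table layout),
#' `diff.tsv`, and `summary.json` with run totals (pairs, meioses,
#' mutations, event-type breakdown, differentiation rate); outputs are
#' deterministic given the same inputs.
#'
#' @param haplotypes a [YstrHaplotypes-class].
#' @param pairs a [PedigreePairs-class].
#' @param outDir optional output directory (created if needed).
#' @param maxMutations exclusion threshold passed to [filterPairs()].
#' @param method,alpha confidence-interval method and level.
#' @param ranges meioses ranges passed to [differentiationRate()].
#' @param rounding report rounding mode, see [countsReport()].
#' @return (invisibly when writing) a list with elements `comparisons`
#'   (kept pairs), `excluded`, `rates`, `differentiation`, `distribution`,
#'   `summary` (the list serialised to `summary.json`) and `files`.
#' @examples
#' sim <- simulatePairs(studyLikeConfig(seed = 5))
#' res <- runPipeline(sim$haplotypes, sim$pairs)
#' res$summary$total_mutations
#' @export
runPipeline <- function(haplotypes, pairs, outDir = NULL, maxMutations = 15L,
                        method = c("clopper_pearson", "wilson"), alpha = 0.05,
                        ranges = list(c(4L, 13L)),
                        rounding = c("half_up_3dp", "full_precision")) {
  method <- match.arg(method)
  rounding <- match.arg(rounding)
  if (length(pairs) == 0L) stop("no pairs", call. = FALSE)
  cmpAll <- tryCatch(comparePairs(haplotypes, pairs), error = function(e)
    stop("comparison stage: ", conditionMessage(e), call. = FALSE))
  flt <- filterPairs(cmpAll, maxMutations)
  cmp <- flt$kept
  if (length(cmp) == 0L) stop("rate stage: all pairs excluded", call. = FALSE)
  rates <- tryCatch(estimateRates(cmp, method = method, alpha = alpha),
                    error = function(e)
                      stop("rate stage: ", conditionMessage(e), call. = FALSE))
  diff <- differentiationRate(cmp, ranges = ranges, alpha = alpha)
  dist <- discordanceDistribution(cmp)

  ev <- mutationEvents(cmp)
  summary <- list(
    n_pairs = length(cmp),
    n_pairs_excluded = length(flt$excluded),
    total_meioses = sum(pairSummary(cmp)$meioses),
    total_mutations = nrow(ev),
    event_types = as.list(table(factor(ev$kind,
      levels = c("single_step", "duplication", "deletion", "complex")))),
    differentiation_rate = diff$rate[diff$stratum == "all"],
    mutations_per_locus = as.list(stats::setNames(rates$mutations,
                                                  rates$locus)),
    mutations_per_pair = as.list(stats::setNames(
      pairSummary(cmp)$n_events, pairSummary(cmp)$family_id)))

  files <- character()
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    rateTab <- data.frame(marker = rates$locus,
                          total_meioses = rates$meioses,
                          mutations = rates$mutations,
                          mutation_rate = rates$rate,
                          ci_lower = rates$ci_lower,
                          ci_upper = rates$ci_upper,
                          stringsAsFactors = FALSE)
    rateTab <- .roundCols(rateTab,
                          c("mutation_rate", "ci_lower", "ci_upper"),
                          rounding)
    diffTab <- .roundCols(diff, c("rate", "ci_lower", "ci_upper"), rounding)
    files <- c(events = .writeTsv(ev, file.path(outDir, "events.tsv")),
               rates = .writeTsv(rateTab, file.path(outDir, "rates.tsv")),
               diff = .writeTsv(diffTab, file.path(outDir, "diff.tsv")))
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, summary = file.path(outDir, "summary.json"))
  }
  res <- list(comparisons = cmp, excluded = flt$excluded, rates = rates,
              differentiation = diff, distribution = dist,
              summary = summary, files = files)
  if (is.null(outDir)) res else invisible(res)
}
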