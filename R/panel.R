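#' Construct a Y-STR marker panel
#'
#' @param locus character vector of marker names.
#' @param copies integer vector (recycled) of expected copy numbers, 1 or 2.
#' @param mu numeric vector (recycled) of per-meiosis mutation probabilities.
#' @param min_allele,max_allele numeric vectors (recycled) giving the founder
#'   repeat range used in simulation.
#'
#' @return a [YstrPanel-class] object.
#' @examples
#' YstrPanel(c("DYS390", "DYS385"), copies = c(1, 2), mu = 0.002)
#' @export
YstrPanel <- function(locus, copies = 1L, mu = 0,
                      min_allele = 5, max_allele = 50) {
  n <- length(locus)
  specs <- data.frame(locus = as.character(locus),
                      copies = rep_len(as.integer(copies), n),
                      mu = rep_len(as.numeric(mu), n),
                      min_allele = rep_len(as.numeric(min_allele), n),
                      max_allele = rep_len(as.numeric(max_allele), n),
                      stringsAsFactors = FALSE)
  new("YstrPanel", specs = specs)
}

#' The 25-marker Yfiler Plus panel
#'
#' Returns the 25 Yfiler Plus markers analysed as rate units (the two-copy
#' markers DYS385 and DYF387S1 each count once, so the panel spans 27 Y-STR
#' loci), with founder allele ranges taken from the bundled panel file and
#' per-meiosis mutation probabilities taken from the bundled pedigree study
#' counts (`mu = mutations / meioses`, at full precision).
#'
#' @param rates `"study"` to load mutation probabilities from the bundled
#'   pedigree counts, `"zero"` for a mutation-free panel.
#' @return a [YstrPanel-class] with 25 markers.
#' @examples
#' p <- yfilerPlusPanel()
#' mutationRates(p)[["DYS627"]]   # 21/1576
#' @export
yfilerPlusPanel <- function(rates = c("study", "zero")) {
  rates <- match.arg(rates)
  f <- system.file("extdata", "yfiler_plus_panel.tsv", package = "ystrpedigree",
                   mustWork = TRUE)
  specs <- utils::read.delim(f, stringsAsFactors = FALSE)
  mu <- rep(0, nrow(specs))
  if (rates == "study") {
    cnt <- studyCounts()
    mu <- cnt$mutations[match(specs$locus, cnt$locus)] /
      cnt$meioses[match(specs$locus, cnt$locus)]
  }
  YstrPanel(specs$locus, specs$copies, mu, specs$min_allele, specs$max_allele)
}

#' Published per-locus mutation counts of the pedigree study
#'
#' Per-marker totals from the two-man-pedigree study the package models:
#' total meioses, observed mutation count, and the reference per-meiosis
#' rates from a father-son compilation (`ref_rate_fatherson`) and a
#' large-scale pedigree study (`ref_rate_pedigree`) used for cross-study
#' comparison.
#'
#' @return a `data.frame` with columns `locus`, `meioses`, `mutations`,
#'   `ref_rate_fatherson`, `ref_rate_pedigree`.
#' @examples
#' head(studyCounts())
#' sum(studyCounts()$mutations)   # 161
#' @export
studyCounts <- function() {
  f <- system.file("extdata", "pedigree_study_counts.tsv",
                   package = "ystrpedigree", mustWork = TRUE)
  utils::read.delim(f, stringsAsFactors = FALSE)
}

#' @rdname YstrPanel-class
#' @aliases panelLoci,YstrPanel-method
setMethod("panelLoci", "YstrPanel", function(x) x@specs$locus)

#' @rdname YstrPanel-class
#' @aliases expectedCopies,YstrPanel-method
setMethod("expectedCopies", "YstrPanel", function(x) {
  stats::setNames(x@specs$copies, x@specs$locus)
})

#' @rdname YstrPanel-class
#' @aliases mutationRates,YstrPanel-method
setMethod("mutationRates", "YstrPanel", function(x) {
  stats::setNames(x@specs$mu, x@specs$locus)
})

setMethod("length", "YstrPanel", function(x) nrow(x@specs))

setMethod("show", "YstrPanel", function(object) {
  s <- object@specs
  cat(sprintf("YstrPanel with %d markers (%d loci)\n",
              nrow(s), sum(s$copies)))
  cat(sprintf("  multi-copy: %s\n",
              paste(s$locus[s$copies > 1L], collapse = ", ")))
  cat(sprintf("  mean mu: %.4g\n", mean(s$mu)))
})

#' Coerce a panel to its specification table
#'
#' @param x a [YstrPanel-class].
#' @param ... ignored.
#' @return the underlying `data.frame`.
#' @export
as.data.frame.YstrPanel <- function(x, ...) x@specs
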