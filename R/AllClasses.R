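#' @import methods
NULL

#' Y-STR marker panel
#'
#' An S4 container describing a Y-STR marker panel: one row per marker with
#' its name, expected copy number (1 for single-copy markers, 2 for the
#' multi-copy markers DYS385 and DYF387S1), a per-meiosis mutation
#' probability `mu` (a simulation truth or a reference estimate), and the
#' integer repeat range used when drawing founder alleles in simulation.
#'
#' @slot specs a `data.frame` with columns `locus` (character), `copies`
#'   (integer, 1 or 2), `mu` (numeric in \[0, 1\]), `min_allele` and
#'   `max_allele` (numeric repeat counts).
#'
#' @seealso [YstrPanel()], [yfilerPlusPanel()]
#' @name YstrPanel-class
#' @rdname YstrPanel-class
#' @exportClass YstrPanel
setClass("YstrPanel", representation(specs = "data.frame"))

setValidity("YstrPanel", function(object) {
  s <- object@specs
  need <- c("locus", "copies", "mu", "min_allele", "max_allele")
  if (!all(need %in% names(s)))
    return(paste("specs must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(s$locus)) return("duplicated locus names in panel")
  if (!all(s$copies %in% c(1L, 2L))) return("copies must be 1 or 2")
  if (any(s$mu < 0 | s$mu > 1)) return("mu must lie in [0, 1]")
  if (any(s$min_allele < 1 | s$max_allele < s$min_allele))
    return("invalid founder allele ranges")
  TRUE
})

#' Multi-locus Y-STR haplotypes for a set of males
#'
#' Stores one multi-locus genotype per sampled male. Each call is a per-locus
#' allele multiset kept canonically sorted; a locus-wide null ("NEG", i.e. no
#' amplification product) is a one-element multiset containing `NA`.
#' Microvariant alleles carry a decimal partial-repeat part (e.g. 20.2).
#'
#' @slot sampleIds character vector of sample identifiers.
#' @slot calls named list (one element per sample) of named lists mapping each
#'   panel locus to a sorted numeric allele vector (`NA` = null call).
#' @slot panel the [YstrPanel-class] the calls are indexed against.
#'
#' @seealso [readHaplotypeTable()], [YstrHaplotypes()]
#' @name YstrHaplotypes-class
#' @rdname YstrHaplotypes-class
#' @exportClass YstrHaplotypes
setClass("YstrHaplotypes",
         representation(sampleIds = "character", calls = "list",
                        panel = "YstrPanel"))

setValidity("YstrHaplotypes", function(object) {
  if (length(object@calls) != length(object@sampleIds))
    return("one call set per sample required")
  if (!identical(names(object@calls), object@sampleIds))
    return("calls must be named by sampleIds")
  if (anyDuplicated(object@sampleIds)) return("duplicated sample ids")
  loci <- object@panel@specs$locus
  for (s in object@sampleIds) {
    cl <- object@calls[[s]]
    if (!setequal(names(cl), loci) || length(cl) != length(loci))
      return(sprintf("sample %s does not cover the panel exactly once", s))
    for (l in names(cl)) {
      a <- cl[[l]]
      if (!is.numeric(a) || length(a) < 1L)
        return(sprintf("empty call at %s / %s", s, l))
      if (anyNA(a) && length(a) != 1L)
        return(sprintf("null call mixed with alleles at %s / %s", s, l))
      if (!anyNA(a) && is.unsorted(a))
        return(sprintf("alleles not canonically sorted at %s / %s", s, l))
    }
  }
  TRUE
})

#' Two-man pedigree pairs
#'
#' A manifest of pedigree pairs: two distantly related males per pedigree and
#' the number of meioses (germline transmissions) separating them along the
#' patrilineal path. With exactly two sampled men per pedigree the pairwise
#' and actual meioses coincide, so no transmission is double-counted.
#'
#' @slot pairs a `data.frame` with columns `family_id`, `sample1`, `sample2`
#'   (character) and `meioses` (integer >= 1).
#'
#' @seealso [readPairManifest()], [PedigreePairs()]
#' @name PedigreePairs-class
#' @rdname PedigreePairs-class
#' @exportClass PedigreePairs
setClass("PedigreePairs", representation(pairs = "data.frame"))

setValidity("PedigreePairs", function(object) {
  p <- object@pairs
  need <- c("family_id", "sample1", "sample2", "meioses")
  if (!all(need %in% names(p)))
    return(paste("pairs must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(p$family_id)) return("duplicated family_id")
  if (any(p$sample1 == p$sample2))
    return("a pair must reference two distinct samples")
  if (any(p$meioses < 1L)) return("meioses must be >= 1")
  TRUE
})

#' Parsimony comparison results for a set of pedigree pairs
#'
#' Holds the inferred minimum-mutation explanation for every compared pair:
#' the individual mutation events (one row per event; a decomposed k-step
#' difference contributes k single-step rows) and a per-pair summary with the
#' total event count and the number of discordant loci.
#'
#' @slot events `data.frame` with columns `family_id`, `locus`, `kind` (one of
#'   `single_step`, `duplication`, `deletion`, `complex`) and `steps`
#'   (integer, 1: every row is one counted mutation).
#' @slot perPair `data.frame` with columns `family_id`, `meioses`, `n_events`,
#'   `n_loci_discordant`.
#' @slot panel the [YstrPanel-class] used for the comparison.
#'
#' @seealso [comparePairs()], [filterPairs()], [estimateRates()]
#' @name PairComparisonSet-class
#' @rdname PairComparisonSet-class
#' @exportClass PairComparisonSet
setClass("PairComparisonSet",
         representation(events = "data.frame", perPair = "data.frame",
                        panel = "YstrPanel"))

setValidity("PairComparisonSet", function(object) {
  ev <- object@events
  pp <- object@perPair
  if (!all(c("family_id", "locus", "kind", "steps") %in% names(ev)))
    return("events needs family_id, locus, kind, steps")
  if (!all(c("family_id", "meioses", "n_events", "n_loci_discordant")
           %in% names(pp)))
    return("perPair needs family_id, meioses, n_events, n_loci_discordant")
  if (nrow(ev) &&
      !all(ev$kind %in% c("single_step", "duplication", "deletion", "complex")))
    return("unknown event kind")
  if (nrow(ev) && !all(ev$family_id %in% pp$family_id))
    return("events reference unknown pairs")
  if (sum(pp$n_events) != nrow(ev))
    return("per-pair event totals do not match the event table")
  TRUE
})

#' Stepwise-mutation pedigree simulation configuration
#'
#' Parameters of the generative model used by [simulatePairs()]: a panel with
#' true per-locus mutation probabilities, the number of two-man pedigrees, the
#' distribution of separating meioses, and the mutation-event law (probability
#' of a multi-step event, geometric tail parameter for its size, and the
#' per-meiosis copy-number event probability at multi-copy loci).
#'
#' @slot panel [YstrPanel-class] with true `mu` per locus.
#' @slot nPairs integer, number of pedigree pairs.
#' @slot meiosesProb named numeric: probability for each meioses value (names
#'   are the integer meioses counts); must sum to 1.
#' @slot pMultistep probability that a mutation event moves more than one
#'   repeat unit.
#' @slot stepGeomP geometric parameter for the extra step count of multi-step
#'   events (size = 1 + Geom(stepGeomP)).
#' @slot pDupDel per-meiosis probability of a copy-number event (duplication
#'   or deletion) at each multi-copy locus.
#' @slot seed integer RNG seed.
#'
#' @seealso [simConfig()], [studyLikeConfig()]
#' @name SimConfig-class
#' @rdname SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig",
         representation(panel = "YstrPanel", nPairs = "integer",
                        meiosesProb = "numeric", pMultistep = "numeric",
                        stepGeomP = "numeric", pDupDel = "numeric",
                        seed = "integer"))

setValidity("SimConfig", function(object) {
  if (object@nPairs < 1L) return("nPairs must be >= 1")
  mp <- object@meiosesProb
  if (is.null(names(mp)) || anyNA(suppressWarnings(as.integer(names(mp)))))
    return("meiosesProb must be named by integer meioses values")
  if (any(as.integer(names(mp)) < 1L)) return("meioses values must be >= 1")
  if (any(mp < 0) || abs(sum(mp) - 1) > 1e-8)
    return("meiosesProb must be a probability distribution")
  for (p in c(object@pMultistep, object@pDupDel))
    if (p < 0 || p > 1) return("probabilities must lie in [0, 1]")
  if (object@stepGeomP <= 0 || object@stepGeomP > 1)
    return("stepGeomP must lie in (0, 1]")
  TRUE
})
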