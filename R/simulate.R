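#' Build a simulation configuration
#'
#' @param panel [YstrPanel-class] carrying true per-locus mutation
#'   probabilities (`mu`) and founder allele ranges.
#' @param nPairs number of two-man pedigrees to simulate.
#' @param meiosesProb named numeric vector: probability of each separating
#'   meioses count (names are the integer values); normalised to sum to 1.
#' @param pMultistep probability that a mutation event moves more than one
#'   repeat unit (0 = pure single-step walk).
#' @param stepGeomP geometric parameter of the multi-step size law
#'   (event size = 1 + Geom(stepGeomP)).
#' @param pDupDel per-meiosis probability of a copy-number event at each
#'   multi-copy marker.
#' @param seed integer RNG seed recorded in the configuration.
#' @return a [SimConfig-class].
#' @seealso [studyLikeConfig()], [simulatePairs()]
#' @export
simConfig <- function(panel, nPairs, meiosesProb, pMultistep = 0,
                      stepGeomP = 0.5, pDupDel = 0, seed = 1L) {
  mp <- meiosesProb / sum(meiosesProb)
  new("SimConfig", panel = panel, nPairs = as.integer(nPairs),
      meiosesProb = mp, pMultistep = pMultistep, stepGeomP = stepGeomP,
      pDupDel = pDupDel, seed = as.integer(seed))
}

#' Study-scale simulation configuration
#'
#' Configuration emulating the pedigree study's design: 183 two-man
#' pedigrees separated by 4 to 16 meioses, per-marker mutation probabilities
#' equal to the study's estimated rates (x/1576 at full precision), and a
#' small copy-number event probability at the two multi-copy markers
#' (2/1576 per meiosis each, i.e. four expected copy-number events per run,
#' matching the study's observed count). The meioses distribution is
#' 4 + Binomial(12, 0.3843352): support 4..16 with mean 1576/183 = 8.612, so
#' the expected meioses total over 183 pairs is 1576.
#'
#' @param seed integer RNG seed.
#' @return a [SimConfig-class].
#' @examples
#' cfg <- studyLikeConfig(seed = 42)
#' sum(as.integer(names(cfg@meiosesProb)) * cfg@meiosesProb) * 183  # ~1576
#' @export
studyLikeConfig <- function(seed = 1L) {
  panel <- yfilerPlusPanel(rates = "study")
  p <- (1576 / 183 - 4) / 12
  mp <- stats::setNames(stats::dbinom(0:12, 12, p), 4:16)
  simConfig(panel, nPairs = 183L, meiosesProb = mp,
            pMultistep = 0, stepGeomP = 0.5, pDupDel = 2 / 1576, seed = seed)
}

## apply one step event to an allele state; reflect at repeat count 1
.applyStep <- function(alleles, copy, size, sign) {
  a <- alleles[copy] + sign * size
  reflected <- FALSE
  if (a < 1) {            # reflect at 1: non-biological repeat counts
    a <- 2 - a
    reflected <- TRUE
  }
  alleles[copy] <- a
  list(alleles = sort(alleles), value = a, reflected = reflected)
}

#' Simulate two-man pedigrees under a stepwise mutation model
#'
#' For each pedigree, a founder haplotype is drawn uniformly from the
#' panel's founder ranges (multi-copy markers draw each copy independently).
#' The pair's separating meioses m are split into two branches descending
#' from the founder, with the split m1 drawn uniformly from 1..(m - 1). Along
#' each branch, every marker mutates independently per meiosis with its
#' probability `mu`: a uniformly chosen copy moves +-1 repeat (or further,
#' with probability `pMultistep` and geometric size). Multi-copy markers
#' additionally undergo copy-number events with per-meiosis probability
#' `pDupDel`: a gain copies an existing allele shifted by -1, 0 or +1 repeat
#' (capped at 4 copies), a loss removes a uniformly chosen copy (floored at
#' 1 copy). Alleles reflect at repeat count 1 (logged). Deterministic under a
#' fixed seed.
#'
#' @param config a [SimConfig-class].
#' @param seed optional seed overriding `config@seed`.
#' @return a list with elements `haplotypes` ([YstrHaplotypes-class], two
#'   samples per pedigree), `pairs` ([PedigreePairs-class]), and `truth`
#'   (`data.frame` logging every simulated event: `family_id`, `locus`,
#'   `branch`, `meiosis`, `type` = step/duplication/deletion, `size` (signed
#'   step size, 0 for copy-number events), `reflected`).
#' @examples
#' sim <- simulatePairs(studyLikeConfig(seed = 3))
#' nrow(sim$truth)        # around 165 events
#' @export
simulatePairs <- function(config, seed = NULL) {
  validObject(config)
  set.seed(if (is.null(seed)) config@seed else as.integer(seed))
  specs <- config@panel@specs
  nL <- nrow(specs)
  nP <- config@nPairs
  mVals <- as.integer(names(config@meiosesProb))
  m <- mVals[sample.int(length(mVals), nP, replace = TRUE,
                        prob = config@meiosesProb)]
  m1 <- vapply(m, function(mm)
    if (mm == 1L) 1L else sample.int(mm - 1L, 1L), integer(1))
  branchLen <- cbind(m1, m - m1)

  famIds <- sprintf("P%03d", seq_len(nP))
  sampleIds <- c(rbind(paste0(famIds, "_1"), paste0(famIds, "_2")))
  calls <- vector("list", 2L * nP)
  names(calls) <- sampleIds
  truth <- list()

  for (i in seq_len(nP)) {
    founder <- lapply(seq_len(nL), function(j)
      sort(sample(specs$min_allele[j]:specs$max_allele[j], specs$copies[j],
                  replace = TRUE)))
    names(founder) <- specs$locus
    for (br in 1:2) {
      state <- founder
      mb <- branchLen[i, br]
      nStep <- stats::rbinom(nL, mb, specs$mu)
      nCopy <- stats::rbinom(nL, mb, ifelse(specs$copies > 1L,
                                            config@pDupDel, 0))
      for (j in which(nStep + nCopy > 0L)) {
        l <- specs$locus[j]
        ## interleave step and copy-number events in random meiosis order
        types <- c(rep("step", nStep[j]), rep("copy", nCopy[j]))
        when <- sample.int(mb, length(types), replace = TRUE)
        ord <- order(when)
        for (e in seq_along(ord)) {
          ty <- types[ord[e]]
          if (ty == "step") {
            size <- 1L
            if (config@pMultistep > 0 &&
                stats::runif(1) < config@pMultistep)
              size <- 1L + stats::rgeom(1L, config@stepGeomP)
            sgn <- sample(c(-1L, 1L), 1L)
            copy <- sample.int(length(state[[l]]), 1L)
            res <- .applyStep(state[[l]], copy, size, sgn)
            state[[l]] <- res$alleles
            truth[[length(truth) + 1L]] <-
              data.frame(family_id = famIds[i], locus = l, branch = br,
                         meiosis = when[ord[e]], type = "step",
                         size = sgn * size, reflected = res$reflected,
                         stringsAsFactors = FALSE)
          } else {
            gain <- stats::runif(1) < 0.5
            if (gain && length(state[[l]]) < 4L) {
              src <- sample.int(length(state[[l]]), 1L)
              shift <- sample(-1L:1L, 1L)
              newA <- max(1, state[[l]][src] + shift)
              state[[l]] <- sort(c(state[[l]], newA))
              truth[[length(truth) + 1L]] <-
                data.frame(family_id = famIds[i], locus = l, branch = br,
                           meiosis = when[ord[e]], type = "duplication",
                           size = 0L, reflected = FALSE,
                           stringsAsFactors = FALSE)
            } else if (!gain && length(state[[l]]) > 1L) {
              drop <- sample.int(length(state[[l]]), 1L)
              state[[l]] <- state[[l]][-drop]
              truth[[length(truth) + 1L]] <-
                data.frame(family_id = famIds[i], locus = l, branch = br,
                           meiosis = when[ord[e]], type = "deletion",
                           size = 0L, reflected = FALSE,
                           stringsAsFactors = FALSE)
            }                         # saturated states skip the event
          }
        }
      }
      calls[[2L * (i - 1L) + br]] <- state
    }
  }

  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(family_id = character(), locus = character(),
               branch = integer(), meiosis = integer(), type = character(),
               size = integer(), reflected = logical(),
               stringsAsFactors = FALSE)
  list(haplotypes = YstrHaplotypes(calls, config@panel),
       pairs = PedigreePairs(famIds, paste0(famIds, "_1"),
                             paste0(famIds, "_2"), m),
       truth = truth)
}

setMethod("show", "SimConfig", function(object) {
  mv <- as.integer(names(object@meiosesProb))
  cat(sprintf(paste0("SimConfig: %d pairs, %d markers, meioses %d-%d ",
                     "(mean %.2f), seed %d\n"),
              object@nPairs, length(object@panel), min(mv), max(mv),
              sum(mv * object@meiosesProb), object@seed))
  cat(sprintf("  pMultistep=%.3g stepGeomP=%.3g pDupDel=%.3g\n",
              object@pMultistep, object@stepGeomP, object@pDupDel))
})
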