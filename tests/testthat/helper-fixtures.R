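# small panels and in-code fixtures shared across test files

toyPanel <- function(mu = 0) {
  YstrPanel(c("DYS390", "DYS627", "DYS448", "DYS385"),
            copies = c(1L, 1L, 1L, 2L), mu = mu,
            min_allele = c(17, 11, 15, 7), max_allele = c(29, 27, 24, 28))
}

# two haplotypes differing as directed; `edits` is a named list of calls
# overriding haplotype 2
toyPairSet <- function(edits = list(), meioses = 8L, panel = toyPanel()) {
  base <- list(DYS390 = 24, DYS627 = 20, DYS448 = 20, DYS385 = c(11, 14))
  h2 <- utils::modifyList(base, edits)
  haps <- YstrHaplotypes(list(A = base, B = h2), panel)
  pairs <- PedigreePairs("F1", "A", "B", meioses)
  comparePairs(haps, pairs)
}

# write a haplotype table + manifest to temp files, returning the paths
writeToyFiles <- function(ext = "tsv") {
  panel <- toyPanel()
  haps <- YstrHaplotypes(
    list(A = list(DYS390 = 24, DYS627 = 20.2, DYS448 = NA_real_,
                  DYS385 = c(11, 14)),
         B = list(DYS390 = 22, DYS627 = 20, DYS448 = 20,
                  DYS385 = c(14, 15))),
    panel)
  hp <- tempfile(fileext = paste0(".", ext))
  pp <- tempfile(fileext = paste0(".", ext))
  writeHaplotypeTable(haps, hp)
  writePairManifest(PedigreePairs("F1", "A", "B", 8L), pp)
  list(haplotypes = hp, pairs = pp, panel = panel, object = haps)
}
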