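## Allele tokens follow forensic STR nomenclature: an integer full-repeat
## count, optionally followed by a partial-repeat microvariant digit .1/.2/.3
## ("15.0" is accepted and canonicalised to 15). "NEG" marks a locus-wide
## null call (no amplification product) and is stored as NA.
.ALLELE_RE <- "^[0-9]+(\\.[0-3])?$"

#' Parse and format allele tokens
#'
#' `parseAllele()` converts character tokens from an allele table into
#' numeric repeat counts; `formatAllele()` is its inverse. The null call
#' `"NEG"` (case-insensitive) maps to `NA`; `"15"` and `"15.0"` map to the
#' same allele. Parsing is locale-independent (the decimal separator is
#' always a dot).
#'
#' @param tok character vector of allele tokens.
#' @param a numeric vector of repeat counts (`NA` = null).
#' @return `parseAllele()`: a numeric vector; `formatAllele()`: a character
#'   vector.
#' @examples
#' parseAllele(c("20.2", "NEG", "15.0"))
#' formatAllele(c(20.2, NA, 15))
#' @export
parseAllele <- function(tok) {
  tok <- trimws(tok)
  out <- rep(NA_real_, length(tok))
  null <- toupper(tok) == "NEG"
  bad <- !null & !grepl(.ALLELE_RE, tok)
  if (any(bad))
    stop("unparseable allele token(s): ",
         paste(sQuote(tok[bad]), collapse = ", "), call. = FALSE)
  out[!null] <- as.numeric(tok[!null])
  if (any(out[!null] <= 0))
    stop("allele repeat counts must be positive", call. = FALSE)
  out
}

#' @rdname parseAllele
#' @export
formatAllele <- function(a) {
  out <- ifelse(is.na(a), "NEG",
                ifelse(.deci(a) %% 10L == 0L,
                       format(as.integer(round(a)), trim = TRUE),
                       sprintf("%.1f", a)))
  out
}

## integer deci-repeats (15.2 -> 152): exact arithmetic for step distances
## and microvariant (fractional-part) comparisons
.deci <- function(a) as.integer(round(a * 10))

.sepFor <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Construct haplotypes from a list of calls
#'
#' @param calls named list (by sample id) of named lists mapping each panel
#'   locus to a numeric allele vector (`NA` for a null call). Allele vectors
#'   are canonically sorted on construction.
#' @param panel a [YstrPanel-class].
#' @return a [YstrHaplotypes-class] object.
#' @examples
#' p <- YstrPanel(c("DYS390", "DYS385"), copies = c(1, 2))
#' h <- YstrHaplotypes(list(A = list(DYS390 = 24, DYS385 = c(14, 11))), p)
#' alleleCalls(h, "A")$DYS385
#' @export
YstrHaplotypes <- function(calls, panel) {
  loci <- panelLoci(panel)
  calls <- lapply(calls, function(cl) {
    cl <- lapply(cl, function(a) if (anyNA(a)) NA_real_ else sort(a))
    cl[loci]
  })
  new("YstrHaplotypes", sampleIds = names(calls), calls = calls, panel = panel)
}

#' Read a haplotype allele table
#'
#' Reads a GeneMapper-export-like table: one row per sample, a `sample_id`
#' column, and one column per panel marker. Multi-copy cells list alleles
#' separated by `alleleSep` (comma by default; the cell is quoted in CSV
#' dialect). `"NEG"` denotes a locus-wide null. The file dialect (CSV/TSV) is
#' auto-detected from the extension and can be overridden with `sep`.
#'
#' @param path path to the table.
#' @param panel a [YstrPanel-class]; every panel marker must appear as a
#'   column, and no unknown marker column may be present.
#' @param sep field separator; `NULL` (default) auto-detects by extension.
#' @param alleleSep within-cell allele delimiter for multi-copy loci.
#' @return a [YstrHaplotypes-class] object with canonically sorted alleles.
#' @seealso [writeHaplotypeTable()]
#' @export
readHaplotypeTable <- function(path, panel, sep = NULL, alleleSep = ",") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- .sepFor(path, sep)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"")
  if (!"sample_id" %in% names(tab))
    stop("haplotype table must have a 'sample_id' column", call. = FALSE)
  loci <- panelLoci(panel)
  cols <- setdiff(names(tab), "sample_id")
  unknown <- setdiff(cols, loci)
  if (length(unknown))
    stop("unknown locus column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(loci, cols)
  if (length(missing))
    stop("panel locus column(s) missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  calls <- vector("list", nrow(tab))
  names(calls) <- tab$sample_id
  for (i in seq_len(nrow(tab))) {
    row <- vector("list", length(loci))
    names(row) <- loci
    for (l in loci) {
      cell <- tab[[l]][i]
      if (is.na(cell) || !nzchar(trimws(cell)))
        stop(sprintf("missing call at row %d (%s), column %s",
                     i, tab$sample_id[i], l), call. = FALSE)
      toks <- trimws(strsplit(cell, alleleSep, fixed = TRUE)[[1]])
      a <- tryCatch(parseAllele(toks), error = function(e)
        stop(sprintf("row %d (%s), column %s: %s",
                     i, tab$sample_id[i], l, conditionMessage(e)),
             call. = FALSE))
      row[[l]] <- a
    }
    calls[[i]] <- row
  }
  YstrHaplotypes(calls, panel)
}

#' Write a haplotype allele table
#'
#' Inverse of [readHaplotypeTable()]: writes one row per sample with
#' canonically sorted alleles; multi-copy cells are joined with `alleleSep`
#' and quoted when the field separator is a comma.
#'
#' @param haplotypes a [YstrHaplotypes-class].
#' @param path output path; dialect auto-detected from the extension.
#' @inheritParams readHaplotypeTable
#' @return `path`, invisibly.
#' @export
writeHaplotypeTable <- function(haplotypes, path, sep = NULL,
                                alleleSep = ",") {
  sep <- .sepFor(path, sep)
  loci <- panelLoci(haplotypes@panel)
  rows <- lapply(haplotypes@sampleIds, function(s) {
    cl <- haplotypes@calls[[s]]
    vapply(loci, function(l) paste(formatAllele(cl[[l]]), collapse = alleleSep),
           character(1))
  })
  tab <- do.call(rbind, rows)
  df <- data.frame(sample_id = haplotypes@sampleIds, tab,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = (sep == ","))
  invisible(path)
}

#' Construct a pedigree-pair manifest
#'
#' @param family_id character vector of unique pedigree identifiers.
#' @param sample1,sample2 character vectors of the two sampled males.
#' @param meioses integer vector of separating meioses counts (>= 1).
#' @return a [PedigreePairs-class] object.
#' @examples
#' PedigreePairs("FS_2", "RS_13", "RS_29", 8)
#' @export
PedigreePairs <- function(family_id, sample1, sample2, meioses) {
  m <- suppressWarnings(as.integer(meioses))
  if (anyNA(m) || any(as.numeric(meioses) != m))
    stop("meioses must be integer", call. = FALSE)
  new("PedigreePairs",
      pairs = data.frame(family_id = as.character(family_id),
                         sample1 = as.character(sample1),
                         sample2 = as.character(sample2),
                         meioses = m, stringsAsFactors = FALSE))
}

#' Read a pedigree-pair manifest
#'
#' Expects columns `family_id`, `sample1`, `sample2`, `meioses` (CSV or TSV,
#' auto-detected by extension). Duplicate pedigree ids, self-pairs, and
#' meioses below 1 are hard errors; whether a referenced sample exists in the
#' haplotype table is checked at comparison time.
#'
#' @inheritParams readHaplotypeTable
#' @return a [PedigreePairs-class] object.
#' @seealso [writePairManifest()], [comparePairs()]
#' @export
readPairManifest <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- .sepFor(path, sep)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"")
  need <- c("family_id", "sample1", "sample2", "meioses")
  if (!all(need %in% names(tab)))
    stop("pair manifest needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  PedigreePairs(tab$family_id, tab$sample1, tab$sample2, tab$meioses)
}

#' @rdname readPairManifest
#' @param pairs a [PedigreePairs-class].
#' @export
writePairManifest <- function(pairs, path, sep = NULL) {
  sep <- .sepFor(path, sep)
  utils::write.table(pairs@pairs, path, sep = sep, row.names = FALSE,
                     quote = (sep == ","))
  invisible(path)
}

#' @rdname YstrHaplotypes-class
#' @aliases sampleIds,YstrHaplotypes-method
setMethod("sampleIds", "YstrHaplotypes", function(x) x@sampleIds)

#' @rdname YstrHaplotypes-class
#' @aliases alleleCalls,YstrHaplotypes-method
setMethod("alleleCalls", "YstrHaplotypes", function(x, sample) {
  if (!sample %in% x@sampleIds)
    stop("unknown sample: ", sample, call. = FALSE)
  x@calls[[sample]]
})

setMethod("length", "YstrHaplotypes", function(x) length(x@sampleIds))

setMethod("show", "YstrHaplotypes", function(object) {
  cat(sprintf("YstrHaplotypes: %d samples x %d markers\n",
              length(object@sampleIds), length(object@panel)))
  n <- min(3L, length(object@sampleIds))
  if (n) cat("  samples:", paste(utils::head(object@sampleIds, n),
                                 collapse = ", "),
             if (length(object@sampleIds) > n) "..." else "", "\n")
})

#' @rdname PedigreePairs-class
#' @aliases familyIds,PedigreePairs-method
setMethod("familyIds", "PedigreePairs", function(x) x@pairs$family_id)

#' @rdname PedigreePairs-class
#' @aliases meioses,PedigreePairs-method
setMethod("meioses", "PedigreePairs", function(x) {
  stats::setNames(x@pairs$meioses, x@pairs$family_id)
})

setMethod("length", "PedigreePairs", function(x) nrow(x@pairs))

setMethod("show", "PedigreePairs", function(object) {
  m <- object@pairs$meioses
  cat(sprintf("PedigreePairs: %d pairs, meioses %d-%d (total %d)\n",
              nrow(object@pairs), min(m), max(m), sum(m)))
})

#' Coerce a pair manifest to a data frame
#'
#' @param x a [PedigreePairs-class].
#' @param ... ignored.
#' @return the underlying `data.frame`.
#' @export
as.data.frame.PedigreePairs <- function(x, ...) x@pairs
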