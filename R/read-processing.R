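## Adapter anchoring and variable-region extraction.
##
## Library inserts are fixed-length, so adapters are matched at their
## expected offsets allowing substitutions only (no indels): this keeps
## trimming alignment-free and bit-reproducible.

#' Read sequencing reads from FASTQ or FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]: preserves record
#' order and ids, upper-cases sequences, accepts gzip-compressed input.
#'
#' @param path input file (`.gz` accepted).
#' @param format `"auto"` (from the file name), `"fastq"` or `"fasta"`.
#' @return a [Biostrings::DNAStringSet-class].
#' @export
parseReads <- function(path, format = c("auto", "fastq", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    format <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE)) {
      "fastq"
    } else {
      "fasta"
    }
  }
  if (file.size(path) == 0L) return(Biostrings::DNAStringSet())
  reads <- tryCatch(
    Biostrings::readDNAStringSet(path, format = format),
    error = function(e) {
      stop("failed to parse ", path, " as ", format, ": ",
           conditionMessage(e))
    }
  )
  ## FASTQ ids may carry comments after whitespace; keep the id token
  if (!is.null(names(reads))) {
    names(reads) <- sub("\\s.*$", "", names(reads))
  }
  reads
}

## per-position substitution count of an anchored adapter segment;
## 'start' is the 1-based offset of the adapter within each read
anchoredMismatches <- function(seqs, widths, adapter, start) {
  mm <- integer(length(seqs))
  for (j in seq_len(nchar(adapter))) {
    pos <- start + j - 1L
    active <- widths >= pos
    ch <- substr(seqs[active], pos, pos)
    mm[active] <- mm[active] + (ch != substr(adapter, j, j))
  }
  mm
}

#' Extract variable regions by anchored adapter matching
#'
#' Anchors the 5' adapter at the read start allowing up to `maxMismatch`
#' substitutions, takes the following `variableLength(design)` bases as the
#' variable region, and verifies the 3' adapter prefix (as much of it as
#' the read covers) the same way.  Rejected reads are counted by reason
#' (`too_short`, `adapter5`, `adapter3`, `alphabet`); rejection is a
#' reported outcome, not an error, and accepted + rejected always equals
#' the input read count.
#'
#' @param reads a [Biostrings::DNAStringSet-class] (or character vector).
#' @param design the [LibraryDesign-class] the reads were built from.
#' @param maxMismatch maximum substitutions tolerated per adapter
#'   (default 2).
#' @return a list with `accepted` (an [S4Vectors::DataFrame-class] of
#'   `read_id`, `region`, `adapter_mismatches`), `rejected` (named integer
#'   vector of counts by reason) and `total`.
#' @export
extractVariableRegions <- function(reads, design, maxMismatch = 2L) {
  validObject(design)
  s <- as.character(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- as.character(seq_along(s))
  n <- length(s)
  L <- variableLength(design)
  n5 <- nchar(design@adapter5)
  widths <- nchar(s)
  reason <- rep(NA_character_, n)

  reason[widths < n5 + L] <- "too_short"
  live <- is.na(reason)

  mm5 <- integer(n)
  mm5[live] <- anchoredMismatches(s[live], widths[live], design@adapter5, 1L)
  reason[live & mm5 > maxMismatch] <- "adapter5"
  live <- is.na(reason)

  ## 3' adapter: check the portion the read actually covers
  mm3 <- integer(n)
  if (any(live)) {
    mm3[live] <- anchoredMismatches(s[live], widths[live], design@adapter3,
                                    n5 + L + 1L)
  }
  reason[live & mm3 > maxMismatch] <- "adapter3"
  live <- is.na(reason)

  region <- substr(s, n5 + 1L, n5 + L)
  reason[live & !grepl("^[ACGT]+$", region)] <- "alphabet"
  live <- is.na(reason)

  accepted <- S4Vectors::DataFrame(
    read_id = unname(ids[live]),
    region = unname(region[live]),
    adapter_mismatches = unname(mm5[live] + mm3[live])
  )
  reasons <- c("too_short", "adapter5", "adapter3", "alphabet")
  rejected <- vapply(reasons, function(r) sum(reason == r, na.rm = TRUE), 0L)
  list(accepted = accepted, rejected = rejected, total = n)
}

#' Tally variable regions
#'
#' @param regions character vector of variable regions (or the `accepted`
#'   DataFrame from [extractVariableRegions()]).
#' @return an [S4Vectors::DataFrame-class] with `region` and `count`,
#'   sorted by decreasing count (ties lexicographic).
#' @export
regionCounts <- function(regions) {
  if (methods::is(regions, "DataFrame")) regions <- regions$region
  tab <- table(regions)
  out <- S4Vectors::DataFrame(region = names(tab),
                              count = as.integer(tab))
  out[order(-out$count, out$region), , drop = FALSE]
}

#' Write / read a region-count table
#'
#' Tab-separated `region<TAB>count`, optionally preceded by `#` header
#' lines (as written by the pipeline: tool version, seed, config hash).
#'
#' @param counts a DataFrame or data.frame with `region` and `count`.
#' @param path file path.
#' @param header optional character vector of header lines (written with a
#'   leading `# `).
#' @return `readRegionCounts` returns an [S4Vectors::DataFrame-class];
#'   `writeRegionCounts` invisibly returns `path`.
#' @export
writeRegionCounts <- function(counts, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  writeLines("region\tcount", con)
  writeLines(paste(counts$region, counts$count, sep = "\t"), con)
  invisible(path)
}

#' @rdname writeRegionCounts
#' @export
readRegionCounts <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          colClasses = c("character", "integer"))
  S4Vectors::DataFrame(region = df$region, count = df$count)
}
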