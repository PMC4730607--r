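## Bait layouts and the extended position alphabet:
##   A C G T  fixed base
##   N        uniform random base
##   a c g t  doped base, consensus kept at the design's retention rate

#' Construct a library design
#'
#' @param name label for the design.
#' @param adapter5,adapter3 constant adapter sequences (ACGT).
#' @param positions either a character vector of per-position codes or a
#'   single string in the extended alphabet (`ACGT` fixed, `N` uniform,
#'   lowercase doped).
#' @param retention consensus retention probability for doped positions,
#'   in (0, 1]. The three alternative bases each receive
#'   `(1 - retention) / 3`.
#'
#' @return a [LibraryDesign-class] object.
#' @examples
#' d <- LibraryDesign("toy", "ACGT", "TTTT", "NNtaatNN", retention = 0.91)
#' variableLength(d)
#' @export
LibraryDesign <- function(name, adapter5, adapter3, positions,
                          retention = 0.91) {
  if (length(positions) == 1L && nchar(positions) > 1L) {
    positions <- strsplit(positions, "", fixed = TRUE)[[1L]]
  }
  new("LibraryDesign",
    name = as.character(name),
    adapter5 = toupper(as.character(adapter5)),
    adapter3 = toupper(as.character(adapter3)),
    positions = as.character(positions),
    retention = as.numeric(retention)
  )
}

## Constant Nextera-style adapters shared by both bait designs
BAIT_ADAPTER5 <- "TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG"
BAIT_ADAPTER3 <- "CTGTCTCTTATACACATCTCCGAGCCCACGAGAC"

#' Built-in bait designs
#'
#' `baitOne()` is the randomized design: 8 uniform-random bases, a fixed
#' TAAT core, and 8 more uniform-random bases (20-nt variable region).
#' `baitTwo()` is the doped design: an 11-bp core synthesized around the
#' TT-flavor consensus TAATTTAATCA with each position kept at 91% and the
#' three alternatives at 3% each, flanked by 3 fully random bases on each
#' side (17-nt variable region).  Both use the same constant adapters.
#'
#' @param retention doping retention rate for `baitTwo` (default 0.91).
#' @return a [LibraryDesign-class].
#' @export
baitOne <- function() {
  LibraryDesign("bait1", BAIT_ADAPTER5, BAIT_ADAPTER3,
                "NNNNNNNNTAATNNNNNNNN", retention = 0.91)
}

#' @rdname baitOne
#' @export
baitTwo <- function(retention = 0.91) {
  LibraryDesign("bait2", BAIT_ADAPTER5, BAIT_ADAPTER3,
                "NNNtaatttaatcaNNN", retention = retention)
}

#' Doped-core design around an arbitrary consensus
#'
#' A bait laid out like `baitTwo()` but doped around `motif`: useful for
#' planted-motif simulations.
#'
#' @param motif consensus sequence of the doped core (ACGT string).
#' @param flank number of uniform-random bases on each side.
#' @param retention consensus retention rate at doped positions.
#' @return a [LibraryDesign-class].
#' @export
dopedDesign <- function(motif, flank = 3L, retention = 0.91) {
  stopifnot(grepl("^[ACGT]+$", motif))
  pos <- paste0(strrep("N", flank), tolower(motif), strrep("N", flank))
  LibraryDesign(paste0("doped_", motif), BAIT_ADAPTER5, BAIT_ADAPTER3,
                pos, retention = retention)
}

#' @describeIn LibraryDesign-accessors length of the variable region
#' @export
variableLength <- function(design) length(design@positions)

#' Accessors for LibraryDesign
#'
#' @param design a [LibraryDesign-class].
#' @name LibraryDesign-accessors
#' @aliases variableLength positionProbs coreIndex positionLabels
#'   designName adapter5 adapter3
NULL

#' @describeIn LibraryDesign-accessors design name
#' @export
designName <- function(design) design@name

#' @describeIn LibraryDesign-accessors 5' adapter sequence
#' @export
adapter5 <- function(design) design@adapter5

#' @describeIn LibraryDesign-accessors 3' adapter sequence
#' @export
adapter3 <- function(design) design@adapter3

#' @describeIn LibraryDesign-accessors 4 x L matrix of per-position base
#'   probabilities implied by the design (rows A,C,G,T)
#' @export
positionProbs <- function(design) {
  L <- variableLength(design)
  p <- matrix(0, nrow = 4L, ncol = L, dimnames = list(DNA_BASES, NULL))
  r <- design@retention
  alt <- (1 - r) / 3
  for (i in seq_len(L)) {
    code <- design@positions[i]
    if (code == "N") {
      p[, i] <- 0.25
    } else if (code %in% DNA_BASES) {
      p[code, i] <- 1
    } else {
      base <- toupper(code)
      p[, i] <- alt
      p[base, i] <- r
    }
  }
  p
}

#' @describeIn LibraryDesign-accessors indices of the non-uniform (fixed or
#'   doped) core run of the variable region
#' @export
coreIndex <- function(design) which(design@positions != "N")

#' @describeIn LibraryDesign-accessors consensus sequence of the core
#'   (fixed/doped bases, upper-cased)
#' @export
coreConsensus <- function(design) {
  paste(toupper(design@positions[coreIndex(design)]), collapse = "")
}

#' @describeIn LibraryDesign-accessors per-position labels: core positions
#'   `1..m`, upstream flanks `-f..-1`, downstream flanks `+1..+f`
#' @export
positionLabels <- function(design) {
  L <- variableLength(design)
  core <- coreIndex(design)
  if (length(core) == 0L) return(as.character(seq_len(L)))
  lab <- character(L)
  first <- min(core); last <- max(core)
  lab[seq_len(L) < first] <- as.character(seq_len(L)[seq_len(L) < first] - first)
  lab[seq_len(L) > last] <- paste0("+", seq_len(L)[seq_len(L) > last] - last)
  lab[first:last] <- as.character(seq_len(last - first + 1L))
  lab
}

#' Read or write a library-design file
#'
#' Plain `key = value` text format with keys `name`, `adapter5`, `adapter3`,
#' `positions` (extended-alphabet string) and `retention`.  Lines starting
#' with `#` are comments.
#'
#' @param path file path.
#' @return `readDesign` returns a [LibraryDesign-class]; `writeDesign`
#'   invisibly returns `path`.
#' @export
readDesign <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed design line(s): ", paste(lines[bad], collapse = "; "))
  }
  keys <- vapply(kv, `[`, "", 2L)
  vals <- trimws(vapply(kv, `[`, "", 3L))
  names(vals) <- keys
  required <- c("name", "adapter5", "adapter3", "positions")
  missing <- setdiff(required, keys)
  if (length(missing)) {
    stop("design file missing key(s): ", paste(missing, collapse = ", "))
  }
  retention <- if ("retention" %in% keys) as.numeric(vals["retention"]) else 0.91
  LibraryDesign(vals["name"], vals["adapter5"], vals["adapter3"],
                vals["positions"], retention)
}

#' @rdname readDesign
#' @param design a [LibraryDesign-class] to serialize.
#' @export
writeDesign <- function(design, path) {
  writeLines(c(
    paste("name =", design@name),
    paste("adapter5 =", design@adapter5),
    paste("adapter3 =", design@adapter3),
    paste("positions =", paste(design@positions, collapse = "")),
    paste("retention =", format(design@retention, digits = 15))
  ), path)
  invisible(path)
}

#' @rdname LibraryDesign-class
#' @param object object to display
#' @export
setMethod("show", "LibraryDesign", function(object) {
  cat("LibraryDesign '", object@name, "'\n", sep = "")
  cat("  layout: ", object@adapter5, "[",
      paste(object@positions, collapse = ""), "]", object@adapter3,
      "\n", sep = "")
  nd <- sum(object@positions %in% tolower(DNA_BASES))
  cat("  variable region: ", variableLength(object), " nt (",
      sum(object@positions == "N"), " uniform, ", nd, " doped at ",
      format(object@retention), ", ",
      sum(object@positions %in% DNA_BASES), " fixed)\n", sep = "")
})
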