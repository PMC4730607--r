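## Per-position selection-bias analysis of doped libraries: the ratio of
## base frequencies between the pulled-down pool and the unselected
## control, position by position.

#' Per-position base frequencies of aligned regions
#'
#' @param regions character vector of variable regions, or a DataFrame
#'   with `region` and `count`.
#' @param design the [LibraryDesign-class] the regions align to (fixes the
#'   expected length and the position labels).
#' @param counts optional per-region multiplicities.
#' @return list with `freq` (4 x L matrix, columns sum to 1), `counts`
#'   (underlying weighted base counts) and `labels` (from
#'   [positionLabels()]).
#' @export
baseFrequencyMatrix <- function(regions, design, counts = NULL) {
  validObject(design)
  if (methods::is(regions, "DataFrame") && is.null(counts)) {
    counts <- regions$count
    regions <- regions$region
  }
  regions <- as.character(regions)
  if (is.null(counts)) counts <- rep(1, length(regions))
  L <- variableLength(design)
  if (any(nchar(regions) != L)) {
    stop("region length(s) do not match the design (", L, " nt)")
  }
  codes <- encodeSequences(regions)
  cnt <- matrix(0, nrow = 4L, ncol = L, dimnames = list(DNA_BASES, NULL))
  for (i in seq_len(L)) {
    acc <- rowsum(counts, codes[, i])
    cnt[as.integer(rownames(acc)), i] <- acc[, 1L]
  }
  freq <- sweep(cnt, 2L, colSums(cnt), "/")
  list(freq = freq, counts = cnt, labels = positionLabels(design))
}

#' Selection-bias ratio matrix (pulled-down vs control)
#'
#' The central doped-library statistic: base frequency in the pulled-down
#' pool divided by base frequency in the control, per position and base.
#' A ratio above 1 means the base was positively selected at that position.
#' Cells with zero control frequency are flagged `NA` rather than raising
#' an error.
#'
#' @param selected,control outputs of [baseFrequencyMatrix()] on the
#'   selected-round and control (round 0) regions of the same design.
#' @param design the shared [LibraryDesign-class].
#' @return a [BiasMatrix-class].
#' @export
selectionBias <- function(selected, control, design) {
  if (!identical(selected$labels, control$labels)) {
    stop("selected and control position sets do not match")
  }
  ratio <- selected$freq / control$freq
  ratio[control$freq == 0] <- NA_real_
  new("BiasMatrix",
      labels = selected$labels,
      core = which(design@positions != "N"),
      selectedFreq = selected$freq, controlFreq = control$freq,
      selectedCounts = selected$counts, controlCounts = control$counts,
      ratio = ratio)
}

#' @describeIn selectionBias the 4 x P ratio matrix (columns named by
#'   position label)
#' @param bias a [BiasMatrix-class].
#' @export
biasRatios <- function(bias) {
  r <- bias@ratio
  colnames(r) <- bias@labels
  r
}

#' Log-ratio weight matrix over the core positions
#'
#' The per-position binding-preference matrix implied by a selection-bias
#' analysis: `log(ratio)` restricted to the core (doped) positions, with
#' ratios floored at `floor` so that unobserved cells score very
#' unfavourably instead of `-Inf`.
#'
#' @param bias a [BiasMatrix-class].
#' @param floor minimum ratio before taking logs (default `1e-6`).
#' @return 4 x m numeric matrix (rows `A,C,G,T`), suitable for
#'   [scoreOligoPanel()].
#' @export
biasWeightMatrix <- function(bias, floor = 1e-6) {
  r <- bias@ratio[, bias@core, drop = FALSE]
  r[is.na(r)] <- floor
  log(pmax(r, floor))
}

wilsonInterval <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  cbind(low = center - half, high = center + half)
}

#' Call the preferred consensus from a bias matrix
#'
#' Per core position, the base with the maximal selection-bias ratio;
#' confidence is `log(top ratio / second ratio)`.  Ratios within
#' `tieTolerance` (relative) of the top are reported as ties, in which
#' case the consensus letter is the IUPAC code covering the tied bases
#' (deterministic ordering); a position where all four bases tie is a
#' no-call (`N`).
#'
#' @param bias a [BiasMatrix-class].
#' @param tieTolerance relative tolerance within which ratios count as
#'   tied (default 0.02).
#' @return list with `consensus` (character; IUPAC codes at ties),
#'   `called` (logical per position: exactly one untied top base),
#'   `confidence` (numeric per position), and `ties` (list of tied base
#'   sets).
#' @export
callConsensus <- function(bias, tieTolerance = 0.02) {
  r <- bias@ratio[, bias@core, drop = FALSE]
  m <- ncol(r)
  rev_map <- stats::setNames(names(Biostrings::IUPAC_CODE_MAP),
                             Biostrings::IUPAC_CODE_MAP)
  consensus <- character(m)
  called <- logical(m)
  confidence <- numeric(m)
  ties <- vector("list", m)
  for (i in seq_len(m)) {
    v <- r[, i]
    v[is.na(v)] <- 0
    ord <- order(-v, DNA_BASES)
    top <- v[ord[1L]]
    tied <- DNA_BASES[v >= top * (1 - tieTolerance)]
    ties[[i]] <- tied
    called[i] <- length(tied) == 1L
    consensus[i] <- rev_map[[paste(sort(tied), collapse = "")]]
    confidence[i] <- if (v[ord[2L]] > 0) log(top / v[ord[2L]]) else Inf
  }
  list(consensus = paste(consensus, collapse = ""), called = called,
       confidence = confidence, ties = ties)
}

#' Export a bias matrix as a tidy TSV table
#'
#' One row per position x base with the selected and control frequencies,
#' the ratio, and Wilson 95% intervals on the selected frequency.
#'
#' @param bias a [BiasMatrix-class].
#' @param path file path.
#' @param header optional `#` header lines.
#' @return invisibly, the data.frame written.
#' @export
writeBiasTable <- function(bias, path, header = NULL) {
  p <- length(bias@labels)
  selN <- colSums(bias@selectedCounts)
  ci <- wilsonInterval(as.vector(bias@selectedCounts),
                       rep(selN, each = 4L))
  df <- data.frame(
    position = rep(bias@labels, each = 4L),
    base = rep(DNA_BASES, p),
    freq_selected = as.vector(bias@selectedFreq),
    freq_control = as.vector(bias@controlFreq),
    ratio = as.vector(bias@ratio),
    ci_low = ci[, "low"],
    ci_high = ci[, "high"]
  )
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  utils::write.table(format(df, digits = 10, trim = TRUE), con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(df)
}

#' @rdname BiasMatrix-class
#' @param object object to display
#' @export
setMethod("show", "BiasMatrix", function(object) {
  cat("BiasMatrix: ", length(object@labels), " positions (",
      length(object@core), " core)\n", sep = "")
  r <- round(object@ratio, 3L)
  colnames(r) <- object@labels
  print(r)
})
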