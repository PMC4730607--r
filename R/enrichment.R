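## k-mer counting, enrichment calling against the Markov background, and
## consensus matching / oligo scoring.

#' Count k-mers over weighted regions
#'
#' Tiles every region with all contiguous k-windows; each window inherits
#' the region's multiplicity.  In `"both"` strands mode the reverse
#' complement of every region is tiled as well, so the total equals
#' `2 * sum((len - k + 1) * count)`.
#'
#' @param regions character vector of regions, or a DataFrame with
#'   `region` and `count` (e.g. from [regionCounts()]).
#' @param k k-mer length (at most the shortest region length).
#' @param counts optional per-region multiplicities.
#' @param strands `"forward_only"` or `"both"`.
#' @return named numeric vector of k-mer counts (sorted by k-mer).
#' @export
countKmers <- function(regions, k, counts = NULL,
                       strands = c("forward_only", "both")) {
  strands <- match.arg(strands)
  if (methods::is(regions, "DataFrame") && is.null(counts)) {
    counts <- regions$count
    regions <- regions$region
  }
  regions <- as.character(regions)
  if (is.null(counts)) counts <- rep(1, length(regions))
  k <- as.integer(k)
  if (any(nchar(regions) < k)) {
    stop("'k' exceeds the shortest region length")
  }
  if (strands == "both") {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(regions)
    ))
    regions <- c(regions, rc)
    counts <- c(counts, counts)
  }
  acc <- numeric(0)
  lens <- nchar(regions)
  for (Lg in unique(lens)) {
    sel <- lens == Lg
    s <- regions[sel]
    w <- counts[sel]
    for (off in seq_len(Lg - k + 1L)) {
      km <- substr(s, off, off + k - 1L)
      part <- rowsum(w, km)
      hit <- match(rownames(part), names(acc))
      new <- is.na(hit)
      if (any(!new)) acc[hit[!new]] <- acc[hit[!new]] + part[!new, 1L]
      if (any(new)) {
        acc <- c(acc, stats::setNames(part[new, 1L], rownames(part)[new]))
      }
    }
  }
  acc[order(names(acc))]
}

#' Concatenated non-core k-mers of a randomized bait
#'
#' The alternative reading of "k-mer" for designs with a fixed core (e.g.
#' the randomized bait with its fixed central TAAT): the uniform-random
#' positions with the fixed core excised, concatenated into one k-mer per
#' read (16 nt for the built-in randomized bait), instead of contiguous
#' windows tiling the whole region.
#'
#' @inheritParams countKmers
#' @param design the [LibraryDesign-class] declaring the fixed core.
#' @return named numeric vector of k-mer counts.
#' @export
gappedCoreKmers <- function(regions, design, counts = NULL) {
  if (methods::is(regions, "DataFrame") && is.null(counts)) {
    counts <- regions$count
    regions <- regions$region
  }
  regions <- as.character(regions)
  if (is.null(counts)) counts <- rep(1, length(regions))
  core <- coreIndex(design)
  if (length(core) == 0L) stop("design has no fixed/doped core to excise")
  keep <- setdiff(seq_len(variableLength(design)), core)
  m <- encodeSequences(regions)[, keep, drop = FALSE]
  gapped <- decodeSequences(m)
  acc <- rowsum(counts, gapped)
  stats::setNames(acc[, 1L], rownames(acc))
}

#' Call enriched k-mers against background expectations
#'
#' For each observed k-mer: `ratio = observed / expected`; a one-sided
#' Poisson upper-tail p-value at the expected count; Benjamini-Hochberg
#' q-values across all scored k-mers; and a round-normalized relative
#' affinity `(ratio / max ratio)^(1/rounds)` (the R-th root of enrichment,
#' proportional to binding affinity under idealized affinity-proportional
#' selection), clipped to \[0, 1\].  Records are ranked by ratio, ties
#' broken lexicographically.
#'
#' @param observed named numeric vector of observed k-mer counts.
#' @param expected named numeric vector of expected counts (must cover the
#'   observed k-mers and be strictly positive, as guaranteed by a positive
#'   Markov pseudocount).
#' @param rounds number of selection rounds behind the observed counts
#'   (>= 1).
#' @return an [S4Vectors::DataFrame-class] with columns `kmer`, `observed`,
#'   `expected`, `ratio`, `p_value`, `q_value`, `rel_affinity`.
#' @export
enrichKmers <- function(observed, expected, rounds) {
  if (length(rounds) != 1L || is.na(rounds) || rounds < 1) {
    stop("'rounds' must be >= 1")
  }
  kmers <- names(observed)
  if (is.null(kmers)) stop("'observed' must be a named vector")
  exp_ <- expected[kmers]
  if (anyNA(exp_)) {
    stop("expected counts missing for k-mer(s): ",
         paste(utils::head(kmers[is.na(exp_)], 5L), collapse = ", "))
  }
  if (any(exp_ <= 0)) stop("expected counts must be > 0")
  obs <- as.numeric(observed)
  ratio <- obs / exp_
  p <- stats::ppois(obs - 1, lambda = exp_, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  rel <- pmin(pmax((ratio / max(ratio))^(1 / rounds), 0), 1)
  out <- S4Vectors::DataFrame(
    kmer = kmers, observed = obs, expected = unname(exp_),
    ratio = unname(ratio), p_value = unname(p), q_value = unname(q),
    rel_affinity = unname(rel)
  )
  out[order(-out$ratio, out$kmer), , drop = FALSE]
}

iupacToRegex <- function(pattern) {
  map <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1L]]
  if (!all(chars %in% names(map))) {
    stop("pattern contains non-IUPAC symbol(s)")
  }
  paste(vapply(chars, function(ch) {
    b <- map[[ch]]
    if (nchar(b) == 1L) b else paste0("[", b, "]")
  }, ""), collapse = "")
}

#' Match k-mers against a degenerate consensus pattern
#'
#' A k-mer matches if any window of pattern length (on the allowed strands)
#' matches the IUPAC-degenerate pattern.  For the 11-bp tandem-TAAT
#' consensus (default `TAATYYAATCA`, i.e. TAAT\[T/C\]\[T/C\]AATCA) the
#' flavor label is the pair of bases at pattern positions 5-6 of the
#' matched window: `TT`, `CT`, `TC` or `CC`.
#'
#' @param kmers character vector of ACGT strings, each at least as long as
#'   the pattern.
#' @param pattern IUPAC-degenerate consensus (default `"TAATYYAATCA"`).
#' @param strands `"forward_only"` or `"both"`.
#' @return an [S4Vectors::DataFrame-class] with `kmer`, `match` (logical)
#'   and `flavor` (`NA` for non-matches).
#' @examples
#' matchConsensus("TAATCTAATCA")$flavor  # "CT"
#' @export
matchConsensus <- function(kmers, pattern = "TAATYYAATCA",
                           strands = c("forward_only", "both")) {
  strands <- match.arg(strands)
  kmers <- toupper(as.character(kmers))
  m <- nchar(pattern)
  if (any(nchar(kmers) < m)) {
    stop("k-mers must be at least as long as the pattern")
  }
  rx <- iupacToRegex(pattern)
  pos <- regexpr(rx, kmers)
  searched <- kmers
  if (strands == "both") {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(kmers)
    ))
    rcpos <- regexpr(rx, rc)
    use_rc <- pos < 0L & rcpos > 0L
    pos[use_rc] <- rcpos[use_rc]
    searched[use_rc] <- rc[use_rc]
  }
  hit <- pos > 0L
  flavor <- rep(NA_character_, length(kmers))
  if (m == 11L && any(hit)) {
    win <- substr(searched[hit], pos[hit], pos[hit] + m - 1L)
    flavor[hit] <- substr(win, 5L, 6L)
  }
  S4Vectors::DataFrame(kmer = kmers, match = hit, flavor = flavor)
}

#' The band-shift oligo panel
#'
#' The double-stranded oligo sequences used in the band-shift (EMSA)
#' assays: the four flavors of the tandem-TAAT consensus, spacing mutants
#' (one base deleted or inserted between the half-sites), the MaLR
#' near-consensus, the Pitx1 promoter sequences, and three
#' selection-derived motifs, each embedded in the same constant flanks.
#'
#' @return named character vector of oligo sequences.
#' @export
dux4OligoPanel <- function() {
  c(
    `DUX4(TT)` = "GGCAGTCTAATTTAATCAAGTCGGC",
    `DUX4(CT)` = "GGCAGTCTAATCTAATCAAGTCGGC",
    `DUX4(TC)` = "GGCAGTCTAATTCAATCAAGTCGGC",
    `DUX4(CC)` = "GGCAGTCTAATCCAATCAAGTCGGC",
    `DUX4-del` = "GGCAGTCTAATTAATCAAGTCGGC",
    `DUX4-ins` = "GGCAGTCTAATCTTAATCAAGTCGGC",
    MALR       = "GGCAGTCTAATTGAATCAAGTCGGC",
    `Pitx1-25` = "GGCAGTCTTCTAATTAGTAGTCGGC",
    `Pitx1-30` = "CGGATGCTGTCTTCTAATTAGTTTGGACCC",
    SELEX2     = "GGCAGTCTAATTCAATCCAGTCGGC",
    SELEX3     = "GGCAGTCTAATTAGCTTTAGTCGGC",
    SELEX4     = "GGCAGTCTAATGTTTTATAGTCGGC"
  )
}

#' Score an oligo panel with a positional weight matrix
#'
#' Scores each oligo by its best motif-length window under a per-position,
#' per-base log-odds matrix (typically the log selection-bias ratios from
#' [biasWeightMatrix()]): the window score is the sum of the weights of its
#' bases.  Ranking is deterministic (score descending, ties by name).
#'
#' @param weights 4 x m numeric matrix (rows `A,C,G,T`).
#' @param oligos named character vector of ACGT sequences, each at least
#'   `m` long.
#' @param strands `"forward_only"` or `"both"`.
#' @return an [S4Vectors::DataFrame-class] with `name`, `oligo`, `score`
#'   and `start` (best-window offset; negative = reverse strand), ranked.
#' @export
scoreOligoPanel <- function(weights, oligos,
                            strands = c("forward_only", "both")) {
  strands <- match.arg(strands)
  stopifnot(is.matrix(weights), nrow(weights) == 4L)
  rownames(weights) <- DNA_BASES
  m <- ncol(weights)
  if (is.null(names(oligos))) names(oligos) <- as.character(seq_along(oligos))
  if (any(nchar(oligos) < m)) {
    stop("oligo(s) shorter than the weight matrix (", m, " positions)")
  }
  scoreOne <- function(seq) {
    codes <- match(strsplit(seq, "", fixed = TRUE)[[1L]], DNA_BASES)
    nw <- length(codes) - m + 1L
    sc <- vapply(seq_len(nw), function(off) {
      sum(weights[cbind(codes[off:(off + m - 1L)], seq_len(m))])
    }, 0)
    best <- which.max(sc)
    c(score = sc[best], start = best)
  }
  res <- t(vapply(toupper(oligos), scoreOne, c(score = 0, start = 0)))
  start <- res[, "start"]
  score <- res[, "score"]
  if (strands == "both") {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(toupper(oligos))
    ))
    res2 <- t(vapply(rc, scoreOne, c(score = 0, start = 0)))
    better <- res2[, "score"] > score
    score[better] <- res2[better, "score"]
    start[better] <- -res2[better, "start"]
  }
  out <- S4Vectors::DataFrame(name = names(oligos),
                              oligo = unname(toupper(oligos)),
                              score = unname(score),
                              start = as.integer(unname(start)))
  out[order(-out$score, out$name), , drop = FALSE]
}
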