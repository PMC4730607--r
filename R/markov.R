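## Order-k Markov background model of unselected (control) reads.
##
## The model is the standard background-correction device of SELEX-seq
## analysis: fitted on the round-0 library, it predicts how many copies of
## each k-mer the sequencer should see absent selection, so that
## observed/expected ratios isolate binding preference from library
## composition.

allContexts <- function(order) {
  ctx <- ""
  for (i in seq_len(order)) {
    ctx <- paste0(rep(ctx, each = 4L), DNA_BASES)
  }
  ctx
}

#' Fit an order-k Markov model on control regions
#'
#' Conditional probabilities are pooled over all start positions:
#' `P(b | context) = (count + pseudocount) / (context total + 4 *
#' pseudocount)`.  The marginal over order-mers is the occurrence frequency
#' of each context across all start positions (smoothed the same way), so
#' that chain probabilities reflect the position-averaged composition of
#' the short regions rather than a stationary approximation.
#'
#' @param regions character vector or DNAStringSet of control variable
#'   regions, each strictly longer than `order`.
#' @param order Markov order k >= 0 (default 5, the standard choice for
#'   randomized-bait SELEX).
#' @param pseudocount smoothing constant per conditional cell (default 0.5;
#'   keeps every expected count positive).
#' @param counts optional per-region multiplicities (e.g. from
#'   [regionCounts()]).
#' @return a [MarkovModel-class].
#' @examples
#' m <- fitMarkov(c("ACAC"), order = 1, pseudocount = 0)
#' kmerProbability(m, "CA")  # 0.5
#' @export
fitMarkov <- function(regions, order = 5L, pseudocount = 0.5,
                      counts = NULL) {
  if (methods::is(regions, "DataFrame") && is.null(counts)) {
    counts <- regions$count
    regions <- regions$region
  }
  regions <- as.character(regions)
  if (is.null(counts)) counts <- rep(1, length(regions))
  order <- as.integer(order)
  if (order < 0L) stop("'order' must be >= 0")
  lens <- nchar(regions)
  short <- which(lens <= order)
  if (length(short)) {
    stop("region(s) not longer than the model order (", order, "): record ",
         paste(utils::head(short, 5L), collapse = ", "),
         if (length(short) > 5L) ", ..." else "")
  }
  ctxs <- allContexts(order)
  nc <- length(ctxs)
  condCounts <- matrix(0, nrow = nc, ncol = 4L,
                       dimnames = list(ctxs, DNA_BASES))
  margCounts <- stats::setNames(numeric(nc), ctxs)
  for (Lg in unique(lens)) {
    sel <- lens == Lg
    s <- regions[sel]
    w <- counts[sel]
    for (off in seq_len(Lg - order)) {
      ctx <- substr(s, off, off + order - 1L)
      nxt <- substr(s, off + order, off + order)
      i <- match(ctx, ctxs)
      j <- match(nxt, DNA_BASES)
      if (anyNA(i) || anyNA(j)) stop("regions must contain only ACGT")
      idx <- (j - 1L) * nc + i
      acc <- rowsum(w, idx)
      condCounts[as.integer(rownames(acc))] <-
        condCounts[as.integer(rownames(acc))] + acc[, 1L]
    }
    ## marginal: every context occurrence, including the final offset
    for (off in seq_len(Lg - order + 1L)) {
      ctx <- substr(s, off, off + order - 1L)
      acc <- rowsum(w, match(ctx, ctxs))
      margCounts[as.integer(rownames(acc))] <-
        margCounts[as.integer(rownames(acc))] + acc[, 1L]
    }
  }
  tot <- rowSums(condCounts)
  cond <- (condCounts + pseudocount) / (tot + 4 * pseudocount)
  if (pseudocount == 0) {
    unseen <- tot == 0
    cond[unseen, ] <- 0.25  # unreachable contexts: uniform placeholder
  }
  marg <- (margCounts + pseudocount) /
    (sum(margCounts) + nc * pseudocount)
  new("MarkovModel", order = order, conditionals = cond,
      marginal = marg, pseudocount = pseudocount)
}

#' @describeIn fitMarkov the model order
#' @param model a [MarkovModel-class].
#' @export
markovOrder <- function(model) model@order

## context distribution advanced one base under the chain
stepContextDistribution <- function(model, d) {
  order <- model@order
  if (order == 0L) return(d)
  ctxs <- rownames(model@conditionals)
  nc <- length(ctxs)
  suffix <- substr(ctxs, 2L, order)
  tgt <- match(paste0(rep(suffix, 4L), rep(DNA_BASES, each = nc)), ctxs)
  contrib <- as.vector(d * model@conditionals)  # column-major: base-major
  out <- numeric(nc)
  acc <- rowsum(contrib, tgt)
  out[as.integer(rownames(acc))] <- acc[, 1L]
  stats::setNames(out, ctxs)
}

## chain probability of each kmer given a named context distribution for
## its first min(order, len) bases
chainProbability <- function(model, kmers, contextDist) {
  order <- model@order
  lens <- nchar(kmers)
  if (length(unique(lens)) > 1L) stop("k-mers must have equal length")
  len <- lens[1L]
  ctxs <- rownames(model@conditionals)
  if (len >= order) {
    if (order == 0L) {
      p <- rep(1, length(kmers))
    } else {
      p <- unname(contextDist[match(substr(kmers, 1L, order), ctxs)])
    }
    start <- order + 1L
  } else {
    pref <- rowsum(unname(contextDist), substr(ctxs, 1L, len))
    p <- pref[match(kmers, rownames(pref)), 1L]
    start <- len + 1L
  }
  if (start <= len) {
    for (j in start:len) {
      ctx <- substr(kmers, j - order, j - 1L)
      b <- substr(kmers, j, j)
      p <- p * model@conditionals[cbind(match(ctx, ctxs),
                                        match(b, DNA_BASES))]
    }
  }
  p
}

#' Chain probability of k-mers under a Markov model
#'
#' `P(kmer) = P(first min(order, len) bases from the marginal) *
#' prod(conditionals)`.  Vectorized over equal-length k-mers; probabilities
#' over all 4^k k-mers of a given length sum to 1.
#'
#' @param model a [MarkovModel-class].
#' @param kmers character vector of equal-length ACGT strings.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
kmerProbability <- function(model, kmers) {
  validObject(model)
  kmers <- toupper(as.character(kmers))
  if (!all(grepl("^[ACGT]+$", kmers))) {
    stop("k-mers must contain only A, C, G, T")
  }
  chainProbability(model, kmers, model@marginal)
}

#' Expected k-mer counts under the background model
#'
#' The window probability of a k-mer is averaged over start positions: the
#' marginal context distribution is propagated along the chain to each
#' window start `s = 1 .. regionLength - k + 1`, so edge effects of the
#' short regions are represented exactly.  With `regionLength = NULL` a
#' single chain law (started from the marginal) is used for all windows.
#' Expected counts are `nWindows * P_window` and, over all 4^k k-mers, sum
#' to `nWindows`.
#'
#' @param model a [MarkovModel-class].
#' @param k k-mer length (>= 1).
#' @param nWindows total number of k-mer windows counted, i.e.
#'   `sum over reads of (region length - k + 1)`.
#' @param regionLength common region length for position averaging
#'   (optional).
#' @param kmers k-mers to score; defaults to all 4^k for k <= 8 (larger k
#'   requires an explicit set, e.g. the observed k-mers).
#' @return named numeric vector of expected counts.
#' @export
expectedKmerCounts <- function(model, k, nWindows, regionLength = NULL,
                               kmers = NULL) {
  validObject(model)
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be >= 1")
  if (!is.null(regionLength) && k > regionLength) {
    stop("'k' exceeds the region length (no windows)")
  }
  if (is.null(kmers)) {
    if (k > 8L) {
      stop("enumerating all 4^", k, " k-mers is not supported; ",
           "pass 'kmers' explicitly")
    }
    kmers <- allContexts(k)
  }
  if (is.null(regionLength)) {
    p <- chainProbability(model, kmers, model@marginal)
  } else {
    nStarts <- regionLength - k + 1L
    d <- model@marginal
    p <- numeric(length(kmers))
    for (s in seq_len(nStarts)) {
      p <- p + chainProbability(model, kmers, d)
      if (s < nStarts) d <- stepContextDistribution(model, d)
    }
    p <- p / nStarts
  }
  stats::setNames(nWindows * p, kmers)
}

#' Log-likelihood of regions under a Markov model
#'
#' Sum over regions of the log chain probability, weighted by `counts`.
#' Useful for held-out comparison of model orders.
#'
#' @inheritParams fitMarkov
#' @param model a [MarkovModel-class].
#' @return total log-likelihood (natural log).
#' @export
markovLogLik <- function(model, regions, counts = NULL) {
  if (methods::is(regions, "DataFrame") && is.null(counts)) {
    counts <- regions$count
    regions <- regions$region
  }
  regions <- as.character(regions)
  if (is.null(counts)) counts <- rep(1, length(regions))
  ll <- 0
  for (Lg in unique(nchar(regions))) {
    sel <- nchar(regions) == Lg
    ll <- ll + sum(counts[sel] * log(kmerProbability(model, regions[sel])))
  }
  ll
}

#' Serialize / deserialize a Markov model as TSV
#'
#' Columns `context`, `base`, `probability`; marginal rows use base `"*"`.
#' The header records the order and pseudocount.
#'
#' @param model a [MarkovModel-class].
#' @param path file path.
#' @param header optional extra header lines.
#' @return `readMarkovModel` returns a [MarkovModel-class];
#'   `writeMarkovModel` invisibly returns `path`.
#' @export
writeMarkovModel <- function(model, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  writeLines(sprintf("# markov order=%d pseudocount=%s", model@order,
                     format(model@pseudocount, digits = 15)), con)
  writeLines("context\tbase\tprobability", con)
  ctxs <- rownames(model@conditionals)
  writeLines(sprintf("%s\t*\t%.17g", ctxs, model@marginal), con)
  for (b in DNA_BASES) {
    writeLines(sprintf("%s\t%s\t%.17g", ctxs, b,
                       model@conditionals[, b]), con)
  }
  invisible(path)
}

#' @rdname writeMarkovModel
#' @export
readMarkovModel <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^# markov ", lines, value = TRUE)
  if (length(meta) != 1L) stop("not a Markov model file: ", path)
  order <- as.integer(sub(".*order=(\\d+).*", "\\1", meta))
  pc <- as.numeric(sub(".*pseudocount=([0-9.eE+-]+).*", "\\1", meta))
  df <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                          colClasses = c("character", "character",
                                         "numeric"))
  ctxs <- allContexts(order)
  marg <- df[df$base == "*", ]
  cond <- df[df$base != "*", ]
  marginal <- stats::setNames(marg$probability[match(ctxs, marg$context)],
                              ctxs)
  cm <- matrix(NA_real_, nrow = length(ctxs), ncol = 4L,
               dimnames = list(ctxs, DNA_BASES))
  cm[cbind(match(cond$context, ctxs), match(cond$base, DNA_BASES))] <-
    cond$probability
  new("MarkovModel", order = order, conditionals = cm, marginal = marginal,
      pseudocount = pc)
}

#' @rdname MarkovModel-class
#' @param object object to display
#' @export
setMethod("show", "MarkovModel", function(object) {
  cat("MarkovModel: order ", object@order, ", ",
      nrow(object@conditionals), " context(s), pseudocount ",
      format(object@pseudocount), "\n", sep = "")
})
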