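## Independent oracles used to cross-check the package implementation.
## These deliberately use naive loops / exhaustive enumeration and share no
## code with the functions they verify.

BASES <- c("A", "C", "G", "T")

## minimum window energy of a sequence under a 4 x m energy matrix,
## computed character by character
naiveBestWindowEnergy <- function(seq, energy) {
  chars <- strsplit(seq, "")[[1]]
  m <- ncol(energy)
  best <- Inf
  for (off in 1:(length(chars) - m + 1)) {
    e <- 0
    for (j in 1:m) {
      e <- e + energy[match(chars[off + j - 1], BASES), j]
    }
    best <- min(best, e)
  }
  best
}

## chain probability of one sequence under a MarkovModel, naive loops
naiveChainProb <- function(model, seq) {
  order <- markovOrder(model)
  cond <- model@conditionals
  marg <- model@marginal
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  if (L >= order) {
    ctx0 <- paste(chars[seq_len(order)], collapse = "")
    p <- if (order == 0) 1 else unname(marg[ctx0])
    jstart <- order + 1
  } else {
    keep <- substr(names(marg), 1, L) == seq
    p <- sum(marg[keep])
    jstart <- L + 1
  }
  j <- jstart
  while (j <= L) {
    row <- if (order == 0) {
      1L
    } else {
      match(paste(chars[(j - order):(j - 1)], collapse = ""),
            rownames(cond))
    }
    p <- p * cond[row, chars[j]]
    j <- j + 1
  }
  p
}

## exhaustive enumeration: expected counts of every k-mer in regions of
## length L drawn from the model, given nWindows total counted windows
enumerationExpectedCounts <- function(model, L, k, nWindows) {
  seqs <- ""
  for (i in seq_len(L)) seqs <- paste0(rep(seqs, each = 4), BASES)
  probs <- vapply(seqs, function(s) naiveChainProb(model, s), 0)
  kmers <- ""
  for (i in seq_len(k)) kmers <- paste0(rep(kmers, each = 4), BASES)
  exp_per_read <- setNames(numeric(length(kmers)), kmers)
  for (idx in seq_along(seqs)) {
    s <- seqs[idx]
    for (off in 1:(L - k + 1)) {
      w <- substr(s, off, off + k - 1)
      exp_per_read[w] <- exp_per_read[w] + probs[idx]
    }
  }
  ## per-window probability * total windows
  exp_per_read / (L - k + 1) * nWindows
}

## textbook Benjamini-Hochberg step-up q-values
textbookBH <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

## draw n regions of length L directly from a MarkovModel's chain
## (initial context from the marginal), independent of package code paths
sampleFromMarkov <- function(model, n, L, seed) {
  order <- markovOrder(model)
  cond <- model@conditionals
  nc <- nrow(cond)
  cum <- t(apply(cond, 1, cumsum))
  withr::with_seed(seed, {
    ctx <- sample.int(nc, n, replace = TRUE, prob = model@marginal)
    out <- matrix("", nrow = n, ncol = L)
    init <- strsplit(rownames(cond)[ctx], "")
    for (j in seq_len(order)) {
      out[, j] <- vapply(init, `[`, "", j)
    }
    j <- order + 1
    while (j <= L) {
      u <- stats::runif(n)
      b <- 1L + (u > cum[ctx, 1]) + (u > cum[ctx, 2]) + (u > cum[ctx, 3])
      out[, j] <- BASES[b]
      if (order > 0) {
        ctx <- ((ctx - 1L) %% (4L^(order - 1L))) * 4L + b
      }
      j <- j + 1
    }
    do.call(paste0, as.data.frame(out, stringsAsFactors = FALSE))
  })
}

## 99% binomial CI bounds for a true proportion p at sample size n
binomBand99 <- function(p, n) {
  z <- qnorm(0.995)
  half <- z * sqrt(p * (1 - p) / n)
  c(low = p - half, high = p + half)
}

## write a temporary FASTQ file from sequences (constant quality)
writeTempFastq <- function(seqs, ids = NULL, gz = FALSE) {
  if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
  path <- tempfile(fileext = if (gz) ".fastq.gz" else ".fastq")
  con <- if (gz) gzfile(path, "w") else file(path, "w")
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+",
                             strrep("I", nchar(seqs)))), con)
  close(con)
  path
}
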