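## Library generation and affinity-proportional selection.
##
## All randomness goes through withr::with_seed on an explicitly supplied
## seed, so every operation is reproducible in isolation.  Hot paths work on
## integer-encoded base matrices; DNAStringSet is the interchange type.

#' Derive a child seed from a master seed
#'
#' Hierarchical RNG streams: each pipeline stage / round draws its own seed
#' deterministically from the master seed, so stages can be rerun
#' independently yet reproducibly.  Results stay inside the 32-bit integer
#' range.
#'
#' @param seed master seed (integer).
#' @param index nonnegative stream index.
#' @return an integer seed.
#' @export
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 +
                as.numeric(index) * 1299709 + 1) %% 2147483647)
}

## integer base codes (A=1, C=2, G=3, T=4) for a set of equal-length
## sequences; Biostrings does the string -> matrix conversion in C
encodeSequences <- function(x) {
  if (!methods::is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  if (length(unique(Biostrings::width(x))) > 1L) {
    stop("sequences must have equal length")
  }
  m <- as.matrix(x)
  codes <- match(m, DNA_BASES)
  dim(codes) <- dim(m)
  codes
}

decodeSequences <- function(codes) {
  m <- matrix(DNA_BASES[codes], nrow = nrow(codes))
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Generate a synthetic SELEX library
#'
#' Samples `n` reads from a [LibraryDesign-class]: each variable-region
#' position is drawn independently per read from the design's per-position
#' base distribution (fixed / uniform / doped at the retention rate), and
#' the constant adapters are attached.
#'
#' @param design a [LibraryDesign-class].
#' @param n number of reads (> 0).
#' @param seed integer seed; identical seeds give identical libraries.
#' @param adapters attach the constant adapters (default `TRUE`); with
#'   `FALSE` only variable regions are returned.
#' @return a [Biostrings::DNAStringSet-class] of length `n`, named
#'   `<design>_<serial>`.
#' @examples
#' lib <- generateLibrary(baitTwo(), 10, seed = 1)
#' @export
generateLibrary <- function(design, n, seed, adapters = TRUE) {
  validObject(design)
  if (n <= 0) stop("'n' must be > 0")
  p <- positionProbs(design)
  L <- ncol(p)
  codes <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(L), function(i) {
      sample.int(4L, n, replace = TRUE, prob = p[, i])
    }, integer(n))
  })
  if (n == 1L) codes <- matrix(codes, nrow = 1L)
  regions <- decodeSequences(codes)
  seqs <- if (adapters) {
    paste0(design@adapter5, regions, design@adapter3)
  } else {
    regions
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("%s_%0*d", design@name, nchar(as.character(n)),
                        seq_len(n))
  out
}

## 4 x m energy matrix for scoring the reverse-complement strand with
## forward-encoded sequences: complement the base and flip the positions
revcompEnergy <- function(energy) {
  energy[4:1, rev(seq_len(ncol(energy))), drop = FALSE]
}

## n x n_windows matrix of window energies for encoded sequences
windowEnergies <- function(codes, energy) {
  m <- ncol(energy)
  L <- ncol(codes)
  nw <- L - m + 1L
  E <- matrix(0, nrow = nrow(codes), ncol = nw)
  for (off in seq_len(nw)) {
    e <- numeric(nrow(codes))
    for (j in seq_len(m)) {
      e <- e + energy[codes[, off + j - 1L], j]
    }
    E[, off] <- e
  }
  E
}

#' Binding affinity of sequences under an energy model
#'
#' Under the `best_window` rule the affinity of a sequence is
#' `exp(-beta * E_min)` where `E_min` is the minimum window energy over all
#' motif-length windows (both strands if the model says so); under
#' `sum_over_windows` it is the sum of `exp(-beta * E)` over windows.
#' Affinity is 1 for a sequence containing the optimal motif (best-window
#' rule) and decreases monotonically in the minimal window energy.
#'
#' @param model a [BindingModel-class].
#' @param x character vector or [Biostrings::DNAStringSet-class] of
#'   equal-length sequences, each at least as long as the motif.
#' @return numeric vector of positive affinities.
#' @examples
#' m <- plantedBindingModel("TAATCTAATCA")
#' sequenceAffinity(m, "TAATCTAATCA")  # 1
#' @export
sequenceAffinity <- function(model, x) {
  validObject(model)
  codes <- encodeSequences(x)
  if (ncol(codes) < motifLength(model)) {
    stop("sequence length ", ncol(codes), " is shorter than the motif (",
         motifLength(model), ")")
  }
  E <- windowEnergies(codes, model@energy)
  if (model@strands == "both") {
    E <- cbind(E, windowEnergies(codes, revcompEnergy(model@energy)))
  }
  if (model@scoringRule == "best_window") {
    exp(-model@beta * apply(E, 1L, min))
  } else {
    rowSums(exp(-model@beta * E))
  }
}

#' One round of affinity-proportional selection
#'
#' Models a protein-limited pulldown plus exact re-amplification: `nOut`
#' reads are drawn with replacement from the input pool with probability
#' proportional to [sequenceAffinity()].  An optional saturation capacity
#' caps individual weights (off by default: plain multinomial sampling,
#' which yields the closed-form enrichment law
#' ratio = (affinity / mean affinity)^rounds).
#'
#' @param reads character vector or DNAStringSet of the input pool (the
#'   sequences that are scored; pass variable regions, not adapters, when
#'   scoring a core motif model).
#' @param model a [BindingModel-class].
#' @param nOut number of reads sampled into the next round.
#' @param seed integer seed.
#' @param saturation optional positive cap applied to affinities before
#'   normalization (`Inf` = off).
#' @return object of the same class as `reads`, length `nOut`.
#' @export
runSelectionRound <- function(reads, model, nOut, seed, saturation = Inf) {
  if (length(reads) == 0L) stop("'reads' must be nonempty")
  if (nOut <= 0) stop("'nOut' must be > 0")
  aff <- pmin(sequenceAffinity(model, reads), saturation)
  if (all(aff == 0)) {
    stop("degenerate selection: all affinities are zero")
  }
  idx <- withr::with_seed(as.integer(seed), {
    sample.int(length(reads), nOut, replace = TRUE, prob = aff)
  })
  reads[idx]
}

#' Construct a SELEX experiment
#'
#' @param design a [LibraryDesign-class].
#' @param rounds number of selection rounds (>= 0).
#' @param readsPerRound reads emitted per round.
#' @param seed master seed for the experiment.
#' @return a [SelexExperiment-class].
#' @export
SelexExperiment <- function(design, rounds, readsPerRound, seed = 1L) {
  new("SelexExperiment", design = design, rounds = as.integer(rounds),
      readsPerRound = as.integer(readsPerRound), seed = as.integer(seed))
}

#' @rdname SelexExperiment-class
#' @param object object to display
#' @export
setMethod("show", "SelexExperiment", function(object) {
  cat("SelexExperiment on design '", object@design@name, "': ",
      object@rounds, " selection round(s), ", object@readsPerRound,
      " reads/round, seed ", object@seed, "\n", sep = "")
})

writeFastq <- function(seqs, path) {
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(seqs)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' Simulate a full SELEX experiment to FASTQ
#'
#' Generates the unselected input library (round 0), then applies `rounds`
#' rounds of affinity-proportional selection with exact re-amplification,
#' writing one FASTQ file per round (constant quality `I`, Phred+33).
#' Selection scores the variable region only; adapters are constant and are
#' re-attached on output.  Per-round seeds are derived from the experiment
#' seed, so the whole run is reproducible byte-for-byte.
#'
#' @param experiment a [SelexExperiment-class].
#' @param model a [BindingModel-class] driving selection.
#' @param outDir output directory (created if missing).
#' @param verbose log a per-round summary to stderr.
#' @return invisibly, a list with `files` (per-round FASTQ paths, round 0
#'   first) and `summary` (data.frame of round, reads and mean affinity).
#' @export
runExperiment <- function(experiment, model, outDir, verbose = FALSE) {
  validObject(experiment)
  validObject(model)
  design <- experiment@design
  if (motifLength(model) > variableLength(design)) {
    stop("motif length exceeds the design's variable region")
  }
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE)) {
    stop("cannot create output directory: ", outDir)
  }
  n <- experiment@readsPerRound
  regions <- as.character(generateLibrary(
    design, n, seed = deriveSeed(experiment@seed, 0L), adapters = FALSE
  ))
  files <- character(experiment@rounds + 1L)
  summary <- data.frame(round = 0:experiment@rounds, reads = n,
                        mean_affinity = NA_real_)
  for (r in 0:experiment@rounds) {
    if (r > 0L) {
      regions <- as.character(runSelectionRound(
        regions, model, n, seed = deriveSeed(experiment@seed, r)
      ))
    }
    summary$mean_affinity[r + 1L] <- mean(sequenceAffinity(model, regions))
    out <- Biostrings::DNAStringSet(
      paste0(design@adapter5, regions, design@adapter3)
    )
    names(out) <- sprintf("%s_r%d_%0*d", design@name, r,
                          nchar(as.character(n)), seq_len(n))
    path <- file.path(outDir, sprintf("%s_round%d.fastq", design@name, r))
    tryCatch(writeFastq(out, path),
             error = function(e) stop("failed writing ", path, ": ",
                                      conditionMessage(e)))
    files[r + 1L] <- path
    if (verbose) {
      message(sprintf("round %d: %d reads, mean affinity %.4g",
                      r, n, summary$mean_affinity[r + 1L]))
    }
  }
  invisible(list(files = files, summary = summary))
}
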