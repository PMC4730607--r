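#' @importFrom methods new validObject is setClass setValidity setGeneric
#'   setMethod show slot
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' LibraryDesign: declarative layout of a SELEX bait
#'
#' A bait is a constant 5' adapter, an ordered run of variable-region
#' positions, and a constant 3' adapter.  Each position is one of: a fixed
#' base (`"A"`, `"C"`, `"G"`, `"T"`), a uniform-random base (`"N"`), or a
#' doped base (lowercase `"a"`/`"c"`/`"g"`/`"t"`), synthesized with the
#' consensus base at probability `retention` and each of the three
#' alternatives at `(1 - retention)/3`.
#'
#' @slot name single character label.
#' @slot adapter5,adapter3 constant adapter sequences (ACGT only).
#' @slot positions character vector of per-position codes (see above).
#' @slot retention doping retention probability in (0, 1], shared by all
#'   doped positions of the design.
#'
#' @seealso [LibraryDesign()], [baitOne()], [baitTwo()]
#' @exportClass LibraryDesign
setClass("LibraryDesign",
  representation(
    name = "character",
    adapter5 = "character",
    adapter3 = "character",
    positions = "character",
    retention = "numeric"
  )
)

setValidity("LibraryDesign", function(object) {
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "'name' must be length 1")
  for (ad in c("adapter5", "adapter3")) {
    a <- slot(object, ad)
    if (length(a) != 1L || is.na(a) ||
        !grepl("^[ACGT]+$", a)) {
      msg <- c(msg, sprintf("'%s' must be a non-empty ACGT string", ad))
    }
  }
  if (length(object@positions) == 0L) {
    msg <- c(msg, "variable region must have at least one position")
  }
  ok <- object@positions %in% c(DNA_BASES, "N", tolower(DNA_BASES))
  if (!all(ok)) {
    msg <- c(msg, sprintf(
      "invalid position code(s): %s",
      paste(unique(object@positions[!ok]), collapse = ", ")
    ))
  }
  if (length(object@retention) != 1L || is.na(object@retention) ||
      object@retention <= 0 || object@retention > 1) {
    msg <- c(msg, "'retention' must be in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' BindingModel: position-specific energy model for protein-DNA affinity
#'
#' Binding energies are in units of the selection exponent (kT times the
#' selection scale beta): the optimal base at each motif position has energy
#' 0 and the affinity of a sequence is `exp(-beta * E)` where `E` is the
#' energy of its best-scoring window (or, under `sum_over_windows`, the sum
#' over windows of Boltzmann weights is used).
#'
#' @slot energy 4 x m numeric matrix, rows `A,C,G,T`, columns motif
#'   positions; every column minimum must be 0.
#' @slot scoringRule `"best_window"` (default) or `"sum_over_windows"`.
#' @slot strands `"forward_only"` (default; bait libraries are directional)
#'   or `"both"`.
#' @slot beta positive selection scale.
#'
#' @seealso [BindingModel()], [defaultBindingModel()], [plantedBindingModel()]
#' @exportClass BindingModel
setClass("BindingModel",
  representation(
    energy = "matrix",
    scoringRule = "character",
    strands = "character",
    beta = "numeric"
  )
)

setValidity("BindingModel", function(object) {
  msg <- character()
  e <- object@energy
  if (!is.numeric(e) || nrow(e) != 4L || ncol(e) < 1L) {
    msg <- c(msg, "'energy' must be a numeric 4 x m matrix")
  } else {
    if (!identical(rownames(e), DNA_BASES)) {
      msg <- c(msg, "'energy' rows must be named A, C, G, T")
    }
    if (any(is.na(e)) || any(e < 0)) {
      msg <- c(msg, "energies must be finite and >= 0")
    } else if (any(abs(apply(e, 2L, min)) > 1e-12)) {
      msg <- c(msg, "each energy column must have minimum 0 (an optimal base)")
    }
  }
  if (!object@scoringRule %in% c("best_window", "sum_over_windows")) {
    msg <- c(msg, "scoringRule must be 'best_window' or 'sum_over_windows'")
  }
  if (!object@strands %in% c("forward_only", "both")) {
    msg <- c(msg, "strands must be 'forward_only' or 'both'")
  }
  if (length(object@beta) != 1L || is.na(object@beta) || object@beta <= 0) {
    msg <- c(msg, "'beta' must be a positive scalar")
  }
  if (length(msg)) msg else TRUE
})

#' SelexExperiment: a library design plus a round structure
#'
#' @slot design a [LibraryDesign-class].
#' @slot rounds number of selection rounds (>= 0; round 0 is the unselected
#'   input library).
#' @slot readsPerRound reads drawn per emitted round.
#' @slot seed master seed; per-round streams are derived from it.
#'
#' @seealso [SelexExperiment()], [runExperiment()]
#' @exportClass SelexExperiment
setClass("SelexExperiment",
  representation(
    design = "LibraryDesign",
    rounds = "integer",
    readsPerRound = "integer",
    seed = "integer"
  )
)

setValidity("SelexExperiment", function(object) {
  msg <- character()
  if (object@rounds < 0L) msg <- c(msg, "'rounds' must be >= 0")
  if (object@readsPerRound <= 0L) msg <- c(msg, "'readsPerRound' must be > 0")
  if (is.na(object@seed)) msg <- c(msg, "'seed' must be a finite integer")
  if (length(msg)) msg else TRUE
})

#' MarkovModel: order-k background model of unselected reads
#'
#' Conditional base probabilities given the preceding `order` bases, pooled
#' over all positions of the fitted regions, plus a marginal distribution
#' over order-mers (the occurrence frequency of each context across all
#' start positions).  With a positive pseudocount every probability is
#' strictly positive.
#'
#' @slot order Markov order k >= 0.
#' @slot conditionals 4^k x 4 matrix of P(base | context); rows named by
#'   context (a single `""` row for order 0), columns `A,C,G,T`; rows sum
#'   to 1.
#' @slot marginal numeric 4^k vector of context occurrence probabilities,
#'   named like the conditional rows; sums to 1.
#' @slot pseudocount the smoothing constant added per conditional cell.
#'
#' @seealso [fitMarkov()], [kmerProbability()], [expectedKmerCounts()]
#' @exportClass MarkovModel
setClass("MarkovModel",
  representation(
    order = "integer",
    conditionals = "matrix",
    marginal = "numeric",
    pseudocount = "numeric"
  )
)

setValidity("MarkovModel", function(object) {
  msg <- character()
  k <- object@order
  if (length(k) != 1L || is.na(k) || k < 0L) {
    msg <- c(msg, "'order' must be a single integer >= 0")
    return(msg)
  }
  nc <- 4L^k
  cm <- object@conditionals
  if (nrow(cm) != nc || ncol(cm) != 4L) {
    msg <- c(msg, sprintf("'conditionals' must be %d x 4", nc))
  } else {
    if (!identical(colnames(cm), DNA_BASES)) {
      msg <- c(msg, "'conditionals' columns must be A, C, G, T")
    }
    rs <- rowSums(cm)
    if (any(abs(rs - 1) > 1e-8)) {
      msg <- c(msg, "conditional rows must each sum to 1")
    }
  }
  if (length(object@marginal) != nc) {
    msg <- c(msg, sprintf("'marginal' must have length %d", nc))
  } else if (abs(sum(object@marginal) - 1) > 1e-8) {
    msg <- c(msg, "'marginal' must sum to 1")
  }
  if (object@pseudocount < 0) msg <- c(msg, "'pseudocount' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' BiasMatrix: per-position, per-base selection-bias ratios
#'
#' The central doped-library statistic: the frequency of each base at each
#' aligned position in the pulled-down pool divided by its frequency in the
#' control pool.  A ratio above 1 means the base was positively selected at
#' that position.  Core positions (the doped/fixed run of the design) are
#' labelled `1..m`; uniform-random flanks are labelled `-3..-1` and
#' `+1..+3` style.
#'
#' @slot labels per-position labels (see above).
#' @slot core integer index of the core positions within the matrix columns.
#' @slot selectedFreq,controlFreq 4 x P base-frequency matrices (columns sum
#'   to 1).
#' @slot selectedCounts,controlCounts the underlying weighted base counts.
#' @slot ratio 4 x P matrix `selectedFreq / controlFreq`; cells with zero
#'   control frequency are `NA` (flagged, not an error).
#'
#' @seealso [selectionBias()], [callConsensus()], [biasWeightMatrix()]
#' @exportClass BiasMatrix
setClass("BiasMatrix",
  representation(
    labels = "character",
    core = "integer",
    selectedFreq = "matrix",
    controlFreq = "matrix",
    selectedCounts = "matrix",
    controlCounts = "matrix",
    ratio = "matrix"
  )
)

setValidity("BiasMatrix", function(object) {
  msg <- character()
  p <- length(object@labels)
  for (nm in c("selectedFreq", "controlFreq", "selectedCounts",
               "controlCounts", "ratio")) {
    m <- slot(object, nm)
    if (nrow(m) != 4L || ncol(m) != p) {
      msg <- c(msg, sprintf("'%s' must be 4 x %d", nm, p))
    }
  }
  if (any(object@ratio < 0, na.rm = TRUE)) {
    msg <- c(msg, "ratios must be >= 0")
  }
  for (nm in c("selectedFreq", "controlFreq")) {
    cs <- colSums(slot(object, nm))
    if (any(abs(cs - 1) > 1e-6)) {
      msg <- c(msg, sprintf("'%s' columns must sum to 1", nm))
    }
  }
  if (length(object@core) && (min(object@core) < 1L ||
                              max(object@core) > p)) {
    msg <- c(msg, "'core' indices out of range")
  }
  if (length(msg)) msg else TRUE
})

#' RunConfig: validated configuration of a full pipeline run
#'
#' @slot designPath path to a library-design file.
#' @slot rounds,readsPerRound round structure of the simulated experiment.
#' @slot order,k,pseudocount Markov background and k-mer parameters.
#' @slot strands `"forward_only"` or `"both"`.
#' @slot maxMismatch adapter-anchoring tolerance for trimming.
#' @slot motif optimal motif of the binding model used for simulation
#'   (`NA` means the built-in DUX4 CT-optimal model).
#' @slot seed master seed.
#' @slot outDir output directory.
#'
#' @seealso [validateConfig()], [runPipeline()]
#' @exportClass RunConfig
setClass("RunConfig",
  representation(
    designPath = "character",
    rounds = "integer",
    readsPerRound = "integer",
    order = "integer",
    k = "integer",
    pseudocount = "numeric",
    strands = "character",
    maxMismatch = "integer",
    motif = "character",
    seed = "integer",
    outDir = "character"
  )
)
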