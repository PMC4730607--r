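#' Construct a binding-energy model
#'
#' @param energy 4 x m numeric matrix of per-position, per-base energies
#'   (rows `A,C,G,T`; 0 marks the optimal base at each position).
#' @param scoringRule `"best_window"` (affinity from the minimum-energy
#'   window) or `"sum_over_windows"` (Boltzmann weights summed over
#'   windows).
#' @param strands `"forward_only"` or `"both"`.
#' @param beta positive selection scale; affinities are
#'   `exp(-beta * energy)`.
#' @return a [BindingModel-class].
#' @export
BindingModel <- function(energy, scoringRule = "best_window",
                         strands = "forward_only", beta = 1) {
  energy <- as.matrix(energy)
  rownames(energy) <- DNA_BASES
  new("BindingModel", energy = energy, scoringRule = scoringRule,
      strands = strands, beta = beta)
}

#' @describeIn BindingModel motif length (number of energy columns)
#' @param model a [BindingModel-class].
#' @export
motifLength <- function(model) ncol(model@energy)

#' @describeIn BindingModel the energy matrix
#' @export
bindingEnergy <- function(model) model@energy

#' @describeIn BindingModel the minimum-energy (optimal) sequence
#' @export
optimalSequence <- function(model) {
  paste(DNA_BASES[apply(model@energy, 2L, which.min)], collapse = "")
}

#' Mismatch energy model around a planted optimum
#'
#' Energy 0 for the planted motif and a flat `mismatch` penalty for every
#' other base at every position.
#'
#' @param motif the optimal sequence (ACGT string).
#' @param mismatch energy penalty per mismatching base (default 2).
#' @inheritParams BindingModel
#' @return a [BindingModel-class].
#' @export
plantedBindingModel <- function(motif, mismatch = 2,
                                scoringRule = "best_window",
                                strands = "forward_only", beta = 1) {
  stopifnot(grepl("^[ACGT]+$", motif))
  bases <- strsplit(motif, "", fixed = TRUE)[[1L]]
  e <- matrix(mismatch, nrow = 4L, ncol = length(bases),
              dimnames = list(DNA_BASES, NULL))
  e[cbind(match(bases, DNA_BASES), seq_along(bases))] <- 0
  BindingModel(e, scoringRule, strands, beta)
}

#' The default DUX4 double-homeodomain energy model
#'
#' Encodes the binding preferences of the DUX4 double homeodomain used for
#' simulation: the optimum is the CT-flavor consensus TAATCTAATCA.  Core
#' positions 1-4 and 6-11 penalize any mismatch by 2; position 5 (the base
#' between the two TAAT half-sites) has C optimal, T mildly penalized (+1,
#' T remains functional) and A/G penalized (+2).  With
#' `flanks = TRUE` (the default) the model spans the full 17-nt doped-bait
#' region: the 3 uniform-random bases on each side of the core prefer A/T
#' (energy 0), mildly disfavor C (+0.5) and disfavor G (+1), reproducing
#' the depletion of G in the sequence flanking the motif.
#'
#' @param flanks include the 3-bp flank preferences on each side (17
#'   positions) or restrict to the 11-bp core.
#' @inheritParams BindingModel
#' @return a [BindingModel-class].
#' @examples
#' optimalSequence(defaultBindingModel(flanks = FALSE))  # "TAATCTAATCA"
#' @export
defaultBindingModel <- function(flanks = TRUE, scoringRule = "best_window",
                                strands = "forward_only", beta = 1) {
  core <- "TAATCTAATCA"
  bases <- strsplit(core, "", fixed = TRUE)[[1L]]
  e <- matrix(2, nrow = 4L, ncol = 11L, dimnames = list(DNA_BASES, NULL))
  e[cbind(match(bases, DNA_BASES), 1:11)] <- 0
  e["T", 5L] <- 1  # TT flavor binds, but C is preferred between half-sites
  if (flanks) {
    fl <- matrix(c(0, 0.5, 1, 0), nrow = 4L, ncol = 3L,
                 dimnames = list(DNA_BASES, NULL))
    e <- cbind(fl, e, fl)
  }
  BindingModel(e, scoringRule, strands, beta)
}

#' @rdname BindingModel-class
#' @param object object to display
#' @export
setMethod("show", "BindingModel", function(object) {
  cat("BindingModel (", object@scoringRule, ", ", object@strands,
      ", beta = ", format(object@beta), ")\n", sep = "")
  cat("  motif length ", motifLength(object), ", optimum ",
      optimalSequence(object), "\n", sep = "")
})
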