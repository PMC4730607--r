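---
title: "Modelling and analysing SELEX-seq binding specificity with selexr"
author: "selexr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and analysing SELEX-seq binding specificity with selexr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selexr)
```

## The experiment being modelled

SELEX-seq characterises the DNA-binding specificity of a protein by
iterated in vitro selection: a partially randomized oligonucleotide
library is incubated with the protein, bound molecules are pulled down,
re-amplified, and the cycle repeated; sequencing the selected pool and an
unselected control reveals which sequences the protein prefers.  selexr
implements this workflow for the DUX4 double homeodomain, the
transcription factor whose misexpression causes facioscapulohumeral
muscular dystrophy.  DUX4 recognises an 11-bp tandem-TAAT consensus,
`TAAT[T/C][T/C]AATCA`, whose four variants ("flavors") are labelled by the
two central bases: TT, CT, TC and CC.

Two bait layouts are built in:

* `baitOne()` — 8 uniform-random bases, a fixed `TAAT`, 8 more random
  bases (20-nt variable region).  This is the unbiased screen: selection
  must discover the full motif around the seeded half-site.
* `baitTwo()` — an 11-bp core synthesized around the TT flavor
  `TAATTTAATCA` in which each position retains its consensus base with
  probability 0.91 and receives each of the three alternatives with
  probability 0.03, flanked by 3 fully random bases on each side (17-nt
  variable region).  This is the saturation-mutagenesis view of the
  motif: every single and most double mutants are present at known input
  frequencies.

Both are framed by the constant Nextera-style adapters used for
amplification and sequencing, and serialized as plain-text design files
(`inst/extdata/*.design`) in an extended per-position alphabet: `ACGT`
fixed, `N` uniform, lowercase doped.

## The selection model

Pulldown is simulated as affinity-proportional multinomial sampling.
Each variable region is scored by a position-specific energy matrix
(`BindingModel`): the optimal base at each motif position has energy 0,
and the affinity of a sequence is

$$a(s) = \exp\!\big(-\beta \min_{w \in \text{windows}} E(s_w)\big)$$

under the default `best_window` rule (a `sum_over_windows` Boltzmann sum
is available).  A selection round draws `n` reads with replacement with
probability proportional to affinity; re-amplification is treated as
exact resampling, with no PCR bias.  This is the simplest model
consistent with a protein-limited pulldown in which sequences compete
for a fixed amount of protein, and it has an exact closed form: after
$R$ rounds the frequency ratio of sequence $i$ against the input pool is

$$\frac{f_{R,i}}{f_{0,i}} \;=\; \frac{a_i^R}{\sum_j f_{0,j}\, a_j^R},$$

i.e. $a^R$ divided by the product of the per-round mean input
affinities.  The test suite verifies the simulator against this closed
form on a three-sequence pool with affinities $(1, e^{-1}, e^{-2})$.
Saturation of the capture reagent is exposed as an optional affinity cap
(`saturation` in `runSelectionRound()`) and is off by default, because
the closed form above — and therefore the interpretability of enrichment
ratios as relative affinities — only holds without it.

### The default DUX4 energy model

`defaultBindingModel()` encodes what the selection experiments and
band-shift assays established about DUX4:

* optimum `TAATCTAATCA` (the CT flavor);
* +2 per mismatching base at core positions 1–4 and 6–11;
* position 5 (between the two half-sites): C optimal, T penalized by
  only +1 (the TT flavor binds, but C is preferred), A and G by +2;
* the three random bases flanking the core on each side: A and T at 0,
  C at +0.5, G at +1.

The flank terms are part of the default model because the flanking
preferences are part of the biology being emulated: G is depleted at all
six flank positions of the selected pool, with a moderate preference for
A and T.  Under best-window scoring an 11-position core model could
never reproduce this — off-centre windows of a doped library are always
≥ ~10 energy units worse than the centred core window, so flank bases
would have no effect on affinity at all.  With the flank terms the model
spans the full 17-nt doped region (a single window), while
`defaultBindingModel(flanks = FALSE)` gives the bare 11-mer core model,
which is the right scorer when the query sequences are candidate 11-bp
sites themselves.  Energies are expressed directly in units of the
selection exponent ($\beta = 1$ by default).

## Read processing

Library inserts are fixed-length, so adapters are matched at their
expected offsets allowing substitutions only (default budget: 2 per
adapter).  This deliberately avoids alignment: it is bit-reproducible,
fast, and exactly inverts the simulator for clean reads (the suite
checks 100% acceptance and exact region recovery on simulator output).
Reads are rejected — counted, never silently dropped — for four reasons:
too short, 5′ adapter mismatch over budget, 3′ adapter mismatch over
budget, or non-ACGT symbols inside the variable region.  Accepted plus
rejected always equals the input count.

## The Markov background model

Enrichment cannot be read directly off k-mer counts because even an
unselected library has non-uniform k-mer abundances.  The standard
correction is an order-$k$ Markov model fitted on the unselected
(round-0) control: conditional base probabilities given the preceding
`order` bases, pooled over all positions, smoothed with a pseudocount
(default 0.5 per conditional cell so every expected count is strictly
positive).  The default order is 5 and the default k-mer length 16,
tiling the 20-nt randomized-bait region with five windows per read; the
alternative reading of "16-mer" — the 16 random positions with the fixed
TAAT excised — is available via `gappedCoreKmers()`.

Two choices deserve a note, since the methodology leaves them open:

* **The marginal.**  The distribution over initial `order`-mers is the
  occurrence frequency of each context across *all* start positions, not
  just read prefixes.  Regions are short, so prefix-only estimation
  would waste most of the data and make probabilities of k-mers shorter
  than the order depend on a single position.
* **Position averaging.**  `expectedKmerCounts()` does not use a
  stationary approximation: the marginal is propagated through the chain
  to every window start, and window probabilities are averaged over
  starts.  Edge effects are material at these lengths.  This definition
  is verified against exhaustive enumeration of all $4^L$ sequences
  weighted by the chain (orders ≤ 2, $L \le 8$) to within $10^{-9}$
  relative error.

A position-pooled Markov model is an honest fit for the randomized bait,
whose composition is close to homogeneous, and the suite shows the null
calibration there (control scored against its own background has median
ratio ≈ 1 and approximately uniform Poisson p-values).  It is *not* a
good background for the heavily doped bait, whose composition is
strongly position-dependent — which is why the doped design is analysed
with the positional-bias statistic below rather than through the Markov
route, mirroring how the two experiments differ in practice.

## Enrichment calling

For each observed k-mer: `ratio = observed / expected`, a one-sided
Poisson upper-tail p-value at the model-predicted expectation,
Benjamini–Hochberg q-values across all scored k-mers, and a
round-normalized relative affinity $(\text{ratio}/\text{max
ratio})^{1/R}$, which under the idealized selection model is
proportional to binding affinity.  The experimental literature reports
"significantly enriched" sequences without naming a test; the Poisson
null is the natural choice when the expectation comes from a background
model, and BH the standard multiplicity correction.  Ranking is by
ratio (not p-value), matching how top enriched sequences are usually
presented, with lexicographic tie-breaking for determinism.

Two practical caveats, both demonstrated in the test suite:

* When k-mer windows are shorter than the region, windows overlapping a
  selected motif ("shadows" of the motif, shifted by a few bases) are
  themselves enriched even though they are poor binding sites.  For
  affinity recovery the package is therefore validated on core-aligned
  windows (one candidate site per read).
* A flat mismatch-penalty model assigns many k-mers exactly equal true
  affinity; the ordering inside such a tie class is meaningless, so
  rank-recovery is assessed on tie-aware class medians.

## Positional selection bias

For the doped bait the central statistic is per-position: the frequency
of each base at each aligned position in the pulled-down pool divided by
its frequency in the control pool (`selectionBias()`).  A ratio above 1
means positive selection.  Ratios are reported raw (unsmoothed), with
Wilson 95% intervals on the underlying frequencies in the TSV export;
cells with zero control frequency are flagged `NA` rather than raising.
The three uniform flank positions on each side are included, labelled
`-3..-1` and `+1..+3` around core positions `1..11`.

`callConsensus()` takes, per core position, the base with the maximal
ratio; ratios within 2% (relative) of the top are treated as ties and
reported as IUPAC ambiguity codes, so a control-vs-control comparison
yields an all-`N` no-call rather than a spurious consensus.  Confidence
per position is `log(top/second)`.  The derived weight matrix
(`biasWeightMatrix()`, log ratios over the core, floored at $10^{-6}$
before the log) scores arbitrary oligos by their best window
(`scoreOligoPanel()`); scored on the built-in band-shift panel
(`dux4OligoPanel()`), the CT-flavor probe ranks first, above the Pitx1
25-mer and the single-base spacing mutants, matching the competitive
band-shift ordering.

## Pipeline, seeds and reproducibility

`runPipeline()` chains simulate → trim → fit-background → enrich →
posbias → report from one validated YAML config (`validateConfig()`,
strict keys, exhaustive error reporting).  All randomness flows from a
single master seed through `deriveSeed()`, a deterministic per-stage
stream derivation, so any stage can be rerun in isolation and a full
rerun is byte-identical.  Every tabular output begins with a header line
recording the package version, seed and a hash of the run parameters;
FASTQ files cannot carry such a line without breaking the format, so
their provenance lives in the run's report.  A thin command-line
front end over the same functions ships in `inst/scripts/selex-cli.R`.

```{r pipeline-example, eval = FALSE}
cfg <- validateConfig("run.yaml")   # design, rounds, reads, order, k, seed
res <- runPipeline(cfg, verbose = TRUE)
res$consensus                        # "TAATCTAATCA" under the default model
```

## Problem sizes used by the test suite

The shipped checks run at the scale the analysis is designed for where
that is cheap, and at reduced but statistically adequate scale
elsewhere: doping fidelity and the positional-bias signatures use the
full 200,000 reads per round (3 rounds, 5 seeds); planted-motif recovery
uses 20 replicates of 2 rounds × 200,000 reads with the optimum planted
one mutation away from the doped consensus, so recovery must overcome
the library bias exactly as the real experiment's CT-over-TT finding
did; the enrichment-law check uses a $10^6$-read toy pool; Markov oracle
checks are exhaustive and exact.  Null-calibration and affinity-recovery
properties run at $10^5$–$10^6$ reads, where the binomial/Poisson error
bands they assert are comfortably narrower than the effects being
excluded.

## What the simulator does and does not capture

The generator reproduces the synthesis scheme (doping rates, uniform
flanks, constant adapters), affinity-proportional competition, and
round-to-round enrichment dynamics, deterministically per seed.  It does
not model PCR amplification bias or jackpotting, sequencing errors or
quality variation (qualities are written as a constant), primer-dimer
artifacts, bead-chemistry saturation (beyond the optional affinity cap),
or paired-end structure (inserts are fully covered by a single read).
Passing tests therefore demonstrate that the *analysis* recovers the
truth of this idealized generative process at realistic scale — they do
not certify robustness to amplification or sequencing artifacts in real
libraries, which is exactly the gap the control-library normalization in
the enrichment and bias statistics is designed to absorb.

## Known limitations

* The Markov background assumes position-homogeneous composition; for
  strongly position-structured (doped) libraries use the positional-bias
  route.
* Enrichment p-values assume independent Poisson counts; overlapping
  windows of the same read violate independence mildly at small k.
* `best_window` scoring ignores multi-site occupancy within one read;
  the `sum_over_windows` rule is a first-order account of it.
* Dinucleotide (epistatic) preferences are out of scope: the bias
  matrix and the derived weight matrix are strictly per-position.
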