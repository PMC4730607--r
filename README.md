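# selexr

Simulation and specificity analysis of SELEX-seq experiments, built around
the DUX4 double homeodomain.

SELEX-seq determines a transcription factor's DNA-binding preferences by
iterated in vitro selection: a partially randomized oligonucleotide
library is pulled down with the protein, re-amplified, and sequenced
alongside an unselected control.  DUX4 — the double-homeodomain factor
whose misexpression causes facioscapulohumeral muscular dystrophy (FSHD)
— recognises an 11-bp tandem-TAAT consensus, `TAAT[T/C][T/C]AATCA`, with
four flavors named by the two central bases (TT, CT, TC, CC).  selexr is
for computational biologists who want to analyse such experiments, or to
study the statistical behaviour of the analysis itself on fully
controlled synthetic data:

* **Library simulation** — declarative bait designs (`LibraryDesign`):
  a doped 11-bp core (91% consensus base, 3% each alternative) with
  random flanks (`baitTwo()`), or random flanks around a fixed TAAT
  (`baitOne()`); rounds of affinity-proportional pulldown under an
  explicit position-specific energy model, emitted as FASTQ
  (`runExperiment()`).
* **Read processing** — anchored adapter matching and variable-region
  extraction with per-reason rejection accounting
  (`extractVariableRegions()`).
* **Markov background** — an order-*k* model fitted on the unselected
  control predicts expected k-mer counts absent selection
  (`fitMarkov()`, `expectedKmerCounts()`); defaults: order 5, k = 16.
* **Enrichment** — observed/expected ratios, Poisson upper-tail
  p-values with Benjamini–Hochberg correction, and round-normalized
  relative affinities `(ratio/max)^(1/R)` (`enrichKmers()`), plus
  consensus-flavor annotation (`matchConsensus()`).
* **Positional selection bias** — the doped-library statistic: base
  frequency in the pulled-down pool divided by base frequency in the
  control, per position (`selectionBias()`), consensus calling
  (`callConsensus()`) and scoring of candidate oligos with the derived
  log-ratio weight matrix (`scoreOligoPanel()`, `dux4OligoPanel()`).
* **Pipeline** — one reproducible run from a YAML config with a single
  master seed and hierarchical per-stage streams (`validateConfig()`,
  `runPipeline()`); a thin CLI lives in `inst/scripts/selex-cli.R`.

The central quantities, in the field's notation: a sequence's affinity is
`a(s) = exp(-β · min_w E(s_w))` over motif-length windows `w` of a 4 × m
energy matrix `E`; after `R` rounds of affinity-proportional selection a
sequence's frequency ratio versus the input is `a^R / Σ_j f0_j a_j^R`;
k-mer enrichment is `observed / expected` under the order-k Markov chain
`P(kmer) = P(context) Π P(base | context)`; and the per-position
selection bias is `freq_selected(base, pos) / freq_control(base, pos)`.

## Worked example

Three rounds of selection on the doped bait under the default CT-optimal
DUX4 model, then the positional-bias analysis:

```r
library(selexr)
design <- baitTwo()               # NNN + doped TAATTTAATCA + NNN
model  <- defaultBindingModel()   # optimum TAATCTAATCA, flank G penalty
n <- 50000
ctl <- as.character(generateLibrary(design, n, seed = deriveSeed(42, 0),
                                    adapters = FALSE))
sel <- ctl
for (r in 1:3)
  sel <- as.character(runSelectionRound(sel, model, n,
                                        seed = deriveSeed(42, r)))
bias <- selectionBias(baseFrequencyMatrix(sel, design),
                      baseFrequencyMatrix(ctl, design), design)
round(biasRatios(bias)[, c("-1", "4", "5", "6")], 3)
#>      -1     4      5     6
#> A 1.859 0.000  0.038 0.007
#> C 0.423 0.002 15.830 0.001
#> G 0.080 0.006  0.037 0.003
#> T 1.639 1.100  0.576 1.099
```

Read the columns as selection ratios (selected / control frequency) at
flank position −1 and core positions 4–6.  At the flank, A and T are
mildly favoured and G strongly depleted (ratio 0.08).  At core position
4 the library consensus T is still positively selected (1.10) while
mutants are purged.  Position 5 — the base between the two TAAT
half-sites, where the library was doped with T — shows the signature
result: C is enriched 15.8-fold over its input frequency while the
doped-in T is *depleted* (0.58), so selection overturns the library's
own consensus at exactly this position.

```r
callConsensus(bias)$consensus
#> [1] "TAATCTAATCA"

ranked <- scoreOligoPanel(biasWeightMatrix(bias), dux4OligoPanel())
head(as.data.frame(ranked)[, c("name", "score")], 5)
#>       name      score
#> 1 DUX4(CT)  3.7005096
#> 2 DUX4(TT)  0.3869001
#> 3 DUX4(CC) -3.7157044
#> 4     MALR -5.6135070
#> 5 DUX4(TC) -7.0293139
```

The called consensus is the CT flavor, and scoring the band-shift oligo
panel with the weight matrix derived from the run ranks the CT probe
first (scores are best-window sums of per-position log selection
ratios; positive means net positively selected bases).

The same analysis, end to end with all intermediate TSVs and a report:

```r
cfg <- validateConfig("run.yaml")  # design/out_dir/rounds/reads/seed/...
res <- runPipeline(cfg, verbose = TRUE)
```

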