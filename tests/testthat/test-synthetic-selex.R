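test_that("a fully fixed design yields identical adapter-flanked reads", {
  d <- LibraryDesign("fix", "ACGT", "GGCC", "TAAT")
  lib <- generateLibrary(d, 5, seed = 7)
  expect_length(lib, 5L)
  expect_equal(unique(as.character(lib)), "ACGTTAATGGCC")
})

test_that("sampled base frequencies follow the design distribution", {
  ## uniform position: frequencies near 0.25
  d <- LibraryDesign("uni", "AA", "TT", "N")
  lib <- generateLibrary(d, 1e5, seed = 11, adapters = FALSE)
  f <- table(as.character(lib)) / 1e5
  band <- binomBand99(0.25, 1e5)
  expect_true(all(f > band["low"] & f < band["high"]))

  ## doping law: global chi-square goodness of fit over all positions
  ## (independent per-position statistics add) not rejected at alpha = 0.001
  d2 <- baitTwo()
  lib2 <- generateLibrary(d2, 1e5, seed = 12, adapters = FALSE)
  m <- as.matrix(Biostrings::DNAStringSet(lib2))
  p <- positionProbs(d2)
  stat <- sum(vapply(seq_len(ncol(m)), function(i) {
    obs <- table(factor(m[, i], levels = rownames(p)))
    suppressWarnings(stats::chisq.test(obs, p = p[, i])$statistic)
  }, 0))
  pGlobal <- stats::pchisq(stat, df = 3L * ncol(m), lower.tail = FALSE)
  expect_gt(pGlobal, 0.001)
})

test_that("library generation is deterministic given the seed", {
  d <- baitTwo()
  a <- generateLibrary(d, 500, seed = 3)
  b <- generateLibrary(d, 500, seed = 3)
  c_ <- generateLibrary(d, 500, seed = 4)
  expect_identical(as.character(a), as.character(b))
  expect_false(identical(as.character(a), as.character(c_)))
})

test_that("affinity follows the Boltzmann form of the best window", {
  m <- plantedBindingModel("TAATCTAATCA")
  expect_equal(sequenceAffinity(m, "TAATCTAATCA"), 1.0)
  ## single mismatch of penalty 2 at the only window
  expect_equal(sequenceAffinity(m, "GAATCTAATCA"), exp(-2))
  ## monotone decreasing in the minimal window energy
  expect_lt(sequenceAffinity(m, "GGATCTAATCA"),
            sequenceAffinity(m, "GAATCTAATCA"))
  expect_error(sequenceAffinity(m, "TAATCTAAT"), "shorter than the motif")
})

test_that("multi-window affinities match a naive window scorer", {
  m <- defaultBindingModel(flanks = FALSE)  # 11-mer core model
  regions <- as.character(generateLibrary(baitTwo(), 50, seed = 21,
                                          adapters = FALSE))
  got <- sequenceAffinity(m, regions)  # 17 nt -> 7 windows
  want <- vapply(regions, function(s) {
    exp(-naiveBestWindowEnergy(s, bindingEnergy(m)))
  }, 0)
  expect_equal(got, unname(want), tolerance = 1e-12)
})

test_that("sum-over-windows affinity adds Boltzmann weights", {
  m <- plantedBindingModel("TAAT", scoringRule = "sum_over_windows")
  ## windows of "TAATAAT": TAAT (0), AATA (4 mm? -> by hand), ...
  region <- "TAATTAAT"
  e <- bindingEnergy(m)
  want <- sum(vapply(1:5, function(off) {
    chars <- strsplit(region, "")[[1]][off:(off + 3)]
    exp(-sum(e[cbind(match(chars, c("A", "C", "G", "T")), 1:4)]))
  }, 0))
  expect_equal(sequenceAffinity(m, region), want)
  expect_gt(sequenceAffinity(m, "TAATTAAT"),
            sequenceAffinity(m, "TAATGGGG"))
})

test_that("both-strand scoring recognizes the reverse complement", {
  fwd <- plantedBindingModel("TAATCTAATCA", strands = "forward_only")
  both <- plantedBindingModel("TAATCTAATCA", strands = "both")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("TAATCTAATCA")
  ))
  expect_lt(sequenceAffinity(fwd, rc), 1)
  expect_equal(sequenceAffinity(both, rc), 1.0)
})

test_that("selection excludes zero-affinity reads and keeps composition", {
  ## affinities 1 and numerically 0
  m <- plantedBindingModel("ACGT", mismatch = 2000)
  out <- runSelectionRound(c("ACGT", "TTTT"), m, 200, seed = 5)
  expect_true(all(out == "ACGT"))
  ## all reads identical
  out2 <- runSelectionRound(rep("ACGT", 3), m, 50, seed = 6)
  expect_true(all(out2 == "ACGT"))
  ## degenerate: every affinity zero
  expect_error(runSelectionRound(c("TTTT", "GGGG"), m, 10, seed = 7),
               "degenerate")
  ## constant-affinity model reproduces input frequencies (selection
  ## invariance): uniform energies are disallowed to shift anything
  flat <- BindingModel(matrix(0, 4, 4, dimnames = list(c("A","C","G","T"),
                                                       NULL)))
  pool <- c(rep("AAAA", 7000), rep("CCCC", 3000))
  sel <- runSelectionRound(pool, flat, 1e4, seed = 8)
  expect_equal(mean(sel == "AAAA"), 0.7, tolerance = 0.02)
})

test_that("selection proportions match the closed-form expectation", {
  m <- plantedBindingModel("ACGT", mismatch = 1)
  reads <- c("ACGT", "ACGA")  # affinities 1 and exp(-1)
  sel <- runSelectionRound(reads, m, 2e5, seed = 9)
  frac <- mean(sel == "ACGT")
  expect_equal(frac, 1 / (1 + exp(-1)), tolerance = 0.005)
})

test_that("repeated selection follows the enrichment law on a toy pool", {
  ## frequencies after R rounds scale as (affinity / mean affinity)^R
  m <- plantedBindingModel("ACGT", mismatch = 1)
  pool <- c(rep("ACGT", 1e4), rep("ACGA", 1e4), rep("ACAA", 1e4))
  aff <- c(1, exp(-1), exp(-2))
  sel <- runSelectionRound(pool, m, 3e5, seed = 10)
  f <- table(factor(sel, levels = unique(pool))) / 3e5
  want <- (aff / mean(aff)) / 3  # input freq 1/3 each, R = 1
  expect_equal(as.numeric(f), want, tolerance = 0.02)
})

test_that("experiments emit one FASTQ per round with rising mean affinity", {
  d <- baitTwo()
  m <- defaultBindingModel()
  out <- tempfile()
  res <- runExperiment(SelexExperiment(d, 3, 20000, seed = 31), m, out)
  expect_length(res$files, 4L)
  expect_true(all(file.exists(res$files)))
  expect_true(all(diff(res$summary$mean_affinity) > 0))
  ## round 0 is unselected: base frequencies match the design
  r0 <- parseReads(res$files[1], format = "fastq")
  expect_length(r0, 20000L)

  ## rounds = 0 emits only the input library
  res0 <- runExperiment(SelexExperiment(d, 0, 1000, seed = 32), m,
                        tempfile())
  expect_length(res0$files, 1L)
})

test_that("identical experiment seeds give byte-identical FASTQ", {
  d <- baitTwo()
  m <- defaultBindingModel()
  o1 <- tempfile(); o2 <- tempfile()
  r1 <- runExperiment(SelexExperiment(d, 2, 3000, seed = 33), m, o1)
  r2 <- runExperiment(SelexExperiment(d, 2, 3000, seed = 33), m, o2)
  for (i in seq_along(r1$files)) {
    expect_identical(unname(tools::md5sum(r1$files[i])),
                     unname(tools::md5sum(r2$files[i])))
  }
})
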