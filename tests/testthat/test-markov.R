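test_that("hand-computable fits recover exact conditional probabilities", {
  m0 <- fitMarkov(c("AAAA", "CCCC"), order = 0, pseudocount = 0)
  expect_equal(unname(m0@conditionals[1, ]), c(0.5, 0.5, 0, 0))

  m1 <- fitMarkov("ACAC", order = 1, pseudocount = 0)
  expect_equal(unname(m1@conditionals["A", "C"]), 1)
  expect_equal(unname(m1@conditionals["C", "A"]), 1)
  ## marginal pooled over all context occurrences: A,C,A,C
  expect_equal(unname(m1@marginal[c("A", "C")]), c(0.5, 0.5))
  expect_equal(kmerProbability(m1, "CA"), 0.5)

  expect_error(fitMarkov(c("ACGTA", "AC"), order = 2), "record 2")
  expect_error(fitMarkov("ACNGT", order = 1, pseudocount = 0), "ACGT")
})

test_that("fitted conditionals concentrate on the generating distribution", {
  regions <- sampleFromMarkov(
    fitMarkov("ACGT", order = 0, pseudocount = 1),  # uniform source
    1e5, 20, seed = 51
  )
  m <- fitMarkov(regions, order = 5, pseudocount = 0.5)
  expect_true(all(abs(m@conditionals - 0.25) < 0.05))
})

test_that("chain probabilities normalize and match closed forms", {
  uni <- fitMarkov("ACGT", order = 0, pseudocount = 1)
  expect_equal(kmerProbability(uni, strrep("A", 16)), 0.25^16)
  m2 <- fitMarkov(as.character(generateLibrary(baitTwo(), 300, seed = 52,
                                               adapters = FALSE)),
                  order = 2, pseudocount = 0.5)
  twomers <- apply(expand.grid(BASES, BASES), 1, paste, collapse = "")
  expect_equal(sum(kmerProbability(m2, twomers)), 1, tolerance = 1e-12)
  expect_error(kmerProbability(m2, "ACNG"), "A, C, G, T")
})

test_that("expected counts match exhaustive enumeration", {
  ## small fitted models, every k-mer, against a naive full enumeration of
  ## all 4^L sequences weighted by the chain
  regions <- as.character(generateLibrary(
    LibraryDesign("mini", "AC", "GT", "NtaN", retention = 0.85), 200,
    seed = 53, adapters = FALSE
  ))
  L <- 6
  regions <- substr(paste0(regions, regions), 1, L)
  for (order in 0:2) {
    model <- fitMarkov(regions, order = order, pseudocount = 0.5)
    for (k in c(1, 3)) {
      nWin <- 1000 * (L - k + 1)
      got <- expectedKmerCounts(model, k, nWin, regionLength = L)
      want <- enumerationExpectedCounts(model, L, k, nWin)
      expect_equal(got, want[names(got)], tolerance = 1e-9)
      expect_equal(sum(got), nWin, tolerance = 1e-6)
    }
  }
})

test_that("expected counts are uniform under a uniform model", {
  uni <- fitMarkov("ACGT", order = 0, pseudocount = 1)
  e <- expectedKmerCounts(uni, 2, 160)
  expect_length(e, 16L)
  expect_true(all(abs(e - 10) < 1e-12))
  expect_error(expectedKmerCounts(uni, 5, 10, regionLength = 4),
               "region length")
  expect_error(expectedKmerCounts(uni, 16, 10), "explicitly")
})

test_that("sampling from the model reproduces expected k-mer counts", {
  ## self-consistency at ~1.7e6 windows: 99% of k-mers inside 3*sqrt bands
  src <- fitMarkov(as.character(generateLibrary(baitOne(), 2000, seed = 54,
                                                adapters = FALSE)),
                   order = 2, pseudocount = 0.5)
  n <- 1e5; L <- 20; k <- 4
  regions <- sampleFromMarkov(src, n, L, seed = 55)
  obs <- countKmers(regions, k)
  nWin <- n * (L - k + 1)
  expd <- expectedKmerCounts(src, k, nWin, regionLength = L)
  z_ok <- abs(obs - expd[names(obs)]) <= 3 * sqrt(expd[names(obs)])
  expect_gte(mean(z_ok), 0.99)
})

test_that("held-out log-likelihood is non-decreasing with model order", {
  d <- baitOne()  # fixed TAAT core induces strong local structure
  fit <- as.character(generateLibrary(d, 5e4, seed = 56, adapters = FALSE))
  held <- as.character(generateLibrary(d, 2e4, seed = 57, adapters = FALSE))
  ll <- vapply(0:5, function(ord) {
    markovLogLik(fitMarkov(fit, order = ord, pseudocount = 0.5), held)
  }, 0)
  expect_true(all(diff(ll) >= 0))
})

test_that("models round-trip through the TSV serialization", {
  m <- fitMarkov(as.character(generateLibrary(baitTwo(), 500, seed = 58,
                                              adapters = FALSE)),
                 order = 3, pseudocount = 0.5)
  path <- tempfile(fileext = ".tsv")
  writeMarkovModel(m, path, header = "tool x seed=1")
  m2 <- readMarkovModel(path)
  expect_equal(markovOrder(m2), 3L)
  expect_equal(m2@pseudocount, 0.5)
  expect_equal(m2@conditionals, m@conditionals, tolerance = 1e-12)
  expect_equal(m2@marginal, m@marginal, tolerance = 1e-12)
})
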