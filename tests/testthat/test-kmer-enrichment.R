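test_that("k-mer counting tiles windows and conserves totals", {
  expect_equal(countKmers("ACGT", 2),
               c(AC = 1, CG = 1, GT = 1))
  ## palindrome counted once per strand
  expect_equal(countKmers("ACGT", 4, strands = "both"), c(ACGT = 2))
  ## weighted regions
  rc <- S4Vectors::DataFrame(region = c("AAAA", "AAAC"), count = c(3L, 2L))
  got <- countKmers(rc, 3)
  expect_equal(got, c(AAA = 8, AAC = 2))
  ## conservation on a random sample
  regions <- as.character(generateLibrary(baitTwo(), 1e4, seed = 61,
                                          adapters = FALSE))
  k <- 11
  counts <- countKmers(regions, k)
  expect_equal(sum(counts), sum(nchar(regions) - k + 1))
  both <- countKmers(regions, k, strands = "both")
  expect_equal(sum(both), 2 * sum(nchar(regions) - k + 1))
  expect_error(countKmers("ACG", 4), "shortest region")
})

test_that("gapped-core extraction excises the fixed core", {
  d <- baitOne()
  region <- paste0("AAAACCCC", "TAAT", "GGGGTTTT")
  got <- gappedCoreKmers(region, d)
  expect_equal(got, c(AAAACCCCGGGGTTTT = 1))
  rc <- S4Vectors::DataFrame(region = rep(region, 2), count = c(2L, 3L))
  expect_equal(unname(gappedCoreKmers(rc, d)), 5)
  expect_error(gappedCoreKmers(region, LibraryDesign("x", "A", "T", "NN")),
               "no fixed/doped core")
})

test_that("enrichment records carry ratios, Poisson p-values and BH q-values", {
  ## observed equal to expected: null ratios, nothing enriched
  expd <- c(AAAA = 50, CCCC = 50, GGGG = 50, TTTT = 50)
  e0 <- enrichKmers(c(AAAA = 50, CCCC = 50, GGGG = 50, TTTT = 50),
                    expd, rounds = 1)
  expect_true(all(e0$ratio == 1))
  expect_gt(min(e0$p_value), 0.4)
  expect_true(all(e0$q_value >= e0$p_value))

  ## closed-form record: ratio 2, top of the table, rel_affinity 1
  e1 <- enrichKmers(c(AAAA = 20, CCCC = 9), c(AAAA = 10, CCCC = 10),
                    rounds = 1)
  expect_equal(e1$kmer[1], "AAAA")
  expect_equal(e1$ratio[1], 2)
  expect_equal(e1$rel_affinity[1], 1)
  expect_equal(e1$p_value[1],
               stats::ppois(19, 10, lower.tail = FALSE))

  ## ties rank lexicographically
  et <- enrichKmers(c(TTTT = 20, AAAA = 20), c(TTTT = 10, AAAA = 10),
                    rounds = 2)
  expect_equal(et$kmer, c("AAAA", "TTTT"))
  expect_equal(et$rel_affinity, c(1, 1))  # (ratio/max)^(1/2)

  expect_error(enrichKmers(c(A = 1), c(A = 1), rounds = 0), "rounds")
  expect_error(enrichKmers(c(AAAA = 1), c(CCCC = 1), rounds = 1),
               "missing")
})

test_that("BH q-values match a textbook step-up implementation exactly", {
  withr::with_seed(62, {
    obs <- stats::setNames(rpois(300, 20), paste0("k", 1:300))
    expd <- stats::setNames(rep(20, 300), names(obs))
  })
  e <- enrichKmers(obs, expd, rounds = 1)
  expect_equal(e$q_value, textbookBH(e$p_value), tolerance = 1e-12)
})

test_that("a control round scored against its own background is null", {
  ## exact-model null: uniform regions vs the uniform chain
  uni <- fitMarkov("ACGT", order = 0, pseudocount = 1)
  n <- 2.5e5; L <- 20; k <- 5
  regions <- sampleFromMarkov(uni, n, L, seed = 63)
  obs <- countKmers(regions, k)
  nWin <- n * (L - k + 1)
  expd <- expectedKmerCounts(uni, k, nWin, regionLength = L,
                             kmers = names(obs))
  e <- enrichKmers(obs, expd, rounds = 1)
  expect_gt(median(e$ratio), 0.9)
  expect_lt(median(e$ratio), 1.1)
  ## p-values approximately uniform
  ks <- suppressWarnings(stats::ks.test(e$p_value, "punif"))
  expect_gt(ks$p.value, 0.001)

  ## fitted-model null on the randomized-bait control (the design the
  ## background model is meant for): ratio distribution centred at 1
  ctl <- as.character(generateLibrary(baitOne(), 1e5, seed = 64,
                                      adapters = FALSE))
  bg <- fitMarkov(ctl, order = 5, pseudocount = 0.5)
  obs2 <- countKmers(ctl, 6)
  nWin2 <- 1e5 * (20 - 6 + 1)
  expd2 <- expectedKmerCounts(bg, 6, nWin2, regionLength = 20,
                              kmers = names(obs2))
  e2 <- enrichKmers(obs2, expd2, rounds = 1)
  expect_gt(median(e2$ratio), 0.9)
  expect_lt(median(e2$ratio), 1.1)
})

test_that("consensus matching recognizes flavors, windows and strands", {
  got <- matchConsensus(c("TAATCTAATCA",   # CT flavor
                          "TAATTGAATCA",   # middle G: not a consensus
                          "GTAATTTAATCAG"))# embedded TT window
  expect_equal(got$match, c(TRUE, FALSE, TRUE))
  expect_equal(got$flavor, c("CT", NA, "TT"))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("TAATCCAATCA")
  ))
  expect_false(matchConsensus(rc)$match)
  both <- matchConsensus(rc, strands = "both")
  expect_true(both$match)
  expect_equal(both$flavor, "CC")
  expect_error(matchConsensus("TAAT"), "at least as long")
})

test_that("oligo scoring is deterministic and honors the energy model", {
  ## weights straight from the true model: log-affinity per position
  w <- -bindingEnergy(defaultBindingModel(flanks = FALSE))
  panel <- dux4OligoPanel()
  ranked <- scoreOligoPanel(w, panel)
  expect_equal(ranked$name[1], "DUX4(CT)")
  sc <- stats::setNames(ranked$score, ranked$name)
  expect_gt(sc["DUX4(CT)"], sc["Pitx1-25"])
  expect_gt(sc["DUX4(CT)"], sc["DUX4-del"])
  expect_gt(sc["DUX4(CT)"], sc["DUX4-ins"])
  ## identical oligos get identical scores
  twice <- scoreOligoPanel(w, c(x = panel[["DUX4(CT)"]],
                                y = panel[["DUX4(CT)"]]))
  expect_equal(twice$score[1], twice$score[2])
  expect_error(scoreOligoPanel(w, c(short = "ACGT")), "shorter")
})

test_that("relative affinities recover true affinities from simulation", {
  ## 3 rounds of selection on the doped bait, scored at the core (one
  ## 11-mer window per read, observed vs round-0 baseline) so that each
  ## counted k-mer is itself a candidate binding site.  The mismatch
  ## energy model assigns many k-mers exactly the same true affinity, and
  ## the ordering inside such a tie class carries no information, so the
  ## rank agreement is assessed on tie-aware (class-median) estimates.
  d <- baitTwo()
  model <- defaultBindingModel()
  n <- 1e5
  ctl <- as.character(generateLibrary(d, n, seed = 65, adapters = FALSE))
  sel <- ctl
  for (r in 1:3) {
    sel <- as.character(runSelectionRound(sel, model, n, seed = 65 + r))
  }
  core <- coreIndex(d)
  obs <- countKmers(substr(sel, min(core), max(core)), 11)
  base <- countKmers(substr(ctl, min(core), max(core)), 11)
  common <- intersect(names(obs), names(base)[base >= 20])
  expd <- base[common] * (sum(obs) / sum(base))
  e <- enrichKmers(obs[common], expd, rounds = 3)
  top <- utils::head(e, 100)
  trueAff <- sequenceAffinity(defaultBindingModel(flanks = FALSE),
                              top$kmer)
  classMedian <- tapply(top$rel_affinity, trueAff, stats::median)
  tieAware <- unname(classMedian[as.character(trueAff)])
  expect_gte(stats::cor(tieAware, trueAff, method = "spearman"), 0.9)
  ## and the class medians themselves are strictly ordered by affinity
  expect_true(all(diff(classMedian[order(as.numeric(names(classMedian)))])
                  > 0))
})
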