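test_that("parameter construction validates the time ordering", {
  p <- dipSimParams()
  expect_s4_class(p, "DipSimParams")
  expect_equal(c(p@tInt, p@tAlpha, p@tBeta, p@tGamma), c(1, 4, 8, 12))

  ps <- dipSimParams(scaleFactor = 0.1)
  expect_equal(c(ps@tInt, ps@tAlpha, ps@tBeta, ps@tGamma),
               c(0.1, 0.4, 0.8, 1.2))

  pr <- dipSimParams(relIntTime = 0.8)
  expect_equal(pr@tInt, 0.8 * 4)

  # introgression coincident with (or after) the first speciation is invalid
  expect_error(dipSimParams(tInt = 4, tAlpha = 4), "tInt < tAlpha")
  expect_error(dipSimParams(tInt = 5), "tInt < tAlpha")
  expect_error(dipSimParams(scaleFactor = -1), "scaleFactor")
  expect_error(dipSimParams(locusLength = 0), "locusLength")
  expect_error(dipSimParams(baseFreqs = c(0.5, 0.5, 0.5, 0.5)), "baseFreqs")
  expect_error(dipSimParams(pMove = 0), "pMove")
})

test_that("gene-tree draws respect the coalescent closed forms", {
  ## discordance among speciation-history loci: (2/3) exp(-2 (tBeta-tAlpha));
  ## testable at scaleFactor 0.1 where it is ~0.2996
  set.seed(101)
  p <- dipSimParams(scaleFactor = 0.1)
  n <- 4000
  cls <- character(n)
  t12 <- numeric(n)
  for (i in seq_len(n)) {
    tr <- drawGeneTree(p, "SP")
    cls[i] <- classifyTopology(tr@phy)
    t12[i] <- ape::cophenetic.phylo(tr@phy)["P1", "P2"] / 2
  }
  pDisc <- (2 / 3) * exp(-2 * (p@tBeta - p@tAlpha))
  sd3 <- 3 * sqrt(pDisc * (1 - pDisc) / n)
  expect_lt(abs(mean(cls != "SP") - pDisc), sd3)
  ## the two discordant quartets are (roughly) equally frequent
  expect_lt(abs(sum(cls == "INT") - sum(cls == "ALT")),
            3 * sqrt(n * pDisc / 2))
  ## E[T(P1,P2)] = tAlpha + 1/2 for speciation histories
  expect_lt(abs(mean(t12) - (p@tAlpha + 0.5)), 0.05)

  ## with certain transfer, E[T(P2,P3)] = tInt + 1/2 on introgressed loci
  set.seed(102)
  pd <- dipSimParams()
  t23 <- replicate(2000, {
    tr <- drawGeneTree(pd, "INT_P3_TO_P2")
    expect_true(tr@realizedTransfer)
    ape::cophenetic.phylo(tr@phy)["P2", "P3"] / 2
  })
  expect_lt(abs(mean(t23) - (pd@tInt + 0.5)), 0.05)
})

test_that("discordance decreases as the tree is stretched", {
  set.seed(103)
  disc <- sapply(c(0.1, 0.5, 1), function(sf) {
    p <- dipSimParams(scaleFactor = sf)
    mean(replicate(600, classifyTopology(drawGeneTree(p, "SP")@phy) != "SP"))
  })
  expect_true(disc[1] > disc[2])
  expect_true(disc[2] >= disc[3])
})

test_that("pMove controls whether the recipient lineage transfers", {
  set.seed(104)
  p <- dipSimParams(pMove = 0.6)
  moved <- replicate(800, drawGeneTree(p, "INT_P3_TO_P2")@realizedTransfer)
  expect_lt(abs(mean(moved) - 0.6), 3 * sqrt(0.6 * 0.4 / 800))
})

test_that("sequence evolution matches substitution-model closed forms", {
  ## zero branch lengths: no substitutions, four identical sequences
  set.seed(105)
  tr <- makeGeneTree()
  tr@phy$edge.length[] <- 0
  la <- evolveSequences(tr, dipSimParams(locusLength = 200))
  s <- alnToStrings(la@seqs)
  expect_true(all(s == s[1]))

  ## two tips separated by 0.16 subs/site under Jukes-Cantor settings:
  ## expected p-distance (3/4)(1 - exp(-4*0.16/3)) ~ 0.1441
  set.seed(106)
  trJC <- makeGeneTree(tPair = 8, tMid = 9, tRoot = 10)  # P1-P2 path = 16
  pJC <- dipSimParams(locusLength = 300000, kappa = 1)
  laJC <- evolveSequences(trJC, pJC)
  pd <- pairwiseDistance(laJC@seqs["P1", ], laJC@seqs["P2", ], model = "raw")
  expected <- 0.75 * (1 - exp(-4 * 0.16 / 3))
  expect_lt(abs(as.numeric(pd) - expected),
            3 * sqrt(expected * (1 - expected) / 300000))

  ## stationarity: long branches reproduce the stationary base composition
  set.seed(107)
  bf <- c(0.4, 0.3, 0.2, 0.1)
  trS <- makeGeneTree(tPair = 100, tMid = 150, tRoot = 200)
  pS <- dipSimParams(locusLength = 100000, baseFreqs = bf)
  laS <- evolveSequences(trS, pS)
  comp <- ape::base.freq(laS@seqs["P1", , drop = FALSE])
  expect_lt(max(abs(comp[c("a", "c", "g", "t")] - bf)), 0.01)
})

test_that("genome simulation has deterministic composition and is seed-reproducible", {
  p <- dipSimParams(locusLength = 100)
  set.seed(1)
  gs <- simulateGenome(20, 0.5, 1, p)
  tt <- truthTable(gs)
  expect_equal(sum(tt$history == "SP"), 10)
  expect_equal(sum(tt$history == "INT_P3_TO_P2"), 10)
  expect_equal(sum(tt$history == "INT_P2_TO_P3"), 0)

  set.seed(2)
  expect_true(all(truthTable(simulateGenome(15, 0, 0.5, p))$history == "SP"))

  expect_error(simulateGenome(10, 1.5, 0, p), "pInt")
  expect_error(simulateGenome(10, 0.5, -0.1, p), "pP3toP2")

  ## byte-identical under the same seed
  set.seed(7)
  a <- simulateGenome(5, 0.5, 0.5, p)
  set.seed(7)
  b <- simulateGenome(5, 0.5, 0.5, p)
  expect_identical(truthTable(a), truthTable(b))
  expect_identical(lapply(a@loci, function(l) alnToStrings(l@seqs)),
                   lapply(b@loci, function(l) alnToStrings(l@seqs)))
})

test_that("simulated SP loci reproduce the expected mean divergence", {
  ## E[K23 | SP] = 2 * seqScale * (tBeta + 1/2) = 0.17 under defaults
  set.seed(108)
  p <- dipSimParams(locusLength = 1000)
  gs <- simulateGenome(150, 0, 0, p)
  tab <- locusTable(classifyLoci(gs))
  expect_lt(abs(mean(tab$K23) - 0.17), 0.01)
})

test_that("chromosome simulation tiles the sequence with labeled blocks", {
  set.seed(109)
  p <- dipSimParams()
  ## no recombination: one block spanning the chromosome
  ch0 <- simulateChromosome(3000, 0, c(0.5, 0), p)
  expect_equal(nrow(ch0$truth), 1L)
  expect_equal(ch0$truth$start, 0L)
  expect_equal(ch0$truth$end, 3000L)
  expect_equal(ncol(ch0$alignment), 3000L)

  ## breakpoints form a Poisson process: block count ~ 1 + L * intensity
  set.seed(110)
  counts <- replicate(40, nrow(simulateChromosome(20000, 1 / 2000,
                                                  c(0, 0), p)$truth))
  lambda <- 20000 / 2000
  expect_lt(abs(mean(counts) - (1 + lambda)), 3 * sqrt(lambda / 40))

  ## blocks tile [0, L) without gaps or overlaps
  set.seed(111)
  ch <- simulateChromosome(30000, 1 / 5000, c(0.4, 0.2), p)
  tt <- ch$truth
  expect_equal(tt$start[1], 0L)
  expect_equal(tt$end[nrow(tt)], 30000L)
  if (nrow(tt) > 1) expect_equal(tt$start[-1], tt$end[-nrow(tt)])
  expect_equal(ncol(ch$alignment), 30000L)

  ## windows wholly inside one block share that block's genealogy, so under
  ## deep divergence they classify identically to the block truth
  wins <- partitionWindows(ch$alignment, 1000, contig = "sim")
  wins <- labelWindowsFromBlocks(wins, tt)
  inner <- Filter(function(w) {
    any(tt$start <= w@start & tt$end >= w@end)
  }, wins)
  cl <- classifyLoci(inner)
  tabw <- locusTable(cl)
  expect_true(all(tabw$class ==
                  ifelse(tabw$truth == "SP", "SP", "INT")))
})
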