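test_that("the delta-K profile reproduces the directional signatures", {
  ## P3=>P2 signature: K23 collapses and K12 inflates among INT loci
  cl <- makeClassified(nSp = 50, nInt = 50,
                       mSp = c(0.17, 0.09, 0.17), mInt = c(0.03, 0.17, 0.17))
  expect_equal(unname(deltaKProfile(cl)), c(0.14, 0.08, 0.00),
               tolerance = 1e-12)

  ## P2=>P3 signature: K13 collapses instead
  cl2 <- makeClassified(nSp = 50, nInt = 50,
                        mSp = c(0.17, 0.09, 0.17), mInt = c(0.03, 0.09, 0.09))
  expect_equal(unname(deltaKProfile(cl2)), c(0.14, 0.00, 0.08),
               tolerance = 1e-12)

  ## identical class means: all shifts vanish
  cl3 <- makeClassified(nSp = 30, nInt = 30,
                        mSp = c(0.1, 0.1, 0.1), mInt = c(0.1, 0.1, 0.1))
  expect_equal(unname(deltaKProfile(cl3)), c(0, 0, 0))

  ## empty SP or INT class is not computable
  expect_error(deltaKProfile(makeClassified(nSp = 10, nAlt = 5)),
               "not computable")
})

test_that("swapping the K12 and K13 columns behaves per the sign conventions", {
  ## under the definitions dK12 = INT - SP and dK13 = SP - INT, swapping the
  ## stored columns maps dK12 -> -dK13 and dK13 -> -dK12, which leaves
  ## ddK = dK12 - dK13 exactly invariant
  set.seed(21)
  cl <- makeClassified(nSp = 80, nInt = 60, nAlt = 20, jitter = 0.02)
  pk <- deltaKProfile(cl)
  ps <- deltaKProfile(swapK1213(cl))
  expect_equal(unname(ps["dk12"]), -unname(pk["dk13"]), tolerance = 1e-12)
  expect_equal(unname(ps["dk13"]), -unname(pk["dk12"]), tolerance = 1e-12)
  expect_equal(unname(ps["dk12"] - ps["dk13"]),
               unname(pk["dk12"] - pk["dk13"]), tolerance = 1e-12)
})

test_that("the ALT-substituted statistic follows its defining arithmetic", {
  ## symmetric ILS: ALT mirrors SP with the pair roles exchanged
  clSym <- makeClassified(nSp = 40, nInt = 10, nAlt = 40,
                          mSp = c(0.17, 0.09, 0.17),
                          mAlt = c(0.09, 0.17, 0.09))
  expect_equal(deltaDeltaKAlt(clSym), 0, tolerance = 1e-12)

  cl <- makeClassified(nSp = 40, nInt = 10, nAlt = 40,
                       mSp = c(0.17, 0.09, 0.17),
                       mAlt = c(0.10, 0.15, 0.10))
  expect_equal(deltaDeltaKAlt(cl), (0.15 - 0.09) - (0.17 - 0.10),
               tolerance = 1e-12)

  expect_error(deltaDeltaKAlt(makeClassified(nSp = 10, nInt = 10)),
               "no ALT")
})

test_that("the corrected statistic dddK follows the weighted-difference formula", {
  ## constant class means chosen so ddk = 0.04, ddkAlt = 0.03
  cl <- makeClassified(nSp = 500, nInt = 800, nAlt = 200,
                       mSp = c(0.17, 0.09, 0.17),
                       mInt = c(0.03, 0.17, 0.13),
                       mAlt = c(0.14, 0.15, 0.10))
  td <- tripleDip(cl, nBoot = 30)
  expect_equal(td@ddk, 0.04, tolerance = 1e-12)
  expect_equal(td@ddkAlt, 0.03, tolerance = 1e-12)
  expect_equal(td@dddk, (0.04 * 800 - 0.03 * 200) / 600, tolerance = 1e-12)
  expect_true(td@computable)

  ## no ALT loci: flagged, ddk still reported
  td0 <- tripleDip(makeClassified(nSp = 50, nInt = 50), nBoot = 10)
  expect_false(td0@computable)
  expect_equal(td0@reason, "no ALT loci")
  expect_false(is.na(td0@ddk))

  ## equal INT and ALT counts: distinct degenerate flag
  tdE <- tripleDip(makeClassified(nSp = 50, nInt = 20, nAlt = 20),
                   nBoot = 10)
  expect_false(tdE@computable)
  expect_equal(tdE@reason, "equal INT and ALT counts")
})

test_that("dddK converges to ddK as the ALT class vanishes", {
  ## |dddk - ddk| <= |ddk - ddkAlt| * nAlt / (nInt - nAlt)
  set.seed(22)
  for (i in 1:20) {
    nInt <- sample(200:800, 1)
    nAlt <- sample(1:50, 1)
    cl <- makeClassified(nSp = 300, nInt = nInt, nAlt = nAlt, jitter = 0.02)
    td <- tripleDip(cl, nBoot = 2)
    bound <- abs(td@ddk - td@ddkAlt) * nAlt / (nInt - nAlt) + 1e-12
    expect_lte(abs(td@dddk - td@ddk), bound)
  }
})

test_that("bootstrap replicates honor their contract", {
  ## separation construction: every INT K12 above every SP K12, so every
  ## replicate has dk12 > 0 and the one-sided p sits at the resolution floor
  set.seed(23)
  n <- 200
  cl <- makeClassified(nSp = n, nInt = n, jitter = 0)
  tab <- cl@loci
  tab$K12[tab$class == "SP"] <- runif(n, 0.01, 0.05)
  tab$K12[tab$class == "INT"] <- runif(n, 0.20, 0.30)
  cl@loci <- tab
  reps <- bootstrapStatistics(cl, 1000)
  expect_true(all(reps$dk12 > 0))
  expect_equal(nrow(reps), 1000L)
  ## every replicate resamples to the original locus count
  expect_true(all(reps$nSp + reps$nInt + reps$nAlt == 2 * n))
  pd <- oneDip(cl, reps = reps)
  expect_lte(pd@p12, 1 / 1000)

  ## identical seed, identical replicate set
  set.seed(99)
  r1 <- bootstrapStatistics(cl, 50)
  set.seed(99)
  r2 <- bootstrapStatistics(cl, 50)
  expect_identical(r1, r2)

  expect_error(bootstrapStatistics(cl, 0), "nBoot")
})

test_that("bootstrap p-values live in [resolution floor, 1]", {
  set.seed(24)
  for (i in 1:4) {
    cl <- makeClassified(nSp = 60, nInt = 40, nAlt = 10, jitter = 0.03)
    nb <- 200
    pd <- oneDip(cl, nBoot = nb)
    dd <- doubleDip(cl, nBoot = nb)
    ps <- c(pValues(pd), dd@p)
    expect_true(all(ps >= 1 / nb - 1e-12))
    expect_true(all(ps <= 1))
    expect_gte(dd@p, dd@pFloor)
  }
})

test_that("degenerate symmetric input gives ddK = 0 with p = 1", {
  ## constant, identical class means: the replicate distribution is a point
  ## mass at zero, which must read as "no evidence", not significance
  cl <- makeClassified(nSp = 50, nInt = 50,
                       mSp = c(0.1, 0.12, 0.12), mInt = c(0.05, 0.12, 0.12))
  dd <- doubleDip(cl, nBoot = 100)
  expect_equal(dd@ddk, 0)
  expect_equal(dd@p, 1)
})

test_that("the directionality call follows the significance pattern", {
  set.seed(25)
  ## clear P3=>P2 pattern with mild noise
  cl32 <- makeClassified(nSp = 150, nInt = 150,
                         mSp = c(0.17, 0.09, 0.17),
                         mInt = c(0.03, 0.17, 0.17), jitter = 0.01)
  expect_equal(dipCall(oneDip(cl32, nBoot = 300)), "P3_TO_P2")

  cl23 <- makeClassified(nSp = 150, nInt = 150,
                         mSp = c(0.17, 0.09, 0.17),
                         mInt = c(0.03, 0.09, 0.09), jitter = 0.01)
  expect_equal(dipCall(oneDip(cl23, nBoot = 300)), "P2_TO_P3")

  clBi <- makeClassified(nSp = 150, nInt = 150,
                         mSp = c(0.17, 0.09, 0.17),
                         mInt = c(0.03, 0.13, 0.13), jitter = 0.01)
  expect_equal(dipCall(oneDip(clBi, nBoot = 300)), "BIDIRECTIONAL")

  ## no signal anywhere: inconclusive
  clNull <- makeClassified(nSp = 150, nInt = 150,
                           mSp = c(0.1, 0.1, 0.1), mInt = c(0.1, 0.1, 0.1),
                           jitter = 0.01)
  expect_equal(dipCall(oneDip(clNull, nBoot = 300)), "INCONCLUSIVE")
})
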