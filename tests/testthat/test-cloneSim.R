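test_that("per-generation transition matrices are stochastic and exact", {
  m0 <- AllelicModel("cis_only", kC = 0)
  P0 <- divisionTransitionMatrix(rateMatrix(m0), 20)
  expect_equal(unname(P0), diag(4))
  ## scalar switch probability 1 - exp(-k dt)
  m <- AllelicModel("cis_only", kC = 0.0042)
  P <- divisionTransitionMatrix(rateMatrix(m), 20)
  expect_equal(P["C00", "C10"],
               (1 - exp(-0.084)) * exp(-0.084), tolerance = 1e-10)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
  expect_true(all(P >= 0))
  ## two sequential steps at rate k: completing both within dt has
  ## probability 1 - exp(-k dt)(1 + k dt) (2-step Poisson closed form)
  k <- 0.0042; dt <- 20
  Q2 <- matrix(c(-k, k, 0, 0, -k, k, 0, 0, 0), 3, 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  P2 <- divisionTransitionMatrix(Q2, dt)
  expect_equal(P2["a", "c"], 1 - exp(-k * dt) * (1 + k * dt),
               tolerance = 1e-10)
})

test_that("clone classification implements the class definitions", {
  expect_equal(classifyClone(c("monoY", "bi")), "single_mono_allelic")
  expect_equal(classifyClone(c("monoR")), "single_mono_allelic")
  expect_equal(classifyClone(c("monoY", "monoR")), "mixed_mono_allelic")
  expect_equal(classifyClone(c("monoY", "monoR", "bi")), "mixed_mono_allelic")
  expect_equal(classifyClone(c("bi", "none")), "bi_allelic_only")
  expect_equal(classifyClone(c("none")), "non_expressing")
  expect_equal(classifyClone(character(0)), "non_expressing")
})

test_that("degenerate rate limits produce the expected clones", {
  ## no transitions: every clone stays non-expressing with 2^5 leaves
  m0 <- AllelicModel("parallel", kC = 0, kT = 0)
  rec <- simulateClone(m0, cloneSimConfig(nClones = 1, seed = 3))
  expect_equal(nrow(rec), 63L)           # binary tree over 5 divisions
  expect_equal(sum(rec$generation == 5L), 32L)
  expect_equal(classifyClone(rec), "non_expressing")
  d0 <- cloneClassDistribution(m0, cloneSimConfig(nClones = 200, seed = 4))
  expect_equal(unname(cloneCounts(d0)["non_expressing"]), 200)
  expect_true(d0@flagged)                # expressing distribution undefined
  ## huge cis rate: both alleles flip essentially immediately -> clones
  ## are bi-allelic (the embedded path passes through mono, so strictly
  ## bi-only clones require the boundary view; assert bi dominates)
  mBig <- AllelicModel("cis_only", kC = 5)
  dBig <- cloneClassDistribution(mBig, cloneSimConfig(nClones = 300, seed = 5),
                                 observe = "boundary")
  expect_gt(cloneFractions(dBig)[["bi_allelic_only"]], 0.95)
})

test_that("lineage records are well-formed trees", {
  m <- AllelicModel("parallel", kC = 0.01, kT = 0.02)
  rec <- simulateClone(m, cloneSimConfig(nClones = 1, seed = 7))
  expect_true(all(rec$parent_id[-1] %in% rec$cell_id))
  expect_equal(sum(is.na(rec$parent_id)), 1L)   # single root
  ## children born when the parent divides
  kids <- rec[!is.na(rec$parent_id), ]
  pidx <- match(kids$parent_id, rec$cell_id)
  expect_equal(kids$birth_h, rec$division_h[pidx])
  ## seeded determinism
  rec2 <- simulateClone(m, cloneSimConfig(nClones = 1, seed = 7))
  expect_identical(rec, rec2)
  ## text rendering covers every cell
  expect_length(formatCloneTree(rec), nrow(rec))
})

test_that("lineage marginals match the exact master equation", {
  ## the lineage simulator and the matrix solution describe the same
  ## process: pooled class fractions per generation agree within MC error
  cfgN <- 2500
  for (kind in c("cis_only", "sequential", "parallel")) {
    m <- AllelicModel(kind, kC = 0.0042, kT = 0.012)
    d <- cloneClassDistribution(m, cloneSimConfig(nClones = cfgN, seed = 17))
    gc <- attr(d, "genCounts")
    sim <- gc / rowSums(gc)
    ex <- as.matrix(populationFractions(m, seq(0, 100, 20))[, 2:5])
    se <- sqrt(ex * (1 - ex) / cfgN)     # clones are the independent units
    expect_true(all(abs(sim - ex) <= 3 * pmax(se, 2e-3)),
                label = paste("marginals for", kind))
  }
})

test_that("clone-class distributions are deterministic under a seed", {
  m <- AllelicModel("parallel", kC = 0.004, kT = 0.012)
  d1 <- cloneClassDistribution(m, cloneSimConfig(nClones = 2000, seed = 23))
  d2 <- cloneClassDistribution(m, cloneSimConfig(nClones = 2000, seed = 23))
  expect_identical(cloneCounts(d1), cloneCounts(d2))
  expect_identical(cloneFractions(d1), cloneFractions(d2))
  d3 <- cloneClassDistribution(m, cloneSimConfig(nClones = 2000, seed = 24))
  expect_false(identical(cloneCounts(d1), cloneCounts(d3)))
})

test_that("model families leave their clone-class signatures", {
  ## study condition: progenitors sorted non-expressing after pre-culture
  kC <- 0.006; kT <- 0.005
  mSeq <- AllelicModel("sequential", kC = kC, kT = kT,
                       init = sortedNoneInit("sequential", kC, kT))
  mPar <- AllelicModel("parallel", kC = kC, kT = kT,
                       init = sortedNoneInit("parallel", kC, kT))
  dSeq <- cloneClassDistribution(mSeq, cloneSimConfig(nClones = 8000, seed = 31))
  dPar <- cloneClassDistribution(mPar, cloneSimConfig(nClones = 8000, seed = 31))
  fSeq <- cloneFractions(dSeq); fPar <- cloneFractions(dPar)
  ## sequential: mixed mono-allelic is the modal expressing class
  expect_equal(names(which.max(fSeq)), "mixed_mono_allelic")
  ## parallel: single mono-allelic is the modal expressing class
  expect_equal(names(which.max(fPar)), "single_mono_allelic")
  ## a sequential path to bi always traverses mono: no bi-only clones
  expect_equal(unname(fSeq[["bi_allelic_only"]]), 0)
  expect_gt(fPar[["bi_allelic_only"]], 0)
})

test_that("the clone-level statistic reproduces the printed values", {
  ## single-category form (O - E)^2 / E
  t1 <- cloneClassChi2(7, 9, 0.201)
  expect_equal(t1$statistic, 14.9, tolerance = 0.005)
  expect_equal(t1$df, 1)
  expect_lt(t1$pValue, 0.001)
  t2 <- cloneClassChi2(7, 9, 0.639)
  expect_equal(t2$statistic, 0.27, tolerance = 0.005)
  expect_gt(t2$pValue, 0.05)
  ## exact expectation gives zero
  expect_equal(cloneClassChi2(3, 10, 0.3)$statistic, 0)
  ## two-category Pearson form is larger by 1/(1 - p)
  p1 <- cloneClassChi2(7, 9, 0.201, method = "pearson")
  expect_equal(p1$statistic, t1$statistic / (1 - 0.201), tolerance = 1e-9)
  expect_equal(p1$statistic, 18.65, tolerance = 0.01)
  p2 <- cloneClassChi2(7, 9, 0.639, method = "pearson")
  expect_equal(p2$statistic, 0.751, tolerance = 0.001)
  expect_error(cloneClassChi2(7, 9, 1), "expectedFraction")
})
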