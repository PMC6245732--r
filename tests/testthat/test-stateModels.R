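test_that("state spaces have the documented structure", {
  expect_equal(nrow(stateSpace("cis_only")), 4L)
  expect_equal(nrow(stateSpace("sequential")), 5L)
  expect_equal(nrow(stateSpace("parallel")), 8L)
  ## sequential: cis cannot precede trans
  ss <- stateSpace("sequential")
  expect_true(all(ss$trans | (!ss$cisY & !ss$cisR)))
  ## parallel: trans-off states are non-expressing whatever the cis flags
  sp <- stateSpace("parallel")
  expect_true(all(sp$class[!sp$trans] == "none"))
  ## non-expressing sub-states: 1 / 2 / 5
  expect_equal(sum(stateSpace("cis_only")$class == "none"), 1L)
  expect_equal(sum(ss$class == "none"), 2L)
  expect_equal(sum(sp$class == "none"), 5L)
})

test_that("rate matrix rows sum to zero with symmetric allele rates", {
  for (kind in c("cis_only", "sequential", "parallel")) {
    m <- AllelicModel(kind, kC = 0.0042, kT = 0.01, kCrev = 0.001,
                      kTrev = 0.002)
    Q <- rateMatrix(m)
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    expect_true(all(Q[row(Q) != col(Q)] >= 0))
    ## allele symmetry: swapping the two cis flags permutes Q onto itself
    ss <- stateSpace(kind)
    swapped <- ss$label[match(
      paste(ss$trans, ss$cisR, ss$cisY),
      paste(ss$trans, ss$cisY, ss$cisR))]
    expect_equal(unname(Q[swapped, swapped]), unname(Q))
  }
})

test_that("rate matrix matches hand-enumerated transitions", {
  expect_equal(rateMatrix(AllelicModel("cis_only", kC = 0)),
               matrix(0, 4, 4, dimnames = list(rownames(stateSpace("cis_only")),
                                               rownames(stateSpace("cis_only")))))
  Q <- rateMatrix(AllelicModel("parallel", kC = 0.0042, kT = 0.01))
  expect_equal(-Q["T0.C00", "T0.C00"], 0.01 + 2 * 0.0042)
  expect_equal(Q["T0.C00", "T1.C00"], 0.01)
  expect_equal(Q["T0.C00", "T0.C10"], 0.0042)
  expect_equal(Q["T1.C10", "T1.C11"], 0.0042)
  ## sequential gating: no cis transitions while trans is off
  Qs <- rateMatrix(AllelicModel("sequential", kC = 0.0042, kT = 0.01))
  expect_equal(unname(Qs["T0.C00", c("T1.C10", "T1.C01", "T1.C11")]),
               c(0, 0, 0))
  expect_equal(-Qs["T0.C00", "T0.C00"], 0.01)
})

test_that("perturbations rescale targeted rates with bi attenuation", {
  m <- AllelicModel("parallel", kC = 0.0042, kT = 0.01)
  ## uniform halving of cis forward rates
  Q <- rateMatrix(m, Perturbation("cis", forwardFactor = 0.5,
                                  biAttenuation = 1))
  expect_equal(Q["T0.C00", "T0.C10"], 0.0021)
  expect_equal(Q["T1.C10", "T1.C11"], 0.0021)
  expect_equal(Q["T0.C00", "T1.C00"], 0.01)  # trans untouched
  ## attenuation interpolates transitions touching the bi class
  Qa <- rateMatrix(m, Perturbation("cis", forwardFactor = 0.5,
                                   biAttenuation = 0.4))
  expect_equal(Qa["T0.C00", "T0.C10"], 0.0021)        # none -> none: full
  expect_equal(Qa["T1.C10", "T1.C11"],                 # mono -> bi: 40%
               0.0042 + 0.4 * (0.0021 - 0.0042))
  ## trans reverse perturbation adds a reverse rate
  Qt <- rateMatrix(m, Perturbation("trans", reverseRate = 0.02,
                                   biAttenuation = 1))
  expect_equal(Qt["T1.C00", "T0.C00"], 0.02)
  expect_equal(Qt["T1.C11", "T0.C11"], 0.02)
  Qt2 <- rateMatrix(m, Perturbation("trans", reverseRate = 0.02,
                                    biAttenuation = 0.25))
  expect_equal(Qt2["T1.C11", "T0.C11"], 0.005)
  ## negative rates rejected
  expect_error(AllelicModel("parallel", kC = -1, kT = 0.01), "kC")
})

test_that("matrix-exponential fractions match the cis-only closed form", {
  for (kC in c(1e-4, 1e-3, 0.0042, 0.02, 0.1)) {
    tms <- c(0, 1, 10, 50, 100, 250)
    m <- AllelicModel("cis_only", kC = kC)
    pf <- populationFractions(m, tms)
    cf <- cisOnlyFractions(kC, tms)
    expect_lt(max(abs(as.matrix(pf[, 2:5]) - cf)), 1e-10)
  }
  ## frozen values at kC = 0.0042/hr, t = 100 h
  cf <- cisOnlyFractions(0.0042, 100)
  expect_equal(unname(cf[1, ]),
               c(0.4317105, 0.2253363, 0.2253363, 0.1176169),
               tolerance = 1e-6)
  expect_equal(unname(cisOnlyFractions(0.005, 0)[1, ]), c(1, 0, 0, 0))
  expect_equal(unname(cisOnlyFractions(0.005, 1e7)[1, ]), c(0, 0, 0, 1),
               tolerance = 1e-12)
})

test_that("fractions conserve probability and allele symmetry", {
  tms <- seq(0, 150, 25)
  cases <- list(
    AllelicModel("cis_only", kC = 0.0042),
    AllelicModel("sequential", kC = 0.0042, kT = 0.01),
    AllelicModel("parallel", kC = 0.004, kT = 0.012),
    AllelicModel("parallel", kC = 0.004, kT = 0.012, kCrev = 0.002,
                 kTrev = 0.003))
  for (m in cases) {
    pf <- populationFractions(m, tms)
    expect_lt(max(abs(rowSums(pf[, 2:5]) - 1)), 1e-9)
    expect_true(all(as.matrix(pf[, 2:5]) > -1e-12))
    expect_equal(pf$f_monoY, pf$f_monoR, tolerance = 1e-9)
  }
  ## at t = 0 the fractions equal the init's class marginal
  m <- AllelicModel("parallel", kC = 0.004, kT = 0.01,
                    init = c(T0.C00 = 0.5, T0.C10 = 0.3, T1.C00 = 0.2))
  pf0 <- populationFractions(m, 0)
  expect_equal(pf0$f_none, 1)
  expect_error(AllelicModel("parallel", kC = 0.004, kT = 0.01,
                            init = c(T1.C10 = 1)), "non-expressing")
})

test_that("early-time lag: bi is quadratic while mono is linear", {
  for (t in c(1, 0.1, 0.01)) {
    cf <- cisOnlyFractions(0.0042, t)
    ratio <- cf[1, "bi"] / (cf[1, "monoY"] + cf[1, "monoR"])
    expect_lt(ratio, 0.0042 * t)  # ratio ~ kC t / 2 -> 0 as t -> 0
  }
})

test_that("parallel model converges to cis-only as the trans step becomes fast", {
  tms <- seq(0, 100, 20)
  fast <- AllelicModel("parallel", kC = 0.0042, kT = 50)
  pf <- populationFractions(fast, tms)
  cf <- cisOnlyFractions(0.0042, tms)
  expect_lt(max(abs(as.matrix(pf[, 2:5]) - cf)), 2e-3)
})

test_that("sequential trajectories embed in the parallel state space", {
  ## a parallel chain started in the trans-off naive state whose cis
  ## rates are zeroed off trans mimics the sequential chain; compare the
  ## sequential model against the parallel chain with matched generator
  m_seq <- AllelicModel("sequential", kC = 0.005, kT = 0.008)
  Qp <- rateMatrix(AllelicModel("parallel", kC = 0.005, kT = 0.008))
  ## zero cis transitions out of trans-off states
  off <- grep("^T0", rownames(Qp), value = TRUE)
  for (s in off) for (s2 in setdiff(colnames(Qp), s)) {
    if (startsWith(s2, "T0")) Qp[s, s2] <- 0
  }
  diag(Qp) <- 0; diag(Qp) <- -rowSums(Qp)
  occ <- alleleKinetics:::occupancyAtTimes(Qp, c(T0.C00 = 1), c(50, 100))
  ssp <- stateSpace("parallel")
  pf_seq <- populationFractions(m_seq, c(50, 100))
  for (cl in c("monoY", "monoR", "bi")) {
    got <- rowSums(occ[, ssp$label[ssp$class == cl], drop = FALSE])
    expect_equal(unname(got), pf_seq[[paste0("f_", cl)]], tolerance = 1e-9)
  }
})

test_that("matrix solution agrees with an independent Gillespie oracle", {
  m <- AllelicModel("parallel", kC = 0.0042, kT = 0.012)
  Q <- rateMatrix(m)
  tms <- c(25, 60, 100)
  nCells <- 100000
  counts <- oracleGillespie(Q, 1L, tms, nCells, seed = 42)
  sim <- classFractionsFromCounts(counts, "parallel")
  ex <- as.matrix(populationFractions(m, tms)[, 2:5])
  se <- sqrt(ex * (1 - ex) / nCells)
  expect_true(all(abs(sim - ex) <= 3 * pmax(se, 1e-5)))
})

test_that("the ODE fallback reproduces the matrix exponential", {
  m <- AllelicModel("parallel", kC = 0.004, kT = 0.012, kTrev = 0.001)
  Q <- rateMatrix(m)
  p0 <- c(T0.C00 = 1)
  tms <- c(10, 50, 100)
  a <- alleleKinetics:::occupancyAtTimes(Q, p0, tms)
  b <- alleleKinetics:::occupancyODE(Q, p0, tms)
  expect_lt(max(abs(a - b)), 1e-7)
})

test_that("sorted non-expressing init is a proper distribution on none states", {
  for (kind in c("cis_only", "sequential", "parallel")) {
    w <- sortedNoneInit(kind, kC = 0.0042, kT = 0.01)
    expect_equal(sum(w), 1)
    ss <- stateSpace(kind)
    expect_true(all(names(w) %in% ss$label[ss$class == "none"]))
  }
  ## parallel: silently cis-activated states carry mass
  wp <- sortedNoneInit("parallel", kC = 0.0042, kT = 0.005)
  expect_gt(wp[["T0.C10"]], 0.05)
  expect_equal(wp[["T0.C10"]], wp[["T0.C01"]], tolerance = 1e-12)
})
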