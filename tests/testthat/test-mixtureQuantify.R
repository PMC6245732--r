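test_that("bivariate density has the right peak, symmetry and volume", {
  comp <- GaussianComponent(N = 1, muR = 0, muY = 0, sigmaR = 1, sigmaY = 1,
                            rho = 0)
  expect_equal(dbigauss(0, 0, comp), 1 / (2 * pi))
  expect_equal(dbigauss(1.3, -0.2, comp), dbigauss(-1.3, -0.2, comp))
  ## quadrature oracle: grid integral recovers N within 0.1%
  comp2 <- GaussianComponent(N = 540, muR = 3, muY = -2, sigmaR = 1.5,
                             sigmaY = 0.7, rho = 0.6)
  g <- seq(-12, 18, length.out = 601)
  h <- diff(g)[1]
  R <- rep(g, times = length(g)); Y <- rep(g, each = length(g))
  integral <- sum(dbigauss(R, Y, comp2)) * h^2
  expect_equal(integral, 540, tolerance = 1e-3)
  expect_error(GaussianComponent(1, 0, 0, 1, 1, rho = 1), "rho")
})

test_that("fraction error propagation follows the quadrature formula", {
  expect_equal(propagateFractionError(c(1, 2, 3, 4), c(0, 0, 0, 0)),
               c(0, 0, 0, 0))
  ## direct evaluation of the stated formula:
  ## 0.25 * sqrt((10/100)^2 + 100/400^2) = 0.0257694
  df <- propagateFractionError(c(100, 100, 100, 100), c(10, 0, 0, 0))
  expect_equal(df[1], 0.0257694, tolerance = 1e-6)
  expect_equal(df[2], 0.25 * sqrt(100 / 400^2), tolerance = 1e-9)
  ## scale invariance
  expect_equal(propagateFractionError(10 * c(100, 100, 100, 100),
                                      10 * c(10, 0, 0, 0)), df)
  ## zero-weight component: additive term only (no 0/0)
  df0 <- propagateFractionError(c(0, 100, 100, 100), c(5, 0, 0, 0))
  expect_equal(df0[1], 5 / 300)
  expect_error(propagateFractionError(c(0, 0, 0, 0), c(1, 1, 1, 1)), "positive")
})

test_that("anchor fit recovers known non-expressing parameters", {
  set.seed(7)
  n <- 5000
  cells <- data.frame(mch = rnorm(n, 100, 60), yfp = rnorm(n, 120, 50))
  a <- fitNegativeAnchor(cells)
  expect_lt(abs(a@muR - 100), 3 * 60 / sqrt(n) + 1)   # 3 SE + binning slack
  expect_lt(abs(a@muY - 120), 3 * 50 / sqrt(n) + 1)
  expect_lt(abs(a@sigmaR - 60) / 60, 0.05)
  expect_lt(abs(a@sigmaY - 50) / 50, 0.05)
  ## correlated data: rho within +/- 0.05 at n = 10000
  set.seed(8)
  z1 <- rnorm(10000); z2 <- rnorm(10000)
  cells2 <- data.frame(mch = 100 + 60 * z1,
                       yfp = 120 + 50 * (0.5 * z1 + sqrt(0.75) * z2))
  a2 <- fitNegativeAnchor(cells2)
  expect_lt(abs(a2@rho - 0.5), 0.05)
  ## guard rails
  expect_error(fitNegativeAnchor(cells[1:50, ]), "at least")
  dup <- data.frame(mch = rep(1, 500), yfp = rep(2, 500))
  expect_error(fitNegativeAnchor(dup), "degenerate")
})

test_that("constrained four-component fit recovers known weights", {
  fl <- fluorescenceModel()
  anchor <- local({
    set.seed(11)
    fitNegativeAnchor(sampleMixtureCells(c(none = 1), 5000, seed = 11))
  })
  for (w in list(c(none = 0.25, monoY = 0.25, monoR = 0.25, bi = 0.25),
                 c(none = 0.4, monoY = 0.4, monoR = 0.1, bi = 0.1))) {
    cells <- sampleMixtureCells(w, 20000, seed = 21 + round(100 * w[2]))
    fit <- fitTimeBin(cells, anchor)
    Ns <- vapply(components(fit), slot, numeric(1), "N")
    expect_true(all(abs(Ns / sum(Ns) - w) < 0.03))
  }
  ## single-population limit
  cells1 <- sampleMixtureCells(c(none = 1), 8000, seed = 31)
  fit1 <- fitTimeBin(cells1, anchor)
  Ns <- vapply(components(fit1), slot, numeric(1), "N")
  f <- Ns / sum(Ns)
  expect_gt(f[1], 0.98)
  expect_true(all(f[2:4] < 0.02))
  expect_error(fitTimeBin(cells1[0, ], anchor), "empty")
})

test_that("weight recovery holds across seeded mixtures spanning [0.05, 0.85]", {
  anchor <- local({
    set.seed(11)
    fitNegativeAnchor(sampleMixtureCells(c(none = 1), 5000, seed = 11))
  })
  errs <- numeric()
  set.seed(99)
  for (k in 1:20) {
    raw <- 0.05 + stats::runif(4)
    w <- raw / sum(raw)
    w <- pmin(pmax(w, 0.05), 0.85); w <- w / sum(w)
    names(w) <- c("none", "monoY", "monoR", "bi")
    cells <- sampleMixtureCells(w, 20000, seed = 1000 + k)
    fit <- fitTimeBin(cells, anchor)
    Ns <- vapply(components(fit), slot, numeric(1), "N")
    errs <- c(errs, abs(Ns / sum(Ns) - w))
  }
  expect_lt(mean(errs), 0.03)
})

test_that("fraction series freezes the anchor and respects time structure", {
  mv <- generateMovie(movieSpec(
    cloneConfig = cloneSimConfig(divisionTime = 20, nGenerations = 3,
                                 observeUntil = 60, nClones = 150),
    seed = 3))
  ser <- fractionsOverTime(mv$tracks, binWidthH = 10)
  expect_s4_class(ser, "FractionSeries")
  expect_lt(max(abs(rowSums(fractions(ser)) - 1)), 1e-9)
  ## anchor freezing: identical anchor reused across bins (stored once)
  expect_s4_class(ser@meta$anchor, "GaussianComponent")
  ## single-bin consistency with fitTimeBin
  cells <- mv$tracks[mv$tracks$time_h >= 30 & mv$tracks$time_h < 40, ]
  fit <- fitTimeBin(cells, ser@meta$anchor)
  Ns <- vapply(components(fit), slot, numeric(1), "N")
  row <- ser@data[ser@data$bin_center_h == 35, ]
  expect_equal(unname(as.numeric(row[paste0("f_", c("none", "monoY",
                                                    "monoR", "bi"))])),
               unname(Ns / sum(Ns)), tolerance = 1e-8)
  ## translation equivariance
  shifted <- mv$tracks
  shifted$time_h <- shifted$time_h + 100
  ser2 <- fractionsOverTime(shifted, binWidthH = 10, anchor = ser@meta$anchor)
  expect_equal(binCenters(ser2), binCenters(ser) + 100)
  expect_equal(fractions(ser2), fractions(ser), tolerance = 1e-12)
  ## monotone decline of the non-expressing fraction (irreversible model)
  fn <- fractions(ser)[, "none"]
  expect_true(all(diff(fn) < 0.05))
  ## missing column reported by name
  bad <- mv$tracks[, c("time_h", "yfp")]
  expect_error(fractionsOverTime(bad, 10), "mch")
})
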