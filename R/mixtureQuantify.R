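## Quantification of allelic-class population fractions from two-channel
## single-cell intensity tables, by the constrained two-step four-component
## bivariate Gaussian decomposition of the 2D intensity histogram:
## the non-expressing component's shape is anchored on an early time
## window of sorted non-expressing cells and frozen; per time bin, the
## four component weights (and the shapes of the three expressing
## components, within bounds) are fit by nonlinear least squares.

#' Construct a bivariate Gaussian mixture component
#'
#' @param N cell-count weight (volume under the component).
#' @param muR,muY channel means (mCherry, YFP intensity units).
#' @param sigmaR,sigmaY channel standard deviations (> 0).
#' @param rho channel correlation, |rho| < 1.
#' @return A [GaussianComponent-class].
#' @examples
#' GaussianComponent(100, muR = 0, muY = 0, sigmaR = 1, sigmaY = 1)
#' @export
GaussianComponent <- function(N = 1, muR, muY, sigmaR, sigmaY, rho = 0) {
  new("GaussianComponent", N = N, muR = muR, muY = muY,
      sigmaR = sigmaR, sigmaY = sigmaY, rho = rho)
}

#' Scaled bivariate normal density
#'
#' Density of one mixture component at (r, y): `N` times the bivariate
#' normal pdf with the component's means, standard deviations and
#' correlation. Integrates to `N` over the plane.
#'
#' @param r,y numeric vectors of mCherry / YFP intensities (recycled).
#' @param component a [GaussianComponent-class].
#' @return numeric vector of density values.
#' @examples
#' comp <- GaussianComponent(1, 0, 0, 1, 1, 0)
#' dbigauss(0, 0, comp)  # 1 / (2 * pi)
#' @export
dbigauss <- function(r, y, component) {
  stopifnot(is(component, "GaussianComponent"))
  validObject(component)
  zr <- (r - component@muR) / component@sigmaR
  zy <- (y - component@muY) / component@sigmaY
  rho <- component@rho
  q <- (zr^2 + zy^2 - 2 * rho * zr * zy) / (1 - rho^2)
  component@N / (2 * pi * component@sigmaR * component@sigmaY *
                   sqrt(1 - rho^2)) * exp(-q / 2)
}

## Intensity transforms applied before histogramming. The identity is the
## default (the class-conditional noise model is Gaussian on the linear
## scale); asinh/log10 are available for heavier-tailed data and are
## recorded in fit metadata.
applyTransform <- function(x, transform = c("linear", "asinh", "log10"),
                           cofactor = 150) {
  transform <- match.arg(transform)
  switch(transform,
         linear = x,
         asinh = asinh(x / cofactor),
         log10 = log10(pmax(x, 0) + cofactor))
}

## 2D histogram of (mch, yfp) on a fixed nbins x nbins grid.
## Returns bin centers, counts (matrix r x y) and the bin area.
hist2d <- function(mch, yfp, nbins = 64, rangeR = NULL, rangeY = NULL) {
  pad <- function(rng) rng + c(-1, 1) * max(diff(rng), 1e-8) * 0.02
  rangeR <- rangeR %||% pad(range(mch))
  rangeY <- rangeY %||% pad(range(yfp))
  brR <- seq(rangeR[1], rangeR[2], length.out = nbins + 1)
  brY <- seq(rangeY[1], rangeY[2], length.out = nbins + 1)
  iR <- findInterval(mch, brR, rightmost.closed = TRUE, all.inside = TRUE)
  iY <- findInterval(yfp, brY, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0, nbins, nbins)
  tab <- table(factor(iR, levels = seq_len(nbins)),
               factor(iY, levels = seq_len(nbins)))
  counts[] <- as.numeric(tab)
  list(centerR = (brR[-1] + brR[-(nbins + 1)]) / 2,
       centerY = (brY[-1] + brY[-(nbins + 1)]) / 2,
       counts = counts,
       binArea = diff(brR)[1] * diff(brY)[1])
}

## Plain-math scaled bivariate normal density (no S4 construction; this
## sits inside the least-squares residual loop).
biGaussRaw <- function(r, y, N, muR, muY, sR, sY, rho) {
  zr <- (r - muR) / sR
  zy <- (y - muY) / sY
  q <- (zr^2 + zy^2 - 2 * rho * zr * zy) / (1 - rho^2)
  N / (2 * pi * sR * sY * sqrt(1 - rho^2)) * exp(-q / 2)
}

## Predicted histogram counts for a list of components (density at bin
## center times bin area). grid from hist2d().
predictedCounts <- function(componentList, grid) {
  R <- rep(grid$centerR, times = length(grid$centerY))
  Y <- rep(grid$centerY, each = length(grid$centerR))
  acc <- 0
  for (comp in componentList)
    acc <- acc + biGaussRaw(R, Y, comp@N, comp@muR, comp@muY,
                            comp@sigmaR, comp@sigmaY, comp@rho)
  matrix(acc * grid$binArea, length(grid$centerR), length(grid$centerY))
}

#' Fit the non-expressing anchor component
#'
#' Step one of the two-step quantification: a single bivariate Gaussian is
#' fit (least squares on the 2D histogram) to cells from an early time
#' window in which both alleles are known inactive. Its shape parameters
#' (means, SDs, correlation) are then frozen for every subsequent time-bin
#' fit.
#'
#' @param cells data.frame with numeric columns `yfp` and `mch`.
#' @param minCells minimum number of cells required (default 100).
#' @param nbins histogram bins per axis (default 64).
#' @param transform,cofactor intensity transform applied before
#'   histogramming (see Details in [fitTimeBin()]).
#' @return A [GaussianComponent-class] whose `N` equals the fitted volume.
#' @export
fitNegativeAnchor <- function(cells, minCells = 100, nbins = 64,
                              transform = "linear", cofactor = 150) {
  stopifnot(all(c("yfp", "mch") %in% names(cells)))
  if (nrow(cells) < minCells)
    stop(sprintf("anchor fit needs at least %d cells, got %d",
                 minCells, nrow(cells)))
  r <- applyTransform(cells$mch, transform, cofactor)
  y <- applyTransform(cells$yfp, transform, cofactor)
  if (stats::sd(r) < 1e-12 || stats::sd(y) < 1e-12)
    stop("degenerate anchor data: zero variance in at least one channel")
  grid <- hist2d(r, y, nbins)
  obs <- as.numeric(grid$counts)
  start <- c(N = length(r), muR = mean(r), muY = mean(y),
             sigmaR = stats::sd(r), sigmaY = stats::sd(y),
             rho = stats::cor(r, y))
  lower <- c(0, min(r), min(y), stats::sd(r) / 20, stats::sd(y) / 20, -0.95)
  upper <- c(5 * length(r), max(r), max(y), 5 * stats::sd(r), 5 * stats::sd(y),
             0.95)
  Rv <- rep(grid$centerR, times = length(grid$centerY))
  Yv <- rep(grid$centerY, each = length(grid$centerR))
  resid <- function(p)
    biGaussRaw(Rv, Yv, max(p[1], 0), p[2], p[3], p[4], p[5], p[6]) *
      grid$binArea - obs
  fit <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = resid,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- fit$par
  GaussianComponent(p[[1]], p[[2]], p[[3]], p[[4]], p[[5]], p[[6]])
}

## Default parameter boxes for the three expressing components, derived
## from the anchor: channel thresholds at anchor mean + 3 SD split the
## plane into quadrants; expressing means are confined to their quadrant
## and SDs to [0.3, 3] times the anchor SDs.
defaultComponentBounds <- function(anchor, r, y) {
  thrR <- anchor@muR + 3 * anchor@sigmaR
  thrY <- anchor@muY + 3 * anchor@sigmaY
  ## means stay inside the observed range: a component whose mass leaves
  ## the histogram window has an unidentified weight
  hiR <- max(max(r), thrR + anchor@sigmaR)
  hiY <- max(max(y), thrY + anchor@sigmaY)
  loR <- min(min(r), anchor@muR - 5 * anchor@sigmaR)
  loY <- min(min(y), anchor@muY - 5 * anchor@sigmaY)
  sR <- anchor@sigmaR * c(0.3, 3)
  sY <- anchor@sigmaY * c(0.3, 3)
  list(thrR = thrR, thrY = thrY,
       monoY = list(muR = c(loR, thrR), muY = c(thrY, hiY),
                    sigmaR = sR, sigmaY = sY, rho = c(-0.95, 0.95)),
       monoR = list(muR = c(thrR, hiR), muY = c(loY, thrY),
                    sigmaR = sR, sigmaY = sY, rho = c(-0.95, 0.95)),
       bi = list(muR = c(thrR, hiR), muY = c(thrY, hiY),
                 sigmaR = sR, sigmaY = sY, rho = c(-0.95, 0.95)))
}

#' Constrained four-component mixture fit for one time bin
#'
#' Step two of the quantification: the 2D intensity histogram of one time
#' bin is fit by least squares to the sum of four bivariate Gaussians. The
#' non-expressing component's shape is frozen to the `anchor`; its weight
#' and all parameters of the three expressing components vary within
#' `bounds` (default: quadrant boxes from [defaultComponentBounds()]).
#' Weight uncertainties come from the least-squares parameter covariance
#' (Jacobian-based, scaled by residual variance).
#'
#' @param cells data.frame with numeric columns `yfp` and `mch`
#'   (untransformed intensities).
#' @param anchor [GaussianComponent-class] from [fitNegativeAnchor()],
#'   fit under the same `transform`.
#' @param bounds optional list as returned by [defaultComponentBounds()].
#' @param nbins histogram bins per axis (default 64).
#' @param transform,cofactor intensity transform; the default `"linear"`
#'   fits on the raw intensity scale.
#' @return A [MixtureFit-class]. Non-convergence and collapsed components
#'   are reported in `@flags`, never silently dropped.
#' @export
fitTimeBin <- function(cells, anchor, bounds = NULL, nbins = 64,
                       transform = "linear", cofactor = 150) {
  stopifnot(is(anchor, "GaussianComponent"),
            all(c("yfp", "mch") %in% names(cells)))
  if (nrow(cells) == 0) stop("empty time bin: no cells to fit")
  r <- applyTransform(cells$mch, transform, cofactor)
  y <- applyTransform(cells$yfp, transform, cofactor)
  n <- length(r)
  bounds <- bounds %||% defaultComponentBounds(anchor, r, y)
  ## histogram range must cover the anchor component even if the bin has
  ## drifted away from it
  pad <- function(v, lo, hi) range(c(v, lo, hi))
  grid <- hist2d(r, y, nbins,
                 rangeR = pad(r, anchor@muR - 4 * anchor@sigmaR,
                              anchor@muR + 4 * anchor@sigmaR),
                 rangeY = pad(y, anchor@muY - 4 * anchor@sigmaY,
                              anchor@muY + 4 * anchor@sigmaY))
  obs <- as.numeric(grid$counts)

  ## quadrant occupancy provides starting values
  quad <- ifelse(r >= bounds$thrR & y >= bounds$thrY, "bi",
          ifelse(y >= bounds$thrY, "monoY",
          ifelse(r >= bounds$thrR, "monoR", "none")))
  qn <- table(factor(quad, levels = OBSERVED_CLASSES))
  startComp <- function(cl) {
    b <- bounds[[cl]]
    sel <- quad == cl
    muR <- if (sum(sel) >= 5) stats::median(r[sel]) else mean(b$muR)
    muY <- if (sum(sel) >= 5) stats::median(y[sel]) else mean(b$muY)
    c(N = as.numeric(qn[cl]) + 0.5,
      muR = min(max(muR, b$muR[1]), b$muR[2]),
      muY = min(max(muY, b$muY[1]), b$muY[2]),
      sigmaR = anchor@sigmaR, sigmaY = anchor@sigmaY, rho = 0)
  }
  ## parameter vector: N_none, then (N, muR, muY, sigmaR, sigmaY, rho)
  ## for monoY, monoR, bi
  start <- c(Nnone = as.numeric(qn["none"]) + 0.5,
             unlist(lapply(EXPRESSING_CLASSES, startComp)))
  lower <- c(0, unlist(lapply(EXPRESSING_CLASSES, function(cl) {
    b <- bounds[[cl]]
    c(0, b$muR[1], b$muY[1], b$sigmaR[1], b$sigmaY[1], b$rho[1])
  })))
  upper <- c(2 * n, unlist(lapply(EXPRESSING_CLASSES, function(cl) {
    b <- bounds[[cl]]
    c(2 * n, b$muR[2], b$muY[2], b$sigmaR[2], b$sigmaY[2], b$rho[2])
  })))

  buildComponents <- function(p) {
    ## clamp weights: finite-difference probes may step just below 0
    comps <- list(none = GaussianComponent(max(p[1], 0), anchor@muR,
                                           anchor@muY, anchor@sigmaR,
                                           anchor@sigmaY, anchor@rho))
    for (k in seq_along(EXPRESSING_CLASSES)) {
      q <- p[(2 + (k - 1) * 6):(1 + k * 6)]
      comps[[EXPRESSING_CLASSES[k]]] <-
        GaussianComponent(max(q[1], 0), q[2], q[3], q[4], q[5], q[6])
    }
    comps
  }
  Rv <- rep(grid$centerR, times = length(grid$centerY))
  Yv <- rep(grid$centerY, each = length(grid$centerR))
  resid <- function(p) {
    acc <- biGaussRaw(Rv, Yv, max(p[1], 0), anchor@muR, anchor@muY,
                      anchor@sigmaR, anchor@sigmaY, anchor@rho)
    for (k in 1:3) {
      q <- p[(2 + (k - 1) * 6):(1 + k * 6)]
      acc <- acc + biGaussRaw(Rv, Yv, max(q[1], 0), q[2], q[3], q[4],
                              q[5], q[6])
    }
    acc * grid$binArea - obs
  }
  fit <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = resid,
                            control = minpack.lm::nls.lm.control(maxiter = 300))
  comps <- buildComponents(fit$par)
  flags <- character()
  if (fit$info %in% c(0, 5, 9)) flags <- c(flags, "optimizer_not_converged")

  ## weight uncertainties from the LS covariance at the optimum
  dN <- lsWeightErrors(fit$par, resid, nIdx = c(1, 2, 8, 14))
  ## collapsed-component diagnostic
  mus <- vapply(comps, function(cc) c(cc@muR, cc@muY), numeric(2))
  sds <- vapply(comps, function(cc) c(cc@sigmaR, cc@sigmaY), numeric(2))
  for (a in 2:3) for (b in (a + 1):4) {
    d <- sqrt(sum((mus[, a] - mus[, b])^2))
    pooled <- sqrt(mean(c(sds[, a]^2, sds[, b]^2)))
    if (d < 0.5 * pooled)
      flags <- c(flags, sprintf("collapsed_components_%s_%s",
                                OBSERVED_CLASSES[a], OBSERVED_CLASSES[b]))
  }
  new("MixtureFit", components = comps, dN = dN,
      residual = sum(fit$fvec^2),
      converged = !("optimizer_not_converged" %in% flags),
      flags = flags, nCells = n,
      meta = list(nbins = nbins, transform = transform, cofactor = cofactor,
                  bounds = bounds, optimizerInfo = fit$info))
}

## Standard errors of the component weights from a numeric Jacobian at the
## optimum: cov = s^2 (J'J)^-1 with s^2 = RSS / (nres - npar). A rank-
## deficient J'J (components pinned at bounds or empty) is inverted by
## pseudo-inverse.
lsWeightErrors <- function(par, residFn, nIdx) {
  f0 <- residFn(par)
  npar <- length(par)
  J <- matrix(0, length(f0), npar)
  for (j in seq_len(npar)) {
    h <- max(1e-6, abs(par[j]) * 1e-6)
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- pm[j] - h
    J[, j] <- (residFn(pp) - residFn(pm)) / (2 * h)
  }
  s2 <- sum(f0^2) / max(length(f0) - npar, 1)
  JtJ <- crossprod(J)
  covm <- tryCatch(solve(JtJ), error = function(e) {
    sv <- svd(JtJ)
    pos <- sv$d > max(sv$d) * 1e-10
    sv$v[, pos, drop = FALSE] %*% diag(1 / sv$d[pos], sum(pos)) %*%
      t(sv$u[, pos, drop = FALSE])
  })
  se <- sqrt(pmax(diag(covm) * s2, 0))
  se[nIdx]
}

#' Quadrature propagation of weight errors to fraction errors
#'
#' Propagates least-squares weight uncertainties to the normalized
#' fractions `f_i = N_i / sum(N)`:
#' `df_i = sqrt( (dN_i / S)^2 + f_i^2 * sum(dN^2) / S^2 )` with
#' `S = sum(N)` — algebraically `f_i * sqrt((dN_i/N_i)^2 + sum(dN^2)/S^2)`,
#' written so that `N_i = 0` contributes through the first (additive) term
#' only instead of 0/0.
#'
#' @param N four component weights (sum > 0).
#' @param dN four weight uncertainties (>= 0).
#' @return four fraction uncertainties.
#' @examples
#' propagateFractionError(c(100, 100, 100, 100), c(10, 0, 0, 0))
#' @export
propagateFractionError <- function(N, dN) {
  stopifnot(length(N) == 4, length(dN) == 4, all(dN >= 0))
  S <- sum(N)
  if (S <= 0) stop("total weight must be positive")
  f <- N / S
  sqrt((dN / S)^2 + f^2 * sum(dN^2) / S^2)
}

#' Time-resolved class fractions from a tracks table
#'
#' Bins a single-cell intensity table by time and runs the constrained
#' four-component fit ([fitTimeBin()]) in every bin, producing the
#' observed fraction series `f_i(t) = N_i(t) / sum_j N_j(t)` with
#' uncertainties from [propagateFractionError()].
#'
#' @param tracks data.frame with numeric columns `time_h`, `yfp`, `mch`
#'   (clone/cell/parent id columns are ignored here).
#' @param binWidthH time bin width in hours (default 5).
#' @param anchor optional [GaussianComponent-class]; when `NULL` it is fit
#'   from cells inside `anchorWindow`.
#' @param anchorWindow time window (hours) of known non-expressing cells
#'   used for the anchor fit (default 0-10 h).
#' @param minCells bins with fewer cells are flagged (default 30); empty
#'   bins are dropped.
#' @param minAnchorCells passed to [fitNegativeAnchor()].
#' @param nbins,transform,cofactor histogram settings shared by all fits.
#' @return A [FractionSeries-class]; per-bin flags and the frozen anchor
#'   are kept in `@meta`.
#' @export
fractionsOverTime <- function(tracks, binWidthH = 5, anchor = NULL,
                              anchorWindow = c(0, 10), minCells = 30,
                              minAnchorCells = 100, nbins = 64,
                              transform = "linear", cofactor = 150) {
  need <- c("time_h", "yfp", "mch")
  miss <- setdiff(need, names(tracks))
  if (length(miss))
    stop("tracks table is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(tracks) == 0) stop("empty tracks table")
  stopifnot(binWidthH > 0)
  if (is.null(anchor)) {
    early <- tracks[tracks$time_h >= anchorWindow[1] &
                      tracks$time_h < anchorWindow[2], ]
    anchor <- fitNegativeAnchor(early, minCells = minAnchorCells,
                                nbins = nbins, transform = transform,
                                cofactor = cofactor)
  }
  t0 <- floor(min(tracks$time_h) / binWidthH) * binWidthH
  binIdx <- floor((tracks$time_h - t0) / binWidthH)
  rows <- list(); fits <- list()
  for (b in sort(unique(binIdx))) {
    cells <- tracks[binIdx == b, ]
    fit <- fitTimeBin(cells, anchor, nbins = nbins, transform = transform,
                      cofactor = cofactor)
    Ns <- vapply(fit@components, slot, numeric(1), "N")
    f <- Ns / sum(Ns)
    df <- propagateFractionError(Ns, fit@dN)
    rows[[length(rows) + 1L]] <- data.frame(
      bin_center_h = t0 + (b + 0.5) * binWidthH,
      n_cells = nrow(cells),
      f_none = f[1], f_monoY = f[2], f_monoR = f[3], f_bi = f[4],
      df_none = df[1], df_monoY = df[2], df_monoR = df[3], df_bi = df[4],
      flagged = nrow(cells) < minCells || length(fit@flags) > 0)
    fits[[length(fits) + 1L]] <- fit
  }
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  new("FractionSeries", data = d,
      meta = list(anchor = anchor, binWidthH = binWidthH, nbins = nbins,
                  transform = transform, cofactor = cofactor,
                  minCells = minCells,
                  binFlags = lapply(fits, slot, "flags")))
}
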