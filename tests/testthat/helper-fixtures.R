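## Shared fixtures and independent oracles, built in code.

DELAY0 <- stats::setNames(c(0, 0, 0, 0), c("none", "monoY", "monoR", "bi"))

## FractionSeries straight from a fraction matrix (columns none, monoY,
## monoR, bi), with constant uncertainties.
seriesFromFractions <- function(times, fr, df = 0.01, n = 200) {
  d <- data.frame(bin_center_h = times, n_cells = n,
                  f_none = fr[, 1], f_monoY = fr[, 2],
                  f_monoR = fr[, 3], f_bi = fr[, 4],
                  df_none = df, df_monoY = df, df_monoR = df, df_bi = df,
                  flagged = FALSE)
  new("FractionSeries", data = d, meta = list())
}

## Binomial-noise series: per bin, draw n cells from the model's exact
## class distribution and use observed proportions with binomial SEs.
noisySeriesFromModel <- function(model, times, nPerBin = 200, seed = 1) {
  pf <- populationFractions(model, times)
  fr <- as.matrix(pf[, c("f_none", "f_monoY", "f_monoR", "f_bi")])
  set.seed(seed)
  obs <- t(apply(fr, 1, function(p) stats::rmultinom(1, nPerBin, p)[, 1]))
  f <- obs / nPerBin
  ## binomial SE from the generating fractions, floored at one cell
  pfloor <- pmax(fr, 1 / nPerBin)
  df <- sqrt(pfloor * (1 - pfloor) / nPerBin)
  d <- data.frame(bin_center_h = times, n_cells = nPerBin,
                  f_none = f[, 1], f_monoY = f[, 2], f_monoR = f[, 3],
                  f_bi = f[, 4],
                  df_none = df[, 1], df_monoY = df[, 2], df_monoR = df[, 3],
                  df_bi = df[, 4], flagged = FALSE)
  new("FractionSeries", data = d, meta = list())
}

## Independent Gillespie oracle for the hidden-state chain: simulates
## nCells independent cells under rate matrix Q from state `start` and
## returns hidden-state counts at the requested times. Deliberately
## separate from the package's simulators.
oracleGillespie <- function(Q, start, times, nCells, seed = 1) {
  set.seed(seed)
  nS <- nrow(Q)
  counts <- matrix(0L, length(times), nS,
                   dimnames = list(NULL, rownames(Q)))
  horizon <- max(times)
  for (i in seq_len(nCells)) {
    s <- start; t <- 0
    jt <- c(0); js <- c(s)
    repeat {
      lam <- -Q[s, s]
      if (lam <= 0) break
      t <- t + stats::rexp(1, lam)
      if (t >= horizon) break
      p <- Q[s, ]; p[s] <- 0
      s <- sample.int(nS, 1, prob = p)
      jt <- c(jt, t); js <- c(js, s)
    }
    idx <- js[findInterval(times, jt)]
    counts[cbind(seq_along(times), idx)] <-
      counts[cbind(seq_along(times), idx)] + 1L
  }
  counts
}

## Class fractions of a hidden-state count matrix.
classFractionsFromCounts <- function(counts, kind) {
  ss <- stateSpace(kind)
  out <- sapply(c("none", "monoY", "monoR", "bi"), function(cl)
    rowSums(counts[, ss$label[ss$class == cl], drop = FALSE]))
  out / rowSums(counts)
}

## Small sampled mixture of the default fluorescence components.
sampleMixtureCells <- function(weights, n, seed = 1,
                               fl = fluorescenceModel()) {
  set.seed(seed)
  cls <- sample(names(weights), n, replace = TRUE, prob = weights)
  out <- data.frame(yfp = numeric(n), mch = numeric(n), true_class = cls)
  for (cl in unique(cls)) {
    comp <- fl$components[[cl]]
    idx <- which(cls == cl)
    z1 <- stats::rnorm(length(idx)); z2 <- stats::rnorm(length(idx))
    out$mch[idx] <- comp@muR + comp@sigmaR * z1
    out$yfp[idx] <- comp@muY + comp@sigmaY *
      (comp@rho * z1 + sqrt(1 - comp@rho^2) * z2)
  }
  out
}
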