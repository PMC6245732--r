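## Synthetic timelapse-track and endpoint-snapshot generators with the
## statistical structure the analysis assumes: per-allele stochastic
## first-order activation (exact exponential waiting times inside
## generations, so onset times are continuous), an optional shared trans
## switch, synchronous division, fluorescent-reporter maturation as an
## exponential approach to the mature intensity, and class-conditional
## bivariate Gaussian intensity noise. Every run is seeded and
## reproducible byte-for-byte.

#' Class-conditional fluorescence model
#'
#' Intensity distributions per observed class, plus the reporter
#' maturation time constant. Intensities are arbitrary units with the
#' non-expressing component near the origin and expressing components
#' separated from it by ~10 anchor SDs. After a channel's expression
#' onset, its mean rises from the non-expressing level toward the mature
#' class level as `1 - exp(-(t - t_on) / maturationTau)`; the resulting
#' population-level detection delay (the quantity [estimateDelays()]
#' recovers) is documented by `detectLagTarget`.
#'
#' @param components named list of four [GaussianComponent-class]s
#'   (`none`, `monoY`, `monoR`, `bi`); defaults as described.
#' @param maturationTau maturation time constant in hours (default 15).
#'   With the default intensity geometry a cell crosses the detection
#'   threshold a few hours after onset, and the population-level delay
#'   recovered by [estimateDelays()] lands near `detectLagTarget` for the
#'   first-detected mono-allelic class (later for the rarer classes,
#'   whose fractions stay near the detection floor longer).
#' @param detectLagTarget nominal population-level detection delay in
#'   hours the defaults are tuned to induce (15-20 h band; default 16).
#' @return list of class `fluorescenceModel`.
#' @export
fluorescenceModel <- function(components = NULL, maturationTau = 15,
                              detectLagTarget = 16) {
  stopifnot(maturationTau >= 0)
  if (is.null(components))
    components <- list(
      none  = GaussianComponent(1, muR = 100, muY = 100,
                                sigmaR = 60, sigmaY = 60, rho = 0),
      monoY = GaussianComponent(1, muR = 120, muY = 700,
                                sigmaR = 70, sigmaY = 150, rho = 0),
      monoR = GaussianComponent(1, muR = 700, muY = 120,
                                sigmaR = 150, sigmaY = 70, rho = 0),
      bi    = GaussianComponent(1, muR = 700, muY = 700,
                                sigmaR = 150, sigmaY = 150, rho = 0))
  stopifnot(identical(sort(names(components)), sort(OBSERVED_CLASSES)))
  structure(list(components = components[OBSERVED_CLASSES],
                 maturationTau = maturationTau,
                 detectLagTarget = detectLagTarget),
            class = "fluorescenceModel")
}

#' Per-class detection delays implied by a fluorescence model
#'
#' The physical detectability lag of the generator: after onset, a
#' channel's mean rises toward the mature level as
#' `1 - exp(-t/maturationTau)`, and a cell becomes distinguishable from
#' the non-expressing population once the mean crosses the quadrant
#' threshold (non-expressing mean + `zSigma` SD — the same threshold
#' geometry [fitTimeBin()] uses). Half a time bin is added for binning
#' smear. The bi-allelic delay is the larger of the two channel delays.
#' Use these as the `delays` argument of [fitModel()] when the data come
#' from [generateMovie()] and the ground-truth optics are known;
#' [estimateDelays()] is the data-driven counterpart for real data.
#'
#' @param fluorescence a [fluorescenceModel()].
#' @param binWidthH time-bin width of the downstream quantification
#'   (default 5).
#' @param zSigma detection threshold in anchor SDs (default 3).
#' @return named numeric delays (hours) over the four classes.
#' @export
detectionDelay <- function(fluorescence, binWidthH = 5, zSigma = 3) {
  stopifnot(inherits(fluorescence, "fluorescenceModel"))
  comps <- fluorescence$components
  none <- comps$none
  lag <- function(muNone, sigmaNone, muExpr) {
    frac <- zSigma * sigmaNone / max(muExpr - muNone, 1e-12)
    if (frac >= 1) return(Inf)   # expressing level below threshold
    -fluorescence$maturationTau * log(1 - frac)
  }
  tauY <- lag(none@muY, none@sigmaY, comps$monoY@muY)
  tauR <- lag(none@muR, none@sigmaR, comps$monoR@muR)
  stats::setNames(c(0, tauY, tauR, max(tauY, tauR)) + c(0, rep(binWidthH / 2, 3)),
                  OBSERVED_CLASSES)
}

#' Specification of a synthetic timelapse movie
#'
#' @param model an [AllelicModel-class] (default: parallel model at
#'   kC = 0.004/hr, kT = 0.012/hr).
#' @param cloneConfig a [cloneSimConfig()]; the movie default follows the
#'   imaging experiment's scale: ~200 starting cells followed for 105 h
#'   with ~20 h divisions.
#' @param frameIntervalH time between frames in hours (default 1).
#' @param fluorescence a [fluorescenceModel()].
#' @param seed RNG seed.
#' @return list of class `movieSpec`.
#' @export
movieSpec <- function(model = AllelicModel("parallel", kC = 0.004, kT = 0.012),
                      cloneConfig = cloneSimConfig(divisionTime = 20,
                                                   nGenerations = 6,
                                                   observeUntil = 105,
                                                   nClones = 200),
                      frameIntervalH = 1,
                      fluorescence = fluorescenceModel(),
                      seed = 1) {
  stopifnot(frameIntervalH > 0, is(model, "AllelicModel"),
            inherits(cloneConfig, "cloneSimConfig"),
            inherits(fluorescence, "fluorescenceModel"))
  structure(list(model = model, cloneConfig = cloneConfig,
                 frameIntervalH = frameIntervalH,
                 fluorescence = fluorescence, seed = seed),
            class = "movieSpec")
}

## Exact continuous-time trajectory of one cell over [t0, t1): jump times
## and states, starting in state s0 (index into the state space).
gillespiePath <- function(Q, s0, t0, t1) {
  times <- t0; states <- s0
  s <- s0; t <- t0
  repeat {
    lam <- -Q[s, s]
    if (lam <= 0) break
    w <- stats::rexp(1, lam)
    if (t + w >= t1) break
    t <- t + w
    probs <- Q[s, ]; probs[s] <- 0
    s <- sample.int(ncol(Q), 1L, prob = probs)
    times <- c(times, t); states <- c(states, s)
  }
  list(times = times, states = states)
}

#' Generate a synthetic timelapse tracks table
#'
#' Simulates clonal lineages with continuous-time state switching inside
#' generations (the per-generation Markov chain of [simulateClone()] is
#' the coarse-grained view of the same process), then emits per-frame
#' two-channel intensities: after a channel's expression onset its mean
#' intensity (and SD) interpolates from the non-expressing component
#' toward the cell's current class component as
#' `1 - exp(-(t - t_on)/maturationTau)`, with bivariate Gaussian noise.
#' Onset times are inherited through division.
#'
#' @param spec a [movieSpec()].
#' @return list with `tracks` (data.frame: `clone_id`, `cell_id`,
#'   `parent_id`, `time_h`, `yfp`, `mch`) and `truth` (data.frame:
#'   per-frame hidden `state`/`class` per cell plus per-channel onset
#'   times `yfp_on_h`, `mch_on_h`).
#' @export
generateMovie <- function(spec) {
  stopifnot(inherits(spec, "movieSpec"))
  model <- spec$model
  cfg <- spec$cloneConfig
  fl <- spec$fluorescence
  ss <- stateSpace(model@kind)
  Q <- rateMatrix(model)
  horizon <- cfg$observeUntil
  G <- nObservedGenerations(cfg)
  exprY <- ss$trans & ss$cisY
  exprR <- ss$trans & ss$cisR
  comps <- fl$components
  tau <- fl$maturationTau
  frameTimes <- seq(0, horizon, by = spec$frameIntervalH)

  withSeed(spec$seed, {
    p0 <- numeric(nrow(ss)); names(p0) <- ss$label
    p0[names(model@init)] <- model@init
    trackRows <- list(); truthRows <- list()
    for (cl in seq_len(cfg$nClones)) {
      ## stack of cells: state at birth, birth time, inherited onsets
      queue <- list(list(id = "1", parent = NA_character_, gen = 0L,
                         s = sample.int(nrow(ss), 1L, prob = p0),
                         tb = 0, onY = NA_real_, onR = NA_real_))
      while (length(queue)) {
        cell <- queue[[1L]]; queue <- queue[-1L]
        te <- min(cell$tb + cfg$divisionTime, horizon)
        path <- gillespiePath(Q, cell$s, cell$tb, te)
        ## channel onsets: first time the channel's expression flag is on
        onY <- cell$onY; onR <- cell$onR
        for (k in seq_along(path$times)) {
          if (is.na(onY) && exprY[path$states[k]]) onY <- path$times[k]
          if (is.na(onR) && exprR[path$states[k]]) onR <- path$times[k]
        }
        ft <- frameTimes[frameTimes >= cell$tb &
                           (frameTimes < te | (te == horizon & frameTimes == te))]
        if (length(ft)) {
          si <- path$states[findInterval(ft, path$times)]
          cls <- ss$class[si]
          mY <- ifelse(!is.na(onY) & ft >= onY,
                       1 - exp(-(ft - onY) / max(tau, 1e-12)), 0)
          if (tau == 0) mY <- as.numeric(!is.na(onY) & ft >= onY)
          mR <- ifelse(!is.na(onR) & ft >= onR,
                       1 - exp(-(ft - onR) / max(tau, 1e-12)), 0)
          if (tau == 0) mR <- as.numeric(!is.na(onR) & ft >= onR)
          ## per-frame target component = current class's component
          tgt <- comps[cls]
          none <- comps$none
          muY <- none@muY + mY * (vapply(tgt, slot, numeric(1), "muY") - none@muY)
          muR <- none@muR + mR * (vapply(tgt, slot, numeric(1), "muR") - none@muR)
          sdY <- none@sigmaY + mY * (vapply(tgt, slot, numeric(1), "sigmaY") - none@sigmaY)
          sdR <- none@sigmaR + mR * (vapply(tgt, slot, numeric(1), "sigmaR") - none@sigmaR)
          yfp <- stats::rnorm(length(ft), muY, sdY)
          mch <- stats::rnorm(length(ft), muR, sdR)
          trackRows[[length(trackRows) + 1L]] <- data.frame(
            clone_id = cl, cell_id = cell$id, parent_id = cell$parent,
            time_h = ft, yfp = yfp, mch = mch)
          truthRows[[length(truthRows) + 1L]] <- data.frame(
            clone_id = cl, cell_id = cell$id, time_h = ft,
            state = ss$label[si], class = cls,
            yfp_on_h = onY, mch_on_h = onR)
        }
        if (te < horizon && cell$gen < G) {
          sEnd <- path$states[length(path$states)]
          for (dgt in 0:1)
            queue[[length(queue) + 1L]] <-
              list(id = paste0(cell$id, dgt), parent = cell$id,
                   gen = cell$gen + 1L, s = sEnd, tb = te,
                   onY = onY, onR = onR)
        }
      }
    }
    tracks <- do.call(rbind, trackRows)
    truth <- do.call(rbind, truthRows)
    rownames(tracks) <- rownames(truth) <- NULL
    list(tracks = tracks, truth = truth)
  })
}

#' Generate a synthetic endpoint snapshot table
#'
#' Draws terminal observed-class labels from the exact class distribution
#' of the (possibly perturbed) model at the horizon, then intensities
#' from the mature class components (maturation is ignored at endpoint,
#' as in flow-style measurements of multi-day cultures).
#'
#' @param model an [AllelicModel-class].
#' @param start start-population label or distribution (see
#'   [startPopulation()]).
#' @param horizonH culture time in hours (default 96).
#' @param nCells number of cells to draw.
#' @param fluorescence a [fluorescenceModel()].
#' @param perturbation optional [Perturbation-class].
#' @param seed RNG seed.
#' @return data.frame with columns `yfp`, `mch`, `true_class`.
#' @export
generateSnapshot <- function(model, start = "none", horizonH = 96,
                             nCells = 10000,
                             fluorescence = fluorescenceModel(),
                             perturbation = NULL, seed = 1) {
  stopifnot(nCells >= 1, inherits(fluorescence, "fluorescenceModel"))
  ss <- stateSpace(model@kind)
  p0 <- if (is.character(start)) startPopulation(model, start) else start
  Q <- rateMatrix(model, perturbation)
  occ <- occupancyAtTimes(Q, p0, horizonH)[1, ]
  classProb <- vapply(OBSERVED_CLASSES,
                      function(cl) sum(occ[ss$class == cl]), numeric(1))
  withSeed(seed, {
    cls <- sample(OBSERVED_CLASSES, nCells, replace = TRUE, prob = classProb)
    out <- data.frame(yfp = numeric(nCells), mch = numeric(nCells),
                      true_class = cls)
    for (cl in OBSERVED_CLASSES) {
      idx <- which(cls == cl)
      if (!length(idx)) next
      comp <- fluorescence$components[[cl]]
      z1 <- stats::rnorm(length(idx)); z2 <- stats::rnorm(length(idx))
      out$mch[idx] <- comp@muR + comp@sigmaR * z1
      out$yfp[idx] <- comp@muY + comp@sigmaY *
        (comp@rho * z1 + sqrt(1 - comp@rho^2) * z2)
    }
    out
  })
}
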