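## Delay-corrected least-squares fitting of the candidate activation
## models to an observed fraction series, reduced chi-squared scoring, and
## F-test model comparison.
##
## Detection delays: fluorescent reporters accumulate for hours before a
## newly activated state is distinguishable from the non-expressing
## population, so the observed fraction of class i lags the model's
## f_i(t). The correction fits f_i(t - tau_i) with per-class delays tau_i
## estimated from the data and held fixed (optionally co-fit).

#' Estimate per-class detection delays from a fraction series
#'
#' The delay of class i is the earliest bin center at which its observed
#' fraction rises significantly above zero — here, exceeds
#' `zThreshold * df` in that bin *and* the next (persistence guards
#' against single-bin noise). Classes that never exceed the threshold get
#' the last bin center and are flagged.
#'
#' @param series a [FractionSeries-class] with at least 3 bins.
#' @param zThreshold significance multiple of the per-bin uncertainty
#'   (default 2).
#' @param minFraction absolute detection floor (default 0.01): a fraction
#'   below it is not counted as a rise even if nominally significant, so
#'   that sub-percent spurious mixture weights (whose least-squares
#'   errors are also tiny) cannot fake an early onset.
#' @param biRule how to treat the bi-allelic class (default `"monoCap"`):
#'   detection lag is a property of the two reporters, and a bi-allelic
#'   cell is detectable once both reporters are, so the bi delay is
#'   capped at the larger of the two mono-class delays. The raw
#'   `"threshold"` rule applied to the bi fraction instead measures
#'   mostly the class's intrinsically late (quadratic-in-time) rise when
#'   bi cells are rare early.
#' @return named numeric of delays (hours) over the four classes (`none`
#'   fixed at 0), with a logical `flagged` attribute per class.
#' @export
estimateDelays <- function(series, zThreshold = 2, minFraction = 0.01,
                           biRule = c("monoCap", "threshold")) {
  biRule <- match.arg(biRule)
  stopifnot(is(series, "FractionSeries"))
  d <- series@data
  if (nrow(d) < 3) stop("delay estimation needs at least 3 time bins")
  tau <- stats::setNames(numeric(4), OBSERVED_CLASSES)
  flagged <- stats::setNames(logical(4), OBSERVED_CLASSES)
  for (cl in EXPRESSING_CLASSES) {
    f <- d[[paste0("f_", cl)]]
    df <- d[[paste0("df_", cl)]]
    sig <- f > pmax(zThreshold * df, minFraction)
    persist <- which(sig[-length(sig)] & sig[-1])
    if (length(persist)) {
      tau[cl] <- d$bin_center_h[persist[1]]
    } else {
      tau[cl] <- d$bin_center_h[nrow(d)]
      flagged[cl] <- TRUE
    }
  }
  if (biRule == "monoCap")
    tau["bi"] <- min(tau[["bi"]], max(tau[["monoY"]], tau[["monoR"]]))
  attr(tau, "flagged") <- flagged
  tau
}

#' Delay-corrected model prediction
#'
#' Evaluates the delayed prediction `f'_i(t) = f_i(t - tau_i)` for the
#' three expressing classes, holding each class at its initial value for
#' `t < tau_i`; the non-expressing fraction is re-derived as one minus the
#' expressing sum so each time point still sums to 1.
#'
#' @param model an [AllelicModel-class], or a trajectory data.frame from
#'   [populationFractions()] (then linear interpolation is used).
#' @param delays named numeric over the four classes (hours); `none` must
#'   be 0.
#' @param times evaluation times (hours).
#' @param perturbation optional [Perturbation-class] (model input only).
#' @return data.frame with columns `time_h`, `f_none`, `f_monoY`,
#'   `f_monoR`, `f_bi`.
#' @export
delayedModelSeries <- function(model, delays, times, perturbation = NULL) {
  stopifnot(identical(sort(names(delays)), sort(OBSERVED_CLASSES)),
            all(delays >= 0), delays[["none"]] == 0)
  shifted <- lapply(EXPRESSING_CLASSES,
                    function(cl) pmax(times - delays[[cl]], 0))
  if (is(model, "AllelicModel")) {
    allT <- sort(unique(c(0, unlist(shifted))))
    traj <- populationFractions(model, allT, perturbation)
    lookup <- function(cl, tt)
      traj[[paste0("f_", cl)]][match(tt, traj$time_h)]
  } else {
    traj <- model
    stopifnot(is.data.frame(traj), "time_h" %in% names(traj))
    lookup <- function(cl, tt)
      stats::approx(traj$time_h, traj[[paste0("f_", cl)]], xout = tt,
                    rule = 2)$y
  }
  out <- data.frame(time_h = times)
  for (k in seq_along(EXPRESSING_CLASSES))
    out[[paste0("f_", EXPRESSING_CLASSES[k])]] <-
      lookup(EXPRESSING_CLASSES[k], shifted[[k]])
  out$f_none <- 1 - out$f_monoY - out$f_monoR - out$f_bi
  out[, c("time_h", "f_none", "f_monoY", "f_monoR", "f_bi")]
}

## Internal parameterization of the free parameters of each model family:
## log rates (positivity) and softmax logits for the initial weights over
## the non-expressing hidden states (first state is the softmax
## reference). Returns builders between parameter vector and AllelicModel.
fitParameterization <- function(kind, coFitDelays = FALSE, tauMax = 50) {
  ss <- stateSpace(kind)
  noneStates <- ss$label[ss$class == "none"]
  nInit <- length(noneStates) - 1L
  nm <- c("logkC",
          if (kind != "cis_only") "logkT",
          if (nInit > 0) paste0("z_", noneStates[-1]),
          if (coFitDelays) paste0("tau_", EXPRESSING_CLASSES))
  lower <- c(log(1e-6),
             if (kind != "cis_only") log(1e-6),
             rep(-20, nInit),
             if (coFitDelays) rep(0, 3))
  upper <- c(log(1),
             if (kind != "cis_only") log(100),
             rep(20, nInit),
             if (coFitDelays) rep(tauMax, 3))
  default <- c(log(0.005),
               if (kind != "cis_only") log(0.01),
               rep(0, nInit),
               if (coFitDelays) rep(10, 3))
  toModel <- function(p) {
    names(p) <- nm
    z <- if (nInit > 0) c(0, p[paste0("z_", noneStates[-1])]) else 0
    w <- exp(z - max(z)); w <- w / sum(w)
    AllelicModel(kind, kC = exp(p[["logkC"]]),
                 kT = if (kind != "cis_only") exp(p[["logkT"]]) else 0,
                 init = stats::setNames(w, noneStates))
  }
  toDelays <- function(p, fixedDelays) {
    if (!coFitDelays) return(fixedDelays)
    names(p) <- nm
    stats::setNames(c(0, p[paste0("tau_", EXPRESSING_CLASSES)]),
                    OBSERVED_CLASSES)
  }
  list(names = nm, lower = lower, upper = upper, default = default,
       toModel = toModel, toDelays = toDelays, nFree = length(nm))
}

#' Fit an activation model to an observed fraction series
#'
#' Minimizes the sum of squared standardized residuals
#' `sum_ij ((f_pred_i(t_j) - f_obs_i(t_j)) / df_i(t_j))^2` over the free
#' parameters of the chosen model family (cis rate; trans rate and initial
#' non-expressing sub-state weights where the family has them), with
#' per-class detection delays held fixed (default) or co-fit. Points with
#' zero uncertainty, and points earlier than their class's delay, are
#' excluded from the sum and from the degrees of freedom. The optimizer is
#' bounded Levenberg-Marquardt least squares restarted from
#' Latin-hypercube seeds (the likelihood surface has plateaus at extreme
#' trans rates); the best optimum is returned.
#'
#' @param kind model family (see [stateSpace()]).
#' @param series a [FractionSeries-class].
#' @param delays optional named delay vector; default
#'   `estimateDelays(series, zThreshold)`.
#' @param zThreshold passed to [estimateDelays()] when `delays` is `NULL`.
#' @param includeNone include the non-expressing class in the residual sum
#'   (default `FALSE`: the fit is driven by the expressing classes, whose
#'   residuals already determine the non-expressing one by closure).
#' @param coFitDelays co-fit the three delays instead of fixing them
#'   (sensitivity analysis; default `FALSE`).
#' @param nStarts number of Latin-hypercube restarts (default 20).
#' @param seed RNG seed for the restart design.
#' @return An [AllelicFit-class].
#' @export
fitModel <- function(kind = MODEL_KINDS, series, delays = NULL,
                     zThreshold = 2, includeNone = FALSE,
                     coFitDelays = FALSE, nStarts = 20, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(is(series, "FractionSeries"))
  d <- series@data
  if (is.null(delays)) delays <- estimateDelays(series, zThreshold)
  delays <- delays[OBSERVED_CLASSES]
  tms <- d$bin_center_h
  classes <- if (includeNone) OBSERVED_CLASSES else EXPRESSING_CLASSES

  par0 <- fitParameterization(kind, coFitDelays, tauMax = max(tms))
  includeMask <- function(dl) {
    m <- list()
    for (cl in classes) {
      df <- d[[paste0("df_", cl)]]
      m[[cl]] <- df > 0 & tms >= dl[[cl]]
    }
    m
  }
  residFor <- function(p) {
    model <- par0$toModel(p)
    dl <- par0$toDelays(p, delays)
    pred <- delayedModelSeries(model, dl, tms)
    mask <- includeMask(dl)
    unlist(lapply(classes, function(cl) {
      sel <- mask[[cl]]
      ((pred[[paste0("f_", cl)]] - d[[paste0("f_", cl)]]) /
         d[[paste0("df_", cl)]])[sel]
    }))
  }
  nPoints <- sum(unlist(includeMask(delays)))
  dofVal <- nPoints - par0$nFree
  if (dofVal <= 0)
    stop(sprintf("non-positive degrees of freedom: %d points, %d parameters",
                 nPoints, par0$nFree))

  starts <- withSeed(seed, {
    u <- lhs::randomLHS(max(nStarts - 1L, 0L), par0$nFree)
    rbind(par0$default,
          t(par0$lower + t(u) * (par0$upper - par0$lower)))
  })
  best <- NULL
  nFail <- 0L
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = par0$lower,
                         upper = par0$upper, fn = residFor,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) { nFail <- nFail + 1L; next }
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best))
    stop("optimizer failed on all restarts")

  pHat <- best$fit$par
  model <- par0$toModel(pHat)
  dlHat <- par0$toDelays(pHat, delays)
  ## parameter covariance in the internal parameterization
  covm <- tryCatch({
    J <- matrix(0, length(best$fit$fvec), par0$nFree)
    f0 <- residFor(pHat)
    for (j in seq_len(par0$nFree)) {
      h <- max(1e-6, abs(pHat[j]) * 1e-5)
      pp <- pHat; pp[j] <- pp[j] + h
      J[, j] <- (residFor(pp) - f0) / h
    }
    s2 <- best$sse / max(dofVal, 1)
    solve(crossprod(J)) * s2
  }, error = function(e) matrix(NA_real_, par0$nFree, par0$nFree))
  dimnames(covm) <- list(par0$names, par0$names)

  new("AllelicFit", model = model, delays = dlHat,
      chi2red = best$sse / dofVal, sse = best$sse, dof = dofVal,
      nPoints = nPoints, paramCov = covm,
      converged = best$fit$info %in% 1:4,
      settings = list(includeNone = includeNone, coFitDelays = coFitDelays,
                      nStarts = nStarts, seed = seed,
                      zThreshold = zThreshold, paramNames = par0$names,
                      nFailedStarts = nFail, fixedDelays = delays))
}

#' Compare two model fits by F-test
#'
#' Takes the ratio of the two fits' reduced chi-squared values — the worse
#' (larger chi2_red) fit in the numerator, so F >= 1 — and evaluates it
#' against the F distribution with the two fits' degrees of freedom.
#'
#' @param fitA,fitB [AllelicFit-class] objects fit to the same series.
#' @return A [ModelComparison-class]. A perfect denominator fit
#'   (chi2_red = 0) yields `F = Inf`.
#' @export
compareModels <- function(fitA, fitB) {
  stopifnot(is(fitA, "AllelicFit"), is(fitB, "AllelicFit"))
  fits <- list(fitA, fitB)
  worseIdx <- if (fitA@chi2red >= fitB@chi2red) 1L else 2L
  worse <- fits[[worseIdx]]; better <- fits[[3L - worseIdx]]
  Fval <- if (better@chi2red == 0) Inf else worse@chi2red / better@chi2red
  p <- stats::pf(Fval, worse@dof, better@dof, lower.tail = FALSE)
  new("ModelComparison", F = Fval, pValue = p,
      worse = worse@model@kind, better = better@model@kind,
      dofWorse = worse@dof, dofBetter = better@dof)
}
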