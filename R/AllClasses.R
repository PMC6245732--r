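#' @import methods
NULL

#' Candidate allelic-activation model
#'
#' An `AllelicModel` bundles one of the three candidate hidden-state
#' continuous-time Markov models of allelic gene activation with its rate
#' constants and initial hidden-state distribution:
#'
#' * `cis_only` — each allele switches on independently by a single
#'   stochastic cis-activation step (4 hidden states);
#' * `sequential` — a cell-wide trans step must complete before either
#'   allele can cis-activate (5 hidden states);
#' * `parallel` — the trans step and the per-allele cis steps proceed
#'   independently, and expression requires both (8 hidden states).
#'
#' Rates are first-order rate constants per hour. Reverse rates default to
#' zero: in unperturbed conditions activation is irreversible. Both alleles
#' share the same cis rate (allele symmetry).
#'
#' @slot kind one of `"cis_only"`, `"sequential"`, `"parallel"`.
#' @slot kC cis-activation rate per allele (/hr).
#' @slot kT trans-step rate (/hr); ignored by `cis_only`.
#' @slot kCrev,kTrev reversal rates (/hr), zero unless modelling a
#'   perturbation baseline.
#' @slot init named numeric: initial probability over the model's
#'   non-expressing hidden states (sums to 1).
#'
#' @seealso [AllelicModel()], [rateMatrix()], [populationFractions()]
#' @exportClass AllelicModel
setClass("AllelicModel",
         representation(kind = "character", kC = "numeric", kT = "numeric",
                        kCrev = "numeric", kTrev = "numeric", init = "numeric"))

setValidity("AllelicModel", function(object) {
  msg <- character()
  if (!(object@kind %in% MODEL_KINDS))
    msg <- c(msg, sprintf("unknown model kind '%s'", object@kind))
  for (r in c("kC", "kT", "kCrev", "kTrev")) {
    v <- slot(object, r)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      msg <- c(msg, sprintf("rate '%s' must be a single non-negative number", r))
  }
  if (length(msg)) return(msg)
  ss <- stateSpace(object@kind)
  noneStates <- ss$label[ss$class == "none"]
  if (is.null(names(object@init)) || !all(names(object@init) %in% noneStates))
    msg <- c(msg, "init must be named and supported on non-expressing hidden states")
  if (any(object@init < -1e-12))
    msg <- c(msg, "init weights must be non-negative")
  if (abs(sum(object@init) - 1) > 1e-9)
    msg <- c(msg, "init weights must sum to 1 (within 1e-9)")
  if (length(msg)) msg else TRUE
})

#' Perturbation of a targeted reaction step
#'
#' Encodes a graded perturbation of either the cis-activation steps or the
#' trans step of an [AllelicModel]: the targeted forward rate is multiplied
#' by `forwardFactor` (1 = no effect), the targeted reverse rate is
#' increased by `reverseRate` (/hr), and both modifications are linearly
#' attenuated toward no effect on transitions into or out of the bi-allelic
#' expressing state by `biAttenuation` (1 = uniform perturbation, 0 =
#' perturbation fully suppressed on bi-allelic transitions).
#'
#' @slot target `"cis"` or `"trans"`.
#' @slot forwardFactor multiplier in \[0, 1\] on the targeted forward rate.
#' @slot reverseRate added reverse rate (/hr, >= 0).
#' @slot biAttenuation attenuation weight in \[0, 1\] for bi-allelic
#'   transitions.
#'
#' @seealso [Perturbation()], [perturbationSweep()]
#' @exportClass Perturbation
setClass("Perturbation",
         representation(target = "character", forwardFactor = "numeric",
                        reverseRate = "numeric", biAttenuation = "numeric"))

setValidity("Perturbation", function(object) {
  msg <- character()
  if (!(object@target %in% c("cis", "trans")))
    msg <- c(msg, "target must be 'cis' or 'trans'")
  if (object@forwardFactor < 0 || object@forwardFactor > 1)
    msg <- c(msg, "forwardFactor must lie in [0, 1]")
  if (object@reverseRate < 0)
    msg <- c(msg, "reverseRate must be >= 0")
  if (object@biAttenuation < 0 || object@biAttenuation > 1)
    msg <- c(msg, "biAttenuation must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' One bivariate Gaussian mixture component
#'
#' A single component of the four-component mixture over (mCherry, YFP)
#' intensities. `N` is the volume under the component — an estimate of the
#' number of cells it accounts for — not a normalized mixing proportion.
#'
#' @slot N cell-count weight (>= 0).
#' @slot muR,muY channel means (intensity units; mCherry, YFP).
#' @slot sigmaR,sigmaY channel standard deviations (> 0).
#' @slot rho channel correlation in (-1, 1).
#'
#' @seealso [GaussianComponent()], [dbigauss()], [fitTimeBin()]
#' @exportClass GaussianComponent
setClass("GaussianComponent",
         representation(N = "numeric", muR = "numeric", muY = "numeric",
                        sigmaR = "numeric", sigmaY = "numeric", rho = "numeric"))

setValidity("GaussianComponent", function(object) {
  msg <- character()
  if (object@N < 0) msg <- c(msg, "N must be >= 0")
  if (object@sigmaR <= 0 || object@sigmaY <= 0)
    msg <- c(msg, "sigmaR and sigmaY must be > 0")
  if (abs(object@rho) >= 1) msg <- c(msg, "|rho| must be < 1")
  if (length(msg)) msg else TRUE
})

#' Result of a constrained four-component mixture fit
#'
#' Returned by [fitTimeBin()]. Components are stored in the fixed order
#' none, monoY, monoR, bi; the non-expressing component's shape is frozen
#' to the anchor fit, only its weight is free.
#'
#' @slot components list of four [GaussianComponent]s named
#'   `none`, `monoY`, `monoR`, `bi`.
#' @slot dN per-component weight uncertainties (least-squares standard
#'   errors).
#' @slot residual sum of squared histogram residuals.
#' @slot converged logical: optimizer convergence status.
#' @slot flags character vector of quality warnings (e.g. collapsed
#'   components); empty when clean.
#' @slot nCells number of cells entering the histogram.
#' @slot meta list of fit settings (bins, transform, bounds).
#'
#' @exportClass MixtureFit
setClass("MixtureFit",
         representation(components = "list", dN = "numeric",
                        residual = "numeric", converged = "logical",
                        flags = "character", nCells = "numeric",
                        meta = "list"))

setValidity("MixtureFit", function(object) {
  msg <- character()
  if (!identical(names(object@components), OBSERVED_CLASSES))
    msg <- c(msg, "components must be named none, monoY, monoR, bi in order")
  if (length(object@dN) != 4L || any(object@dN < 0))
    msg <- c(msg, "dN must be four non-negative values")
  if (length(msg)) msg else TRUE
})

#' Time-binned observed allelic-class fractions
#'
#' Observed fractions f_i(t) of the four allelic expression classes with
#' propagated uncertainties, one row per time bin, as produced by
#' [fractionsOverTime()] or read from file with [readFractionSeries()].
#'
#' @slot data data.frame with columns `bin_center_h`, `n_cells`,
#'   `f_none`, `f_monoY`, `f_monoR`, `f_bi`,
#'   `df_none`, `df_monoY`, `df_monoR`, `df_bi`, `flagged`.
#' @slot meta list of provenance (anchor parameters, binning, transform).
#'
#' @exportClass FractionSeries
setClass("FractionSeries",
         representation(data = "data.frame", meta = "list"))

setValidity("FractionSeries", function(object) {
  d <- object@data
  need <- c("bin_center_h", "n_cells",
            paste0("f_", OBSERVED_CLASSES), paste0("df_", OBSERVED_CLASSES))
  if (!all(need %in% names(d)))
    return(paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
  fr <- as.matrix(d[, paste0("f_", OBSERVED_CLASSES)])
  if (nrow(d) && any(abs(rowSums(fr) - 1) > 1e-6))
    return("class fractions must sum to 1 in every bin")
  if (nrow(d) && any(as.matrix(d[, paste0("df_", OBSERVED_CLASSES)]) < 0))
    return("uncertainties must be >= 0")
  TRUE
})

#' Fitted model with delay correction
#'
#' Result of [fitModel()]: the best-fit [AllelicModel], the fixed per-class
#' detection delays used, and goodness-of-fit bookkeeping.
#'
#' @slot model the fitted [AllelicModel] (rates and initial distribution at
#'   the optimum).
#' @slot delays named numeric: detection delay (hours) per observed class;
#'   `none` is fixed at 0.
#' @slot chi2red reduced chi-squared of the fit.
#' @slot sse minimized sum of squared standardized residuals.
#' @slot dof degrees of freedom (# fitted points - # free parameters).
#' @slot nPoints number of data points entering the residual sum.
#' @slot paramCov covariance matrix of the free parameters (internal
#'   parameterization; see `settings$paramNames`).
#' @slot converged logical.
#' @slot settings list: optimizer settings, seed, included classes.
#'
#' @exportClass AllelicFit
setClass("AllelicFit",
         representation(model = "AllelicModel", delays = "numeric",
                        chi2red = "numeric", sse = "numeric", dof = "numeric",
                        nPoints = "numeric", paramCov = "matrix",
                        converged = "logical", settings = "list"))

setValidity("AllelicFit", function(object) {
  msg <- character()
  if (object@dof <= 0) msg <- c(msg, "degrees of freedom must be > 0")
  if (object@chi2red < 0) msg <- c(msg, "chi2red must be >= 0")
  if (!identical(names(object@delays), OBSERVED_CLASSES))
    msg <- c(msg, "delays must be named none, monoY, monoR, bi")
  if (length(msg)) msg else TRUE
})

#' F-test comparison of two model fits
#'
#' Ratio of the two fits' reduced chi-squared values (worse model in the
#' numerator, so F >= 1 when the fits are ordered) with a p-value from the
#' F distribution at the two fits' degrees of freedom.
#'
#' @slot F ratio of reduced chi-squared values.
#' @slot pValue upper-tail F-distribution probability.
#' @slot worse,better model kinds of numerator and denominator fits.
#' @slot dofWorse,dofBetter their degrees of freedom.
#'
#' @exportClass ModelComparison
setClass("ModelComparison",
         representation(F = "numeric", pValue = "numeric",
                        worse = "character", better = "character",
                        dofWorse = "numeric", dofBetter = "numeric"))

#' Distribution of clone classes from Monte-Carlo lineage simulation
#'
#' Clone counts per allelic-expression clone class over `nClones` simulated
#' lineages. The three-class fractions condition on clones that expressed
#' at all; the non-expressing count is reported separately.
#'
#' @slot counts named integer counts over
#'   `single_mono_allelic`, `mixed_mono_allelic`, `bi_allelic_only`,
#'   `non_expressing`.
#' @slot fractions named fractions over the three expressing classes
#'   (sum to 1); `NA` and `flagged` when no clone expressed.
#' @slot nClones total clones simulated.
#' @slot modelKind model used.
#' @slot seed RNG seed.
#' @slot flagged logical: TRUE when the expressing-class distribution is
#'   undefined (no expressing clones).
#'
#' @exportClass CloneClassDistribution
setClass("CloneClassDistribution",
         representation(counts = "numeric", fractions = "numeric",
                        nClones = "numeric", modelKind = "character",
                        seed = "numeric", flagged = "logical"))

setValidity("CloneClassDistribution", function(object) {
  msg <- character()
  if (!identical(names(object@counts), CLONE_CLASSES))
    msg <- c(msg, "counts must be named by the four clone classes")
  if (sum(object@counts) != object@nClones)
    msg <- c(msg, "counts must sum to nClones")
  if (!object@flagged &&
      abs(sum(object@fractions) - 1) > 1e-9)
    msg <- c(msg, "expressing-class fractions must sum to 1")
  if (length(msg)) msg else TRUE
})
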