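#' @include AllClasses.R
NULL

#' Accessors for alleleKinetics objects
#'
#' Small accessor generics: `modelKind` returns the model family of an
#' object, `rateParams` its named rate constants, `initialDistribution`
#' the initial hidden-state probabilities, `fractions` / `uncertainties` /
#' `binCenters` / `nCells` the columns of a [FractionSeries],
#' `components` / `weightErrors` the parts of a [MixtureFit], and
#' `chi2Red` / `dof` / `delays` / `fittedModel` the parts of an
#' [AllelicFit]. `cloneCounts` / `cloneFractions` read a
#' [CloneClassDistribution].
#'
#' @param object an alleleKinetics S4 object.
#' @return The corresponding slot content (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("modelKind", function(object) standardGeneric("modelKind"))
#' @rdname accessors
#' @export
setGeneric("rateParams", function(object) standardGeneric("rateParams"))
#' @rdname accessors
#' @export
setGeneric("initialDistribution",
           function(object) standardGeneric("initialDistribution"))
#' @rdname accessors
#' @export
setGeneric("fractions", function(object) standardGeneric("fractions"))
#' @rdname accessors
#' @export
setGeneric("uncertainties", function(object) standardGeneric("uncertainties"))
#' @rdname accessors
#' @export
setGeneric("binCenters", function(object) standardGeneric("binCenters"))
#' @rdname accessors
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))
#' @rdname accessors
#' @export
setGeneric("components", function(object) standardGeneric("components"))
#' @rdname accessors
#' @export
setGeneric("weightErrors", function(object) standardGeneric("weightErrors"))
#' @rdname accessors
#' @export
setGeneric("chi2Red", function(object) standardGeneric("chi2Red"))
#' @rdname accessors
#' @export
setGeneric("dof", function(object) standardGeneric("dof"))
#' @rdname accessors
#' @export
setGeneric("delays", function(object) standardGeneric("delays"))
#' @rdname accessors
#' @export
setGeneric("fittedModel", function(object) standardGeneric("fittedModel"))
#' @rdname accessors
#' @export
setGeneric("cloneCounts", function(object) standardGeneric("cloneCounts"))
#' @rdname accessors
#' @export
setGeneric("cloneFractions", function(object) standardGeneric("cloneFractions"))

#' @rdname accessors
setMethod("modelKind", "AllelicModel", function(object) object@kind)
#' @rdname accessors
setMethod("modelKind", "AllelicFit", function(object) object@model@kind)
#' @rdname accessors
setMethod("modelKind", "CloneClassDistribution", function(object) object@modelKind)
#' @rdname accessors
setMethod("rateParams", "AllelicModel", function(object)
  c(kC = object@kC, kT = object@kT, kCrev = object@kCrev, kTrev = object@kTrev))
#' @rdname accessors
setMethod("rateParams", "AllelicFit", function(object) rateParams(object@model))
#' @rdname accessors
setMethod("initialDistribution", "AllelicModel", function(object) object@init)
#' @rdname accessors
setMethod("initialDistribution", "AllelicFit", function(object) object@model@init)
#' @rdname accessors
setMethod("fractions", "FractionSeries", function(object) {
  m <- as.matrix(object@data[, paste0("f_", OBSERVED_CLASSES)])
  colnames(m) <- OBSERVED_CLASSES
  m
})
#' @rdname accessors
setMethod("uncertainties", "FractionSeries", function(object) {
  m <- as.matrix(object@data[, paste0("df_", OBSERVED_CLASSES)])
  colnames(m) <- OBSERVED_CLASSES
  m
})
#' @rdname accessors
setMethod("binCenters", "FractionSeries", function(object) object@data$bin_center_h)
#' @rdname accessors
setMethod("nCells", "FractionSeries", function(object) object@data$n_cells)
#' @rdname accessors
setMethod("nCells", "MixtureFit", function(object) object@nCells)
#' @rdname accessors
setMethod("components", "MixtureFit", function(object) object@components)
#' @rdname accessors
setMethod("weightErrors", "MixtureFit", function(object) object@dN)
#' @rdname accessors
setMethod("chi2Red", "AllelicFit", function(object) object@chi2red)
#' @rdname accessors
setMethod("dof", "AllelicFit", function(object) object@dof)
#' @rdname accessors
setMethod("delays", "AllelicFit", function(object) object@delays)
#' @rdname accessors
setMethod("fittedModel", "AllelicFit", function(object) object@model)
#' @rdname accessors
setMethod("cloneCounts", "CloneClassDistribution", function(object) object@counts)
#' @rdname accessors
setMethod("cloneFractions", "CloneClassDistribution", function(object) object@fractions)

setMethod("show", "AllelicModel", function(object) {
  cat(sprintf("AllelicModel: %s\n", object@kind))
  r <- rateParams(object)
  cat(sprintf("  rates (/hr): kC=%.4g kT=%.4g kCrev=%.4g kTrev=%.4g\n",
              r["kC"], r["kT"], r["kCrev"], r["kTrev"]))
  cat("  init:", paste(sprintf("%s=%.3g", names(object@init), object@init),
                       collapse = " "), "\n")
})

setMethod("show", "Perturbation", function(object) {
  cat(sprintf("Perturbation of %s step: forward x%.3g, reverse +%.4g/hr, bi-attenuation %.2g\n",
              object@target, object@forwardFactor, object@reverseRate,
              object@biAttenuation))
})

setMethod("show", "GaussianComponent", function(object) {
  cat(sprintf("GaussianComponent: N=%.4g mu=(%.4g, %.4g) sigma=(%.4g, %.4g) rho=%.3f\n",
              object@N, object@muR, object@muY, object@sigmaR, object@sigmaY,
              object@rho))
})

setMethod("show", "MixtureFit", function(object) {
  Ns <- vapply(object@components, slot, numeric(1), "N")
  f <- Ns / sum(Ns)
  cat(sprintf("MixtureFit on %d cells (%s)\n", round(object@nCells),
              if (object@converged) "converged" else "NOT converged"))
  cat("  fractions:",
      paste(sprintf("%s=%.3f", OBSERVED_CLASSES, f), collapse = " "), "\n")
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "FractionSeries", function(object) {
  cat(sprintf("FractionSeries: %d time bins, %.0f-%.0f h, %d cells total\n",
              nrow(object@data),
              if (nrow(object@data)) min(object@data$bin_center_h) else NA,
              if (nrow(object@data)) max(object@data$bin_center_h) else NA,
              round(sum(object@data$n_cells))))
  print(utils::head(object@data, 4))
  if (nrow(object@data) > 4) cat("  ...\n")
})

setMethod("show", "AllelicFit", function(object) {
  cat(sprintf("AllelicFit: %s model, chi2_red=%.4g (dof=%d, %d points)\n",
              object@model@kind, object@chi2red, round(object@dof),
              round(object@nPoints)))
  r <- rateParams(object)
  cat(sprintf("  kC=%.4g/hr kT=%.4g/hr\n", r["kC"], r["kT"]))
  cat("  delays (h):",
      paste(sprintf("%s=%.1f", names(object@delays), object@delays),
            collapse = " "), "\n")
})

setMethod("show", "ModelComparison", function(object) {
  cat(sprintf("ModelComparison: F = %.3g (%s vs %s), p = %.3g [dof %d, %d]\n",
              object@F, object@worse, object@better, object@pValue,
              round(object@dofWorse), round(object@dofBetter)))
})

setMethod("show", "CloneClassDistribution", function(object) {
  cat(sprintf("CloneClassDistribution: %s model, %d clones (seed %d)\n",
              object@modelKind, round(object@nClones), round(object@seed)))
  cat("  counts:",
      paste(sprintf("%s=%d", names(object@counts), round(object@counts)),
            collapse = " "), "\n")
  if (object@flagged) {
    cat("  no expressing clones: class fractions undefined\n")
  } else {
    cat("  expressing-clone fractions:",
        paste(sprintf("%s=%.3f", names(object@fractions), object@fractions),
              collapse = " "), "\n")
  }
})
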