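## Reproducible multi-stage pipeline over a run configuration: quantify ->
## fit & compare -> clone analysis -> perturbation phase sweep. Configs
## are plain lists (or YAML/JSON files); every stochastic stage carries an
## explicit seed, the config is serialized verbatim into the output
## directory, and each output file name is stamped into a manifest with
## the config hash.

#' Load and normalize a run configuration
#'
#' @param config a named list, or a path to a YAML/JSON config file.
#'   Recognized blocks: `input` (`tracks`, `series`), `quantify`
#'   (`bin_width_h`, `min_cells`, `nbins`, `transform`, `anchor_window`),
#'   `fit` (`models`, `z_threshold`, `include_none`, `n_starts`, `seed`),
#'   `clone` (`n_clones`, `division_time`, `observe_until`, `seed`,
#'   `observed`: list with `class`, `count`, `n`), `phase` (`magnitudes`,
#'   `horizon_h`, `forward_factor`, `reverse_rate`, `bi_attenuation`),
#'   `outdir`.
#' @return normalized config list with defaults filled in.
#' @export
runConfig <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  def <- list(
    input = list(tracks = NULL, series = NULL),
    quantify = list(bin_width_h = 5, min_cells = 30, nbins = 64,
                    transform = "linear", cofactor = 150,
                    anchor_window = c(0, 10)),
    fit = list(models = MODEL_KINDS, z_threshold = 2,
               include_none = FALSE, n_starts = 20, seed = 1),
    clone = list(n_clones = 30000, division_time = 20, observe_until = 100,
                 n_generations = 5, seed = 1, observed = NULL),
    phase = list(magnitudes = seq(0, 1, 0.2), horizon_h = 96,
                 forward_factor = 0.3, reverse_rate = 0.005,
                 bi_attenuation = 0.4),
    outdir = "pipeline_out")
  for (blk in names(def)) {
    if (blk == "outdir") next
    user <- config[[blk]] %||% list()
    def[[blk]][names(user)] <- user
  }
  def$outdir <- config$outdir %||% def$outdir
  def
}

stamp <- function(config) {
  list(config_hash = digest::digest(config),
       package_version = as.character(utils::packageVersion("alleleKinetics")))
}

writeStamped <- function(obj, path, config) {
  jsonlite::write_json(c(obj, stamp(config)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Pipeline stage: quantify class fractions from tracks
#'
#' Reads the configured tracks table, runs the anchored mixture
#' quantification, and writes the fraction series TSV, the anchor-fit
#' JSON and a diagnostics JSON into `outdir`.
#'
#' @param config see [runConfig()].
#' @return the [FractionSeries-class], invisibly; files as side effect.
#' @export
runQuantify <- function(config) {
  config <- runConfig(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, file.path(config$outdir, "config.yaml"))
  if (is.null(config$input$tracks))
    stop("config$input$tracks is required for the quantify stage")
  tracks <- if (is.data.frame(config$input$tracks)) config$input$tracks
            else readTracks(config$input$tracks)
  q <- config$quantify
  message(sprintf("[quantify] %d cells, bin width %g h", nrow(tracks),
                  q$bin_width_h))
  series <- fractionsOverTime(tracks, binWidthH = q$bin_width_h,
                              anchorWindow = q$anchor_window,
                              minCells = q$min_cells, nbins = q$nbins,
                              transform = q$transform,
                              cofactor = q$cofactor)
  writeFractionSeries(series, file.path(config$outdir, "fraction_series.tsv"))
  anchor <- series@meta$anchor
  writeStamped(list(anchor = list(N = anchor@N, muR = anchor@muR,
                                  muY = anchor@muY, sigmaR = anchor@sigmaR,
                                  sigmaY = anchor@sigmaY, rho = anchor@rho),
                    transform = q$transform, nbins = q$nbins),
               file.path(config$outdir, "anchor_fit.json"), config)
  flags <- series@data$flagged
  if (any(flags))
    message(sprintf("[quantify] %d/%d bins flagged", sum(flags),
                    length(flags)))
  writeStamped(list(n_bins = nrow(series@data),
                    n_flagged = sum(flags),
                    bin_flags = series@meta$binFlags),
               file.path(config$outdir, "quantify_diagnostics.json"), config)
  invisible(series)
}

#' Pipeline stage: fit and compare candidate models
#'
#' Fits every configured model family to the fraction series (estimating
#' detection delays once from the data), writes one fit JSON per model
#' and one comparison JSON per model pair. A failing model fit is
#' reported and skipped without aborting the other fits.
#'
#' @param config see [runConfig()]; uses `input$series` (path or
#'   [FractionSeries-class]) or the quantify stage's output in `outdir`.
#' @return named list of [AllelicFit-class] objects, invisibly.
#' @export
runFitCompare <- function(config) {
  config <- runConfig(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  src <- config$input$series %||%
    file.path(config$outdir, "fraction_series.tsv")
  series <- if (is(src, "FractionSeries")) src else readFractionSeries(src)
  if (nrow(series@data) == 0) stop("empty fraction series")
  fc <- config$fit
  delays <- estimateDelays(series, fc$z_threshold)
  fits <- list()
  for (kind in fc$models) {
    fit <- tryCatch(
      fitModel(kind, series, delays = delays,
               includeNone = fc$include_none, nStarts = fc$n_starts,
               seed = fc$seed),
      error = function(e) {
        message(sprintf("[fit] %s model failed: %s", kind,
                        conditionMessage(e)))
        NULL
      })
    if (is.null(fit)) next
    message(sprintf("[fit] %s: chi2_red=%.4g (dof=%d), kC=%.4g/hr",
                    kind, fit@chi2red, round(fit@dof),
                    rateParams(fit)["kC"]))
    writeFitResult(fit, file.path(config$outdir,
                                  sprintf("fit_%s.json", kind)))
    fits[[kind]] <- fit
  }
  if (length(fits) >= 2) {
    nms <- names(fits)
    for (i in seq_len(length(fits) - 1L)) for (j in (i + 1L):length(fits)) {
      cmp <- compareModels(fits[[i]], fits[[j]])
      writeComparison(cmp, file.path(config$outdir,
                                     sprintf("compare_%s_vs_%s.json",
                                             nms[i], nms[j])))
      message(sprintf("[compare] %s vs %s: F=%.3g p=%.3g", nms[i], nms[j],
                      cmp@F, cmp@pValue))
    }
  }
  invisible(fits)
}

#' Pipeline stage: clone-class predictions and clone-level test
#'
#' Simulates the configured number of clonal lineages under each fitted
#' (or explicitly supplied) trans-cis model, writes the predicted
#' clone-class distributions, and — when observed clone counts are
#' configured — the observed-vs-predicted single-category chi-squared
#' report (the two-category Pearson value is included alongside).
#'
#' @param config see [runConfig()]. `config$clone$models` may supply
#'   explicit parameter lists `list(kind=, kC=, kT=)`; otherwise fit
#'   JSONs in `outdir` are used.
#' @return list of [CloneClassDistribution-class] objects, invisibly.
#' @export
runCloneAnalysis <- function(config) {
  config <- runConfig(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  cl <- config$clone
  models <- list()
  if (!is.null(cl$models)) {
    for (m in cl$models)
      models[[m$kind]] <- AllelicModel(m$kind, kC = m$kC, kT = m$kT %||% 0)
  } else {
    for (kind in c("sequential", "parallel")) {
      fp <- file.path(config$outdir, sprintf("fit_%s.json", kind))
      if (!file.exists(fp)) next
      fj <- jsonlite::read_json(fp, simplifyVector = TRUE)
      models[[kind]] <- AllelicModel(kind, kC = fj$rates$kC,
                                     kT = fj$rates$kT,
                                     init = unlist(fj$init))
    }
  }
  if (!length(models))
    stop("no clone-simulation models available (fit stage output or ",
         "explicit clone$models required)")
  out <- list(); report <- list()
  for (kind in names(models)) {
    cfg <- cloneSimConfig(divisionTime = cl$division_time,
                          nGenerations = cl$n_generations,
                          observeUntil = cl$observe_until,
                          nClones = cl$n_clones, seed = cl$seed)
    dist <- cloneClassDistribution(models[[kind]], cfg)
    out[[kind]] <- dist
    entry <- list(counts = as.list(cloneCounts(dist)),
                  fractions = as.list(cloneFractions(dist)),
                  n_clones = cl$n_clones, seed = cl$seed)
    if (!is.null(cl$observed) && !dist@flagged) {
      obs <- cl$observed
      expFrac <- cloneFractions(dist)[[obs$class]]
      if (expFrac > 0 && expFrac < 1) {
        single <- cloneClassChi2(obs$count, obs$n, expFrac, "single")
        pearson <- cloneClassChi2(obs$count, obs$n, expFrac, "pearson")
        entry$test <- list(observed = obs,
                           expected_fraction = expFrac,
                           chi2_single = single$statistic,
                           p_single = single$pValue,
                           chi2_pearson = pearson$statistic,
                           p_pearson = pearson$pValue, df = 1)
        message(sprintf("[clone] %s: expected %s=%.3f, chi2=%.3g (p=%.3g)",
                        kind, obs$class, expFrac, single$statistic,
                        single$pValue))
      }
    }
    report[[kind]] <- entry
  }
  writeStamped(report, file.path(config$outdir, "clone_analysis.json"),
               config)
  invisible(out)
}

#' Pipeline stage: perturbation phase sweep
#'
#' Runs graded cis- and trans-perturbation sweeps from all three start
#' populations under the best-fit (or supplied) parallel model and writes
#' a TSV of endpoints per start and magnitude.
#'
#' @param config see [runConfig()]; `config$phase$model` may supply
#'   `list(kind=, kC=, kT=)`, otherwise the parallel fit JSON in `outdir`
#'   is used.
#' @return data.frame of endpoints, invisibly.
#' @export
runPhaseSweep <- function(config) {
  config <- runConfig(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  ph <- config$phase
  model <- if (!is.null(ph$model)) {
    AllelicModel(ph$model$kind, kC = ph$model$kC, kT = ph$model$kT %||% 0)
  } else {
    fp <- file.path(config$outdir, "fit_parallel.json")
    if (!file.exists(fp))
      stop("no phase-sweep model (fit stage output or phase$model required)")
    fj <- jsonlite::read_json(fp, simplifyVector = TRUE)
    AllelicModel("parallel", kC = fj$rates$kC, kT = fj$rates$kT,
                 init = unlist(fj$init))
  }
  rows <- list()
  for (target in c("cis", "trans")) {
    tpl <- Perturbation(target, forwardFactor = ph$forward_factor,
                        reverseRate = ph$reverse_rate,
                        biAttenuation = ph$bi_attenuation)
    sw <- perturbationSweep(model, template = tpl,
                            magnitudes = ph$magnitudes,
                            horizonH = ph$horizon_h)
    sw$target <- target
    rows[[target]] <- sw
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.table(format(out, digits = 10, trim = TRUE),
                     file.path(config$outdir, "phase_sweep.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Run the full pipeline
#'
#' Executes quantify -> fit & compare -> clone analysis -> phase sweep on
#' one configuration, mirroring the analysis order of a dual-reporter
#' activation study. Identical configs (same seeds) produce identical
#' outputs.
#'
#' @param config see [runConfig()].
#' @return named list with the stage results, invisibly.
#' @export
runAll <- function(config) {
  config <- runConfig(config)
  series <- runQuantify(config)
  fits <- runFitCompare(config)
  clones <- tryCatch(runCloneAnalysis(config), error = function(e) {
    message("[clone] skipped: ", conditionMessage(e)); NULL
  })
  phase <- tryCatch(runPhaseSweep(config), error = function(e) {
    message("[phase] skipped: ", conditionMessage(e)); NULL
  })
  invisible(list(series = series, fits = fits, clones = clones,
                 phase = phase))
}
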