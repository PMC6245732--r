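## Readers and writers for the package's tabular interchange formats.
## All files are plain TSV/JSON; every writer produces byte-stable output
## for fixed input.

#' Read a single-cell tracks table
#'
#' Reads a CSV/TSV cell table with required numeric columns `time_h`,
#' `yfp`, `mch` and optional lineage columns (`clone_id`, `cell_id`,
#' `parent_id`). Flow-style endpoint snapshots use the same layout with a
#' constant `time_h`. FCS ingestion is out of scope: export such data to
#' CSV with these columns first.
#'
#' @param path file path (delimiter auto-detected by extension).
#' @return data.frame.
#' @export
readTracks <- function(path) {
  if (!file.exists(path)) stop("tracks file not found: ", path)
  d <- as.data.frame(data.table::fread(path))
  need <- c("time_h", "yfp", "mch")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("tracks file ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  for (cc in need) {
    bad <- which(!is.finite(d[[cc]]))
    if (length(bad))
      stop(sprintf("non-numeric or missing '%s' in %s at row(s) %s",
                   cc, path, paste(utils::head(bad, 5), collapse = ", ")))
  }
  d
}

#' Write / read a fraction series
#'
#' The native TSV layout has the fixed column order `bin_center_h`,
#' `n_cells`, `f_none`, `f_monoY`, `f_monoR`, `f_bi`, `df_none`,
#' `df_monoY`, `df_monoR`, `df_bi` (plus a trailing `flagged` column).
#' `readFractionSeries(format = "ci")` instead ingests a
#' fractions-with-95%-CI table (columns `time_h`, then `f_<class>` and
#' `ci_<class>` for the three expressing classes), converting CI
#' half-widths to 1-sigma uncertainties via CI/1.96 and deriving the
#' non-expressing row by closure.
#'
#' @param series a [FractionSeries-class].
#' @param path file path.
#' @param format `"native"` or `"ci"`.
#' @return `readFractionSeries` returns a [FractionSeries-class];
#'   `writeFractionSeries` returns `path` invisibly.
#' @export
writeFractionSeries <- function(series, path) {
  stopifnot(is(series, "FractionSeries"))
  cols <- c("bin_center_h", "n_cells",
            paste0("f_", OBSERVED_CLASSES), paste0("df_", OBSERVED_CLASSES))
  d <- series@data
  if (!"flagged" %in% names(d)) d$flagged <- FALSE
  utils::write.table(format(d[, c(cols, "flagged")], digits = 10, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFractionSeries
#' @export
readFractionSeries <- function(path, format = c("native", "ci")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("fraction series file not found: ", path)
  d <- as.data.frame(data.table::fread(path))
  if (format == "ci") {
    need <- c("time_h", paste0("f_", EXPRESSING_CLASSES),
              paste0("ci_", EXPRESSING_CLASSES))
    miss <- setdiff(need, names(d))
    if (length(miss))
      stop("CI-format file is missing column(s): ",
           paste(miss, collapse = ", "))
    out <- data.frame(bin_center_h = d$time_h,
                      n_cells = d$n_cells %||% rep(NA_real_, nrow(d)))
    fsum <- 0
    for (cl in EXPRESSING_CLASSES) fsum <- fsum + d[[paste0("f_", cl)]]
    out$f_none <- pmax(1 - fsum, 0)
    for (cl in EXPRESSING_CLASSES) out[[paste0("f_", cl)]] <- d[[paste0("f_", cl)]]
    dfs <- sapply(EXPRESSING_CLASSES,
                  function(cl) d[[paste0("ci_", cl)]] / 1.96)
    out$df_none <- sqrt(rowSums(dfs^2))
    for (k in seq_along(EXPRESSING_CLASSES))
      out[[paste0("df_", EXPRESSING_CLASSES[k])]] <- dfs[, k]
    out$flagged <- FALSE
    out <- out[, c("bin_center_h", "n_cells", paste0("f_", OBSERVED_CLASSES),
                   paste0("df_", OBSERVED_CLASSES), "flagged")]
    return(new("FractionSeries", data = out,
               meta = list(source = path, format = "ci")))
  }
  need <- c("bin_center_h", "n_cells", paste0("f_", OBSERVED_CLASSES),
            paste0("df_", OBSERVED_CLASSES))
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("fraction series file is missing column(s): ",
         paste(miss, collapse = ", "))
  if (!"flagged" %in% names(d)) d$flagged <- FALSE
  new("FractionSeries", data = d[, c(need, "flagged")],
      meta = list(source = path, format = "native"))
}

#' Write a population trajectory as TSV
#'
#' @param traj data.frame from [populationFractions()].
#' @param path file path.
#' @export
writeTrajectory <- function(traj, path) {
  stopifnot(all(c("time_h", paste0("f_", OBSERVED_CLASSES)) %in% names(traj)))
  utils::write.table(format(traj, digits = 10, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a model fit or comparison as JSON
#'
#' @param fit an [AllelicFit-class].
#' @param cmp a [ModelComparison-class].
#' @param path file path.
#' @export
writeFitResult <- function(fit, path) {
  stopifnot(is(fit, "AllelicFit"))
  obj <- list(model = fit@model@kind,
              rates = as.list(rateParams(fit)),
              init = as.list(initialDistribution(fit)),
              delays_h = as.list(fit@delays),
              chi2_red = fit@chi2red, sse = fit@sse,
              dof = fit@dof, n_points = fit@nPoints,
              converged = fit@converged,
              settings = fit@settings[c("includeNone", "coFitDelays",
                                        "nStarts", "seed", "zThreshold")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeFitResult
#' @export
writeComparison <- function(cmp, path) {
  stopifnot(is(cmp, "ModelComparison"))
  jsonlite::write_json(list(F = cmp@F, p_value = cmp@pValue,
                            worse = cmp@worse, better = cmp@better,
                            dof_worse = cmp@dofWorse,
                            dof_better = cmp@dofBetter),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Render a clone record as an indented text tree
#'
#' @param record a `CloneRecord` from [simulateClone()].
#' @return character vector, one line per cell.
#' @export
formatCloneTree <- function(record) {
  stopifnot(is.data.frame(record), "cell_id" %in% names(record))
  cells <- record[!duplicated(record$cell_id), ]
  cells <- cells[order(cells$cell_id), ]
  vapply(seq_len(nrow(cells)), function(i) {
    depth <- nchar(cells$cell_id[i]) - 1L
    sprintf("%s%s [%s] %s (%.0f-%.0f h)",
            strrep("  ", depth), cells$cell_id[i], cells$state[i],
            cells$class[i], cells$birth_h[i], cells$division_h[i])
  }, character(1))
}
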