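## Monte-Carlo simulation of clonal proliferating lineages under any of
## the candidate models, clone classification by the set of allelic
## expression classes ever observed in the clone, and the clone-level
## goodness-of-fit statistic.
##
## The continuous-time chain is coarse-grained to one Markov step per cell
## generation: P = expm(Q * divisionTime). Divisions are synchronous, the
## two daughters of a cell draw their next-generation states independently
## from the row of their parent's state, and observations are taken at
## every generation boundary up to the observation horizon.

#' Clone-simulation configuration
#'
#' @param divisionTime cell-cycle length in hours (default 20).
#' @param nGenerations maximum number of divisions (default 5).
#' @param observeUntil observation horizon in hours (default 100);
#'   generations beyond the horizon are truncated.
#' @param nClones number of independent clones (default 30000).
#' @param seed RNG seed.
#' @return list of class `cloneSimConfig`.
#' @export
cloneSimConfig <- function(divisionTime = 20, nGenerations = 5,
                           observeUntil = 100, nClones = 30000, seed = 1) {
  stopifnot(divisionTime > 0, nGenerations >= 0, observeUntil >= 0,
            nClones >= 1)
  structure(list(divisionTime = divisionTime, nGenerations = nGenerations,
                 observeUntil = observeUntil, nClones = nClones,
                 seed = seed),
            class = "cloneSimConfig")
}

#' Per-generation transition matrix
#'
#' Converts the continuous-time generator to the discrete Markov chain of
#' per-division transition probabilities: `P = expm(Q * divisionTime)`.
#'
#' @param Q rate matrix from [rateMatrix()].
#' @param divisionTime cell-cycle length in hours (default 20).
#' @return Row-stochastic matrix (rows sum to 1, entries >= 0).
#' @examples
#' m <- AllelicModel("cis_only", kC = 0.0042)
#' divisionTransitionMatrix(rateMatrix(m))
#' @export
divisionTransitionMatrix <- function(Q, divisionTime = 20) {
  stopifnot(divisionTime > 0)
  P <- as.matrix(Matrix::expm(Q * divisionTime))
  P[P < 0] <- 0          # clip tiny negative round-off
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q)
  P
}

## Number of observed generations: divisions happen every divisionTime
## hours; observation truncates at the horizon.
nObservedGenerations <- function(config)
  min(config$nGenerations, floor(config$observeUntil / config$divisionTime))

## Vectorized sampler of one generation's worth of continuous-time paths
## for many cells at once: each cell starts in `start` (state indices) and
## evolves under Q for `dt` hours. Returns the end states and, per cell,
## which observed classes were entered along the way (the birth state is
## accounted for by the caller). Exact exponential waiting times; each
## pass moves every still-active cell through one jump.
simulateGenerationPaths <- function(Q, start, dt, classIdx) {
  M <- length(start)
  nS <- nrow(Q)
  exit <- -diag(Q)
  jumpTab <- lapply(seq_len(nS), function(s) {
    p <- Q[s, ]; p[s] <- 0
    tot <- sum(p)
    if (tot <= 0) return(NULL)
    list(to = which(p > 0), cp = cumsum(p[p > 0] / tot))
  })
  visited <- matrix(FALSE, M, 4L)
  cur <- start
  tleft <- rep(dt, M)
  for (iter in seq_len(1000L)) {
    lam <- exit[cur]
    act <- which(lam > 0 & tleft > 0)
    if (!length(act)) break
    w <- stats::rexp(length(act), lam[act])
    stay <- w >= tleft[act]
    tleft[act[stay]] <- 0
    jump <- act[!stay]
    if (!length(jump)) break
    tleft[jump] <- tleft[jump] - w[!stay]
    jumpStates <- cur[jump]            # snapshot before reassignment
    for (s in unique(jumpStates)) {
      idx <- jump[jumpStates == s]
      jt <- jumpTab[[s]]
      nxt <- jt$to[findInterval(stats::runif(length(idx)), jt$cp,
                                left.open = TRUE) + 1L]
      cur[idx] <- nxt
      visited[cbind(idx, classIdx[nxt])] <- TRUE
    }
  }
  list(end = cur, visited = visited)
}

## Vectorized batch simulation. Returns, per clone, which observed classes
## were ever seen, plus per-generation class counts pooled over clones
## (for marginal-consistency checks against the exact solution).
##
## observe = "path" (default) scores every state a lineage passes through
## during a generation — what continuous timelapse observation of the
## model states would see, and the scheme under which a sequential-model
## clone can never be bi-allelic-only (any sequential path to the
## bi-allelic state traverses a mono-allelic state). observe = "boundary"
## samples states only at division boundaries via exp(Q dt). Both schemes
## draw the two daughters of a cell independently from their parent's
## state and have identical per-generation marginals.
simulateCloneClasses <- function(model, config, perturbation = NULL,
                                 observe = c("path", "boundary")) {
  stopifnot(is(model, "AllelicModel"), inherits(config, "cloneSimConfig"))
  observe <- match.arg(observe)
  ss <- stateSpace(model@kind)
  Q <- rateMatrix(model, perturbation)
  G <- nObservedGenerations(config)
  nS <- nrow(ss)
  classIdx <- match(ss$class, OBSERVED_CLASSES)
  n <- config$nClones
  P <- if (observe == "boundary") divisionTransitionMatrix(Q, config$divisionTime)
  withSeed(config$seed, {
    p0 <- numeric(nS); names(p0) <- ss$label
    p0[names(model@init)] <- model@init
    cur <- sample.int(nS, n, replace = TRUE, prob = p0)
    seen <- matrix(FALSE, n, 4L,
                   dimnames = list(NULL, OBSERVED_CLASSES))
    genCounts <- matrix(0L, G + 1L, 4L,
                        dimnames = list(paste0("gen", 0:G), OBSERVED_CLASSES))
    boundary <- function(stateMat, g) {
      cl <- matrix(classIdx[stateMat], nrow(stateMat))
      for (k in 1:4) {
        seen[, k] <<- seen[, k] | (rowSums(cl == k) > 0L)
        genCounts[g + 1L, k] <<- genCounts[g + 1L, k] + sum(cl == k)
      }
    }
    stateMat <- matrix(cur, n, 1L)
    boundary(stateMat, 0L)
    if (G >= 1) for (g in 1:G) {
      parents <- as.integer(stateMat[, rep(seq_len(ncol(stateMat)), each = 2L)])
      if (observe == "boundary") {
        daughters <- integer(length(parents))
        for (s in seq_len(nS)) {
          idx <- which(parents == s)
          if (length(idx))
            daughters[idx] <- sample.int(nS, length(idx), replace = TRUE,
                                         prob = P[s, ])
        }
      } else {
        res <- simulateGenerationPaths(Q, parents, config$divisionTime,
                                       classIdx)
        daughters <- res$end
        for (k in 1:4)
          seen[, k] <- seen[, k] |
            (rowSums(matrix(res$visited[, k], n)) > 0L)
      }
      stateMat <- matrix(daughters, n, 2L^g)
      boundary(stateMat, g)
    }
    list(seen = seen, genCounts = genCounts, generations = G)
  })
}

#' Simulate one clonal lineage tree
#'
#' Simulates a single clone under the per-generation Markov chain and
#' returns the full lineage record: one row per cell with its parent,
#' birth and division (or censoring) times, hidden state and observed
#' class. Cell ids encode the binary lineage path.
#'
#' @param model an [AllelicModel-class].
#' @param config a [cloneSimConfig()].
#' @param perturbation optional [Perturbation-class].
#' @param observe `"path"` (default) also records the classes a lineage
#'   passes through within a generation (continuous observation of the
#'   model states, as in timelapse scoring); `"boundary"` records states
#'   only at division boundaries.
#' @return data.frame of class `CloneRecord` with columns `cell_id`,
#'   `parent_id`, `generation`, `birth_h`, `division_h`, `state` and
#'   `class` (at birth), and `classes_seen` (comma-joined classes observed
#'   along the path that produced the cell, including its birth class).
#' @examples
#' m <- AllelicModel("parallel", kC = 0.01, kT = 0.02)
#' rec <- simulateClone(m, cloneSimConfig(nClones = 1, seed = 7))
#' classifyClone(rec)
#' @export
simulateClone <- function(model, config = cloneSimConfig(nClones = 1),
                          perturbation = NULL,
                          observe = c("path", "boundary")) {
  stopifnot(is(model, "AllelicModel"), inherits(config, "cloneSimConfig"))
  observe <- match.arg(observe)
  ss <- stateSpace(model@kind)
  Q <- rateMatrix(model, perturbation)
  G <- nObservedGenerations(config)
  withSeed(config$seed, {
    p0 <- numeric(nrow(ss)); names(p0) <- ss$label
    p0[names(model@init)] <- model@init
    rows <- list()
    addCell <- function(id, parent, g, state, pathClasses) {
      divides <- g < G
      rows[[length(rows) + 1L]] <<- data.frame(
        cell_id = id, parent_id = parent, generation = g,
        birth_h = g * config$divisionTime,
        division_h = if (divides) (g + 1) * config$divisionTime
                     else min(config$observeUntil,
                              (g + 1) * config$divisionTime),
        state = ss$label[state], class = ss$class[state],
        classes_seen = paste(unique(c(pathClasses, ss$class[state])),
                             collapse = ","))
      if (divides) for (d in 0:1) {
        ## each daughter independently re-draws its parent's generation
        path <- gillespiePath(Q, state, g * config$divisionTime,
                              (g + 1) * config$divisionTime)
        child <- path$states[length(path$states)]
        seenOnPath <- if (observe == "path")
          unique(ss$class[path$states[-1L]]) else character()
        addCell(paste0(id, d), id, g + 1L, child, seenOnPath)
      }
    }
    root <- sample.int(nrow(ss), 1L, prob = p0)
    addCell("1", NA_character_, 0L, root, character())
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("CloneRecord", class(out))
    out
  })
}

#' Classify a clone by the allelic classes it exhibited
#'
#' A clone is `single_mono_allelic` when exactly one of the two
#' mono-allelic classes was ever observed (bi-allelic cells may also be
#' present), `mixed_mono_allelic` when both were, `bi_allelic_only` when
#' bi-allelic expression was observed without either mono class, and
#' `non_expressing` when no expressing class was observed.
#'
#' @param record a `CloneRecord` from [simulateClone()], or a character
#'   vector of observed class labels.
#' @return one of the four clone-class labels.
#' @export
classifyClone <- function(record) {
  classes <- if (is.data.frame(record)) {
    if ("classes_seen" %in% names(record))
      unique(unlist(strsplit(record$classes_seen, ",", fixed = TRUE)))
    else unique(record$class)
  } else unique(as.character(record))
  hasY <- "monoY" %in% classes
  hasR <- "monoR" %in% classes
  hasBi <- "bi" %in% classes
  if (hasY && hasR) "mixed_mono_allelic"
  else if (hasY || hasR) "single_mono_allelic"
  else if (hasBi) "bi_allelic_only"
  else "non_expressing"
}

#' Clone-class distribution from Monte-Carlo lineage simulation
#'
#' Simulates `config$nClones` independent clonal lineages and tabulates
#' the clone classes. Expressing-class fractions condition on clones that
#' expressed at all; the non-expressing count is reported separately (and
#' the distribution is flagged undefined when no clone expressed).
#'
#' @param model an [AllelicModel-class].
#' @param config a [cloneSimConfig()].
#' @param perturbation optional [Perturbation-class].
#' @param observe observation scheme (see [simulateClone()]).
#' @return A [CloneClassDistribution-class]; the pooled per-generation
#'   class counts are attached as attribute `genCounts` for
#'   marginal-consistency diagnostics.
#' @export
cloneClassDistribution <- function(model, config = cloneSimConfig(),
                                   perturbation = NULL,
                                   observe = c("path", "boundary")) {
  sim <- simulateCloneClasses(model, config, perturbation, observe)
  seen <- sim$seen
  cls <- ifelse(seen[, "monoY"] & seen[, "monoR"], "mixed_mono_allelic",
         ifelse(seen[, "monoY"] | seen[, "monoR"], "single_mono_allelic",
         ifelse(seen[, "bi"], "bi_allelic_only", "non_expressing")))
  counts <- table(factor(cls, levels = CLONE_CLASSES))
  counts <- stats::setNames(as.numeric(counts), CLONE_CLASSES)
  expressing <- counts[c("single_mono_allelic", "mixed_mono_allelic",
                         "bi_allelic_only")]
  flagged <- sum(expressing) == 0
  fr <- if (flagged) stats::setNames(rep(NA_real_, 3), names(expressing))
        else expressing / sum(expressing)
  obj <- new("CloneClassDistribution", counts = counts, fractions = fr,
             nClones = config$nClones, modelKind = model@kind,
             seed = config$seed, flagged = flagged)
  attr(obj, "genCounts") <- sim$genCounts
  obj
}

#' Clone-level goodness-of-fit statistic
#'
#' Compares an observed clone-class count against a model-predicted
#' fraction. The default `"single"` form is the one-category statistic
#' `(O - E)^2 / E` with `E = n * expectedFraction`, evaluated against
#' chi-squared with 1 degree of freedom; `"pearson"` adds the
#' complementary category's term `(O - E)^2 / (n - E)`. The one-category
#' form is the paper-compatible default; the two-category Pearson value
#' is systematically larger (by the factor `1/(1 - p)`).
#'
#' @param observed observed count of clones in the class.
#' @param nClones total observed clones.
#' @param expectedFraction model-predicted class fraction, in (0, 1).
#' @param method `"single"` (default) or `"pearson"`.
#' @return list with `statistic`, `df` (= 1), `pValue`, `expected`.
#' @examples
#' cloneClassChi2(7, 9, 0.201)  # statistic 14.9
#' cloneClassChi2(7, 9, 0.639)  # statistic 0.27
#' @export
cloneClassChi2 <- function(observed, nClones, expectedFraction,
                           method = c("single", "pearson")) {
  method <- match.arg(method)
  stopifnot(observed >= 0, observed <= nClones,
            expectedFraction > 0, expectedFraction < 1)
  E <- nClones * expectedFraction
  stat <- (observed - E)^2 / E
  if (method == "pearson")
    stat <- stat + (observed - E)^2 / (nClones - E)
  list(statistic = stat, df = 1,
       pValue = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       expected = E, method = method)
}
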