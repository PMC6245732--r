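## Hidden-state continuous-time Markov models of allelic activation.
##
## Hidden state = (trans step done, cisY open, cisR open). The three model
## families differ only in which combinations exist and which transitions
## are allowed:
##   cis_only   : trans treated as always done -> 4 states (cis flags only)
##   sequential : cis-activation gated on trans -> trans-off states with an
##                open allele do not exist -> 5 states
##   parallel   : all 8 combinations reachable, cis and trans independent
## The observable class collapses the hidden state to what two-color
## fluorescence can distinguish: none / monoY / monoR / bi.

#' Hidden-state space of a candidate model
#'
#' Enumerates the hidden states of one model family. The state diagrams are
#' reconstructed from the models' verbal definitions (single cis switch;
#' trans before cis; independent trans and cis): 4, 5, and 8 states for the
#' cis-only, sequential, and parallel models respectively.
#'
#' @param kind `"cis_only"`, `"sequential"`, or `"parallel"`.
#' @return data.frame with columns `label`, `trans`, `cisY`, `cisR`
#'   (logical flags) and `class` (the observable class of the state).
#' @examples
#' stateSpace("parallel")
#' @export
stateSpace <- function(kind = MODEL_KINDS) {
  kind <- match.arg(kind)
  cached <- .modelCache[[paste0("ss_", kind)]]
  if (!is.null(cached)) return(cached)
  grid <- switch(kind,
    cis_only = expand.grid(trans = TRUE, cisY = c(FALSE, TRUE),
                           cisR = c(FALSE, TRUE)),
    sequential = {
      g <- expand.grid(trans = c(FALSE, TRUE), cisY = c(FALSE, TRUE),
                       cisR = c(FALSE, TRUE))
      g[g$trans | (!g$cisY & !g$cisR), ]   # cis cannot precede trans
    },
    parallel = expand.grid(trans = c(FALSE, TRUE), cisY = c(FALSE, TRUE),
                           cisR = c(FALSE, TRUE)))
  grid <- grid[order(grid$trans, grid$cisY + grid$cisR, grid$cisR), ]
  lab <- function(tr, y, r) {
    cis <- paste0("C", as.integer(y), as.integer(r))
    if (kind == "cis_only") cis else paste0("T", as.integer(tr), ".", cis)
  }
  grid$label <- mapply(lab, grid$trans, grid$cisY, grid$cisR)
  grid$class <- observedClass(grid$trans, grid$cisY, grid$cisR, kind)
  rownames(grid) <- grid$label
  out <- grid[, c("label", "trans", "cisY", "cisR", "class")]
  .modelCache[[paste0("ss_", kind)]] <- out
  out
}

## Per-session cache for the (tiny, immutable) state-space and transition
## tables; rateMatrix sits in the fitting hot path.
.modelCache <- new.env(parent = emptyenv())

#' Observable allelic class of a hidden state
#'
#' Deterministic map from hidden flags to the fluorescence-detectable class.
#' In the parallel model a cell with trans off is non-expressing whatever
#' its cis configuration; otherwise the class follows the two cis flags.
#'
#' @param trans,cisY,cisR logical vectors of hidden flags.
#' @param kind model family (see [stateSpace()]).
#' @return character vector over `"none"`, `"monoY"`, `"monoR"`, `"bi"`.
#' @export
observedClass <- function(trans, cisY, cisR, kind = MODEL_KINDS) {
  kind <- match.arg(kind)
  cls <- ifelse(cisY & cisR, "bi",
         ifelse(cisY, "monoY",
         ifelse(cisR, "monoR", "none")))
  if (kind == "parallel") cls[!trans] <- "none"
  cls
}

#' Construct an allelic-activation model
#'
#' @param kind model family: `"cis_only"`, `"sequential"` or `"parallel"`.
#' @param kC cis-activation rate per allele (/hr).
#' @param kT trans-step rate (/hr); required for the sequential and
#'   parallel models, ignored by `cis_only`.
#' @param kCrev,kTrev reversal rates (/hr); default 0 (irreversible,
#'   the unperturbed baseline).
#' @param init optional named numeric giving the initial probability of
#'   each non-expressing hidden state (must sum to 1). Default: all mass on
#'   the fully naive state (trans off where applicable, both alleles
#'   closed). The number of free initial weights is 0, 1, and 4 for the
#'   cis-only, sequential, and parallel models.
#' @return An [AllelicModel-class] object.
#' @examples
#' AllelicModel("parallel", kC = 0.0042, kT = 0.012)
#' @export
AllelicModel <- function(kind = MODEL_KINDS, kC, kT = 0, kCrev = 0, kTrev = 0,
                         init = NULL) {
  kind <- match.arg(kind)
  assertScalarNumber(kC, "kC", lower = 0)
  assertScalarNumber(kT, "kT", lower = 0)
  assertScalarNumber(kCrev, "kCrev", lower = 0)
  assertScalarNumber(kTrev, "kTrev", lower = 0)
  if (is.null(init)) {
    naive <- if (kind == "cis_only") "C00" else "T0.C00"
    init <- stats::setNames(1, naive)
  }
  ss <- stateSpace(kind)
  full <- stats::setNames(numeric(sum(ss$class == "none")),
                          ss$label[ss$class == "none"])
  if (!all(names(init) %in% names(full)))
    stop("init support outside the model's non-expressing states: ",
         paste(setdiff(names(init), names(full)), collapse = ", "))
  full[names(init)] <- init
  new("AllelicModel", kind = kind, kC = kC, kT = kT, kCrev = kCrev,
      kTrev = kTrev, init = full)
}

#' Construct a perturbation specification
#'
#' @param target `"cis"` or `"trans"` — which reaction step is perturbed.
#' @param forwardFactor multiplier in \[0, 1\] applied to every targeted
#'   forward rate (1 = unperturbed).
#' @param reverseRate rate (/hr) added to every targeted reverse reaction.
#' @param biAttenuation attenuation of the perturbation on transitions
#'   into or out of the bi-allelic expressing state: each modified rate is
#'   interpolated between its unperturbed (weight `1 - biAttenuation`) and
#'   fully perturbed (weight `biAttenuation`) value. Default 0.4, i.e. the
#'   perturbation is ~2.5x weaker once both alleles are active.
#' @return A [Perturbation-class] object.
#' @examples
#' Perturbation("cis", forwardFactor = 0.5, reverseRate = 0.004)
#' @export
Perturbation <- function(target = c("cis", "trans"), forwardFactor = 1,
                         reverseRate = 0, biAttenuation = 0.4) {
  target <- match.arg(target)
  new("Perturbation", target = target, forwardFactor = forwardFactor,
      reverseRate = reverseRate, biAttenuation = biAttenuation)
}

## Elementary transitions of a model: data.frame(from, to, type) with
## type in {cis_fwd, cis_rev, trans_fwd, trans_rev}. A transition exists
## only if its target state exists in the model's state space (this is
## what forbids, e.g., trans reversal of an expressing cell in the
## sequential model).
elementaryTransitions <- function(kind) {
  cached <- .modelCache[[paste0("tr_", kind)]]
  if (!is.null(cached)) return(cached)
  ss <- stateSpace(kind)
  out <- list()
  for (i in seq_len(nrow(ss))) {
    s <- ss[i, ]
    cand <- list()
    for (allele in c("cisY", "cisR")) {
      s2 <- s
      s2[[allele]] <- !s[[allele]]
      type <- if (s[[allele]]) "cis_rev" else "cis_fwd"
      if (type == "cis_fwd" && kind == "sequential" && !s$trans) next
      cand[[length(cand) + 1L]] <- list(s2 = s2, type = type)
    }
    if (kind != "cis_only") {
      s2 <- s
      s2$trans <- !s$trans
      cand[[length(cand) + 1L]] <-
        list(s2 = s2, type = if (s$trans) "trans_rev" else "trans_fwd")
    }
    for (cc in cand) {
      lab2 <- with(cc$s2, {
        cis <- paste0("C", as.integer(cisY), as.integer(cisR))
        if (kind == "cis_only") cis else paste0("T", as.integer(trans), ".", cis)
      })
      if (!(lab2 %in% ss$label)) next
      out[[length(out) + 1L]] <- data.frame(from = s$label, to = lab2,
                                            type = cc$type)
    }
  }
  tr <- do.call(rbind, out)
  tr$fromIdx <- match(tr$from, ss$label)
  tr$toIdx <- match(tr$to, ss$label)
  tr$touchesBi <- ss$class[tr$fromIdx] == "bi" | ss$class[tr$toIdx] == "bi"
  .modelCache[[paste0("tr_", kind)]] <- tr
  tr
}

#' Infinitesimal generator of a model
#'
#' Builds the rate matrix Q of the hidden-state chain: `Q[i, j]` is the
#' rate (/hr) of the `i -> j` transition, diagonal entries make rows sum to
#' zero. Both alleles carry the same cis rates (allele symmetry); in the
#' sequential model cis transitions are impossible while trans is off.
#'
#' When a [Perturbation] is supplied, every targeted forward rate is
#' multiplied by its `forwardFactor` and every targeted reverse rate is
#' increased by its `reverseRate`; on transitions whose source or
#' destination class is `bi`, both modifications are linearly attenuated
#' toward no effect by `biAttenuation`.
#'
#' @param model an [AllelicModel-class].
#' @param perturbation optional [Perturbation-class].
#' @return Square numeric matrix with state labels as dimnames.
#' @examples
#' m <- AllelicModel("parallel", kC = 0.0042, kT = 0.01)
#' Q <- rateMatrix(m)
#' -Q["T0.C00", "T0.C00"]  # total exit rate kT + 2 kC
#' @export
rateMatrix <- function(model, perturbation = NULL) {
  stopifnot(is(model, "AllelicModel"))
  validObject(model)
  if (!is.null(perturbation)) {
    stopifnot(is(perturbation, "Perturbation"))
    validObject(perturbation)
  }
  ss <- stateSpace(model@kind)
  tr <- elementaryTransitions(model@kind)
  base <- c(cis_fwd = model@kC, cis_rev = model@kCrev,
            trans_fwd = model@kT, trans_rev = model@kTrev)
  rate <- unname(base[tr$type])
  if (!is.null(perturbation)) {
    targeted <- if (perturbation@target == "cis")
      tr$type %in% c("cis_fwd", "cis_rev")
    else
      tr$type %in% c("trans_fwd", "trans_rev")
    pert <- rate
    fwd <- targeted & grepl("_fwd$", tr$type)
    rev <- targeted & grepl("_rev$", tr$type)
    pert[fwd] <- rate[fwd] * perturbation@forwardFactor
    pert[rev] <- rate[rev] + perturbation@reverseRate
    a <- ifelse(tr$touchesBi, perturbation@biAttenuation, 1)
    rate <- rate + a * (pert - rate)
  }
  n <- nrow(ss)
  Q <- matrix(0, n, n, dimnames = list(ss$label, ss$label))
  for (k in seq_len(nrow(tr)))
    Q[tr$fromIdx[k], tr$toIdx[k]] <- Q[tr$fromIdx[k], tr$toIdx[k]] + rate[k]
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

## Hidden-state occupancy rows at the requested times: exact matrix
## exponential of Q (state spaces are at most 8 so this is cheap and
## avoids ODE stepping error). p0 is a named probability vector over a
## subset of the state space. A spectral decomposition is used when Q is
## safely diagonalizable (validated against one direct matrix
## exponential); otherwise each time point falls back to Matrix::expm.
occupancyAtTimes <- function(Q, p0, times) {
  n <- nrow(Q)
  p <- numeric(n)
  names(p) <- rownames(Q)
  p[names(p0)] <- p0
  out <- matrix(0, length(times), n, dimnames = list(NULL, rownames(Q)))
  expmRow <- function(t) as.numeric(p %*% as.matrix(Matrix::expm(Q * t)))
  spectral <- NULL
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  if (!is.null(eg) && all(is.finite(Re(eg$values)))) {
    Vinv <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vinv)) {
      ## trust the spectral route only if V Lambda V^-1 reconstructs Q to
      ## near machine precision (guards against near-defective Q)
      recon <- Re(eg$vectors %*% (eg$values * Vinv))
      scale <- max(abs(Q), 1e-12)
      if (max(abs(recon - Q)) < 1e-11 * max(scale, 1)) {
        a <- (p %*% eg$vectors)[1, ]
        spectral <- function(t) Re((a * exp(eg$values * t)) %*% Vinv)[1, ]
      }
    }
  }
  for (i in seq_along(times)) {
    out[i, ] <- if (times[i] == 0) p
    else if (!is.null(spectral)) spectral(times[i])
    else expmRow(times[i])
  }
  out
}

## ODE fallback used for cross-checking the matrix-exponential solution.
occupancyODE <- function(Q, p0, times, rtol = 1e-9) {
  n <- nrow(Q)
  p <- numeric(n); names(p) <- rownames(Q); p[names(p0)] <- p0
  tms <- sort(unique(c(0, times)))
  sol <- deSolve::ode(y = p, times = tms,
                      func = function(t, y, parms) list(as.numeric(y %*% Q)),
                      parms = NULL, rtol = rtol, atol = 1e-12)
  sol[match(times, tms), -1, drop = FALSE]
}

#' Observed-class population fractions over time
#'
#' Solves the hidden-state master equation exactly (matrix exponential of
#' the generator) and marginalizes the occupancy onto the four observable
#' classes.
#'
#' @param model an [AllelicModel-class].
#' @param times non-negative, non-decreasing times in hours.
#' @param perturbation optional [Perturbation-class] applied to the
#'   generator.
#' @return data.frame with columns `time_h`, `f_none`, `f_monoY`,
#'   `f_monoR`, `f_bi`; each row sums to 1.
#' @examples
#' m <- AllelicModel("cis_only", kC = 0.0042)
#' populationFractions(m, times = c(0, 50, 100))
#' @export
populationFractions <- function(model, times, perturbation = NULL) {
  stopifnot(is.numeric(times), all(times >= 0), !is.unsorted(times))
  Q <- rateMatrix(model, perturbation)
  ss <- stateSpace(model@kind)
  occ <- occupancyAtTimes(Q, model@init, times)
  out <- data.frame(time_h = times)
  for (cl in OBSERVED_CLASSES)
    out[[paste0("f_", cl)]] <-
      rowSums(occ[, ss$label[ss$class == cl], drop = FALSE])
  out
}

#' Initial distribution of sorted non-expressing progenitors
#'
#' Progenitor populations are sorted on *fluorescence*, so a
#' "non-expressing" starting population is the model's non-expressing
#' hidden states in the proportions they reach after a pre-culture period
#' — not a point mass on the fully naive state. In the parallel model
#' this includes silently cis-activated (trans-off) sub-states, the
#' model's mechanism for clonal predisposition to same-allele activation;
#' in the sequential model it includes the trans-on, cis-closed sub-state.
#'
#' @param kind model family.
#' @param kC,kT rate constants (/hr).
#' @param preCultureH time (hours) the population evolved from the fully
#'   naive state before sorting (default 100, a multi-day culture).
#' @return named probability vector over the model's non-expressing
#'   hidden states, usable as the `init` argument of [AllelicModel()].
#' @examples
#' sortedNoneInit("parallel", kC = 0.0042, kT = 0.012)
#' @export
sortedNoneInit <- function(kind = MODEL_KINDS, kC, kT = 0, preCultureH = 100) {
  kind <- match.arg(kind)
  m0 <- AllelicModel(kind, kC = kC, kT = kT)
  ss <- stateSpace(kind)
  occ <- occupancyAtTimes(rateMatrix(m0), m0@init, preCultureH)[1, ]
  w <- occ[ss$label[ss$class == "none"]]
  w / sum(w)
}

#' Closed-form class fractions for the cis-only model
#'
#' With two independent, irreversible first-order switches at rate `kC`
#' per allele, the class fractions at time `t` are
#' `none = exp(-2 kC t)`, `monoY = monoR = exp(-kC t)(1 - exp(-kC t))`,
#' `bi = (1 - exp(-kC t))^2`. Used as the analytic oracle for the
#' matrix-exponential solver and for the lag between mono- and bi-allelic
#' appearance (linear vs quadratic leading order in t).
#'
#' @param kC cis-activation rate (/hr), >= 0.
#' @param t time(s) in hours, >= 0.
#' @return matrix with one row per time and columns
#'   `none`, `monoY`, `monoR`, `bi`.
#' @examples
#' cisOnlyFractions(0.0042, c(0, 100))
#' @export
cisOnlyFractions <- function(kC, t) {
  assertScalarNumber(kC, "kC", lower = 0)
  stopifnot(all(t >= 0))
  s <- exp(-kC * t)
  cbind(none = s^2, monoY = s * (1 - s), monoR = s * (1 - s), bi = (1 - s)^2)
}
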