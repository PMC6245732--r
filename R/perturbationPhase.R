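## Phase-space analysis of perturbation responses: populations started
## from non-, mono-, or bi-allelic states are evolved under unperturbed or
## perturbed dynamics to a fixed horizon and summarized as a point
## (F_n, F_m, F_b) in the triangle of allowed compositions (F_m pools the
## two mono-allelic classes). The discriminating signatures are the
## direction of the endpoint shifts with increasing perturbation
## magnitude, not their exact positions.

#' Hidden-state distribution for a sorted start population
#'
#' Builds the initial hidden-state distribution of a population sorted by
#' observable class: `"none"` uses the model's own initial distribution
#' (or a point mass on the fully naive state), `"mono"` splits its mass
#' equally between the two mono-allelic hidden states (trans on where the
#' model has a trans flag — an expressing cell's trans step is complete),
#' `"bi"` is a point mass on the bi-allelic expressing state.
#'
#' @param model an [AllelicModel-class].
#' @param label `"none"`, `"mono"`, or `"bi"`.
#' @return named numeric distribution over hidden states.
#' @export
startPopulation <- function(model, label = c("none", "mono", "bi")) {
  label <- match.arg(label)
  kind <- model@kind
  pre <- if (kind == "cis_only") "" else "T1."
  lab <- function(cis) if (kind == "cis_only") cis else paste0(pre, cis)
  switch(label,
         none = model@init,
         mono = stats::setNames(c(0.5, 0.5), c(lab("C10"), lab("C01"))),
         bi = stats::setNames(1, lab("C11")))
}

#' Phase-space endpoint of an evolved population
#'
#' Evolves a start distribution under the (possibly perturbed) generator
#' to the horizon and marginalizes onto the phase-space coordinates:
#' non-expressing fraction `F_n`, combined mono-allelic fraction `F_m`,
#' and bi-allelic fraction `F_b`.
#'
#' @param model an [AllelicModel-class].
#' @param start `"none"`, `"mono"`, `"bi"`, or a named hidden-state
#'   distribution.
#' @param perturbation optional [Perturbation-class].
#' @param horizonH evolution time in hours (default 96, a four-day
#'   culture).
#' @return named numeric `c(F_n, F_m, F_b)` summing to 1.
#' @examples
#' m <- AllelicModel("parallel", kC = 0.0042, kT = 0.012)
#' phaseEndpoint(m, "none")
#' @export
phaseEndpoint <- function(model, start = "none", perturbation = NULL,
                          horizonH = 96) {
  stopifnot(is(model, "AllelicModel"), horizonH > 0)
  p0 <- if (is.character(start)) startPopulation(model, start) else start
  ss <- stateSpace(model@kind)
  if (!all(names(p0) %in% ss$label))
    stop("start distribution inconsistent with the model's state space")
  Q <- rateMatrix(model, perturbation)
  occ <- occupancyAtTimes(Q, p0, horizonH)[1, ]
  cls <- ss$class
  c(F_n = sum(occ[cls == "none"]),
    F_m = sum(occ[cls %in% c("monoY", "monoR")]),
    F_b = sum(occ[cls == "bi"]))
}

#' Graded perturbation sweep in phase space
#'
#' Applies a perturbation template at increasing magnitudes `m` in
#' \[0, 1\] — the forward factor grades from 1 down to the template's
#' `forwardFactor` and the added reverse rate from 0 up to its
#' `reverseRate` — and records the phase-space endpoint of each start
#' population at each magnitude. Magnitude 0 reproduces the unperturbed
#' endpoint.
#'
#' @param model an [AllelicModel-class].
#' @param starts character vector of start labels (default all three).
#' @param template a [Perturbation-class] defining the full-magnitude
#'   perturbation.
#' @param magnitudes increasing magnitudes in \[0, 1\].
#' @param horizonH evolution time in hours (default 96).
#' @return data.frame with columns `start`, `magnitude`, `F_n`, `F_m`,
#'   `F_b`.
#' @export
perturbationSweep <- function(model, starts = c("none", "mono", "bi"),
                              template, magnitudes = seq(0, 1, 0.25),
                              horizonH = 96) {
  stopifnot(is(template, "Perturbation"), all(magnitudes >= 0),
            all(magnitudes <= 1), !is.unsorted(magnitudes))
  rows <- list()
  for (s in starts) for (m in magnitudes) {
    pert <- new("Perturbation", target = template@target,
                forwardFactor = 1 - m * (1 - template@forwardFactor),
                reverseRate = m * template@reverseRate,
                biAttenuation = template@biAttenuation)
    ep <- phaseEndpoint(model, s, pert, horizonH)
    rows[[length(rows) + 1L]] <-
      data.frame(start = s, magnitude = m,
                 F_n = ep[["F_n"]], F_m = ep[["F_m"]], F_b = ep[["F_b"]])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Decompose reversion flux by path class
#'
#' For a bi-allelic start population under a perturbation with a reverse
#' component, splits the probability mass that has reached the
#' non-expressing class at the horizon by whether the path passed through
#' a mono-allelic observed state. Computed exactly on the hidden-state
#' chain augmented with a "visited mono" flag (states are duplicated, and
#' every transition into a mono-class state sets the flag).
#'
#' @param model an [AllelicModel-class].
#' @param perturbation a [Perturbation-class] (needs `reverseRate > 0`
#'   for any reversion mass to exist).
#' @param start start label or distribution (default `"bi"`).
#' @param horizonH evolution time in hours (default 96).
#' @return named numeric: `direct` (bi -> none without mono intermediates)
#'   and `via_mono` mass, plus `total` reversion mass.
#' @export
classifyReversionPath <- function(model, perturbation, start = "bi",
                                  horizonH = 96) {
  stopifnot(is(model, "AllelicModel"))
  ss <- stateSpace(model@kind)
  Q <- rateMatrix(model, perturbation)
  n <- nrow(ss)
  isMono <- ss$class %in% c("monoY", "monoR")
  isNone <- ss$class == "none"
  ## augmented chain: (state, flag) with flag = visited a mono state
  A <- matrix(0, 2 * n, 2 * n)
  lab <- c(paste0(ss$label, "|0"), paste0(ss$label, "|1"))
  dimnames(A) <- list(lab, lab)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || Q[i, j] == 0) next
    jf <- if (isMono[j]) n + j else j        # entering mono sets the flag
    A[i, jf] <- A[i, jf] + Q[i, j]           # flag 0 source
    A[n + i, n + j] <- A[n + i, n + j] + Q[i, j]  # flag 1 stays 1
  }
  diag(A) <- diag(A) - rowSums(A)
  p0full <- if (is.character(start)) startPopulation(model, start) else start
  startsMono <- isMono[match(names(p0full), ss$label)]
  p0 <- stats::setNames(as.numeric(p0full),
                        paste0(names(p0full), ifelse(startsMono, "|1", "|0")))
  occ <- occupancyAtTimes(A, p0, horizonH)[1, ]
  direct <- sum(occ[which(isNone)])
  via <- sum(occ[n + which(isNone)])
  c(direct = direct, via_mono = via, total = direct + via)
}
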