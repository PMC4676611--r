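## Evaluation: the R_drug treatment score, dose grids and single-agent
## dose-response curves, the Loewe combination index, and the
## one-at-a-time Spearman sensitivity sweep.

#' Composite treatment-efficacy score R_drug
#'
#' \code{R_drug = N_MM120 * |N_OC120 - N_OC0| * |N_OB120 - N_OB0|}:
#' zero iff the tumor is eradicated or either bone lineage is exactly
#' rebalanced; lower is better.
#'
#' @param counts named numeric with \code{N_MM120, N_OC120, N_OB120,
#'   N_OC0, N_OB0} (order suffices), or a [SimulationResult-class].
#' @return non-negative score.
#' @examples
#' rDrug(c(2, 5, 1, 3, 4))  # 2 * |5-3| * |1-4| = 12
#' @export
rDrug <- function(counts) {
  if (is(counts, "SimulationResult")) counts <- endpointCounts(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  unname(counts[1] * abs(counts[2] - counts[4]) * abs(counts[3] - counts[5]))
}

#' Geometric dose grid
#'
#' \code{n} dose levels geometric from \code{lo} to \code{hi} times the
#' reference dose (default 20 levels, 0.1x to 10x, consecutive ratio
#' \code{100^(1/19)}).
#'
#' @param reference reference dose (> 0).
#' @param nLevels number of levels (>= 2).
#' @param lo,hi range multipliers.
#' @return strictly increasing numeric vector.
#' @export
geometricDoseGrid <- function(reference, nLevels = 20L, lo = 0.1, hi = 10) {
  if (reference <= 0) stop("reference dose must be > 0")
  if (nLevels < 2L) stop("nLevels must be >= 2")
  k <- seq_len(nLevels) - 1L
  reference * lo * (hi / lo)^(k / (nLevels - 1L))
}

#' Single-agent dose-response curve
#'
#' Runs single-drug regimens at each dose level, averaging R_drug over
#' replicates.  The result carries the reference dose and a
#' \code{nonMonotone} flag; downstream interpolation is restricted to
#' the monotone branch containing the reference dose.
#'
#' @param drug \code{"BHQ880"}, \code{"GC"} or \code{"LDM"}.
#' @param doseLevels numeric vector of dose levels (>= 2).
#' @param config base configuration.
#' @param replicates replicates per level.
#' @param seeds master seeds, length \code{replicates}.
#' @param reference reference dose defining the monotone branch.
#' @param simulator function \code{(config, seed, schedule) ->
#'   SimulationResult}; replaceable by analytic fixtures in tests.
#' @return data.frame (\code{dose}, \code{effect}) with attributes
#'   \code{reference} and \code{nonMonotone}.
#' @export
doseResponseCurve <- function(drug, doseLevels, config = defaultConfig(),
                              replicates = 1L, seeds = seq_len(replicates),
                              reference = 1,
                              simulator = runSimulation) {
  if (length(doseLevels) < 2L) stop("need >= 2 dose levels")
  if (!drug %in% .DRUGS) stop("unknown drug: ", drug)
  eff <- vapply(doseLevels, function(d) {
    args <- stats::setNames(list(d), drug)
    sched <- do.call(doseSchedule, args)
    mean(vapply(seeds, function(s)
      rDrug(simulator(config, seed = s, schedule = sched)), 0))
  }, 0)
  curveFromSamples(doseLevels, eff, reference = reference)
}

#' Assemble a dose-response curve object
#'
#' @param dose,effect numeric vectors (doses strictly increasing).
#' @param reference reference dose.
#' @return curve data.frame as in [doseResponseCurve()].
#' @export
curveFromSamples <- function(dose, effect, reference = 1) {
  ord <- order(dose)
  dose <- dose[ord]; effect <- effect[ord]
  if (any(diff(dose) <= 0)) stop("dose levels must be distinct")
  d <- diff(effect)
  nonMono <- any(d > 0) && any(d < 0)
  out <- data.frame(dose = dose, effect = effect)
  attr(out, "reference") <- reference
  attr(out, "nonMonotone") <- nonMono
  out
}

## maximal monotone run of the effect sequence containing index i0
.monotoneBranch <- function(effect, i0) {
  n <- length(effect)
  if (n < 2L) return(seq_len(n))
  d <- sign(diff(effect))
  seg <- if (i0 < n && d[i0] != 0) d[i0] else if (i0 > 1L) d[i0 - 1L] else d[1L]
  if (seg == 0) seg <- if (any(d != 0)) d[which(d != 0)[1L]] else 1
  lo <- i0
  while (lo > 1L && (d[lo - 1L] == seg || d[lo - 1L] == 0)) lo <- lo - 1L
  hi <- i0
  while (hi < n && (d[hi] == seg || d[hi] == 0)) hi <- hi + 1L
  lo:hi
}

#' Equi-effective single-agent dose
#'
#' Inverts a dose-response curve at \code{target} by monotone piecewise
#' linear interpolation in log-dose, restricted to the monotone branch
#' containing the reference dose.  No extrapolation: a target outside
#' the branch's achieved effect range is an error.
#'
#' @param curve a curve from [doseResponseCurve()] /
#'   [curveFromSamples()].
#' @param target effect (R_drug) value to invert at.
#' @return dose achieving \code{target}.
#' @export
equiEffectiveDose <- function(curve, target) {
  ref <- attr(curve, "reference")
  i0 <- which.min(abs(log(curve$dose) - log(ref)))
  br <- .monotoneBranch(curve$effect, i0)
  eff <- curve$effect[br]; ld <- log(curve$dose[br])
  if (target < min(eff) || target > max(eff))
    stop("target effect ", target,
         " outside the achieved range [", min(eff), ", ", max(eff),
         "] of the monotone branch")
  hit <- which(eff == target)
  if (length(hit)) return(exp(ld[hit[1L]]))
  exp(stats::approx(x = eff, y = ld, xout = target, ties = "ordered")$y)
}

#' Loewe combination index
#'
#' \code{CI = d1/GCx(1) + d2/GCx(2) + d3/GCx(3)} where \code{GCx(i)} is
#' the single-agent dose of drug \code{i} reaching the target effect
#' (default R_drug = 960).  CI < 1 indicates Loewe synergy, CI = 1
#' additivity, CI > 1 antagonism.  Drugs with combination dose 0 are
#' skipped.
#'
#' @param comboDoses named numeric (subset of BHQ880, GC, LDM): the
#'   combination doses achieving the target effect.
#' @param singleCurves named list of single-agent curves.
#' @param target target effect (R_drug threshold), default 960.
#' @return list with \code{CI}, \code{GCx}, \code{doses}, \code{target}
#'   and \code{verdict} (\code{"synergy"}, \code{"additivity"} or
#'   \code{"antagonism"}).
#' @export
loeweCI <- function(comboDoses, singleCurves, target = 960) {
  used <- names(comboDoses)[comboDoses > 0]
  if (!length(used)) stop("no positive combination dose given")
  gcx <- vapply(used, function(d) {
    if (is.null(singleCurves[[d]]))
      stop("no single-agent curve for ", d)
    equiEffectiveDose(singleCurves[[d]], target)
  }, 0)
  ci <- sum(unlist(comboDoses[used]) / gcx)
  verdict <- if (abs(ci - 1) < 1e-9) "additivity"
             else if (ci < 1) "synergy" else "antagonism"
  list(CI = ci, GCx = gcx, doses = comboDoses, target = target,
       verdict = verdict)
}

## Spearman rho with the t-approximation p-value (n-2 df).
.spearman <- function(x, y) {
  n <- length(x)
  if (n < 3L || length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(c(rho = NA_real_, p = NA_real_))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(c(rho = rho, p = 0))
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  c(rho = rho, p = 2 * stats::pt(-abs(tval), df = n - 2))
}

#' One-at-a-time Spearman sensitivity sweep
#'
#' Varies each named parameter over its range while holding all others
#' at their base values; for each setting the simulation is repeated
#' \code{nSims} times (seeded) and the per-type final counts are
#' averaged.  Spearman's rank correlation of parameter value versus mean
#' final count is reported per cell type with a t-approximation p-value
#' (df = number of settings - 2).  Constant outcomes give NA, not 0.
#'
#' @param parameterRanges named list; each element a numeric vector of
#'   >= 3 values for one \code{config$parameters} entry.
#' @param config base configuration.
#' @param nSims simulations per setting (default 10).
#' @param seeds master seeds, length \code{nSims}.
#' @param simulator function \code{(config, seed) -> SimulationResult};
#'   replaceable in tests.
#' @return data.frame with columns \code{parameter, cellType, rho, p}.
#' @export
sensitivitySpearman <- function(parameterRanges, config = defaultConfig(),
                                nSims = 10L, seeds = seq_len(nSims),
                                simulator = runSimulation) {
  cfg <- validateConfig(config)
  rows <- list()
  for (pn in names(parameterRanges)) {
    vals <- parameterRanges[[pn]]
    if (length(vals) < 3L) stop("range for ", pn, " needs >= 3 values")
    if (!pn %in% names(cfg$parameters))
      stop("unknown parameter: ", pn)
    outc <- matrix(0, nrow = length(vals), ncol = 3L,
                   dimnames = list(NULL, .CELL_TYPES))
    for (v in seq_along(vals)) {
      c2 <- cfg
      c2$parameters[[pn]] <- vals[v]
      finals <- vapply(seeds, function(s) {
        res <- simulator(c2, seed = s)
        cm <- cellCounts(res)
        cm[nrow(cm), ]
      }, numeric(3L))
      outc[v, ] <- rowMeans(finals)
    }
    for (ct in .CELL_TYPES) {
      sp <- .spearman(vals, outc[, ct])
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = pn, cellType = ct, rho = sp[["rho"]], p = sp[["p"]],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
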