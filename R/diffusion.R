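## Tissue scale: explicit per-step update of cytokine and drug fields.
## C'(P) = [C(P)(1-lambda) + (lambda/6) * sum_{6 neighbors} C
##          + chi(P) * influx] * (1 - decay)
## with no-flux (default, mass conserving) or absorbing boundaries.

#' @useDynLib myelomaABM, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.latticeStep <- function(field, lambda, srcIdx, influx, uniformInflux,
                         decay, boundary) {
  dims <- dim(field)
  out <- .latticeStepC(as.numeric(field), as.integer(dims), lambda,
                       as.integer(srcIdx), influx, uniformInflux, decay,
                       boundary == "noflux")
  array(out, dim = dims)
}

.checkDiffParams <- function(lambda, decay) {
  if (lambda < 0 || lambda > 1) stop("diffusivity must be in [0,1]")
  if (decay < 0 || decay > 1) stop("degradation/uptake must be in [0,1]")
}

#' One diffusion-secretion-degradation step for a cytokine field
#'
#' @param field non-negative numeric 3D array.
#' @param sourceMask logical array marking secreting-cell sites (or NULL
#'   for no sources).
#' @param params parameter list; uses \code{lambda_C}, \code{Se_G},
#'   \code{DEG}.
#' @param boundary \code{"noflux"} (default) or \code{"absorbing"}.
#' @return updated field, same shape, non-negative.
#' @export
cytokineStep <- function(field, sourceMask, params, boundary = "noflux") {
  .checkDiffParams(params$lambda_C, params$DEG)
  src <- if (is.null(sourceMask)) integer(0) else which(sourceMask)
  .latticeStep(field, params$lambda_C, src, params$Se_G, 0,
               params$DEG, boundary)
}

#' One diffusion-influx-uptake step for a drug field
#'
#' Influx \code{Pe_d * dose} is applied at the sites flagged by
#' \code{sourceMask} (or everywhere if \code{uniform = TRUE}, modeling
#' vascular delivery) while the schedule is active; uptake removes the
#' fraction \code{U_d} per step.
#'
#' @inheritParams cytokineStep
#' @param dose relative dose level scaling the influx.
#' @param uniform if TRUE ignore \code{sourceMask} and inject at every
#'   site.
#' @return updated field.
#' @export
drugStep <- function(field, sourceMask, params, dose = 1,
                     uniform = FALSE, boundary = "noflux") {
  .checkDiffParams(params$lambda_d, params$U_d)
  influx <- params$Pe_d * dose
  if (uniform)
    .latticeStep(field, params$lambda_d, integer(0), 0, influx,
                 params$U_d, boundary)
  else {
    src <- if (is.null(sourceMask)) integer(0) else which(sourceMask)
    .latticeStep(field, params$lambda_d, src, influx, 0,
                 params$U_d, boundary)
  }
}

#' Secretion / influx source masks for every species
#'
#' DKK1 and RANKL are secreted at MM-occupied sites, OPG at OB sites and
#' TNFa at OC sites.  Drug masks depend on the delivery mode: with
#' \code{drug_source = "uniform"} every site receives influx while the
#' drug's schedule is active; \code{"as_printed"} restricts influx to
#' OC-occupied sites.  Inactive drugs get an all-FALSE mask.
#'
#' @param state a [TumorState-class].
#' @param dosingActive named logical (BHQ880, GC, LDM).
#' @param drugSource \code{"uniform"} or \code{"as_printed"}.
#' @return named list of logical arrays, one per species.
#' @export
buildSourceMasks <- function(state, dosingActive = c(BHQ880 = FALSE,
                                                     GC = FALSE,
                                                     LDM = FALSE),
                             drugSource = "uniform") {
  dims <- dim(state@occupancy)
  a <- state@agents
  live <- a[a$alive, , drop = FALSE]
  maskFor <- function(type) {
    m <- array(FALSE, dim = dims)
    rows <- live[live$type == type, , drop = FALSE]
    if (nrow(rows)) m[.linIndex(rows$i, rows$j, rows$k, dims)] <- TRUE
    m
  }
  mmMask <- maskFor("MM"); obMask <- maskFor("OB"); ocMask <- maskFor("OC")
  drugMask <- function(active) {
    if (!active) array(FALSE, dim = dims)
    else if (drugSource == "uniform") array(TRUE, dim = dims)
    else ocMask
  }
  list(DKK1 = mmMask, RANKL = mmMask, OPG = obMask, TNFa = ocMask,
       BHQ880 = drugMask(isTRUE(dosingActive[["BHQ880"]])),
       GC     = drugMask(isTRUE(dosingActive[["GC"]])),
       LDM    = drugMask(isTRUE(dosingActive[["LDM"]])))
}
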