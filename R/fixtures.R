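## Deterministic synthetic fixtures: tiny grids with explicit agent
## layouts and field presets, plus analytic dose-response curves, so
## every operation is testable in milliseconds.

#' Build a small deterministic grid fixture
#'
#' @param dims integer triple (default 5x5x5).
#' @param agents data.frame with columns \code{type, i, j, k}; may be
#'   empty or NULL.
#' @param fields named list of presets, one per species (missing species
#'   are zero).  A preset is either a numeric array of the grid shape, a
#'   single number (uniform field), or a list \code{list(kind =
#'   "point", site = c(i,j,k), value = v)} /
#'   \code{list(kind = "ramp", axis = 1..3, from, to)}.
#' @param spacing lattice spacing (um).
#' @return a [TumorState-class] with exactly the requested agents and
#'   fields.
#' @examples
#' st <- makeGridFixture(agents = data.frame(type = "MM", i = 3, j = 3, k = 3))
#' @export
makeGridFixture <- function(dims = c(5L, 5L, 5L), agents = NULL,
                            fields = list(), spacing = 5) {
  dims <- as.integer(dims)
  fl <- .emptyFields(dims)
  for (nm in names(fields)) {
    if (!nm %in% .FIELDS) stop("unknown field in fixture spec: ", nm)
    fl[[nm]] <- .fieldPreset(fields[[nm]], dims)
    if (any(fl[[nm]] < 0)) stop("fixture fields must be non-negative")
  }
  a <- .newAgents()
  occ <- array(0L, dim = dims)
  if (!is.null(agents) && nrow(agents)) {
    if (!all(agents$type %in% .CELL_TYPES))
      stop("unknown cell type in fixture spec")
    if (any(agents$i < 1 | agents$i > dims[1] |
            agents$j < 1 | agents$j > dims[2] |
            agents$k < 1 | agents$k > dims[3]))
      stop("fixture agent out of bounds")
    if (anyDuplicated(paste(agents$i, agents$j, agents$k)))
      stop("duplicate agent position in fixture spec")
    n <- nrow(agents)
    a <- .newAgents(n)
    a$type <- as.character(agents$type)
    a$i <- as.integer(agents$i); a$j <- as.integer(agents$j)
    a$k <- as.integer(agents$k)
    a$age <- if (!is.null(agents$age)) agents$age else 0
    a$phenotype <- if (!is.null(agents$phenotype)) agents$phenotype
                   else "quiescent"
    a$phase <- if (!is.null(agents$phase)) agents$phase else "none"
    a$phaseStep <- if (!is.null(agents$phaseStep)) agents$phaseStep else 0L
    a$countdown <- if (!is.null(agents$countdown)) agents$countdown else 0L
    a$rest <- if (!is.null(agents$rest)) agents$rest else 0L
    a$alive <- TRUE
    occ[.linIndex(a$i, a$j, a$k, dims)] <- seq_len(n)
  }
  new("TumorState", agents = a, occupancy = occ, fields = fl,
      spacing = spacing)
}

.fieldPreset <- function(preset, dims) {
  if (is.array(preset)) {
    if (!identical(dim(preset), dims)) stop("preset array shape mismatch")
    return(preset)
  }
  if (is.numeric(preset) && length(preset) == 1L)
    return(array(preset, dim = dims))
  if (is.list(preset)) {
    f <- array(0, dim = dims)
    if (identical(preset$kind, "point")) {
      s <- preset$site
      f[s[1], s[2], s[3]] <- preset$value
      return(f)
    }
    if (identical(preset$kind, "ramp")) {
      ax <- preset$axis
      v <- seq(preset$from, preset$to, length.out = dims[ax])
      idx <- slice.index(f, ax)
      return(array(v[idx], dim = dims))
    }
  }
  stop("unknown field preset")
}

#' Analytic dose-response curve fixtures
#'
#' \code{linear}: effect = a + b * log(dose) (closed-form invertible);
#' \code{hill}: effect = top / (1 + (K / dose)^2) (half of \code{top} at
#' dose K); \code{nonmonotone}: a parabola in log-dose with a rebound,
#' raising the monotone-branch flag downstream.
#'
#' @param kind \code{"linear"}, \code{"hill"} or \code{"nonmonotone"}.
#' @param doses dose levels (default [geometricDoseGrid()] of 1).
#' @param params named list of curve constants (\code{a}, \code{b},
#'   \code{top}, \code{K}, \code{dip} as applicable).
#' @param reference reference dose recorded on the curve.
#' @return curve data.frame as from [curveFromSamples()].
#' @export
makeCurveFixture <- function(kind, doses = geometricDoseGrid(1),
                             params = list(), reference = 1) {
  p <- utils::modifyList(list(a = 0, b = 1, top = 1, K = 1, dip = 1), params)
  eff <- switch(kind,
    linear = p$a + p$b * log(doses),
    hill = p$top / (1 + (p$K / doses)^2),
    nonmonotone = p$a + (log(doses) - log(p$dip))^2,
    stop("unknown curve kind: ", kind))
  curveFromSamples(doses, eff, reference = reference)
}
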