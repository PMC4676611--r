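#' @import methods
NULL

## Internal coding tables shared across the package.
.CELL_TYPES  <- c("MM", "OB", "OC")
.PHENOTYPES  <- c("migrating", "proliferating", "quiescent", "apoptotic")
.PHASES      <- c("none", "G0G1", "S", "G2", "M")
.CYTOKINES   <- c("DKK1", "RANKL", "OPG", "TNFa")
.DRUGS       <- c("BHQ880", "GC", "LDM")
.FIELDS      <- c(.CYTOKINES, .DRUGS)
.APOPTOSIS_STEPS <- 10L

#' DoseSchedule: per-drug dosing window
#'
#' Holds, for each of the three drugs (BHQ880, glucocorticoids as
#' \code{GC}, Lidamycin as \code{LDM}), a relative dose level and the
#' half-open window of simulation steps \code{[start, stop)} during which
#' the drug is delivered.
#'
#' @slot schedule a data.frame with rownames \code{BHQ880, GC, LDM} and
#'   columns \code{dose}, \code{start}, \code{stop}.
#' @seealso [doseSchedule()], [standardRegimens()]
#' @export
setClass("DoseSchedule", representation(schedule = "data.frame"))

setValidity("DoseSchedule", function(object) {
  s <- object@schedule
  if (!identical(rownames(s), .DRUGS))
    return("schedule rownames must be BHQ880, GC, LDM")
  if (!all(c("dose", "start", "stop") %in% colnames(s)))
    return("schedule needs columns dose, start, stop")
  if (any(s$dose < 0)) return("dose must be >= 0")
  if (any(s$start > s$stop)) return("start must be <= stop")
  TRUE
})

#' TumorState: agents, occupancy and lattice fields
#'
#' The full spatial state of the simulation: one row per agent (alive or
#' completing apoptosis), an occupancy array with at most one agent per
#' lattice site, and one non-negative scalar field per cytokine
#' (DKK1, RANKL, OPG, TNFa) and drug (BHQ880, GC, LDM).
#'
#' @slot agents data.frame with columns \code{type} (MM/OB/OC), integer
#'   lattice coordinates \code{i,j,k}, \code{age} (hours),
#'   \code{phenotype}, cell-cycle \code{phase}, \code{phaseStep} (steps
#'   spent in the current phase), \code{countdown} (apoptosis steps
#'   remaining, 10 at entry) and \code{alive}.
#' @slot occupancy integer array, 0 for empty or the row index of the
#'   occupying agent.
#' @slot fields named list of numeric arrays (one per species), each with
#'   the grid's dimensions.
#' @slot spacing lattice spacing in micrometers (default 5).
#' @export
setClass("TumorState",
         representation(agents = "data.frame", occupancy = "array",
                        fields = "list", spacing = "numeric"))

setValidity("TumorState", function(object) {
  a <- object@agents
  occ <- object@occupancy
  d <- dim(occ)
  if (length(d) != 3L) return("occupancy must be a 3D array")
  if (!identical(sort(names(object@fields)), sort(.FIELDS)))
    return(paste("fields must be named", paste(.FIELDS, collapse = ", ")))
  for (f in object@fields) {
    if (!identical(dim(f), d)) return("field shape must equal grid shape")
    if (any(f < 0)) return("fields must be non-negative")
  }
  if (nrow(a)) {
    live <- which(a$alive)
    if (any(a$i < 1 | a$i > d[1] | a$j < 1 | a$j > d[2] |
            a$k < 1 | a$k > d[3]))
      return("agent position outside grid bounds")
    key <- paste(a$i[live], a$j[live], a$k[live])
    if (anyDuplicated(key)) return("two agents occupy the same site")
    if (!all(a$type %in% .CELL_TYPES)) return("unknown cell type")
    if (!all(a$phenotype %in% .PHENOTYPES)) return("unknown phenotype")
    if (!all(a$phase %in% .PHASES)) return("unknown cycle phase")
    if (any(a$countdown < 0 | a$countdown > .APOPTOSIS_STEPS))
      return("apoptosis countdown out of [0,10]")
    bad <- (a$phase != "none") != (a$phenotype == "proliferating")
    if (any(bad[a$alive]))
      return("cycle phase must be set iff phenotype is proliferating")
  }
  if (object@spacing <= 0) return("spacing must be > 0")
  TRUE
})

#' SimulationResult: recorded trajectory of one simulation
#'
#' @slot counts integer matrix with \code{T+1} rows (steps 0..T) and
#'   columns \code{MM, OB, OC}; row \code{t+1} holds the population after
#'   step \code{t}.
#' @slot snapshots data.frame (\code{step, type, i, j, k}) of agent
#'   positions at the configured snapshot steps.
#' @slot config the configuration list the run used (echo).
#' @slot seed integer master seed of the run.
#' @export
setClass("SimulationResult",
         representation(counts = "matrix", snapshots = "data.frame",
                        config = "list", seed = "integer"))

setValidity("SimulationResult", function(object) {
  if (!identical(colnames(object@counts), .CELL_TYPES))
    return("counts columns must be MM, OB, OC")
  if (any(object@counts < 0)) return("counts must be non-negative")
  TRUE
})

setMethod("show", "DoseSchedule", function(object) {
  cat("DoseSchedule (steps are half-open [start, stop))\n")
  print(object@schedule)
})

setMethod("show", "TumorState", function(object) {
  d <- dim(object@occupancy)
  a <- object@agents
  cat(sprintf("TumorState: %d x %d x %d lattice (%g um spacing)\n",
              d[1], d[2], d[3], object@spacing))
  if (nrow(a)) {
    tab <- table(factor(a$type[a$alive], levels = .CELL_TYPES))
    cat("  agents:", paste(sprintf("%s=%d", names(tab), tab),
                           collapse = ", "), "\n")
  } else cat("  agents: none\n")
  tot <- vapply(object@fields, sum, 0)
  cat("  field mass:", paste(sprintf("%s=%.3g", names(tot), tot),
                             collapse = ", "), "\n")
})

setMethod("show", "SimulationResult", function(object) {
  n <- nrow(object@counts)
  cat(sprintf("SimulationResult: %d steps (seed %d)\n", n - 1L,
              object@seed))
  cat("  initial:", paste(sprintf("%s=%d", .CELL_TYPES,
                                  object@counts[1, ]), collapse = ", "), "\n")
  cat("  final:  ", paste(sprintf("%s=%d", .CELL_TYPES,
                                  object@counts[n, ]), collapse = ", "), "\n")
})

#' Construct a dosing schedule
#'
#' @param BHQ880,GC,LDM relative dose level per drug (0 disables a drug).
#' @param start,stop dosing window in simulation steps, half-open
#'   \code{[start, stop)}; defaults 20 and 60.
#' @return a [DoseSchedule-class] object.
#' @examples
#' doseSchedule(BHQ880 = 1, GC = 1, LDM = 1)
#' @export
doseSchedule <- function(BHQ880 = 0, GC = 0, LDM = 0, start = 20, stop = 60) {
  s <- data.frame(dose = c(BHQ880, GC, LDM),
                  start = rep_len(start, 3L), stop = rep_len(stop, 3L),
                  row.names = .DRUGS)
  new("DoseSchedule", schedule = s)
}

#' The seven standard treatment regimens
#'
#' Single drugs, the three pairwise combinations and the triple
#' combination, all at equal relative dose (1:1 ratio) over the same
#' dosing window.
#'
#' @param dose relative dose given to every active drug.
#' @param start,stop dosing window (steps).
#' @return named list of seven [DoseSchedule-class] objects.
#' @export
standardRegimens <- function(dose = 1, start = 20, stop = 60) {
  combos <- list(
    "BHQ880"            = c(1, 0, 0),
    "GCs"               = c(0, 1, 0),
    "Lidamycin"         = c(0, 0, 1),
    "BHQ880/GCs"        = c(1, 1, 0),
    "BHQ880/Lidamycin"  = c(1, 0, 1),
    "GCs/Lidamycin"     = c(0, 1, 1),
    "BHQ880/GCs/Lidamycin" = c(1, 1, 1))
  lapply(combos, function(m)
    doseSchedule(BHQ880 = dose * m[1], GC = dose * m[2], LDM = dose * m[3],
                 start = start, stop = stop))
}
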