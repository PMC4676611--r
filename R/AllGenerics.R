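#' Accessors for simulation objects
#'
#' \code{cellCounts} returns the per-step population matrix of a
#' [SimulationResult-class] (rows = steps 0..T, columns MM/OB/OC);
#' \code{snapshots} the recorded agent positions; \code{agents},
#' \code{fields}, \code{occupancy} and \code{gridDims} expose the slots
#' of a [TumorState-class]; \code{endpointCounts} extracts the count
#' vector that feeds the R_drug score.
#'
#' @param object a [SimulationResult-class] or [TumorState-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cellCounts", function(object) standardGeneric("cellCounts"))
#' @rdname accessors
#' @export
setGeneric("snapshots", function(object) standardGeneric("snapshots"))
#' @rdname accessors
#' @export
setGeneric("agents", function(object) standardGeneric("agents"))
#' @rdname accessors
#' @export
setGeneric("fields", function(object) standardGeneric("fields"))
#' @rdname accessors
#' @export
setGeneric("occupancy", function(object) standardGeneric("occupancy"))
#' @rdname accessors
#' @export
setGeneric("gridDims", function(object) standardGeneric("gridDims"))
#' @rdname accessors
#' @export
setGeneric("endpointCounts", function(object) standardGeneric("endpointCounts"))

#' @rdname accessors
setMethod("cellCounts", "SimulationResult", function(object) object@counts)
#' @rdname accessors
setMethod("snapshots", "SimulationResult", function(object) object@snapshots)
#' @rdname accessors
setMethod("agents", "TumorState", function(object) object@agents)
#' @rdname accessors
setMethod("fields", "TumorState", function(object) object@fields)
#' @rdname accessors
setMethod("occupancy", "TumorState", function(object) object@occupancy)
#' @rdname accessors
setMethod("gridDims", "TumorState", function(object) dim(object@occupancy))

#' @rdname accessors
setMethod("endpointCounts", "SimulationResult", function(object) {
  n <- nrow(object@counts)
  c(N_MM120 = unname(object@counts[n, "MM"]),
    N_OC120 = unname(object@counts[n, "OC"]),
    N_OB120 = unname(object@counts[n, "OB"]),
    N_OC0   = unname(object@counts[1, "OC"]),
    N_OB0   = unname(object@counts[1, "OB"]))
})
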