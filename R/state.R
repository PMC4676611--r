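#' Face neighbors of a lattice site
#'
#' The six sites at Manhattan distance 1 (von Neumann neighborhood),
#' truncated at the grid boundary, in the fixed order
#' \code{+i, -i, +j, -j, +k, -k}.
#'
#' @param position integer triple (i, j, k), 1-based.
#' @param dims grid dimensions, integer triple.
#' @return integer matrix with one row per in-bounds neighbor.
#' @examples
#' faceNeighbors(c(1, 1, 1), c(5, 5, 5))  # corner: 3 neighbors
#' @export
faceNeighbors <- function(position, dims) {
  if (length(position) != 3L || length(dims) != 3L)
    stop("position and dims must be integer triples")
  if (any(position < 1L) || any(position > dims))
    stop("position out of grid bounds")
  off <- matrix(c(1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1),
                ncol = 3L, byrow = TRUE)
  nb <- sweep(off, 2L, as.numeric(position), "+")
  keep <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
  matrix(as.integer(nb[keep, , drop = FALSE]), ncol = 3L,
         dimnames = list(NULL, c("i", "j", "k")))
}

#' Number of occupied face neighbors
#'
#' Counts the face neighbors of \code{position} holding a living
#' (not yet absorbed) agent; apoptotic agents still occupy their site
#' until absorption completes.
#'
#' @param position integer triple.
#' @param occupancy integer occupancy array (0 = empty) or a
#'   [TumorState-class].
#' @return integer in 0..6.
#' @export
countOccupiedNeighbors <- function(position, occupancy) {
  if (is(occupancy, "TumorState")) occupancy <- occupancy@occupancy
  nb <- faceNeighbors(position, dim(occupancy))
  if (!nrow(nb)) return(0L)
  sum(occupancy[nb] != 0L)
}

## Linear index helper (1-based) for (i,j,k) triples on dims.
.linIndex <- function(i, j, k, dims) {
  i + (j - 1L) * dims[1] + (k - 1L) * dims[1] * dims[2]
}

## All sites of the lattice ball of radius r (Euclidean, lattice units)
## around center, clipped to the grid.
.ballSites <- function(center, r, dims) {
  lo <- pmax(1L, as.integer(floor(center - r)))
  hi <- pmin(as.integer(dims), as.integer(ceiling(center + r)))
  g <- expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3])
  d2 <- (g$i - center[1])^2 + (g$j - center[2])^2 + (g$k - center[3])^2
  g[d2 <= r^2, , drop = FALSE]
}

.emptyFields <- function(dims) {
  z <- array(0, dim = dims)
  stats::setNames(lapply(.FIELDS, function(f) z), .FIELDS)
}

.newAgents <- function(n = 0L) {
  data.frame(type = character(n), i = integer(n), j = integer(n),
             k = integer(n), age = numeric(n),
             phenotype = character(n), phase = character(n),
             phaseStep = integer(n), countdown = integer(n),
             rest = integer(n), alive = logical(n),
             stringsAsFactors = FALSE)
}

#' Initialize the simulation state
#'
#' Places the requested number of MM, OB and OC agents on distinct sites,
#' uniformly at random within the smallest central lattice ball that
#' holds them all, with ages uniform on \[0, 24\] hours and all cytokine
#' and drug fields zero.
#'
#' @param config configuration list (see [defaultConfig()]); grid and
#'   \code{initial_counts} are used.
#' @param seed integer seed for placement.
#' @return a [TumorState-class].
#' @examples
#' st <- initializeState(list(grid = list(nx = 21, ny = 21, nz = 21),
#'                            initial_counts = list(MM = 20, OB = 20, OC = 20)),
#'                       seed = 1)
#' st
#' @export
initializeState <- function(config, seed = 1L) {
  cfg <- validateConfig(config)
  dims <- as.integer(unlist(cfg$grid[c("nx", "ny", "nz")]))
  counts <- unlist(cfg$initial_counts[.CELL_TYPES])
  total <- sum(counts)
  occ <- array(0L, dim = dims)
  state <- new("TumorState", agents = .newAgents(), occupancy = occ,
               fields = .emptyFields(dims), spacing = cfg$grid$spacing)
  if (total == 0L) return(state)

  center <- (dims + 1) / 2
  rmax <- sqrt(sum(pmax(center - 1, dims - center)^2))
  r <- 0
  repeat {
    sites <- .ballSites(center, r, dims)
    if (nrow(sites) >= total) break
    if (r > rmax) stop("initial counts exceed central sphere capacity")
    r <- r + 1  # smallest integer radius whose ball holds the agents
  }
  set.seed(as.integer(seed))
  pick <- sites[sample.int(nrow(sites), total), , drop = FALSE]
  type <- sample(rep(.CELL_TYPES, times = counts))
  a <- .newAgents(total)
  a$type <- type
  a$i <- pick$i; a$j <- pick$j; a$k <- pick$k
  a$age <- stats::runif(total, 0, 24)
  a$phenotype <- "quiescent"
  a$phase <- "none"
  a$alive <- TRUE
  ## Start each cell at a random position of its proliferative cycle with
  ## the steady-state in-cycle probability C/(C + 1/p0), where p0 is the
  ## zero-field gate probability; avoids artificial division waves from a
  ## synchronized first cycle.
  par <- cfg$parameters
  p0 <- c(MM = par$P0_mm,
          OB = min(1, par$P0_ob + par$beta_ob *
                     .hill2(par$E0 + par$beta_w, par$K_W)),
          OC = min(1, par$P0_oc + par$P_pathway_oc))
  for (ct in .CELL_TYPES) {
    rows <- which(a$type == ct)
    if (!length(rows)) next
    L <- as.integer(unlist(cfg$cycle[[ct]][c("G0G1", "S", "G2", "M")]))
    C <- sum(L)
    f <- C / (C + cfg$cycle[[ct]]$rest / p0[[ct]])
    rest <- as.integer(cfg$cycle[[ct]]$rest)
    if (rest > 1L)   # stagger the first gate attempts of resting cells
      a$rest[rows] <- as.integer(floor(stats::runif(length(rows)) * rest))
    inCycle <- rows[stats::runif(length(rows)) < f]
    if (!length(inCycle)) next
    g <- floor(stats::runif(length(inCycle)) * C)  # progress in steps
    cum <- cumsum(L)
    ph <- findInterval(g, c(0, cum), rightmost.closed = FALSE)
    a$phase[inCycle] <- .PHASES[ph + 1L]
    a$phaseStep[inCycle] <- as.integer(g - c(0, cum)[ph])
    a$rest[inCycle] <- 0L
    a$phenotype[inCycle] <- "proliferating"
  }
  occ[.linIndex(a$i, a$j, a$k, dims)] <- seq_len(total)
  initialize(state, agents = a, occupancy = occ)
}
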