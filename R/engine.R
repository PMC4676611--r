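## Engine: the per-step scheduler.  Fields are updated synchronously from
## the time-t snapshot (cytokines, then drugs), then every living agent
## acts on the updated fields in a freshly randomized order.

## ---- fast mutable representation ---------------------------------------
.TYPE_CODE <- stats::setNames(1:3, .CELL_TYPES)
.PHEN_CODE <- stats::setNames(1:4, .PHENOTYPES)
.PHASE_CODE <- stats::setNames(0:4, .PHASES)

.stateToEnv <- function(state, cfg) {
  a <- state@agents
  e <- new.env(parent = emptyenv())
  e$dims <- dim(state@occupancy)
  e$n <- nrow(a)
  ## private copies throughout: the sweep kernel updates them in place
  e$type <- unname(.TYPE_CODE[a$type])
  e$i <- a$i + 0L; e$j <- a$j + 0L; e$k <- a$k + 0L; e$age <- a$age + 0
  e$phen <- unname(.PHEN_CODE[a$phenotype])
  e$phase <- unname(.PHASE_CODE[a$phase])
  e$phaseStep <- a$phaseStep + 0L
  e$cd <- a$countdown + 0L
  e$rest <- a$rest + 0L
  e$alive <- a$alive | FALSE
  ## private linear copy: updated in place during the sweep
  occ <- integer(prod(e$dims)); occ[] <- state@occupancy
  e$occ <- occ
  e$fDKK1 <- state@fields$DKK1; e$fRANKL <- state@fields$RANKL
  e$fOPG <- state@fields$OPG; e$fTNFa <- state@fields$TNFa
  e$fBHQ <- state@fields$BHQ880; e$fGC <- state@fields$GC
  e$fLDM <- state@fields$LDM
  e$spacing <- state@spacing
  e$par <- cfg$parameters
  amps <- .mmAmplitudes(cfg$parameters, cfg$options$beta_binding)
  e$ampApop <- amps$apop; e$ampProl <- amps$prolif
  e$cyclen <- t(vapply(.CELL_TYPES, function(ct)
    as.integer(unlist(cfg$cycle[[ct]][c("G0G1", "S", "G2", "M")])),
    integer(4L)))
  e$restlen <- vapply(.CELL_TYPES, function(ct)
    as.integer(cfg$cycle[[ct]]$rest), 1L)
  e$boundary <- cfg$options$boundary
  e$drugSource <- cfg$options$drug_source
  e$dosing <- cfg$dosing
  e
}

.envToState <- function(e) {
  idx <- seq_len(e$n)
  keep <- e$alive[idx]           # absorbed agents are dropped
  a <- data.frame(type = .CELL_TYPES[e$type[idx][keep]],
                  i = e$i[idx][keep], j = e$j[idx][keep],
                  k = e$k[idx][keep], age = e$age[idx][keep],
                  phenotype = .PHENOTYPES[e$phen[idx][keep]],
                  phase = .PHASES[e$phase[idx][keep] + 1L],
                  phaseStep = e$phaseStep[idx][keep],
                  countdown = e$cd[idx][keep],
                  rest = e$rest[idx][keep],
                  alive = e$alive[idx][keep],
                  stringsAsFactors = FALSE)
  occ <- array(0L, dim = e$dims)
  if (nrow(a)) occ[.linIndex(a$i, a$j, a$k, e$dims)] <- seq_len(nrow(a))
  fl <- list(DKK1 = e$fDKK1, RANKL = e$fRANKL, OPG = e$fOPG,
             TNFa = e$fTNFa, BHQ880 = e$fBHQ, GC = e$fGC, LDM = e$fLDM)
  fl <- lapply(fl, function(f) array(f, dim = e$dims))
  new("TumorState", agents = a, occupancy = occ,
      fields = fl, spacing = e$spacing)
}

## source indices per species from the live agent vectors
.sourceIdx <- function(e, type) {
  sel <- e$alive & e$type == type
  sel[-seq_len(e$n)] <- FALSE
  .linIndex(e$i[sel], e$j[sel], e$k[sel], e$dims)
}

## ---- one full sweep -----------------------------------------------------
.stepCore <- function(e, t) {
  par <- e$par
  noflux <- e$boundary == "noflux"
  dims <- as.integer(e$dims)

  mmIdx <- .sourceIdx(e, 1L)
  obIdx <- .sourceIdx(e, 2L)
  ocIdx <- .sourceIdx(e, 3L)

  cyt <- function(field, src)
    .latticeStepC(field, dims, par$lambda_C, src, par$Se_G, 0,
                  par$DEG, noflux)
  e$fDKK1  <- cyt(e$fDKK1,  mmIdx)
  e$fRANKL <- cyt(e$fRANKL, mmIdx)
  e$fOPG   <- cyt(e$fOPG,   obIdx)
  e$fTNFa  <- cyt(e$fTNFa,  ocIdx)

  drg <- function(field, drug) {
    ds <- e$dosing[[drug]]
    active <- ds$dose > 0 && t >= ds$start && t < ds$stop
    influx <- par$Pe_d * ds$dose * ds$reference
    if (!active)
      .latticeStepC(field, dims, par$lambda_d, integer(0), 0, 0,
                    par$U_d, noflux)
    else if (e$drugSource == "uniform")
      .latticeStepC(field, dims, par$lambda_d, integer(0), 0, influx,
                    par$U_d, noflux)
    else
      .latticeStepC(field, dims, par$lambda_d, ocIdx, influx, 0,
                    par$U_d, noflux)
  }
  e$fBHQ <- drg(e$fBHQ, "BHQ880")
  e$fGC  <- drg(e$fGC,  "GC")
  e$fLDM <- drg(e$fLDM, "LDM")

  ## agents act on the updated fields, in randomized order (compiled
  ## sweep kernel; .advanceAgentCore is the R reference path)
  ids <- which(e$alive[seq_len(e$n)])
  if (length(ids)) {
    ids <- ids[sample.int(length(ids))]
    need <- e$n + length(ids)
    if (length(e$type) < need) .growStorage(e, need - length(e$type))
    e$n <- .sweepAgentsC(ids, e$n, e$type, e$i, e$j, e$k, e$phen,
                         e$phase, e$phaseStep, e$cd, e$rest, e$alive,
                         e$occ, dims, e$fDKK1, e$fRANKL, e$fOPG, e$fTNFa,
                         e$fBHQ, e$fGC, e$fLDM, .sweepParams(e),
                         e$cyclen, e$restlen)
    living <- which(e$alive[seq_len(e$n)])
    e$age[living] <- e$age[living] + par$dt
  }
  invisible(e)
}

.sweepParams <- function(e) {
  p <- e$par
  c(p$dt, p$K_L_mm, p$lambda0_mm, p$K_GC_1, p$lambda0_1, p$beta1_GC,
    p$K_GC_2, p$lambda0_2, p$beta2_GC, p$K_T_mm, p$P0_mm, p$E0, p$beta_w,
    p$K_D, p$K_W, p$P0_ob, p$beta_ob, p$K_O_RL, p$P0_oc, p$P_pathway_oc,
    p$epsilon_ratio, e$ampApop, e$ampProl)
}

.growStorage <- function(e, by) {
  grow <- max(by, 256L)
  e$type <- c(e$type, integer(grow)); e$i <- c(e$i, integer(grow))
  e$j <- c(e$j, integer(grow)); e$k <- c(e$k, integer(grow))
  e$age <- c(e$age, numeric(grow)); e$phen <- c(e$phen, integer(grow))
  e$phase <- c(e$phase, integer(grow))
  e$phaseStep <- c(e$phaseStep, integer(grow))
  e$cd <- c(e$cd, integer(grow)); e$rest <- c(e$rest, integer(grow))
  e$alive <- c(e$alive, logical(grow))
  invisible(e)
}

.countsOf <- function(e) {
  idx <- seq_len(e$n)
  sel <- e$alive[idx]
  ty <- e$type[idx][sel]
  c(MM = sum(ty == 1L), OB = sum(ty == 2L), OC = sum(ty == 3L))
}

.snapshotOf <- function(e, step) {
  idx <- seq_len(e$n)
  sel <- e$alive[idx]
  data.frame(step = rep(as.integer(step), sum(sel)),
             type = .CELL_TYPES[e$type[idx][sel]],
             i = e$i[idx][sel], j = e$j[idx][sel], k = e$k[idx][sel],
             stringsAsFactors = FALSE)
}

#' Advance a simulation state by one step
#'
#' One full sweep of the scheduler: build secretion/influx sources
#' (a drug is active iff \code{start <= t < stop}), update the four
#' cytokine fields and the three drug fields synchronously from the
#' time-\code{t} snapshot, then let every living agent act on the
#' updated fields in a randomized (RNG-stream) order; ages advance by
#' \code{dt}.
#'
#' @param state a [TumorState-class].
#' @param t current step index (0-based).
#' @param schedule a [DoseSchedule-class] or NULL for no drugs.
#' @param config configuration list.
#' @return the updated [TumorState-class].
#' @export
simStep <- function(state, t, schedule = NULL, config = defaultConfig()) {
  cfg <- validateConfig(config)
  if (!is.null(schedule)) cfg$dosing <- .scheduleToDosing(schedule, cfg$dosing)
  e <- .stateToEnv(state, cfg)
  .stepCore(e, t)
  .envToState(e)
}

.scheduleToDosing <- function(schedule, base) {
  s <- schedule@schedule
  stats::setNames(lapply(.DRUGS, function(d)
    list(dose = s[d, "dose"], start = s[d, "start"], stop = s[d, "stop"],
         reference = base[[d]]$reference)), .DRUGS)
}

#' Run a full simulation
#'
#' Initializes the state from the configuration (placement RNG stream
#' derived from the master seed), then advances \code{steps} steps with
#' a second derived stream for all phenotype and site-selection draws.
#' Identical (config, seed) pairs give bit-identical results.
#'
#' @param config configuration list, see [defaultConfig()].
#' @param seed master seed (integer).
#' @param schedule optional [DoseSchedule-class] overriding
#'   \code{config$dosing}.
#' @param steps optional override of \code{config$run$steps}.
#' @param keepState if TRUE, attach the final [TumorState-class] as
#'   attribute \code{"finalState"}.
#' @return a [SimulationResult-class].
#' @examples
#' cfg <- defaultConfig()
#' cfg$grid <- list(nx = 15, ny = 15, nz = 15, spacing = 5)
#' cfg$initial_counts <- list(MM = 10, OB = 10, OC = 10)
#' res <- runSimulation(cfg, seed = 1, steps = 5)
#' cellCounts(res)
#' @export
runSimulation <- function(config = defaultConfig(), seed = 1L,
                          schedule = NULL, steps = NULL,
                          keepState = FALSE) {
  cfg <- validateConfig(config)
  if (!is.null(schedule)) cfg$dosing <- .scheduleToDosing(schedule, cfg$dosing)
  if (!is.null(steps)) cfg$run$steps <- steps
  T <- as.integer(cfg$run$steps)
  seed <- as.integer(seed)

  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, 2L)
  state <- initializeState(cfg, seed = subseeds[1L])
  e <- .stateToEnv(state, cfg)

  counts <- matrix(0L, nrow = T + 1L, ncol = 3L,
                   dimnames = list(NULL, .CELL_TYPES))
  counts[1L, ] <- .countsOf(e)
  snapSteps <- as.integer(cfg$run$snapshot_steps)
  snaps <- list()
  if (0L %in% snapSteps) snaps[["0"]] <- .snapshotOf(e, 0L)

  set.seed(subseeds[2L])
  if (T > 0) for (t in 0:(T - 1L)) {
    .stepCore(e, t)
    counts[t + 2L, ] <- .countsOf(e)
    if ((t + 1L) %in% snapSteps)
      snaps[[as.character(t + 1L)]] <- .snapshotOf(e, t + 1L)
  }
  snapshots <- if (length(snaps)) do.call(rbind, snaps) else
    data.frame(step = integer(0), type = character(0), i = integer(0),
               j = integer(0), k = integer(0))
  rownames(snapshots) <- NULL
  res <- new("SimulationResult", counts = counts, snapshots = snapshots,
             config = cfg, seed = seed)
  if (keepState) attr(res, "finalState") <- .envToState(e)
  res
}

#' Run a suite of treatment regimens
#'
#' One simulation per (regimen, replicate); deterministic given the seed
#' vector.  Returns a long-format table with the endpoint counts and
#' R_drug score per run, mirroring the regimen-response table layout.
#'
#' @param config base configuration.
#' @param regimens named list of [DoseSchedule-class] objects.
#' @param replicates replicates per regimen.
#' @param seeds integer vector of length \code{replicates} (master seed
#'   per replicate, shared across regimens).
#' @return data.frame with columns \code{regimen, replicate, seed,
#'   N_MM120, N_OB120, N_OC120, R_drug}.
#' @export
runRegimenSuite <- function(config = defaultConfig(),
                            regimens = standardRegimens(),
                            replicates = 1L,
                            seeds = seq_len(replicates)) {
  stopifnot(length(regimens) >= 1L)
  replicates <- as.integer(replicates)
  if (replicates == 0L)
    return(data.frame(regimen = character(0), replicate = integer(0),
                      seed = integer(0), N_MM120 = integer(0),
                      N_OB120 = integer(0), N_OC120 = integer(0),
                      R_drug = numeric(0)))
  stopifnot(length(seeds) == replicates)
  rows <- list()
  for (rg in names(regimens)) {
    for (rep in seq_len(replicates)) {
      res <- runSimulation(config, seed = seeds[rep],
                           schedule = regimens[[rg]])
      ec <- endpointCounts(res)
      rows[[length(rows) + 1L]] <- data.frame(
        regimen = rg, replicate = rep, seed = as.integer(seeds[rep]),
        N_MM120 = ec[["N_MM120"]], N_OB120 = ec[["N_OB120"]],
        N_OC120 = ec[["N_OC120"]], R_drug = rDrug(ec),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
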