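## Intracellular scale: per-step phenotype decisions driven by
## Hill-function responses to the local cytokine and drug fields.

.hill2 <- function(x, K) {
  h <- (x / K)^2
  h / (1 + h)
}

#' Per-step apoptosis probability from a hazard rate
#'
#' Exponential-survival conversion: \code{1 - exp(-rate * dt)}.
#'
#' @param rate apoptosis hazard, per hour (>= 0).
#' @param dt step length in hours (> 0).
#' @return probability in \[0, 1).
#' @examples
#' apoptosisProbability(3.5e-2, 2)  # 1 - exp(-0.07)
#' @export
apoptosisProbability <- function(rate, dt) {
  if (any(rate < 0)) stop("apoptosis rate must be >= 0")
  if (any(dt <= 0)) stop("dt must be > 0")
  1 - exp(-rate * dt)
}

#' Lidamycin-modulated MM apoptosis rate
#'
#' Basal rate plus a Hill (n = 2) response to the local Lidamycin
#' concentration: \code{lambda0_mm + beta * (L/K)^2 / (1 + (L/K)^2)}.
#' The amplitude \code{beta} is resolved from the configuration's
#' \code{beta_binding} option (see [defaultConfig()]).
#'
#' @param L local Lidamycin concentration (>= 0).
#' @param params parameter list (\code{config$parameters}).
#' @param binding \code{"symbols"} or \code{"labels"}.
#' @return hazard rate per hour.
#' @export
mmApoptosisRate <- function(L, params, binding = "labels") {
  if (any(L < 0)) stop("Lidamycin concentration must be >= 0")
  amp <- .mmAmplitudes(params, binding)$apop
  params$lambda0_mm + amp * .hill2(L, params$K_L_mm)
}

#' Glucocorticoid-modulated OB/OC apoptosis rate
#'
#' \code{lambda0_n + beta_n * (G/K_GC_n)^2 / (1 + (G/K_GC_n)^2)} with the
#' OB triple (lambda0_1, beta1_GC, K_GC_1) or the OC triple
#' (lambda0_2, beta2_GC, K_GC_2).  The OC threshold is orders of
#' magnitude below the OB threshold, so a low GC dose can act on OCs
#' while sparing OBs.
#'
#' @param G local glucocorticoid concentration (>= 0).
#' @param target \code{"OB"} or \code{"OC"}.
#' @param params parameter list.
#' @return hazard rate per hour.
#' @export
gcApoptosisRate <- function(G, target, params) {
  if (any(G < 0)) stop("GC concentration must be >= 0")
  if (identical(target, "OB"))
    params$lambda0_1 + params$beta1_GC * .hill2(G, params$K_GC_1)
  else if (identical(target, "OC"))
    params$lambda0_2 + params$beta2_GC * .hill2(G, params$K_GC_2)
  else stop("target must be 'OB' or 'OC'")
}

#' Proliferation probability of a cell
#'
#' MM: basal plus a Hill-2 response to local TNFa.  OB: basal plus a
#' Hill-2 response to the effective Wnt signal.  OC: basal plus an
#' amplitude inhibited by the OPG:RANKL ratio,
#' \code{P0_oc + P_pathway_oc / (1 + (O_RL/K_O_RL)^2)}.  The sum is
#' clamped to \[0, 1\] (the OB basal + amplitude can exceed 1 at
#' saturation).
#'
#' @param cellType \code{"MM"}, \code{"OB"} or \code{"OC"}.
#' @param env local environment: list with (as needed) \code{TNFa},
#'   \code{EWnt}, \code{O_RL}, all >= 0.
#' @param params parameter list.
#' @param binding amplitude binding, as in [mmApoptosisRate()].
#' @return probability in \[0, 1\].
#' @export
proliferationProbability <- function(cellType, env, params,
                                     binding = "labels") {
  p <- switch(cellType,
    MM = params$P0_mm +
      .mmAmplitudes(params, binding)$prolif * .hill2(env$TNFa, params$K_T_mm),
    OB = params$P0_ob + params$beta_ob * .hill2(env$EWnt, params$K_W),
    OC = params$P0_oc +
      params$P_pathway_oc / (1 + (env$O_RL / params$K_O_RL)^2),
    stop("unknown cell type: ", cellType))
  min(max(p, 0), 1)
}

#' Bernoulli gate into the cell cycle
#'
#' @param pProl proliferation probability in \[0, 1\].
#' @param u uniform draw in \[0, 1).
#' @return TRUE iff \code{u < pProl} (cell enters the cycle).
#' @export
cellCycleGate <- function(pProl, u) {
  if (pProl < 0 || pProl > 1) stop("pProl must be in [0,1]")
  if (u < 0 || u >= 1) stop("u must be in [0,1)")
  u < pProl
}

## ---- per-agent decision core -------------------------------------------
## Operates on the fast engine environment `e` (see engine.R) so the
## public advanceCell() wrapper and the step scheduler share one code
## path.  Returns the decision label.
.advanceAgentCore <- function(e, id) {
  par <- e$par
  if (!e$alive[id]) return("dead")

  ## (0) agents already committed to apoptosis count down to absorption
  if (e$phen[id] == 4L) {
    e$cd[id] <- e$cd[id] - 1L
    if (e$cd[id] <= 0L) {
      .setIntInPlace(e$occ, .linIndex(e$i[id], e$j[id], e$k[id], e$dims), 0L)
      e$alive[id] <- FALSE
      return("absorbed")
    }
    return("apoptotic")
  }

  li <- .linIndex(e$i[id], e$j[id], e$k[id], e$dims)
  ty <- e$type[id]

  ## (1) apoptosis draw against the drug-modulated hazard
  lam <- if (ty == 1L) {
    h <- (e$fLDM[li] / par$K_L_mm)^2
    par$lambda0_mm + e$ampApop * h / (1 + h)
  } else if (ty == 2L) {
    h <- (e$fGC[li] / par$K_GC_1)^2
    par$lambda0_1 + par$beta1_GC * h / (1 + h)
  } else {
    h <- (e$fGC[li] / par$K_GC_2)^2
    par$lambda0_2 + par$beta2_GC * h / (1 + h)
  }
  if (lam > 0 && stats::runif(1) < 1 - exp(-lam * par$dt)) {
    e$phen[id] <- 4L
    e$phase[id] <- 0L
    e$cd[id] <- .APOPTOSIS_STEPS
    return("apoptose")
  }

  ## (2) cycle gate for cells not already cycling; a failed draw is
  ## followed by a rest of `restlen - 1` steps before the next draw
  if (e$phase[id] == 0L && e$rest[id] > 0L) {
    e$rest[id] <- e$rest[id] - 1L
  } else if (e$phase[id] == 0L) {
    p <- if (ty == 1L) {
      h <- (e$fTNFa[li] / par$K_T_mm)^2
      par$P0_mm + e$ampProl * h / (1 + h)
    } else if (ty == 2L) {
      D <- e$fDKK1[li]; B <- e$fBHQ[li]
      De <- if (D > 0) D * D / (D + B) else 0
      EWnt <- par$E0 + par$beta_w / (1 + (De / par$K_D)^2)
      h <- (EWnt / par$K_W)^2
      par$P0_ob + par$beta_ob * h / (1 + h)
    } else {
      orl <- e$fOPG[li] / max(e$fRANKL[li], par$epsilon_ratio)
      par$P0_oc + par$P_pathway_oc / (1 + (orl / par$K_O_RL)^2)
    }
    p <- min(max(p, 0), 1)
    if (stats::runif(1) < p) {
      e$phase[id] <- 1L         # enter G0/G1
      e$phaseStep[id] <- 0L
      e$phen[id] <- 2L
    } else {
      e$rest[id] <- e$restlen[ty] - 1L
    }
  }

  ## (3) cycling cells progress; M phase attempts division
  if (e$phase[id] > 0L) {
    e$phaseStep[id] <- e$phaseStep[id] + 1L
    if (e$phase[id] < 4L) {                 # G0/G1, S, G2: migrate
      if (e$phaseStep[id] >= e$cyclen[ty, e$phase[id]]) {
        e$phase[id] <- e$phase[id] + 1L
        e$phaseStep[id] <- 0L
      }
      moved <- .migrateAgent(e, id)
      return(if (moved) "migrate" else "quiesce")
    }
    ## M phase: divide into an empty face-neighbor site
    site <- .selectEmptyNeighbor(e, id)
    if (is.null(site)) {
      return("quiesce")  # reversibly quiescent, phase retained
    }
    .spawnDaughter(e, id, site)
    e$phase[id] <- 0L    # parent returns to the resting pool
    e$phaseStep[id] <- 0L
    e$phen[id] <- 3L
    return("divide")
  }

  ## (4) non-cycling cells migrate; nowhere to go -> quiescent
  moved <- .migrateAgent(e, id)
  if (moved) "migrate" else "quiesce"
}

#' Advance a single agent one step
#'
#' Applies the phenotype-switch flow to one agent of a
#' [TumorState-class]: apoptosis draw against the drug-modulated hazard,
#' Bernoulli cycle entry, cycle progression with migration in G0/G1, S
#' and G2 and division in M (into an empty face neighbor chosen by the
#' ranked-site rule), migration of non-cycling cells, and reversible
#' quiescence when no site is free.  Uses the current R RNG stream.
#'
#' @param state a [TumorState-class].
#' @param id agent row index.
#' @param config configuration list.
#' @return list with elements \code{state} (updated) and \code{decision}
#'   (one of \code{absorbed, apoptotic, apoptose, migrate, divide,
#'   quiesce, dead}).
#' @export
advanceCell <- function(state, id, config = defaultConfig()) {
  cfg <- validateConfig(config)
  e <- .stateToEnv(state, cfg)
  decision <- .advanceAgentCore(e, id)
  list(state = .envToState(e), decision = decision)
}
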