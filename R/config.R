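## Configuration: every model constant lives in one nested list that
## round-trips losslessly through YAML.  Parameter names follow the
## symbols of the published parameter table (ASCII-ized: beta_w for the
## maximum Wnt amplitude, lambda0_1 for the basal OB apoptosis rate, ...).

.PARAM_DEFAULTS <- list(
  ## Wnt / DKK1 axis
  E0        = 0,      # basal Wnt effect
  beta_w    = 0.5,    # maximum Wnt effect
  K_D       = 1,      # DKK1 threshold inhibiting Wnt
  ## proliferation
  P0_ob     = 0.1,    # basal OB proliferation probability per step
  beta_ob   = 1,      # maximum Wnt-driven OB stimulation
  K_W       = 0.8,    # Wnt threshold activating OBs
  P0_oc     = 0.1,    # basal OC proliferation probability
  K_O_RL    = 1,      # OPG:RANKL ratio threshold inhibiting OCs
  P0_mm     = 0.15,   # basal MM proliferation probability
  beta_mm_L = 0.5,    # amplitude tabulated against symbol beta_mm^L
  K_T_mm    = 1,      # TNFa threshold promoting MM proliferation
  beta_mm_T = 0.05,   # amplitude tabulated against symbol beta_mm^T
  ## apoptosis
  lambda0_mm = 0,       # basal MM apoptosis rate (per hour)
  K_L_mm     = 1e-07,   # Lidamycin threshold for MM apoptosis
  lambda0_1  = 3.5e-02, # basal OB apoptosis rate (per hour)
  beta1_GC   = 0.15,    # GC amplitude on OB apoptosis
  K_GC_1     = 0.15,    # GC threshold for OB apoptosis
  lambda0_2  = 0,       # basal OC apoptosis rate
  K_GC_2     = 1.5e-06, # GC threshold for OC apoptosis
  ## tabulated as 0 (the row label duplicates the lambda0_2 row, an
  ## apparent copy error); kept as printed here -- the calibrated
  ## baseline (inst/extdata/calibrated.yaml) sets it positive so GCs
  ## can act on OCs at all
  beta2_GC   = 0,       # GC amplitude on OC apoptosis
  ## rates the published table leaves unvalued (calibration knobs)
  P_pathway_oc = 0.26,  # OPG:RANKL-sensitive OC proliferation amplitude
  lambda_C     = 0.4,   # cytokine diffusivity per step, in [0,1]
  Se_G         = 0.54,  # cytokine secretion per occupied site per step
  DEG          = 0.001, # cytokine degradation per step, in [0,1]
  lambda_d     = 0.5,   # drug diffusivity per step
  Pe_d         = 0.1,   # vessel permeability (drug influx scale)
  U_d          = 0.04,  # drug uptake per step, in [0,1]
  D_mot        = 0.08,  # motility scale (distance^2 per hour) in Eq for p(r)
  dt           = 2,     # hours per simulation step
  epsilon_ratio = 1e-09 # guard for the OPG:RANKL ratio at RANKL ~ 0
)

.CYCLE_DEFAULTS <- list(
  ## Phase lengths in steps, per cell type, plus `rest`: the number of
  ## steps a cell waits after a failed cycle-entry draw before drawing
  ## again (1 = re-draw every step).
  MM = list(G0G1 = 5L, S = 4L, G2 = 2L, M = 1L, rest = 16L),
  OB = list(G0G1 = 4L, S = 3L, G2 = 2L, M = 1L, rest = 1L),
  OC = list(G0G1 = 5L, S = 4L, G2 = 2L, M = 1L, rest = 17L))

.OPTION_DEFAULTS <- list(
  ## 'symbols' binds the tabulated 0.5 to the MM apoptosis amplitude (the
  ## symbol used in the apoptosis equation) and 0.05 to MM proliferation;
  ## 'labels' binds by the table's row labels (0.5 -> proliferation).
  beta_binding = "labels",
  drug_source  = "uniform",   # or "as_printed" (influx at OC sites only)
  boundary     = "noflux"     # or "absorbing"
)

.GRID_DEFAULTS <- list(nx = 100L, ny = 100L, nz = 100L, spacing = 5)

#' Default model configuration
#'
#' Returns the full nested configuration: \code{grid}, \code{parameters}
#' (every symbol of the system-parameter table plus the diffusion /
#' secretion / motility rates the table leaves unvalued), \code{cycle}
#' (cell-cycle phase lengths in steps, per cell type), \code{initial_counts},
#' \code{dosing}, \code{options}, \code{run} and \code{output}.  The
#' shipped values are the package's calibrated baseline; see the methods
#' vignette for how each free rate was chosen.
#'
#' @return nested named list.
#' @examples
#' cfg <- defaultConfig()
#' cfg$parameters$K_D
#' @export
defaultConfig <- function() {
  list(
    grid = .GRID_DEFAULTS,
    parameters = .PARAM_DEFAULTS,
    cycle = .CYCLE_DEFAULTS,
    initial_counts = list(MM = 100L, OB = 100L, OC = 100L),
    ## dose is in relative units; `reference` converts one relative unit
    ## into the influx scale (multiplies Pe_d), one value per drug
    dosing = list(
      BHQ880 = list(dose = 0, start = 20L, stop = 60L, reference = 30),
      GC     = list(dose = 0, start = 20L, stop = 60L, reference = 1e-3),
      LDM    = list(dose = 0, start = 20L, stop = 60L, reference = 1.35e-7)),
    options = .OPTION_DEFAULTS,
    run = list(steps = 120L,
               snapshot_steps = c(0L, 40L, 50L, 60L, 65L, 70L, 85L, 90L, 120L)),
    output = list(dir = ".")
  )
}

#' The calibrated configuration shipped with the package
#'
#' Reads \code{inst/extdata/calibrated.yaml}: the baseline used for the
#' drug-free and regimen experiments.
#'
#' @return validated configuration list.
#' @export
calibratedConfig <- function() {
  loadConfig(system.file("extdata", "calibrated.yaml",
                         package = "myelomaABM", mustWork = TRUE))
}

.mergeConfig <- function(base, user, path = "") {
  for (nm in names(user)) {
    here <- if (nzchar(path)) paste0(path, "$", nm) else nm
    if (!nm %in% names(base))
      stop("unknown configuration key: ", here, call. = FALSE)
    if (is.list(base[[nm]]) && !is.null(user[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], as.list(user[[nm]]), here)
    else if (!is.null(user[[nm]]))
      base[[nm]] <- user[[nm]]
  }
  base
}

.checkPositive <- function(p, keys, strict = FALSE) {
  for (k in keys) {
    v <- p[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) ||
        (strict && v <= 0) || (!strict && v < 0))
      stop("invalid value for parameter ", k,
           if (strict) " (must be > 0)" else " (must be >= 0)",
           call. = FALSE)
  }
}

#' Validate a configuration list
#'
#' Checks every invariant of the parameter set (all rates non-negative,
#' diffusivities/degradation/uptake in \[0,1\], Hill thresholds strictly
#' positive, dosing windows ordered) and rejects unknown keys by name.
#'
#' @param config nested list as produced by [defaultConfig()].
#' @return the validated (fully defaulted) configuration, invisibly.
#' @export
validateConfig <- function(config) {
  cfg <- .mergeConfig(defaultConfig(), config)
  p <- cfg$parameters
  .checkPositive(p, c("E0", "beta_w", "P0_ob", "beta_ob", "P0_oc", "P0_mm",
                      "beta_mm_L", "beta_mm_T", "lambda0_mm", "lambda0_1",
                      "beta1_GC", "lambda0_2", "beta2_GC", "P_pathway_oc",
                      "Se_G", "Pe_d", "epsilon_ratio"))
  .checkPositive(p, c("K_D", "K_W", "K_O_RL", "K_T_mm", "K_L_mm", "K_GC_1",
                      "K_GC_2", "D_mot", "dt"), strict = TRUE)
  for (k in c("lambda_C", "lambda_d", "DEG", "U_d"))
    if (p[[k]] < 0 || p[[k]] > 1)
      stop("invalid value for parameter ", k, " (must be in [0,1])",
           call. = FALSE)
  g <- cfg$grid
  if (any(unlist(g[c("nx", "ny", "nz")]) < 1))
    stop("invalid grid dimensions", call. = FALSE)
  if (g$spacing <= 0) stop("invalid value for grid$spacing", call. = FALSE)
  if (any(unlist(cfg$cycle) < 1))
    stop("cycle phase lengths must be >= 1 step", call. = FALSE)
  if (any(unlist(cfg$initial_counts) < 0))
    stop("initial_counts must be >= 0", call. = FALSE)
  for (d in .DRUGS) {
    ds <- cfg$dosing[[d]]
    if (ds$dose < 0) stop("invalid dose for ", d, call. = FALSE)
    if (ds$reference <= 0)
      stop("invalid reference dose for ", d, call. = FALSE)
    if (ds$start > ds$stop)
      stop("dosing start must be <= stop for ", d, call. = FALSE)
  }
  if (!cfg$options$beta_binding %in% c("symbols", "labels"))
    stop("options$beta_binding must be 'symbols' or 'labels'", call. = FALSE)
  if (!cfg$options$drug_source %in% c("uniform", "as_printed"))
    stop("options$drug_source must be 'uniform' or 'as_printed'",
         call. = FALSE)
  if (!cfg$options$boundary %in% c("noflux", "absorbing"))
    stop("options$boundary must be 'noflux' or 'absorbing'", call. = FALSE)
  if (cfg$run$steps < 0) stop("run$steps must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' Load / save a configuration file
#'
#' Configurations are YAML; an empty file yields the full default
#' configuration.  \code{saveConfig} followed by \code{loadConfig} is the
#' identity on validated configurations.
#'
#' @param path file path.
#' @param config configuration list.
#' @return \code{loadConfig}: the validated configuration list.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path,
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  validateConfig(user)
}

#' @rdname loadConfig
#' @export
saveConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

## Resolve the two contested MM amplitudes.  The parameter table prints
## beta_mm^L = 0.5 labelled "maximum activation of MM proliferation" and
## beta_mm^T = 0.05 labelled "maximum increase in MM apoptosis", while
## the equations use beta_mm^L in the apoptosis response and beta_mm^T in
## the proliferation response.  'symbols' follows the equations,
## 'labels' follows the row labels.
.mmAmplitudes <- function(params, binding) {
  if (binding == "symbols")
    list(apop = params$beta_mm_L, prolif = params$beta_mm_T)
  else
    list(apop = params$beta_mm_T, prolif = params$beta_mm_L)
}
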