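test_that("R_drug arithmetic and zero conditions", {
  expect_equal(rDrug(c(2, 5, 1, 3, 4)), 12)
  expect_equal(rDrug(c(0, 50, 10, 100, 100)), 0)       # tumor eradicated
  expect_equal(rDrug(c(40, 100, 10, 100, 100)), 0)     # OC rebalanced
  # symmetric under swapping the OB and OC deviations
  expect_equal(rDrug(c(7, 120, 80, 100, 100)),
               rDrug(c(7, 80, 120, 100, 100)))
  expect_error(rDrug(c(-1, 0, 0, 0, 0)), "non-negative")
})

test_that("geometric dose grid spans 0.1x..10x with constant ratio", {
  g <- geometricDoseGrid(2)
  expect_length(g, 20L)
  expect_equal(g[1], 0.2)
  expect_equal(g[20], 20)
  expect_equal(unique(round(g[-1] / g[-20], 12)),
               round(100^(1 / 19), 12))
  expect_equal(geometricDoseGrid(1, nLevels = 2), c(0.1, 10))
  expect_error(geometricDoseGrid(1, nLevels = 1), "nLevels")
  expect_error(geometricDoseGrid(0), "reference")
})

test_that("equi-effective dose inverts analytic curves exactly", {
  lin <- makeCurveFixture("linear", params = list(a = 5, b = 2))
  # at a grid point
  expect_equal(equiEffectiveDose(lin, lin$effect[7]), lin$dose[7])
  # midway in effect equals midpoint in log-dose (linear fixture)
  tgt <- (lin$effect[4] + lin$effect[5]) / 2
  expect_equal(log(equiEffectiveDose(lin, tgt)),
               (log(lin$dose[4]) + log(lin$dose[5])) / 2,
               tolerance = 1e-12)
  # closed-form inverse across the whole range
  for (tg in seq(min(lin$effect), max(lin$effect), length.out = 7))
    expect_equal(equiEffectiveDose(lin, tg), exp((tg - 5) / 2),
                 tolerance = 1e-9)
  expect_error(equiEffectiveDose(lin, min(lin$effect) - 1), "outside")
  # hill curve at half-max returns K (log-linear interpolation error
  # on the 20-level grid is ~1e-4 relative)
  hill <- makeCurveFixture("hill", params = list(top = 8, K = 0.7))
  expect_equal(equiEffectiveDose(hill, 4), 0.7, tolerance = 1e-3)
})

test_that("non-monotone curves restrict inversion to the reference branch", {
  nm <- makeCurveFixture("nonmonotone", params = list(a = 1, dip = 1),
                         reference = 0.2)
  expect_true(attr(nm, "nonMonotone"))
  # reference 0.2 sits on the decreasing branch; inversion stays there
  tgt <- nm$effect[3]
  expect_equal(equiEffectiveDose(nm, tgt), nm$dose[3])
  mono <- makeCurveFixture("linear")
  expect_false(attr(mono, "nonMonotone"))
})

test_that("Loewe CI obeys the sham-combination axiom and arithmetic", {
  lin <- makeCurveFixture("linear", params = list(a = 0, b = 1))
  target <- 0.5
  gcx <- equiEffectiveDose(lin, target)
  curves <- list(BHQ880 = lin, GC = lin, LDM = lin)
  # sham: one drug split in half against itself
  sham <- loeweCI(c(BHQ880 = gcx / 2, GC = gcx / 2, LDM = 0), curves,
                  target = target)
  expect_equal(sham$CI, 1, tolerance = 1e-9)
  # one-sixth of each equi-effective dose: CI = 0.5, synergy
  syn <- loeweCI(c(BHQ880 = gcx / 6, GC = gcx / 6, LDM = gcx / 6), curves,
                 target = target)
  expect_equal(syn$CI, 0.5, tolerance = 1e-9)
  expect_equal(syn$verdict, "synergy")
  # full equi-effective dose of all three: CI = 3, antagonism
  ant <- loeweCI(c(BHQ880 = gcx, GC = gcx, LDM = gcx), curves,
                 target = target)
  expect_equal(ant$CI, 3, tolerance = 1e-9)
  expect_equal(ant$verdict, "antagonism")
})

test_that("dose-response machinery flags analytic non-monotone fixtures", {
  doses <- geometricDoseGrid(1, nLevels = 10)
  # simulator stub whose R_drug is a deterministic parabola in log-dose:
  # counts (v, 0, 0) against zero initials give R_drug = v * 0 * 0 = 0,
  # so encode the effect in all three factors instead
  stubSim <- function(config, seed, schedule) {
    d <- sum(schedule@schedule$dose)
    v <- as.integer(round(100 * ((log(d) - 1)^2 + 1)))
    cnt <- matrix(c(1L, 0L, 0L, v, 1L, 1L), nrow = 2, byrow = TRUE,
                  dimnames = list(NULL, c("MM", "OB", "OC")))
    new("SimulationResult", counts = cnt, snapshots = data.frame(),
        config = list(), seed = as.integer(seed))
  }
  curve <- doseResponseCurve("LDM", doses, replicates = 1,
                             simulator = stubSim)
  expect_true(attr(curve, "nonMonotone"))
  expect_equal(curve$effect,
               round(100 * ((log(doses) - 1)^2 + 1)))
  curve2 <- doseResponseCurve("LDM", doses, replicates = 1,
                              simulator = stubSim)
  expect_identical(curve, curve2)  # reproducible under fixed seeds
})

test_that("Spearman sweep matches the rank-then-Pearson oracle", {
  vals <- c(0.2, 0.5, 0.9, 1.4, 2.2, 3.0, 4.1, 5.5, 7.0, 9.0)
  # simulator hook: outcome = -parameter + small deterministic jitter
  hook <- function(config, seed) {
    v <- config$parameters$K_D
    n <- round(1000 - 90 * v + 7 * sin(13 * v))
    new("SimulationResult",
        counts = matrix(as.integer(c(n, n + 1, n + 2)), 1, 3,
                        dimnames = list(NULL, c("MM", "OB", "OC"))),
        snapshots = data.frame(), config = list(), seed = 1L)
  }
  rep <- sensitivitySpearman(list(K_D = vals), nSims = 2, seeds = c(1, 2),
                             simulator = hook)
  expect_equal(nrow(rep), 3L)
  # brute-force oracle: rank then Pearson
  outc <- vapply(vals, function(v) 1000 - 90 * v + 7 * sin(13 * v), 0)
  oracle <- stats::cor(rank(vals), rank(round(outc)))
  expect_equal(rep$rho[rep$cellType == "MM"], oracle, tolerance = 1e-12)
  expect_lt(rep$rho[1], -0.9)
  # perfect monotone hook gives rho exactly 1
  hookUp <- function(config, seed) {
    v <- config$parameters$K_D
    n <- as.integer(round(10 * v))
    new("SimulationResult",
        counts = matrix(c(n, n, n), 1, 3,
                        dimnames = list(NULL, c("MM", "OB", "OC"))),
        snapshots = data.frame(), config = list(), seed = 1L)
  }
  repUp <- sensitivitySpearman(list(K_D = vals), nSims = 1, seeds = 1,
                               simulator = hookUp)
  expect_equal(repUp$rho, rep(1, 3))
  expect_equal(repUp$p, rep(0, 3))
  # constant outcome: undefined correlation reported as missing
  hookConst <- function(config, seed)
    new("SimulationResult",
        counts = matrix(5L, 1, 3, dimnames = list(NULL, c("MM", "OB", "OC"))),
        snapshots = data.frame(), config = list(), seed = 1L)
  repC <- sensitivitySpearman(list(K_D = vals), nSims = 1, seeds = 1,
                              simulator = hookConst)
  expect_true(all(is.na(repC$rho)))
})
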