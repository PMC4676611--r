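par <- refParams()

test_that("apoptosis probability follows the exponential closed form", {
  expect_equal(apoptosisProbability(0, 2), 0)
  expect_equal(apoptosisProbability(1e6, 2), 1, tolerance = 1e-12)
  # basal OB hazard 3.5e-2 per hour over a 2 h step (frozen closed form)
  expect_equal(apoptosisProbability(3.5e-2, 2), 0.067606180094052,
               tolerance = 1e-12)
  expect_error(apoptosisProbability(-0.1, 2), ">= 0")
  expect_error(apoptosisProbability(0.1, 0), "> 0")
})

test_that("Lidamycin response has Hill half-saturation and bounds", {
  amp <- 0.05  # labels binding: apoptosis amplitude
  expect_equal(mmApoptosisRate(0, par), 0)
  expect_equal(mmApoptosisRate(par$K_L_mm, par), amp / 2)
  expect_equal(mmApoptosisRate(10 * par$K_L_mm, par), amp * 100 / 101)
  # symbols binding swaps in the 0.5 amplitude
  expect_equal(mmApoptosisRate(par$K_L_mm, par, binding = "symbols"),
               0.5 / 2)
  # monotone, saturating
  L <- c(0, 10^seq(-9, -4, length.out = 30))
  r <- vapply(L, mmApoptosisRate, 0, params = par)
  expect_true(all(diff(r) >= 0))
  expect_true(all(r <= par$lambda0_mm + 0.05))
})

test_that("GC response uses the right per-target triple", {
  expect_equal(gcApoptosisRate(0, "OB", par), 3.5e-2)
  expect_equal(gcApoptosisRate(par$K_GC_1, "OB", par),
               par$lambda0_1 + par$beta1_GC / 2)
  # tabulated OC amplitude is zero: GCs leave OC apoptosis at basal
  expect_equal(gcApoptosisRate(5, "OC", par), 0)
  p2 <- par; p2$beta2_GC <- 0.1
  expect_equal(gcApoptosisRate(p2$K_GC_2, "OC", p2),
               p2$lambda0_2 + 0.05)
  G <- seq(0, 2, length.out = 40)
  r <- vapply(G, gcApoptosisRate, 0, target = "OB", params = par)
  expect_true(all(diff(r) >= 0))
  expect_error(gcApoptosisRate(1, "MM", par), "target")
})

test_that("proliferation probabilities match the Hill forms and clamp", {
  expect_equal(proliferationProbability("MM", list(TNFa = 0), par), 0.15)
  # OB at half-saturation Wnt: 0.1 + 1/2 with the tabulated values
  expect_equal(proliferationProbability("OB", list(EWnt = par$K_W), par),
               0.6)
  # OB at saturation would be 1.1; clamped to 1
  expect_equal(proliferationProbability("OB", list(EWnt = 1e9), par), 1)
  # OC with no OPG:RANKL inhibition sits at basal + amplitude
  expect_equal(proliferationProbability("OC", list(O_RL = 0), par),
               par$P0_oc + par$P_pathway_oc)
  expect_equal(proliferationProbability("OC", list(O_RL = par$K_O_RL), par),
               par$P0_oc + par$P_pathway_oc / 2)
  # monotonicity in the ligand
  pm <- vapply(seq(0, 5, 0.25), function(T)
    proliferationProbability("MM", list(TNFa = T), par), 0)
  expect_true(all(diff(pm) >= 0))
  po <- vapply(seq(0, 5, 0.25), function(x)
    proliferationProbability("OC", list(O_RL = x), par), 0)
  expect_true(all(diff(po) <= 0))
  expect_error(proliferationProbability("XX", list(), par), "cell type")
})

test_that("cycle gate is an exact Bernoulli threshold", {
  expect_true(cellCycleGate(1, 0.999))
  expect_false(cellCycleGate(0, 0))
  u <- seq(0, 0.99, by = 0.01)
  expect_equal(mean(vapply(u, function(x) cellCycleGate(0.6, x), TRUE)),
               0.60)
  expect_error(cellCycleGate(1.2, 0.5), "pProl")
  expect_error(cellCycleGate(0.5, 1), "u must")
})

test_that("apoptotic countdown removes the agent at zero", {
  st <- triState()
  a <- agents(st)
  a$phenotype[1] <- "apoptotic"
  a$countdown[1] <- 1L
  st2 <- makeGridFixture(dims = c(7L, 7L, 7L), agents = a)
  out <- advanceCell(st2, 1L, smallConfig())
  expect_equal(out$decision, "absorbed")
  expect_equal(nrow(agents(out$state)), 2L)
  expect_equal(sum(occupancy(out$state) != 0L), 2L)
})

test_that("M-phase cell with no free neighbor quiesces, phase retained", {
  # center cell in M phase, all 6 face neighbors occupied
  ag <- data.frame(type = "MM",
                   i = c(2L, 3L, 1L, 2L, 2L, 2L, 2L),
                   j = c(2L, 2L, 2L, 3L, 1L, 2L, 2L),
                   k = c(2L, 2L, 2L, 2L, 2L, 3L, 1L))
  ag$phenotype <- c("proliferating", rep("quiescent", 6))
  ag$phase <- c("M", rep("none", 6))
  st <- makeGridFixture(dims = c(3L, 3L, 3L), agents = ag)
  cfg <- smallConfig()
  out <- advanceCell(st, 1L, cfg)
  expect_equal(out$decision, "quiesce")
  expect_equal(agents(out$state)$phase[1], "M")
  expect_equal(nrow(agents(out$state)), 7L)
})

test_that("with zero hazards and zero gate the only branch is migration", {
  st <- makeGridFixture(dims = c(5L, 5L, 5L),
                        agents = data.frame(type = "MM", i = 3L, j = 3L,
                                            k = 3L))
  cfg <- smallConfig()
  cfg$parameters$P0_mm <- 0
  cfg$parameters$beta_mm_L <- 0; cfg$parameters$beta_mm_T <- 0
  set.seed(1)
  out <- advanceCell(st, 1L, cfg)
  expect_equal(out$decision, "migrate")
  a <- agents(out$state)
  expect_equal(abs(a$i - 3) + abs(a$j - 3) + abs(a$k - 3), 1)
})

test_that("empirical apoptosis frequency matches the hazard probability", {
  cfg <- smallConfig()
  cfg$parameters$lambda0_mm <- 0.06   # per hour
  p <- apoptosisProbability(0.06, cfg$parameters$dt)
  st <- makeGridFixture(dims = c(5L, 5L, 5L),
                        agents = data.frame(type = "MM", i = 3L, j = 3L,
                                            k = 3L))
  n <- 1200
  set.seed(42)
  hits <- sum(vapply(seq_len(n), function(...)
    advanceCell(st, 1L, cfg)$decision == "apoptose", TRUE))
  sigma <- sqrt(p * (1 - p) / n)
  expect_lt(abs(hits / n - p), 3 * sigma + 1e-9)
})
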