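fastCfg <- function(...) smallConfig(n = 13L,
                                     counts = c(MM = 12L, OB = 12L,
                                                OC = 12L), ...)

test_that("seeded runs are bit-identical and counts start at initials", {
  cfg <- fastCfg()
  r1 <- runSimulation(cfg, seed = 5, steps = 8)
  r2 <- runSimulation(cfg, seed = 5, steps = 8)
  expect_identical(cellCounts(r1), cellCounts(r2))
  expect_identical(snapshots(r1), snapshots(r2))
  expect_equal(unname(cellCounts(r1)[1, ]), c(12, 12, 12))
  expect_equal(nrow(cellCounts(r1)), 9L)
  r0 <- runSimulation(cfg, seed = 5, steps = 0)
  expect_equal(nrow(cellCounts(r0)), 1L)
})

test_that("an empty state evolves fields but keeps zero counts", {
  cfg <- smallConfig(n = 9L, counts = c(MM = 0L, OB = 0L, OC = 0L))
  res <- runSimulation(cfg, seed = 1, steps = 5)
  expect_true(all(cellCounts(res) == 0))
})

test_that("no agent ever shares a site through a multi-step run", {
  cfg <- fastCfg()
  res <- runSimulation(cfg, seed = 9, steps = 15, keepState = TRUE)
  st <- attr(res, "finalState")
  a <- agents(st)
  expect_equal(anyDuplicated(paste(a$i, a$j, a$k)), 0L)
  occ <- occupancy(st)
  expect_equal(sum(occ != 0L), nrow(a))
  expect_true(validObject(st))
})

test_that("zero hazards and zero proliferation freeze the populations", {
  cfg <- fastCfg(P0_mm = 0, P0_ob = 0, P0_oc = 0, beta_mm_L = 0,
                 beta_mm_T = 0, beta_ob = 0, P_pathway_oc = 0,
                 lambda0_1 = 0)
  res <- runSimulation(cfg, seed = 3, steps = 12)
  cm <- cellCounts(res)
  expect_true(all(cm[, "MM"] == 12))
  expect_true(all(cm[, "OB"] == 12))
  expect_true(all(cm[, "OC"] == 12))
})

test_that("pure basal apoptosis decays as exponential survival", {
  # no proliferation; OB basal hazard only; absorption lags 10 steps
  lam <- 0.06
  cfg <- smallConfig(n = 17L, counts = c(MM = 0L, OB = 60L, OC = 0L),
                     P0_ob = 0, beta_ob = 0, lambda0_1 = lam)
  steps <- 30L
  p <- apoptosisProbability(lam, cfg$parameters$dt)
  nrep <- 8
  finals <- vapply(seq_len(nrep), function(s) {
    cm <- cellCounts(runSimulation(cfg, seed = s, steps = steps))
    cm[steps + 1L, "OB"]
  }, 0L)
  # counts include cells still completing the 10-step absorption, so the
  # expectation is survivors(t) + those that entered apoptosis in the
  # last 10 steps
  surv <- (1 - p)^(steps)
  dying <- sum((1 - p)^((steps - 10):(steps - 1)) * p)
  expv <- 60 * (surv + dying)
  sdv <- sqrt(60 * (surv + dying) * (1 - (surv + dying))) / sqrt(nrep)
  expect_lt(abs(mean(finals) - expv), 3 * sdv + 1e-9)
})

test_that("population bookkeeping: counts equal the agent table every
           step and change only by births and absorptions", {
  cfg <- fastCfg()
  st <- initializeState(cfg, seed = 2)
  prev <- st
  for (t in 0:9) {
    nxt <- simStep(prev, t = t, config = cfg)
    a0 <- agents(prev); a1 <- agents(nxt)
    # daughters carry age dt (born this step, then aged once)
    births <- sum(a1$age == cfg$parameters$dt &
                    !(a1$phaseStep > 0 | a1$phase != "none"))
    absorbed <- sum(a0$countdown == 1L)
    expect_equal(nrow(a1), nrow(a0) + births - absorbed)
    expect_equal(sum(occupancy(nxt) != 0L), nrow(a1))
    expect_true(validObject(nxt))
    prev <- nxt
  }
})

test_that("regimen suite is deterministic with seed sharing", {
  cfg <- fastCfg()
  cfg$run$steps <- 6L
  regs <- standardRegimens()[c(1, 7)]
  t1 <- runRegimenSuite(cfg, regs, replicates = 2, seeds = c(4, 5))
  t2 <- runRegimenSuite(cfg, regs, replicates = 2, seeds = c(4, 5))
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 4L)
  expect_equal(unique(t1$regimen), names(regs))
  t0 <- runRegimenSuite(cfg, regs, replicates = 0)
  expect_equal(nrow(t0), 0L)
  # seven standard regimens produce a seven-row summary table
  expect_length(standardRegimens(), 7L)
})

test_that("dosing window gates the drug fields half-open", {
  cfg <- smallConfig(n = 9L, counts = c(MM = 0L, OB = 0L, OC = 0L))
  cfg$parameters$U_d <- 0
  sched <- doseSchedule(GC = 2, start = 1, stop = 3)
  st <- initializeState(cfg, seed = 1)
  s0 <- simStep(st, t = 0, schedule = sched, config = cfg)
  expect_equal(sum(fields(s0)$GC), 0)             # before start
  s1 <- simStep(s0, t = 1, schedule = sched, config = cfg)
  ref <- validateConfig(cfg)$dosing$GC$reference
  gcPerSite <- cfg$parameters$Pe_d * 2 * ref
  expect_equal(sum(fields(s1)$GC), gcPerSite * 9^3, tolerance = 1e-9)
  s2 <- simStep(s1, t = 2, schedule = sched, config = cfg)
  s3 <- simStep(s2, t = 3, schedule = sched, config = cfg)  # stop: no influx
  expect_equal(sum(fields(s3)$GC), sum(fields(s2)$GC), tolerance = 1e-9)
})
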