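sqResolved <- function(T_half = 10, nCycles = 4) {
  resolveSchedule(glucoseSchedule("square_wave", Glc0_on = 2,
                                  Glc0_off = 0, T_on = T_half),
                  2 * T_half * nCycles)
}

test_that("covariance balancedness matches the hand-computed two-point
           value and its sign conventions", {
  res <- sqResolved(10, 2)
  tr <- syntheticSquareTrack(res, 2, glcVals = c(2, 0), atpVals = c(2, 1))
  n <- nrow(tr)
  # two-point distribution with equal dwell: population covariance 0.5
  expect_equal(balancednessCov(tr, res), 0.5 * n / (n - 1))
  # ATP affine in glucose with positive slope: positive covariance
  tr2 <- tr
  tr2$ATP <- 0.3 + 0.7 * tr2$Glc
  expect_gt(balancednessCov(tr2, res), 0)
  # anti-phase ATP: negative
  tr3 <- tr
  tr3$ATP <- ifelse(tr$Glc > 0, 1, 2)
  expect_lt(balancednessCov(tr3, res), 0)
  # constant-glucose schedules have no cycles to average over
  const <- resolveSchedule(glucoseSchedule("constant"), 100)
  expect_error(balancednessCov(tr, const), "cycle")
})

test_that("phase balancedness is the ON-OFF ATP difference and requires
           both phases", {
  res <- sqResolved(10, 2)
  tr <- syntheticSquareTrack(res, 2, glcVals = c(2, 0.01),
                             atpVals = c(2, 0.5))
  expect_equal(balancednessPhase(tr, res), 1.5)
  trC <- tr
  trC$ATP <- 1.3
  expect_equal(balancednessPhase(trC, res), 0)
  # a track shorter than one full cycle fails
  expect_error(balancednessPhase(tr[tr$time <= 5, ], res), "cycle")
  # the two balancedness measures agree in sign on strictly in-phase and
  # strictly anti-phase tracks
  trA <- syntheticSquareTrack(res, 2, c(2, 0.01), c(0.5, 2))
  expect_lt(balancednessPhase(trA, res), 0)
  expect_lt(balancednessCov(trA, res), 0)
  expect_gt(balancednessPhase(tr, res) * balancednessCov(tr, res), 0)
})

test_that("the balanced-state criterion separates balanced from imbalanced
           constant-glucose trajectories", {
  fp <- balancedFixedPoint(refGeno, 2)
  trB <- simulateCell(refGeno, metaboliteState(fp$state[1], fp$state[2],
                                               fp$state[3]), glc = 2,
                      tEnd = 300)
  expect_true(isBalancedTrajectory(trB, refGeno))
  # standard initial conditions also settle into the balanced state
  trB2 <- simulateCell(refGeno, metaboliteState(2, 1, 10.4), glc = 2,
                       tEnd = 300)
  expect_true(isBalancedTrajectory(trB2, refGeno))
  # phosphate-poor start: FBP grows monotonically, never balanced
  trI <- simulateCell(refGeno, metaboliteState(2, 1, 1), glc = 2,
                      tEnd = 300)
  expect_true(all(diff(trI$FBP) > 0))
  expect_false(isBalancedTrajectory(trI, refGeno))
})

test_that("genotypic balancedness lies on the glucose grid, is seed
           reproducible, scan-order invariant, and monotone under UG
           stress", {
  grid <- seq(2, 0.05, by = -0.05)
  set.seed(41)
  b1 <- genotypicBalancedness(refGeno, nInit = 30)
  expect_true(b1 %in% c(0, grid))
  set.seed(41)
  b2 <- genotypicBalancedness(refGeno, nInit = 30)
  expect_identical(b1, b2)
  set.seed(41)
  b3 <- genotypicBalancedness(refGeno, nInit = 30,
                              glcGrid = sample(grid))
  expect_identical(b1, b3)
  # a genotype with negligible UG flux is balanced everywhere
  set.seed(42)
  expect_equal(genotypicBalancedness(genotype(1e-6, 10, 10, 0.3),
                                     nInit = 20), 2)
  # increasing vmax_up at fixed vmax_lo never increases balancedness
  ups <- c(8, 10, 12, 14)
  bs <- sapply(ups, function(u) {
    set.seed(43)
    genotypicBalancedness(genotype(u, 10, 10, 0.3), nInit = 30)
  })
  expect_true(all(diff(bs) <= 0))
  # mode 2 uses the observed state and requires one
  expect_error(genotypicBalancedness(refGeno, mode = 2), "observed")
})

test_that("reproduction rate is the gated growth flux averaged over
           complete cycles", {
  res <- sqResolved(10, 2)
  tr <- syntheticSquareTrack(res, 2, c(2, 0.01), c(1.27, 1.27))
  # constant ATP 1.27 at maximal health: v_atp_g = 12.7 - 5 = 7.7
  r <- reproductionRate(tr, res, refGeno, vatp_e = 5, H_max = 1)
  expect_equal(r, log(2) / 90, tolerance = 1e-12)
  # a cell below maximal health never grows
  tr$H <- 0.8
  expect_equal(reproductionRate(tr, res, refGeno, 5, 1), 0)
  # non-growing cell: ATP too low to cover costs
  tr2 <- syntheticSquareTrack(res, 2, c(2, 0.01), c(0.2, 0.2))
  expect_equal(reproductionRate(tr2, res, refGeno, 5, 1), 0)
  # bounded by the maximal gated growth rate over the window
  tr3 <- syntheticSquareTrack(res, 2, c(2, 0.01), c(2, 0.5))
  r3 <- reproductionRate(tr3, res, refGeno, 5, 1)
  expect_gte(r3, 0)
  expect_lte(r3, physTest$u_g * max(refGeno[["k_atp"]] * tr3$ATP - 5))
})

test_that("fraction balanced counts positive covariance balancedness", {
  expect_equal(fractionBalanced(c(0.2, 1, 3)), 1)
  expect_equal(fractionBalanced(c(-0.2, -1)), 0)
  expect_equal(fractionBalanced(c(1, 2, 3, -1)), 0.75)
  expect_error(fractionBalanced(numeric(0)), "no cells")
})

test_that("competition bookkeeping: monomorphic populations stay
           monomorphic", {
  cfg <- presetConfig("chemostat_pulse_T100_cv5")
  cfg$simulation <- simulationConfig(N0 = 60, N_star = 60, N_tr = 10,
                                     t_s = 0, t_ms = 0, t_me = 0,
                                     t_e = 300, mu = 0, track_start = 301)
  cfg$environment$V_ch <- 1e-10
  ccB <- runCompetition(cfg, f_b0 = 1, seed = 5)
  expect_true(all(ccB$f_b$f_b == 1))
  ccI <- runCompetition(cfg, f_b0 = 0, seed = 5)
  expect_true(all(ccI$f_b$f_b == 0))
  expect_error(runCompetition(cfg, f_b0 = 1.2), "f_b0")
})

test_that("the 4/s fixation-time rule", {
  expect_equal(fixationGenerations(0.03), 400 / 3)
  expect_equal(fixationGenerations(0.03), 133, tolerance = 0.005)
  expect_error(fixationGenerations(0), "positive")
})

test_that("catastrophe heuristic flags a crash-and-recovery", {
  tt <- seq(5, 5000, by = 5)
  N <- rep(1000, length(tt))
  N[tt > 2000 & tt <= 2400] <- 300
  N[tt > 2400] <- 900
  ev <- catastropheEvents(data.frame(time = tt, N = N), cycleLength = 100)
  expect_equal(nrow(ev), 1)
  expect_true(ev$recoveryTime > ev$dropTime)
  expect_null(catastropheEvents(data.frame(time = tt,
                                           N = rep(1000, length(tt))),
                                cycleLength = 100))
})
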