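smallCfg <- function(...) {
  args <- list(...)
  defaults <- list(N0 = 40, N_star = 40, N_tr = 10, t_s = 0, t_ms = 0,
                   t_me = 0, t_e = 100, track_start = 0)
  do.call(simulationConfig, utils::modifyList(defaults, args))
}

test_that("population initialization draws the stated distributions", {
  cfg <- smallCfg(N0 = 20000)
  set.seed(31)
  pop <- initializePopulation(cfg, refGeno, cmTest, physTest, glc = 2)
  expect_true(all(pop$geno[, "vmax_up"] >= 1 &
                  pop$geno[, "vmax_up"] <= 100))
  expect_true(all(pop$geno[, "k_p"] >= 0.03 & pop$geno[, "k_p"] <= 3))
  expect_identical(pop$state[, "H"], pop$Hmax)
  expect_equal(mean(pop$state[, "V"]), physTest$V_c, tolerance = 0.01)
  expect_true(all(pop$state[, "FBP"] == 2 & pop$state[, "ATP"] == 1 &
                  pop$state[, "Pi"] == 10.4))
  expect_equal(sum(pop$tracked), cfg$N_tr)
})

test_that("total cytosolic phosphate is conserved for a non-growing,
           transport-free cell", {
  g <- genotype(10, 10, 10, 1e-9)
  # large expression cost keeps the growth flux negative: no dilution
  tr <- simulateCell(g, metaboliteState(2, 1, 10.4), glc = 2, tEnd = 100,
                     vatp_e = 50)
  ptot <- tr$Pi + 2 * tr$FBP + tr$ATP
  expect_lt(max(abs(ptot - ptot[1])), 1e-2)
  expect_true(all(tr$V == tr$V[1]))
})

test_that("halving solver tolerances moves the endpoint by less than ten
           times the original tolerance", {
  tol1 <- solverTolerances()
  tol2 <- tol1
  tol2$atol_c <- tol1$atol_c / 2
  tol2$rtol_c <- tol1$rtol_c / 2
  a <- simulateCell(refGeno, metaboliteState(2, 1, 1), glc = 2, tEnd = 50,
                    tol = tol1)
  b <- simulateCell(refGeno, metaboliteState(2, 1, 1), glc = 2, tEnd = 50,
                    tol = tol2)
  for (col in c("FBP", "ATP", "Pi")) {
    scale <- tol1$atol_c + tol1$rtol_c * abs(a[[col]][51])
    expect_lt(abs(a[[col]][51] - b[[col]][51]), 10 * scale * 50)
  }
})

test_that("demography is frozen within intervals and events reconcile", {
  cfg <- smallCfg(t_e = 500)
  env <- environmentConfig("ncg", schedule = glucoseSchedule("constant",
                                                             Glc0_on = 2),
                           D = 5, d = 1e-6)
  config <- defaultConfig()
  config$simulation <- cfg
  config$environment <- env
  run <- runSimulation(config, seed = 4, genotypes = rbind(refGeno))
  s <- run$summary
  ctr <- run$population$counters
  expect_equal(nrow(run$population$state),
               cfg$N0 + ctr[["births"]] - ctr[["deaths"]] -
                 ctr[["washouts"]], ignore_attr = TRUE)
  expect_equal(nrow(s), 100)
  # N changes only at interval boundaries by construction; the summary is
  # one row per boundary
  expect_equal(s$time, seq(5, 500, by = 5))
})

test_that("identical seed and configuration reproduce a run exactly", {
  config <- defaultConfig()
  config$simulation <- smallCfg(t_e = 300, t_ms = 100, t_me = 300, mu = 0.2)
  gm <- rbind(refGeno, builtinGenotypes()$BC)
  r1 <- runSimulation(config, seed = 99, genotypes = gm)
  r2 <- runSimulation(config, seed = 99, genotypes = gm)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$population$state, r2$population$state)
  expect_identical(r1$population$geno, r2$population$geno)
  expect_identical(r1$tracks, r2$tracks)
  r3 <- runSimulation(config, seed = 100, genotypes = gm)
  expect_false(identical(r1$summary, r3$summary))
})

test_that("without mutation the set of distinct genotypes never grows", {
  config <- defaultConfig()
  # two fixed genotypes only, mutation disabled throughout
  gm <- rbind(refGeno, builtinGenotypes()$BC)
  config$simulation <- smallCfg(t_e = 400, mu = 0)
  run <- runSimulation(config, seed = 12, genotypes = gm,
                       types = c(1L, 2L))
  key <- unique(apply(run$population$geno, 1, paste, collapse = ";"))
  key0 <- apply(gm, 1, paste, collapse = ";")
  expect_true(all(key %in% key0))
})

test_that("division at a boundary conserves volume and passes mutation only
           during the mutation-on segment", {
  config <- defaultConfig()
  config$simulation <- smallCfg(N0 = 10, t_e = 300, mu = 0.9, t_ms = 100,
                                t_me = 200)
  set.seed(77)
  pop <- initializePopulation(config$simulation, refGeno, cmTest, physTest,
                              glc = 2)
  pop$state[, "V"] <- 2.2 * physTest$V_c
  streams <- glycosim:::makeStreams(5)
  pop2 <- lifecycleUpdate(pop, config$environment, config$simulation,
                          physTest, cmTest, mutationOn = FALSE, streams)
  expect_equal(nrow(pop2$state), 20)
  expect_equal(sum(pop2$state[, "V"]), 10 * 2.2 * physTest$V_c,
               tolerance = 1e-12)
  # mutation off: both daughters carry the parental genotype
  expect_equal(sort(unique(round(pop2$geno[, 1], 9))),
               sort(unique(round(pop$geno[, 1], 9))))
  expect_identical(pop2$counters[["births"]], 10)
  # all daughters start at their fresh maximal health
  expect_identical(pop2$state[, "H"], pop2$Hmax)

  pop3 <- lifecycleUpdate(pop, config$environment, config$simulation,
                          physTest, cmTest, mutationOn = TRUE, streams)
  expect_gt(length(unique(round(pop3$geno[, 1], 9))),
            length(unique(round(pop$geno[, 1], 9))))
})

test_that("a small constant-glucose population persists with positive mean
           growth flux", {
  config <- presetConfig("ncg_constant")
  config$simulation <- simulationConfig(N0 = 2000, N_star = 150, N_tr = 20,
                                        t_s = 0, t_ms = 1000, t_me = 4000,
                                        t_e = 5000, track_start = 5001)
  config$environment$d <- 1e-5
  run <- runSimulation(config, seed = 8)
  expect_identical(run$status, "completed")
  expect_gt(nrow(run$population$state), 50)
  vatpg <- run$population$geno[, "k_atp"] * run$population$state[, "ATP"] -
    run$population$vatpe
  expect_gt(mean(vatpg), 0)
})

test_that("an empty interval and a zero-duration run are handled", {
  config <- defaultConfig()
  config$simulation <- smallCfg(t_e = 0)
  run <- runSimulation(config, seed = 2)
  expect_equal(run$population$time, 0)
  expect_equal(nrow(run$population$state), 40)
  expect_identical(run$status, "completed")
})

test_that("the built-in integrator agrees with an independent ode45
           integration of the same dynamics", {
  g <- refGeno
  rhs <- function(t, y, p) {
    s <- c(FBP = max(y[1], 0), ATP = min(max(y[2], 0), kinTest$a_tot),
           Pi = max(y[3], 0))
    vatpg <- growthFlux(atpaseRate(s, g), 5, physTest)
    gr <- volumeRate(vatpg, y[5], 1, physTest)
    d <- metaboliteDerivatives(s, 2, gr, g, kinTest)
    list(c(d, gr * y[4], healthRate(vatpg, y[5], 1, physTest)))
  }
  for (y0 in list(c(2, 1, 10.4, physTest$V_c, 1),
                  c(2, 1, 1, physTest$V_c, 1))) {
    o <- deSolve::ode(y0, seq(0, 100, 1), rhs, NULL, method = "ode45",
                      atol = 1e-10, rtol = 1e-10)
    tr <- simulateCell(g, metaboliteState(y0[1], y0[2], y0[3]), glc = 2,
                       tEnd = 100)
    expect_lt(max(abs(o[, 2:4] -
                        as.matrix(tr[, c("FBP", "ATP", "Pi")]))), 5e-4)
    expect_equal(o[101, 5], tr$V[101], tolerance = 1e-4,
                 ignore_attr = TRUE)
  }
})
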