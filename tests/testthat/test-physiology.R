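test_that("expression cost reproduces the normalization and the competitor
           genotype costs", {
  bg <- builtinGenotypes()
  expect_equal(cmTest$k_e, 5 / 30000.0081)
  expect_equal(expressionCost(bg$reference, cmTest), 5, tolerance = 1e-15)
  expect_equal(round(expressionCost(bg$BC, cmTest), 2), 2.24)
  expect_equal(round(expressionCost(bg$IC, cmTest), 2), 2.63)
  expect_error(expressionCost(bg$BC, costModel()), "normalized")
})

test_that("the two cost variants coincide at exponent 1 and scale linearly
           in the reference cost", {
  set.seed(1)
  c1 <- normalizeCost(costModel("power_sum", n = 1))
  c2 <- normalizeCost(costModel("power_of_sum", n = 1))
  for (i in 1:20) {
    g <- genotype(runif(4, 0.1, 20))
    expect_equal(expressionCost(g, c1), expressionCost(g, c2))
  }
  cDouble <- normalizeCost(costModel(vatp_e_ref = 10))
  g <- genotype(3, 7, 2, 1)
  expect_equal(expressionCost(g, cDouble), 2 * expressionCost(g, cmTest))
})

test_that("growth flux arithmetic and gating of volume and health rates", {
  expect_equal(growthFlux(12.7, 5, physTest), 7.7)
  expect_equal(growthFlux(0.46, 5, physTest), -4.54)
  expect_equal(growthFlux(5, 5, physTest), 0)

  expect_equal(volumeRate(7.7, 1, 1, physTest), log(2) / 90)
  expect_equal(volumeRate(7.7, 0.95, 1, physTest), 0)
  expect_equal(volumeRate(-1, 1, 1, physTest), 0)
  expect_equal(volumeRate(0, 1, 1, physTest), 0)

  expect_equal(healthRate(-4.54, 0.5, 1, physTest), -1 / 420)
  expect_equal(healthRate(7.7, 1, 1, physTest), 0)
  expect_equal(healthRate(7.7, 0.5, 1, physTest), log(2) / 90)
})

test_that("calibration identities hold exactly", {
  expect_equal(physTest$u_g * (12.7 - 5 - 0), log(2) / 90, tolerance = 1e-15)
  expect_equal(physTest$u_d * (0.46 - 5 - 0), 1 / 420, tolerance = 1e-15)
  expect_lt(physTest$u_d, 0)  # literal sign convention
  expect_error(physiologyParameters(vatp_e_ref = 13), "positive")
  expect_error(physiologyParameters(vatp_ref_imbalanced = 6), "negative")
})

test_that("division conserves volume, copies concentrations, and draws the
           stated volume distribution", {
  parent <- newCell(refGeno, metaboliteState(3, 1.2, 9), 2.2 * physTest$V_c,
                    H_max = 1.05, cm = cmTest)
  set.seed(7)
  d <- divideCell(parent, physTest)
  expect_equal(d[[1]]$V + d[[2]]$V, parent$V)
  expect_identical(d[[1]]$state, parent$state)
  expect_identical(d[[2]]$state, parent$state)
  expect_identical(d[[1]]$genotype, parent$genotype)
  expect_equal(d[[1]]$H, d[[1]]$H_max)
  expect_true(all(c(d[[1]]$H_max, d[[2]]$H_max) >= 0.9))
  expect_true(all(c(d[[1]]$H_max, d[[2]]$H_max) <= 1.1))
  small <- newCell(refGeno, parent$state, 1.5 * physTest$V_c, cm = cmTest)
  expect_error(divideCell(small, physTest), "division volume")

  # distributional check: first-daughter volumes are uniform on
  # (0.5, 1.5) * V_c when the parent sits exactly at 2 * V_c
  p2 <- newCell(refGeno, parent$state, 2 * physTest$V_c, cm = cmTest)
  set.seed(11)
  v1 <- replicate(2000, divideCell(p2, physTest)[[1]]$V)
  ks <- suppressWarnings(
    ks.test(v1, "punif", 0.5 * physTest$V_c, 1.5 * physTest$V_c))
  expect_gt(ks$p.value, 0.01)
})

test_that("mutation is a multiplicative log-normal step applied per
           parameter with probability mu", {
  expect_identical(mutateGenotype(refGeno, mu = 0), refGeno)
  set.seed(3)
  g <- mutateGenotype(refGeno, mu = 1, sigma = 1e-12)
  expect_equal(g, refGeno, tolerance = 1e-9)
  set.seed(5)
  n <- 1e4
  ratios <- replicate(n, mutateGenotype(refGeno, 1, 0.1)[["vmax_up"]] / 10)
  lr <- log(ratios)
  expect_equal(mean(lr), 0, tolerance = 0.005)
  expect_equal(sd(lr), 0.1, tolerance = 0.02)
  # medians of mutated parameters equal parental values
  expect_equal(median(ratios), 1, tolerance = 0.01)
  # partial mutation: with small mu most parameters are inherited exactly
  set.seed(9)
  hits <- replicate(2000, sum(mutateGenotype(refGeno, 0.01, 0.1) != refGeno))
  expect_equal(mean(hits), 0.04, tolerance = 0.3)
})

test_that("volume grows exponentially and health declines linearly at
           constant growth flux", {
  fp <- balancedFixedPoint(refGeno, 2)
  tr <- simulateCell(refGeno,
                     metaboliteState(fp$state[1], fp$state[2], fp$state[3]),
                     glc = 2, tEnd = 100)
  fit <- lm(log(tr$V) ~ tr$time)
  expect_equal(unname(coef(fit)[2]), fp$fracGrowth, tolerance = 1e-4)
  expect_gt(summary(fit)$r.squared, 1 - 1e-10)

  # starving cell (no glucose): ATP collapses, then H falls linearly at
  # the maximal-deficit rate u_d * (vatp_e + vatp_m)
  trS <- simulateCell(refGeno, metaboliteState(0, 0.01, 1), glc = 0,
                      tEnd = 200)
  late <- trS[trS$time >= 50, ]
  slope <- coef(lm(late$H ~ late$time))[2]
  expect_equal(unname(slope), physTest$u_d * 5, tolerance = 1e-3)
})
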