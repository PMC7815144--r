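test_that("upper glycolysis rate matches direct evaluation and limits", {
  s <- metaboliteState(3.6, 1.27, 10)
  expect_equal(upperGlycolysisRate(s, 0, refGeno, kinTest), 0)
  s0 <- metaboliteState(3.6, 0, 10)
  expect_equal(upperGlycolysisRate(s0, 2, refGeno, kinTest), 0)
  # direct scalar evaluation of the ATP-inhibited two-substrate form
  vup <- 10 * 2 * 1.27 / ((0.1 + 2) * (0.1 + 1.27 * (1 + 1.27 / 3)))
  expect_equal(upperGlycolysisRate(s, 2, refGeno, kinTest), vup)
  expect_equal(vup, 6.3404, tolerance = 1e-4)
  # consistent with a balanced ATPase flux of 12.7 = 2 * v_up
  expect_equal(2 * vup, 12.7, tolerance = 0.01)
  expect_error(upperGlycolysisRate(s, -1, refGeno, kinTest), "negative")
})

test_that("upper glycolysis rate is unimodal in ATP with the predicted
           interior maximum", {
  atp <- seq(0.001, 4.999, by = 0.001)
  v <- vapply(atp, function(a)
    upperGlycolysisRate(metaboliteState(2, a, 10), 2, refGeno, kinTest),
    numeric(1))
  peak <- atp[which.max(v)]
  expect_equal(peak, sqrt(kinTest$KM_atp * kinTest$Ki_atp),
               tolerance = 2e-3)
  expect_equal(peak, 0.548, tolerance = 1e-2)
  # single sign change of the finite differences: unimodal
  sgn <- sign(diff(v))
  expect_equal(sum(diff(sgn) != 0), 1)
})

test_that("rates are monotone in substrates and scale linearly in their
           genotype parameter", {
  glcs <- seq(0.1, 10, by = 0.1)
  s <- metaboliteState(2, 1, 10)
  vg <- vapply(glcs, function(g)
    upperGlycolysisRate(s, g, refGeno, kinTest), numeric(1))
  expect_true(all(diff(vg) > 0))
  for (up in list(c("FBP", 1), c("ATP", 2), c("Pi", 3))) {
    base <- c(FBP = 1, ATP = 1, Pi = 5)
    vs <- vapply(seq(0.1, 4, 0.1), function(x) {
      b <- base; b[up[[1]]] <- x
      lowerGlycolysisRate(metaboliteState(b[1], b[2], b[3]), refGeno,
                          kinTest)
    }, numeric(1))
    if (up[[1]] == "ATP") vs <- rev(vs)  # more ATP means less ADP substrate
    expect_true(all(diff(vs) > 0))
  }
  g2 <- genotype(20, 10, 10, 0.3)
  expect_equal(upperGlycolysisRate(s, 2, g2, kinTest),
               2 * upperGlycolysisRate(s, 2, refGeno, kinTest))
  g3 <- genotype(10, 20, 10, 0.3)
  expect_equal(lowerGlycolysisRate(s, g3, kinTest),
               2 * lowerGlycolysisRate(s, refGeno, kinTest))
})

test_that("lower glycolysis rate: direct value, zero-substrate and
           saturation limits", {
  expect_equal(lowerGlycolysisRate(metaboliteState(3.6, 1.27, 0), refGeno,
                                   kinTest), 0)
  vlo <- 10 * 3.6 * (5 - 1.27) * 10 /
    ((1 + 3.6) * (0.1 + (5 - 1.27)) * (2 + 10))
  expect_equal(lowerGlycolysisRate(metaboliteState(3.6, 1.27, 10), refGeno,
                                   kinTest), vlo)
  expect_equal(vlo, 6.35, tolerance = 1e-3)
  # saturation in FBP and Pi at maximal ADP approaches vmax_lo
  sat <- lowerGlycolysisRate(metaboliteState(1e7, 0, 1e7), refGeno, kinTest)
  expect_gt(sat, 0.97 * refGeno[["vmax_lo"]])
  expect_lt(sat, refGeno[["vmax_lo"]])
  expect_error(
    lowerGlycolysisRate(list(FBP = 1, ATP = 6, Pi = 1), refGeno, kinTest),
    "a_tot")
})

test_that("ATPase rate is first order", {
  expect_equal(atpaseRate(metaboliteState(1, 0, 1), refGeno), 0)
  expect_equal(atpaseRate(metaboliteState(1, 1, 1), refGeno), 10)
  expect_equal(atpaseRate(metaboliteState(1, 1.27, 1), refGeno), 12.7)
})

test_that("vacuolar phosphate buffering is a decreasing sigmoid with the
           stated anchors", {
  expect_equal(vacuolePhosphate(0, kinTest), 10)
  expect_equal(vacuolePhosphate(250, kinTest), 5)
  expect_equal(vacuolePhosphate(500, kinTest), 10 / 17)
  p <- seq(0, 1000, by = 5)
  expect_true(all(diff(vacuolePhosphate(p, kinTest)) < 0))
})

test_that("phosphate transport follows the vacuole-cytosol gradient", {
  # equilibrium: cytosolic Pi equal to the buffered vacuolar level
  piEq <- uniroot(function(p) vacuolePhosphate(p, kinTest) - p, c(0, 10),
                  tol = 1e-12)$root
  expect_equal(phosphateTransportRate(metaboliteState(0, 0, piEq), refGeno,
                                      kinTest), 0, tolerance = 1e-9)
  s2 <- metaboliteState(0.05, 0.1, 0.81)
  expect_equal(phosphateTransportRate(s2, refGeno, kinTest), 2.76,
               tolerance = 2e-3)
  s3 <- metaboliteState(0, 0, 20)
  expect_lt(phosphateTransportRate(s3, refGeno, kinTest), 0)
})

test_that("metabolite derivatives conserve phosphate accounting on random
           states", {
  set.seed(42)
  for (i in 1:200) {
    s <- metaboliteState(runif(1, 0, 100), runif(1, 0, 5), runif(1, 0, 30))
    g <- genotype(runif(4, 0.1, 20))
    fg <- runif(1, 0, 0.01)
    d <- metaboliteDerivatives(s, runif(1, 0, 5), fg, g, kinTest)
    ptot <- s[["Pi"]] + 2 * s[["FBP"]] + s[["ATP"]]
    dptot <- d[["Pi"]] + 2 * d[["FBP"]] + d[["ATP"]]
    vp <- phosphateTransportRate(s, g, kinTest)
    expect_equal(dptot, vp - ptot * fg, tolerance = 1e-12)
  }
})

test_that("all derivatives vanish at the balanced fixed point", {
  fp <- balancedFixedPoint(refGeno, 2)
  expect_lt(fp$residual, 1e-9)
  d <- metaboliteDerivatives(fp$state, 2, fp$fracGrowth, refGeno, kinTest)
  expect_true(all(abs(d) < 1e-9))
  expect_gt(fp$fracGrowth, 0)
})
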