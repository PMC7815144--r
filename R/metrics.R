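# Balancedness statistics and downstream analyses. A "track" throughout is
# the long-format record of one tracked cell: columns time, FBP, ATP, Pi,
# V, H, Glc sampled every dt_s.

# Complete supply cycles fully covered by the track's time range.
.completeCycles <- function(times, resolved) {
  cyc <- resolved$cycles
  if (is.null(cyc)) stop("schedule has no cycles (constant supply)")
  dt <- if (length(times) > 1) min(diff(sort(times))) else 0
  lo <- min(times) - dt - 1e-9
  hi <- max(times) + 1e-9
  cyc[cyc$start >= lo & cyc$end <= hi, , drop = FALSE]
}

.cycleWindowSamples <- function(track, resolved) {
  cyc <- .completeCycles(track$time, resolved)
  if (nrow(cyc) < 1)
    stop("track does not span a full supply cycle")
  sel <- track$time > cyc$start[1] + 1e-9 &
         track$time <= cyc$end[nrow(cyc)] + 1e-9
  list(track = track[sel, , drop = FALSE], cycles = cyc)
}

#' Phenotypic balancedness as glucose-ATP covariance
#'
#' Sample covariance between the external glucose concentration and the
#' intracellular ATP concentration over the largest integral number of
#' supply cycles covered by the track. Positive values indicate balanced
#' dynamics (high ATP coincides with high glucose), negative values
#' imbalanced dynamics.
#'
#' @param track Track data frame of a single cell.
#' @param resolved Resolved supply schedule (provides cycle boundaries).
#' @return Covariance in mM^2.
#' @export
balancednessCov <- function(track, resolved) {
  w <- .cycleWindowSamples(track, resolved)
  stats::cov(w$track$Glc, w$track$ATP)
}

#' Phenotypic balancedness as ON-OFF ATP difference
#'
#' Mean intracellular ATP during ON phases minus mean ATP during OFF
#' phases, over the complete cycles covered by the track. Positive for
#' balanced cells (ATP is high while glucose is supplied), negative for
#' imbalanced cells (ATP is produced from stored FBP during starvation).
#'
#' @inheritParams balancednessCov
#' @return Difference of means in mM.
#' @export
balancednessPhase <- function(track, resolved) {
  w <- .cycleWindowSamples(track, resolved)
  cyc <- w$cycles
  tt <- w$track$time
  idx <- findInterval(tt - 1e-9, cyc$start)
  on <- idx >= 1 & tt <= cyc$onEnd[pmax(idx, 1)] + 1e-9
  if (!any(on) || all(on))
    stop("track must contain both ON and OFF phase samples")
  mean(w$track$ATP[on]) - mean(w$track$ATP[!on])
}

# Fluxes recomputed from sampled states.
.trackFluxes <- function(track, geno, kin, phys, vatp_e, H_max) {
  G <- pmax(track$Glc, 0)
  A <- pmin(pmax(track$ATP, 0), kin$a_tot)
  F <- pmax(track$FBP, 0)
  P <- pmax(track$Pi, 0)
  adp <- kin$a_tot - A
  vup <- geno[["vmax_up"]] * G * A /
    ((kin$KM_glc + G) * (kin$KM_atp + A * (1 + A / kin$Ki_atp)))
  vlo <- geno[["vmax_lo"]] * F * adp * P /
    ((kin$KM_fbp + F) * (kin$KM_adp + adp) * (kin$KM_p + P))
  vatp <- geno[["k_atp"]] * A
  vatpg <- vatp - (vatp_e + phys$vatp_m)
  atmax <- track$H >= H_max - 1e-9
  g <- ifelse(atmax & vatpg > 0, phys$u_g * vatpg, 0)
  list(vup = vup, vlo = vlo, vatp = vatp, vatpg = vatpg, fracGrowth = g)
}

#' Balanced-state criterion for a constant-glucose trajectory
#'
#' In a balanced phenotype at constant glucose, FBP settles to a steady
#' state in which the UG flux equals the LG flux plus the dilution of FBP
#' by growth: `v_up = v_lo + FBP * V'/V`. The trajectory is classified
#' balanced if this identity holds within 0.1 % relative error for more
#' than 10 % of the simulated time. Samples with `v_up = 0` are assessed
#' with the absolute metabolite tolerance instead.
#'
#' @param track Track data frame from a constant-glucose single-cell run
#'   (e.g. [simulateCell()]).
#' @param geno Genotype of the cell.
#' @param vatp_e Its expression cost (mM/min).
#' @param H_max Its maximal health.
#' @param kin,phys Kinetics and physiology parameters.
#' @param relTol Relative flux-balance tolerance.
#' @param timeFrac Fraction of samples that must satisfy the balance.
#' @param atol Absolute fallback tolerance (mM/min).
#' @return `TRUE` if the trajectory is balanced.
#' @export
isBalancedTrajectory <- function(track, geno, vatp_e = 5, H_max = 1,
                                 kin = kineticParameters(),
                                 phys = physiologyParameters(),
                                 relTol = 1e-3, timeFrac = 0.1,
                                 atol = 1e-5) {
  fl <- .trackFluxes(track, geno, kin, phys, vatp_e, H_max)
  resid <- abs(fl$vup - (fl$vlo + track$FBP * fl$fracGrowth))
  ok <- ifelse(fl$vup > 0, resid / fl$vup < relTol, resid < atol)
  mean(ok) > timeFrac
}

#' Genotypic balancedness
#'
#' The propensity of a genotype to exhibit balanced dynamics: for glucose
#' concentrations scanned over `glcGrid` (2.00, 1.95, ..., 0.05 mM by
#' default), `nInit` single-cell trajectories of `tSim` minutes are
#' simulated from initial metabolite concentrations drawn normally (CV 6 %)
#' around either the standard means FBP 2, ATP 1, Pi 10 mM (mode 1) or an
#' observed metabolite state of an evolved cell (mode 2), truncated to
#' valid ranges. The result is the largest glucose concentration at which
#' all trajectories are balanced, or 0 if none is. Uses the current R
#' random stream; the result does not depend on the order in which the
#' grid is scanned.
#'
#' @param geno Genotype.
#' @param mode 1 (standard means) or 2 (observed means).
#' @param observedState Metabolite state of an evolved cell (mode 2).
#' @param kin,phys Kinetics and physiology parameters.
#' @param vatp_e Expression cost of the genotype (mM/min).
#' @param glcGrid Glucose grid (mM), scanned from the largest value down.
#' @param nInit Number of random initializations per glucose value.
#' @param tSim Length of each trajectory (min).
#' @param cv Coefficient of variation of the initial concentrations.
#' @return Balancedness in mM (an element of `glcGrid`, or 0).
#' @export
genotypicBalancedness <- function(geno, mode = 1, observedState = NULL,
                                  kin = kineticParameters(),
                                  phys = physiologyParameters(),
                                  vatp_e = 5,
                                  glcGrid = seq(2, 0.05, by = -0.05),
                                  nInit = 100, tSim = 300, cv = 0.06) {
  mode <- match.arg(as.character(mode), c("1", "2"))
  means <- if (mode == "1") c(2, 1, 10) else {
    if (is.null(observedState))
      stop("mode 2 requires an observed metabolite state")
    as.numeric(observedState[c("FBP", "ATP", "Pi")])
  }
  glcGrid <- sort(glcGrid, decreasing = TRUE)
  # draw all initializations up front so the scan order cannot matter
  inits <- lapply(seq_along(glcGrid), function(i) {
    m <- matrix(stats::rnorm(3 * nInit, rep(means, each = nInit),
                             rep(cv * means, each = nInit)), nInit, 3)
    m[m < 0] <- 0
    m[, 2] <- pmin(m[, 2], kin$a_tot)
    m
  })
  for (i in seq_along(glcGrid)) {
    if (.allBalancedAt(geno, glcGrid[i], inits[[i]], kin, phys, vatp_e,
                       tSim))
      return(glcGrid[i])
  }
  0
}

# Simulate nInit cells at constant glc in one integrator call and test the
# balance criterion on every trajectory.
.allBalancedAt <- function(geno, glc, inits, kin, phys, vatp_e, tSim) {
  n <- nrow(inits)
  st <- cbind(inits, rep(phys$V_c, n), rep(1, n))
  gm <- matrix(genotype(geno), n, 4, byrow = TRUE)
  physL <- list(u_g = phys$u_g, u_d = phys$u_d, vatp_m = phys$vatp_m)
  times <- seq(1, tSim, by = 1)
  res <- cppIntegrateNCG(st, gm, rep(vatp_e, n), rep(1, n), unclass(kin),
                         physL, pop_tol(solverTolerances()), 0, times,
                         rep(TRUE, length(times)),
                         rep(FALSE, length(times)), 0, glc, glc, 0,
                         seq_len(n) - 1L)
  if (!res$ok) return(FALSE)
  a <- res$samples  # n x tSim x 6
  A <- pmin(pmax(a[, , 2, drop = FALSE], 0), kin$a_tot)[, , 1]
  F <- pmax(a[, , 1, drop = FALSE], 0)[, , 1]
  P <- pmax(a[, , 3, drop = FALSE], 0)[, , 1]
  H <- a[, , 5, drop = FALSE][, , 1]
  if (n == 1) { A <- rbind(A); F <- rbind(F); P <- rbind(P); H <- rbind(H) }
  adp <- kin$a_tot - A
  vup <- geno[["vmax_up"]] * glc * A /
    ((kin$KM_glc + glc) * (kin$KM_atp + A * (1 + A / kin$Ki_atp)))
  vlo <- geno[["vmax_lo"]] * F * adp * P /
    ((kin$KM_fbp + F) * (kin$KM_adp + adp) * (kin$KM_p + P))
  vatpg <- geno[["k_atp"]] * A - vatp_e - phys$vatp_m
  g <- ifelse(H >= 1 - 1e-9 & vatpg > 0, phys$u_g * vatpg, 0)
  resid <- abs(vup - (vlo + F * g))
  ok <- ifelse(vup > 0, resid / vup < 1e-3, resid < 1e-5)
  all(rowMeans(ok) > 0.1)
}

#' Cell reproduction rate over complete supply cycles
#'
#' Time average of the fractional volume increase rate `V'/V` (equivalent
#' to the reproduction rate in population-dynamic terms), recomputed from
#' the gated growth flux `u_g * v_atp_g` at each sample, so division
#' discontinuities in the volume trace do not enter.
#'
#' @param track Track data frame of a single cell.
#' @param resolved Resolved supply schedule.
#' @param geno Genotype of the cell.
#' @param vatp_e Its expression cost.
#' @param H_max Its maximal health.
#' @param kin,phys Kinetics and physiology parameters.
#' @return Mean reproduction rate (1/min).
#' @export
reproductionRate <- function(track, resolved, geno, vatp_e = 5, H_max = 1,
                             kin = kineticParameters(),
                             phys = physiologyParameters()) {
  w <- .cycleWindowSamples(track, resolved)
  fl <- .trackFluxes(w$track, geno, kin, phys, vatp_e, H_max)
  mean(fl$fracGrowth)
}

#' Fraction of balanced cells
#'
#' A cell counts as balanced when its phenotypic balancedness (glucose-ATP
#' covariance) is positive.
#'
#' @param B_cov Numeric vector of per-cell covariance balancedness values.
#' @return Fraction in `[0, 1]`.
#' @export
fractionBalanced <- function(B_cov) {
  if (!length(B_cov)) stop("no cells supplied")
  mean(B_cov > 0)
}

#' Balancedness report for all tracked cells of a run
#'
#' Computes per-cell phenotypic balancedness (both definitions where
#' available) and the reproduction rate over the complete supply cycles
#' covered by each cell's track. Cells whose track does not span at least
#' one full cycle are dropped.
#'
#' @param run A `glycoRun`.
#' @return Data frame: cell, type, B_p_cov, B_p_phs, r, cycles.
#' @export
balancednessReport <- function(run) {
  if (is.null(run$tracks)) stop("run has no tracked samples")
  balancednessTable(run$tracks, run$trackedCells, run$resolved,
                    run$config$kinetics, run$config$physiology)
}

#' Balancedness table from raw track components
#'
#' Same computation as [balancednessReport()], but from the long tracks
#' table, the per-cell constants table and the cycle boundaries directly
#' (as written by [writeOutputs()]), so reports can be rebuilt from files.
#'
#' @param tracks Long-format track samples (time, cell, FBP, ATP, Pi, V,
#'   H, Glc).
#' @param cells Per-cell constants (cell, vmax_up, vmax_lo, k_atp, k_p,
#'   vatp_e, H_max, type).
#' @param resolved Resolved schedule, or any list with a `cycles` data
#'   frame (start, onEnd, end).
#' @param kin,phys Kinetics and physiology parameters.
#' @return Data frame: cell, type, B_p_cov, B_p_phs, r, cycles.
#' @export
balancednessTable <- function(tracks, cells, resolved,
                              kin = kineticParameters(),
                              phys = physiologyParameters()) {
  out <- lapply(seq_len(nrow(cells)), function(i) {
    id <- cells$cell[i]
    tr <- tracks[tracks$cell == id, , drop = FALSE]
    g <- genotype(as.numeric(cells[i, c("vmax_up", "vmax_lo", "k_atp",
                                        "k_p")]))
    res <- try({
      w <- .cycleWindowSamples(tr, resolved)
      data.frame(cell = id, type = cells$type[i],
                 B_p_cov = balancednessCov(tr, resolved),
                 B_p_phs = balancednessPhase(tr, resolved),
                 r = reproductionRate(tr, resolved, g, cells$vatp_e[i],
                                      cells$H_max[i], kin, phys),
                 cycles = nrow(w$cycles))
    }, silent = TRUE)
    if (inherits(res, "try-error")) NULL else res
  })
  do.call(rbind, out)
}

#' Two-genotype competition experiment
#'
#' Runs the chemostat engine with exactly two genotypes (no mutation) from
#' an initial balanced-cell fraction `f_b0`, and reports the trajectory of
#' the balanced-type fraction together with per-type mean reproduction
#' rates of tracked cells over the final complete cycles.
#'
#' @param config Full run configuration (chemostat environment).
#' @param f_b0 Initial fraction of the balanced genotype.
#' @param seed Integer seed.
#' @param genotypeBC,genotypeIC The two competing genotypes (defaults: the
#'   built-in balanced/imbalanced competitor pair).
#' @param calibrate Calibrate `V_ch` with a pre-simulation first.
#' @return List with `f_b` (data frame time, f_b), `rates` (per-type mean
#'   reproduction rate, possibly `NULL` if no track spans a cycle) and
#'   `run` (the full `glycoRun`).
#' @export
runCompetition <- function(config, f_b0 = 0.5, seed = 1,
                           genotypeBC = builtinGenotypes()$BC,
                           genotypeIC = builtinGenotypes()$IC,
                           calibrate = FALSE) {
  if (f_b0 < 0 || f_b0 > 1) stop("f_b0 must lie in [0, 1]")
  if (config$environment$mode != "chemostat")
    stop("competition experiments use the chemostat environment")
  config$simulation$mu <- 0
  n <- config$simulation$N0
  nb <- round(f_b0 * n)
  gm <- rbind(matrix(genotypeBC, max(nb, 1), 4, byrow = TRUE),
              matrix(genotypeIC, max(n - nb, 1), 4, byrow = TRUE))
  types <- c(rep(1L, max(nb, 1)), rep(2L, max(n - nb, 1)))
  if (nb == 0) { gm <- gm[-1, , drop = FALSE]; types <- types[-1] }
  if (nb == n) { gm <- gm[seq_len(n), , drop = FALSE]
                 types <- types[seq_len(n)] }
  run <- runSimulation(config, seed = seed, calibrate = calibrate,
                       genotypes = gm, types = types)
  rates <- NULL
  rep <- try(balancednessReport(run), silent = TRUE)
  if (!inherits(rep, "try-error") && !is.null(rep))
    rates <- tapply(rep$r, rep$type, mean)
  list(f_b = data.frame(time = run$summary$time,
                        f_b = run$summary$f_type1),
       rates = rates, run = run)
}

#' Expected fixation time of a beneficial strategy
#'
#' Rule-of-thumb sweep time of a beneficial allele starting at frequency
#' 0.5 with selective advantage `s`: about `4 / s` generations.
#'
#' @param s Selective advantage (dimensionless).
#' @return Expected number of generations.
#' @export
fixationGenerations <- function(s) {
  if (s <= 0) stop("s must be positive")
  4 / s
}

#' Detect population catastrophes (summary heuristic)
#'
#' A simple reporting heuristic, not a statistic from the underlying
#' model analysis: a catastrophe is a drop of more than 50 % of the
#' population within one mean supply cycle, followed by a recovery above
#' 80 % of the pre-drop size.
#'
#' @param summary Per-interval population summary (from a `glycoRun`).
#' @param cycleLength Mean supply cycle length (min).
#' @return Data frame of events (dropTime, preN, minN, recoveryTime), or
#'   `NULL` if none found.
#' @export
catastropheEvents <- function(summary, cycleLength) {
  tt <- summary$time
  N <- summary$N
  events <- NULL
  i <- 1L
  lag <- max(1L, round(cycleLength / diff(tt[1:2])))
  while (i + lag <= length(N)) {
    if (N[i + lag] < 0.5 * N[i]) {
      j <- i + lag
      while (j < length(N) && N[j + 1] < N[j]) j <- j + 1L
      rec <- which(N[j:length(N)] > 0.8 * N[i])[1]
      events <- rbind(events,
                      data.frame(dropTime = tt[i], preN = N[i],
                                 minN = N[j],
                                 recoveryTime = if (is.na(rec)) NA_real_
                                                else tt[j + rec - 1L]))
      i <- if (is.na(rec)) length(N) else j + rec - 1L
    }
    i <- i + 1L
  }
  events
}
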