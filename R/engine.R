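#' Simulation protocol configuration
#'
#' Times follow the three-segment protocol: mutation is disabled from `t_s`
#' to `t_ms` (so that a viable steady-state population establishes itself
#' from the initial standing variation), enabled on `[t_ms, t_me)`, and
#' disabled again until `t_e` so that only the fittest genotypes remain.
#' Demography (division, death, washout) is applied only at `dt_p`
#' boundaries; within an interval the population composition is frozen and
#' all cells (plus chamber glucose in a chemostat) are integrated jointly.
#'
#' @param N0 Initial population size.
#' @param N_star Target population size after calibration.
#' @param N_tr Number of tracked cells.
#' @param t_s,t_ms,t_me,t_e Segment boundaries (min).
#' @param dt_p Demographic interval (min).
#' @param dt_s Sampling interval for tracked cells (min).
#' @param mu Per-parameter mutation probability at division.
#' @param sigma Log-scale mutation effect standard deviation.
#' @param init_genotype_span Initial genotypes are drawn uniformly from
#'   `(P/span, span * P)` around each reference parameter `P`.
#' @param track_start Time from which tracked-cell samples are recorded
#'   (min); earlier dynamics is simulated but not stored.
#' @param mutate_both_daughters If `TRUE` (default) mutation is applied
#'   independently to both daughters at division.
#' @param tol Solver tolerance list (see [solverTolerances()]).
#' @return List of class `glycoSimConfig`.
#' @export
simulationConfig <- function(N0 = 10000, N_star = 10000, N_tr = 100,
                             t_s = 0, t_ms = 10000, t_me = 500000,
                             t_e = 800000, dt_p = 5, dt_s = 1, mu = 0.01,
                             sigma = 0.1, init_genotype_span = 10,
                             track_start = t_s,
                             mutate_both_daughters = TRUE,
                             tol = solverTolerances()) {
  if (!(t_s <= t_ms && t_ms <= t_me && t_me <= t_e))
    stop("segment times must satisfy t_s <= t_ms <= t_me <= t_e")
  if (dt_s > dt_p) stop("dt_s must not exceed dt_p")
  if (any(unlist(tol)[c("atol_c", "rtol_c", "atol_v", "atol_h")] <= 0))
    stop("tolerances must be positive")
  structure(list(N0 = N0, N_star = N_star, N_tr = N_tr, t_s = t_s,
                 t_ms = t_ms, t_me = t_me, t_e = t_e, dt_p = dt_p,
                 dt_s = dt_s, mu = mu, sigma = sigma,
                 init_genotype_span = init_genotype_span,
                 track_start = track_start,
                 mutate_both_daughters = mutate_both_daughters, tol = tol),
            class = "glycoSimConfig")
}

#' Default ODE solver tolerances
#'
#' Per-state-family absolute/relative tolerances of the adaptive
#' Dormand-Prince integrator: metabolite concentrations (mM), cell volume
#' (L) and health (dimensionless).
#'
#' @return Named list.
#' @export
solverTolerances <- function() {
  list(atol_c = 1e-5, rtol_c = 1e-5, atol_v = 1e-17, rtol_v = 0,
       atol_h = 1e-2, rtol_h = 0)
}

#' Initial cytosolic metabolite concentrations
#'
#' The standard initial state (FBP 2 mM, ATP 1 mM, Pi 10.4 mM) used for all
#' population simulations; genotypic-balancedness scans use Pi = 10 mM.
#'
#' @param Pi0 Initial cytosolic phosphate (mM).
#' @return Metabolite state vector.
#' @export
initialMetabolites <- function(Pi0 = 10.4) metaboliteState(2, 1, Pi0)

#' Initialize a population
#'
#' Draws `N0` cells with genotype parameters uniform on `(P/span, span * P)`
#' around the reference genotype, volumes uniform on `(0.5, 1.5) * V_c`,
#' individual `H_max ~ U(0.9, 1.1)` with `H = H_max`, and the standard
#' initial metabolite state for every cell. Uses the current R random
#' stream.
#'
#' @param cfg Simulation configuration.
#' @param reference Reference genotype around which initial genotypes are
#'   drawn.
#' @param cm Normalized cost model.
#' @param phys Physiology parameters.
#' @param glc Initial chamber glucose (mM).
#' @param genotypes Optional N x 4 matrix of genotypes to use instead of
#'   random draws (recycled to `N0` rows).
#' @param types Optional integer labels per cell (e.g. competing strains).
#' @return Population state (class `glycoPopulation`).
#' @export
initializePopulation <- function(cfg, reference = referenceGenotype(),
                                 cm = normalizeCost(costModel()),
                                 phys = physiologyParameters(), glc = 2,
                                 genotypes = NULL, types = NULL) {
  n <- cfg$N0
  if (is.null(genotypes)) {
    span <- cfg$init_genotype_span
    geno <- sapply(reference, function(p) stats::runif(n, p / span,
                                                       span * p))
    if (n == 1) geno <- matrix(geno, 1)
  } else {
    geno <- genotypes[rep_len(seq_len(nrow(genotypes)), n), , drop = FALSE]
  }
  colnames(geno) <- c("vmax_up", "vmax_lo", "k_atp", "k_p")
  hmax <- stats::runif(n, 0.9, 1.1)
  st <- cbind(FBP = rep(2, n), ATP = rep(1, n), Pi = rep(10.4, n),
              V = stats::runif(n, 0.5 * phys$V_c, 1.5 * phys$V_c),
              H = hmax)
  vatpe <- apply(geno, 1, function(g) {
    expressionCost(genotype(g), cm)
  })
  tracked <- logical(n)
  tracked[sample.int(n, min(cfg$N_tr, n))] <- TRUE
  structure(list(state = st, geno = geno, vatpe = vatpe, Hmax = hmax,
                 id = seq_len(n),
                 type = if (is.null(types)) integer(n)
                        else rep_len(as.integer(types), n),
                 tracked = tracked, glc = glc, time = cfg$t_s,
                 counters = c(births = 0, deaths = 0, washouts = 0),
                 nextId = n + 1L, status = "running"),
            class = "glycoPopulation")
}

#' @export
print.glycoPopulation <- function(x, ...) {
  cat(sprintf(paste0("<glycoPopulation> %d cells at t = %g min, ",
                     "[Glc] = %.4g mM\n"),
              nrow(x$state), x$time, x$glc))
  cat(sprintf("  births %d, deaths %d, washouts %d; %d tracked\n",
              x$counters[["births"]], x$counters[["deaths"]],
              x$counters[["washouts"]], sum(x$tracked)))
  invisible(x)
}

# Build the break-point vectors for one integration interval.
.intervalBreaks <- function(t0, t1, resolved, sampleTimes) {
  sw <- resolved$switchT
  sw <- sw[sw > t0 + 1e-9 & sw < t1 - 1e-9]
  breaks <- sort(unique(c(sw, sampleTimes, t1)))
  list(breaks = breaks,
       isSample = breaks %in% sampleTimes,
       isSeg = breaks %in% sw)
}

#' Integrate one demographic interval
#'
#' Advances every cell's metabolites, volume and health (and, in a
#' chemostat, the shared chamber glucose as one coupled system) over `dt`
#' with the adaptive Dormand-Prince 5(4) method and the non-negativity
#' projection. Population membership is unchanged within the interval. In
#' NCG mode the chamber glucose follows its closed-form relaxation toward
#' the supply concentration and each cell is integrated independently.
#'
#' @param pop Population state.
#' @param env Environment configuration.
#' @param resolved Resolved schedule covering the run.
#' @param dt Interval length (min).
#' @param kin,phys Kinetic and physiology parameters.
#' @param tol Solver tolerances.
#' @param sampleTimes Times within `(time, time + dt]` at which tracked
#'   cells are sampled (possibly empty).
#' @return List with the advanced `pop` and a `samples` array
#'   (tracked x times x 6: FBP, ATP, Pi, V, H, Glc) or `NULL`.
#' @export
integrateInterval <- function(pop, env, resolved, dt,
                              kin = kineticParameters(),
                              phys = physiologyParameters(),
                              tol = solverTolerances(),
                              sampleTimes = numeric(0)) {
  t0 <- pop$time
  t1 <- t0 + dt
  bk <- .intervalBreaks(t0, t1, resolved, sampleTimes)
  trackedIdx <- if (length(sampleTimes)) which(pop$tracked) - 1L
                else integer(0)
  physL <- list(u_g = phys$u_g, u_d = phys$u_d, vatp_m = phys$vatp_m)
  if (env$mode == "ncg") {
    segs <- ncgSegments(resolved, env$D, t0, t1, pop$glc)
    res <- cppIntegrateNCG(pop$state, pop$geno, pop$vatpe, pop$Hmax,
                           unclass(kin), physL, pop_tol(tol), t0, bk$breaks,
                           bk$isSample, bk$isSeg, segs$ts, segs$g0, segs$gi,
                           env$D, trackedIdx)
  } else {
    swIn <- resolved$switchT[resolved$switchT > t0 + 1e-9 &
                             resolved$switchT < t1 - 1e-9]
    swT <- c(t0, swIn)
    res <- cppIntegrateChemostat(pop$state, pop$geno, pop$vatpe, pop$Hmax,
                                 unclass(kin), physL, pop_tol(tol),
                                 pop$glc, env$V_ch, env$D, t0, bk$breaks,
                                 bk$isSample, swT,
                                 supplyConcentration(swT, resolved),
                                 trackedIdx)
  }
  if (!res$ok) {
    stop(sprintf(paste0("integration failure (step-size underflow) at ",
                        "t = %.6g min, cell id %s"),
                 res$badT,
                 if (is.na(res$badCell)) "<coupled system>"
                 else pop$id[res$badCell]))
  }
  colnames(res$states) <- colnames(pop$state)
  pop$state <- res$states
  pop$glc <- res$glcEnd
  pop$time <- t1
  samples <- NULL
  if (length(trackedIdx) && length(res$samples)) {
    ti <- trackedIdx + 1L
    samples <- list(times = bk$breaks[bk$isSample], id = pop$id[ti],
                    arr = res$samples, hmax = pop$Hmax[ti],
                    geno = pop$geno[ti, , drop = FALSE],
                    vatpe = pop$vatpe[ti], type = pop$type[ti])
  }
  list(pop = pop, samples = samples)
}

pop_tol <- function(tol) {
  tol[c("atol_c", "rtol_c", "atol_v", "rtol_v", "atol_h", "rtol_h")]
}

# Chamber glucose at the start of a run: the supply value for a constant
# schedule, otherwise the OFF-phase level (pulses have not yet fed the
# chamber).
initialGlucose <- function(resolved) {
  if (resolved$sched$kind == "constant") resolved$sched$Glc0_on
  else resolved$sched$Glc0_off
}

.removeCells <- function(pop, idx) {
  if (!length(idx)) return(pop)
  keep <- setdiff(seq_len(nrow(pop$state)), idx)
  pop$state <- pop$state[keep, , drop = FALSE]
  pop$geno <- pop$geno[keep, , drop = FALSE]
  pop$vatpe <- pop$vatpe[keep]
  pop$Hmax <- pop$Hmax[keep]
  pop$id <- pop$id[keep]
  pop$type <- pop$type[keep]
  pop$tracked <- pop$tracked[keep]
  pop
}

#' Demographic events at an interval boundary
#'
#' Applies, in this fixed order: (1) death of cells whose health has reached
#' zero; (2) division of every cell whose volume has reached `2 * V_c`, with
#' mutation applied to the daughters only when `mutationOn`; (3) washout
#' removals sampled from the exponential survival probability; (4) refresh
#' of the tracked set back to `N_tr` cells (a dividing tracked cell passes
#' tracking to one daughter chosen by a fair coin; lost tracked cells are
#' replaced uniformly). Division and washout draws come from the
#' `demography` stream and mutation draws from the `mutation` stream of
#' `streams`.
#'
#' @param pop Population state.
#' @param env Environment configuration.
#' @param cfg Simulation configuration.
#' @param phys Physiology parameters.
#' @param cm Normalized cost model.
#' @param mutationOn Whether the current time lies in the mutation-on
#'   segment.
#' @param streams RNG streams (internal; created by the run driver).
#' @return The updated population; `status` becomes `"extinct"` if no cell
#'   remains.
#' @export
lifecycleUpdate <- function(pop, env, cfg, phys = physiologyParameters(),
                            cm = normalizeCost(costModel()),
                            mutationOn = FALSE, streams = NULL) {
  if (is.null(streams)) streams <- makeStreams(0L)

  # 1. death
  dead <- which(pop$state[, "H"] <= 0)
  pop$counters[["deaths"]] <- pop$counters[["deaths"]] + length(dead)
  pop <- .removeCells(pop, dead)
  if (nrow(pop$state) == 0) { pop$status <- "extinct"; return(pop) }

  # 2. division (+ mutation of daughters during the mutation-on segment)
  div <- which(pop$state[, "V"] >= 2 * phys$V_c)
  nd <- length(div)
  if (nd) {
    drw <- withStream(streams, "demography", {
      list(vNew = stats::runif(nd, 0.5 * phys$V_c, 1.5 * phys$V_c),
           coin = stats::runif(nd) < 0.5,
           hmax = matrix(stats::runif(2 * nd, 0.9, 1.1), nd, 2),
           keepA = stats::runif(nd) < 0.5)
    })
    volParent <- pop$state[div, "V"]
    volA <- ifelse(drw$coin, drw$vNew, volParent - drw$vNew)
    volB <- volParent - volA

    genoA <- pop$geno[div, , drop = FALSE]
    genoB <- genoA
    vatpeA <- pop$vatpe[div]
    vatpeB <- vatpeA
    if (mutationOn && cfg$mu > 0) {
      mutate <- function(gm) {
        hit <- matrix(stats::runif(length(gm)) < cfg$mu, nrow(gm))
        if (any(hit))
          gm[hit] <- gm[hit] * exp(stats::rnorm(sum(hit), 0, cfg$sigma))
        list(gm = gm, changed = rowSums(hit) > 0)
      }
      withStream(streams, "mutation", {
        if (cfg$mutate_both_daughters) {
          ra <- mutate(genoA); genoA <- ra$gm
          rb <- mutate(genoB); genoB <- rb$gm
        } else {
          ra <- list(changed = logical(nd))
          rb <- mutate(genoB); genoB <- rb$gm
        }
      })
      for (j in which(ra$changed))
        vatpeA[j] <- expressionCost(genotype(genoA[j, ]), cm)
      for (j in which(rb$changed))
        vatpeB[j] <- expressionCost(genotype(genoB[j, ]), cm)
    }

    # daughter A replaces the parent row; daughter B is appended
    parentTracked <- pop$tracked[div]
    pop$state[div, "V"] <- volA
    pop$state[div, "H"] <- drw$hmax[, 1]
    pop$Hmax[div] <- drw$hmax[, 1]
    pop$geno[div, ] <- genoA
    pop$vatpe[div] <- vatpeA
    idA <- pop$nextId + seq_len(nd) - 1L
    idB <- pop$nextId + nd + seq_len(nd) - 1L
    pop$nextId <- pop$nextId + 2L * nd
    pop$id[div] <- idA
    pop$tracked[div] <- parentTracked & drw$keepA

    stB <- pop$state[div, , drop = FALSE]
    stB[, "V"] <- volB
    stB[, "H"] <- drw$hmax[, 2]
    pop$state <- rbind(pop$state, stB)
    pop$geno <- rbind(pop$geno, genoB)
    pop$vatpe <- c(pop$vatpe, vatpeB)
    pop$Hmax <- c(pop$Hmax, drw$hmax[, 2])
    pop$id <- c(pop$id, idB)
    pop$type <- c(pop$type, pop$type[div])
    pop$tracked <- c(pop$tracked, parentTracked & !drw$keepA)
    pop$counters[["births"]] <- pop$counters[["births"]] + nd
  }

  # 3. washout
  n <- nrow(pop$state)
  nOut <- withStream(streams, "demography", removalCount(n, env, cfg$dt_p))
  if (nOut > 0) {
    victims <- withStream(streams, "demography", sample.int(n, nOut))
    pop$counters[["washouts"]] <- pop$counters[["washouts"]] + nOut
    pop <- .removeCells(pop, victims)
  }
  n <- nrow(pop$state)
  if (n == 0) { pop$status <- "extinct"; return(pop) }

  # 4. tracked-set refresh
  want <- min(cfg$N_tr, n)
  short <- want - sum(pop$tracked)
  if (short > 0) {
    cand <- which(!pop$tracked)
    add <- withStream(streams, "demography",
                      cand[sample.int(length(cand), short)])
    pop$tracked[add] <- TRUE
  } else if (short < 0) {
    cur <- which(pop$tracked)
    drop <- withStream(streams, "demography",
                       cur[sample.int(length(cur), -short)])
    pop$tracked[drop] <- FALSE
  }
  pop
}

# Core simulation loop shared by runs and pre-simulations.
.runLoop <- function(pop, env, resolved, cfg, kin, phys, cm, streams,
                     tEnd, record = TRUE) {
  nInt <- max(0L, as.integer(round((tEnd - pop$time) / cfg$dt_p)))
  sumRows <- vector("list", nInt)
  sampleChunks <- list()
  for (k in seq_len(nInt)) {
    t0 <- pop$time
    doSample <- record && (t0 + cfg$dt_s) > cfg$track_start
    sampleTimes <- if (doSample)
      seq(t0 + cfg$dt_s, t0 + cfg$dt_p, by = cfg$dt_s) else numeric(0)
    res <- integrateInterval(pop, env, resolved, cfg$dt_p, kin, phys,
                             cfg$tol, sampleTimes)
    pop <- res$pop
    if (!is.null(res$samples))
      sampleChunks[[length(sampleChunks) + 1L]] <- res$samples
    mutationOn <- t0 >= cfg$t_ms && t0 < cfg$t_me
    pop <- lifecycleUpdate(pop, env, cfg, phys, cm, mutationOn, streams)
    sumRows[[k]] <- c(time = pop$time, N = nrow(pop$state), glc = pop$glc,
                      colMeans(pop$geno),
                      f_type1 = if (nrow(pop$state)) mean(pop$type == 1L)
                                else NA_real_,
                      births = pop$counters[["births"]],
                      deaths = pop$counters[["deaths"]],
                      washouts = pop$counters[["washouts"]])
    if (pop$status == "extinct") {
      sumRows <- sumRows[seq_len(k)]
      break
    }
  }
  summary <- as.data.frame(do.call(rbind, sumRows))
  list(pop = pop, summary = summary,
       tracks = .bindSamples(sampleChunks))
}

.bindSamples <- function(chunks) {
  if (!length(chunks)) return(list(tracks = NULL, cells = NULL))
  dfs <- lapply(chunks, function(ch) {
    a <- ch$arr
    d <- dim(a)
    data.frame(time = rep(ch$times, each = d[1]),
               cell = rep(ch$id, d[2]),
               FBP = as.vector(a[, , 1]), ATP = as.vector(a[, , 2]),
               Pi = as.vector(a[, , 3]), V = as.vector(a[, , 4]),
               H = as.vector(a[, , 5]), Glc = as.vector(a[, , 6]))
  })
  cells <- lapply(chunks, function(ch) {
    data.frame(cell = ch$id, ch$geno, vatp_e = ch$vatpe, H_max = ch$hmax,
               type = ch$type, row.names = NULL)
  })
  cells <- do.call(rbind, cells)
  cells <- cells[!duplicated(cells$cell), , drop = FALSE]
  list(tracks = do.call(rbind, dfs), cells = cells)
}

#' Pre-simulation calibration of the population-size control parameter
#'
#' Runs a mutation-free simulation of the same duration as the first
#' protocol segment with the provisional chamber volume (`V_ch,0`,
#' chemostat) or removal constant (`d_0`, NCG), measures the steady-state
#' population size `N_p` as the mean over the final quarter of the
#' pre-simulation, and rescales: `V_ch = V_ch,0 * N_star / N_p` or
#' `d = d_0 * N_p / N_star`.
#'
#' @param config Full run configuration (see [defaultConfig()]).
#' @param seed Integer seed for the pre-simulation.
#' @return The environment configuration with the calibrated parameter.
#' @export
presimCalibrate <- function(config, seed = 1) {
  cfg <- config$simulation
  env <- config$environment
  streams <- makeStreams(seed)
  resolved <- withStream(streams, "schedule",
                         resolveSchedule(env$schedule, cfg$t_ms))
  cm <- normalizeCost(config$cost, config$reference)
  phys <- config$physiology
  pop <- withStream(streams, "init",
                    initializePopulation(cfg, config$reference, cm, phys,
                      glc = initialGlucose(resolved)))
  cfgPre <- cfg
  cfgPre$t_ms <- cfg$t_ms
  cfgPre$t_me <- cfg$t_ms  # mutation never switches on
  res <- .runLoop(pop, env, resolved, cfgPre, config$kinetics, phys, cm,
                  streams, tEnd = cfg$t_ms, record = FALSE)
  if (res$pop$status == "extinct")
    stop("pre-simulation went extinct; cannot calibrate")
  nInt <- nrow(res$summary)
  idx <- seq.int(min(nInt, floor(0.75 * nInt) + 1L), nInt)
  Np <- mean(res$summary$N[idx])
  if (env$mode == "chemostat") {
    env$V_ch <- env$V_ch * cfg$N_star / Np
  } else {
    env$d <- env$d * Np / cfg$N_star
  }
  attr(env, "N_p") <- Np
  env
}

#' Run a full three-segment simulation
#'
#' Alternates coupled ODE integration over `dt_p` intervals with
#' demographic updates from `t_s` to `t_e`; mutation is active only on
#' `[t_ms, t_me)`. Tracked cells are sampled every `dt_s` from
#' `track_start` onward. All randomness derives from `seed` through named
#' streams (initialization, schedule, demography, mutation), so identical
#' seed and configuration reproduce the run exactly.
#'
#' @param config Full run configuration (see [defaultConfig()]); its
#'   `environment` element should already be calibrated (see
#'   [presimCalibrate()]) unless `calibrate = TRUE`.
#' @param seed Integer seed.
#' @param calibrate If `TRUE`, run the pre-simulation first and use the
#'   calibrated environment.
#' @param genotypes,types Optional explicit initial genotypes/type labels
#'   (passed to [initializePopulation()]).
#' @return List of class `glycoRun` with elements `population` (final
#'   state), `tracks` (long data frame: time, cell, FBP, ATP, Pi, V, H,
#'   Glc), `summary` (one row per demographic interval), `resolved` (the
#'   realized supply schedule), `environment`, `config`, `seed` and
#'   `status` (`"completed"` or `"extinct"`).
#' @export
runSimulation <- function(config, seed = 1, calibrate = FALSE,
                          genotypes = NULL, types = NULL) {
  set.seed(as.integer(seed))
  subSeeds <- sample.int(.Machine$integer.max - 1L, 2)
  if (calibrate)
    config$environment <- presimCalibrate(config, seed = subSeeds[1])
  cfg <- config$simulation
  env <- config$environment
  streams <- makeStreams(subSeeds[2])
  resolved <- withStream(streams, "schedule",
                         resolveSchedule(env$schedule, cfg$t_e))
  cm <- normalizeCost(config$cost, config$reference)
  phys <- config$physiology
  pop <- withStream(streams, "init",
                    initializePopulation(cfg, config$reference, cm, phys,
                      glc = initialGlucose(resolved),
                      genotypes = genotypes, types = types))
  res <- .runLoop(pop, env, resolved, cfg, config$kinetics, phys, cm,
                  streams, tEnd = cfg$t_e, record = TRUE)
  structure(list(population = res$pop, tracks = res$tracks$tracks,
                 trackedCells = res$tracks$cells,
                 summary = res$summary, resolved = resolved,
                 environment = env, config = config, seed = seed,
                 status = if (res$pop$status == "extinct") "extinct"
                          else "completed"),
            class = "glycoRun")
}

#' @export
print.glycoRun <- function(x, ...) {
  cat(sprintf("<glycoRun> %s at t = %g min; N = %d\n", x$status,
              x$population$time, nrow(x$population$state)))
  if (!is.null(x$tracks))
    cat(sprintf("  %d tracked samples from %d cells\n", nrow(x$tracks),
                length(unique(x$tracks$cell))))
  invisible(x)
}

#' Integrate a single cell at an imposed glucose concentration
#'
#' Convenience wrapper used for fixed-point checks, genotypic-balancedness
#' scans and the flux worked examples: one cell, no demography, chamber
#' glucose following the supply schedule exactly (constant supply) or its
#' closed-form relaxation.
#'
#' @param geno Genotype.
#' @param state0 Initial metabolite state `c(FBP, ATP, Pi)`.
#' @param glc Constant glucose concentration (mM).
#' @param tEnd Simulation length (min).
#' @param dt_s Sampling interval (min).
#' @param V0 Initial volume (L).
#' @param H_max,H0 Health bounds/initial value.
#' @param kin,phys Kinetics and physiology parameters.
#' @param vatp_e Expression cost of the genotype (mM/min).
#' @param tol Solver tolerances.
#' @return Data frame: time, FBP, ATP, Pi, V, H, Glc (including t = 0).
#' @export
simulateCell <- function(geno, state0 = initialMetabolites(), glc = 2,
                         tEnd = 300, dt_s = 1, V0 = NULL, H_max = 1,
                         H0 = H_max, kin = kineticParameters(),
                         phys = physiologyParameters(), vatp_e = 5,
                         tol = solverTolerances()) {
  if (is.null(V0)) V0 <- phys$V_c
  st <- matrix(c(state0[["FBP"]], state0[["ATP"]], state0[["Pi"]], V0, H0),
               1, 5)
  geno <- matrix(genotype(geno), 1, 4)
  physL <- list(u_g = phys$u_g, u_d = phys$u_d, vatp_m = phys$vatp_m)
  times <- seq(dt_s, tEnd, by = dt_s)
  res <- cppIntegrateNCG(st, geno, vatp_e, H_max, unclass(kin), physL,
                         pop_tol(tol), 0, times,
                         rep(TRUE, length(times)),
                         rep(FALSE, length(times)),
                         0, glc, glc, 0, 0L)
  if (!res$ok)
    stop(sprintf("integration failure at t = %.6g min", res$badT))
  a <- res$samples
  data.frame(time = c(0, times),
             FBP = c(st[1], a[1, , 1]), ATP = c(st[2], a[1, , 2]),
             Pi = c(st[3], a[1, , 3]), V = c(st[4], a[1, , 4]),
             H = c(st[5], a[1, , 5]), Glc = c(glc, a[1, , 6]))
}
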