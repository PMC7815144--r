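#' Glucose supply schedule
#'
#' Describes the glucose concentration `Glc0(t)` in the inflow medium:
#' constant, a square wave of equal-duration ON/OFF phases, or a pulse train
#' of short ON pulses separated by long OFF phases whose durations may vary
#' from cycle to cycle (normally distributed with coefficient of variation
#' `T_off_cv`, truncated at a 1 min floor).
#'
#' @param kind `"constant"`, `"square_wave"` or `"pulse_train"`.
#' @param Glc0_on Supply concentration during the ON phase (mM); for
#'   `"constant"` this is the supply at all times.
#' @param Glc0_off Supply concentration during the OFF phase (mM).
#' @param T_on ON phase duration (min).
#' @param T_off_mean Mean OFF phase duration (min). A square wave uses equal
#'   ON and OFF durations, so it must equal `T_on` there.
#' @param T_off_cv Coefficient of variation of the OFF duration (0 for a
#'   deterministic schedule).
#' @param origin Phase origin (min): the first ON phase starts here.
#' @return List of class `glycoSchedule`.
#' @export
glucoseSchedule <- function(kind = c("constant", "square_wave",
                                     "pulse_train"),
                            Glc0_on = 2, Glc0_off = 0.01, T_on = 20,
                            T_off_mean = T_on, T_off_cv = 0, origin = 0) {
  kind <- match.arg(kind)
  if (Glc0_on < 0 || Glc0_off < 0) stop("supply concentrations must be >= 0")
  if (kind != "constant") {
    if (T_on <= 0 || T_off_mean <= 0) stop("phase durations must be > 0")
    if (kind == "square_wave" && abs(T_off_mean - T_on) > 1e-9)
      stop("a square wave has ON and OFF phases of equal duration")
    if (T_off_cv < 0) stop("T_off_cv must be >= 0")
  }
  structure(list(kind = kind, Glc0_on = Glc0_on, Glc0_off = Glc0_off,
                 T_on = T_on, T_off_mean = T_off_mean, T_off_cv = T_off_cv,
                 origin = origin),
            class = "glycoSchedule")
}

#' Resolve a schedule over a time horizon
#'
#' Draws the per-cycle OFF durations once (from the current R random stream)
#' and caches the resulting switch times, so that the realized schedule is
#' reproducible from the seed and can be queried cheaply. Cycle boundaries
#' for the balancedness statistics are taken from this resolved schedule,
#' never inferred from the glucose trace.
#'
#' @param sched A `glycoSchedule`.
#' @param t_end Horizon (min): the resolved schedule covers `[0, t_end]`.
#' @return List of class `glycoResolvedSchedule` with `switchT`/`switchV`
#'   (piecewise-constant supply) and `cycles` (data frame with columns
#'   `start`, `onEnd`, `end`; `NULL` for a constant supply).
#' @export
resolveSchedule <- function(sched, t_end) {
  if (sched$kind == "constant") {
    return(structure(list(sched = sched, switchT = 0,
                          switchV = sched$Glc0_on, cycles = NULL,
                          t_end = t_end),
                     class = "glycoResolvedSchedule"))
  }
  starts <- c()
  onEnds <- c()
  ends <- c()
  t <- sched$origin
  while (t < t_end) {
    toff <- if (sched$T_off_cv > 0) {
      max(1, stats::rnorm(1, sched$T_off_mean,
                          sched$T_off_cv * sched$T_off_mean))
    } else sched$T_off_mean
    starts <- c(starts, t)
    onEnds <- c(onEnds, t + sched$T_on)
    ends <- c(ends, t + sched$T_on + toff)
    t <- t + sched$T_on + toff
  }
  switchT <- c(0, as.vector(rbind(starts, onEnds)))
  switchV <- c(sched$Glc0_off,
               rep(c(sched$Glc0_on, sched$Glc0_off), length(starts)))
  if (sched$origin == 0) {
    switchT <- switchT[-1]
    switchV <- switchV[-1]
  }
  structure(list(sched = sched, switchT = switchT, switchV = switchV,
                 cycles = data.frame(start = starts, onEnd = onEnds,
                                     end = ends),
                 t_end = t_end),
            class = "glycoResolvedSchedule")
}

#' Supply concentration at given times
#'
#' @param t Time(s) in min.
#' @param resolved A resolved schedule (see [resolveSchedule()]).
#' @return `Glc0(t)` in mM (vectorized).
#' @export
supplyConcentration <- function(t, resolved) {
  idx <- findInterval(t, resolved$switchT)
  idx[idx < 1] <- 1
  resolved$switchV[idx]
}

#' Environment configuration
#'
#' @param mode `"chemostat"` (cells deplete shared glucose; per-capita
#'   washout rate `D`) or `"ncg"` (no competition for glucose: imposed
#'   glucose dynamics, per-capita loss rate `d * N`).
#' @param schedule Glucose supply schedule.
#' @param D Dilution rate (1/min). In NCG mode this still drives the chamber
#'   glucose toward the supply concentration.
#' @param V_ch Chemostat chamber volume (L); chemostat mode only.
#' @param d Removal rate constant (1/min); NCG mode only.
#' @return List of class `glycoEnvironment`.
#' @export
environmentConfig <- function(mode = c("chemostat", "ncg"),
                              schedule = glucoseSchedule("constant"),
                              D = if (match.arg(mode) == "ncg") 5 else 4e-3,
                              V_ch = 1e-8, d = 1e-6) {
  mode <- match.arg(mode)
  if (D <= 0) stop("D must be positive")
  if (mode == "chemostat" && V_ch <= 0) stop("V_ch must be positive")
  if (mode == "ncg" && d <= 0) stop("d must be positive")
  structure(list(mode = mode, schedule = schedule, D = D, V_ch = V_ch,
                 d = d),
            class = "glycoEnvironment")
}

#' Chamber glucose derivative
#'
#' Chemostat: `-sum(v_up_i V_i) / V_ch + D (Glc0 - Glc)` (uptake by all
#' cells plus medium exchange). NCG: `D (Glc0 - Glc)` (cells do not affect
#' the chamber glucose).
#'
#' @param glc Current chamber glucose (mM).
#' @param cells Population view: a data frame or list with elements `vup`
#'   (per-cell UG rate, mM/min) and `V` (cell volumes, L). Ignored in NCG
#'   mode; may be `NULL` for an empty chamber.
#' @param env Environment configuration.
#' @param glc0_now Current supply concentration (mM).
#' @return d`Glc`/dt in mM/min.
#' @export
glucoseDerivative <- function(glc, cells, env, glc0_now) {
  if (glc < 0) stop("glc must be >= 0")
  base <- env$D * (glc0_now - glc)
  if (env$mode == "ncg" || is.null(cells) || length(cells$vup) == 0)
    return(base)
  base - sum(cells$vup * cells$V) / env$V_ch
}

#' Number of cells removed by outflow in an interval
#'
#' Washout is discretized per demographic interval using the exact
#' exponential survival probability: each cell is removed independently with
#' probability `1 - exp(-rate * dt)`, where the per-capita rate is `D` in a
#' chemostat and `d * N` in the NCG scenario (total loss rate `d N^2`).
#' Uses the current R random stream.
#'
#' @param N Population size.
#' @param env Environment configuration.
#' @param dt Interval length (min).
#' @return Integer number of cells removed.
#' @export
removalCount <- function(N, env, dt) {
  if (N < 0 || dt <= 0) stop("need N >= 0 and dt > 0")
  if (N == 0) return(0L)
  rate <- if (env$mode == "chemostat") env$D else env$d * N
  stats::rbinom(1, N, 1 - exp(-rate * dt))
}

# Piecewise closed-form chamber glucose for the NCG scenario over [t0, t1]:
# between supply switches, Glc(t) relaxes toward Glc0 at rate D. Returns the
# segment table consumed by the C++ integrator and the endpoint value.
ncgSegments <- function(resolved, D, t0, t1, glcInit) {
  sw <- resolved$switchT
  inRange <- sw > t0 + 1e-12 & sw < t1 - 1e-12
  ts <- c(t0, sw[inRange])
  g0 <- supplyConcentration(ts, resolved)
  gi <- numeric(length(ts))
  gi[1] <- glcInit
  if (length(ts) > 1) {
    for (k in seq_len(length(ts) - 1)) {
      gi[k + 1] <- g0[k] + (gi[k] - g0[k]) * exp(-D * (ts[k + 1] - ts[k]))
    }
  }
  nseg <- length(ts)
  glcEnd <- g0[nseg] + (gi[nseg] - g0[nseg]) * exp(-D * (t1 - ts[nseg]))
  list(ts = ts, g0 = g0, gi = gi, glcEnd = glcEnd)
}
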