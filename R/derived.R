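# Derived single-cell quantities: the calibration-level observables of the
# model (steady-state ATPase flux, volume doubling time, death time, and
# the quasi-steady ATPase flux of the imbalanced mode).

#' ATPase flux at the balanced steady state
#'
#' Root-finds the balanced fixed point of the coupled metabolite/growth
#' dynamics at constant glucose and returns the ATPase flux there
#' (`k_atp * [ATP]`).
#'
#' @param geno Genotype.
#' @param glc Constant glucose (mM).
#' @param kin,phys Kinetics and physiology parameters.
#' @param vatp_e Expression cost of the genotype (mM/min).
#' @param start Initial guess for the metabolite root-finder.
#' @return ATPase flux (mM/min).
#' @export
balancedAtpaseFlux <- function(geno = referenceGenotype(), glc = 2,
                               kin = kineticParameters(),
                               phys = physiologyParameters(), vatp_e = 5,
                               start = c(2, 1.27, 10)) {
  balancedFixedPoint(geno, glc, kin, phys, vatp_e, start)$v_atp
}

#' Volume doubling time from the balanced steady state
#'
#' Places a cell at the balanced fixed point at maximal health, integrates
#' the coupled metabolite/volume dynamics, and returns the time at which
#' the volume reaches twice its initial value (linear interpolation
#' between samples).
#'
#' @inheritParams balancedAtpaseFlux
#' @param tMax Give up after this many minutes.
#' @return Doubling time (min).
#' @export
volumeDoublingTime <- function(geno = referenceGenotype(), glc = 2,
                               kin = kineticParameters(),
                               phys = physiologyParameters(), vatp_e = 5,
                               tMax = 2000) {
  fp <- balancedFixedPoint(geno, glc, kin, phys, vatp_e)
  tr <- simulateCell(geno,
                     metaboliteState(fp$state[["FBP"]], fp$state[["ATP"]],
                                     fp$state[["Pi"]], kin$a_tot),
                     glc = glc, tEnd = tMax, dt_s = 0.5, kin = kin,
                     phys = phys, vatp_e = vatp_e)
  i <- which(tr$V >= 2 * tr$V[1])[1]
  if (is.na(i)) stop("volume did not double within tMax")
  f <- (2 * tr$V[1] - tr$V[i - 1]) / (tr$V[i] - tr$V[i - 1])
  tr$time[i - 1] + f * (tr$time[i] - tr$time[i - 1])
}

#' Time to death under a constant energy deficit
#'
#' With the growth flux held at a constant negative value, health falls
#' linearly at `-u_d * v_atp_g`; the exact solution of the health equation
#' gives the time for `H` to reach zero from `H0`.
#'
#' @param v_atp_g Constant (negative) growth flux (mM/min).
#' @param H0 Initial health.
#' @param phys Physiology parameters.
#' @return Time to death (min).
#' @export
timeToDeath <- function(v_atp_g, H0 = 1, phys = physiologyParameters()) {
  rate <- healthRate(v_atp_g, H = H0 / 2, H_max = H0, phys = phys)
  if (rate >= 0) stop("cell is not losing health at this growth flux")
  -H0 / rate
}

#' Quasi-steady ATPase flux of the imbalanced mode
#'
#' Integrates a cell from a phosphate-poor initial state at constant
#' glucose into the FBP-accumulating (imbalanced) regime and returns the
#' plateau value of `k_atp * [ATP]`: the median ATPase flux over samples
#' where FBP is still rising, the total imported phosphate `P_tot` is below
#' `ptotMax`, and the relative ATP drift per minute is below `driftTol`
#' (which excludes the initial transient).
#'
#' @inheritParams balancedAtpaseFlux
#' @param state0 Phosphate-poor initial metabolite state.
#' @param tEnd Integration horizon (min).
#' @param ptotMax Cap on `P_tot` (mM) before vacuolar depletion matters.
#' @param driftTol Maximum relative ATP change per minute within the
#'   plateau.
#' @return Plateau ATPase flux (mM/min).
#' @export
imbalancedAtpasePlateau <- function(geno = referenceGenotype(), glc = 2,
                                    state0 = metaboliteState(2, 1, 1),
                                    kin = kineticParameters(),
                                    phys = physiologyParameters(),
                                    vatp_e = 5, tEnd = 300, ptotMax = 50,
                                    driftTol = 0.005) {
  tr <- simulateCell(geno, state0, glc = glc, tEnd = tEnd, dt_s = 0.5,
                     kin = kin, phys = phys, vatp_e = vatp_e)
  dt <- diff(tr$time)
  rising <- c(FALSE, diff(tr$FBP) > 0)
  ptot <- tr$Pi + 2 * tr$FBP + tr$ATP
  drift <- c(Inf, abs(diff(tr$ATP)) / dt) / pmax(tr$ATP, 1e-12)
  sel <- rising & ptot < ptotMax & drift < driftTol
  if (!any(sel))
    stop("no quasi-steady imbalanced plateau found (is the cell balanced?)")
  stats::median(geno[["k_atp"]] * tr$ATP[sel])
}
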