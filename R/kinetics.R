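#' Kinetic constants of the core glycolysis pathway
#'
#' Bundles the non-evolvable kinetic constants of the simplified pathway:
#' Michaelis constants of the lumped upper-glycolysis (UG) and
#' lower-glycolysis (LG) reactions, the allosteric ATP-inhibition constant of
#' UG, the conserved adenine nucleotide pool `a_tot`, and the parameters of
#' the buffered vacuolar phosphate store. Defaults are the standard parameter
#' set used throughout the package.
#'
#' @param KM_glc Michaelis constant for glucose in UG (mM).
#' @param KM_atp Michaelis constant for ATP in UG (mM).
#' @param Ki_atp Inhibitor constant for ATP in UG (mM).
#' @param a_tot Total (conserved) concentration of ATP + ADP (mM).
#' @param KM_fbp Michaelis constant for FBP in LG (mM).
#' @param KM_adp Michaelis constant for ADP in LG (mM).
#' @param KM_p Michaelis constant for inorganic phosphate in LG (mM).
#' @param Pi_vac_max Vacuolar phosphate concentration with an empty cytosolic
#'   pool (mM).
#' @param K_vac Total cytosolic phosphate that halves the vacuolar
#'   concentration (mM); effectively the capacity of the vacuolar store.
#' @param m Graduality exponent (> 0) of vacuolar phosphate depletion.
#' @return A named list of class `glycoKinetics`.
#' @export
kineticParameters <- function(KM_glc = 0.1, KM_atp = 0.1, Ki_atp = 3,
                              a_tot = 5, KM_fbp = 1, KM_adp = 0.1, KM_p = 2,
                              Pi_vac_max = 10, K_vac = 250, m = 4) {
  k <- list(KM_glc = KM_glc, KM_atp = KM_atp, Ki_atp = Ki_atp, a_tot = a_tot,
            KM_fbp = KM_fbp, KM_adp = KM_adp, KM_p = KM_p,
            Pi_vac_max = Pi_vac_max, K_vac = K_vac, m = m)
  vals <- unlist(k)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all kinetic constants must be strictly positive and finite")
  structure(k, class = "glycoKinetics")
}

#' Evolvable genotype: the four expression-level rate constants
#'
#' The genotype of a model cell is given by the maximal rates of upper and
#' lower glycolysis and the first-order rate constants of the ATPase demand
#' reaction and of vacuole-cytosol phosphate transport, all proportional to
#' the expression levels of the corresponding enzymes.
#'
#' @param vmax_up Maximal UG rate (mM/min).
#' @param vmax_lo Maximal LG rate (mM/min).
#' @param k_atp ATPase rate constant (1/min).
#' @param k_p Phosphate transport rate constant (1/min).
#' @return Named numeric vector of length 4.
#' @export
genotype <- function(vmax_up, vmax_lo, k_atp, k_p) {
  if (missing(vmax_lo) && length(vmax_up) == 4) {
    g <- as.numeric(vmax_up)
  } else {
    g <- c(vmax_up, vmax_lo, k_atp, k_p)
  }
  names(g) <- c("vmax_up", "vmax_lo", "k_atp", "k_p")
  if (any(!is.finite(g)) || any(g <= 0))
    stop("all four genotype parameters must be strictly positive")
  g
}

#' Cytosolic metabolite state
#'
#' Concentrations of the three dynamical metabolites. ADP is never stored: it
#' is always derived as `a_tot - ATP`.
#'
#' @param FBP Fructose-1,6-bisphosphate concentration (mM).
#' @param ATP ATP concentration (mM); must not exceed `a_tot`.
#' @param Pi Cytosolic inorganic phosphate concentration (mM).
#' @param a_tot Conserved adenine nucleotide pool (mM), used for validation.
#' @return Named numeric vector `c(FBP, ATP, Pi)`.
#' @export
metaboliteState <- function(FBP, ATP, Pi, a_tot = 5) {
  s <- c(FBP = as.numeric(FBP), ATP = as.numeric(ATP), Pi = as.numeric(Pi))
  if (any(!is.finite(s)) || any(s < 0))
    stop("metabolite concentrations must be finite and non-negative")
  if (s[["ATP"]] > a_tot)
    stop("ATP exceeds the conserved pool a_tot")
  s
}

.chkconc <- function(x, what) {
  x <- as.numeric(x)
  if (any(!is.finite(x)) || any(x < -1e-12))
    stop("negative ", what, " concentration")
  pmax(x, 0)
}

#' Upper glycolysis rate
#'
#' Irreversible two-substrate Michaelis-Menten kinetics with allosteric
#' substrate inhibition of the pathway by its ATP product:
#' `v_up = vmax_up * Glc * ATP / ((KM_glc + Glc) *
#' (KM_atp + ATP * (1 + ATP / Ki_atp)))`. The inhibition term makes `v_up`
#' unimodal in ATP, with an interior maximum at `sqrt(KM_atp * Ki_atp)`.
#'
#' @param state Metabolite state (see [metaboliteState()]).
#' @param glc Extracellular glucose concentration (mM).
#' @param geno Genotype (see [genotype()]).
#' @param kin Kinetic constants (see [kineticParameters()]).
#' @return Flux in mM/min.
#' @export
upperGlycolysisRate <- function(state, glc, geno, kin = kineticParameters()) {
  glc <- .chkconc(glc, "glucose")
  atp <- .chkconc(state[["ATP"]], "ATP")
  geno[["vmax_up"]] * glc * atp /
    ((kin$KM_glc + glc) *
     (kin$KM_atp + atp * (1 + atp / kin$Ki_atp)))
}

#' Lower glycolysis rate
#'
#' Irreversible three-substrate Michaelis-Menten kinetics in FBP, ADP and
#' inorganic phosphate, with ADP derived from the conserved pool:
#' `ADP = a_tot - ATP`.
#'
#' @inheritParams upperGlycolysisRate
#' @return Flux in mM/min.
#' @export
lowerGlycolysisRate <- function(state, geno, kin = kineticParameters()) {
  fbp <- .chkconc(state[["FBP"]], "FBP")
  atp <- .chkconc(state[["ATP"]], "ATP")
  pi <- .chkconc(state[["Pi"]], "Pi")
  if (atp > kin$a_tot)
    stop("ATP exceeds the conserved pool a_tot")
  adp <- kin$a_tot - atp
  geno[["vmax_lo"]] * fbp * adp * pi /
    ((kin$KM_fbp + fbp) * (kin$KM_adp + adp) * (kin$KM_p + pi))
}

#' ATPase (general ATP demand) rate
#'
#' First-order kinetics, `v_atp = k_atp * ATP`.
#'
#' @inheritParams upperGlycolysisRate
#' @return Flux in mM/min.
#' @export
atpaseRate <- function(state, geno) {
  geno[["k_atp"]] * .chkconc(state[["ATP"]], "ATP")
}

#' Buffered vacuolar phosphate concentration
#'
#' The vacuolar store is buffered and depletes as the total phosphate
#' imported into the cytosol, `P_tot = Pi + 2 FBP + ATP`, grows:
#' `Pi_vac = Pi_vac_max / (1 + (P_tot / K_vac)^m)`. Strictly decreasing in
#' `P_tot`, with half-depletion at `P_tot = K_vac`.
#'
#' @param P_tot Total cytosolic phosphate concentration (mM).
#' @param kin Kinetic constants.
#' @return Vacuolar phosphate concentration (mM).
#' @export
vacuolePhosphate <- function(P_tot, kin = kineticParameters()) {
  P_tot <- .chkconc(P_tot, "total phosphate")
  kin$Pi_vac_max / (1 + (P_tot / kin$K_vac)^kin$m)
}

#' Vacuole-cytosol phosphate transport rate
#'
#' `v_p = k_p * (Pi_vac - Pi)`: positive (import into the cytosol) when the
#' cytosolic phosphate concentration lies below the buffered vacuolar level,
#' negative (export) otherwise.
#'
#' @inheritParams upperGlycolysisRate
#' @return Flux in mM/min (signed).
#' @export
phosphateTransportRate <- function(state, geno, kin = kineticParameters()) {
  ptot <- state[["Pi"]] + 2 * state[["FBP"]] + state[["ATP"]]
  geno[["k_p"]] * (vacuolePhosphate(ptot, kin) - state[["Pi"]])
}

#' Metabolite derivatives with growth dilution
#'
#' Right-hand side of the intracellular metabolite dynamics, including the
#' dilution of every concentration at the fractional volume growth rate
#' `V'/V`:
#' \preformatted{
#' FBP' = v_up - v_lo            - FBP * V'/V
#' ATP' = -2 v_up + 4 v_lo - v_atp - ATP * V'/V
#' Pi'  = -2 v_lo + v_atp + v_p    - Pi  * V'/V
#' }
#' The stoichiometry conserves phosphate:
#' `dP_tot/dt = v_p - P_tot * V'/V` identically.
#'
#' @param state Metabolite state.
#' @param glc Extracellular glucose (mM).
#' @param fracGrowth Fractional volume growth rate `V'/V` (1/min, >= 0).
#' @param geno Genotype.
#' @param kin Kinetic constants.
#' @return Named numeric vector `c(FBP, ATP, Pi)` of time derivatives
#'   (mM/min).
#' @export
metaboliteDerivatives <- function(state, glc, fracGrowth, geno,
                                  kin = kineticParameters()) {
  if (fracGrowth < 0) stop("fracGrowth must be non-negative")
  vup <- upperGlycolysisRate(state, glc, geno, kin)
  vlo <- lowerGlycolysisRate(state, geno, kin)
  vatp <- atpaseRate(state, geno)
  vp <- phosphateTransportRate(state, geno, kin)
  c(FBP = vup - vlo - state[["FBP"]] * fracGrowth,
    ATP = -2 * vup + 4 * vlo - vatp - state[["ATP"]] * fracGrowth,
    Pi = -2 * vlo + vatp + vp - state[["Pi"]] * fracGrowth)
}

#' Balanced fixed point of the coupled metabolite/growth dynamics
#'
#' Solves for the steady state of the metabolite equations at a constant
#' glucose concentration, with the growth dilution rate determined
#' self-consistently from the ATPase flux (a cell at maximal health grows at
#' `u_g * v_atp_g` whenever the growth flux is positive).
#'
#' @param geno Genotype.
#' @param glc Constant extracellular glucose (mM).
#' @param kin Kinetic constants.
#' @param phys Physiology parameters (see [physiologyParameters()]).
#' @param vatp_e Expression cost of the genotype (mM/min).
#' @param start Initial guess `c(FBP, ATP, Pi)`.
#' @return List with `state` (the fixed point), `fracGrowth` (`V'/V` there),
#'   `v_atp` (ATPase flux) and `residual` (max abs derivative).
#' @export
balancedFixedPoint <- function(geno, glc, kin = kineticParameters(),
                               phys = physiologyParameters(), vatp_e = 5,
                               start = c(2, 1.27, 10)) {
  fn <- function(x) {
    s <- c(FBP = x[1], ATP = x[2], Pi = x[3])
    vatpg <- growthFlux(atpaseRate(s, geno), vatp_e, phys)
    g <- if (vatpg > 0) phys$u_g * vatpg else 0
    unname(metaboliteDerivatives(s, glc, g, geno, kin))
  }
  sol <- pracma::fsolve(fn, start, tol = 1e-12)
  s <- c(FBP = sol$x[1], ATP = sol$x[2], Pi = sol$x[3])
  vatpg <- growthFlux(atpaseRate(s, geno), vatp_e, phys)
  list(state = s,
       fracGrowth = if (vatpg > 0) phys$u_g * vatpg else 0,
       v_atp = atpaseRate(s, geno),
       residual = max(abs(fn(sol$x))))
}
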