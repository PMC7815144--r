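#' Enzyme expression cost model
#'
#' The cost of expressing the four pathway enzymes is an increasing function
#' of the genotype parameters. Two functional forms are supported:
#' `power_sum` (a weighted sum of each parameter raised to the power `n`,
#' the default form) and `power_of_sum` (the weighted sum itself raised to
#' `n`, the alternative form). Rate constants `k_atp` and `k_p` are
#' multiplied by the unit concentration `c_u` = 1 mM for dimensional
#' consistency. The prefactor `k_e` is fixed by [normalizeCost()] so that a
#' chosen reference genotype is assigned the cost `vatp_e_ref`.
#'
#' @param variant `"power_sum"` or `"power_of_sum"`.
#' @param w_up,w_lo,w_atp,w_p Dimensionless weights of the four parameters.
#' @param n Cost exponent.
#' @param vatp_e_ref Cost assigned to the reference genotype (mM/min).
#' @param c_u Unit concentration (mM).
#' @return List of class `glycoCostModel`; `k_e` is `NA` until normalized.
#' @export
costModel <- function(variant = c("power_sum", "power_of_sum"),
                      w_up = 1, w_lo = 1, w_atp = 1, w_p = 1, n = 4,
                      vatp_e_ref = 5, c_u = 1) {
  variant <- match.arg(variant)
  structure(list(variant = variant, w_up = w_up, w_lo = w_lo, w_atp = w_atp,
                 w_p = w_p, n = n, vatp_e_ref = vatp_e_ref, c_u = c_u,
                 k_e = NA_real_),
            class = "glycoCostModel")
}

.costRaw <- function(g, cm) {
  terms <- c(cm$w_up * g[["vmax_up"]], cm$w_lo * g[["vmax_lo"]],
             cm$w_atp * cm$c_u * g[["k_atp"]], cm$w_p * cm$c_u * g[["k_p"]])
  if (cm$variant == "power_sum") sum(terms^cm$n) else sum(terms)^cm$n
}

#' Normalize a cost model against a reference genotype
#'
#' Sets the prefactor `k_e` so that `expressionCost(reference) ==
#' vatp_e_ref` exactly.
#'
#' @param cm Cost model from [costModel()].
#' @param reference Reference genotype.
#' @return The normalized cost model.
#' @export
normalizeCost <- function(cm, reference = referenceGenotype()) {
  raw <- .costRaw(reference, cm)
  if (raw <= 0) stop("reference genotype has zero raw cost")
  cm$k_e <- cm$vatp_e_ref / raw
  cm
}

#' Expression cost of a genotype
#'
#' @param g Genotype.
#' @param cm Normalized cost model.
#' @return ATP flux spent on enzyme expression (mM/min).
#' @export
expressionCost <- function(g, cm) {
  if (!inherits(cm, "glycoCostModel") || is.na(cm$k_e))
    stop("cost model must be normalized first (see normalizeCost)")
  cm$k_e * .costRaw(g, cm)
}

#' Reference genotype
#'
#' The wild-type-like reference parameter set (`vmax_up` = 10 mM/min,
#' `vmax_lo` = 10 mM/min, `k_atp` = 10 /min, `k_p` = 0.3 /min) against which
#' the growth, death and expression-cost scales are calibrated.
#'
#' @return A genotype vector.
#' @export
referenceGenotype <- function() genotype(10, 10, 10, 0.3)

#' Physiology parameters: growth/health coupling constants
#'
#' The proportionality constants `u_g` (volume growth per unit growth flux)
#' and `u_d` (health loss per unit energy deficit) are calibrated so that a
#' reference cell in the balanced state at 2 mM glucose (ATPase flux
#' `vatp_ref_balanced`) doubles its volume in `tau_g`, and a reference cell
#' stuck in the imbalanced state (ATPase flux `vatp_ref_imbalanced`) dies in
#' `tau_d`:
#' \preformatted{
#' u_g = ln(2) / (tau_g * (vatp_ref_balanced  - vatp_e_ref - vatp_m))
#' u_d =     1 / (tau_d * (vatp_ref_imbalanced - vatp_e_ref - vatp_m))
#' }
#' `u_d` keeps its literal (negative) sign; the health equation uses it
#' verbatim, so the reference imbalanced cell loses health at exactly
#' `1/tau_d`.
#'
#' @param vatp_m General maintenance cost (mM/min).
#' @param tau_g Generation (volume doubling) time of the reference balanced
#'   cell (min).
#' @param tau_d Death time of the reference imbalanced cell (min).
#' @param vatp_ref_balanced Reference balanced ATPase flux (mM/min).
#' @param vatp_ref_imbalanced Reference imbalanced ATPase flux (mM/min).
#' @param vatp_e_ref Expression cost of the reference genotype (mM/min).
#' @param V_c Standard cell (cytosol) volume (L).
#' @return List of class `glycoPhysiology` with derived `u_g`, `u_d`.
#' @export
physiologyParameters <- function(vatp_m = 0, tau_g = 90, tau_d = 420,
                                 vatp_ref_balanced = 12.7,
                                 vatp_ref_imbalanced = 0.46,
                                 vatp_e_ref = 5, V_c = 3.35e-15) {
  vgb <- vatp_ref_balanced - vatp_e_ref - vatp_m
  vgi <- vatp_ref_imbalanced - vatp_e_ref - vatp_m
  if (vgb <= 0) stop("reference balanced growth flux must be positive")
  if (vgi >= 0) stop("reference imbalanced growth flux must be negative")
  structure(list(vatp_m = vatp_m, tau_g = tau_g, tau_d = tau_d,
                 vatp_ref_balanced = vatp_ref_balanced,
                 vatp_ref_imbalanced = vatp_ref_imbalanced,
                 vatp_e_ref = vatp_e_ref, V_c = V_c,
                 u_g = log(2) / (tau_g * vgb),
                 u_d = 1 / (tau_d * vgi),
                 H_min = 0),
            class = "glycoPhysiology")
}

#' Growth flux: ATPase flux net of maintenance
#'
#' `v_atp_g = v_atp - (vatp_e + vatp_m)`. May be negative (energy deficit).
#'
#' @param v_atp ATPase flux (mM/min).
#' @param vatp_e Expression cost of the genotype (mM/min).
#' @param phys Physiology parameters.
#' @return Growth flux (mM/min).
#' @export
growthFlux <- function(v_atp, vatp_e, phys = physiologyParameters()) {
  v_atp - (vatp_e + phys$vatp_m)
}

#' Fractional volume growth rate
#'
#' `V'/V = u_g * v_atp_g` when the cell is at maximal health and the growth
#' flux is positive; zero otherwise (energy is first spent replenishing
#' health).
#'
#' @param v_atp_g Growth flux (mM/min).
#' @param H,H_max Current and maximal health.
#' @param phys Physiology parameters.
#' @return `V'/V` in 1/min.
#' @export
volumeRate <- function(v_atp_g, H, H_max, phys = physiologyParameters()) {
  if (H >= H_max - 1e-12 && v_atp_g > 0) phys$u_g * v_atp_g else 0
}

#' Health dynamics rate
#'
#' Health falls at `-u_d * v_atp_g` under an energy deficit (`u_d` is
#' negative, so this is a loss), recovers at `u_g * v_atp_g` when the growth
#' flux is positive but health is below its maximum, and is constant at
#' maximal health.
#'
#' @inheritParams volumeRate
#' @return `dH/dt` in 1/min.
#' @export
healthRate <- function(v_atp_g, H, H_max, phys = physiologyParameters()) {
  if (v_atp_g <= 0) return(-phys$u_d * v_atp_g)
  if (H >= H_max - 1e-12) 0 else phys$u_g * v_atp_g
}

#' Construct a cell
#'
#' @param geno Genotype.
#' @param state Metabolite state.
#' @param V Cell volume (L).
#' @param H_max Individual maximal health (drawn U(0.9, 1.1) at birth).
#' @param H Current health; defaults to `H_max` (newborn).
#' @param cm Normalized cost model used to cache the expression cost.
#' @return List of class `glycoCell`.
#' @export
newCell <- function(geno, state, V, H_max = 1, H = H_max,
                    cm = normalizeCost(costModel())) {
  if (V <= 0) stop("cell volume must be positive")
  if (H < 0 || H > H_max) stop("H must lie in [0, H_max]")
  structure(list(genotype = geno, state = state, V = V, H = H,
                 H_max = H_max, vatp_e = expressionCost(geno, cm)),
            class = "glycoCell")
}

#' Divide a cell into two daughters
#'
#' A cell divides once its volume reaches twice the standard cell volume
#' `V_c`. One daughter (chosen by a fair coin) receives a fresh volume drawn
#' uniformly from (0.5, 1.5) x `V_c`; the other receives the complement, so
#' total volume is conserved. Each daughter draws a fresh individual
#' `H_max ~ U(0.9, 1.1)` and starts at `H = H_max`. Metabolite
#' concentrations and the genotype are copied unchanged (a physical
#' division); mutation, if any, is applied separately.
#'
#' Uses the current R random number stream.
#'
#' @param cell A `glycoCell` with `V >= 2 * V_c`.
#' @param phys Physiology parameters (supplies `V_c`).
#' @return List of two `glycoCell` daughters.
#' @export
divideCell <- function(cell, phys = physiologyParameters()) {
  if (cell$V < 2 * phys$V_c)
    stop("cell has not reached the division volume 2 * V_c")
  vNew <- stats::runif(1, 0.5 * phys$V_c, 1.5 * phys$V_c)
  vols <- if (stats::runif(1) < 0.5) c(vNew, cell$V - vNew)
          else c(cell$V - vNew, vNew)
  hmaxes <- stats::runif(2, 0.9, 1.1)
  lapply(1:2, function(i) {
    d <- cell
    d$V <- vols[i]
    d$H_max <- hmaxes[i]
    d$H <- hmaxes[i]
    d
  })
}

#' Mutate a genotype
#'
#' Upon division, each of the four genotype parameters of a daughter cell is
#' independently replaced with probability `mu` by `x * exp(X)` with
#' `X ~ N(0, sigma^2)` (a multiplicative log-normal step), or inherited
#' unchanged otherwise. Uses the current R random number stream.
#'
#' @param g Parental genotype.
#' @param mu Per-parameter mutation probability.
#' @param sigma Standard deviation of the log-scale mutation effect.
#' @return The (possibly mutated) daughter genotype.
#' @export
mutateGenotype <- function(g, mu = 0.01, sigma = 0.1) {
  if (mu < 0 || mu > 1) stop("mu must lie in [0, 1]")
  if (sigma < 0) stop("sigma must be non-negative")
  hit <- stats::runif(4) < mu
  if (any(hit))
    g[hit] <- g[hit] * exp(stats::rnorm(sum(hit), 0, sigma))
  g
}
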