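## Farquhar kinetic constants at 25 C (umol mol-1 / mmol mol-1) and
## activation energies (J mol-1); peaked Arrhenius terms for Vcmax/Jmax.
KC25 <- 404.9;  EA_KC <- 79430
KO25 <- 278.4;  EA_KO <- 36380
GSTAR25 <- 42.75; EA_GSTAR <- 37830
O2_MMOL <- 210
EA_VCMAX <- 72000; HD_VCMAX <- 200000; DS_VCMAX <- 649
EA_JMAX <- 50000;  HD_JMAX <- 200000;  DS_JMAX <- 646
RGAS <- 8.314
COLIM_THETA <- 0.98

arrhenius <- function(k25, ea, tleaf) {
  tk <- tleaf + 273.15
  k25 * exp(ea * (tk - 298.15) / (298.15 * RGAS * tk))
}

peaked_arrhenius <- function(k25, ea, hd, ds, tleaf) {
  tk <- tleaf + 273.15
  arrhenius(k25, ea, tleaf) *
    (1 + exp((298.15 * ds - hd) / (298.15 * RGAS))) /
    (1 + exp((tk * ds - hd) / (tk * RGAS)))
}

## smooth co-limited minimum: smaller root of
## theta x^2 - (a+b) x + a b = 0
smooth_min <- function(a, b, theta) {
  ((a + b) - sqrt(pmax((a + b)^2 - 4 * theta * a * b, 0))) / (2 * theta)
}

#' Farquhar leaf net assimilation
#'
#' Rubisco-limited (`Ac`) and RuBP-regeneration-limited (`Aj`) gross rates
#' with peaked-Arrhenius temperature scaling of the kinetic constants,
#' electron transport from a non-rectangular hyperbola in absorbed PAR, a
#' smooth co-limited minimum (quadratic, curvature 0.98), and dark
#' respiration subtracted.
#'
#' @param ci intercellular CO2, umol mol-1.
#' @param tleaf leaf temperature, C.
#' @param apar absorbed PAR per unit leaf area, umol m-2 s-1.
#' @param params a [leaf_params()].
#' @param f_capacity multiplier on `Vcmax25` (seasonal capacity x drought x
#'   nitrogen), default 1.
#' @return list: `an` (net), `ac`, `aj` (gross), `rd`, `gamma_star`
#'   (umol m-2 s-1 / umol mol-1). All vectorized.
#' @export
farquhar_an <- function(ci, tleaf, apar, params, f_capacity = 1) {
  vcmax <- params$vcmax25 * f_capacity *
    peaked_arrhenius(1, EA_VCMAX, HD_VCMAX, DS_VCMAX, tleaf)
  jmax <- params$vcmax25 * f_capacity * params$jmax25_ratio *
    peaked_arrhenius(1, EA_JMAX, HD_JMAX, DS_JMAX, tleaf)
  rd <- params$vcmax25 * f_capacity * params$rd25_ratio *
    exp(0.069 * (tleaf - 25))
  kc <- arrhenius(KC25, EA_KC, tleaf)
  ko <- arrhenius(KO25, EA_KO, tleaf)
  gstar <- arrhenius(GSTAR25, EA_GSTAR, tleaf)
  km <- kc * (1 + O2_MMOL / ko)

  ib <- params$alpha_j * apar
  j <- smooth_min(ib, jmax, params$theta_j)

  ci_pos <- pmax(ci, 0)
  ac <- vcmax * (ci_pos - gstar) / (ci_pos + km)
  aj <- j / 4 * (ci_pos - gstar) / (ci_pos + 2 * gstar)
  a <- smooth_min(ac, aj, COLIM_THETA)
  # co-limitation quadratic is for positive limitation rates; below the
  # compensation point fall back to the stricter (more negative) limit
  neg <- ac < 0 | aj < 0
  a[neg] <- pmin(ac, aj)[neg]
  list(an = a - rd, ac = ac, aj = aj, rd = rd, gamma_star = gstar,
       j = j, vcmax = vcmax)
}

#' Medlyn optimal stomatal conductance
#'
#' `gs = g0 + (1 + g1/sqrt(Dl)) An/cs`, the conductance for CO2 implied by
#' maximizing carbon gain per unit water loss. `Dl` is floored at 0.05 kPa;
#' non-positive `An` gives the residual conductance. With
#' `params$medlyn_16` the slope term carries the 1.6 diffusivity prefactor
#' (the water-vapor formulation of the published model).
#'
#' @param an net assimilation, umol m-2 s-1.
#' @param cs leaf-surface CO2, umol mol-1.
#' @param dl leaf-to-air vapor pressure deficit, kPa.
#' @param params a [leaf_params()].
#' @param f_g1 drought multiplier on `g1` (default 1).
#' @return stomatal conductance for CO2, mol m-2(leaf) s-1. Vectorized.
#' @export
medlyn_gs <- function(an, cs, dl, params, f_g1 = 1) {
  dl <- pmax(dl, 0.05)
  pref <- if (isTRUE(params$medlyn_16)) 1.6 else 1
  gs <- params$g0 + pref * (1 + params$g1 * f_g1 / sqrt(dl)) *
    pmax(an, 0) / pmax(cs, 1)
  pmax(gs, params$g0)
}

## flat-plate leaf boundary-layer conductances (mol m-2 s-1), forced +
## free convection in parallel (two-sided for heat, one-sided for mass)
leaf_gb <- function(u, leaf_dim, dtleaf = 0) {
  forced_h <- 1.4 * 0.135 * sqrt(pmax(u, 0.1) / leaf_dim)
  free_h <- 0.05 * (pmax(abs(dtleaf), 0.01) / leaf_dim)^0.25
  gb_h <- forced_h + free_h
  list(heat = gb_h, vapor = 1.075 * gb_h, co2 = gb_h / 1.37)
}

#' Coupled leaf gas-exchange solver
#'
#' Fixed-point iteration of the Farquhar demand, Medlyn conductance and
#' Fickian diffusion (`cs = ca - An/gb`, `ci = cs - An/gs`) relations, with
#' an optional leaf energy balance (flat-plate convection, linearized
#' longwave) for leaf temperature. Damped updates (factor 0.5), at most
#' `max_iter` iterations, convergence when successive `ci` change falls
#' below `tol_ci`. Non-converged elements are flagged, never silently
#' accepted. All environmental arguments are vectorized.
#'
#' @param apar absorbed PAR per unit leaf area, umol m-2 s-1.
#' @param ta air temperature, C.
#' @param d air vapor pressure deficit, kPa.
#' @param ca ambient CO2, umol mol-1.
#' @param u wind speed, m s-1.
#' @param patm ambient pressure, kPa.
#' @param params a [leaf_params()].
#' @param f_capacity,f_g1 capacity and g1 multipliers (drought, season,
#'   nitrogen), default 1.
#' @param mode `"isothermal"` (leaf at air temperature, default) or
#'   `"energy_balance"`.
#' @param leaf_dim characteristic leaf dimension, m.
#' @param sw_abs absorbed shortwave for the energy balance, W m-2 (default
#'   derived from `apar`).
#' @param max_iter,tol_ci iteration controls.
#' @return list of class `leaf_state`: `an`, `gs`, `ci`, `cs`, `tleaf`,
#'   `gb`, `transp` (mol m-2(leaf) s-1), `rd`, `converged`, `iterations`,
#'   `energy_residual` (W m-2, energy-balance mode).
#' @export
solve_leaf <- function(apar, ta, d, ca, u = 3, patm = PATM_KPA,
                       params = leaf_params(),
                       f_capacity = 1, f_g1 = 1,
                       mode = c("isothermal", "energy_balance"),
                       leaf_dim = 0.002, sw_abs = NULL,
                       max_iter = 50, tol_ci = 1e-4) {
  mode <- match.arg(mode)
  n <- max(length(apar), length(ta), length(d), length(ca), length(u),
           length(patm), length(f_capacity), length(f_g1))
  apar <- rep_len(apar, n); ta <- rep_len(ta, n); d <- rep_len(pmax(d, 0), n)
  ca <- rep_len(ca, n); u <- rep_len(u, n); patm <- rep_len(patm, n)
  f_capacity <- rep_len(f_capacity, n); f_g1 <- rep_len(f_g1, n)
  if (is.null(sw_abs)) sw_abs <- apar / 4.57 * 2   # PAR + NIR, crude
  sw_abs <- rep_len(sw_abs, n)

  tleaf <- ta
  ci <- 0.7 * ca
  gb <- leaf_gb(u, leaf_dim)
  an <- rep(0, n); gs <- rep(params$g0, n); cs <- ca; dl <- d
  lambda <- 44100      # J mol-1 latent heat
  cp_mol <- 29.3       # J mol-1 K-1
  converged <- rep(FALSE, n)
  iter_used <- rep(max_iter, n)

  for (it in seq_len(max_iter)) {
    ph <- farquhar_an(ci, tleaf, apar, params, f_capacity)
    an <- ph$an
    cs <- pmax(ca - an / gb$co2, 10)
    dl <- if (mode == "energy_balance")
      pmax(esat_kpa(tleaf) - (esat_kpa(ta) - d), 0.01) else d
    gs <- medlyn_gs(an, cs, dl, params, f_g1)
    ci_new <- cs - an / gs
    ci_new <- pmin(pmax(ci_new, 1), 2.5 * ca)
    dci <- abs(ci_new - ci)
    ci <- ci + 0.5 * (ci_new - ci)

    if (mode == "energy_balance") {
      gw <- 1.6 * gs * gb$vapor / (1.6 * gs + gb$vapor)
      e_mol <- gw * dl / patm
      # linearized balance: sw_abs = 2 gbh cp dT + lambda E + lw loss
      lw_lin <- 0.92 * 4 * 5.67e-8 * (ta + 273.15)^3 # W m-2 K-1
      tl_new <- ta + (sw_abs - lambda * e_mol) /
        (2 * gb$heat * cp_mol + 2 * lw_lin)
      tleaf <- tleaf + 0.5 * (tl_new - tleaf)
      gb <- leaf_gb(u, leaf_dim, tleaf - ta)
    }

    newly <- !converged & dci < tol_ci
    iter_used[newly] <- it
    converged <- converged | newly
    if (all(converged) && it > 2) break
  }
  gw <- 1.6 * gs * gb$vapor / (1.6 * gs + gb$vapor)
  transp <- gw * (if (mode == "energy_balance")
    pmax(esat_kpa(tleaf) - (esat_kpa(ta) - d), 0) else d) / patm
  energy_residual <- if (mode == "energy_balance") {
    lw_lin <- 0.92 * 4 * 5.67e-8 * (ta + 273.15)^3
    sw_abs - lambda * transp -
      (2 * leaf_gb(u, leaf_dim, tleaf - ta)$heat * cp_mol +
         2 * lw_lin) * (tleaf - ta)
  } else rep(0, n)
  structure(list(an = an, gs = gs, ci = ci, cs = cs, tleaf = tleaf,
                 gb = gb$co2, transp = transp, rd = farquhar_an(
                   ci, tleaf, apar, params, f_capacity)$rd,
                 converged = converged, iterations = iter_used,
                 energy_residual = energy_residual),
            class = "leaf_state")
}
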