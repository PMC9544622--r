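#' Big-leaf canopy state
#'
#' Container for the big-leaf GPP/transpiration framework:
#' `GPP = LAI ca gs (1 - ci/ca)` and `ET = Tr + E = 1.6 (gs LAI) D + E`
#' (D as a mole fraction, i.e. divided by ambient pressure).
#'
#' @param lai leaf-area index, m2 m-2.
#' @param ca ambient CO2, umol mol-1.
#' @param gs effective canopy-average stomatal conductance per unit leaf
#'   area, mol m-2(leaf) s-1.
#' @param ci_ca internal-to-ambient CO2 ratio, in `[0, 1)` for productive
#'   states.
#' @param d vapor pressure deficit, kPa.
#' @param e non-stomatal evaporation, mol m-2 s-1.
#' @param patm ambient pressure, kPa.
#' @return list of class `bigleaf_state`.
#' @export
bigleaf_state <- function(lai, ca, gs, ci_ca, d = 1, e = 0,
                          patm = PATM_KPA) {
  stopifnot(lai >= 0, gs >= 0, ca > 0, ci_ca >= 0, d >= 0, e >= 0)
  structure(list(lai = lai, ca = ca, gs = gs, ci_ca = ci_ca, d = d, e = e,
                 patm = patm), class = "bigleaf_state")
}

#' Big-leaf GPP
#'
#' @param state a [bigleaf_state()].
#' @return GPP, umol m-2 s-1.
#' @export
bigleaf_gpp <- function(state) {
  state$lai * state$ca * state$gs * (1 - state$ci_ca)
}

#' Big-leaf transpiration and total ET
#'
#' `Tr = 1.6 gs LAI D/Patm` (the 1.6 is the water/CO2 molecular
#' diffusivity ratio); `ET = Tr + E`.
#'
#' @param state a [bigleaf_state()].
#' @return named vector `c(Tr, ET)` in mol m-2 s-1.
#' @export
bigleaf_transpiration <- function(state) {
  tr <- 1.6 * state$gs * state$lai * state$d / state$patm
  c(Tr = tr, ET = tr + state$e)
}

#' Invert the big-leaf relation for effective conductance
#'
#' `gs = GPP / (LAI ca (1 - ci/ca))`; expressing measured ecosystem fluxes
#' in the big-leaf framework. Round-trips with [bigleaf_gpp()] exactly.
#'
#' @param gpp GPP, umol m-2 s-1.
#' @param lai leaf-area index, m2 m-2.
#' @param ca ambient CO2, umol mol-1.
#' @param ci_ca internal-to-ambient CO2 ratio `< 1`.
#' @return gs, mol m-2(leaf) s-1 (`NA` where the denominator degenerates).
#' @export
invert_effective_gs <- function(gpp, lai, ca, ci_ca) {
  den <- lai * ca * (1 - ci_ca)
  out <- gpp / den
  out[!is.finite(out) | den <= 0] <- NA_real_
  out
}

#' First-order decomposition of relative GPP and transpiration changes
#'
#' Splits the relative change between two big-leaf states into the
#' fertilization (`dca/ca`), structural (`dLAI/LAI`) and physiological
#' (`dgs/gs` and `d(1-ci/ca)/(1-ci/ca)`) terms, plus the hydroclimatic
#' `dD/D` term for transpiration. Each term is `dx/x` with `x` the initial
#' (state A) value by default, or the mean of the two states with
#' `denominator = "mean"`. The exact relative change is the product ratio
#' minus one; `residual` is exact minus the first-order sum and vanishes
#' quadratically for small perturbations. The transpiration change is
#' evaluated both directly (`dLAI/LAI + dD/D + dgs/gs`) and through the GPP
#' identity (`dGPP/GPP + dD/D - dca/ca - d(1-ci/ca)/(1-ci/ca)`); the two
#' agree exactly when the first-order GPP sum is used.
#'
#' @param state_a,state_b initial and final [bigleaf_state()]s, all factors
#'   strictly positive.
#' @param denominator `"initial"` (default) or `"mean"`.
#' @return list of class `bigleaf_decomposition` with elements `gpp`
#'   (terms, first-order sum, exact, residual), `tr` (both forms, exact,
#'   residual) and the log-exact factor decomposition `log_terms`.
#' @export
decompose_changes <- function(state_a, state_b,
                              denominator = c("initial", "mean")) {
  denominator <- match.arg(denominator)
  fa <- c(ca = state_a$ca, lai = state_a$lai, gs = state_a$gs,
          u = 1 - state_a$ci_ca, d = state_a$d)
  fb <- c(ca = state_b$ca, lai = state_b$lai, gs = state_b$gs,
          u = 1 - state_b$ci_ca, d = state_b$d)
  if (any(fa <= 0)) stop("all state-A factors must be strictly positive")
  base <- if (denominator == "initial") fa else (fa + fb) / 2
  rel <- (fb - fa) / base

  gpp_terms <- c(fertilization = rel[["ca"]], structural = rel[["lai"]],
                 physiological_gs = rel[["gs"]],
                 physiological_cica = rel[["u"]])
  gpp_exact <- prod(fb[c("ca", "lai", "gs", "u")]) /
    prod(fa[c("ca", "lai", "gs", "u")]) - 1
  gpp_sum <- sum(gpp_terms)

  tr_direct <- rel[["lai"]] + rel[["d"]] + rel[["gs"]]
  tr_via_gpp <- gpp_sum + rel[["d"]] - rel[["ca"]] - rel[["u"]]
  tr_exact <- prod(fb[c("lai", "d", "gs")]) /
    prod(fa[c("lai", "d", "gs")]) - 1

  structure(list(
    gpp = list(terms = gpp_terms, first_order = gpp_sum,
               exact = gpp_exact, residual = gpp_exact - gpp_sum),
    tr = list(direct = tr_direct, via_gpp = tr_via_gpp,
              form_difference = tr_direct - tr_via_gpp,
              exact = tr_exact, residual = tr_exact - tr_direct),
    log_terms = log(fb / fa),
    denominator = denominator), class = "bigleaf_decomposition")
}

#' @export
print.bigleaf_decomposition <- function(x, ...) {
  cat("Big-leaf decomposition of relative changes\n  GPP terms:\n")
  for (nm in names(x$gpp$terms))
    cat(sprintf("    %-20s %+.4f\n", nm, x$gpp$terms[[nm]]))
  cat(sprintf("  first-order sum %+.4f, exact %+.4f, residual %+.2e\n",
              x$gpp$first_order, x$gpp$exact, x$gpp$residual))
  cat(sprintf("  Tr: direct %+.4f, via GPP %+.4f, exact %+.4f\n",
              x$tr$direct, x$tr$via_gpp, x$tr$exact))
  invisible(x)
}

#' Respiration budget under constant carbon-use efficiency
#'
#' With time-constant CUE, a GPP change implies an autotrophic respiration
#' change `dRa = (1 - CUE) dGPP`, and the ecosystem respiration change is
#' `dRe = dRa + dRh`.
#'
#' @param d_gpp change in GPP, gC m-2.
#' @param cue carbon-use efficiency, in `(0, 1)`.
#' @param d_rh change in heterotrophic respiration, gC m-2 (default 0).
#' @return named vector `c(dRa, dRe)`.
#' @export
respiration_budget <- function(d_gpp, cue, d_rh = 0) {
  if (any(cue <= 0 | cue >= 1)) stop("CUE must be in (0, 1)")
  dra <- (1 - cue) * d_gpp
  c(dRa = dra, dRe = dra + d_rh)
}
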