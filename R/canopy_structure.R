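#' Layered canopy structure
#'
#' Discretizes the canopy into `n_layers` horizontal layers and distributes
#' the leaf area of each plant type over them. Tree types follow a
#' beta-shaped leaf-area density profile; the understory occupies the
#' lowest tenth of the canopy. The per-layer leaf areas of all types sum
#' exactly to `lai_total`.
#'
#' @param lai_total total one-sided leaf-area index, m2 m-2.
#' @param n_layers number of canopy layers (default 100).
#' @param type_fractions named fractions of `lai_total` per plant type;
#'   must sum to 1. Defaults: pine 0.55, spruce 0.20, deciduous 0.10,
#'   understory 0.15.
#' @param height canopy height, m (used only for reporting).
#' @param leaf_dim characteristic leaf dimension, m (boundary-layer
#'   conductance).
#' @return list of class `canopy_structure`: `lai_layer` matrix
#'   `[n_layers x n_types]` (layer 1 = canopy top), `lai_cum` cumulative
#'   leaf area above each layer midpoint, `lai_total`, `n_layers`, etc.
#' @export
canopy_structure <- function(lai_total, n_layers = 100,
                             type_fractions = c(pine = 0.55, spruce = 0.20,
                                                deciduous = 0.10,
                                                understory = 0.15),
                             height = 18, leaf_dim = 0.002) {
  stopifnot(lai_total >= 0, n_layers >= 1,
            abs(sum(type_fractions) - 1) < 1e-9)
  # relative depth of layer midpoints, 0 = top, 1 = bottom
  z <- (seq_len(n_layers) - 0.5) / n_layers
  dens <- matrix(0, n_layers, length(type_fractions),
                 dimnames = list(NULL, names(type_fractions)))
  for (k in seq_along(type_fractions)) {
    nm <- names(type_fractions)[k]
    w <- if (nm == "understory") {
      ifelse(z > 0.9, 1, 0)
    } else {
      stats::dbeta(z, 2.5, 2.5)
    }
    if (all(w == 0)) w[n_layers] <- 1
    dens[, k] <- w / sum(w) * type_fractions[[k]] * lai_total
  }
  lai_layer_tot <- rowSums(dens)
  lai_cum <- cumsum(lai_layer_tot) - lai_layer_tot / 2
  structure(list(lai_layer = dens, lai_layer_total = lai_layer_tot,
                 lai_cum = lai_cum, lai_total = lai_total,
                 n_layers = n_layers, height = height, leaf_dim = leaf_dim),
            class = "canopy_structure")
}

#' Leaf physiological parameters
#'
#' Farquhar photosynthesis and Medlyn optimal-conductance parameters per
#' plant type. `Jmax25` and dark respiration at 25 C are proportional to
#' `Vcmax25`; drought modifiers reduce `Vcmax25` and `g1` below a
#' relative-extractable-water threshold; a sigmoid of a 5-day delayed
#' temperature state expresses the spring recovery of photosynthetic
#' capacity; `Vcmax25` scales linearly with relative leaf nitrogen.
#'
#' @param type one of `"pine"`, `"spruce"`, `"deciduous"`, `"understory"`
#'   (presets), or any name with explicit values.
#' @param vcmax25 maximum carboxylation rate at 25 C, umol m-2(leaf) s-1.
#' @param jmax25_ratio Jmax25/Vcmax25 (in `[1, 3]`).
#' @param rd25_ratio Rd25/Vcmax25.
#' @param g1 Medlyn slope, kPa^0.5.
#' @param g0 residual conductance, mol m-2(leaf) s-1.
#' @param alpha_j quantum yield of electron transport, mol e- per mol
#'   photons.
#' @param theta_j curvature of the J light response.
#' @param rew_crit relative extractable water below which drought modifiers
#'   engage.
#' @param nl_scaling relative Vcmax25 change per relative leaf-N change.
#' @param medlyn_16 include the 1.6 diffusivity prefactor on the Medlyn
#'   slope term (default FALSE: conductance for CO2 as the optimality
#'   result is stated).
#' @return list of class `leaf_params`.
#' @export
leaf_params <- function(type = "pine",
                        vcmax25 = NULL, jmax25_ratio = 1.9,
                        rd25_ratio = 0.015, g1 = NULL, g0 = 1e-3,
                        alpha_j = 0.3, theta_j = 0.7,
                        rew_crit = 0.44, nl_scaling = 1,
                        medlyn_16 = FALSE) {
  presets <- list(pine = c(vcmax25 = 55, g1 = 2.3),
                  spruce = c(vcmax25 = 60, g1 = 2.3),
                  deciduous = c(vcmax25 = 50, g1 = 4.5),
                  understory = c(vcmax25 = 40, g1 = 2.3))
  if (is.null(vcmax25))
    vcmax25 <- if (type %in% names(presets)) presets[[type]][["vcmax25"]] else 50
  if (is.null(g1))
    g1 <- if (type %in% names(presets)) presets[[type]][["g1"]] else 2.3
  stopifnot(vcmax25 >= 0, jmax25_ratio >= 1, jmax25_ratio <= 3,
            rd25_ratio >= 0, g1 >= 0, g0 >= 0)
  structure(list(type = type, vcmax25 = vcmax25,
                 jmax25_ratio = jmax25_ratio, rd25_ratio = rd25_ratio,
                 g1 = g1, g0 = g0, alpha_j = alpha_j, theta_j = theta_j,
                 rew_crit = rew_crit, nl_scaling = nl_scaling,
                 medlyn_16 = medlyn_16), class = "leaf_params")
}

## drought modifiers: saturating power functions of relative extractable
## water, equal to 1 above rew_crit
f_drought_vcmax <- function(rew, rew_crit = 0.44) {
  pmin((pmax(rew, 0) / rew_crit)^0.5, 1)
}
f_drought_g1 <- function(rew, rew_crit = 0.44) {
  pmin((pmax(rew, 0) / rew_crit)^0.75, 1)
}
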