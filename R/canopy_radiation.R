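#' Sunlit/shaded radiation profile through the canopy
#'
#' Beer-law extinction with a spherical leaf-angle distribution: the
#' direct-beam extinction coefficient is `kb = 0.5/cos(zenith)` and the
#' sunlit fraction at cumulative leaf area `L` is `exp(-kb L)`; diffuse PAR
#' attenuates with `kd = 0.7`. Per-layer absorbed fluxes are computed as
#' differences of the transmitted flux across layer boundaries, so canopy
#' absorption plus the flux reaching the forest floor equals the incident
#' flux exactly (zero-albedo PAR mode).
#'
#' @param structure a [canopy_structure()].
#' @param zenith solar zenith angle, degrees.
#' @param par_direct,par_diffuse incident direct-beam and diffuse PAR,
#'   umol m-2 s-1.
#' @param kd diffuse extinction coefficient (default 0.7).
#' @return list: `f_sun` sunlit fraction per layer (midpoint), `q_sun` and
#'   `q_shade` absorbed PAR per unit sunlit/shaded leaf area, `floor_par`
#'   transmitted to the forest floor, `absorbed_total`, and the incident
#'   total for conservation checks. Layer 1 is the canopy top.
#' @export
radiation_profile <- function(structure, zenith, par_direct, par_diffuse,
                              kd = 0.7) {
  nl <- structure$n_layers
  dlai <- structure$lai_layer_total
  bounds <- c(0, cumsum(dlai))            # cumulative LAI at layer edges
  mids <- structure$lai_cum
  cosz <- cos(zenith * pi / 180)
  if (zenith >= 90 && par_direct > 0) {
    warning("sun below horizon: direct beam forced to 0")
    par_direct <- 0
  }
  kb <- if (cosz > 0.01) 0.5 / cosz else 50
  f_sun <- exp(-kb * mids)

  dir_edge <- par_direct * exp(-kb * bounds)
  dif_edge <- par_diffuse * exp(-kd * bounds)
  dir_abs <- -diff(dir_edge)              # per-layer absorbed direct
  dif_abs <- -diff(dif_edge)

  q_shade <- ifelse(dlai > 0, dif_abs / dlai, 0)
  sun_lai <- f_sun * dlai
  q_sun_dir <- ifelse(sun_lai > 0, dir_abs / sun_lai, 0)
  q_sun <- q_shade + q_sun_dir

  list(f_sun = f_sun, q_sun = q_sun, q_shade = q_shade,
       floor_par = dir_edge[nl + 1] + dif_edge[nl + 1],
       absorbed_total = sum(dir_abs) + sum(dif_abs),
       incident = par_direct + par_diffuse, kb = kb, kd = kd)
}
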