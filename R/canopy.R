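#' Run the multilayer canopy gas-exchange model
#'
#' For every half-hour: the radiation profile splits PAR into per-layer
#' sunlit/shaded absorbed fluxes; the coupled Farquhar-Medlyn leaf solver
#' is applied per plant type and leaf class; leaf-area-weighted aggregation
#' yields canopy GPP and transpiration. Canopy air is assumed well mixed
#' (above-canopy Ta, D and ca reach every layer; wind attenuates
#' exponentially). Rain is intercepted into a canopy store (0.2 mm per
#' unit LAI) evaporating at an energy-limited rate while suppressing
#' transpiration on the wet fraction; the forest floor evaporates a fixed
#' fraction of the below-canopy radiation; soil respiration is Q10 on soil
#' temperature. NEP = GPP - (soil respiration + foliage dark respiration).
#'
#' @param forcing a `forcing_series` (any subset of rows, chronological).
#' @param structure a [canopy_structure()].
#' @param params a [leaf_params()] or named list of them, one per column of
#'   `structure$lai_layer`.
#' @param soil list: `r10` base soil respiration at 10 C (umol m-2 s-1)
#'   and `q10` (defaults 2.0, 2.2).
#' @param mode leaf solver mode, `"isothermal"` (default) or
#'   `"energy_balance"`.
#' @param f_nl relative leaf-nitrogen multiplier on Vcmax25 (scalar or
#'   per-row), default 1.
#' @param n_sub optional integer: use every `n_sub`-th half-hour (thinning
#'   for sensitivity sweeps).
#' @return data.frame of class `canopy_run`: per half-hour `GPP`, `Re`,
#'   `NEP` (umol m-2 s-1), `Tr`, `E_wet`, `E_floor`, `ET` (mmol m-2 s-1),
#'   `gs_mean`, `cica_mean` (leaf-area-weighted), `wet_frac`; attributes
#'   `radiation_closure` (max absolute PAR conservation error) and
#'   `water_closure` (max absolute interception budget error, mm), and
#'   `n_nonconverged`.
#' @export
run_canopy <- function(forcing, structure, params = leaf_params(),
                       soil = list(r10 = 2.0, q10 = 2.2),
                       mode = "isothermal", f_nl = 1, n_sub = NULL) {
  if (anyNA(forcing$PAR) || anyNA(forcing$Ta))
    stop("forcing must be complete")
  if (!is.null(n_sub)) forcing <- forcing[seq(1, nrow(forcing), n_sub), ]
  nt <- nrow(forcing)
  nl <- structure$n_layers
  types <- colnames(structure$lai_layer)
  if (inherits(params, "leaf_params"))
    params <- stats::setNames(rep(list(params), length(types)), types)

  cosz <- pmax(cos(forcing$zenith * pi / 180), 0)
  par_dir <- forcing$PAR * (1 - forcing$fd)
  par_dir[cosz <= 0.01] <- 0
  par_dif <- forcing$PAR - par_dir

  dlai <- structure$lai_layer_total
  bounds <- c(0, cumsum(dlai))
  mids <- structure$lai_cum
  kb <- ifelse(cosz > 0.01, 0.5 / pmax(cosz, 0.01), 50)
  kd <- 0.7

  eb_dir <- exp(-outer(kb, bounds))        # nt x (nl+1)
  eb_dif <- matrix(exp(-kd * bounds), nt, nl + 1, byrow = TRUE)
  dir_edge <- par_dir * eb_dir
  dif_edge <- par_dif * eb_dif
  dir_abs <- dir_edge[, 1:nl, drop = FALSE] - dir_edge[, -1, drop = FALSE]
  dif_abs <- dif_edge[, 1:nl, drop = FALSE] - dif_edge[, -1, drop = FALSE]
  f_sun <- exp(-outer(kb, mids))
  floor_par <- dir_edge[, nl + 1] + dif_edge[, nl + 1]
  rad_closure <- max(abs(rowSums(dir_abs) + rowSums(dif_abs) + floor_par -
                           forcing$PAR))

  # per-leaf absorbed PAR [nt x nl]
  q_shade <- sweep(dif_abs, 2, ifelse(dlai > 0, dlai, 1), "/")
  sun_lai <- sweep(f_sun, 2, dlai, "*")
  q_sun <- q_shade + ifelse(sun_lai > 0, dir_abs / pmax(sun_lai, 1e-12), 0)

  day <- forcing$PAR > 0
  tstate <- season_state(forcing$Ta)
  fsea <- season_capacity(tstate)
  u_l <- outer(forcing$U, exp(-0.5 * mids))

  gpp <- re_leaf <- tr <- gs_w <- cica_w <- area_w <- numeric(nt)
  n_noncv <- 0L

  solve_class <- function(apar_mat, p, fcap, fg1, area_mat) {
    # solve daytime rows only, flattened [day x layer]
    an <- rd <- gs <- ci <- e <- matrix(0, nt, nl)
    rd_night <- farquhar_an(400, forcing$Ta, 0, p, fcap)$rd
    if (any(day)) {
      idx <- which(day)
      ap <- apar_mat[idx, , drop = FALSE]
      st <- solve_leaf(as.vector(ap),
                       rep(forcing$Ta[idx], nl), rep(forcing$D[idx], nl),
                       rep(forcing$ca[idx], nl), as.vector(u_l[idx, ,
                                                                drop = FALSE]),
                       rep(forcing$Patm[idx], nl), p,
                       f_capacity = rep(fcap[idx], nl),
                       f_g1 = rep(fg1[idx], nl), mode = mode,
                       leaf_dim = structure$leaf_dim)
      n_noncv <<- n_noncv + sum(!st$converged)
      an[idx, ] <- st$an; rd[idx, ] <- st$rd; gs[idx, ] <- st$gs
      ci[idx, ] <- st$ci; e[idx, ] <- st$transp
    }
    night_idx <- which(!day)
    if (length(night_idx)) {
      rd[night_idx, ] <- rd_night[night_idx]
      an[night_idx, ] <- -rd_night[night_idx]
      gs[night_idx, ] <- p$g0
      ci[night_idx, ] <- forcing$ca[night_idx] * 1.1
    }
    list(gpp = rowSums((an + rd) * area_mat),
         rd = rowSums(rd * area_mat),
         tr = rowSums(e * area_mat),
         gs_area = rowSums(gs * area_mat),
         cica_area = rowSums(ci / forcing$ca * area_mat),
         area = rowSums(area_mat))
  }

  for (ty in types) {
    p <- params[[ty]]
    lai_ty <- structure$lai_layer[, ty]
    if (all(lai_ty == 0)) next
    fcap <- fsea * f_drought_vcmax(forcing$Rew, p$rew_crit) *
      (1 + p$nl_scaling * (rep_len(f_nl, nt) - 1))
    fg1 <- f_drought_g1(forcing$Rew, p$rew_crit)
    area_sun <- sweep(f_sun, 2, lai_ty, "*")
    area_shade <- sweep(1 - f_sun, 2, lai_ty, "*")
    cs_sun <- solve_class(q_sun, p, fcap, fg1, area_sun)
    cs_sh <- solve_class(q_shade, p, fcap, fg1, area_shade)
    gpp <- gpp + cs_sun$gpp + cs_sh$gpp
    re_leaf <- re_leaf + cs_sun$rd + cs_sh$rd
    tr <- tr + cs_sun$tr + cs_sh$tr
    gs_w <- gs_w + cs_sun$gs_area + cs_sh$gs_area
    cica_w <- cica_w + cs_sun$cica_area + cs_sh$cica_area
    area_w <- area_w + cs_sun$area + cs_sh$area
  }

  # interception store and wet-canopy evaporation (sequential, mm)
  cap <- 0.2 * structure$lai_total
  sw_canopy <- (forcing$PAR - floor_par) / 4.57 * 2   # W m-2, PAR+NIR
  ep_wet_mm <- pmax(0.7 * sw_canopy / 44100, 0) * HALF_HOUR * 0.018015
  s <- numeric(nt); inter <- numeric(nt); ewet_mm <- numeric(nt)
  wet_frac <- numeric(nt)
  s_prev <- 0
  for (i in seq_len(nt)) {
    inter[i] <- min(forcing$P[i], cap - s_prev)
    s_now <- s_prev + inter[i]
    wet_frac[i] <- if (cap > 0) s_now / cap else 0
    ewet_mm[i] <- min(s_now, ep_wet_mm[i] * wet_frac[i])
    s[i] <- s_now - ewet_mm[i]
    s_prev <- s[i]
  }
  throughfall <- forcing$P - inter
  water_closure <- max(abs(forcing$P - (diff(c(0, s)) + throughfall +
                                          ewet_mm)))
  ewet_mol <- ewet_mm / (HALF_HOUR * 0.018015)
  efloor_mol <- pmax(0.25 * (floor_par / 4.57 * 2) / 44100, 0)

  tr_dry <- tr * (1 - wet_frac)
  et_mol <- tr_dry + ewet_mol + efloor_mol
  rsoil <- soil$r10 * soil$q10^((forcing$Ts - 10) / 10)
  re <- rsoil + re_leaf

  out <- data.frame(timestamp = forcing$timestamp,
                    year = forcing$year, doy = forcing$doy,
                    GPP = gpp, Re = re, NEP = gpp - re,
                    Tr = tr_dry * 1000, E_wet = ewet_mol * 1000,
                    E_floor = efloor_mol * 1000, ET = et_mol * 1000,
                    gs_mean = ifelse(area_w > 0, gs_w / area_w, NA),
                    cica_mean = ifelse(area_w > 0, cica_w / area_w, NA),
                    wet_frac = wet_frac)
  attr(out, "radiation_closure") <- rad_closure
  attr(out, "water_closure") <- water_closure
  attr(out, "n_nonconverged") <- n_noncv
  class(out) <- c("canopy_run", "data.frame")
  out
}

#' Scenario engine: sequential attribution of flux trends
#'
#' Runs the canopy model over multiple years under scenarios in which the
#' measured meteorology always varies while ambient CO2, leaf area and
#' leaf nitrogen are either held at their record means or follow their
#' time series: `met`, `met_ca`, `met_lai`, `met_ca_lai`, `met_ca_lai_nl`.
#' May-September daytime dry-canopy sums are formed per year and their
#' trends (Sen + OLS, % a-1 of the scenario mean) computed; attribution is
#' the trend difference against the `met` baseline.
#'
#' @param forcing multi-year `forcing_series`.
#' @param structure reference [canopy_structure()] (record-mean LAI).
#' @param params leaf parameters as in [run_canopy()].
#' @param lai_by_year data.frame `year`, `lai` (e.g. [annual_lai()]).
#' @param scenarios character vector of scenario names (must include
#'   `"met"`).
#' @param nl_trend relative leaf-nitrogen trend, fraction a-1 (default
#'   0.018).
#' @param period inclusive `c("MM-DD","MM-DD")` analysis window (default
#'   May-September).
#' @param soil,mode,n_sub passed to [run_canopy()].
#' @return list of class `scenario_result`: `annual` (long data.frame of
#'   per-scenario annual sums), `trends` (per scenario and variable:
#'   relative Sen/OLS slope, p), `attribution` (trend minus `met` trend).
#' @export
scenario_engine <- function(forcing, structure, params, lai_by_year,
                            scenarios = c("met", "met_ca", "met_lai",
                                          "met_ca_lai", "met_ca_lai_nl"),
                            nl_trend = 0.018,
                            period = c("05-01", "09-30"),
                            soil = list(r10 = 2.0, q10 = 2.2),
                            mode = "isothermal", n_sub = NULL) {
  stopifnot("met" %in% scenarios)
  md <- sprintf("%02d-%02d", as.POSIXlt(forcing$timestamp)$mon + 1,
                as.POSIXlt(forcing$timestamp)$mday)
  sel <- md >= period[1] & md <= period[2]
  fsub <- forcing[sel, ]
  years <- sort(unique(fsub$year))
  ca_mean <- mean(forcing$ca)
  lai_mean <- mean(lai_by_year$lai)
  dry <- dry_canopy_mask(fsub$P, 12)

  annual <- list()
  for (sc in scenarios) {
    use_ca <- grepl("ca", sc)
    use_lai <- grepl("lai", sc)
    use_nl <- grepl("nl", sc)
    for (y in years) {
      rows <- fsub$year == y
      fy <- fsub[rows, ]
      if (!use_ca) fy$ca <- ca_mean
      lai_y <- if (use_lai) lai_by_year$lai[lai_by_year$year == y] else lai_mean
      st_y <- canopy_structure(lai_y, structure$n_layers,
                               leaf_dim = structure$leaf_dim)
      f_nl <- if (use_nl) 1 + nl_trend * (y - years[1]) else 1
      run <- run_canopy(fy, st_y, params, soil = soil, mode = mode,
                        f_nl = f_nl, n_sub = n_sub)
      step <- if (is.null(n_sub)) 1L else as.integer(n_sub)
      keep <- seq(1, nrow(fy), step)
      fy_used <- fy[keep, ]
      dsel <- dry[rows][keep] & run$GPP > 0
      w <- HALF_HOUR * step
      annual[[length(annual) + 1L]] <- data.frame(
        scenario = sc, year = y,
        GPP = sum(run$GPP[dsel]) * w * UMOL_CO2_TO_GC,
        ET = sum(run$ET[dsel]) * w * MMOL_H2O_TO_MM,
        Gs = stats::median(surface_conductance(
          run$ET[dsel] / 1000, fy_used$D[dsel], fy_used$Patm[dsel]),
          na.rm = TRUE),
        gs_leaf = mean(run$gs_mean[dsel], na.rm = TRUE),
        cica = mean(run$cica_mean[dsel], na.rm = TRUE))
    }
  }
  annual <- do.call(rbind, annual)

  vars <- c("GPP", "ET", "Gs", "gs_leaf", "cica")
  trends <- do.call(rbind, lapply(scenarios, function(sc) {
    a <- annual[annual$scenario == sc, ]
    do.call(rbind, lapply(vars, function(v) {
      tr <- linear_trend(a[[v]], a$year)
      data.frame(scenario = sc, variable = v,
                 rel_sen = 100 * tr$sen_slope / tr$mean,
                 rel_ols = 100 * tr$ols_slope / tr$mean,
                 p = tr$p)
    }))
  }))
  base <- trends[trends$scenario == "met", c("variable", "rel_sen")]
  attribution <- trends
  attribution$attr_sen <- trends$rel_sen -
    base$rel_sen[match(trends$variable, base$variable)]
  structure(list(annual = annual, trends = trends,
                 attribution = attribution), class = "scenario_result")
}

#' Leaf- and ecosystem-scale response curves to CO2 and leaf area
#'
#' Normalized responses of GPP, conductance, WUE and ci/ca to an ambient
#' CO2 grid (leaf and ecosystem scale) and of the ecosystem to a LAI grid,
#' evaluated as growing-season means of daytime dry-canopy half-hours
#' (PAR > 100 umol m-2 s-1) of a reference year; the leaf scale is a
#' sunlit leaf at the canopy top. Responses are normalized at
#' `ca0` / the reference LAI. Distributions of instantaneous relative GPP
#' responses between the grid ends are returned as well.
#'
#' @param forcing_ref single-year `forcing_series` (the reference growing
#'   season is extracted internally).
#' @param structure reference [canopy_structure()].
#' @param params leaf parameters (single [leaf_params()] or list).
#' @param ca_grid CO2 grid, ppm (should contain `ca0`).
#' @param lai_grid LAI grid, m2 m-2 (should contain the reference LAI).
#' @param ca0 normalization CO2 (default 375 ppm).
#' @param n_sub thinning passed to [run_canopy()] (default 4).
#' @param soil,mode passed to [run_canopy()].
#' @return list of class `response_curves`: `ca` (data.frame scale x ca:
#'   normalized GPP, gs, WUE, cica), `lai` (ecosystem LAI responses),
#'   `inst_rel_gpp` (instantaneous ecosystem relative responses between
#'   the CO2 grid ends).
#' @export
response_curves <- function(forcing_ref, structure, params,
                            ca_grid = seq(325, 525, by = 50),
                            lai_grid = seq(2, 6, by = 1),
                            ca0 = 375, n_sub = 4,
                            soil = list(r10 = 2.0, q10 = 2.2),
                            mode = "isothermal") {
  md <- sprintf("%02d-%02d", as.POSIXlt(forcing_ref$timestamp)$mon + 1,
                as.POSIXlt(forcing_ref$timestamp)$mday)
  dry <- dry_canopy_mask(forcing_ref$P, 24)
  sel <- md >= "05-01" & md <= "09-30" & dry & forcing_ref$PAR > 100
  fgs <- forcing_ref[sel, ]
  if (!is.null(n_sub)) fgs <- fgs[seq(1, nrow(fgs), n_sub), ]

  p_top <- if (inherits(params, "leaf_params")) params else params[[1]]

  eco_run <- function(ca_val, st) {
    f <- fgs; f$ca <- ca_val
    r <- run_canopy(f, st, params, soil = soil, mode = mode)
    gs_big <- surface_conductance(r$ET / 1000, f$D, f$Patm)
    c(gpp = mean(r$GPP), gs = mean(r$gs_mean, na.rm = TRUE),
      Gs = stats::median(gs_big, na.rm = TRUE),
      wue = sum(r$GPP) / sum(r$ET), cica = mean(r$cica_mean, na.rm = TRUE))
  }
  leaf_run <- function(ca_val) {
    kb <- 0.5 / pmax(cos(fgs$zenith * pi / 180), 0.05)
    apar <- kb * fgs$PAR * (1 - fgs$fd) + 0.7 * fgs$PAR * fgs$fd
    st <- solve_leaf(apar, fgs$Ta, fgs$D, rep(ca_val, nrow(fgs)),
                     fgs$U, fgs$Patm, p_top,
                     f_capacity = season_capacity(season_state(fgs$Ta)) *
                       f_drought_vcmax(fgs$Rew, p_top$rew_crit),
                     f_g1 = f_drought_g1(fgs$Rew, p_top$rew_crit),
                     mode = mode)
    c(gpp = mean(st$an + st$rd), gs = mean(st$gs),
      wue = mean(st$an + st$rd) / mean(st$transp),
      cica = mean(st$ci / ca_val))
  }

  eco_ca <- t(vapply(ca_grid, eco_run, numeric(5), st = structure))
  leaf_ca <- t(vapply(ca_grid, leaf_run, numeric(4)))
  i0 <- which.min(abs(ca_grid - ca0))
  ca_tab <- rbind(
    data.frame(scale = "ecosystem", ca = ca_grid,
               gpp = eco_ca[, "gpp"] / eco_ca[i0, "gpp"],
               gs = eco_ca[, "gs"] / eco_ca[i0, "gs"],
               Gs = eco_ca[, "Gs"] / eco_ca[i0, "Gs"],
               wue = eco_ca[, "wue"] / eco_ca[i0, "wue"],
               cica = eco_ca[, "cica"]),
    data.frame(scale = "leaf", ca = ca_grid,
               gpp = leaf_ca[, "gpp"] / leaf_ca[i0, "gpp"],
               gs = leaf_ca[, "gs"] / leaf_ca[i0, "gs"],
               Gs = NA_real_,
               wue = leaf_ca[, "wue"] / leaf_ca[i0, "wue"],
               cica = leaf_ca[, "cica"]))

  lai0 <- structure$lai_total
  eco_lai <- t(vapply(lai_grid, function(l)
    eco_run(ca0, canopy_structure(l, structure$n_layers,
                                  leaf_dim = structure$leaf_dim)),
    numeric(5)))
  iL <- which.min(abs(lai_grid - lai0))
  lai_tab <- data.frame(lai = lai_grid,
                        gpp = eco_lai[, "gpp"] / eco_lai[iL, "gpp"],
                        gs = eco_lai[, "gs"] / eco_lai[iL, "gs"],
                        Gs = eco_lai[, "Gs"] / eco_lai[iL, "Gs"],
                        wue = eco_lai[, "wue"] / eco_lai[iL, "wue"],
                        cica = eco_lai[, "cica"])

  f_lo <- fgs; f_lo$ca <- min(ca_grid)
  f_hi <- fgs; f_hi$ca <- max(ca_grid)
  r_lo <- run_canopy(f_lo, structure, params, soil = soil, mode = mode)
  r_hi <- run_canopy(f_hi, structure, params, soil = soil, mode = mode)
  ok <- r_lo$GPP > 0.5
  inst <- (r_hi$GPP[ok] - r_lo$GPP[ok]) / r_lo$GPP[ok]

  structure(list(ca = ca_tab, lai = lai_tab, inst_rel_gpp = inst,
                 ca0 = ca0, lai0 = lai0), class = "response_curves")
}
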