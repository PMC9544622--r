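test_that("radiation profile conserves PAR and obeys Beer's law", {
  st <- canopy_structure(4, n_layers = 1)
  rp <- radiation_profile(st, 0, 1000, 200)
  # single layer of LAI 4: midpoint depth 2, kb = 0.5 at zenith 0
  expect_equal(rp$f_sun, exp(-1), tolerance = 1e-12)
  expect_equal(rp$absorbed_total + rp$floor_par, rp$incident,
               tolerance = 1e-9)

  st2 <- canopy_structure(3.8, n_layers = 20)
  for (zen in c(0, 35, 70)) {
    rp2 <- radiation_profile(st2, zen, 800, 400)
    expect_equal(rp2$absorbed_total + rp2$floor_par, 1200,
                 tolerance = 1e-9)
    expect_true(all(diff(rp2$f_sun) <= 0))     # monotone with depth
    expect_true(all(rp2$q_sun >= rp2$q_shade))
  }
  # zero LAI: everything transmitted, sunlit everywhere
  st0 <- canopy_structure(0, n_layers = 5)
  rp0 <- radiation_profile(st0, 30, 700, 300)
  expect_equal(rp0$floor_par, 1000)
  expect_true(all(rp0$f_sun == 1))
  expect_warning(radiation_profile(st2, 95, 100, 0), "horizon")
})

test_that("Farquhar assimilation matches hand-evaluated kinetics at 25 C", {
  p <- leaf_params(vcmax25 = 50, jmax25_ratio = 1.9, rd25_ratio = 0.015)
  ph <- farquhar_an(ci = 300, tleaf = 25, apar = 2000, params = p)
  # oracle: direct evaluation with the published constants
  km <- 404.9 * (1 + 210 / 278.4)
  ac_oracle <- 50 * (300 - 42.75) / (300 + km)
  expect_equal(ph$ac, ac_oracle, tolerance = 1e-10)
  expect_equal(ph$rd, 50 * 0.015, tolerance = 1e-10)
  # dark leaf respires
  dark <- farquhar_an(300, 15, 0, p)
  expect_equal(dark$an, -dark$rd, tolerance = 1e-10)
  # compensation point: gross assimilation zero
  comp <- farquhar_an(ph$gamma_star, 25, 800, p)
  expect_equal(comp$an, -comp$rd, tolerance = 1e-8)
})

test_that("Medlyn conductance follows the optimality form", {
  p <- leaf_params(g1 = 2.3, g0 = 0.001)
  expect_equal(medlyn_gs(10, 400, 1, p),
               0.001 + (1 + 2.3) * 10 / 400, tolerance = 1e-12)
  expect_equal(medlyn_gs(10, 400, 4, p),
               0.001 + (1 + 2.3 / 2) * 10 / 400, tolerance = 1e-12)
  expect_equal(medlyn_gs(0, 400, 1, p), 0.001)
  expect_equal(medlyn_gs(-3, 400, 1, p), 0.001)
  # the 1.6 water-vapor prefactor variant scales the slope term
  p16 <- leaf_params(g1 = 2.3, g0 = 0.001, medlyn_16 = TRUE)
  expect_equal(medlyn_gs(10, 400, 1, p16),
               0.001 + 1.6 * (1 + 2.3) * 10 / 400, tolerance = 1e-12)
})

test_that("the coupled leaf solver satisfies its defining relations", {
  p <- leaf_params()
  st <- solve_leaf(apar = c(0, 50, 400, 1200), ta = 18, d = 1, ca = 400)
  expect_true(all(st$converged))
  # dark: efflux, residual conductance, ci above ca
  expect_equal(st$an[1], -st$rd[1], tolerance = 1e-8)
  expect_equal(st$gs[1], p$g0)
  expect_gt(st$ci[1], 400)
  # converged states satisfy the conductance and diffusion relations
  set.seed(30)
  apar <- runif(50, 30, 1500); ta <- runif(50, 5, 25)
  d <- runif(50, 0.2, 2.5); ca <- runif(50, 350, 450)
  s <- solve_leaf(apar, ta, d, ca)
  gs_chk <- medlyn_gs(s$an, s$cs, pmax(d, 0.05), p)
  expect_lt(max(abs(gs_chk - s$gs) / s$gs), 1e-5)
  ci_chk <- s$cs - s$an / s$gs
  expect_lt(max(abs(ci_chk - s$ci)), 2e-3)
})

test_that("the solver agrees with an independent bisection oracle", {
  p <- leaf_params()
  set.seed(31)
  for (i in 1:50) {
    apar <- runif(1, 50, 1500); ta <- runif(1, 5, 25)
    d <- runif(1, 0.2, 2.5); ca <- runif(1, 350, 450); u <- runif(1, 1, 5)
    s <- solve_leaf(apar, ta, d, ca, u)
    # oracle: root of the supply/demand mismatch in ci, using only the
    # component functions
    gb_c <- (1.4 * 0.135 * sqrt(u / 0.002) +
               0.05 * (0.01 / 0.002)^0.25) / 1.37
    mismatch <- function(ci) {
      an <- farquhar_an(ci, ta, apar, p)$an
      cs <- max(ca - an / gb_c, 10)
      gs <- medlyn_gs(an, cs, max(d, 0.05), p)
      (cs - an / gs) - ci
    }
    root <- uniroot(mismatch, c(1, 2 * ca), tol = 1e-8)$root
    expect_lt(abs(s$ci - root), 1e-3)
  }
})

test_that("energy-balance mode closes the leaf energy budget", {
  s <- solve_leaf(apar = c(300, 900, 1500), ta = 20, d = 1.2, ca = 400,
                  mode = "energy_balance")
  expect_true(all(abs(s$energy_residual) < 1))
  expect_true(all(s$tleaf > 20))     # sunlit leaves above air temperature
})

test_that("one well-mixed layer upscales to LAI times the leaf flux", {
  # all-diffuse light makes sunlit and shaded classes identical
  f <- constant_forcing(2)
  f$fd <- 1
  st <- canopy_structure(3, n_layers = 1,
                         type_fractions = c(pine = 1))
  p <- leaf_params("pine")
  run <- run_canopy(f, st, p)
  day <- which(f$PAR > 0)[10]
  # equivalent single leaf: absorbed PAR = layer absorption / LAI
  apar <- f$PAR[day] * (1 - exp(-0.7 * 3)) / 3
  fcap <- borealflux:::season_capacity(borealflux:::season_state(f$Ta))[day] *
    borealflux:::f_drought_vcmax(f$Rew[day], p$rew_crit)
  leaf <- solve_leaf(apar, f$Ta[day], f$D[day], f$ca[day],
                     f$U[day] * exp(-0.5 * 1.5), f$Patm[day], p,
                     f_capacity = fcap,
                     f_g1 = borealflux:::f_drought_g1(f$Rew[day], p$rew_crit))
  expect_equal(run$GPP[day], 3 * (leaf$an + leaf$rd), tolerance = 1e-9)
})

test_that("a dark day yields zero GPP and respiratory NEP", {
  f <- constant_forcing(2)
  f$PAR <- 0; f$Rg <- 0; f$zenith <- 120
  st <- canopy_structure(3.8, n_layers = 5)
  run <- run_canopy(f, st, leaf_params())
  expect_true(all(run$GPP == 0))
  expect_equal(run$NEP, -run$Re, tolerance = 1e-12)
  expect_true(all(run$Re > 0))
})

test_that("canopy closures hold on a stochastic month", {
  x <- fx_two_year()
  f <- x$forcing[x$forcing$doy >= 170 & x$forcing$doy <= 184 &
                   x$forcing$year == 2003, ]
  st <- canopy_structure(3.8, n_layers = 10)
  run <- run_canopy(f, st, leaf_params())
  expect_lt(attr(run, "radiation_closure"), 1e-9)
  expect_lt(attr(run, "water_closure"), 1e-9)
  expect_equal(attr(run, "n_nonconverged"), 0)
  expect_true(all(run$ET >= 0))
  # missing forcing rejected before the run
  f_bad <- f; f_bad$PAR[5] <- NA
  expect_error(run_canopy(f_bad, st, leaf_params()), "complete")
})
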