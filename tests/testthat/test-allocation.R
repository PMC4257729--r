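# Store classification, the priority ladder, and the composition correction.

mk_budget <- function(maint = 8, growth_fm = 0, growth_ffm = 0, at = 0) {
  structure(list(bmr = maint, pa = 0, tef = 0, growth_fm = growth_fm,
                 growth_ffm = growth_ffm, turnover = 0, at_adjustment = at,
                 total = maint + growth_fm + growth_ffm + at),
            class = "gs_budget")
}

mk_ind <- function(fm_star, ffm_star) {
  structure(list(bmi_star = NA, bw_star = fm_star + ffm_star,
                 fmi_star = NA, fm_star = fm_star, ffm_star = ffm_star),
            class = "gs_indicated")
}

test_that("stores split into extra and essential around the indicated masses", {
  st <- body_state(fm = 15, ffm = 55, h = 1.7, age = yr(30))
  s1 <- classify_stores(st, mk_ind(15, 55))
  expect_identical(c(s1$extra_fm, s1$essential_fm), c(0, 15))
  s2 <- classify_stores(st, mk_ind(12, 55))
  expect_identical(c(s2$extra_fm, s2$essential_fm), c(3, 12))
  s3 <- classify_stores(st, mk_ind(18, 55))
  expect_identical(c(s3$extra_fm, s3$essential_fm), c(0, 15))
  expect_equal(s2$extra_ffm + s2$essential_ffm, st$ffm)
})

test_that("equilibrium intake produces no flows beyond intake-to-maintenance", {
  st <- body_state(fm = 15, ffm = 60, h = 1.75, age = yr(30))
  ind <- mk_ind(15, 60)
  a <- allocate(8, mk_budget(8), classify_stores(st, ind), 0.5, st, ind,
                PARAMS$comp, PARAMS$met)
  expect_equal(a$flows[["ei_maintenance"]], 8)
  expect_identical(unname(a$flows[names(a$flows) != "ei_maintenance"]),
                   rep(0, length(a$flows) - 1))
  expect_identical(c(a$net_dfm, a$net_dffm), c(0, 0))
  expect_false(a$collapse)
})

test_that("surplus deposits extra mass with the hand-computed ledger", {
  # efficiencies 1, densities (39.5, 5): 1 MJ surplus at p_FFM 0.5 deposits
  # m = 1/(0.5*5 + 0.5*39.5) kg of mixed mass, half of it fat-free (p_FFM
  # is the mass split of a marginal body-weight change)
  met1 <- metabolic_params(dep_eff_fm = 1, dep_eff_ffm = 1)
  st <- body_state(fm = 15, ffm = 60, h = 1.75, age = yr(30))  # saturated FFM
  ind <- mk_ind(15, 60)
  a <- allocate(9, mk_budget(8), classify_stores(st, ind), 0.5, st, ind,
                PARAMS$comp, met1)
  m <- 1 / (0.5 * 5 + 0.5 * 39.5)
  expect_equal(a$net_dffm, 0.5 * m, tolerance = 1e-12)
  expect_equal(a$net_dfm, 0.5 * m, tolerance = 1e-12)
  # deposited energy splits 5:39.5 across the compartments and conserves
  expect_equal(a$net_dffm * 5 + a$net_dfm * 39.5, 1, tolerance = 1e-12)
  expect_equal(a$flows[["ei_extra_deposit"]], 1)
})

test_that("starvation drains extra stores before touching essential ones", {
  # 3-day toy run: extra fat funds maintenance fully while it lasts
  ind <- mk_ind(13, 55)
  st <- body_state(fm = 15, ffm = 55, h = 1.7, age = yr(30))  # 2 kg extra fat
  for (d in 1:3) {
    stores <- classify_stores(st, ind)
    a <- allocate(0, mk_budget(8), stores, 0.5, st, ind, PARAMS$comp, PARAMS$met)
    expect_equal(a$flows[["essential_maintenance_fm"]], 0)
    expect_equal(a$flows[["essential_maintenance_ffm"]], 0)
    expect_equal(a$flows[["extra_maintenance_fm"]] +
                   a$flows[["extra_maintenance_ffm"]], 8)
    st <- body_state(st$fm + a$net_dfm, st$ffm + a$net_dffm, st$h, st$age + 1)
  }
  # essential untouched while extra remained
  expect_gt(st$fm, 13)
  expect_identical(st$ffm, 55)
})

test_that("priority order and conservation hold over random states", {
  set.seed(99)
  worst <- 0
  for (k in 1:2000) {
    fm_star <- runif(1, 5, 25); ffm_star <- runif(1, 25, 65)
    ind <- mk_ind(fm_star, ffm_star)
    st <- body_state(fm = fm_star * runif(1, 0.5, 1.8),
                     ffm = ffm_star * runif(1, 0.7, 1.4),
                     h = runif(1, 1, 2), age = yr(runif(1, 2, 80)))
    stores <- classify_stores(st, ind)
    bud <- mk_budget(maint = runif(1, 2, 12), growth_fm = runif(1, 0, 0.5),
                     growth_ffm = runif(1, 0, 1), at = runif(1, -0.5, 0.5))
    ei <- runif(1, 0, 20)
    a <- allocate(ei, bud, stores, runif(1, 0.2, 0.8), st, ind,
                  PARAMS$comp, PARAMS$met)
    expect_true(all(a$flows >= 0))
    worst <- max(worst, abs(a$energy_residual))
    ess_out <- a$flows[["essential_maintenance_fm"]] +
      a$flows[["essential_maintenance_ffm"]]
    # essential stores flow only once the extra-store energy is exhausted
    if (ess_out > 0) {
      extra_energy <- stores$extra_fm * PARAMS$comp$rho_fm +
        stores$extra_ffm * ffm_energy_density(st$ffm, PARAMS$comp)
      extra_drained <- a$flows[["extra_maintenance_fm"]] +
        a$flows[["extra_maintenance_ffm"]] + a$flows[["extra_growth_fm"]] +
        a$flows[["extra_growth_ffm"]]
      expect_lt(extra_energy - extra_drained, 1e-6)
    }
    # extra deposition only once maintenance and growth are fully served
    if (a$flows[["ei_extra_deposit"]] > 1e-9) {
      expect_equal(a$maintenance_unserved, 0)
      expect_equal(a$growth_funded_fraction, 1)
    }
    # no flow drives masses negative within the step
    expect_gte(st$fm + a$net_dfm, 0)
    expect_gte(st$ffm + a$net_dffm, 0)
  }
  expect_lt(worst, 1e-9)
})

test_that("composition correction relaxes fat mass toward the indicated FMI", {
  st <- body_state(fm = 18, ffm = 52, h = 1.7, age = yr(30))
  expect_identical(composition_correction(st, 18, tau = 60)$dfm, 0)
  c2 <- composition_correction(st, 16, tau = 100)
  expect_equal(c2$dfm, -0.02)
  expect_equal(c2$dffm, 0.02)
  expect_error(composition_correction(st, 16, tau = 0), "positive")
})

test_that("a composition perturbation at fixed weight decays back to indicated", {
  # +3 kg FM / -3 kg FFM at constant BW, fed maintenance: fat fraction
  # returns to the indicated FMI within 1%
  st0 <- adult_state(80)
  pert <- body_state(st0$fm + 3, st0$ffm - 3, st0$h, st0$age)
  r <- simulate_scenario(subj_m, crv_m, scenario(st0$age, st0$age + 365, init = pert),
                         PARAMS)
  fs <- attr(r, "final_state")
  a <- biological_age(fs$age, subj_m)
  target_fm <- indicated_fmi((fs$fm + fs$ffm) / fs$h^2, crv_m$bmi_ref(a),
                             crv_m$fmi_ref(a), subj_m, a, PARAMS$comp) * fs$h^2
  expect_equal(fs$fm / target_fm, 1, tolerance = 0.01)
  expect_equal(fs$fm + fs$ffm, 80, tolerance = 1)   # weight stays put
})
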