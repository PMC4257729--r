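# Indicated BMI/FMI, the marginal partition, and body-energy accounting.

test_that("indicated BMI is the stated blend of current and reference", {
  for (lam in c(0, 0.3, 0.5, 1)) {
    cp <- composition_params(lambda_bmi = lam)
    expect_equal(indicated_bmi(22, 22, subj_m, cp), 22)       # fixed point
  }
  expect_identical(indicated_bmi(30, 22, subj_m, composition_params(lambda_bmi = 1)), 30)
  expect_equal(indicated_bmi(30, 22, subj_m, composition_params(lambda_bmi = 0.5)), 26)
  # between the two inputs for a neutral subject
  expect_true(indicated_bmi(30, 22, subj_m, composition_params(lambda_bmi = 0.7)) < 30)
})

test_that("indicated FMI anchors at the reference and is increasing in BMI", {
  a <- yr(10)
  cp <- PARAMS$comp
  fr <- crv_m$fmi_ref(a); br <- crv_m$bmi_ref(a)
  expect_equal(indicated_fmi(br, br, fr, subj_m, a, cp), fr)   # anchor
  # gamma = 0: constant in BMI
  cp0 <- composition_params(gamma = 0)
  expect_equal(indicated_fmi(25, br, fr, subj_m, a, cp0),
               indicated_fmi(18, br, fr, subj_m, a, cp0))
  # strictly increasing in BMI; FMI*/BMI stays in (0,1) over 12-60
  bmis <- seq(12, 60, by = 0.5)
  f <- vapply(bmis, function(b) indicated_fmi(b, br, fr, subj_m, a, cp), 0)
  expect_true(all(diff(f) > 0))
  expect_true(all(f / bmis > 0 & f / bmis < 1))
  # subject fat offset and race term shift the anchor additively
  s_off <- subject("male", fmi_offset = 0.7)
  expect_equal(indicated_fmi(br, br, fr, s_off, a, cp), fr + 0.7)
  s_mx <- subject("male", race = "mexican_american")
  expect_equal(indicated_fmi(br, br, fr, s_mx, a, cp),
               fr + cp$race_terms[["mexican_american"]])
})

test_that("equilibrium adult fat fraction matches the reported magnitude", {
  st <- adult_state(80)
  expect_equal(st$fm / (st$fm + st$ffm), 0.205, tolerance = 0.05)
})

test_that("partition fraction equals the analytical derivative of the FMI family", {
  # worked case: FMI* = 5 at BMI 22 with gamma 2 -> p_FFM = 1 - 2*5/22
  a <- yr(30)
  cp <- composition_params(gamma = 2, age_slope = 0)
  # choose fmi_ref so that FMI*(22) = 5 at bmi_ref 22
  expect_equal(partition_fraction(22, 22, 5, subj_m, a, cp), 1 - 2 * 5 / 22)
  # central finite difference of FFM*(BW) at fixed height, step 1e-4 kg
  h <- 1.7
  set.seed(11)
  for (k in 1:40) {
    gam <- runif(1, 0.8, 2)
    cpk <- composition_params(gamma = gam, age_slope = runif(1, 0, 0.01))
    br <- runif(1, 16, 24); fr <- runif(1, 2.5, 5)
    bmi <- runif(1, 0.85, 1.3) * br
    age <- runif(1, yr(5), yr(50))
    p <- partition_fraction(bmi, br, fr, subj_m, age, cpk)
    eps_bw <- 1e-4
    ffm_star <- function(bw) {
      b <- bw / h^2
      bw - indicated_fmi(b, br, fr, subj_m, age, cpk) * h^2
    }
    bw0 <- bmi * h^2
    fd <- (ffm_star(bw0 + eps_bw) - ffm_star(bw0 - eps_bw)) / (2 * eps_bw)
    expect_equal(p, fd, tolerance = 1e-6)
  }
})

test_that("partition fraction declines with BMI for gamma > 1 and clips at extremes", {
  a <- yr(30)
  cp <- composition_params(gamma = 2, age_slope = 0)
  p <- vapply(seq(15, 45, by = 1), function(b)
    partition_fraction(b, 23, 4.3, subj_m, a, cp), 0)
  expect_true(all(diff(p) < 0))
  # degenerate elasticity: all marginal mass is fat-free, up to the clip
  expect_warning(
    p0 <- partition_fraction(22, 22, 5, subj_m, a, composition_params(gamma = 0)),
    "clipped")
  expect_identical(p0, 0.99)
  expect_warning(p_hi <- partition_fraction(80, 23, 4.3, subj_m, a, cp), "clipped")
  expect_gte(p_hi, 0.01)
})

test_that("indicated-state split conserves mass and scales with height squared", {
  a <- yr(30)
  ind <- split_indicated(22, 1.0, 23, 5 / (22 / 23)^2, subj_m, a,
                         composition_params(age_slope = 0))
  expect_equal(ind$bw_star, 22)
  expect_equal(ind$fm_star, 5)
  expect_equal(ind$ffm_star, 17)
  set.seed(3)
  for (k in 1:1000) {
    h <- runif(1, 0.5, 2); age <- runif(1, yr(2), yr(80))
    br <- runif(1, 15, 25); fr <- runif(1, 2.5, 5.5)
    b <- runif(1, 0.8, 1.5) * br
    ind <- split_indicated(b, h, br, fr, subj_m, age, PARAMS$comp)
    expect_lt(abs(ind$fm_star + ind$ffm_star - ind$bw_star), 1e-12)
  }
  i1 <- split_indicated(22, 0.8, 23, 4.3, subj_m, a, PARAMS$comp)
  i2 <- split_indicated(22, 1.6, 23, 4.3, subj_m, a, PARAMS$comp)
  expect_equal(i2$bw_star / i1$bw_star, 4)
  expect_equal(i2$fm_star / i1$fm_star, 4)
  expect_equal(i2$ffm_star / i1$ffm_star, 4)
})

test_that("FFM energy density ramps to the 5 MJ/kg adult saturation", {
  cp <- PARAMS$comp
  expect_identical(ffm_energy_density(60, cp), 5)
  # continuity at the junction from both branches
  s <- cp$rho_ffm_sat
  expect_equal(ffm_energy_density(s - 1e-9, cp), ffm_energy_density(s + 1e-9, cp),
               tolerance = 1e-7)
  expect_equal(ffm_energy_density(s, cp), 5)
  d <- ffm_energy_density(seq(0, 80, by = 0.1), cp)
  expect_true(all(diff(d) >= 0))
})

test_that("body energy is additive, zero at zero mass, and increasing", {
  cp <- PARAMS$comp
  expect_identical(body_energy(0, 0, cp), 0)
  # saturated regime closed form: quadratic ramp up to sat + flat beyond
  ramp <- cp$rho_ffm_intercept * cp$rho_ffm_sat +
    cp$rho_ffm_slope * cp$rho_ffm_sat^2 / 2
  expect_equal(body_energy(10, 60, cp),
               10 * cp$rho_fm + ramp + 5 * (60 - cp$rho_ffm_sat))
  # matches numerical integration of the marginal density
  num <- integrate(function(x) ffm_energy_density(x, cp), 0, 33,
                   rel.tol = 1e-10)$value
  expect_equal(body_energy(0, 33, cp), num, tolerance = 1e-8)
  g <- seq(0, 80, by = 2)
  expect_true(all(diff(vapply(g, function(f) body_energy(f, 30, cp), 0)) > 0))
  expect_true(all(diff(vapply(g, function(f) body_energy(10, f, cp), 0)) > 0))
})

test_that("Forbes partition has its classical fixed points and monotonicity", {
  expect_equal(forbes_partition(60, 10.4), 0.5)
  expect_gt(forbes_partition(60, 0.01), 0.999)  # p_FFM -> 1 as fm -> 0
  p <- vapply(seq(2, 40, by = 1), function(f) forbes_partition(80, f), 0)
  expect_true(all(diff(p) < 0))
  expect_error(forbes_partition(60, 60), "fm < bw")
})
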