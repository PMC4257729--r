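# Reference-curve construction, loading, and queries.

test_that("LMS tables are interpolated through their knots and P50 equals M", {
  p_m <- write_lms_fixture(median_col = "M")
  p_p50 <- write_lms_fixture(median_col = "P50")
  crv1 <- load_lms_table(c(height = p_m), sex = "male")
  crv2 <- load_lms_table(c(height = p_p50), sex = "male")
  knots <- utils::read.csv(p_m)
  expect_equal(crv1$height_ref(knots$age_days), knots$M, tolerance = 0)
  expect_equal(crv1$height_ref(365), 0.75)
  # identical curves whichever median column is used
  ages <- seq(0, 7305, by = 50)
  expect_identical(crv1$height_ref(ages), crv2$height_ref(ages))
})

test_that("shape-preserving interpolation does not overshoot between knots", {
  p <- write_lms_fixture()
  crv <- load_lms_table(c(height = p), sex = "male")
  knots <- utils::read.csv(p)
  for (i in seq_len(nrow(knots) - 1)) {
    mid <- (knots$age_days[i] + knots$age_days[i + 1]) / 2
    v <- crv$height_ref(mid)
    expect_gte(v, min(knots$M[i], knots$M[i + 1]))
    expect_lte(v, max(knots$M[i], knots$M[i + 1]))
    # close to the dense linear-interpolation oracle, within knot curvature
    lin <- approx(knots$age_days, knots$M, xout = mid)$y
    expect_lt(abs(v - lin), 0.5 * abs(knots$M[i + 1] - knots$M[i]))
  }
})

test_that("malformed LMS tables raise informative format errors", {
  bad1 <- file.path(tempdir(), "bad1.csv")
  utils::write.csv(data.frame(age = 1:3, M = 1:3), bad1, row.names = FALSE)
  expect_error(load_lms_table(c(height = bad1), sex = "male"), "age_days")
  bad2 <- file.path(tempdir(), "bad2.csv")
  utils::write.csv(data.frame(age_days = c(0, 100, 50), M = 1:3), bad2,
                   row.names = FALSE)
  expect_error(load_lms_table(c(height = bad2), sex = "male"), "row 3")
  bad3 <- file.path(tempdir(), "bad3.csv")
  utils::write.csv(data.frame(age_days = 0, M = 1), bad3, row.names = FALSE)
  expect_error(load_lms_table(c(height = bad3), sex = "male"), "empty")
})

test_that("loaded curves round-trip through export bit-identically", {
  p <- write_lms_fixture()
  crv <- load_lms_table(c(height = p), sex = "male")
  knots <- utils::read.csv(p)
  out <- export_curves(crv, tempfile("curves"), ages = knots$age_days)
  re <- utils::read.csv(out[grepl("height", out)])
  expect_identical(re$P50, knots$M)
})

test_that("synthetic height curve is monotone with one adolescent velocity peak", {
  for (sex in c("male", "female")) {
    crv <- synthetic_reference(sex)
    ages <- seq(0, yr(30), by = 5)
    h <- crv$height_ref(ages)
    expect_true(all(diff(h) >= -1e-12))
    # zero velocity at and beyond the adult stop age
    expect_identical(crv$height_vel(seq(crv$adult_stop_days, yr(40), by = 100)),
                     rep(0, length(seq(crv$adult_stop_days, yr(40), by = 100))))
    # boundary values
    p <- synthetic_reference_params(sex)
    expect_equal(crv$height_ref(0), p$birth_height, tolerance = 1e-10)
    expect_equal(crv$height_ref(crv$adult_stop_days), p$adult_height,
                 tolerance = 1e-10)
    # exactly one interior local maximum of the velocity (dense grid scan
    # over the region of appreciable growth), located in adolescence
    g <- seq(yr(2), crv$adult_stop_days - 1, by = 10)
    v <- crv$height_vel(g)
    keep <- v > 0.05 * max(v)
    peaks <- which(diff(sign(diff(v[keep]))) == -2) + 1
    expect_length(peaks, 1)
    peak_age <- dy(g[keep][peaks])
    expect_gt(peak_age, 9); expect_lt(peak_age, 16)
  }
})

test_that("synthetic BMI curve has a unique mid-childhood minimum", {
  g <- seq(yr(2), yr(19.9), by = 5)
  for (crv in list(crv_m, crv_f)) {
    b <- crv$bmi_ref(g)
    i <- which.min(b)
    expect_gt(dy(g[i]), 3); expect_lt(dy(g[i]), 8)
    # convex-then-rising: decreasing before the minimum, increasing after
    expect_true(all(diff(b[1:i]) <= 1e-9))
    expect_true(all(diff(b[i:length(b)]) >= -1e-9))
  }
})

test_that("curve-set invariants hold over random generator parameters", {
  set.seed(42)
  for (k in 1:100) {
    sex <- sample(c("male", "female"), 1)
    p <- list(adult_height = runif(1, 1.5, 1.95),
              birth_height = runif(1, 0.45, 0.55),
              spurt_age = runif(1, 10, 15),
              childhood_bmi_min = runif(1, 14, 16.5),
              adult_bmi = runif(1, 20, 26),
              adult_fmi = runif(1, 3.5, 7),
              adult_pa = runif(1, 2, 3.5))
    crv <- synthetic_reference(sex, params = p)
    ages <- seq(0, yr(100), length.out = 120)
    expect_true(all(diff(crv$height_ref(ages)) >= -1e-12))
    expect_true(all(crv$bmi_ref(ages) > 0))
    expect_true(all(crv$fmi_ref(ages) > 0))
    expect_true(all(crv$pa_ref(ages) >= 0))
    expect_true(all(crv$cellularity(ages) > 0 & crv$cellularity(ages) <= 1))
    frac_sum <- Reduce(`+`, lapply(crv$organ_frac, function(f) f(ages)))
    expect_true(all(frac_sum < 1))
  }
  expect_error(synthetic_reference("male", params = list(adult_height = 0.4)),
               "adult height")
})

test_that("evaluation outside the tabulated span raises", {
  expect_error(crv_m$height_ref(yr(111)), "span")
  expect_error(crv_m$bmi_ref(-5), "span")
  expect_error(indicated_height(crv_m, subj_m, yr(120)), "span")
  expect_error(reference_pa(crv_m, subj_m, -1), "span")
})

test_that("indicated height applies factor and race offset additively", {
  a <- yr(10)
  base <- crv_m$height_ref(a)
  expect_identical(indicated_height(crv_m, subj_m, a), base) # neutral, nh_white offset 0
  s2 <- subject("male", height_factor = 1.05)
  expect_equal(indicated_height(crv_m, s2, a), 1.05 * base)
  crv_b <- synthetic_reference("male", race = "nh_black")
  expect_equal(indicated_height(crv_b, subject("male", race = "nh_black"), a),
               base + 0.005)
})

test_that("biological age is a strictly increasing multiple of calendar age", {
  expect_identical(biological_age(1000, subj_m), 1000)
  slow <- subject("male", bioage_multiplier = 0.9)
  expect_equal(biological_age(1000, slow), 900)
  set.seed(7)
  a <- sort(runif(50, 0, yr(80)))
  expect_true(all(diff(biological_age(a, slow)) > 0))
  expect_error(subject("male", bioage_multiplier = 0), "positive")
})

test_that("reference physical activity scales with the subject factor", {
  a <- yr(12)
  expect_identical(reference_pa(crv_m, subject("male", pa_factor = 0), a), 0)
  expect_identical(reference_pa(crv_m, subj_m, a), crv_m$pa_ref(a))
  expect_equal(reference_pa(crv_m, subject("male", pa_factor = 1.3), a),
               1.3 * crv_m$pa_ref(a))
})
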