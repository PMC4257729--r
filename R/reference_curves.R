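# Reference growth curves: the exogenous age-indexed inputs that canalize growth.
# All curves are functions of biological age in days; years are accepted at the
# interface via yr()/dy(). Evaluation outside the tabulated span is an error,
# never an extrapolation.

DAYS_PER_YEAR <- 365.25

#' Convert years to days
#'
#' Ages are handled in days internally (the integration step is one day);
#' `yr()` converts a year-valued age to days at the interface.
#'
#' @param years age in years
#' @return age in days
#' @export
yr <- function(years) years * DAYS_PER_YEAR

#' Convert days to years
#' @param days age in days
#' @return age in years
#' @export
dy <- function(days) days / DAYS_PER_YEAR

RACES <- c("mexican_american", "nh_white", "nh_black", "other")
SEXES <- c("male", "female")

## ---- interpolation -------------------------------------------------------

# Shape-preserving piecewise-cubic interpolant (Fritsch-Carlson monotone
# Hermite). Reproduces knot values exactly and cannot overshoot between
# knots, which keeps finite-difference velocities clean.
shape_spline <- function(age_days, values) {
  stopifnot(length(age_days) == length(values), length(age_days) >= 2)
  if (any(diff(age_days) <= 0)) stop("knot ages must be strictly increasing")
  f <- stats::splinefun(age_days, values, method = "monoH.FC")
  lo <- age_days[1L]; hi <- age_days[length(age_days)]
  function(a, deriv = 0L) {
    if (any(a < lo - 1e-9 | a > hi + 1e-9))
      stop(sprintf("age %.1f d outside tabulated span [%.1f, %.1f] d",
                   a[which(a < lo - 1e-9 | a > hi + 1e-9)][1L], lo, hi))
    f(pmin(pmax(a, lo), hi), deriv = deriv)
  }
}

## ---- subject -------------------------------------------------------------

#' Create a simulated subject
#'
#' A subject carries the discrete descriptors (sex, race) and the individual
#' variation factors that shift the population reference curves: a multiplier
#' on potential height, a predisposition multiplier on reference BMI, an
#' additive fat-mass-index offset (fat beyond the BMI/race expectation), a
#' physical-activity multiplier, and a biological-age multiplier (slow- or
#' fast-developing children). Defaults are exactly neutral.
#'
#' @param sex `"male"` or `"female"`
#' @param race one of `"mexican_american"`, `"nh_white"`, `"nh_black"`, `"other"`
#' @param height_factor dimensionless multiplier on reference height (> 0)
#' @param bmi_factor dimensionless multiplier on reference BMI (> 0)
#' @param fmi_offset additive offset on the reference fat mass index, kg/m^2
#' @param pa_factor dimensionless multiplier on reference physical activity (>= 0)
#' @param bioage_multiplier biological age = multiplier * calendar age (> 0)
#' @return an object of class `gs_subject`
#' @examples
#' subject("male")                      # reference individual
#' subject("female", height_factor = 1.05)
#' @export
subject <- function(sex = c("male", "female"),
                    race = c("nh_white", "mexican_american", "nh_black", "other"),
                    height_factor = 1, bmi_factor = 1, fmi_offset = 0,
                    pa_factor = 1, bioage_multiplier = 1) {
  sex <- match.arg(sex)
  race <- match.arg(race)
  num <- c(height_factor, bmi_factor, fmi_offset, pa_factor, bioage_multiplier)
  if (!all(is.finite(num))) stop("subject factors must be finite")
  if (height_factor <= 0 || bmi_factor <= 0 || pa_factor < 0)
    stop("height_factor and bmi_factor must be positive, pa_factor non-negative")
  if (bioage_multiplier <= 0) stop("bioage_multiplier must be positive")
  structure(list(sex = sex, race = race, height_factor = height_factor,
                 bmi_factor = bmi_factor, fmi_offset = fmi_offset,
                 pa_factor = pa_factor, bioage_multiplier = bioage_multiplier),
            class = "gs_subject")
}

#' Biological age of a subject
#'
#' Biological age (which drives every reference-curve lookup) is a constant
#' multiple of calendar age, so slow (fast) developers are simulated with a
#' multiplier below (above) one.
#'
#' @param calendar_age age in days, >= 0
#' @param subject a [subject()]
#' @return biological age in days
#' @export
biological_age <- function(calendar_age, subject) {
  if (any(calendar_age < 0)) stop("calendar_age must be non-negative")
  subject$bioage_multiplier * calendar_age
}

## ---- synthetic reference curves ------------------------------------------

# Knot templates emulating CDC-chart-shaped curves (ages in years).  BMI has
# the infancy peak, the adiposity-rebound minimum in mid childhood, and the
# rise to the adult value; FMI is sex specific; PA follows childhood
# activity-budget estimates with a late-adult decline.
.bmi_template_ages <- c(0, 0.5, 1, 2, 3, 4, 5, 6, 7, 8, 10, 12, 14, 16, 18, 20)
.bmi_template     <- c(13.3, 17.0, 17.2, 16.5, 16.0, 15.7, 15.45, 15.4, 15.5,
                       15.8, 16.6, 17.8, 19.2, 20.7, 22.0, 23.0)
.fmi_knots <- list(
  male   = list(age = c(0, 0.5, 1, 2, 4, 6, 8, 10, 12, 14, 16, 18, 20),
                fmi = c(1.7, 4.0, 3.8, 3.3, 2.7, 2.4, 2.4, 2.7, 3.0, 3.0, 3.3, 3.8, 4.3)),
  female = list(age = c(0, 0.5, 1, 2, 4, 6, 8, 10, 12, 14, 16, 18, 20),
                fmi = c(1.8, 4.1, 3.9, 3.5, 3.0, 2.9, 3.1, 3.6, 4.2, 4.8, 5.4, 5.8, 6.2)))
.pa_knots <- list(age = c(0, 1, 3, 5, 8, 12, 16, 20, 40, 60, 80, 110),
                  pa  = c(0.15, 0.5, 0.9, 1.2, 1.6, 2.2, 2.6, 2.8, 2.8, 2.5, 1.9, 1.5))

# Organ composition defaults: mass fraction of indicated body weight by age and
# tissue-specific metabolic rates (MJ/kg/day).  Residual fat-free mass and fat
# mass are handled separately in the BMR assembly.
.organ_fraction_knots <- list(
  age     = c(0, 1, 2, 5, 10, 15, 20, 110),
  brain   = c(0.106, 0.095, 0.084, 0.068, 0.042, 0.025, 0.0185, 0.0185),
  liver   = c(0.034, 0.031, 0.029, 0.030, 0.026, 0.025, 0.0247, 0.0247),
  heart   = c(0.0057, 0.0050, 0.0048, 0.0052, 0.0056, 0.0047, 0.0045, 0.0045),
  kidneys = c(0.0071, 0.0073, 0.0072, 0.0062, 0.0059, 0.0045, 0.0042, 0.0042))
.organ_sigma <- c(brain = 1.004, liver = 0.837, heart = 1.841, kidneys = 1.841)
.cellularity_knots <- list(age = c(0, 5, 20, 30, 60, 80, 100, 110),
                           cell = c(0.85, 0.95, 1.00, 1.00, 0.94, 0.88, 0.82, 0.79))

# Additive height offsets by race (m) and span defaults.  Magnitudes are
# synthetic placeholders (config-overridable); the reference race is
# non-Hispanic white.
.height_race_offsets <- c(mexican_american = -0.02, nh_white = 0,
                          nh_black = 0.005, other = 0)

#' Default parameters of the synthetic reference-curve generator
#'
#' @param sex `"male"` or `"female"`
#' @return named list of curve-shape parameters (heights in m, ages in years,
#'   BMI/FMI in kg/m^2, PA in MJ/day)
#' @export
synthetic_reference_params <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (sex == "male") {
    list(birth_height = 0.50, adult_height = 1.78, spurt_age = 13.5,
         spurt_width = 1.0, spurt_intensity = 0.040, infancy_velocity = 0.32,
         infancy_tau = 0.75, childhood_velocity = 0.055, velocity_stop_age = 16,
         velocity_stop_width = 0.7, adult_stop_age = 20,
         childhood_bmi_min = 15.4, adult_bmi = 23.0, adult_fmi = 4.3,
         adult_pa = 2.8, pa_scale = 1, max_age = 110)
  } else {
    list(birth_height = 0.49, adult_height = 1.64, spurt_age = 11.5,
         spurt_width = 1.0, spurt_intensity = 0.040, infancy_velocity = 0.32,
         infancy_tau = 0.75, childhood_velocity = 0.055, velocity_stop_age = 14.5,
         velocity_stop_width = 0.7, adult_stop_age = 20,
         childhood_bmi_min = 15.2, adult_bmi = 21.7, adult_fmi = 6.2,
         adult_pa = 2.4, pa_scale = 1, max_age = 110)
  }
}

#' Generate a synthetic reference curve set
#'
#' Builds smooth parametric stand-ins for growth-chart reference inputs: a
#' monotone height-for-age curve with an infancy deceleration, a single
#' adolescent velocity peak and zero velocity after the adult stop age; a
#' BMI-for-age curve with an infancy peak, a mid-childhood minimum and a rise
#' to the adult value; sex-specific FMI-for-age; and a physical-activity
#' reference. All tests and analyses can therefore run without any downloaded
#' growth-chart tables.
#'
#' @param sex `"male"` or `"female"`
#' @param race race label stored on the curve set (selects the additive
#'   height offset applied by [indicated_height()])
#' @param params curve-shape parameters, see [synthetic_reference_params()];
#'   entries supplied here override the defaults
#' @return an object of class `gs_curves`: list of evaluator functions
#'   (`height_ref`, `height_vel`, `bmi_ref`, `fmi_ref`, `pa_ref`, `bw_ref`,
#'   `cellularity`, per-organ `organ_frac`), the organ table, the supported
#'   age span in days, and the adult growth-stop age
#' @examples
#' crv <- synthetic_reference("male")
#' crv$height_ref(yr(10))   # reference height at age 10 y
#' @export
synthetic_reference <- function(sex = c("male", "female"), race = "nh_white",
                                params = list()) {
  sex <- match.arg(sex)
  race <- match.arg(race, RACES)
  p <- utils::modifyList(synthetic_reference_params(sex), params)
  if (p$adult_height <= p$birth_height)
    stop("adult height must exceed birth height")

  ## height: integrate a positive parametric velocity on a fine grid, then
  ## rescale so the adult height is hit exactly; zero velocity afterwards.
  stop_d <- yr(p$adult_stop_age)
  grid_y <- seq(0, p$adult_stop_age, by = 1 / 24)   # half-month grid
  vel <- p$infancy_velocity * exp(-grid_y / p$infancy_tau) +
    p$childhood_velocity / (1 + exp((grid_y - p$velocity_stop_age) / p$velocity_stop_width)) +
    p$spurt_intensity * exp(-((grid_y - p$spurt_age)^2) / (2 * p$spurt_width^2))
  h <- cumsum(c(0, (vel[-1] + vel[-length(vel)]) / 2 * diff(grid_y)))
  h <- p$birth_height + h * (p$adult_height - p$birth_height) / h[length(h)]
  knots_d <- yr(grid_y)
  max_d <- yr(p$max_age)
  h_fun <- shape_spline(c(knots_d, max_d), c(h, p$adult_height))
  # the Hermite segment joining the last growth knot to the flat adult span
  # can bump microscopically above the adult height; the curve is monotone
  # up to that value, so capping there flattens adulthood exactly
  height_ref <- function(a) pmin(h_fun(a), p$adult_height)
  height_vel <- function(a) ifelse(a >= stop_d, 0, pmax(0, h_fun(a, deriv = 1L)))

  ## BMI: affine rescaling of the template to the requested minimum/adult
  ## values; constant at the adult value through adulthood.
  tmin <- min(.bmi_template); tadult <- .bmi_template[length(.bmi_template)]
  bmi_v <- p$childhood_bmi_min +
    (.bmi_template - tmin) * (p$adult_bmi - p$childhood_bmi_min) / (tadult - tmin)
  bmi_fun <- shape_spline(yr(c(.bmi_template_ages, p$max_age)),
                          c(bmi_v, bmi_v[length(bmi_v)]))

  ## FMI: sex-specific template scaled to the requested adult level; any
  ## post-childhood aging drift is a composition parameter, not a curve.
  fk <- .fmi_knots[[sex]]
  fmi_v <- fk$fmi * p$adult_fmi / fk$fmi[length(fk$fmi)]
  fmi_fun <- shape_spline(yr(c(fk$age, p$max_age)),
                          c(fmi_v, fmi_v[length(fmi_v)]))

  pa_v <- .pa_knots$pa * p$adult_pa / 2.8 * p$pa_scale
  pa_fun <- shape_spline(yr(.pa_knots$age), pa_v)

  organ_frac <- lapply(names(.organ_sigma), function(org)
    shape_spline(yr(.organ_fraction_knots$age), .organ_fraction_knots[[org]]))
  names(organ_frac) <- names(.organ_sigma)
  # relative cellularity is capped at 1 (the Hermite interpolant can bump
  # marginally above the plateau between the rising limb and the flat knots)
  cell_fun_raw <- shape_spline(yr(.cellularity_knots$age), .cellularity_knots$cell)
  cell_fun <- function(a) pmin(1, cell_fun_raw(a))

  crv <- structure(list(
    sex = sex, race = race,
    height_ref = height_ref, height_vel = height_vel,
    bmi_ref = function(a) bmi_fun(a),
    fmi_ref = function(a) fmi_fun(a),
    pa_ref = function(a) pa_fun(a),
    cellularity = function(a) cell_fun(a),
    organ_frac = organ_frac, organ_sigma = .organ_sigma,
    height_race_offset = unname(.height_race_offsets[race]),
    adult_stop_days = stop_d,
    span = c(0, max_d),
    params = p), class = "gs_curves")
  crv$bw_ref <- function(a) crv$bmi_ref(a) * crv$height_ref(a)^2
  crv
}

#' @export
print.gs_curves <- function(x, ...) {
  cat(sprintf("<gs_curves> sex=%s race=%s span=[0, %.0f] d (adult stop %.0f d)\n",
              x$sex, x$race, x$span[2], x$adult_stop_days))
  invisible(x)
}

## ---- LMS table loading ----------------------------------------------------

read_lms_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"age_days" %in% names(tab))
    stop(sprintf("LMS table %s: missing required column 'age_days'", path))
  med_col <- if ("M" %in% names(tab)) "M" else if ("P50" %in% names(tab)) "P50" else
    stop(sprintf("LMS table %s: need a median column 'M' or 'P50'", path))
  if (nrow(tab) < 2) stop(sprintf("LMS table %s: empty or single-row table", path))
  bad <- which(diff(tab$age_days) <= 0)
  if (length(bad))
    stop(sprintf("LMS table %s: ages not strictly increasing at row %d", path, bad[1] + 1L))
  if (any(!is.finite(tab[[med_col]])))
    stop(sprintf("LMS table %s: non-finite median at row %d", path,
                 which(!is.finite(tab[[med_col]]))[1L]))
  list(age = tab$age_days, median = tab[[med_col]])
}

#' Load growth-chart style LMS tables into a reference curve set
#'
#' Reads one CSV per measure in the LMS dialect (`age_days,L,M,S` or
#' `age_days,P50`; the 50th percentile of an LMS family is the M column) and
#' interpolates the median with the same shape-preserving piecewise-cubic
#' scheme used for synthetic curves, so knot values are reproduced exactly.
#' Measures not supplied fall back to the synthetic generator, so a curve set
#' is always complete.
#'
#' @param paths named character vector of file paths; recognised names are
#'   `height` (median in m) and `bmi`, `fmi` (kg/m^2), `pa` (MJ/day)
#' @param sex,race as in [synthetic_reference()]
#' @param params synthetic-generator overrides for the measures not loaded
#' @return a `gs_curves` object
#' @export
load_lms_table <- function(paths, sex = c("male", "female"), race = "nh_white",
                           params = list()) {
  sex <- match.arg(sex)
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    stop("'paths' must be a named vector, e.g. c(height = \"...\")")
  unknown <- setdiff(names(paths), c("height", "bmi", "fmi", "pa"))
  if (length(unknown)) stop("unknown LMS measures: ", paste(unknown, collapse = ", "))
  crv <- synthetic_reference(sex, race, params)
  knots <- list()
  for (measure in names(paths)) {
    lms <- read_lms_csv(paths[[measure]])
    knots[[measure]] <- lms
    fun <- local({ f <- shape_spline(lms$age, lms$median); function(a, deriv = 0L) f(a, deriv) })
    if (measure == "height") {
      stop_d <- crv$adult_stop_days
      crv$height_ref <- fun
      crv$height_vel <- local({
        f <- fun
        function(a) ifelse(a >= stop_d, 0, pmax(0, f(a, deriv = 1L)))
      })
    } else {
      crv[[paste0(measure, "_ref")]] <- fun
    }
    crv$span <- c(max(crv$span[1], lms$age[1]),
                  min(crv$span[2], lms$age[length(lms$age)]))
  }
  crv$bw_ref <- function(a) crv$bmi_ref(a) * crv$height_ref(a)^2
  crv$lms_knots <- knots
  crv
}

## ---- curve queries --------------------------------------------------------

check_span <- function(curves, age) {
  if (any(age < curves$span[1] - 1e-9 | age > curves$span[2] + 1e-9))
    stop(sprintf("age %.1f d outside curve span [%.1f, %.1f] d",
                 age[1], curves$span[1], curves$span[2]))
  invisible(age)
}

#' Indicated (potential) height for a subject
#'
#' The canalization target for height: the population reference height at the
#' subject's biological age, shifted additively by race and scaled by the
#' subject's individual potential-height factor.
#'
#' @param curves a `gs_curves` object
#' @param subject a [subject()]
#' @param bio_age biological age in days
#' @return indicated height H* in m
#' @export
indicated_height <- function(curves, subject, bio_age) {
  check_span(curves, bio_age)
  subject$height_factor * (curves$height_ref(bio_age) + curves$height_race_offset)
}

#' Reference physical-activity energy for a subject
#'
#' The age-indexed reference activity budget scaled by the subject's activity
#' factor; the bed-rest limit is `pa_factor = 0`.
#'
#' @inheritParams indicated_height
#' @return physical activity energy, MJ/day
#' @export
reference_pa <- function(curves, subject, bio_age) {
  check_span(curves, bio_age)
  subject$pa_factor * curves$pa_ref(bio_age)
}

#' Export the knots of a curve set to CSV tables
#'
#' Writes one LMS-dialect CSV (`age_days,P50`) per measure sampled at the
#' given ages, so a loaded or synthetic curve set can be round-tripped.
#'
#' @param curves a `gs_curves` object
#' @param dir output directory
#' @param ages ages (days) at which to tabulate; defaults to monthly knots
#' @return invisibly, the written file paths
#' @export
export_curves <- function(curves, dir,
                          ages = seq(curves$span[1], curves$span[2], by = 30)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character()
  for (measure in c("height", "bmi", "fmi", "pa")) {
    fn <- switch(measure, height = curves$height_ref, bmi = curves$bmi_ref,
                 fmi = curves$fmi_ref, pa = curves$pa_ref)
    path <- file.path(dir, sprintf("%s_%s_p50.csv", measure, curves$sex))
    utils::write.csv(data.frame(age_days = ages, P50 = fn(ages)), path,
                     row.names = FALSE)
    out <- c(out, path)
  }
  invisible(out)
}
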