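# Applied analyses: intake and height-factor calibration, BMI-percentile
# tracking, and the two energy-gap policy computations.

#' Calibrate a fractional intake multiplier to a target weight
#'
#' Finds, by bisection, the constant multiplier `m` on the running reference
#' intake such that simulating from `start_age` with `EI = m * reference`
#' reaches the target body weight at the target age within `tol` kg.
#'
#' @param subject a [subject()]
#' @param curves a `gs_curves`
#' @param target_weight kg
#' @param target_age days
#' @param params a [model_params()]
#' @param start_age days (default birth)
#' @param init optional initial [body_state()] at `start_age`
#' @param interval multiplier search interval
#' @param tol weight tolerance, kg
#' @return list with `multiplier`, `achieved_weight`, `result` (the final run)
#' @export
calibrate_intake_multiplier <- function(subject, curves, target_weight,
                                        target_age, params = model_params(),
                                        start_age = 0, init = NULL,
                                        interval = c(0.3, 3), tol = 0.05) {
  ref_fun <- reference_intake(subject, curves, params, start_age,
                              target_age + params$sim$dt)
  run <- function(m) {
    scn <- scenario(start_age, target_age,
                    ei = function(age, ref) m * ref, init = init)
    simulate_scenario(subject, curves, scn, params, ref_intake = ref_fun)
  }
  final_bw <- function(m) { r <- run(m); r$bw[nrow(r)] + 0 }
  f_lo <- final_bw(interval[1]) - target_weight
  f_hi <- final_bw(interval[2]) - target_weight
  if (f_lo * f_hi > 0)
    stop(sprintf("target weight %.1f kg unreachable: bracket weights [%.1f, %.1f] kg",
                 target_weight, f_lo + target_weight, f_hi + target_weight))
  lo <- interval[1]; hi <- interval[2]
  repeat {
    mid <- (lo + hi) / 2
    fm <- final_bw(mid) - target_weight
    if ((hi - lo) < 1e-3 && abs(fm) < tol) break
    if ((hi - lo) < 1e-6) break
    if (sign(fm) == sign(f_lo)) { lo <- mid; f_lo <- fm } else hi <- mid
  }
  res <- run(mid)
  list(multiplier = mid, achieved_weight = res$bw[nrow(res)], result = res)
}

#' Calibrate the individual height factor to an observed height
#'
#' Finds, by bisection, the potential-height multiplier that reproduces an
#' observed height at a stated age under reference feeding.
#'
#' @param subject a [subject()] (its `height_factor` is replaced)
#' @param curves a `gs_curves`
#' @param observed_height m
#' @param at_age days
#' @param params a [model_params()]
#' @param interval factor search interval
#' @param tol height tolerance, m (default 1 mm)
#' @return list with `height_factor`, `achieved_height`
#' @export
calibrate_height_factor <- function(subject, curves, observed_height, at_age,
                                    params = model_params(),
                                    interval = c(0.7, 1.4), tol = 1e-3) {
  if (observed_height <= 0) stop("observed_height must be positive")
  achieved <- function(f) {
    subj <- subject
    subj$height_factor <- f
    scn <- scenario(0, at_age)
    r <- simulate_scenario(subj, curves, scn, params)
    r$h[nrow(r)]
  }
  f_lo <- achieved(interval[1]) - observed_height
  f_hi <- achieved(interval[2]) - observed_height
  if (f_lo * f_hi > 0) stop("observed height outside reachable bracket")
  lo <- interval[1]; hi <- interval[2]
  repeat {
    mid <- (lo + hi) / 2
    fm <- achieved(mid) - observed_height
    if (abs(fm) < tol || (hi - lo) < 1e-6) break
    if (sign(fm) == sign(f_lo)) { lo <- mid; f_lo <- fm } else hi <- mid
  }
  list(height_factor = mid, achieved_height = fm + observed_height)
}

# Intake required over one step so that next-day BMI hits `target_bmi`
# (given the realized height change). Near the balance intake the BMI
# response to intake is almost flat (extra mass gain and height-growth
# funding offset), so the solve is anchored at the full-growth balance
# intake and searches only on the side the target requires; targets within
# `eps` BMI units of the own-trajectory outcome snap to the balance intake.
required_intake_for_bmi <- function(state, subject, curves, target_bmi,
                                    params, eps = 5e-4) {
  miss <- function(ei) {
    s2 <- step_core(state, subject, curves, params, ei = ei)$state
    (s2$fm + s2$ffm) / s2$h^2 - target_bmi
  }
  bal <- step_core(state, subject, curves, params,
                   ei_fun = function(age, ref) ref)
  floor_ei <- bal$ei
  m_floor <- (bal$state$fm + bal$state$ffm) / bal$state$h^2 - target_bmi
  if (abs(m_floor) < eps)
    return(list(ei = floor_ei, feasible = TRUE))
  if (m_floor < 0) {                      # surplus side: deposit extra mass
    hi <- 30
    if (miss(hi) < 0) return(list(ei = hi, feasible = FALSE))
    return(list(ei = stats::uniroot(miss, c(floor_ei, hi), tol = 1e-5)$root,
                feasible = TRUE))
  }
  m0 <- miss(0)                           # deficit side: drain stores
  if (m0 >= 0) return(list(ei = 0, feasible = FALSE))
  list(ei = stats::uniroot(miss, c(0, floor_ei), tol = 1e-5)$root,
       feasible = TRUE)
}

#' Intake series that tracks a BMI-for-age curve
#'
#' Per-step inversion of the energy balance: each day the intake is solved so
#' that the next day's BMI lands on the given curve. Infeasible days (the
#' curve would require negative intake) are run at zero intake and flagged --
#' this is exactly the stunting regime at low percentiles.
#'
#' @param subject a [subject()]
#' @param curves a `gs_curves`
#' @param bmi_curve function age(days) -> target BMI kg/m^2
#' @param t_start,t_end age span, days
#' @param params a [model_params()]
#' @return data.frame with per-day `age_days`, `ei`, `ref_ei`, `bmi`, `fm`,
#'   `h`, `feasible`
#' @export
percentile_tracking_intake <- function(subject, curves, bmi_curve,
                                       t_start, t_end,
                                       params = model_params()) {
  dt <- params$sim$dt
  h0 <- indicated_height(curves, subject, biological_age(t_start, subject))
  bmi0 <- bmi_curve(t_start)
  fmi0 <- indicated_fmi(bmi0, curves$bmi_ref(biological_age(t_start, subject)),
                        curves$fmi_ref(biological_age(t_start, subject)),
                        subject, biological_age(t_start, subject), params$comp)
  state <- body_state(fm = fmi0 * h0^2, ffm = (bmi0 - fmi0) * h0^2,
                      h = h0, age = t_start)
  n <- floor((t_end - t_start) / dt)
  out <- matrix(NA_real_, nrow = n, ncol = 7,
                dimnames = list(NULL, c("age_days", "ei", "ref_ei", "bmi",
                                        "fm", "h", "feasible")))
  for (i in seq_len(n)) {
    target <- bmi_curve(state$age + dt)
    sol <- required_intake_for_bmi(state, subject, curves, target, params)
    det <- step_core(state, subject, curves, params, ei = sol$ei)
    bw <- state$fm + state$ffm
    out[i, ] <- c(state$age, sol$ei, det$ref_ei, bw / state$h^2, state$fm,
                  state$h, as.numeric(sol$feasible))
    state <- det$state
  }
  res <- as.data.frame(out)
  res$feasible <- as.logical(res$feasible)
  attr(res, "final_state") <- state
  res
}

#' Energy gap of a one-year BMI reduction
#'
#' For an individual `delta_bmi` units above the reference BMI-for-age: the
#' average daily difference between (a) the intake that maintains the
#' elevated BMI status over the year and (b) the constant intake that brings
#' BMI to the reference-for-age in exactly `horizon` days. Also returned as a
#' fraction of the maintenance intake (a).
#'
#' @param subject a [subject()]
#' @param curves a `gs_curves`
#' @param delta_bmi BMI excess over reference, kg/m^2 (> 0)
#' @param age starting age, days
#' @param horizon days (default 365)
#' @param params a [model_params()]
#' @return list with `gap` (MJ/day), `fraction`, `maintain_ei`, `reduce_ei`
#' @export
weight_loss_energy_gap <- function(subject, curves, delta_bmi, age,
                                   horizon = 365, params = model_params()) {
  if (delta_bmi <= 0) stop("delta_bmi must be positive")
  bio0 <- biological_age(age, subject)
  ## (a) maintain the elevated BMI status over the horizon
  maintain_curve <- function(a)
    subject$bmi_factor * curves$bmi_ref(biological_age(a, subject)) + delta_bmi
  track <- percentile_tracking_intake(subject, curves, maintain_curve,
                                      age, age + horizon, params)
  maintain_ei <- mean(track$ei)
  ## (b) constant intake reaching the reference BMI at exactly the horizon
  h0 <- indicated_height(curves, subject, bio0)
  bmi0 <- maintain_curve(age)
  fmi0 <- indicated_fmi(bmi0, curves$bmi_ref(bio0), curves$fmi_ref(bio0),
                        subject, bio0, params$comp)
  init <- body_state(fm = fmi0 * h0^2, ffm = (bmi0 - fmi0) * h0^2,
                     h = h0, age = age)
  target_bmi <- subject$bmi_factor *
    curves$bmi_ref(biological_age(age + horizon, subject))
  final_bmi <- function(ei) {
    scn <- scenario(age, age + horizon, ei = ei, init = init)
    r <- simulate_scenario(subject, curves, scn, params)
    r$bmi[nrow(r)]
  }
  lo <- 0.2; hi <- maintain_ei
  f_lo <- final_bmi(lo) - target_bmi
  f_hi <- final_bmi(hi) - target_bmi
  if (f_lo * f_hi > 0) stop("horizon infeasible: no bracketing intake")
  repeat {
    mid <- (lo + hi) / 2
    fm <- final_bmi(mid) - target_bmi
    if (abs(fm) < 1e-3 || (hi - lo) < 1e-4) break
    if (sign(fm) == sign(f_lo)) { lo <- mid; f_lo <- fm } else hi <- mid
  }
  gap <- maintain_ei - mid
  list(gap = gap, fraction = gap / maintain_ei,
       maintain_ei = maintain_ei, reduce_ei = mid)
}

#' Maintenance energy gap relative to the reference BMI curve
#'
#' Per age, the difference between the intake that maintains the observed
#' (actual) BMI-for-age and the intake that maintains the reference
#' BMI-for-age: the energy surplus embedded in elevated population weight
#' even without further gain. The fraction uses the intake at the actual
#' (elevated) BMI as denominator.
#'
#' @param subject a [subject()]
#' @param curves a `gs_curves`
#' @param actual_bmi_curve function age(days) -> observed BMI kg/m^2
#' @param age_grid ages (days) at which to evaluate
#' @param params a [model_params()]
#' @return data.frame of class `gs_gap_report`: `age_years`, `actual_ei`,
#'   `reference_ei`, `absolute_gap` (MJ/day), `fractional_gap`; the
#'   average-over-ages summary is in attribute `summary`
#' @export
maintenance_energy_gap <- function(subject, curves, actual_bmi_curve,
                                   age_grid, params = model_params()) {
  maint_ei <- function(bmi_fun, a) {
    bio <- biological_age(a, subject)
    h <- indicated_height(curves, subject, bio)
    bmi <- bmi_fun(a)
    fmi <- indicated_fmi(bmi, curves$bmi_ref(bio), curves$fmi_ref(bio),
                         subject, bio, params$comp)
    st <- body_state(fm = fmi * h^2, ffm = (bmi - fmi) * h^2, h = h, age = a)
    equilibrium_intake(st, subject, curves, params)
  }
  ref_curve <- function(a) subject$bmi_factor *
    curves$bmi_ref(biological_age(a, subject))
  actual <- vapply(age_grid, function(a) maint_ei(actual_bmi_curve, a), 0)
  refei <- vapply(age_grid, function(a) maint_ei(ref_curve, a), 0)
  res <- data.frame(age_years = dy(age_grid), actual_ei = actual,
                    reference_ei = refei, absolute_gap = actual - refei,
                    fractional_gap = (actual - refei) / actual)
  attr(res, "summary") <- c(mean_absolute_gap = mean(actual - refei),
                            mean_fractional_gap = mean((actual - refei) / actual))
  class(res) <- c("gs_gap_report", class(res))
  res
}
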