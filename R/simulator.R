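# Daily explicit-Euler integration of the three state variables (fat mass,
# fat-free mass, height) under an intake scenario, with canalized height
# growth, stunting, and catch-up.

#' Create a body state
#'
#' @param fm fat mass, kg (> 0)
#' @param ffm fat-free mass, kg (> 0)
#' @param h height, m (> 0)
#' @param age age, days (>= 0)
#' @return an object of class `gs_state`
#' @export
body_state <- function(fm, ffm, h, age) {
  if (any(c(fm, ffm, h) <= 0) || age < 0) stop("invalid body state")
  structure(list(fm = fm, ffm = ffm, h = h, age = age), class = "gs_state")
}

#' @export
print.gs_state <- function(x, ...) {
  cat(sprintf("<gs_state> age %.1f y: BW %.2f kg (FM %.2f, FFM %.2f), H %.3f m, BMI %.1f\n",
              dy(x$age), x$fm + x$ffm, x$fm, x$ffm, x$h, (x$fm + x$ffm) / x$h^2))
  invisible(x)
}

#' Simulation parameters
#'
#' @param dt integration step, days
#' @param tau_height height gap-closing time constant, days: the catch-up
#'   velocity increment is (height deficit)/tau
#' @param catchup_cap maximum realized height velocity as a multiple of the
#'   age-specific reference velocity
#' @param stunt_threshold BMI-to-reference ratio at and above which height
#'   growth is unconstrained (the reduction engages strictly below it)
#' @param stunt_floor BMI ratio at which height velocity reaches zero
#' @param correction_tau composition-correction time constant, days
#' @param collapse_fraction survival floor on essential stores, as a fraction
#'   of the indicated masses
#' @return an object of class `gs_sim_params`
#' @export
sim_params <- function(dt = 1, tau_height = 180, catchup_cap = 4,
                       stunt_threshold = 0.85, stunt_floor = 0.60,
                       correction_tau = 60, collapse_fraction = 0.2) {
  if (dt <= 0) stop("dt must be positive")
  if (stunt_floor >= stunt_threshold) stop("stunt_floor must be below stunt_threshold")
  structure(list(dt = dt, tau_height = tau_height, catchup_cap = catchup_cap,
                 stunt_threshold = stunt_threshold, stunt_floor = stunt_floor,
                 correction_tau = correction_tau,
                 collapse_fraction = collapse_fraction),
            class = "gs_sim_params")
}

#' Bundle of all model parameters
#'
#' @param composition a [composition_params()]
#' @param metabolic a [metabolic_params()]
#' @param simulation a [sim_params()]
#' @return list with elements `comp`, `met`, `sim`
#' @export
model_params <- function(composition = composition_params(),
                         metabolic = metabolic_params(),
                         simulation = sim_params()) {
  list(comp = composition, met = metabolic, sim = simulation)
}

#' Desired height velocity under canalization
#'
#' On-trajectory growth proceeds at the reference velocity; a height deficit
#' adds a catch-up increment (deficit over the gap time constant), with total
#' velocity capped at a multiple of the age-specific reference velocity.
#' After the adult growth stop the reference velocity is zero, so the desired
#' velocity is zero and any remaining deficit is permanent stunting.
#'
#' @param h current height, m
#' @param h_star indicated height, m
#' @param v_ref age-specific reference height velocity, m/day (>= 0)
#' @param tau_height gap-closing time constant, days
#' @param catchup_cap velocity cap as a multiple of `v_ref`
#' @return desired height velocity, m/day
#' @export
desired_height_velocity <- function(h, h_star, v_ref, tau_height = 180,
                                    catchup_cap = 4) {
  if (any(v_ref < 0)) stop("v_ref must be non-negative")
  pmin(v_ref + pmax(0, h_star - h) / tau_height, catchup_cap * v_ref)
}

#' Stunting factor on height growth
#'
#' Height growth is unconstrained at or above the threshold BMI-to-reference
#' ratio (default 85% of BMI-for-age) and ramps linearly to zero at the floor
#' ratio; the factor multiplies the desired height velocity.
#'
#' @param bmi current BMI, kg/m^2
#' @param bmi_ref reference BMI-for-age, kg/m^2
#' @param threshold ratio at which the reduction engages (inclusive boundary:
#'   the factor is 1 exactly at the threshold)
#' @param floor ratio at which the factor reaches 0
#' @return dimensionless factor in `[0,1]`
#' @export
stunting_factor <- function(bmi, bmi_ref, threshold = 0.85, floor = 0.60) {
  if (any(bmi <= 0) || any(bmi_ref <= 0)) stop("BMI values must be positive")
  r <- bmi / bmi_ref
  pmin(1, pmax(0, (r - floor) / (threshold - floor)))
}

# Indicated state and reference-growth velocities at a given body state.
# Velocities are the per-day change of the indicated masses from aging and
# desired height growth, holding the current BMI contribution fixed.
indicated_and_velocities <- function(state, subject, curves, params) {
  comp <- params$comp; sim <- params$sim
  bio_age <- biological_age(state$age, subject)
  check_span(curves, bio_age)
  bw <- state$fm + state$ffm
  bmi <- bw / state$h^2
  bmi_ref <- curves$bmi_ref(bio_age)
  fmi_ref <- curves$fmi_ref(bio_age)
  bmi_star <- indicated_bmi(bmi, bmi_ref, subject, comp)
  ind <- split_indicated(bmi_star, state$h, bmi_ref, fmi_ref, subject, bio_age, comp)

  h_star <- indicated_height(curves, subject, bio_age)
  v_ref <- subject$height_factor * curves$height_vel(bio_age)
  v_des <- desired_height_velocity(state$h, h_star, v_ref,
                                   sim$tau_height, sim$catchup_cap) *
    stunting_factor(bmi, bmi_ref, sim$stunt_threshold, sim$stunt_floor)

  bio_next <- biological_age(state$age + sim$dt, subject)
  check_span(curves, bio_next)
  h_next <- state$h + v_des * sim$dt
  bmi_ref_next <- curves$bmi_ref(bio_next)
  # the current-BMI contribution to the indicated trajectory runs parallel
  # (in relative terms) to the reference curve, so an on-reference child
  # follows the reference exactly and an off-reference adult sees no
  # spurious indicated velocity
  bmi_next <- bmi * bmi_ref_next / bmi_ref
  bmi_star_next <- indicated_bmi(bmi_next, bmi_ref_next, subject, comp)
  ind_next <- split_indicated(bmi_star_next, h_next, bmi_ref_next,
                              curves$fmi_ref(bio_next), subject, bio_next, comp)
  list(bio_age = bio_age, bmi = bmi, bmi_ref = bmi_ref, fmi_ref = fmi_ref,
       indicated = ind, h_star = h_star, v_ref = v_ref, v_des = v_des,
       vel = list(fm = (ind_next$fm_star - ind$fm_star) / sim$dt,
                  ffm = (ind_next$ffm_star - ind$ffm_star) / sim$dt))
}

# Full step pipeline. `ei` may be NULL, in which case `ei_fun(age, ref_ei)`
# supplies the intake; ref_ei is the closed-form balance intake
# (bmr + pa + growth + turnover)/(1 - tef_fraction), at which the
# thermic-effect term is self-consistent and the adaptive-thermogenesis gap
# is zero (it equals the bisection solution of equilibrium_intake).
step_core <- function(state, subject, curves, params, ei = NULL,
                      ei_fun = NULL) {
  comp <- params$comp; met <- params$met; sim <- params$sim
  ctx <- indicated_and_velocities(state, subject, curves, params)
  bmr <- bmr_demand(state, ctx$indicated, curves, ctx$bio_age, met)
  pa <- reference_pa(curves, subject, ctx$bio_age)
  if (met$pa_scales_with_weight)
    pa <- pa * (state$fm + state$ffm) / curves$bw_ref(ctx$bio_age)
  target_fm <- fmi_anchor(ctx$fmi_ref, subject, ctx$bio_age, comp) *
    (ctx$bmi / ctx$bmi_ref)^comp$gamma * state$h^2
  corr <- composition_correction(state, target_fm, sim$correction_tau)
  p_ffm <- partition_fraction(ctx$bmi, ctx$bmi_ref, ctx$fmi_ref, subject,
                              ctx$bio_age, comp)
  stores <- classify_stores(state, ctx$indicated)

  resolve <- function(rho_ffm, ei_fixed) {
    gr <- growth_demand(ctx$vel$fm, ctx$vel$ffm, state, comp, met,
                        rho_ffm = rho_ffm)
    growth_e <- gr$growth_fm + gr$growth_ffm
    ref_ei <- (bmr + pa + growth_e + gr$turnover) / (1 - met$tef_fraction)
    ei_here <- ei_fixed
    if (is.null(ei_here)) {
      ei_here <- ei_fun(state$age, ref_ei)
      if (!is.finite(ei_here) || ei_here < 0) ei_here <- 0
    }
    tef_v <- tef(ei_here, met)
    pre_at <- bmr + pa + tef_v + gr$turnover +
      if (met$at_includes_growth) growth_e else 0
    at <- adaptive_thermogenesis(ei_here, pre_at, bmr, met)
    budget <- structure(list(bmr = bmr, pa = pa, tef = tef_v,
                             growth_fm = gr$growth_fm,
                             growth_ffm = gr$growth_ffm,
                             turnover = gr$turnover, at_adjustment = at,
                             total = bmr + pa + tef_v + growth_e +
                               gr$turnover + at),
                        class = "gs_budget")
    alloc <- allocate(ei_here, budget, stores, p_ffm, state, ctx$indicated,
                      comp, met, correction = corr, dt = sim$dt,
                      collapse_fraction = sim$collapse_fraction,
                      rho_ffm = rho_ffm)
    list(budget = budget, alloc = alloc, ei = ei_here, ref_ei = ref_ei)
  }

  ## first pass at the start-of-step density; second pass re-prices FFM
  ## flows at the step-midpoint density, which makes the energy ledger agree
  ## with the body-energy integral on the linear density ramp
  rho1 <- ffm_energy_density(state$ffm, comp)
  pass <- resolve(rho1, ei)
  rho_mid <- ffm_energy_density(
    max(0, state$ffm + pass$alloc$net_dffm * sim$dt / 2), comp)
  if (abs(rho_mid - rho1) > 1e-12)
    pass <- resolve(rho_mid, pass$ei)

  alloc <- pass$alloc
  new_state <- body_state(
    fm = max(1e-9, state$fm + alloc$net_dfm * sim$dt),
    ffm = max(1e-9, state$ffm + alloc$net_dffm * sim$dt),
    h = state$h + ctx$v_des * alloc$growth_funded_fraction * sim$dt,
    age = state$age + sim$dt)
  list(state = new_state, budget = pass$budget, alloc = alloc,
       indicated = ctx$indicated, ctx = ctx, ei = pass$ei,
       ref_ei = pass$ref_ei)
}

#' Advance the body state by one step
#'
#' One explicit-Euler step: biological age, indicated state and reference
#' velocities are computed from the start-of-step state; the energy budget is
#' assembled at the given intake; the composition correction and priority
#' allocation resolve the net mass flows; height advances at the desired
#' velocity scaled by the fraction of growth energy the allocation actually
#' funded.
#'
#' @param state a [body_state()]
#' @param subject a [subject()]
#' @param curves a `gs_curves`
#' @param ei energy intake, MJ/day
#' @param params a [model_params()] bundle
#' @param details if `TRUE`, return a list with the new state plus the
#'   budget, allocation, and indicated values of the step
#' @return the new `gs_state` (or a detail list)
#' @export
step <- function(state, subject, curves, ei, params = model_params(),
                 details = FALSE) {
  det <- step_core(state, subject, curves, params, ei = ei)
  if (details) det else det$state
}

#' Reference state at a given age
#'
#' The body state of an individual exactly on their reference trajectory:
#' height at H*, BMI at the subject-scaled reference, composition at the
#' indicated FMI.
#'
#' @param curves a `gs_curves`
#' @param subject a [subject()]
#' @param age calendar age, days
#' @param params a [model_params()]
#' @return a [body_state()]
#' @export
reference_state <- function(curves, subject, age, params = model_params()) {
  bio_age <- biological_age(age, subject)
  h <- indicated_height(curves, subject, bio_age)
  bmi <- subject$bmi_factor * curves$bmi_ref(bio_age)
  fmi <- indicated_fmi(bmi, curves$bmi_ref(bio_age), curves$fmi_ref(bio_age),
                       subject, bio_age, params$comp)
  body_state(fm = fmi * h^2, ffm = (bmi - fmi) * h^2, h = h, age = age)
}

#' Energy intake that keeps the state on its indicated trajectory
#'
#' Solves (by bisection, to 1e-6 MJ/day) for the intake at which supply
#' exactly matches demand: maintenance plus the energy cost of growth along
#' the indicated trajectory, with the thermic effect of feeding evaluated at
#' the solution and zero adaptive-thermogenesis gap. Fed back into [step()],
#' this intake produces no net deviation from the indicated trajectory; for a
#' growing child it is the reference intake.
#'
#' @param state a [body_state()]
#' @param subject a [subject()]
#' @param curves a `gs_curves`
#' @param params a [model_params()]
#' @param interval search interval, MJ/day
#' @return equilibrium intake, MJ/day
#' @export
equilibrium_intake <- function(state, subject, curves, params = model_params(),
                               interval = c(0.05, 60)) {
  comp <- params$comp; met <- params$met
  ctx <- indicated_and_velocities(state, subject, curves, params)
  gap <- function(ei) {
    b <- total_demand(state, ctx$indicated, curves, subject, ei,
                      vel = ctx$vel, comp = comp, met = met)
    pre_at <- b$total - b$at_adjustment
    ei - pre_at
  }
  lo <- gap(interval[1]); hi <- gap(interval[2])
  if (lo * hi > 0) stop("equilibrium_intake: no bracketing interval")
  stats::uniroot(gap, interval, tol = 1e-6)$root
}

#' Reference intake series of an individual
#'
#' The daily energy intake of the subject growing exactly on their reference
#' trajectory: a reference run is integrated from `t_start` feeding the
#' running equilibrium intake, and the resulting intake-for-age series is
#' returned as an interpolating function. Multiplier-of-reference scenarios
#' are defined against this series (intake is exogenous), not against the
#' equilibrium intake of the perturbed state.
#'
#' @param subject a [subject()]
#' @param curves a `gs_curves`
#' @param params a [model_params()]
#' @param t_start,t_end span of ages (days) to cover
#' @return function age(days) -> reference intake MJ/day
#' @export
reference_intake <- function(subject, curves, params = model_params(),
                             t_start = 0, t_end) {
  r <- simulate_scenario(subject, curves, scenario(t_start, t_end), params)
  stats::approxfun(r$age_days, r$ei, rule = 2)
}

#' Define an intake scenario
#'
#' @param t_start,t_end simulation span, days of age
#' @param ei intake schedule: a function `(age_days, ref_ei)` returning
#'   MJ/day -- `ref_ei` is the intake-for-age of the *reference individual*
#'   (see [reference_intake()]), so `function(a, r) 1.2 * r` is a 20%
#'   overfeed relative to reference; a single number (constant MJ/day); or
#'   `NULL` for reference feeding (intake = running equilibrium intake of
#'   the current state, which keeps an on-reference state on-reference)
#' @param init initial [body_state()], or `NULL` to start from the reference
#'   state at `t_start`
#' @param dt step, days (overrides the parameter bundle when given)
#' @return an object of class `gs_scenario`
#' @export
scenario <- function(t_start, t_end, ei = NULL, init = NULL, dt = NULL) {
  if (t_end <= t_start) stop("t_end must exceed t_start")
  ei_fun <- if (is.null(ei)) function(age, ref_ei) ref_ei
    else if (is.function(ei)) ei
    else if (is.numeric(ei) && length(ei) == 1) function(age, ref_ei) ei
    else stop("'ei' must be NULL, a number, or a function(age, ref_ei)")
  structure(list(t_start = t_start, t_end = t_end, ei_fun = ei_fun,
                 reference_fed = is.null(ei), needs_ref = is.function(ei),
                 init = init, dt = dt),
            class = "gs_scenario")
}

#' Simulate a life-course (or shorter) intake scenario
#'
#' Runs daily explicit-Euler steps from `t_start` to `t_end`. Each day the
#' running equilibrium (reference) intake of the current state is available
#' to the intake schedule, so multiplier-of-reference scenarios need no
#' precomputed series. Returns one row per day.
#'
#' @param subject a [subject()]
#' @param curves a `gs_curves`
#' @param scn a [scenario()]
#' @param params a [model_params()]
#' @param stop_when optional `function(state)` returning `TRUE` to end the
#'   run early (checked after each step)
#' @param ref_intake optional precomputed [reference_intake()] function; when
#'   the scenario has an intake schedule and this is `NULL`, the reference
#'   series is computed on the fly from `t_start`
#' @return a `data.frame` of class `gs_sim` with per-day columns: `age_days`,
#'   `fm`, `ffm`, `bw`, `h`, `bmi`, `fat_frac`, `ei`, `ref_ei`, demand
#'   components, indicated values and the realized height velocity; attribute
#'   `collapse` flags starvation collapse (series truncated at the signal)
#' @export
simulate_scenario <- function(subject, curves, scn, params = model_params(),
                              stop_when = NULL, ref_intake = NULL) {
  if (!is.null(scn$dt)) params$sim$dt <- scn$dt
  dt <- params$sim$dt
  state <- if (is.null(scn$init)) reference_state(curves, subject, scn$t_start, params)
           else scn$init
  ref_fun <- NULL
  if (isTRUE(scn$needs_ref)) {
    ref_fun <- if (is.null(ref_intake))
      reference_intake(subject, curves, params, scn$t_start, scn$t_end + dt)
    else ref_intake
  } else if (!isTRUE(scn$reference_fed)) {
    ref_fun <- function(age) NA_real_   # constant schedules ignore the ref
  }
  n <- floor((scn$t_end - scn$t_start) / dt) + 1L
  cols <- c("age_days", "fm", "ffm", "bw", "h", "bmi", "fat_frac", "ei",
            "ref_ei", "bmr", "pa", "tef", "growth", "turnover", "at",
            "demand_total", "h_star", "bmi_ref", "bw_star", "fm_star",
            "height_velocity", "growth_funded", "dissipated",
            "deposition_loss")
  out <- matrix(NA_real_, nrow = n, ncol = length(cols),
                dimnames = list(NULL, cols))
  collapse <- FALSE
  i <- 1L
  while (i <= n) {
    det <- if (is.null(ref_fun)) {
      step_core(state, subject, curves, params, ei_fun = scn$ei_fun)
    } else {
      ei_i <- scn$ei_fun(state$age, ref_fun(state$age))
      if (!is.finite(ei_i) || ei_i < 0) ei_i <- 0
      step_core(state, subject, curves, params, ei = ei_i)
    }
    b <- det$budget; a <- det$alloc; ctx <- det$ctx
    bw <- state$fm + state$ffm
    out[i, ] <- c(state$age, state$fm, state$ffm, bw, state$h, ctx$bmi,
                  state$fm / bw, det$ei, det$ref_ei, b$bmr, b$pa, b$tef,
                  b$growth_fm + b$growth_ffm, b$turnover, b$at_adjustment,
                  b$total, ctx$h_star, ctx$bmi_ref, det$indicated$bw_star,
                  det$indicated$fm_star,
                  ctx$v_des * a$growth_funded_fraction,
                  a$growth_funded_fraction, a$dissipated, a$deposition_loss)
    if (a$collapse) { collapse <- TRUE; i <- i + 1L; break }
    state <- det$state
    if (!is.null(stop_when) && isTRUE(stop_when(state))) { i <- i + 1L; break }
    i <- i + 1L
  }
  res <- as.data.frame(out[seq_len(min(i - 1L, n)), , drop = FALSE])
  attr(res, "collapse") <- collapse
  attr(res, "final_state") <- state
  class(res) <- c("gs_sim", class(res))
  res
}
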