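# Itemized daily energy demand: organ-based BMR, physical activity, thermic
# effect of feeding, growth and turnover costs, and adaptive thermogenesis.

#' Metabolic parameters
#'
#' @param tef_fraction thermic effect of feeding as a fraction of intake
#' @param at_coefficient strength of adaptive thermogenesis: the fractional
#'   intake/demand gap is applied to BMR scaled by this coefficient
#' @param at_includes_growth whether catch-up/growth energy needs enter the
#'   demand against which the adaptive-thermogenesis gap is measured
#' @param dep_eff_fm,dep_eff_ffm deposition efficiencies: energy spent per MJ
#'   stored is `rho/efficiency`
#' @param turnover_rate mass-turnover energy cost, MJ per kg body weight per
#'   day (default 0: folded into the residual BMR rate)
#' @param sigma_fm,sigma_residual specific metabolic rates of fat mass and of
#'   residual (non-organ) fat-free mass, MJ/kg/day
#' @param organ_response named per-organ dimensionless slopes of organ mass
#'   with relative body-weight deviation from indicated
#' @param pa_scales_with_weight if `TRUE` (default) the activity energy cost
#'   scales with current body weight relative to the reference weight-for-age,
#'   as in locomotion-cost models; if `FALSE` the reference activity budget is
#'   used as an absolute demand
#' @param bmr_ceiling sanity ceiling on BMR, MJ/day
#' @return an object of class `gs_met_params`
#' @export
metabolic_params <- function(tef_fraction = 0.10, at_coefficient = 0.25,
                             at_includes_growth = TRUE,
                             dep_eff_fm = 0.98, dep_eff_ffm = 0.85,
                             turnover_rate = 0,
                             sigma_fm = 0.019, sigma_residual = 0.045,
                             organ_response = c(brain = 0, liver = 0.5,
                                                heart = 0.5, kidneys = 0.5),
                             pa_scales_with_weight = TRUE,
                             bmr_ceiling = 30) {
  if (tef_fraction < 0 || tef_fraction >= 0.3) stop("tef_fraction must be in [0, 0.3)")
  if (at_coefficient < 0 || at_coefficient > 1) stop("at_coefficient must be in [0, 1]")
  if (dep_eff_fm <= 0 || dep_eff_fm > 1 || dep_eff_ffm <= 0 || dep_eff_ffm > 1)
    stop("deposition efficiencies must be in (0, 1]")
  structure(list(tef_fraction = tef_fraction, at_coefficient = at_coefficient,
                 at_includes_growth = at_includes_growth,
                 dep_eff_fm = dep_eff_fm, dep_eff_ffm = dep_eff_ffm,
                 turnover_rate = turnover_rate, sigma_fm = sigma_fm,
                 sigma_residual = sigma_residual, organ_response = organ_response,
                 pa_scales_with_weight = pa_scales_with_weight,
                 bmr_ceiling = bmr_ceiling), class = "gs_met_params")
}

organ_masses <- function(bio_age, bw, bw_star, curves, met) {
  dev <- (bw - bw_star) / bw_star
  vapply(names(curves$organ_sigma), function(org) {
    curves$organ_frac[[org]](bio_age) * bw_star *
      (1 + unname(met$organ_response[org]) * dev)
  }, numeric(1))
}

#' Basal metabolic rate from organ masses
#'
#' BMR is assembled from tissue compartments: named organs (brain, liver,
#' heart, kidneys) at their age-indexed mass fractions of indicated body
#' weight (scaled by the body-weight deviation response), weighted by
#' tissue-specific metabolic rates and the age-dependent relative cellularity;
#' plus fat mass and residual fat-free mass at their own specific rates.
#'
#' @param state a [body_state()]
#' @param indicated a `gs_indicated` (see [split_indicated()])
#' @param curves a `gs_curves` object
#' @param bio_age biological age, days
#' @param met a [metabolic_params()]
#' @return BMR, MJ/day
#' @export
bmr_demand <- function(state, indicated, curves, bio_age,
                       met = metabolic_params()) {
  bw <- state$fm + state$ffm
  om <- organ_masses(bio_age, bw, indicated$bw_star, curves, met)
  residual_ffm <- state$ffm - sum(om)
  if (residual_ffm < 0) stop("organ masses exceed fat-free mass: composition error")
  bmr <- sum(om * curves$organ_sigma) * curves$cellularity(bio_age) +
    met$sigma_fm * state$fm + met$sigma_residual * residual_ffm
  if (bmr > met$bmr_ceiling)
    stop(sprintf("BMR %.1f MJ/day exceeds sanity ceiling %.1f", bmr, met$bmr_ceiling))
  bmr
}

#' Growth and turnover energy demand
#'
#' Energy cost of depositing tissue along the indicated trajectory: positive
#' indicated mass velocities are charged at the tissue energy density divided
#' by the deposition efficiency; non-positive velocities demand nothing.
#' Turnover is a configured per-kg cost of body weight.
#'
#' @param vel_fm,vel_ffm indicated mass velocities, kg/day (may be negative)
#' @param state a [body_state()]
#' @param comp a [composition_params()]
#' @param met a [metabolic_params()]
#' @param rho_ffm FFM marginal energy density override, MJ/kg (defaults to
#'   the density at the current FFM; the integrator passes a step-midpoint
#'   value so that energy pricing matches the body-energy integral)
#' @return list with `growth_fm`, `growth_ffm`, `turnover` in MJ/day
#' @export
growth_demand <- function(vel_fm, vel_ffm, state, comp = composition_params(),
                          met = metabolic_params(), rho_ffm = NULL) {
  if (!is.finite(vel_fm) || !is.finite(vel_ffm)) stop("velocities must be finite")
  if (is.null(rho_ffm)) rho_ffm <- ffm_energy_density(state$ffm, comp)
  list(growth_fm = max(0, vel_fm) * comp$rho_fm / met$dep_eff_fm,
       growth_ffm = max(0, vel_ffm) * rho_ffm / met$dep_eff_ffm,
       turnover = met$turnover_rate * (state$fm + state$ffm))
}

#' Thermic effect of feeding
#'
#' @param ei energy intake, MJ/day
#' @param met a [metabolic_params()]
#' @return TEF, MJ/day (a fixed fraction of intake)
#' @export
tef <- function(ei, met = metabolic_params()) {
  if (any(ei < 0)) stop("ei must be non-negative")
  met$tef_fraction * ei
}

#' Adaptive thermogenesis adjustment
#'
#' The fractional gap between intake and the pre-adjustment energy demand
#' (which, by default, includes catch-up growth needs), applied to BMR and
#' scaled by the adaptive-thermogenesis coefficient. Negative under deficit
#' (energy sparing), positive under surplus, zero in balance.
#'
#' @param ei energy intake, MJ/day
#' @param pre_at_demand total demand excluding this adjustment, MJ/day (> 0)
#' @param bmr basal metabolic rate, MJ/day
#' @param met a [metabolic_params()]
#' @return signed adjustment, MJ/day
#' @export
adaptive_thermogenesis <- function(ei, pre_at_demand, bmr,
                                   met = metabolic_params()) {
  if (any(pre_at_demand <= 0)) stop("pre_at_demand must be positive")
  met$at_coefficient * (ei / pre_at_demand - 1) * bmr
}

#' Assemble the itemized daily energy budget
#'
#' Computes every demand component at the current state and intake and checks
#' the additivity invariant. The adaptive-thermogenesis gap is measured
#' against all other components (including thermic effect of feeding, and
#' growth needs unless disabled in the parameters).
#'
#' @param state a [body_state()]
#' @param indicated a `gs_indicated`
#' @param curves a `gs_curves`
#' @param subject a [subject()]
#' @param ei energy intake, MJ/day
#' @param vel list with `fm`, `ffm` indicated velocities, kg/day
#' @param comp a [composition_params()]
#' @param met a [metabolic_params()]
#' @return an object of class `gs_budget` with components `bmr`, `pa`, `tef`,
#'   `growth_fm`, `growth_ffm`, `turnover`, `at_adjustment`, `total`
#' @export
total_demand <- function(state, indicated, curves, subject, ei,
                         vel = list(fm = 0, ffm = 0),
                         comp = composition_params(), met = metabolic_params()) {
  bio_age <- biological_age(state$age, subject)
  bmr <- bmr_demand(state, indicated, curves, bio_age, met)
  pa <- reference_pa(curves, subject, bio_age)
  if (met$pa_scales_with_weight)
    pa <- pa * (state$fm + state$ffm) / curves$bw_ref(bio_age)
  gr <- growth_demand(vel$fm, vel$ffm, state, comp, met)
  tef_v <- tef(ei, met)
  pre_at <- bmr + pa + tef_v + gr$turnover +
    if (met$at_includes_growth) gr$growth_fm + gr$growth_ffm else 0
  at <- adaptive_thermogenesis(ei, pre_at, bmr, met)
  structure(list(bmr = bmr, pa = pa, tef = tef_v, growth_fm = gr$growth_fm,
                 growth_ffm = gr$growth_ffm, turnover = gr$turnover,
                 at_adjustment = at,
                 total = bmr + pa + tef_v + gr$growth_fm + gr$growth_ffm +
                   gr$turnover + at),
            class = "gs_budget")
}
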