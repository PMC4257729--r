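# Body-composition model: indicated BMI/FMI, the energy-partitioning fraction
# derived from the FMI equation, and body-energy accounting.

#' Composition model parameters
#'
#' Parameters of the indicated-BMI blend, the FMI-vs-BMI family, and tissue
#' energy densities. The FMI family is a power law anchored at the reference:
#' `FMI*(BMI) = (FMI_Ref + race_term + fmi_offset + age_term) * (BMI/BMI_Ref)^gamma`,
#' which satisfies the anchor property (FMI* = FMI_Ref at BMI = BMI_Ref for a
#' neutral subject of the reference race) and yields the closed-form marginal
#' partition `p_FFM = 1 - gamma * FMI*/BMI`.
#'
#' @param lambda_bmi weight in `[0,1]` on the *current* BMI in the indicated
#'   BMI blend (1 - lambda on the biological reference BMI)
#' @param gamma elasticity of FMI with respect to BMI (dimensionless)
#' @param race_terms named additive FMI terms, kg/m^2, one per race
#' @param age_slope post-childhood linear FMI aging drift, kg/m^2 per year of
#'   biological age past `adult_age_years`
#' @param adult_age_years biological age (years) at which the aging drift and
#'   the adult FFM energy density are reached
#' @param rho_fm metabolizable energy density of fat mass, MJ/kg
#' @param rho_ffm_adult adult (saturated) FFM energy density, MJ/kg
#' @param rho_ffm_intercept FFM marginal energy density at zero FFM, MJ/kg
#' @param rho_ffm_sat FFM mass (kg) at which the marginal density saturates
#'   at `rho_ffm_adult`
#' @param p_ffm_clip two-sided clip for the partition fraction at pathological
#'   BMI values (a warning is emitted when the clip engages)
#' @return an object of class `gs_comp_params`
#' @export
composition_params <- function(lambda_bmi = 0.5, gamma = 2,
                               race_terms = c(mexican_american = 0.3, nh_white = 0,
                                              nh_black = -0.3, other = 0),
                               age_slope = 0.01, adult_age_years = 20,
                               rho_fm = 39.5, rho_ffm_adult = 5,
                               rho_ffm_intercept = 1, rho_ffm_sat = 47,
                               p_ffm_clip = c(0.01, 0.99)) {
  if (lambda_bmi < 0 || lambda_bmi > 1) stop("lambda_bmi must be in [0,1]")
  if (rho_fm <= rho_ffm_adult || rho_ffm_adult <= 0)
    stop("need rho_fm > rho_ffm_adult > 0")
  if (rho_ffm_intercept > rho_ffm_adult)
    stop("rho_ffm_intercept must not exceed the adult saturation density")
  stopifnot(all(RACES %in% names(race_terms)))
  structure(list(lambda_bmi = lambda_bmi, gamma = gamma,
                 race_terms = race_terms, age_slope = age_slope,
                 adult_age_years = adult_age_years, rho_fm = rho_fm,
                 rho_ffm_adult = rho_ffm_adult,
                 rho_ffm_intercept = rho_ffm_intercept,
                 rho_ffm_sat = rho_ffm_sat,
                 rho_ffm_slope = (rho_ffm_adult - rho_ffm_intercept) / rho_ffm_sat,
                 p_ffm_clip = p_ffm_clip), class = "gs_comp_params")
}

#' Indicated BMI
#'
#' The canalization target for BMI: a weighted sum of the current BMI and the
#' (subject-scaled) biological reference BMI. BMI is less tightly canalized
#' than height, so the target partially follows the current state.
#'
#' @param bmi current BMI, kg/m^2
#' @param bmi_ref reference BMI for (biological) age, kg/m^2
#' @param subject a [subject()]
#' @param params a [composition_params()]
#' @return indicated BMI (BMI*), kg/m^2
#' @export
indicated_bmi <- function(bmi, bmi_ref, subject, params = composition_params()) {
  if (any(bmi <= 0) || any(bmi_ref <= 0)) stop("BMI values must be positive")
  params$lambda_bmi * bmi + (1 - params$lambda_bmi) * subject$bmi_factor * bmi_ref
}

fmi_anchor <- function(fmi_ref, subject, bio_age, params) {
  age_term <- params$age_slope * pmax(0, dy(bio_age) - params$adult_age_years)
  fmi_ref + unname(params$race_terms[subject$race]) + subject$fmi_offset + age_term
}

#' Most likely fat mass index at a given BMI
#'
#' Maps BMI to the expected FMI: the age/sex/race reference FMI (plus the
#' subject's fat offset and the post-childhood aging drift) scaled by the BMI
#' deviation from reference through the power-law elasticity `gamma`.
#'
#' @param bmi current BMI, kg/m^2
#' @param bmi_ref,fmi_ref reference BMI and FMI at the biological age, kg/m^2
#' @param subject a [subject()]
#' @param bio_age biological age in days (drives the aging drift)
#' @param params a [composition_params()]
#' @return indicated FMI (FMI*), kg/m^2
#' @export
indicated_fmi <- function(bmi, bmi_ref, fmi_ref, subject, bio_age,
                          params = composition_params()) {
  if (any(bmi <= 0) || any(bmi_ref <= 0) || any(fmi_ref <= 0))
    stop("BMI/FMI inputs must be positive")
  fmi <- fmi_anchor(fmi_ref, subject, bio_age, params) * (bmi / bmi_ref)^params$gamma
  if (any(fmi >= bmi))
    stop("indicated FMI >= BMI: composition coefficients invalid at this BMI")
  fmi
}

#' Marginal fat-free-mass partition fraction
#'
#' The fraction of a marginal body-weight change (at fixed height) deposited
#' as, or drawn from, fat-free mass. It is the analytical derivative of the
#' FMI family: `p_FFM = 1 - dFMI*/dBMI = 1 - gamma * FMI*(BMI)/BMI`, clipped
#' (with a warning) at pathological BMI values so that flows stay defined in
#' extreme starvation/overfeeding scenarios.
#'
#' @inheritParams indicated_fmi
#' @return partition fraction in `(0,1)`
#' @export
partition_fraction <- function(bmi, bmi_ref, fmi_ref, subject, bio_age,
                               params = composition_params()) {
  fmi <- fmi_anchor(fmi_ref, subject, bio_age, params) * (bmi / bmi_ref)^params$gamma
  p <- 1 - params$gamma * fmi / bmi
  lo <- params$p_ffm_clip[1]; hi <- params$p_ffm_clip[2]
  if (any(p < lo | p > hi)) {
    warning(sprintf("partition fraction clipped to [%.2f, %.2f] at BMI %.1f",
                    lo, hi, bmi[which(p < lo | p > hi)][1L]))
    p <- pmin(pmax(p, lo), hi)
  }
  p
}

#' Split an indicated BMI into indicated masses
#'
#' Converts the indicated BMI at the current height into indicated body
#' weight, fat mass and fat-free mass using the FMI family.
#'
#' @param bmi_star indicated BMI, kg/m^2
#' @param h height, m
#' @inheritParams indicated_fmi
#' @return an object of class `gs_indicated`: `bmi_star`, `bw_star`,
#'   `fmi_star`, `fm_star`, `ffm_star`
#' @export
split_indicated <- function(bmi_star, h, bmi_ref, fmi_ref, subject, bio_age,
                            params = composition_params()) {
  if (any(h <= 0)) stop("height must be positive")
  fmi_star <- indicated_fmi(bmi_star, bmi_ref, fmi_ref, subject, bio_age, params)
  bw_star <- bmi_star * h^2
  fm_star <- fmi_star * h^2
  structure(list(bmi_star = bmi_star, bw_star = bw_star, fmi_star = fmi_star,
                 fm_star = fm_star, ffm_star = bw_star - fm_star),
            class = "gs_indicated")
}

#' Marginal energy density of fat-free mass
#'
#' FFM energy content per kg rises linearly with FFM through growth (lean
#' tissue of small children is mostly water) and saturates at the adult value
#' (default 5 MJ/kg); the two branches join continuously at the saturation
#' mass.
#'
#' @param ffm fat-free mass, kg (vectorised)
#' @param params a [composition_params()]
#' @return marginal energy density, MJ/kg
#' @export
ffm_energy_density <- function(ffm, params = composition_params()) {
  if (any(ffm < 0)) stop("ffm must be non-negative")
  pmin(params$rho_ffm_intercept + params$rho_ffm_slope * ffm, params$rho_ffm_adult)
}

#' Metabolizable energy content of the body
#'
#' Fat mass contributes a constant density; fat-free mass contributes the
#' integral of its marginal density (piecewise quadratic-then-linear).
#'
#' @param fm fat mass, kg
#' @param ffm fat-free mass, kg
#' @param params a [composition_params()]
#' @return body energy, MJ
#' @export
body_energy <- function(fm, ffm, params = composition_params()) {
  if (any(fm < 0) || any(ffm < 0)) stop("masses must be non-negative")
  s <- params$rho_ffm_sat
  below <- pmin(ffm, s)
  e_ffm <- params$rho_ffm_intercept * below + params$rho_ffm_slope * below^2 / 2 +
    params$rho_ffm_adult * pmax(0, ffm - s)
  params$rho_fm * fm + e_ffm
}

#' Forbes marginal partition fraction (comparison alternative)
#'
#' The classical cross-sectional companionship of fat and lean mass implies
#' that the fat-free share of a marginal weight change is
#' `p_FFM = 10.4 / (10.4 + FM)`. Provided only for side-by-side comparison
#' with [partition_fraction()]; the simulator does not use it.
#'
#' @param bw body weight, kg
#' @param fm fat mass, kg (0 < fm < bw)
#' @return fat-free partition fraction in `(0,1)`
#' @export
forbes_partition <- function(bw, fm) {
  if (any(fm <= 0) || any(fm >= bw)) stop("need 0 < fm < bw")
  10.4 / (10.4 + fm)
}
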