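# Per-step energy allocation: which sources (intake, extra stores, essential
# stores) serve which demands (maintenance, essential deposition, extra
# deposition), under strict priority orders on both sides.

#' Partition body mass into extra and essential stores
#'
#' Mass above the indicated trajectory is "extra" (first in line for
#' catabolism); mass composing the indicated trajectory is "essential"
#' (touched only for survival once extra stores are exhausted).
#'
#' @param state a [body_state()]
#' @param indicated a `gs_indicated` (see [split_indicated()])
#' @return an object of class `gs_stores` with `extra_fm`, `extra_ffm`,
#'   `essential_fm`, `essential_ffm` (kg)
#' @export
classify_stores <- function(state, indicated) {
  structure(list(extra_fm = max(0, state$fm - indicated$fm_star),
                 extra_ffm = max(0, state$ffm - indicated$ffm_star),
                 essential_fm = min(state$fm, indicated$fm_star),
                 essential_ffm = min(state$ffm, indicated$ffm_star)),
            class = "gs_stores")
}

#' Composition-correction exchange
#'
#' Homeostatic first-order relaxation of the fat/lean split toward the
#' composition indicated by the current BMI, at fixed body weight: the fat
#' flow is `-(FM - target)/tau` kg/day and the fat-free flow is its negative.
#' The energy difference between the shrinking and growing compartments is
#' settled in the allocation ledger.
#'
#' @param state a [body_state()]
#' @param target_fm fat mass indicated by the current BMI, kg
#' @param tau correction time constant, days (> 0)
#' @return list with `dfm`, `dffm` in kg/day (summing to zero)
#' @export
composition_correction <- function(state, target_fm, tau = 60) {
  if (tau <= 0) stop("correction time constant must be positive")
  dfm <- -(state$fm - target_fm) / tau
  list(dfm = dfm, dffm = -dfm)
}

# Drain up to `energy` MJ/day from a pair of stores with target mass split
# p_ffm, falling back to whichever store has remaining capacity. Returns the
# energy actually supplied and the mass flows (kg/day, positive = drained).
drain_stores <- function(energy, avail_fm, avail_ffm, p_ffm, rho_fm, rho_ffm) {
  if (energy <= 0) return(list(energy = 0, dfm = 0, dffm = 0))
  mix <- p_ffm * rho_ffm + (1 - p_ffm) * rho_fm
  m <- energy / mix
  dffm <- min(p_ffm * m, avail_ffm)
  dfm <- min((1 - p_ffm) * m, avail_fm)
  got <- dffm * rho_ffm + dfm * rho_fm
  if (got < energy - 1e-12) {
    add_fm <- min(avail_fm - dfm, (energy - got) / rho_fm)
    dfm <- dfm + add_fm; got <- got + add_fm * rho_fm
  }
  if (got < energy - 1e-12) {
    add_ffm <- min(avail_ffm - dffm, (energy - got) / rho_ffm)
    dffm <- dffm + add_ffm; got <- got + add_ffm * rho_ffm
  }
  list(energy = got, dfm = dfm, dffm = dffm)
}

#' Allocate energy sources to demands for one step
#'
#' Implements the priority ladder. Sources, in order: energy intake, extra
#' stores, essential stores (survival only). Demands, in order: maintenance
#' (BMR, activity, thermic effect, turnover, adaptive thermogenesis, plus any
#' energy cost of the composition correction), essential deposition
#' (growth along the indicated trajectory), and only then extra deposition of
#' surplus intake. Deposition and consumption of extra mass are both split
#' between fat-free and fat mass by the marginal partition fraction;
#' deposition pays the efficiency surcharge, catabolism releases the full
#' tissue energy. Essential deposition may be funded by intake or extra
#' stores, never by essential stores.
#'
#' @param ei energy intake, MJ/day
#' @param budget a `gs_budget` from [total_demand()]
#' @param stores a `gs_stores` from [classify_stores()]
#' @param p_ffm marginal fat-free partition fraction in (0,1)
#' @param state a [body_state()]
#' @param indicated a `gs_indicated`
#' @param comp a [composition_params()]
#' @param met a [metabolic_params()]
#' @param correction correction flows from [composition_correction()]
#' @param dt step length, days (caps store drains at availability)
#' @param collapse_fraction essential store fraction of indicated below which
#'   the starvation-collapse signal is raised
#' @param rho_ffm FFM marginal energy density override, MJ/kg (see
#'   [growth_demand()])
#' @return an object of class `gs_alloc`: named energy `flows` (MJ/day), net
#'   mass flows `net_dfm`/`net_dffm` (kg/day), `growth_funded_fraction`,
#'   `maintenance_unserved` (MJ/day), `collapse` flag and the ledger
#'   `energy_residual` (MJ/day; zero up to round-off)
#' @export
allocate <- function(ei, budget, stores, p_ffm, state, indicated,
                     comp = composition_params(), met = metabolic_params(),
                     correction = list(dfm = 0, dffm = 0), dt = 1,
                     collapse_fraction = 0.2, rho_ffm = NULL) {
  if (ei < 0) stop("ei must be non-negative")
  if (p_ffm <= 0 || p_ffm >= 1) stop("p_ffm must be in (0,1)")
  if (is.null(rho_ffm)) rho_ffm <- ffm_energy_density(state$ffm, comp)
  rho_fm <- comp$rho_fm

  ## correction exchange: energy released by the shrinking compartment funds
  ## the growing one; the net difference enters the ledger.
  dfm_c <- correction$dfm; dffm_c <- correction$dffm
  corr_loss <- 0
  if (dfm_c < 0) {            # fat -> lean
    release <- -dfm_c * rho_fm
    cost <- dffm_c * rho_ffm / met$dep_eff_ffm
    corr_loss <- cost - dffm_c * rho_ffm
  } else if (dfm_c > 0) {     # lean -> fat
    release <- -dffm_c * rho_ffm
    cost <- dfm_c * rho_fm / met$dep_eff_fm
    corr_loss <- cost - dfm_c * rho_fm
  } else { release <- 0; cost <- 0 }
  corr_net <- release - cost
  corr_supply <- max(0, corr_net)
  corr_demand <- max(0, -corr_net)

  maint <- max(0, budget$bmr + budget$pa + budget$tef + budget$turnover +
                 budget$at_adjustment) + corr_demand
  g_ffm <- budget$growth_ffm
  g_fm <- budget$growth_fm

  pool <- ei + corr_supply
  flows <- c(ei_maintenance = 0, extra_maintenance_fm = 0,
             extra_maintenance_ffm = 0, essential_maintenance_fm = 0,
             essential_maintenance_ffm = 0, ei_growth = 0,
             extra_growth_fm = 0, extra_growth_ffm = 0, ei_extra_deposit = 0)
  avail_extra_fm <- stores$extra_fm / dt
  avail_extra_ffm <- stores$extra_ffm / dt
  avail_ess_fm <- stores$essential_fm / dt
  avail_ess_ffm <- stores$essential_ffm / dt
  dfm_drain <- 0; dffm_drain <- 0

  ## 1) maintenance: pool, then extra stores, then essential stores
  served <- min(pool, maint); pool <- pool - served
  flows["ei_maintenance"] <- served
  short <- maint - served
  if (short > 0) {
    d <- drain_stores(short, avail_extra_fm, avail_extra_ffm, p_ffm, rho_fm, rho_ffm)
    flows["extra_maintenance_fm"] <- d$dfm * rho_fm
    flows["extra_maintenance_ffm"] <- d$dffm * rho_ffm
    avail_extra_fm <- avail_extra_fm - d$dfm
    avail_extra_ffm <- avail_extra_ffm - d$dffm
    dfm_drain <- dfm_drain + d$dfm; dffm_drain <- dffm_drain + d$dffm
    short <- short - d$energy
  }
  if (short > 1e-12) {
    d <- drain_stores(short, avail_ess_fm, avail_ess_ffm, p_ffm, rho_fm, rho_ffm)
    flows["essential_maintenance_fm"] <- d$dfm * rho_fm
    flows["essential_maintenance_ffm"] <- d$dffm * rho_ffm
    avail_ess_fm <- avail_ess_fm - d$dfm
    avail_ess_ffm <- avail_ess_ffm - d$dffm
    dfm_drain <- dfm_drain + d$dfm; dffm_drain <- dffm_drain + d$dffm
    short <- short - d$energy
  }
  maint_unserved <- max(0, short)

  ## 2) essential deposition (growth), funded by pool then extra stores
  g_total <- g_ffm + g_fm
  g_from_pool <- min(pool, g_total); pool <- pool - g_from_pool
  flows["ei_growth"] <- g_from_pool
  g_short <- g_total - g_from_pool
  if (g_short > 0 && maint_unserved == 0) {
    d <- drain_stores(g_short, avail_extra_fm, avail_extra_ffm, p_ffm, rho_fm, rho_ffm)
    flows["extra_growth_fm"] <- d$dfm * rho_fm
    flows["extra_growth_ffm"] <- d$dffm * rho_ffm
    avail_extra_fm <- avail_extra_fm - d$dfm
    avail_extra_ffm <- avail_extra_ffm - d$dffm
    dfm_drain <- dfm_drain + d$dfm; dffm_drain <- dffm_drain + d$dffm
    g_short <- g_short - d$energy
  }
  g_served <- g_total - max(0, g_short)
  growth_funded <- if (g_total > 0) g_served / g_total else 1
  # deposited growth mass, proportional to the funded fraction of each need
  gm_ffm <- if (g_total > 0) g_served * (g_ffm / g_total) * met$dep_eff_ffm / rho_ffm else 0
  gm_fm <- if (g_total > 0) g_served * (g_fm / g_total) * met$dep_eff_fm / rho_fm else 0
  growth_loss <- g_served - gm_ffm * rho_ffm - gm_fm * rho_fm

  ## 3) surplus intake deposits extra mass, split by the partition fraction
  extra_dep_e <- pool
  flows["ei_extra_deposit"] <- extra_dep_e
  cost_per_kg <- p_ffm * rho_ffm / met$dep_eff_ffm + (1 - p_ffm) * rho_fm / met$dep_eff_fm
  m_extra <- extra_dep_e / cost_per_kg
  xm_ffm <- p_ffm * m_extra; xm_fm <- (1 - p_ffm) * m_extra
  extra_loss <- extra_dep_e - xm_ffm * rho_ffm - xm_fm * rho_fm

  net_dfm <- dfm_c + gm_fm + xm_fm - dfm_drain
  net_dffm <- dffm_c + gm_ffm + xm_ffm - dffm_drain

  ## collapse signal: essential stores pressed to (or below) the survival floor
  collapse <- maint_unserved > 1e-9 ||
    avail_ess_fm * dt < collapse_fraction * indicated$fm_star ||
    avail_ess_ffm * dt < collapse_fraction * indicated$ffm_star

  ## ledger audit: supply (intake + catabolized tissue energy) must equal use
  ## (dissipated maintenance + deposited tissue energy + efficiency losses)
  supply <- ei + release + dfm_drain * rho_fm + dffm_drain * rho_ffm
  use <- (maint - corr_demand - maint_unserved) + cost +
    gm_ffm * rho_ffm + gm_fm * rho_fm + growth_loss +
    xm_ffm * rho_ffm + xm_fm * rho_fm + extra_loss
  residual <- supply - use

  structure(list(flows = flows, net_dfm = net_dfm, net_dffm = net_dffm,
                 growth_funded_fraction = growth_funded,
                 maintenance_unserved = maint_unserved,
                 dissipated = maint - corr_demand - maint_unserved,
                 deposition_loss = growth_loss + extra_loss + corr_loss,
                 energy_residual = residual, collapse = collapse),
            class = "gs_alloc")
}
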