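# Steady-state C and N balance of one association.
#
# Supply equals consumption for both elements:
#   C:  FphoD + FphoV = mu * [QCV(1+Ev) + QCH(1+Eh) + QCD(1+Ed)] + FCfix
#   N:  FNfix + VNH4  = mu * (QNV + QNH + QND)
# with Monod ammonium uptake VNH4 = Vmax * QCD * [NH4] / ([NH4] + Km)
# and fixation carbon cost FCfix = FNfix * fcn_fix.

#' Define one model scenario
#'
#' A scenario is the unit of one model evaluation: a growth rate, an
#' ambient ammonium concentration, optionally an irradiance (absent
#' means light-replete mode), the association composition, the
#' physiological parameters and a named sensitivity variant.
#'
#' @param mu Growth rate, d^-1 (> 0 required; a warning is issued
#'   outside the validated range 0.3-0.8 d^-1).
#' @param nh4 Ambient ammonium concentration, mmol m^-3 (>= 0).
#' @param irradiance Irradiance in umol photons m^-2 s^-1, or `NULL`
#'   for light-replete mode.
#' @param composition A [dda_composition()].
#' @param params A [dda_physiology()].
#' @param coeffs Allometric coefficients, as [default_allometry()].
#' @param variant Sensitivity variant name, see [apply_variant()].
#' @param warn_mu Set `FALSE` to silence the growth-rate range warning
#'   (used internally by sweeps).
#' @return An object of class `dda_scenario`, carrying the resolved
#'   quotas in `$quotas` (computed with the variant-adjusted C:N).
#' @examples
#' sc <- dda_scenario(mu = 0.51, nh4 = 0.01)
#' solve_steady_state(sc)
#' @export
dda_scenario <- function(mu, nh4 = 0, irradiance = NULL,
                         composition = dda_composition(),
                         params = dda_physiology(),
                         coeffs = default_allometry(),
                         variant = "none", warn_mu = TRUE) {
  mu <- check_positive(mu, "mu")
  if (length(nh4) != 1 || !is.finite(nh4) || nh4 < 0) {
    stop("nh4 must be >= 0, got ", deparse(nh4), call. = FALSE)
  }
  if (!is.null(irradiance) &&
      (length(irradiance) != 1 || !is.finite(irradiance) ||
       irradiance < 0)) {
    stop("irradiance must be >= 0 or NULL, got ", deparse(irradiance),
         call. = FALSE)
  }
  if (warn_mu && (mu < 0.3 || mu > 0.8)) {
    warning("growth rate ", mu,
            " d^-1 is outside the validated range 0.3-0.8 d^-1",
            call. = FALSE)
  }
  params <- apply_variant(params, variant)
  structure(
    list(mu = mu, nh4 = as.numeric(nh4),
         irradiance = if (is.null(irradiance)) NULL
                      else as.numeric(irradiance),
         composition = composition, params = params, coeffs = coeffs,
         variant = variant,
         quotas = build_quotas(composition, coeffs, params$rCN)),
    class = "dda_scenario"
  )
}

#' Monod ammonium uptake
#'
#' Uptake is performed by the diatom, scaled by its carbon quota:
#' `vmax_nh4 * QCD * nh4 / (nh4 + km_nh4)`; it rises monotonically and
#' saturates at `vmax_nh4 * QCD`.
#'
#' @param nh4 Ammonium concentration, mmol m^-3 (>= 0).
#' @param params A [dda_physiology()].
#' @param quotas A `dda_quotas` object.
#' @return Potential uptake, pmol N d^-1 per association.
#' @export
nh4_uptake <- function(nh4, params, quotas) {
  if (any(!is.finite(nh4)) || any(nh4 < 0)) {
    stop("nh4 must be >= 0, got ", deparse(nh4), call. = FALSE)
  }
  params$vmax_nh4 * quotas$QCD * nh4 / (nh4 + params$km_nh4)
}

#' N2 fixation required to close the nitrogen balance
#'
#' Whole-association N demand is `mu * (QNV + QNH + QND)`; fixation
#' supplies whatever uptake does not, floored at zero (when uptake
#' meets or exceeds demand there is no fixation).
#'
#' @param mu Growth rate, d^-1.
#' @param quotas A `dda_quotas` object.
#' @param uptake Ammonium uptake, pmol N d^-1 (>= 0).
#' @return Fixation rate, pmol N d^-1.
#' @export
n2_fixation_requirement <- function(mu, quotas, uptake) {
  stopifnot(all(uptake >= 0))
  pmax(0, mu * total_qn(quotas) - uptake)
}

#' Carbon cost of N2 fixation
#'
#' @param fn_fix Fixation rate, pmol N d^-1 (>= 0).
#' @param params A [dda_physiology()].
#' @return Cost, pmol C d^-1 (`fn_fix * fcn_fix`).
#' @export
fixation_c_cost <- function(fn_fix, params) {
  stopifnot(all(fn_fix >= 0))
  fn_fix * params$fcn_fix
}

#' Total photosynthesis required to close the carbon balance
#'
#' Growth plus respiration per compartment plus the fixation carbon
#' cost: `mu * [QCV(1+Ev) + QCH(1+Eh) + QCD(1+Ed)] + fc_fix_cost`.
#' With equal E this collapses to `mu * (sum QC) * (1+E) + fc_fix_cost`.
#'
#' @param mu Growth rate, d^-1.
#' @param quotas A `dda_quotas` object.
#' @param params A [dda_physiology()].
#' @param fc_fix_cost Fixation carbon cost, pmol C d^-1.
#' @return Required total photosynthesis, pmol C d^-1.
#' @export
total_photosynthesis <- function(mu, quotas, params, fc_fix_cost) {
  mu * (quotas$QCV * (1 + params$E_vegetative) +
        quotas$QCH * (1 + params$E_heterocyst) +
        quotas$QCD * (1 + params$E_diatom)) + fc_fix_cost
}

#' Split photosynthesis between diatom and vegetative cells
#'
#' Rates are proportional to the photosynthesizing compartments'
#' nitrogen quotas; heterocysts receive none.
#'
#' @param s_total Total photosynthesis, pmol C d^-1 (>= 0).
#' @param quotas A `dda_quotas` object.
#' @return Named numeric vector `c(f_pho_d, f_pho_v)`, pmol C d^-1.
#' @export
partition_photosynthesis <- function(s_total, quotas) {
  stopifnot(s_total >= 0)
  w <- quotas$QND / (quotas$QND + quotas$QNV)
  c(f_pho_d = s_total * w, f_pho_v = s_total * (1 - w))
}

#' Net carbon transfer from diatom to trichomes
#'
#' Trichome carbon demand (growth + respiration of vegetative cells
#' and heterocysts, plus the fixation cost paid in the heterocysts)
#' minus the carbon the trichome fixes itself. Positive means
#' diatom-to-trichome.
#'
#' @param mu Growth rate, d^-1.
#' @param quotas A `dda_quotas` object.
#' @param params A [dda_physiology()].
#' @param fc_fix_cost Fixation carbon cost, pmol C d^-1.
#' @param f_pho_v Vegetative photosynthesis, pmol C d^-1.
#' @return Signed transfer, pmol C d^-1.
#' @export
carbon_transfer <- function(mu, quotas, params, fc_fix_cost, f_pho_v) {
  mu * (quotas$QCV * (1 + params$E_vegetative) +
        quotas$QCH * (1 + params$E_heterocyst)) + fc_fix_cost - f_pho_v
}

#' Net nitrogen transfer from trichomes to diatom
#'
#' Diatom nitrogen demand minus its (effective) ammonium uptake.
#' Positive when fixation subsidizes the diatom; negative when uptake
#' exceeds diatom demand and the excess flows diatom-to-trichome; zero
#' at the no-transfer ammonium concentration.
#'
#' @param mu Growth rate, d^-1.
#' @param quotas A `dda_quotas` object.
#' @param v_eff Effective ammonium uptake, pmol N d^-1.
#' @return Signed transfer, pmol N d^-1.
#' @export
nitrogen_transfer <- function(mu, quotas, v_eff) {
  mu * quotas$QND - v_eff
}

#' Per-compartment light-limited photosynthesis capacity
#'
#' In light mode each photosynthesizing compartment has a saturating
#' light response `Pmax * (1 - exp(-alpha * I / Pmax))` with `Pmax`
#' proportional to its nitrogen quota (`pmax_per_n * QN`, the
#' vegetative maximum additionally scaled by
#' `pmax_factor_vegetative`) and one shared initial slope `alpha`.
#' Heterocysts never photosynthesize.
#'
#' @param irradiance Irradiance, umol photons m^-2 s^-1 (>= 0).
#' @param params A [dda_physiology()].
#' @param quotas A `dda_quotas` object.
#' @return List with `capacity_diatom`, `capacity_vegetative`,
#'   `capacity_total` (pmol C d^-1) and `pmax_diatom`,
#'   `pmax_vegetative`.
#' @export
light_limited_photosynthesis <- function(irradiance, params, quotas) {
  if (length(irradiance) != 1 || !is.finite(irradiance) ||
      irradiance < 0) {
    stop("irradiance must be >= 0, got ", deparse(irradiance),
         call. = FALSE)
  }
  pmax_d <- params$pmax_per_n * quotas$QND
  pmax_v <- params$pmax_per_n * quotas$QNV *
    params$pmax_factor_vegetative
  cap <- function(pmax) {
    if (pmax <= 0) return(0)
    pmax * (1 - exp(-params$alpha_light * irradiance / pmax))
  }
  cd <- cap(pmax_d)
  cv <- cap(pmax_v)
  list(capacity_diatom = cd, capacity_vegetative = cv,
       capacity_total = cd + cv, pmax_diatom = pmax_d,
       pmax_vegetative = pmax_v)
}

#' Solve the steady-state balance for one scenario
#'
#' Composes the balance in order: Monod uptake, fixation requirement
#' (with uptake clipped to total N demand when supply saturates, so
#' no nitrogen is wasted), fixation carbon cost, required total
#' photosynthesis, its partition between diatom and vegetative cells,
#' and the signed carbon and nitrogen transfers. In light mode the
#' partition weights each compartment by its light-limited capacity
#' instead of its nitrogen quota; a scenario whose summed capacity
#' cannot meet the required supply is flagged infeasible rather than
#' silently truncated.
#'
#' @param scenario A [dda_scenario()].
#' @return An object of class `dda_flux` with per-association daily
#'   fluxes: potential and effective uptake (`v_nh4_potential`,
#'   `v_nh4`), fixation and its cost (`fn_fix`, `fc_fix_cost`),
#'   photosynthesis (`s_pho_total`, `f_pho_d`, `f_pho_v`), signed
#'   transfers (`tc` positive diatom-to-trichome, `tn` positive
#'   trichome-to-diatom), relative balance residuals and a `feasible`
#'   flag.
#' @export
solve_steady_state <- function(scenario) {
  stopifnot(inherits(scenario, "dda_scenario"))
  p <- scenario$params
  q <- scenario$quotas
  mu <- scenario$mu

  v_pot <- nh4_uptake(scenario$nh4, p, q)
  demand_n <- mu * total_qn(q)
  v_eff <- min(v_pot, demand_n)
  fn_fix <- n2_fixation_requirement(mu, q, v_eff)
  fc_fix <- fixation_c_cost(fn_fix, p)
  s_total <- total_photosynthesis(mu, q, p, fc_fix)

  feasible <- TRUE
  capacity <- NULL
  if (is.null(scenario$irradiance)) {
    pho <- partition_photosynthesis(s_total, q)
  } else {
    capacity <- light_limited_photosynthesis(scenario$irradiance, p, q)
    if (capacity$capacity_total < s_total * (1 - 1e-12) ||
        (s_total > 0 && capacity$capacity_total == 0)) {
      feasible <- FALSE
      pho <- c(f_pho_d = NA_real_, f_pho_v = NA_real_)
    } else if (capacity$capacity_total == 0) { # s_total == 0 too
      pho <- c(f_pho_d = 0, f_pho_v = 0)
    } else {
      w <- capacity$capacity_diatom / capacity$capacity_total
      pho <- c(f_pho_d = s_total * w, f_pho_v = s_total * (1 - w))
    }
  }

  tc <- if (feasible) {
    carbon_transfer(mu, q, p, fc_fix, pho[["f_pho_v"]])
  } else NA_real_
  tn <- nitrogen_transfer(mu, q, v_eff)

  # residuals of the two balances, relative to total supply
  c_res <- if (feasible) {
    supply <- pho[["f_pho_d"]] + pho[["f_pho_v"]]
    cons <- mu * (q$QCV * (1 + p$E_vegetative) +
                  q$QCH * (1 + p$E_heterocyst) +
                  q$QCD * (1 + p$E_diatom)) + fc_fix
    (supply - cons) / max(supply, .Machine$double.eps)
  } else NA_real_
  n_res <- (fn_fix + v_eff - demand_n) /
    max(demand_n, .Machine$double.eps)

  structure(
    list(mu = mu, nh4 = scenario$nh4, irradiance = scenario$irradiance,
         variant = scenario$variant,
         v_nh4_potential = v_pot, v_nh4 = v_eff, fn_fix = fn_fix,
         fc_fix_cost = fc_fix, s_pho_total = s_total,
         f_pho_d = pho[["f_pho_d"]], f_pho_v = pho[["f_pho_v"]],
         tc = tc, tn = tn, c_residual = c_res, n_residual = n_res,
         feasible = feasible, capacity = capacity,
         quotas = q, params = p),
    class = "dda_flux"
  )
}

#' @export
print.dda_flux <- function(x, digits = 4, ...) {
  cat("DDA steady-state fluxes (pmol d^-1 per association)\n")
  cat("  scenario: mu =", x$mu, "d^-1, NH4+ =", x$nh4, "mmol m^-3",
      if (!is.null(x$irradiance))
        paste(", I =", x$irradiance, "umol photons m^-2 s^-1"),
      if (x$variant != "none") paste(", variant", x$variant), "\n")
  if (!x$feasible) {
    cat("  INFEASIBLE: light-limited capacity below required",
        "photosynthesis\n")
    return(invisible(x))
  }
  v <- c(uptake = x$v_nh4, fixation_N = x$fn_fix,
         fixation_C_cost = x$fc_fix_cost,
         photosynthesis = x$s_pho_total, pho_diatom = x$f_pho_d,
         pho_vegetative = x$f_pho_v, C_transfer = x$tc,
         N_transfer = x$tn)
  print(signif(v, digits))
  cat("  C transfer ", signif(100 * x$tc / x$s_pho_total, 3),
      "% of C supply; N transfer ",
      signif(100 * x$tn / (x$mu * total_qn(x$quotas)), 3),
      "% of N supply\n", sep = "")
  invisible(x)
}

threshold_root <- function(a, km) {
  if (a >= 1) {
    stop("demand exceeds maximum uptake capacity: no finite ",
         "threshold concentration (a = ", signif(a, 4), " >= 1)",
         call. = FALSE)
  }
  km * a / (1 - a)
}

#' Ammonium concentration at which net N transfer is zero
#'
#' Below this concentration the diatom's nitrogen demand exceeds its
#' uptake and fixed nitrogen flows trichome-to-diatom; above it the
#' flow reverses. Closed form: with `a = mu*QND / (vmax_nh4*QCD)`
#' (which reduces to `mu / (rCN * vmax_nh4)` since `QND = QCD/rCN`),
#' the threshold is `km_nh4 * a / (1 - a)`.
#'
#' @param mu Growth rate, d^-1.
#' @param params A [dda_physiology()].
#' @param quotas A `dda_quotas` object.
#' @return Concentration, mmol m^-3.
#' @examples
#' no_transfer_concentration(0.51, dda_physiology(),
#'                           build_quotas(dda_composition())) # ~0.034
#' @export
no_transfer_concentration <- function(mu, params,
                                      quotas = build_quotas(
                                        dda_composition(),
                                        rCN = params$rCN)) {
  stopifnot(mu >= 0)
  a <- mu * quotas$QND / (params$vmax_nh4 * quotas$QCD)
  threshold_root(a, params$km_nh4)
}

#' Ammonium concentration above which N2 fixation is zero
#'
#' The smallest concentration at which uptake alone covers the whole
#' association's nitrogen demand. Closed form with
#' `a = mu*(QNV+QNH+QND) / (vmax_nh4*QCD)`: `km_nh4 * a / (1 - a)`.
#' Always at least the no-transfer concentration at the same growth
#' rate.
#'
#' @inheritParams no_transfer_concentration
#' @return Concentration, mmol m^-3.
#' @export
zero_fixation_concentration <- function(mu, params,
                                        quotas = build_quotas(
                                          dda_composition(),
                                          rCN = params$rCN)) {
  stopifnot(mu >= 0)
  a <- mu * total_qn(quotas) / (params$vmax_nh4 * quotas$QCD)
  threshold_root(a, params$km_nh4)
}
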