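# Element-fate percentage budgets and parameter sweeps.

#' Percentage budget of carbon and nitrogen fates
#'
#' Decomposes a solved scenario into percent shares of total element
#' supply (equal to total consumption at steady state, so one base
#' serves both sides). Carbon supply splits into diatom and vegetative
#' photosynthesis; carbon consumption into growth and respiration of
#' the diatom and the trichome plus the fixation cost. Nitrogen supply
#' splits into fixation and uptake; nitrogen consumption into growth
#' per compartment. The two inter-partner transfers are reported as
#' percentages of the same bases (`n_transfer_percent` is signed,
#' positive trichome-to-diatom). `n_transfer_het_to_veg_percent`
#' additionally reports the heterocyst-to-vegetative leg of the fixed
#' nitrogen.
#'
#' @param solution A feasible `dda_flux` from [solve_steady_state()].
#' @return An object of class `dda_budget` (named list of percents).
#' @export
budget <- function(solution) {
  stopifnot(inherits(solution, "dda_flux"))
  if (!solution$feasible) {
    stop("cannot budget an infeasible solution", call. = FALSE)
  }
  q <- solution$quotas
  p <- solution$params
  mu <- solution$mu
  s <- solution$s_pho_total
  d <- mu * total_qn(q) # total N supply = consumption
  pc <- function(x, base) if (base > 0) 100 * x / base else 0

  # fixed N routed heterocyst -> vegetative cells: vegetative demand
  # not already covered by excess ammonium passed on by the diatom
  excess_uptake <- max(0, solution$v_nh4 - mu * q$QND)
  het_to_veg <- max(0, min(solution$fn_fix - max(0, solution$tn),
                           mu * q$QNV - excess_uptake))

  structure(list(
    c_supply = c(
      photosynthesis_diatom = pc(solution$f_pho_d, s),
      photosynthesis_vegetative = pc(solution$f_pho_v, s)
    ),
    c_consumption = c(
      growth_diatom = pc(mu * q$QCD, s),
      growth_trichome = pc(mu * (q$QCV + q$QCH), s),
      respiration_diatom = pc(mu * q$QCD * p$E_diatom, s),
      respiration_trichome = pc(mu * (q$QCV * p$E_vegetative +
                                      q$QCH * p$E_heterocyst), s),
      fixation_cost = pc(solution$fc_fix_cost, s)
    ),
    n_supply = c(
      fixation = pc(solution$fn_fix, d),
      uptake = pc(solution$v_nh4, d)
    ),
    n_consumption = c(
      growth_diatom = pc(mu * q$QND, d),
      growth_vegetative = pc(mu * q$QNV, d),
      growth_heterocyst = pc(mu * q$QNH, d)
    ),
    c_transfer_percent = pc(solution$tc, s),
    n_transfer_percent = pc(solution$tn, d),
    n_transfer_het_to_veg_percent = pc(het_to_veg, d)
  ), class = "dda_budget")
}

#' @export
print.dda_budget <- function(x, digits = 3, ...) {
  cat("Element-fate budget (% of total supply = consumption):\n")
  cat("  C supply:      ")
  print(signif(x$c_supply, digits))
  cat("  C consumption: ")
  print(signif(x$c_consumption, digits))
  cat("  N supply:      ")
  print(signif(x$n_supply, digits))
  cat("  N consumption: ")
  print(signif(x$n_consumption, digits))
  cat("  C transfer (diatom->trichome): ",
      signif(x$c_transfer_percent, digits), "%\n", sep = "")
  cat("  N transfer (trichome->diatom): ",
      signif(x$n_transfer_percent, digits), "%\n", sep = "")
  invisible(x)
}

budget_row <- function(b) {
  out <- c(
    stats::setNames(b$c_supply,
                    paste0("c_supply_", names(b$c_supply))),
    stats::setNames(b$c_consumption,
                    paste0("c_cons_", names(b$c_consumption))),
    stats::setNames(b$n_supply,
                    paste0("n_supply_", names(b$n_supply))),
    stats::setNames(b$n_consumption,
                    paste0("n_cons_", names(b$n_consumption))),
    c_transfer_percent = b$c_transfer_percent,
    n_transfer_percent = b$n_transfer_percent,
    n_transfer_het_to_veg_percent = b$n_transfer_het_to_veg_percent
  )
  out
}

flux_row <- function(sol) {
  c(v_nh4_potential = sol$v_nh4_potential, v_nh4 = sol$v_nh4,
    fn_fix = sol$fn_fix, fc_fix_cost = sol$fc_fix_cost,
    s_pho_total = sol$s_pho_total, f_pho_d = sol$f_pho_d,
    f_pho_v = sol$f_pho_v, tc = sol$tc, tn = sol$tn,
    c_residual = sol$c_residual, n_residual = sol$n_residual)
}

sweep_axes <- c("nh4", "mu", "n_trichomes", "irradiance")

#' Sweep scenarios over a parameter grid
#'
#' Evaluates the model over the Cartesian product of the requested
#' axes (drawn from `nh4`, `mu`, `n_trichomes`, `irradiance`), in
#' row-major order with the first listed axis varying slowest. Each
#' grid point yields one record of flux and budget fields; infeasible
#' or failing points are flagged in the `status` column with their
#' numeric fields left `NA`, and never abort the sweep.
#'
#' @param axes Named list of non-empty value vectors.
#' @param mu,nh4,irradiance,composition,params,coeffs,variant Base
#'   scenario values, overridden per grid point by the axes.
#' @return A data.frame, one row per grid point.
#' @examples
#' sw <- sweep_scenarios(list(nh4 = c(0, 0.02, 0.04)), mu = 0.51)
#' sw[, c("nh4", "c_transfer_percent")]
#' @export
sweep_scenarios <- function(axes, mu = 0.51, nh4 = 0,
                            irradiance = NULL,
                            composition = dda_composition(),
                            params = dda_physiology(),
                            coeffs = default_allometry(),
                            variant = "none") {
  if (!is.list(axes) || is.null(names(axes)) ||
      any(names(axes) == "")) {
    stop("axes must be a named list", call. = FALSE)
  }
  bad <- setdiff(names(axes), sweep_axes)
  if (length(bad)) {
    stop("unknown sweep axis: ", paste(bad, collapse = ", "),
         "; valid axes are ", paste(sweep_axes, collapse = ", "),
         call. = FALSE)
  }
  if (any(lengths(axes) == 0)) {
    stop("every sweep axis must be non-empty", call. = FALSE)
  }
  # expand.grid varies the first factor fastest; reverse to make the
  # first listed axis the slowest (row-major over axes as listed)
  grid <- do.call(expand.grid,
                  c(rev(axes), KEEP.OUT.ATTRS = FALSE))
  grid <- grid[, rev(seq_along(axes)), drop = FALSE]
  names(grid) <- names(axes)

  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    point <- as.list(grid[i, , drop = FALSE])
    comp_i <- composition
    if (!is.null(point$n_trichomes)) {
      comp_i <- dda_composition(
        n_trichomes = point$n_trichomes,
        vegetative_per_trichome = composition$vegetative_per_trichome,
        heterocysts_per_trichome =
          composition$heterocysts_per_trichome,
        volume_diatom = composition$volume_diatom,
        volume_vegetative = composition$volume_vegetative,
        volume_heterocyst = composition$volume_heterocyst)
    }
    rec <- tryCatch({
      sc <- dda_scenario(
        mu = if (is.null(point$mu)) mu else point$mu,
        nh4 = if (is.null(point$nh4)) nh4 else point$nh4,
        irradiance = if (is.null(point$irradiance)) irradiance
                     else point$irradiance,
        composition = comp_i, params = params, coeffs = coeffs,
        variant = variant, warn_mu = FALSE)
      sol <- solve_steady_state(sc)
      if (!sol$feasible) {
        list(status = "infeasible", values = NULL)
      } else {
        list(status = "ok",
             values = c(flux_row(sol), budget_row(budget(sol))))
      }
    }, error = function(e) {
      list(status = paste0("error: ", conditionMessage(e)),
           values = NULL)
    })
    rows[[i]] <- rec
  }

  # column template from the first successful record (or a reference
  # solve) keeps every row homogeneous
  template <- NULL
  for (rec in rows) {
    if (!is.null(rec$values)) { template <- names(rec$values); break }
  }
  if (is.null(template)) {
    ref <- solve_steady_state(dda_scenario(mu = mu, nh4 = nh4,
                                           composition = composition,
                                           params = params,
                                           coeffs = coeffs,
                                           warn_mu = FALSE))
    template <- names(c(flux_row(ref), budget_row(budget(ref))))
  }
  mat <- do.call(rbind, lapply(rows, function(rec) {
    if (is.null(rec$values)) {
      stats::setNames(rep(NA_real_, length(template)), template)
    } else rec$values[template]
  }))
  out <- cbind(grid, as.data.frame(mat),
               data.frame(status = vapply(rows, `[[`, "", "status"),
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Threshold ammonium concentrations over growth rates
#'
#' @param mu Vector of growth rates, d^-1.
#' @param params A [dda_physiology()].
#' @param quotas A `dda_quotas` object.
#' @return data.frame with columns `mu`, `no_transfer_nh4`,
#'   `zero_fixation_nh4` (mmol m^-3; `NA` where no finite root
#'   exists).
#' @export
threshold_table <- function(mu, params = dda_physiology(),
                            quotas = build_quotas(dda_composition(),
                                                  rCN = params$rCN)) {
  safe <- function(f, m) tryCatch(f(m, params, quotas),
                                  error = function(e) NA_real_)
  data.frame(
    mu = mu,
    no_transfer_nh4 =
      vapply(mu, function(m) safe(no_transfer_concentration, m),
             numeric(1)),
    zero_fixation_nh4 =
      vapply(mu, function(m) safe(zero_fixation_concentration, m),
             numeric(1))
  )
}
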