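test_that("ammonium uptake follows Monod kinetics", {
  p <- default_params()
  q <- default_quotas()
  expect_identical(nh4_uptake(0, p, q), 0)
  expect_equal(nh4_uptake(p$km_nh4, p, q),
               0.5 * p$vmax_nh4 * q$QCD, tolerance = 1e-12)
  expect_equal(nh4_uptake(1e9, p, q), p$vmax_nh4 * q$QCD,
               tolerance = 1e-6)
  conc <- seq(0, 0.5, by = 0.01)
  expect_true(all(diff(nh4_uptake(conc, p, q)) > 0))
  expect_error(nh4_uptake(-0.1, p, q), "nh4")
})

test_that("fixation closes the N balance and is floored at zero", {
  p <- default_params()
  q <- default_quotas()
  demand <- 0.51 * (q$QND + q$QNV + q$QNH)
  expect_equal(n2_fixation_requirement(0.51, q, 0), demand)
  expect_identical(n2_fixation_requirement(0.51, q, demand), 0)
  expect_identical(n2_fixation_requirement(0.51, q, demand * 2), 0)

  # hand-arithmetic oracle at mu = 0.51, nh4 = 0.04:
  # demand minus Monod uptake 1.16 * QCD * 0.04/(0.04 + 0.483)
  uptake <- 1.16 * q$QCD * 0.04 / 0.523
  expect_equal(n2_fixation_requirement(0.51, q, uptake),
               demand - uptake, tolerance = 1e-12)
  expect_equal(demand - uptake, 0.15995, tolerance = 1e-4)
})

test_that("fixation carbon cost is a linear product", {
  p <- dda_physiology(fcn_fix = 2.2)
  expect_identical(fixation_c_cost(0, p), 0)
  expect_equal(fixation_c_cost(1, p), 2.2)
  a <- 0.3; b <- 1.7
  expect_equal(fixation_c_cost(a + b, p),
               fixation_c_cost(a, p) + fixation_c_cost(b, p))
})

test_that("required photosynthesis covers growth, respiration and fixation", {
  p <- default_params()
  q <- default_quotas()
  expect_identical(total_photosynthesis(0, q, p, 0), 0)

  # direct substitution oracle, equal E = 0.38, mu = 0.51, nh4 = 0
  mu <- 0.51
  fn <- mu * (q$QND + q$QNV + q$QNH)
  fc <- fn * p$fcn_fix
  s <- total_photosynthesis(mu, q, p, fc)
  expect_equal(s, mu * (q$QCD + q$QCV + q$QCH) * 1.38 + fc,
               tolerance = 1e-12)

  # doubling only the vegetative E raises the total by mu*QCV*0.38
  p2 <- apply_variant(p, "double_vegetative_E")
  expect_equal(total_photosynthesis(mu, q, p2, fc) - s,
               mu * q$QCV * 0.38, tolerance = 1e-12)
})

test_that("photosynthesis partitions by N quota and conserves", {
  q <- default_quotas()
  pho <- partition_photosynthesis(10, q)
  expect_equal(sum(pho), 10, tolerance = 1e-12)
  expect_equal(pho[["f_pho_d"]] / 10, q$QND / (q$QND + q$QNV),
               tolerance = 1e-12)
  expect_equal(pho[["f_pho_d"]] / 10, 0.850224, tolerance = 1e-6)

  # symmetric quotas split evenly
  qeq <- q
  qeq$QNV <- qeq$QND
  pe <- partition_photosynthesis(8, qeq)
  expect_equal(pe[["f_pho_d"]], pe[["f_pho_v"]])
})

test_that("steady-state solutions balance both elements", {
  grid <- expand.grid(mu = c(0.3, 0.51, 0.8),
                      nh4 = c(0, 0.01, 0.036, 0.1, 1))
  for (i in seq_len(nrow(grid))) {
    sol <- solve_at(grid$mu[i], grid$nh4[i])
    expect_true(sol$feasible)
    expect_lt(abs(sol$c_residual), 1e-9)
    expect_lt(abs(sol$n_residual), 1e-9)
    expect_gte(sol$fn_fix, 0)
    expect_gte(sol$v_nh4, 0)
    expect_lte(sol$v_nh4, sol$params$vmax_nh4 * sol$quotas$QCD + 1e-12)
    expect_equal(sol$f_pho_d + sol$f_pho_v, sol$s_pho_total,
                 tolerance = 1e-12)
  }
})

test_that("supersaturating ammonium caps effective uptake, not fixation", {
  sol <- solve_at(0.4, 5) # far above the zero-fixation point
  q <- sol$quotas
  expect_identical(sol$fn_fix, 0)
  expect_lt(sol$v_nh4, sol$v_nh4_potential)
  expect_equal(sol$v_nh4, 0.4 * (q$QND + q$QNV + q$QNH),
               tolerance = 1e-12)
})

test_that("fluxes are monotone in ammonium at fixed growth rate", {
  conc <- seq(0, 0.08, by = 0.005)
  sols <- lapply(conc, function(n) solve_at(0.51, n))
  g <- function(f) vapply(sols, `[[`, numeric(1), f)
  expect_true(all(diff(g("fn_fix")) <= 1e-12))
  expect_true(all(diff(g("fc_fix_cost")) <= 1e-12))
  expect_true(all(diff(g("s_pho_total")) <= 1e-12))
  expect_true(all(diff(g("tc")) <= 1e-12))
  expect_true(all(diff(g("tn")) <= 1e-12))
  expect_true(all(diff(g("v_nh4")) >= -1e-12))
})

test_that("fluxes are monotone in growth rate at fixed ammonium", {
  mus <- seq(0.3, 0.8, by = 0.05)
  sols <- lapply(mus, function(m) solve_at(m, 0.01))
  g <- function(f) vapply(sols, `[[`, numeric(1), f)
  expect_true(all(diff(g("fn_fix")) >= -1e-12))
  expect_true(all(diff(g("s_pho_total")) >= -1e-12))
  expect_true(all(diff(g("tc")) >= -1e-12))
})

test_that("rescaling all quotas rescales fluxes, not percentages", {
  k <- 3.7
  sc1 <- dda_scenario(0.51, 0.02, warn_mu = FALSE)
  sc2 <- sc1
  for (f in c("QCD", "QCV", "QCH", "QND", "QNV", "QNH")) {
    sc2$quotas[[f]] <- k * sc2$quotas[[f]]
  }
  s1 <- solve_steady_state(sc1)
  s2 <- solve_steady_state(sc2)
  for (f in c("v_nh4", "fn_fix", "fc_fix_cost", "s_pho_total",
              "f_pho_d", "f_pho_v", "tc", "tn")) {
    expect_equal(s2[[f]], k * s1[[f]], tolerance = 1e-9, label = f)
  }
  expect_equal(s2$tc / s2$s_pho_total, s1$tc / s1$s_pho_total,
               tolerance = 1e-12)
  q1 <- sc1$quotas; q2 <- sc2$quotas
  p <- sc1$params
  expect_equal(no_transfer_concentration(0.51, p, q2),
               no_transfer_concentration(0.51, p, q1),
               tolerance = 1e-12)
  expect_equal(zero_fixation_concentration(0.51, p, q2),
               zero_fixation_concentration(0.51, p, q1),
               tolerance = 1e-12)
})

test_that("equal respiration ratios collapse to the single-E balance", {
  p <- dda_physiology(E_diatom = 0.2, E_vegetative = 0.2,
                      E_heterocyst = 0.2, fcn_fix = 2)
  q <- default_quotas()
  fc <- 1.3
  expect_equal(total_photosynthesis(0.6, q, p, fc),
               0.6 * (q$QCD + q$QCV + q$QCH) * 1.2 + fc,
               tolerance = 1e-12)
})
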