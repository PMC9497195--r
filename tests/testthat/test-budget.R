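test_that("budget shares sum to 100 on both sides of both elements", {
  for (case in list(c(0.4, 0.01), c(0.8, 0.01), c(0.4, 0.036),
                    c(0.8, 0.036), c(0.51, 0))) {
    b <- budget(solve_at(case[1], case[2]))
    expect_equal(sum(b$c_supply), 100, tolerance = 1e-6)
    expect_equal(sum(b$c_consumption), 100, tolerance = 1e-6)
    expect_equal(sum(b$n_supply), 100, tolerance = 1e-6)
    expect_equal(sum(b$n_consumption), 100, tolerance = 1e-6)
  }
})

test_that("fixation and uptake shares are complementary across nh4", {
  for (n in seq(0, 0.05, by = 0.01)) {
    b <- budget(solve_at(0.51, n))
    expect_equal(b$n_supply[["fixation"]] + b$n_supply[["uptake"]],
                 100, tolerance = 1e-9)
  }
})

test_that("budget percentages are invariant under quota rescaling", {
  sc <- dda_scenario(0.4, 0.01)
  sck <- sc
  for (f in c("QCD", "QCV", "QCH", "QND", "QNV", "QNH")) {
    sck$quotas[[f]] <- 2.5 * sck$quotas[[f]]
  }
  b1 <- budget(solve_steady_state(sc))
  b2 <- budget(solve_steady_state(sck))
  expect_equal(b2$c_supply, b1$c_supply, tolerance = 1e-9)
  expect_equal(b2$n_supply, b1$n_supply, tolerance = 1e-9)
  expect_equal(b2$c_transfer_percent, b1$c_transfer_percent,
               tolerance = 1e-9)
  expect_equal(b2$n_transfer_percent, b1$n_transfer_percent,
               tolerance = 1e-9)
})

test_that("the four study corners order as low/high growth and ammonium", {
  ct <- function(mu, nh4) budget(solve_at(mu, nh4))$c_transfer_percent
  fx <- function(mu, nh4) {
    budget(solve_at(mu, nh4))$n_supply[["fixation"]]
  }
  lgln <- ct(0.4, 0.01);  hgln <- ct(0.8, 0.01)
  lghn <- ct(0.4, 0.036); hghn <- ct(0.8, 0.036)
  # printed pattern 19 < 21 and 9 < 16; high-ammonium corners lowest
  expect_lt(lghn, hghn)
  expect_lt(hghn, lgln)
  expect_lt(lgln, hgln)
  expect_lt(fx(0.4, 0.01), fx(0.8, 0.01))
  # higher growth widens the gap more at high ammonium (7 vs 2 points)
  expect_gt(hghn - lghn, hgln - lgln)
})

test_that("more trichomes mean more transfer to them and less back", {
  sols <- lapply(1:5, function(k) {
    solve_at(0.51, 0.01, composition = dda_composition(n_trichomes = k))
  })
  tc <- vapply(sols, `[[`, numeric(1), "tc")
  fn <- vapply(sols, `[[`, numeric(1), "fn_fix")
  ntp <- vapply(sols, function(s) budget(s)$n_transfer_percent,
                numeric(1))
  expect_true(all(diff(tc) > 0))
  expect_true(all(diff(fn) > 0))
  # the diatom-bound share of the N supply shrinks as the trichomes'
  # own demand grows
  expect_true(all(diff(ntp) < 0))
})

test_that("sweeps enumerate the grid row-major and deterministically", {
  sw <- sweep_scenarios(list(nh4 = c(0, 0.01, 0.02, 0.03, 0.04)),
                        mu = 0.51)
  expect_equal(nrow(sw), 5)
  expect_true(all(sw$status == "ok"))
  expect_true(all(diff(sw$c_transfer_percent) < 0))
  expect_equal(sw$c_transfer_percent[1], 22.7, tolerance = 0.01)
  expect_equal(sw$c_transfer_percent[5], 11.1, tolerance = 0.05)

  # 2-axis grid: row-major over axes as listed (first axis slowest)
  sw2 <- sweep_scenarios(list(nh4 = c(0, 0.01, 0.02, 0.03, 0.04),
                              mu = seq(0.3, 0.8, by = 0.1)))
  expect_equal(nrow(sw2), 30)
  expect_equal(sw2$nh4, rep(c(0, 0.01, 0.02, 0.03, 0.04), each = 6))
  expect_equal(sw2$mu, rep(seq(0.3, 0.8, by = 0.1), times = 5))

  # single-point sweep reproduces the direct solution
  one <- sweep_scenarios(list(nh4 = 0.02), mu = 0.51)
  sol <- solve_at(0.51, 0.02)
  expect_equal(one$tc, sol$tc, tolerance = 1e-12)
  expect_equal(one$fn_fix, sol$fn_fix, tolerance = 1e-12)

  # byte-identical CSV on identical input
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_records(sw2, f1, "csv")
  write_records(sweep_scenarios(list(nh4 = c(0, 0.01, 0.02, 0.03, 0.04),
                                     mu = seq(0.3, 0.8, by = 0.1))),
                f2, "csv")
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("infeasible grid points are flagged, not fatal", {
  sw <- sweep_scenarios(list(irradiance = c(0, 5, 500)), mu = 0.51,
                        nh4 = 0.01)
  expect_equal(sw$status[1], "infeasible")
  expect_true(is.na(sw$tc[1]))
  expect_equal(sw$status[3], "ok")
  expect_error(sweep_scenarios(list(depth = 1:3)), "unknown sweep axis")
  expect_error(sweep_scenarios(list(nh4 = numeric(0))), "non-empty")
})

test_that("sensitivity variants modify only their parameter", {
  p <- default_params()
  expect_identical(apply_variant(p, "none"), p)
  pd <- apply_variant(p, "double_vegetative_E")
  expect_equal(pd$E_vegetative, 0.76)
  expect_equal(pd$E_diatom, 0.38)
  expect_equal(pd$E_heterocyst, 0.38)
  ph <- apply_variant(p, "half_vegetative_pmax")
  expect_equal(ph$pmax_factor_vegetative, 0.5)
  expect_error(apply_variant(p, "triple_E"), "unknown variant")

  # doubled vegetative respiration keeps the qualitative picture
  conc <- seq(0, 0.04, by = 0.01)
  base <- vapply(conc, function(n) solve_at(0.51, n)$tc, numeric(1))
  dbl <- vapply(conc, function(n) {
    solve_at(0.51, n, variant = "double_vegetative_E")$tc
  }, numeric(1))
  expect_true(all(diff(base) < 0) && all(diff(dbl) < 0))
  expect_true(all(dbl > base)) # extra respiration raises trichome need
})
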