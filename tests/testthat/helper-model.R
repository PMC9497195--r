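# Shared fixtures: every object is built in code at test time.

default_quotas <- function() build_quotas(dda_composition())

default_params <- function(...) dda_physiology(...)

# independent hand-arithmetic oracle for the allometric conversion:
# pg C = 10^(a + b log10 V); pmol C = pg C / 12.011
oracle_quota_pmol <- function(volume, a, b) {
  (10^a * volume^b) / 12.011
}

solve_at <- function(mu, nh4, ...) {
  solve_steady_state(dda_scenario(mu = mu, nh4 = nh4, warn_mu = FALSE,
                                  ...))
}

c_transfer_percent_at <- function(mu, nh4, ...) {
  sol <- solve_at(mu, nh4, ...)
  100 * sol$tc / sol$s_pho_total
}
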