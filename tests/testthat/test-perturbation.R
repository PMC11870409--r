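control_traj <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_constitutive(ref, m2)
    cache
  }
})

test_that("inhibition specs validate and scale the target parameter", {
  expect_error(inhibition_spec("alpha", 1.2, "chemical"), "\\[0, 1\\]")
  expect_error(inhibition_spec("alpha", -0.1, "genetic"), "\\[0, 1\\]")
  inh <- inhibition_spec("beta", 0.25, "chemical")
  expect_equal(inh$target, "beta")
  # f = 0 leaves the trajectory identical to the control
  t0 <- simulate_inhibited(ref, inhibition_spec("beta", 0, "chemical"),
                           m2)
  expect_equal(t0$X, control_traj()$X, tolerance = 1e-10)
  expect_equal(t0$I, control_traj()$I, tolerance = 1e-10)
})

test_that("genetic inhibition rescales steady states analytically", {
  # 90% inhibition of production: intracellular pool at exactly 0.1x
  tg <- simulate_inhibited(ref, inhibition_spec("alpha", 0.9,
                                                "genetic"), m2)
  fc <- fold_changes(tg, control_traj(), times = c(18, 72))
  expect_equal(fc$fold_change, rep(0.1, 4), tolerance = 1e-4)
  expect_equal(fc$log2_fold_change, rep(log2(0.1), 4),
               tolerance = 1e-3)
  # genetic inhibition of extracellular degradation leaves I untouched
  td <- simulate_inhibited(ref, inhibition_spec("delta", 0.7,
                                                "genetic"), m2)
  expect_lt(max(rel_err(td$I, control_traj()$I)), 1e-4)
  # genetic fold change of I matches the ratio of analytic steady states
  tb <- simulate_inhibited(ref, inhibition_spec("beta", 0.9, "genetic"),
                           m2)
  p <- unclass(ref)
  expected <- (p[["beta"]] + p[["gamma"]]) /
    (0.1 * p[["beta"]] + p[["gamma"]])
  got <- fold_changes(tb, control_traj(), times = 50, "I")$fold_change
  expect_equal(got, expected, tolerance = 1e-3)
})

test_that("chemical and genetic modes agree where theory says they must", {
  # delta only affects the extracellular equation, whose initial value is
  # reset in both modes: time courses coincide exactly
  for (sp in c("I", "X")) {
    tc <- simulate_inhibited(ref, inhibition_spec("delta", 0.9,
                                                  "chemical"), m2)
    tg <- simulate_inhibited(ref, inhibition_spec("delta", 0.9,
                                                  "genetic"), m2)
    expect_lt(max(abs(tc[[sp]] - tg[[sp]]) / pmax(tg[[sp]], 1)), 1e-6)
  }
  # beta/gamma: the two modes differ only in the intracellular starting
  # level; started from the inhibited steady state, the chemical
  # protocol reproduces the genetic time course
  for (target in c("beta", "gamma")) {
    inh <- inhibition_spec(target, 0.9, "chemical")
    inhibited <- sflt1sim:::.apply_inhibition(ref, inh)
    tg <- simulate_inhibited(ref, inhibition_spec(target, 0.9,
                                                  "genetic"), m2)
    tc_eq <- simulate_constitutive(inhibited, m2)
    expect_lt(max(abs(tc_eq$X - tg$X) / pmax(tg$X, 1)), 1e-5)
  }
  # and the two modes converge to the same state at long times
  # (about ten times the slowest timescale of the perturbed system)
  p <- unclass(ref)
  slow <- 1 / min(0.1 * p[["beta"]] + p[["gamma"]], p[["delta"]])
  cfg_long <- scenario_config("constitutive",
                              duration = ceiling(10 * slow))
  tcl <- simulate_inhibited(ref, inhibition_spec("beta", 0.9,
                                                 "chemical"), m2,
                            cfg_long)
  tgl <- simulate_inhibited(ref, inhibition_spec("beta", 0.9,
                                                 "genetic"), m2,
                            cfg_long)
  tend <- max(tcl$time_h)
  expect_lt(rel_err(trajectory_values(tcl, tend, "X"),
                    trajectory_values(tgl, tend, "X")), 1e-3)
  expect_lt(rel_err(trajectory_values(tcl, tend, "I"),
                    trajectory_values(tgl, tend, "I")), 1e-3)
})

test_that("fold-change inversion round-trips and flags infeasible observations", {
  cfg <- scenario_config("constitutive", duration = 24)
  # round trip at a known inhibition fraction
  truth <- 0.5
  tr <- simulate_inhibited(ref, inhibition_spec("beta", truth,
                                                "chemical"), m2, cfg)
  ctrl <- simulate_constitutive(ref, m2, cfg)
  obs <- fold_changes(tr, ctrl, 18, "X")$fold_change
  inv <- invert_inhibition(obs, "X", 18, "beta", "chemical", ref, m2,
                           cfg)
  expect_true(inv$feasible)
  expect_equal(inv$f, truth, tolerance = 1e-3)
  # intracellular accumulation beyond the full-inhibition ceiling
  inv2 <- invert_inhibition(5, "I", 18, "beta", "chemical", ref, m2,
                            cfg)
  expect_false(inv2$feasible)
  expect_match(inv2$verdict, "exceeds full inhibition")
  expect_lt(inv2$response_range[2], 2) # ceiling below a 2-fold rise
  # observed decrease where the response can only increase
  inv3 <- invert_inhibition(0.8, "I", 18, "beta", "chemical", ref, m2,
                            cfg)
  expect_false(inv3$feasible)
  expect_match(inv3$verdict, "wrong direction")
  # the delay has no constitutive response at all
  inv4 <- invert_inhibition(1.2, "X", 18, "tau", "chemical", ref, m2,
                            cfg)
  expect_false(inv4$feasible)
  expect_match(inv4$verdict, "insensitive")
})

test_that("inhibition scans expose the parameter-set dependence of responses", {
  cc <- compound_constants(ref)
  p <- unclass(ref)
  scan <- inhibition_scan(cc$c1, cc$c2, p[["delta"]], p[["tau"]],
                          beta_fractions = c(0.2, 0.6, 1),
                          targets = c("alpha", "beta"),
                          fractions = c(0, 0.5, 0.9),
                          times = 18, modes = "chemical",
                          cfg = scenario_config("constitutive",
                                                duration = 24))
  # no inhibition: all fold changes are 1
  f0 <- scan[scan$f == 0, ]
  expect_equal(f0$fold_change, rep(1, nrow(f0)), tolerance = 1e-6)
  # production inhibition is independent of the baseline parameter set
  a9 <- scan[scan$target == "alpha" & scan$f == 0.9 &
               scan$species == "X", ]
  expect_lt(diff(range(a9$fold_change)) / mean(a9$fold_change), 1e-3)
  # higher baseline beta makes I more responsive to beta inhibition
  b9 <- scan[scan$target == "beta" & scan$f == 0.9 &
               scan$species == "I" & scan$time_h == 18, ]
  b9 <- b9[order(b9$beta_fraction), ]
  expect_true(all(diff(b9$fold_change) > 0))
})
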