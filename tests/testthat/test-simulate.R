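test_that("integrate_segment reproduces closed-form kinetics", {
  # no-delay model started at (I_SS, 0): I stays put because production
  # balances removal exactly, so X follows X_SS * (1 - e^(-delta t))
  ss <- steady_state(ref_m1)
  seg <- integrate_segment(ref_m1, m1, c(I = ss$I_SS, X = 0), NULL,
                           c(0, 48), "constitutive")
  d <- unclass(ref)[["delta"]]
  expected <- ss$X_SS * (1 - exp(-d * seg$time_h))
  expect_lt(max(rel_err(seg$X[-1], expected[-1])), 1e-3)
  expect_lt(max(rel_err(seg$I, ss$I_SS)), 1e-6)
  # all-zero rates: constant trajectory
  z <- sflt_params(0, 0, 0, 0)
  segz <- integrate_segment(z, m1, c(I = 5, X = 7), NULL, c(0, 5),
                            "constitutive")
  expect_equal(range(segz$I), c(5, 5))
  expect_equal(range(segz$X), c(7, 7))
  # delayed model from steady state with constant history reaches X_SS
  ss2 <- steady_state(ref)
  seg2 <- integrate_segment(ref, m2, c(I = ss2$I_SS, X = 0), ss2$I_SS,
                            c(0, 72), "constitutive")
  expect_lt(rel_err(seg2$X[nrow(seg2)],
                    ss2$X_SS * (1 - exp(-d * 72))), 5e-3)
})

test_that("pre-simulation reaches the theoretical steady state", {
  ss <- run_to_steady_state(ref, m2)
  expect_lt(rel_err(ss$state[["I"]], steady_state(ref)$I_SS), 0.005)
  expect_gt(ss$t_converged, 20)
  # history covers the delay lookback and is continuous at 0
  expect_equal(ss$history(0), ss$state[["I"]])
  expect_gt(ss$history(-unclass(ref)[["tau"]]), 0)
  # no production: converges immediately at I = 0
  p0 <- sflt_params(0, 0.05, 0.1, 0.06)
  ss0 <- run_to_steady_state(p0, m1)
  expect_equal(ss0$state[["I"]], 0)
  # gamma = 0 member of the constraint family: I_SS = alpha / beta
  cc <- compound_constants(ref)
  p_g0 <- params_from_beta(cc$c2, cc$c1, cc$c2, 0.05743, 1.958)
  ssg <- run_to_steady_state(p_g0, m2)
  expect_lt(rel_err(ssg$state[["I"]],
                    unclass(p_g0)[["alpha"]] / unclass(p_g0)[["beta"]]),
            0.005)
})

test_that("constitutive protocol: media change resets X, I stays at steady state", {
  traj <- simulate_constitutive(ref, m2)
  expect_equal(nrow(traj), 72 * 60 + 1)
  # reset contract
  expect_equal(traj$X[1], 0)
  expect_equal(traj$I[1], attr(traj, "presim")$state[["I"]])
  # intracellular level undisturbed by the media change
  expect_lt(max(rel_err(traj$I, steady_state(ref)$I_SS)), 0.005)
  # strictly increasing times, non-negative values
  expect_true(all(diff(traj$time_h) > 0))
  expect_true(all(traj$I >= 0) && all(traj$X >= 0))
  # extracellular half-time matches ln2/delta on the grid
  x_end <- steady_state(ref)$X_SS
  t_half <- traj$time_h[which(traj$X >= x_end / 2)[1]]
  expect_equal(t_half, log(2) / unclass(ref)[["delta"]],
               tolerance = 5e-3)
  # no production: identically zero
  tz <- simulate_constitutive(sflt_params(0, 0.05, 0.1, 0.06), m1)
  expect_equal(max(tz$I), 0)
  expect_equal(max(tz$X), 0)
})

test_that("pulse-chase protocol gates labeled secretion by the maturation delay", {
  traj <- simulate_pulse_chase(ref, m2)
  tau <- unclass(ref)[["tau"]]
  pl <- 1 / 3
  # no labeled protein reaches the medium before tau - pulse_length
  early <- traj$time_h > 0 & traj$time_h < tau - pl - 0.02
  expect_equal(max(traj$X[early]), 0)
  expect_gt(trajectory_values(traj, tau + 1, "X"), 0)
  # I continuous across the media change; X reset to 0
  chase0 <- traj[traj$phase == "chase", ][1, ]
  expect_equal(chase0$X, 0)
  # the chase starts from the pulse-phase intracellular level at t = 0
  expect_equal(chase0$I, attr(traj, "I_history")(-1e-9),
               tolerance = 1e-6)
  # without the delay, secretion of labeled protein starts immediately
  traj1 <- simulate_pulse_chase(ref_m1, m1)
  expect_gt(trajectory_values(traj1, 0.2, "X"), 0)
  # no production: nothing anywhere
  tz <- simulate_pulse_chase(sflt_params(0, 0.05, 0.1, 0.06), m1)
  expect_equal(max(tz$I) + max(tz$X), 0)
})

test_that("the system is linear in the production rate", {
  v <- unclass(ref)
  v["alpha"] <- v["alpha"] * 3.7
  ref_scaled <- do.call(sflt_params, as.list(v))
  a <- simulate_constitutive(ref, m2)
  b <- simulate_constitutive(ref_scaled, m2)
  expect_lt(max(rel_err(b$I, 3.7 * a$I)), 1e-4)
  expect_lt(max(abs(b$X - 3.7 * a$X) / pmax(3.7 * a$X, 1)), 1e-4)
  pa <- simulate_pulse_chase(ref, m2)
  pb <- simulate_pulse_chase(ref_scaled, m2)
  expect_lt(max(abs(pb$I - 3.7 * pa$I) / pmax(3.7 * pa$I, 1)), 1e-4)
})

test_that("the delayed model approaches the ODE model as tau -> 0", {
  v <- unclass(ref)
  v["tau"] <- 1e-6
  p_tiny <- do.call(sflt_params, as.list(v))
  a <- simulate_constitutive(p_tiny, m2,
                             scenario_config("constitutive",
                                             duration = 24))
  b <- simulate_constitutive(ref_m1, m1,
                             scenario_config("constitutive",
                                             duration = 24))
  expect_lt(max(rel_err(a$I, b$I)), 1e-3)
  expect_lt(max(abs(a$X - b$X) / pmax(b$X, 1)), 1e-3)
})

test_that("finite differences of X match the mass-flow balance", {
  traj <- simulate_constitutive(ref, m2)
  fx <- fluxes(traj)
  dt <- diff(traj$time_h)
  # central differences on the 1-minute grid
  mid <- 2:(nrow(traj) - 1)
  dXdt <- (traj$X[mid + 1] - traj$X[mid - 1]) / (dt[mid] + dt[mid - 1])
  balance <- fx$phi_secr[mid] - fx$phi_xdeg[mid] - fx$phi_int[mid]
  scale <- max(abs(balance))
  expect_lt(max(abs(dXdt - balance)) / scale, 1e-2)
})

test_that("trajectory normalization and export behave as documented", {
  traj <- simulate_constitutive(ref, m2)
  norm <- normalize_trajectory(traj, anchor_X = 24, anchor_I = 0)
  expect_equal(trajectory_values(norm, 24, "X"), 1)
  expect_equal(trajectory_values(norm, 0, "I"), 1)
  expect_equal(trajectory_values(norm, 72, "X"),
               trajectory_values(traj, 72, "X") /
                 trajectory_values(traj, 24, "X"))
  # normalization removes the production-rate scale entirely
  v <- unclass(ref)
  v["alpha"] <- v["alpha"] * 10
  norm2 <- normalize_trajectory(
    simulate_constitutive(do.call(sflt_params, as.list(v)), m2),
    anchor_X = 24, anchor_I = 0)
  expect_lt(max(abs(norm2$X - norm$X)), 1e-4)
  expect_error(normalize_trajectory(traj, anchor_X = 100), "outside")
  tmp <- withr::local_tempfile(fileext = ".csv")
  export_trajectory(traj, tmp)
  tidy <- read.csv(tmp)
  expect_equal(nrow(tidy), 2 * nrow(traj))
  expect_setequal(unique(tidy$species), c("I", "X"))
})
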