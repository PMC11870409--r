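test_that("model table is a bijection between labels and process flags", {
  ids <- paste0("M", 1:8)
  specs <- lapply(ids, sflt_model)
  keys <- vapply(specs, function(m) {
    paste(m$has_delay, m$has_production_decay, m$has_internalization)
  }, character(1))
  expect_equal(length(unique(keys)), 8)
  expect_false(any(unlist(sflt_model("M1")[c("has_delay",
                                             "has_production_decay",
                                             "has_internalization")])))
  expect_true(sflt_model("M2")$has_delay)
  expect_false(sflt_model("M2")$has_production_decay)
  expect_false(sflt_model("M2")$has_internalization)
  # flag -> id lookup inverts id -> flag
  for (m in specs) {
    expect_identical(
      sflt_model(has_delay = m$has_delay,
                 has_production_decay = m$has_production_decay,
                 has_internalization = m$has_internalization)$model_id,
      m$model_id)
  }
  expect_error(sflt_model("M9"), "unknown model_id")
})

test_that("parameter validation enforces non-negativity and model consistency", {
  expect_error(sflt_params(-1, 1, 1, 1), "non-negative")
  expect_error(sflt_params(NA, 1, 1, 1), "finite")
  p_tau <- sflt_params(1e5, 0.05, 0.1, 0.06, tau = 2)
  expect_error(check_params(p_tau, m1), "must be 0")
  expect_silent(check_params(p_tau, m2))
  expect_equal(active_parameters(m1),
               c("alpha", "beta", "gamma", "delta"))
  expect_equal(length(active_parameters(sflt_model("M8"))), 7)
})

test_that("rate terms reproduce the piecewise model equations", {
  # constitutive production from an empty system: dI/dt = alpha
  r <- rate_terms(list(I = 0, X = 0), 0, ref_m1, m1, "constitutive")
  expect_equal(r[["dI"]], 1.419e5)
  expect_equal(r[["dX"]], 0)
  # null system
  z <- sflt_params(0, 0, 0, 0)
  expect_equal(unname(rate_terms(list(I = 0, X = 0), 0, z, m1, "presim")),
               c(0, 0))
  # delayed model at steady state: both derivatives vanish
  ss <- steady_state(ref)
  r2 <- rate_terms(list(I = ss$I_SS, X = ss$X_SS), delayed_I = ss$I_SS,
                   ref, m2, "constitutive")
  expect_equal(unname(r2), c(0, 0), tolerance = 1e-10)
  # chase production: off without decay, exponential with decay
  r3 <- rate_terms(list(I = 1e5, X = 0), 1e5, ref, m2, "chase",
                   t_since_chase = 1)
  expect_equal(r3[["dI"]], -(0.05123 + 0.1215) * 1e5)
  m5 <- sflt_model("M5")
  p5 <- sflt_params(1.419e5, 0.05123, 0.1215, 0.05743, tau = 1.958,
                    kappa = 0.5)
  r4 <- rate_terms(list(I = 0, X = 0), 0, p5, m5, "chase",
                   t_since_chase = 2)
  expect_equal(r4[["dI"]], 1.419e5 * exp(-0.5 * 2))
  # internalization moves molecules from X to I
  m4 <- sflt_model("M4")
  p4 <- sflt_params(0, 0, 0, 0, epsilon = 0.3)
  r5 <- rate_terms(list(I = 0, X = 100), 0, p4, m4, "constitutive")
  expect_equal(r5[["dI"]], 30)
  expect_equal(r5[["dX"]], -30)
  expect_error(rate_terms(list(I = -1, X = 0), 0, ref, m2,
                          "constitutive"),
               "non-negative")
})

test_that("closed-form steady state matches the reference values", {
  ss <- steady_state(ref)
  # reported ensemble median steady state ~8.2e5 #/cell
  expect_equal(ss$I_SS, 8.2e5, tolerance = 0.01)
  expect_equal(ss$I_SS, 1.419e5 / (0.05123 + 0.1215), tolerance = 1e-12)
  expect_equal(ss$X_SS, 7.328e5, tolerance = 1e-3)
  expect_equal(ss$T50_X, 12.07, tolerance = 1e-3)
  expect_equal(ss$X_SS, unclass(ref)[["beta"]] / unclass(ref)[["delta"]] *
                 ss$I_SS)
  # no production -> empty steady state
  ss0 <- steady_state(sflt_params(0, 0.05, 0.1, 0.06))
  expect_equal(ss0$I_SS, 0)
  expect_equal(ss0$X_SS, 0)
  expect_error(steady_state(sflt_params(1, 0, 0, 0.1)), "degenerate")
  expect_error(steady_state(sflt_params(1, 0.1, 0.1, 0)), "degenerate")
})

test_that("compound constants match the reference table and identities", {
  cc <- compound_constants(ref)
  expect_equal(cc$c1, 7.269e3, tolerance = 1e-3)
  expect_equal(cc$c2, 1.727e-1, tolerance = 1e-3)
  # hourly removal of mature intracellular protein stays below 20%/h
  expect_lt(cc$c2, 0.20)
  expect_equal(compound_constants(sflt_params(5, 0, 0.3, 1))$c1, 0)
  expect_equal(compound_constants(sflt_params(5, 0, 0.3, 1))$c2, 0.3)
  # algebraic identity I_SS * c2 = alpha, to 10 significant digits
  for (p in list(ref, sflt_params(3e4, 0.9, 0.02, 0.3),
                 sflt_params(1e7, 1e-3, 2, 1e-2))) {
    expect_equal(steady_state(p)$I_SS * compound_constants(p)$c2,
                 unclass(p)[["alpha"]], tolerance = 1e-10)
  }
})

test_that("params_from_beta satisfies the constraints exactly", {
  cc <- compound_constants(ref)
  d <- unclass(ref)[["delta"]]
  # beta = c2: no intracellular degradation left
  p_hi <- params_from_beta(cc$c2, cc$c1, cc$c2, d, tau = 1.958)
  expect_equal(unclass(p_hi)[["gamma"]], 0)
  expect_equal(unclass(p_hi)[["alpha"]], cc$c1 / cc$c2)
  # beta = c2/2 splits removal evenly
  p_mid <- params_from_beta(cc$c2 / 2, cc$c1, cc$c2, d)
  expect_equal(unclass(p_mid)[["gamma"]], cc$c2 / 2)
  # arithmetic from the reference compound constants
  p_lo <- params_from_beta(0.2 * cc$c2, cc$c1, cc$c2, d)
  expect_equal(unclass(p_lo)[["alpha"]], cc$c1 / (0.2 * cc$c2))
  expect_error(params_from_beta(1.5 * cc$c2, cc$c1, cc$c2, d),
               "constraint violation")
  expect_error(params_from_beta(0, cc$c1, cc$c2, d),
               "constraint violation")
  # round trip: compound_constants o params_from_beta is the identity
  for (b in c(0.2, 0.5, 1) * cc$c2) {
    cc2 <- compound_constants(params_from_beta(b, cc$c1, cc$c2, d))
    expect_equal(cc2$c1, cc$c1, tolerance = 1e-14)
    expect_equal(cc2$c2, cc$c2, tolerance = 1e-14)
  }
})

test_that("theoretical bounds follow from the compound constants", {
  cc <- compound_constants(ref)
  b <- theoretical_bounds(cc)
  expect_equal(b$min_I_SS, cc$c1 / cc$c2^2)
  expect_equal(b$min_I_SS, 2.44e5, tolerance = 0.01)
  expect_equal(b$min_alpha, cc$c1 / cc$c2)
  expect_equal(b$max_beta, cc$c2)
  expect_equal(theoretical_bounds(1, 1),
               list(min_I_SS = 1, min_alpha = 1, max_beta = 1,
                    max_gamma = 1))
  # every constraint-consistent parameter set respects the bounds
  for (bfrac in c(0.2, 0.6, 1)) {
    p <- params_from_beta(bfrac * cc$c2, cc$c1, cc$c2, 0.057, 1.958)
    expect_gte(steady_state(p)$I_SS, b$min_I_SS * (1 - 1e-12))
    expect_gte(unclass(p)[["alpha"]], b$min_alpha * (1 - 1e-12))
    expect_lte(unclass(p)[["beta"]], b$max_beta * (1 + 1e-12))
  }
})

test_that("parameter sets serialize to and from flat key-value files", {
  tmp_yaml <- withr::local_tempfile(fileext = ".yaml")
  write_params(ref, tmp_yaml)
  back <- read_params(tmp_yaml)
  expect_equal(unclass(back), unclass(ref), tolerance = 1e-12)
  expect_equal(params_model(back)$model_id, "M2")
  tmp_json <- withr::local_tempfile(fileext = ".json")
  write_params(ref, tmp_json)
  back2 <- read_params(tmp_json)
  expect_equal(unclass(back2), unclass(ref), tolerance = 1e-12)
})
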