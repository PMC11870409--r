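test_that("the packaged synthetic ELISA-style fixture loads and validates", {
  path <- system.file("extdata", "synthetic_hornig_like.csv",
                      package = "sflt1sim")
  ds <- load_dataset(path)
  expect_s3_class(ds, "sflt_dataset")
  expect_equal(unique(ds$observations$species), "X")
  expect_equal(ds$units, "absolute_concentration")
  expect_equal(ds$scenario, "constitutive")
  expect_true(any(ds$observations$excluded))
  expect_false(is.null(ds$conversion))
})

test_that("dataset validation rejects malformed inputs", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines("time_h,species,value", tmp)
  expect_error(load_dataset(tmp), "empty")
  obs <- data.frame(time_h = c(1, 2), species = c("X", "Q"),
                    value = c(1, 2))
  expect_error(new_dataset("d", "constitutive", obs, "relative",
                           anchor_time_X = 1),
               "unknown species in rows 2")
  obs2 <- data.frame(time_h = c(1, 2), species = "X", value = c(1, -2))
  expect_error(new_dataset("d", "constitutive", obs2, "relative",
                           anchor_time_X = 1),
               "negative values in rows 2")
  obs3 <- data.frame(time_h = 1, species = "I", value = 1)
  expect_error(new_dataset("d", "constitutive", obs3, "relative"),
               "anchor_time_I")
})

test_that("preprocessing drops exclusions, averages replicates, and is idempotent", {
  obs <- data.frame(
    time_h = c(1, 1, 1, 2, 2, 2, 3),
    species = "X",
    value = c(1, 2, 3, 5, 5, 5, 9),
    replicate = c(1, 2, 3, 1, 2, 3, 1),
    excluded = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  ds <- new_dataset("d", "constitutive", obs, "relative",
                    anchor_time_X = 2)
  pp <- preprocess_dataset(ds)
  expect_equal(pp$observations$time_h, c(1, 2))
  expect_equal(pp$observations$value, c(2, 5)) # means of {1,2,3}, {5,5,5}
  expect_false(3 %in% pp$observations$time_h)  # excluded point dropped
  expect_identical(preprocess_dataset(pp)$observations,
                   pp$observations)
  # single-replicate data with no exclusions pass through unchanged
  obs1 <- data.frame(time_h = c(2, 1), species = "X", value = c(5, 2))
  ds1 <- preprocess_dataset(new_dataset("d1", "constitutive", obs1,
                                        "relative", anchor_time_X = 2))
  expect_equal(ds1$observations$value, c(2, 5)) # sorted by time
  # identical replicates collapse to the same values as one replicate
  obs3 <- obs1[rep(1:2, each = 3), ]
  obs3$replicate <- rep(1:3, 2)
  ds3 <- preprocess_dataset(new_dataset("d3", "constitutive", obs3,
                                        "relative", anchor_time_X = 2))
  expect_equal(ds3$observations$value, ds1$observations$value)
})

test_that("predictions convert #/cell into each dataset's units", {
  traj <- simulate_constitutive(ref, m2)
  # relative dataset: prediction at the anchor is exactly 1
  obs <- data.frame(time_h = c(8, 24, 72), species = "X",
                    value = c(0.5, 1, 1.6))
  ds_rel <- new_dataset("rel", "constitutive", obs, "relative",
                        anchor_time_X = 24)
  pred <- predict_in_dataset_units(traj, ds_rel)
  expect_equal(pred$predicted[pred$time_h == 24], 1)
  # identity conversion factor recovers #/cell
  avogadro <- 6.02214076e23
  conv1 <- list(cells_per_volume = 1, molar_mass = avogadro / 1e9)
  ds_abs <- new_dataset("abs", "constitutive", obs,
                        "absolute_concentration", conversion = conv1)
  pred_abs <- predict_in_dataset_units(traj, ds_abs)
  expect_equal(pred_abs$predicted,
               trajectory_values(traj, obs$time_h, "X"),
               tolerance = 1e-12)
  # doubling production doubles absolute but not relative predictions
  v <- unclass(ref)
  v["alpha"] <- 2 * v["alpha"]
  traj2 <- simulate_constitutive(do.call(sflt_params, as.list(v)), m2)
  pred2_abs <- predict_in_dataset_units(traj2, ds_abs)
  pred2_rel <- predict_in_dataset_units(traj2, ds_rel)
  expect_equal(pred2_abs$predicted / pred_abs$predicted, rep(2, 3),
               tolerance = 1e-4)
  expect_equal(pred2_rel$predicted, pred$predicted, tolerance = 1e-4)
  # missing conversion constants are an error for absolute data
  ds_bad <- new_dataset("abs2", "constitutive", obs,
                        "absolute_concentration")
  expect_error(predict_in_dataset_units(traj, ds_bad), "conversion")
})

test_that("datasets round-trip through CSV plus sidecar", {
  ds <- noiseless_datasets()[[2]]
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, tmp)
  back <- load_dataset(tmp)
  expect_equal(back$observations$value, ds$observations$value,
               tolerance = 1e-12)
  expect_equal(back$units, ds$units)
  expect_equal(back$anchor_time_X, ds$anchor_time_X)
})
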