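test_that("the factorial grid enumerates all configurations uniquely", {
  grid <- enumerate_grid()
  expect_equal(nrow(grid), 4 * 3 * 2 * 3 * 2 * 8 * 3 * 2)
  expect_equal(anyDuplicated(grid), 0L)
  slice <- enumerate_grid(dataset = "flowers", prep = "ground",
                          resolution = 16)
  expect_equal(nrow(slice), 384L)
  expect_equal(nrow(enumerate_grid(prep = "ground")), 3456L)
  expect_error(enumerate_grid(reduction = "RS4"), "unknown level")
})

test_that("the rank-stratified split protects extremes and keeps replicates together", {
  cfg <- synth_config(n_samples_by_group = flowers_counts_n(16), seed = 5)
  ds <- generate_dataset(cfg, the_standards)
  sp <- split_calibration_validation(ds, "RUT")
  expect_length(sp$validation, 4L)
  expect_length(sp$calibration, 12L)
  y <- vapply(ds$records, function(r) r$reference[["RUT"]], numeric(1))
  expect_true(names(which.min(y)) %in% sp$calibration)
  expect_true(names(which.max(y)) %in% sp$calibration)
  expect_length(intersect(sp$calibration, sp$validation), 0L)
  expect_error(split_calibration_validation(
    generate_dataset(synth_config(n_samples_by_group = data.frame(
      species = "F. esculentum", plant_part = "flower", prep = "ground",
      n = 5), seed = 1), the_standards), "RUT"), "at least 8")
})

test_that("model verdicts follow the SD thresholds with non-strict RMSE bounds", {
  m <- list(r_cal = 0.91, r_val = 1.00, rmsec = 0.30, rmsev = 0.09)
  v <- evaluate_model(m, sd = 0.1)  # RMSEC sits exactly at 3xSD
  expect_true(v$useful)
  expect_true(v$hplc_comparable)
  v2 <- evaluate_model(list(r_cal = 1, r_val = 1, rmsec = 0, rmsev = 0), 0.5)
  expect_true(v2$hplc_comparable)
  v3 <- evaluate_model(list(r_cal = 1, r_val = 1, rmsec = 0, rmsev = 1), 0.5)
  expect_true(v3$useful)
  expect_false(v3$hplc_comparable)
  v4 <- evaluate_model(list(r_cal = 0.89, r_val = 1, rmsec = 0, rmsev = 0), 0.5)
  expect_false(v4$useful)
  expect_error(evaluate_model(m, 0), "sd")
})

test_that("run_config executes the pipeline and reports row structure", {
  ds <- noise_free_flowers()
  b <- resolution_bundle(ds)
  cfg <- list(flavonoid = "RUT", dataset = "flowers", prep = "ground",
              resolution = 4, replicates = "separate", chain = "SNV",
              reduction = "RS1", aux_vars = FALSE)
  m <- run_config(b, the_standards, cfg)
  # separate replicates: validation rows = 3 x validation samples
  expect_equal(nrow(m$predictions$validation),
               3L * length(m$split$validation))
  expect_s3_class(m$model, "pls1")
  expect_equal(m$row$chain, "SNV")

  # aux variables: 7 species dummies on a single-part dataset
  cfg$aux_vars <- TRUE
  m2 <- run_config(b, the_standards, cfg)
  expect_equal(length(m2$model$x_mean),
               length(m$model$x_mean) + 7L)
})

test_that("noise-free mixtures are recovered exactly by the reference configuration", {
  ds <- noise_free_flowers()
  b <- resolution_bundle(ds)
  cfg <- list(flavonoid = "RUT", dataset = "flowers", prep = "ground",
              resolution = 4, replicates = "averaged", chain = "none",
              reduction = "RS3", aux_vars = FALSE)
  m <- run_config(b, the_standards, cfg)
  expect_equal(m$metrics$r_val, 1, tolerance = 1e-6)
  expect_lte(m$metrics$rmsev, 1e-6)
  expect_true(m$verdict$hplc_comparable)
})

test_that("run_search aggregates rows, survives failures and is deterministic", {
  ds <- noise_free_flowers()  # ground flowers only
  b <- resolution_bundle(ds)
  grid <- enumerate_grid(flavonoid = "RUT", dataset = c("flowers", "leaves"),
                         prep = "ground", resolution = 16,
                         replicates = "averaged", chain = c("none", "SNV"),
                         reduction = "RS3")
  rep1 <- run_search(b, the_standards, grid)
  expect_equal(nrow(rep1), nrow(grid))
  # leaf configurations fail (no leaf samples) but are recorded
  leaf_rows <- rep1[rep1$dataset == "leaves", ]
  expect_true(all(!is.na(leaf_rows$error)))
  expect_true(all(is.na(rep1$error[rep1$dataset == "flowers"])))
  rep2 <- run_search(b, the_standards, grid)
  expect_identical(as.data.frame(rep1), as.data.frame(rep2))
  s <- summary(rep1)
  expect_equal(s$n, nrow(grid))
  f <- withr::local_tempfile(fileext = ".csv")
  j <- withr::local_tempfile(fileext = ".json")
  write_search_report(rep1, f, j)
  expect_equal(nrow(read.csv(f)), nrow(grid))
  expect_true(jsonlite::read_json(j)$n_configurations == nrow(grid))
})

test_that("validation references never influence masks or calibration fits", {
  cfg <- synth_config(n_samples_by_group = flowers_counts_n(20), seed = 9)
  ds <- generate_dataset(cfg, the_standards)
  b <- resolution_bundle(ds)
  config <- list(flavonoid = "RUT", dataset = "flowers", prep = "ground",
                 resolution = 8, replicates = "averaged", chain = "SNV+deriv",
                 reduction = "RS1", aux_vars = FALSE)
  m1 <- run_config(b, the_standards, config)
  # rank-preserving perturbation of the validation references only
  ds2 <- ds
  for (id in m1$split$validation) {
    ref <- ds2$records[[id]]$reference
    ref[["RUT"]] <- ref[["RUT"]] + 1e-4
    ref[["SUM"]] <- ref[["QE"]] + ref[["QI"]] + ref[["RUT"]]
    ds2$records[[id]]$reference <- ref
  }
  b2 <- resolution_bundle(ds2)
  m2 <- run_config(b2, the_standards, config)
  expect_identical(m2$split, m1$split)
  expect_identical(m2$mask$kept_indices, m1$mask$kept_indices)
  expect_identical(m2$model$regression_vector, m1$model$regression_vector)
  expect_identical(m2$metrics$r_cal, m1$metrics$r_cal)
  expect_false(identical(m2$metrics$rmsev, m1$metrics$rmsev))

  # RS2 masks are likewise untouched
  config$reduction <- "RS2"
  expect_identical(run_config(b2, the_standards, config)$mask$kept_indices,
                   run_config(b, the_standards, config)$mask$kept_indices)
})

test_that("ground-sample configurations yield more useful models than whole-sample ones", {
  counts <- rbind(flowers_counts_n(16),
                  transform(flowers_counts_n(16), prep = "whole"))
  cfg <- synth_config(n_samples_by_group = counts, seed = 33)
  ds <- generate_dataset(cfg, the_standards)
  b <- resolution_bundle(ds)
  grid <- enumerate_grid(flavonoid = c("QE", "RUT"), dataset = "flowers",
                         resolution = 16,
                         chain = c("none", "deriv", "SNV", "SNV+deriv"),
                         aux_vars = FALSE)
  rep <- run_search(b, the_standards, grid)
  frac <- tapply(rep$useful, rep$prep, mean)
  expect_gt(frac[["ground"]], frac[["whole"]])
})
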