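test_that("standard spectra are non-negative, concentrated in the band regions, and full rank", {
  std <- the_standards
  g <- std$QE$wavenumbers
  expect_length(g, 876)
  rm <- region_mask(g)
  for (s in std) {
    expect_true(all(s$absorbance >= 0))
    expect_gte(sum(s$absorbance[rm]) / sum(s$absorbance), 0.9)
  }
  S <- cbind(std$QE$absorbance, std$QI$absorbance, std$RUT$absorbance)
  expect_equal(qr(crossprod(S))$rank, 3L)
  # pairwise correlated (shared flavonol core) yet linearly independent
  expect_true(all(cor(S)[upper.tri(diag(3))] > 0.8))
  # determinism
  std2 <- generate_standard_spectra(0)
  expect_identical(std2$RUT$absorbance, std$RUT$absorbance)
  # a different seed perturbs band heights
  expect_false(identical(generate_standard_spectra(1)$RUT$absorbance,
                         std$RUT$absorbance))
})

test_that("generated datasets honor the sample inventory and replicate structure", {
  ds <- noise_free_flowers()
  expect_length(ds, 17L)  # 14 + 1 + 1 + 1 ground flower samples
  expect_equal(sum(vapply(ds$records, function(r) length(r$replicates),
                          integer(1))), 51L)
  sp <- table(vapply(ds$records, `[[`, character(1), "species"))
  expect_equal(unname(sp[["F. esculentum"]]), 14L)
})

test_that("generation is deterministic in (config, seed) and SUM is the component sum", {
  cfg <- synth_config(n_samples_by_group = flower_ground_counts(), seed = 11)
  d1 <- generate_dataset(cfg, the_standards)
  d2 <- generate_dataset(cfg, the_standards)
  expect_identical(d1$records[[5]]$replicates[[2]]$absorbance,
                   d2$records[[5]]$replicates[[2]]$absorbance)
  expect_identical(reference_matrix(d1), reference_matrix(d2))
  refs <- reference_matrix(d1)
  expect_equal(refs[, "SUM"], rowSums(refs[, c("QE", "QI", "RUT")]))
})

test_that("the noise-free configuration yields exact mixtures and exact references", {
  ds <- noise_free_flowers()
  # references equal truth
  for (rec in ds$records) {
    expect_equal(rec$reference[c("QE", "QI", "RUT")],
                 rec$true_concentration[c("QE", "QI", "RUT")])
    # replicates are identical (no heterogeneity, no noise)
    expect_equal(rec$replicates[[1]]$absorbance, rec$replicates[[2]]$absorbance)
    expect_equal(rec$replicates[[1]]$absorbance, rec$replicates[[3]]$absorbance)
  }
  # spectra differ between samples only through the Beer-Lambert term:
  # two samples of the same species satisfy A1 - A2 = E (c1 - c2)
  recs <- ds$records[vapply(ds$records, `[[`, character(1),
                            "species") == "F. esculentum"]
  E <- cbind(the_standards$QE$absorbance, the_standards$QI$absorbance,
             the_standards$RUT$absorbance) * 0.005
  dA <- recs[[1]]$replicates[[1]]$absorbance - recs[[2]]$replicates[[1]]$absorbance
  dc <- recs[[1]]$true_concentration[1:3] - recs[[2]]$true_concentration[1:3]
  expect_equal(dA, as.vector(E %*% dc), tolerance = 1e-10)
})

test_that("noise-free concentrations are linearly identifiable per sample", {
  ds <- noise_free_flowers()
  # blank dataset (all ranges 0-0) isolates the plant-matrix spectrum
  cr <- default_concentration_ranges()
  cr$low <- 0; cr$high <- 0
  blank_cfg <- synth_config_noise_free(
    n_samples_by_group = data.frame(species = "F. esculentum",
                                    plant_part = "flower", prep = "ground",
                                    n = 1),
    concentration_ranges = cr, seed = 1)
  blank <- generate_dataset(blank_cfg, the_standards)
  M <- blank$records[[1]]$replicates[[1]]$absorbance
  E <- cbind(the_standards$QE$absorbance, the_standards$QI$absorbance,
             the_standards$RUT$absorbance) * 0.005
  design <- cbind(E, M)
  for (rec in ds$records[c(1, 9, 17)]) {
    beta <- qr.solve(design, rec$replicates[[1]]$absorbance)
    expect_equal(unname(beta[1:3]), unname(rec$true_concentration[1:3]),
                 tolerance = 1e-8)
    expect_equal(unname(beta[4]), 1, tolerance = 1e-8)
  }
})

test_that("reference noise matches the configured HPLC SD (Monte Carlo)", {
  cfg <- synth_config(n_samples_by_group = flowers_counts_n(40), seed = 1)
  ds <- generate_dataset(cfg, the_standards)
  err <- vapply(ds$records, function(r) {
    r$reference[["RUT"]] - r$true_concentration[["RUT"]]
  }, numeric(1))
  s <- sd(err)
  expect_gte(s, 0.5 * 3)  # configured flower RUT SD is 3 mg/g
  expect_lte(s, 1.5 * 3)
})

test_that("invalid generator configurations are rejected", {
  cr <- default_concentration_ranges()
  cr$low[1] <- cr$high[1] + 1
  expect_error(synth_config(concentration_ranges = cr), "low.*high")
  expect_error(synth_config(noise_sd = -1), ">= 0")
  expect_error(synth_config(replicate_heterogeneity_whole = 0.01,
                            replicate_heterogeneity_ground = 0.05),
               "heterogeneity")
})

test_that("resolution degradation preserves constants, lengths and band areas", {
  g4 <- canonical_grid(4)
  const <- ftir_spectrum(g4, rep(0.3, length(g4)), 4)
  out <- degrade_resolution(const, 16)
  expect_length(out$absorbance, 219)
  expect_equal(out$absorbance, rep(0.3, 219), tolerance = 1e-12)

  sp <- random_spectrum(4)
  expect_length(degrade_resolution(sp, 8)$absorbance, 438)
  expect_error(degrade_resolution(degrade_resolution(sp, 16), 8), "finer")
  expect_identical(degrade_resolution(sp, 4), sp)

  # broad bands (FWHM >= 4x target) keep their integrated area within 1%
  a <- exp(-((g4 - 1500) / (64 / (2 * sqrt(log(2)))))^2) +
    0.6 * exp(-((g4 - 2800) / (80 / (2 * sqrt(log(2)))))^2)
  band <- ftir_spectrum(g4, a, 4)
  out16 <- degrade_resolution(band, 16)
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  area0 <- trapz(g4, a)
  area1 <- trapz(out16$wavenumbers, out16$absorbance)
  expect_lt(abs(area1 - area0) / area0, 0.01)
})

test_that("additive noise shrinks when degrading to coarser resolution", {
  g4 <- canonical_grid(4)
  set.seed(3)
  noise <- ftir_spectrum(g4, rnorm(length(g4), 0, 1), 4)
  out <- degrade_resolution(noise, 16)
  expect_lt(sd(out$absorbance), 0.6 * sd(noise$absorbance))
})
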