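test_that("canonical grids have the documented spacing, origin and length", {
  g4 <- canonical_grid(4)
  expect_length(g4, 876)
  expect_equal(g4[1], 500)
  expect_equal(g4[length(g4)], 4000)
  g16 <- canonical_grid(16)
  expect_length(g16, 219)
  expect_equal(g16[length(g16)], 3988)
  g8 <- canonical_grid(8)
  expect_equal(g8[1], 500)
  expect_true(all(diff(g8) == 8))
  expect_length(g8, 438)
  expect_error(canonical_grid(2), "resolution")
})

test_that("spectrum construction validates grid and lengths", {
  g <- canonical_grid(16)
  expect_s3_class(ftir_spectrum(g, rep(0.1, length(g)), 16), "ftir_spectrum")
  expect_error(ftir_spectrum(g, rep(0.1, 10), 16), "length")
  expect_error(ftir_spectrum(rev(g), rep(0.1, length(g)), 16), "increasing")
  expect_error(ftir_spectrum(g, rep(0.1, length(g)), 8), "spacing")
})

test_that("replicate averaging is the pointwise mean and precedes pretreatment", {
  g <- canonical_grid(16)
  n <- length(g)
  mk <- function(a) ftir_spectrum(g, a, 16)
  s <- abs(sin(g / 300)) + 0.1
  rec <- ftir_sample("s1", "F. esculentum", "flower", "ground",
                     list(mk(s), mk(s), mk(s)),
                     c(QE = 1, QI = 2, RUT = 3))
  expect_equal(average_replicates(rec)$absorbance, s)

  r1 <- c(0, rep(0.2, n - 1)); r2 <- c(0, rep(0.4, n - 1)); r3 <- c(3, rep(0.3, n - 1))
  rec2 <- ftir_sample("s2", "F. esculentum", "flower", "ground",
                      list(mk(r1), mk(r2), mk(r3)),
                      c(QE = 1, QI = 2, RUT = 3))
  expect_equal(average_replicates(rec2)$absorbance[1], 1)  # mean of 0,0,3

  # SNV does not commute with the mean: averaging must happen on raw spectra
  reps <- list(c(1, 2, 4, 8), c(10, 11, 12, 14), c(2, 6, 7, 9))
  mean_of_snv <- rowMeans(sapply(reps, snv))
  snv_of_mean <- snv(rowMeans(sapply(reps, identity)))
  expect_false(isTRUE(all.equal(mean_of_snv, snv_of_mean)))
})

test_that("sample records validate species, replicates and references", {
  g <- canonical_grid(16)
  mk <- function() ftir_spectrum(g, runif(length(g)), 16)
  reps <- list(mk(), mk(), mk())
  expect_error(ftir_sample("x", "F. vulgare", "flower", "ground", reps,
                           c(QE = 1, QI = 1, RUT = 1)), "unknown species")
  expect_error(ftir_sample("x", "F. esculentum", "flower", "ground",
                           reps[1:2], c(QE = 1, QI = 1, RUT = 1)),
               "3 replicate")
  expect_error(ftir_sample("x", "F. esculentum", "flower", "ground", reps,
                           c(QE = 1, QI = 1, RUT = -1)), "negative")
  expect_error(ftir_sample("x", "F. esculentum", "flower", "ground", reps,
                           c(QE = 1, QI = 1, RUT = 1, SUM = 5)), "SUM")
  rec <- ftir_sample("x", "F. esculentum", "flower", "ground", reps,
                     c(QE = 1, QI = 2, RUT = 3))
  expect_equal(unname(rec$reference[["SUM"]]), 6)
})

test_that("subset selection filters parts and preps and rejects empty results", {
  ds <- noise_free_flowers()
  expect_length(select_subset(ds, plant_part = "flower"), 17L)
  expect_length(select_subset(ds), 17L)  # no filter is the identity
  expect_error(select_subset(ds, plant_part = "leaf"), "empty")
})

test_that("dataset write/read round-trip is lossless", {
  ds <- noise_free_flowers()
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(file.path(dir, "spectra.csv"),
                       file.path(dir, "metadata.csv"))
  expect_length(back, length(ds))
  expect_equal(back$resolution, ds$resolution)
  for (id in names(ds$records)) {
    for (k in 1:3) {
      expect_equal(back$records[[id]]$replicates[[k]]$absorbance,
                   ds$records[[id]]$replicates[[k]]$absorbance,
                   tolerance = 1e-12)
    }
    expect_equal(back$records[[id]]$reference, ds$records[[id]]$reference,
                 tolerance = 1e-12)
  }
  # 17 samples -> 51 replicate columns + wavenumber
  hdr <- read.csv(file.path(dir, "spectra.csv"), comment.char = "#",
                  check.names = FALSE, nrows = 1)
  expect_equal(ncol(hdr) - 1L, 51L)
})

test_that("read_dataset reports located validation errors", {
  ds <- noise_free_flowers()
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  meta <- read.csv(file.path(dir, "metadata.csv"), comment.char = "#",
                   check.names = FALSE)
  meta$RUT[3] <- NA
  ftirq:::.write_csv_with_header(meta, file.path(dir, "metadata.csv"), 4)
  expect_error(read_dataset(file.path(dir, "spectra.csv"),
                            file.path(dir, "metadata.csv")),
               paste0(meta$sample_id[3], ".*RUT"))

  # a missing replicate column is named in the error
  write_dataset(ds, dir)
  sp <- read.csv(file.path(dir, "spectra.csv"), comment.char = "#",
                 check.names = FALSE)
  drop <- sprintf("%s:rep2", names(ds$records)[1])
  sp[[drop]] <- NULL
  ftirq:::.write_csv_with_header(sp, file.path(dir, "spectra.csv"), 4)
  expect_error(read_dataset(file.path(dir, "spectra.csv"),
                            file.path(dir, "metadata.csv")),
               "rep2", fixed = TRUE)
})

test_that("standards round-trip through CSV", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "standards.csv")
  write_standards(the_standards, p)
  back <- read_standards(p)
  expect_equal(back$RUT$absorbance, the_standards$RUT$absorbance,
               tolerance = 1e-12)
})

test_that("JCAMP-DX AFFN spectra are parsed and resampled to the canonical grid", {
  g <- canonical_grid(4)
  a <- 0.2 + 0.5 * exp(-((g - 1600) / 40)^2)
  lines <- c("##TITLE=synthetic test spectrum", "##JCAMP-DX=4.24",
             "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
             sprintf("##FIRSTX=%g", g[1]), sprintf("##LASTX=%g", g[length(g)]),
             sprintf("##NPOINTS=%d", length(g)), "##DELTAX=4",
             "##XYDATA=(X++(Y..Y))")
  idx <- split(seq_along(g), ceiling(seq_along(g) / 6))
  lines <- c(lines, vapply(idx, function(i) {
    paste(c(format(g[i[1]]), format(a[i], digits = 10)), collapse = " ")
  }, character(1)), "##END=")
  f <- withr::local_tempfile(fileext = ".jdx")
  writeLines(lines, f)
  sp <- read_jcampdx(f, resolution = 4)
  expect_equal(sp$wavenumbers, g)
  expect_equal(sp$absorbance, a, tolerance = 1e-8)
})
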