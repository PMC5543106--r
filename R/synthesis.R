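# Synthetic ATR-FT-IR data: Beer-Lambert mixtures of three flavonoid
# standards in a plant matrix, with instrument-like noise structure.

.gauss_band <- function(grid, center, fwhm, height) {
  height * exp(-4 * log(2) * ((grid - center) / fwhm)^2)
}

.lorentz_band <- function(grid, center, fwhm, height) {
  hw <- fwhm / 2
  height * hw^2 / ((grid - center)^2 + hw^2)
}

.band_profile <- function(grid, bands, shape = "gaussian") {
  f <- switch(shape, gaussian = .gauss_band, lorentzian = .lorentz_band,
              stop("band shape must be 'gaussian' or 'lorentzian'",
                   call. = FALSE))
  a <- numeric(length(grid))
  for (i in seq_len(nrow(bands))) {
    a <- a + f(grid, bands$center[i], bands$fwhm[i], bands$height[i])
  }
  a
}

# Shared flavonol-core bands: aromatic ring modes, C=O stretch, phenolic
# C-O and OH stretch. All three compounds share these, which is what makes
# them mutually correlated and hard to separate.
.flavonol_core_bands <- function() {
  data.frame(
    center = c(3350, 3070, 1655, 1605, 1560, 1510, 1450, 1360, 1310, 1240,
               1200, 1165, 1090, 1010, 930, 880, 820, 785, 680, 600),
    fwhm   = c(220, 60, 45, 35, 30, 25, 30, 35, 30, 35,
               25, 25, 30, 30, 25, 25, 25, 20, 30, 30),
    height = c(0.45, 0.12, 0.95, 0.85, 0.45, 0.55, 0.40, 0.55, 0.45, 0.50,
               0.60, 0.55, 0.35, 0.40, 0.25, 0.20, 0.30, 0.15, 0.20, 0.25)
  )
}

# Rhamnose ring/C-O bands: present in quercitrin and rutin.
.rhamnose_bands <- function() {
  data.frame(
    center = c(2965, 1130, 980, 840),
    fwhm   = c(55, 25, 25, 20),
    height = c(0.15, 0.30, 0.35, 0.15)
  )
}

# Glucose bands: rutin only (rutinose = glucose + rhamnose).
.glucose_bands <- function() {
  data.frame(
    center = c(2975, 1070, 1040, 1015, 895),
    fwhm   = c(45, 30, 30, 25, 20),
    height = c(0.12, 0.40, 0.45, 0.30, 0.18)
  )
}

# Broad plant-matrix bands: water/carbohydrate OH, CH stretch, pectin ester
# C=O, amide I/II, and the polysaccharide C-O fingerprint envelope.
.matrix_bands <- function() {
  data.frame(
    center = c(3330, 2920, 2850, 1735, 1640, 1550, 1430, 1370, 1240, 1150,
               1100, 1050, 1030, 900, 780, 600),
    fwhm   = c(350, 90, 60, 60, 80, 60, 70, 50, 70, 50,
               40, 60, 40, 40, 60, 80),
    height = c(0.90, 0.25, 0.12, 0.20, 0.50, 0.25, 0.30, 0.25, 0.30, 0.35,
               0.40, 0.55, 0.50, 0.15, 0.12, 0.20)
  )
}

# Fixed per-part amplitude multipliers: flowers are richer in pectin and
# soluble sugars, leaves in structural cellulose and protein.
.part_matrix_profile <- function(plant_part) {
  switch(plant_part,
         flower = c(1.0, 0.9, 0.9, 1.4, 0.9, 0.8, 1.0, 1.0, 1.3, 1.1,
                    1.2, 1.3, 1.2, 1.0, 1.0, 1.0),
         leaf   = c(1.1, 1.1, 1.0, 0.7, 1.3, 1.3, 1.2, 1.1, 0.9, 1.0,
                    0.9, 1.0, 1.0, 1.1, 1.0, 1.1),
         stop("unknown plant part", call. = FALSE))
}

.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Generate pure-standard spectra for rutin, quercetin and quercitrin
#'
#' Builds idealized absorbance spectra of the three flavonoid standards on
#' the 4 cm^-1 canonical grid from fixed band lists: a common flavonol-core
#' band set shared by all three (so the spectra are strongly mutually
#' correlated, as for real quercetin glycosides) plus compound-specific
#' sugar bands -- rhamnose bands for quercitrin, rhamnose + glucose bands
#' for rutin, none for the quercetin aglycone. The three spectra are
#' linearly independent, non-negative, and concentrate at least 90% of
#' their integrated absorbance inside the 500--1700 and 2950--3500 cm^-1
#' band regions. The seed adds a small reproducible band-height jitter
#' (2% relative) emulating lot-to-lot variation of real standards.
#'
#' @param seed Integer RNG seed for the height jitter.
#' @param shape Band line shape, `"gaussian"` (default) or `"lorentzian"`.
#' @return An object of class `ftir_standards`: list with `ftir_spectrum`
#'   elements `QE`, `QI`, `RUT`.
#' @export
generate_standard_spectra <- function(seed = 0L, shape = "gaussian") {
  grid <- canonical_grid(4)
  core <- .flavonol_core_bands()
  rham <- .rhamnose_bands()
  gluc <- .glucose_bands()
  jitter <- .with_seed(seed, {
    lapply(1:3, function(i) stats::rnorm(nrow(core) + nrow(rham) + nrow(gluc),
                                         0, 0.02))
  })
  build <- function(bands, eta) {
    bands$height <- bands$height * pmax(0, 1 + eta[seq_len(nrow(bands))])
    .band_profile(grid, bands, shape)
  }
  qe <- build(core, jitter[[1L]])
  qi <- build(rbind(core, rham), jitter[[2L]])
  rut <- build(rbind(core, rham, gluc), jitter[[3L]])
  structure(
    list(QE = ftir_spectrum(grid, qe, 4),
         QI = ftir_spectrum(grid, qi, 4),
         RUT = ftir_spectrum(grid, rut, 4)),
    class = "ftir_standards"
  )
}

#' @export
print.ftir_standards <- function(x, ...) {
  cat(sprintf("<ftir_standards> QE, QI, RUT on %d-point grid at %g cm^-1\n",
              length(x$QE$wavenumbers), x$QE$resolution))
  invisible(x)
}

#' Default sample counts per species, plant part and preparation
#'
#' The sample-inventory defaults of the generator: how many samples of each
#' Fagopyrum species were measured as whole and ground flowers and leaves
#' in the study design the simulator emulates.
#'
#' @return Data frame with columns `species`, `plant_part`, `prep`, `n`.
#' @export
default_sample_counts <- function() {
  species <- fagopyrum_species()
  # columns: whole leaf, ground leaf, whole flower, ground flower
  counts <- rbind(
    "F. esculentum" = c(14, 15, 14, 14),
    "F. tataricum"  = c(5, 6, 0, 0),
    "F. rotundatum" = c(1, 1, 0, 0),
    "F. giganteum"  = c(6, 6, 1, 1),
    "F. leptopodum" = c(3, 3, 0, 0),
    "F. gracilipes" = c(2, 3, 1, 1),
    "F. cymosum"    = c(4, 5, 1, 1)
  )
  out <- expand.grid(species = species,
                     slot = c("whole:leaf", "ground:leaf", "whole:flower",
                              "ground:flower"),
                     stringsAsFactors = FALSE)
  out$prep <- sub(":.*", "", out$slot)
  out$plant_part <- sub(".*:", "", out$slot)
  out$n <- mapply(function(s, sl) {
    counts[s, match(sl, c("whole:leaf", "ground:leaf", "whole:flower",
                          "ground:flower"))]
  }, out$species, out$slot)
  out <- out[out$n > 0, c("species", "plant_part", "prep", "n")]
  rownames(out) <- NULL
  out
}

#' Default flavonoid concentration ranges (mg/g)
#'
#' Per-plant-part low/high ranges used when drawing true concentrations.
#' SUM is never drawn: it is always the sum of the three components; its
#' row is retained for reporting only.
#'
#' @return Data frame with columns `plant_part`, `flavonoid`, `low`, `high`.
#' @export
default_concentration_ranges <- function() {
  data.frame(
    plant_part = rep(c("flower", "leaf"), each = 4),
    flavonoid = rep(c("QE", "QI", "RUT", "SUM"), 2),
    low  = c(0.09, 4.1, 18, 25, 0, 0, 11, 17),
    high = c(3, 32, 110, 116, 1.8, 22, 112, 112),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic dataset generator
#'
#' Collects the sample inventory, concentration ranges, reference-assay
#' SDs and the dispersion parameters of the spectral noise model. The
#' replicate-composition heterogeneity must be at least as large for whole
#' samples as for ground ones: a whole-sample ATR spectrum probes only a
#' small surface area and so represents the bulk composition less well.
#'
#' @param n_samples_by_group Data frame with columns `species`,
#'   `plant_part`, `prep`, `n`; defaults to [default_sample_counts()].
#' @param concentration_ranges Data frame as [default_concentration_ranges()].
#' @param sd_hplc Data frame with columns `plant_part`, `flavonoid`, `sd`
#'   (mg/g); defaults to the flower/leaf rows of [reference_sd_table()].
#' @param noise_sd Additive absorbance noise SD per point at 4 cm^-1 (AU).
#'   The default, 5e-4 AU, is the RMS noise of a 50-scan average on a
#'   DTGS-detector ATR bench (single-scan RMS of a few mAU divided by
#'   sqrt(50)).
#' @param scatter_sd SD of the log multiplicative scatter factor per
#'   replicate spectrum.
#' @param baseline_amplitude SD of the per-replicate baseline offset (AU);
#'   the baseline slope SD is this value divided by the 3500 cm^-1 span.
#' @param replicate_heterogeneity_whole,replicate_heterogeneity_ground
#'   SD of the log multiplicative composition jitter per replicate.
#' @param matrix_jitter_sd Relative SD of per-(species, plant part) matrix
#'   band amplitudes.
#' @param range_skew Exponent applied to the uniform draw (u^skew); 1 gives
#'   uniform concentrations over the range, > 1 skews low.
#' @param absorptivity_scale Absorbance per mg/g applied to the unit-height
#'   standard spectra (Beer-Lambert proportionality).
#' @param seed Integer RNG seed.
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_samples_by_group = default_sample_counts(),
                         concentration_ranges = default_concentration_ranges(),
                         sd_hplc = NULL,
                         noise_sd = 5e-4,
                         scatter_sd = 0.08,
                         baseline_amplitude = 0.01,
                         replicate_heterogeneity_whole = 0.15,
                         replicate_heterogeneity_ground = 0.02,
                         matrix_jitter_sd = 0.05,
                         range_skew = 1,
                         absorptivity_scale = 0.005,
                         seed = 1L) {
  if (is.null(sd_hplc)) {
    tab <- reference_sd_table()
    tab <- tab[tab$plant_part %in% c("flower", "leaf"), ]
    sd_hplc <- tab
  }
  disp <- c(noise_sd = noise_sd, scatter_sd = scatter_sd,
            baseline_amplitude = baseline_amplitude,
            replicate_heterogeneity_whole = replicate_heterogeneity_whole,
            replicate_heterogeneity_ground = replicate_heterogeneity_ground,
            matrix_jitter_sd = matrix_jitter_sd)
  if (any(disp < 0)) stop("all dispersion parameters must be >= 0",
                          call. = FALSE)
  if (replicate_heterogeneity_whole < replicate_heterogeneity_ground) {
    stop("whole-sample heterogeneity must be >= ground-sample heterogeneity",
         call. = FALSE)
  }
  cr <- concentration_ranges
  if (any(cr$low > cr$high)) {
    bad <- cr[cr$low > cr$high, ][1L, ]
    stop(sprintf("invalid concentration range for %s %s: low %g > high %g",
                 bad$plant_part, bad$flavonoid, bad$low, bad$high),
         call. = FALSE)
  }
  if (any(sd_hplc$sd < 0)) stop("sd_hplc values must be >= 0", call. = FALSE)
  structure(
    list(n_samples_by_group = n_samples_by_group,
         concentration_ranges = cr, sd_hplc = sd_hplc,
         noise_sd = noise_sd, scatter_sd = scatter_sd,
         baseline_amplitude = baseline_amplitude,
         replicate_heterogeneity_whole = replicate_heterogeneity_whole,
         replicate_heterogeneity_ground = replicate_heterogeneity_ground,
         matrix_jitter_sd = matrix_jitter_sd,
         range_skew = range_skew,
         absorptivity_scale = absorptivity_scale,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Noise-free generator configuration
#'
#' Convenience wrapper over [synth_config()] with every dispersion set to
#' zero: no spectral noise, no scatter, no baseline, no replicate
#' heterogeneity, no reference-assay error, and no per-species matrix
#' perturbation. Under this configuration every replicate spectrum equals
#' the exact Beer-Lambert mixture plus the plant-part matrix spectrum, and
#' the reported references equal the true concentrations, so concentrations
#' are exactly linearly identifiable from the spectra.
#'
#' @param ... Passed on to [synth_config()] (e.g. `n_samples_by_group`,
#'   `seed`).
#' @return A `synth_config`.
#' @export
synth_config_noise_free <- function(...) {
  tab <- reference_sd_table()
  tab <- tab[tab$plant_part %in% c("flower", "leaf"), ]
  tab$sd <- 0
  synth_config(sd_hplc = tab, noise_sd = 0, scatter_sd = 0,
               baseline_amplitude = 0,
               replicate_heterogeneity_whole = 0,
               replicate_heterogeneity_ground = 0,
               matrix_jitter_sd = 0, ...)
}

.range_lookup <- function(cr, plant_part, flavonoid) {
  row <- cr[cr$plant_part == plant_part & cr$flavonoid == flavonoid, ]
  if (nrow(row) != 1L) {
    stop(sprintf("no concentration range for (%s, %s)", plant_part, flavonoid),
         call. = FALSE)
  }
  c(row$low, row$high)
}

.sd_lookup_part <- function(sd_hplc, plant_part, flavonoid) {
  row <- sd_hplc[sd_hplc$plant_part == plant_part &
                   sd_hplc$flavonoid == flavonoid, ]
  if (nrow(row) != 1L) {
    stop(sprintf("no sd_hplc entry for (%s, %s)", plant_part, flavonoid),
         call. = FALSE)
  }
  row$sd
}

#' Generate a synthetic dataset of replicate ATR-FT-IR spectra
#'
#' For each sample, true concentrations of QE, QI and RUT are drawn from the
#' plant-part-specific ranges (SUM is always their sum, never drawn), and
#' each of three replicate spectra is built as
#' \deqn{A(\nu) = m [\sum_i c_i \epsilon_i(\nu) + M_s(\nu)] + b_0 + b_1 \nu
#'   + e(\nu)}
#' where \eqn{\epsilon_i} are the standard spectra scaled to absorbance per
#' mg/g, \eqn{M_s} is a smooth species-and-part-specific plant-matrix
#' spectrum, \eqn{m} is a per-replicate log-normal scatter factor,
#' \eqn{(b_0, b_1)} a per-replicate linear baseline and \eqn{e} additive
#' Gaussian noise. Replicate compositions are jittered multiplicatively
#' with the prep-specific heterogeneity (whole >= ground). Reported
#' reference concentrations are true values plus Gaussian reference-assay
#' error (SD from the config), truncated at zero; the reported SUM is
#' always the sum of the three reported components.
#'
#' Spectra are generated on the 4 cm^-1 grid; use [degrade_dataset()] for
#' the coarser resolutions.
#'
#' @param config A `synth_config`.
#' @param standards An `ftir_standards` object on the 4 cm^-1 grid.
#' @return An `ftir_dataset` at 4 cm^-1.
#' @export
generate_dataset <- function(config, standards) {
  stopifnot(inherits(config, "synth_config"),
            inherits(standards, "ftir_standards"))
  grid <- canonical_grid(4)
  if (length(standards$QE$wavenumbers) != length(grid)) {
    stop("standards must be on the 4 cm^-1 canonical grid", call. = FALSE)
  }
  E <- cbind(QE = standards$QE$absorbance,
             QI = standards$QI$absorbance,
             RUT = standards$RUT$absorbance) * config$absorptivity_scale
  groups <- config$n_samples_by_group
  .with_seed(config$seed, {
    # one matrix spectrum per (species, plant part) present in the inventory
    mb <- .matrix_bands()
    key <- unique(groups[c("species", "plant_part")])
    matrices <- list()
    for (i in seq_len(nrow(key))) {
      b <- mb
      b$height <- b$height * .part_matrix_profile(key$plant_part[i]) *
        pmax(0, 1 + stats::rnorm(nrow(b), 0, config$matrix_jitter_sd))
      matrices[[paste(key$species[i], key$plant_part[i])]] <-
        .band_profile(grid, b)
    }
    records <- list()
    counter <- 0L
    for (gi in seq_len(nrow(groups))) {
      sp <- groups$species[gi]; part <- groups$plant_part[gi]
      prep <- groups$prep[gi]; n <- groups$n[gi]
      M <- matrices[[paste(sp, part)]]
      het <- if (prep == "whole") config$replicate_heterogeneity_whole
             else config$replicate_heterogeneity_ground
      for (si in seq_len(n)) {
        counter <- counter + 1L
        cc <- vapply(c("QE", "QI", "RUT"), function(f) {
          r <- .range_lookup(config$concentration_ranges, part, f)
          r[1L] + (r[2L] - r[1L]) * stats::runif(1)^config$range_skew
        }, numeric(1))
        reps <- vector("list", 3L)
        for (k in 1:3) {
          crep <- cc * exp(stats::rnorm(3, 0, het))
          m <- exp(stats::rnorm(1, 0, config$scatter_sd))
          b0 <- stats::rnorm(1, 0, config$baseline_amplitude)
          b1 <- stats::rnorm(1, 0, config$baseline_amplitude / 3500)
          a <- m * (as.vector(E %*% crep) + M) + b0 + b1 * grid +
            stats::rnorm(length(grid), 0, config$noise_sd)
          reps[[k]] <- ftir_spectrum(grid, a, 4)
        }
        reported <- pmax(cc + stats::rnorm(3, 0, vapply(
          c("QE", "QI", "RUT"),
          function(f) .sd_lookup_part(config$sd_hplc, part, f), numeric(1))), 0)
        id <- sprintf("%s_%s_%s_%02d",
                      gsub("[^A-Za-z]", "", sub("^F\\. ", "", sp)),
                      part, prep, si)
        rec <- ftir_sample(id, sp, part, prep, reps,
                           c(reported, SUM = sum(reported)))
        rec$true_concentration <- c(cc, SUM = sum(cc))
        records[[counter]] <- rec
      }
    }
    ftir_dataset(records, 4,
                 provenance = sprintf("synthetic (seed %d)", config$seed))
  })
}

#' Degrade a spectrum to a coarser nominal resolution
#'
#' Convolves the absorbance trace with a Gaussian of FWHM equal to the
#' target resolution (edge-renormalized, so constant spectra stay constant)
#' and resamples it onto the canonical grid of the target resolution by
#' linear interpolation. Additive noise present in the input is smoothed by
#' the convolution, so per-point noise decreases with coarser resolution,
#' as it does on a real interferometer.
#'
#' @param spectrum An `ftir_spectrum`.
#' @param target Target resolution in cm^-1 (4, 8 or 16); must not be finer
#'   than the input resolution. Equal resolution returns the input
#'   unchanged.
#' @return An `ftir_spectrum` on the canonical grid of `target`.
#' @export
degrade_resolution <- function(spectrum, target) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  if (!target %in% c(4, 8, 16)) {
    stop("target resolution must be one of 4, 8, 16", call. = FALSE)
  }
  if (target < spectrum$resolution) {
    stop("target resolution is finer than the input grid", call. = FALSE)
  }
  if (target == spectrum$resolution) return(spectrum)
  dx <- spectrum$resolution
  sigma <- target / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(4 * sigma / dx))
  kernel <- exp(-((-half:half) * dx)^2 / (2 * sigma^2))
  n <- length(spectrum$absorbance)
  num <- stats::convolve(spectrum$absorbance, kernel, type = "open")
  den <- stats::convolve(rep(1, n), kernel, type = "open")
  smoothed <- (num / den)[(half + 1L):(half + n)]
  grid_out <- canonical_grid(target)
  a <- stats::approx(spectrum$wavenumbers, smoothed, xout = grid_out)$y
  ftir_spectrum(grid_out, a, target)
}

#' Degrade a whole dataset to a coarser resolution
#'
#' Applies [degrade_resolution()] to every replicate spectrum of every
#' sample.
#'
#' @param dataset An `ftir_dataset`.
#' @param target Target resolution in cm^-1.
#' @return An `ftir_dataset` at the target resolution.
#' @export
degrade_dataset <- function(dataset, target) {
  stopifnot(inherits(dataset, "ftir_dataset"))
  records <- lapply(dataset$records, function(rec) {
    rec$replicates <- lapply(rec$replicates, degrade_resolution, target = target)
    rec
  })
  ftir_dataset(records, target,
               provenance = sprintf("%s; degraded to %g cm^-1",
                                    dataset$provenance, target))
}

#' Degrade standard spectra to a coarser resolution
#'
#' @param standards An `ftir_standards` object.
#' @param target Target resolution in cm^-1.
#' @return An `ftir_standards` object at the target resolution.
#' @export
degrade_standards <- function(standards, target) {
  stopifnot(inherits(standards, "ftir_standards"))
  structure(lapply(standards, degrade_resolution, target = target),
            class = "ftir_standards")
}

#' Bundle a 4 cm^-1 dataset with its degraded 8 and 16 cm^-1 versions
#'
#' The model search draws each configuration's spectra from this bundle by
#' resolution.
#'
#' @param dataset An `ftir_dataset` at 4 cm^-1.
#' @return Named list of `ftir_dataset` objects (`"4"`, `"8"`, `"16"`),
#'   class `ftir_bundle`.
#' @export
resolution_bundle <- function(dataset) {
  stopifnot(inherits(dataset, "ftir_dataset"))
  if (dataset$resolution != 4) {
    stop("the bundle must start from a 4 cm^-1 dataset", call. = FALSE)
  }
  structure(list(`4` = dataset,
                 `8` = degrade_dataset(dataset, 8),
                 `16` = degrade_dataset(dataset, 16)),
            class = "ftir_bundle")
}
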