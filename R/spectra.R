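#' Canonical wavenumber grid for a nominal resolution
#'
#' Spectra in this package live on fixed grids spanning the mid-infrared
#' range 500--4000 cm^-1, with point spacing equal to the nominal instrument
#' resolution. The grid starts at exactly 500 cm^-1 and ends at the largest
#' multiple of the spacing that does not exceed 4000 cm^-1.
#'
#' @param resolution Nominal resolution in cm^-1; one of 4, 8 or 16.
#' @return Numeric vector of wavenumbers (cm^-1), strictly increasing.
#' @examples
#' length(canonical_grid(4))   # 876
#' length(canonical_grid(16))  # 219, last point 3988
#' @export
canonical_grid <- function(resolution) {
  if (length(resolution) != 1L || !resolution %in% c(4, 8, 16)) {
    stop("`resolution` must be one of 4, 8 or 16 cm^-1", call. = FALSE)
  }
  seq(500, 4000, by = resolution)
}

#' Construct a spectrum
#'
#' A spectrum is an absorbance trace on an explicit, strictly increasing
#' wavenumber grid, together with its nominal resolution. The grid must match
#' the canonical grid spacing for that resolution.
#'
#' @param wavenumbers Strictly increasing numeric vector, cm^-1, within
#'   \[500, 4000\].
#' @param absorbance Numeric vector of the same length (absorbance units).
#' @param resolution Nominal resolution in cm^-1 (the grid spacing).
#' @return An object of class `ftir_spectrum`: a list with elements
#'   `wavenumbers`, `absorbance`, `resolution`.
#' @export
ftir_spectrum <- function(wavenumbers, absorbance, resolution) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) != length(absorbance)) {
    stop("wavenumber and absorbance vectors differ in length", call. = FALSE)
  }
  if (length(wavenumbers) < 2L) {
    stop("a spectrum needs at least two grid points", call. = FALSE)
  }
  d <- diff(wavenumbers)
  if (any(d <= 0)) stop("wavenumbers must be strictly increasing", call. = FALSE)
  if (min(wavenumbers) < 500 - 1e-9 || max(wavenumbers) > 4000 + 1e-9) {
    stop("wavenumbers must lie within [500, 4000] cm^-1", call. = FALSE)
  }
  if (any(abs(d - resolution) > 1e-6)) {
    stop("grid spacing does not match the nominal resolution", call. = FALSE)
  }
  structure(
    list(wavenumbers = wavenumbers, absorbance = absorbance,
         resolution = as.numeric(resolution)),
    class = "ftir_spectrum"
  )
}

#' @export
print.ftir_spectrum <- function(x, ...) {
  cat(sprintf("<ftir_spectrum> %d points, %g-%g cm^-1 at %g cm^-1 resolution\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers),
              x$resolution))
  cat(sprintf("  absorbance range: [%.4g, %.4g] AU\n",
              min(x$absorbance), max(x$absorbance)))
  invisible(x)
}

#' @export
plot.ftir_spectrum <- function(x, ..., xlab = expression(Wavenumber ~ (cm^-1)),
                               ylab = "Absorbance (AU)", type = "l") {
  graphics::plot(x$wavenumbers, x$absorbance, type = type,
                 xlab = xlab, ylab = ylab, xlim = rev(range(x$wavenumbers)), ...)
  invisible(x)
}

#' Construct a sample record
#'
#' One physical sample: its metadata, three replicate spectra on a common
#' grid, and the reference (HPLC) concentrations in mg/g for quercetin (QE),
#' quercitrin (QI), rutin (RUT) and their sum (SUM). SUM, when absent, is
#' computed as QE + QI + RUT; when present it must agree with that sum to
#' 1e-9.
#'
#' @param sample_id Unique identifier string.
#' @param species One of the seven Fagopyrum species (see
#'   [fagopyrum_species()]).
#' @param plant_part `"flower"` or `"leaf"`.
#' @param prep `"whole"` or `"ground"` (sample presentation on the ATR
#'   crystal).
#' @param replicates List of exactly three `ftir_spectrum` objects sharing a
#'   grid.
#' @param reference Named numeric vector with elements QE, QI, RUT and
#'   optionally SUM, all non-negative, in mg/g.
#' @return An object of class `ftir_sample`.
#' @export
ftir_sample <- function(sample_id, species, plant_part, prep, replicates,
                        reference) {
  if (!is.character(sample_id) || length(sample_id) != 1L || !nzchar(sample_id)) {
    stop("sample_id must be a non-empty string", call. = FALSE)
  }
  if (!species %in% fagopyrum_species()) {
    stop(sprintf("sample '%s': unknown species label '%s'", sample_id, species),
         call. = FALSE)
  }
  plant_part <- match.arg(plant_part, c("flower", "leaf"))
  prep <- match.arg(prep, c("whole", "ground"))
  if (!is.list(replicates) || length(replicates) != 3L) {
    stop(sprintf("sample '%s': exactly 3 replicate spectra are required",
                 sample_id), call. = FALSE)
  }
  if (!all(vapply(replicates, inherits, logical(1), "ftir_spectrum"))) {
    stop(sprintf("sample '%s': replicates must be ftir_spectrum objects",
                 sample_id), call. = FALSE)
  }
  g <- replicates[[1L]]$wavenumbers
  for (r in replicates[-1L]) {
    if (length(r$wavenumbers) != length(g) || any(abs(r$wavenumbers - g) > 1e-9)) {
      stop(sprintf("sample '%s': replicate spectra do not share one grid",
                   sample_id), call. = FALSE)
    }
  }
  for (f in c("QE", "QI", "RUT")) {
    if (!f %in% names(reference) || is.na(reference[[f]])) {
      stop(sprintf("sample '%s': missing reference concentration '%s'",
                   sample_id, f), call. = FALSE)
    }
  }
  if (any(reference < 0)) {
    stop(sprintf("sample '%s': negative reference concentration", sample_id),
         call. = FALSE)
  }
  comp_sum <- reference[["QE"]] + reference[["QI"]] + reference[["RUT"]]
  if ("SUM" %in% names(reference)) {
    if (abs(reference[["SUM"]] - comp_sum) > 1e-9) {
      stop(sprintf("sample '%s': SUM reference disagrees with QE+QI+RUT",
                   sample_id), call. = FALSE)
    }
  } else {
    reference <- c(reference, SUM = comp_sum)
  }
  reference <- reference[c("QE", "QI", "RUT", "SUM")]
  structure(
    list(sample_id = sample_id, species = species, plant_part = plant_part,
         prep = prep, replicates = replicates, reference = reference),
    class = "ftir_sample"
  )
}

#' The seven Fagopyrum species handled by the package
#'
#' @return Character vector of species labels.
#' @export
fagopyrum_species <- function() {
  c("F. esculentum", "F. tataricum", "F. rotundatum", "F. giganteum",
    "F. leptopodum", "F. gracilipes", "F. cymosum")
}

#' Construct a dataset of sample records
#'
#' @param records List of `ftir_sample` objects with unique ids, all on the
#'   same wavenumber grid.
#' @param resolution Nominal resolution of the spectra, cm^-1.
#' @param provenance Free-text note recording how the dataset was produced.
#' @return An object of class `ftir_dataset`.
#' @export
ftir_dataset <- function(records, resolution, provenance = "") {
  if (!length(records)) stop("a dataset needs at least one sample", call. = FALSE)
  if (!all(vapply(records, inherits, logical(1), "ftir_sample"))) {
    stop("records must be ftir_sample objects", call. = FALSE)
  }
  ids <- vapply(records, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sample_id '%s'", ids[duplicated(ids)][1L]),
         call. = FALSE)
  }
  g <- records[[1L]]$replicates[[1L]]$wavenumbers
  for (rec in records[-1L]) {
    gr <- rec$replicates[[1L]]$wavenumbers
    if (length(gr) != length(g) || any(abs(gr - g) > 1e-9)) {
      stop(sprintf("sample '%s' is not on the common wavenumber grid",
                   rec$sample_id), call. = FALSE)
    }
  }
  names(records) <- ids
  structure(
    list(records = records, resolution = as.numeric(resolution),
         provenance = provenance),
    class = "ftir_dataset"
  )
}

#' @export
print.ftir_dataset <- function(x, ...) {
  parts <- table(vapply(x$records, `[[`, character(1), "plant_part"))
  preps <- table(vapply(x$records, `[[`, character(1), "prep"))
  cat(sprintf("<ftir_dataset> %d samples at %g cm^-1 (%s)\n",
              length(x$records), x$resolution,
              paste(names(parts), parts, sep = ": ", collapse = ", ")))
  cat(sprintf("  prep: %s\n", paste(names(preps), preps, sep = ": ",
                                    collapse = ", ")))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
length.ftir_dataset <- function(x) length(x$records)

#' Wavenumber grid of a dataset
#' @param dataset An `ftir_dataset`.
#' @return Numeric vector of wavenumbers shared by all spectra.
#' @export
dataset_grid <- function(dataset) {
  dataset$records[[1L]]$replicates[[1L]]$wavenumbers
}

#' Average the three replicate spectra of a sample
#'
#' Pointwise arithmetic mean of the replicate absorbances on their shared
#' grid. Averaging is done on raw spectra, before any pretreatment: SNV and
#' the other per-spectrum transforms do not commute with the mean (see the
#' methods vignette).
#'
#' @param record An `ftir_sample`.
#' @return An `ftir_spectrum`: the mean spectrum.
#' @export
average_replicates <- function(record) {
  stopifnot(inherits(record, "ftir_sample"))
  g <- record$replicates[[1L]]$wavenumbers
  for (r in record$replicates[-1L]) {
    if (any(abs(r$wavenumbers - g) > 1e-9)) {
      stop("replicate grids disagree; cannot average", call. = FALSE)
    }
  }
  a <- rowMeans(vapply(record$replicates, `[[`,
                       numeric(length(g)), "absorbance"))
  ftir_spectrum(g, a, record$replicates[[1L]]$resolution)
}

#' Filter a dataset by plant part and/or sample preparation
#'
#' The combined (flowers + leaves) analysis corresponds to no plant-part
#' filter. An empty result is an error: no calibration model can be built
#' from zero samples.
#'
#' @param dataset An `ftir_dataset`.
#' @param plant_part `NULL` (keep all), `"flower"` or `"leaf"`.
#' @param prep `NULL` (keep all), `"whole"` or `"ground"`.
#' @return A filtered `ftir_dataset`.
#' @export
select_subset <- function(dataset, plant_part = NULL, prep = NULL) {
  stopifnot(inherits(dataset, "ftir_dataset"))
  keep <- rep(TRUE, length(dataset$records))
  if (!is.null(plant_part)) {
    plant_part <- match.arg(plant_part, c("flower", "leaf"))
    keep <- keep & vapply(dataset$records, `[[`, character(1),
                          "plant_part") == plant_part
  }
  if (!is.null(prep)) {
    prep <- match.arg(prep, c("whole", "ground"))
    keep <- keep & vapply(dataset$records, `[[`, character(1), "prep") == prep
  }
  if (!any(keep)) {
    stop("subset is empty: no samples match the requested filters",
         call. = FALSE)
  }
  ftir_dataset(dataset$records[keep], dataset$resolution, dataset$provenance)
}

#' Reference concentrations of a dataset as a matrix
#'
#' @param dataset An `ftir_dataset`.
#' @return Numeric matrix, one row per sample (rownames = sample ids),
#'   columns QE, QI, RUT, SUM, in mg/g.
#' @export
reference_matrix <- function(dataset) {
  t(vapply(dataset$records, `[[`, numeric(4), "reference"))
}
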