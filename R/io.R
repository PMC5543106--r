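#' Write a dataset to CSV files
#'
#' Writes `spectra.csv` (first column `wavenumber`, then one column per
#' replicate spectrum named `<sample_id>:rep<k>`) and `metadata.csv` (one row
#' per sample: `sample_id`, `species`, `plant_part`, `prep`, `QE`, `QI`,
#' `RUT`, `SUM`). Both files carry a `# resolution_cm-1=<r>` header line.
#' Values are written with full double precision so that a write/read
#' round-trip is lossless.
#'
#' @param dataset An `ftir_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of the two files written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "ftir_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- dataset_grid(dataset)
  cols <- list(wavenumber = g)
  for (rec in dataset$records) {
    for (k in 1:3) {
      cols[[sprintf("%s:rep%d", rec$sample_id, k)]] <-
        rec$replicates[[k]]$absorbance
    }
  }
  spectra <- as.data.frame(cols, check.names = FALSE)
  meta <- data.frame(
    sample_id = vapply(dataset$records, `[[`, character(1), "sample_id"),
    species = vapply(dataset$records, `[[`, character(1), "species"),
    plant_part = vapply(dataset$records, `[[`, character(1), "plant_part"),
    prep = vapply(dataset$records, `[[`, character(1), "prep"),
    stringsAsFactors = FALSE
  )
  refs <- reference_matrix(dataset)
  meta <- cbind(meta, as.data.frame(refs))
  sp <- file.path(dir, "spectra.csv")
  mp <- file.path(dir, "metadata.csv")
  .write_csv_with_header(spectra, sp, dataset$resolution)
  .write_csv_with_header(meta, mp, dataset$resolution)
  invisible(c(spectra = sp, metadata = mp))
}

.write_csv_with_header <- function(df, path, resolution) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# resolution_cm-1=%g", resolution), con)
  # full precision: format numerics with %.17g before writing
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
}

.read_csv_with_header <- function(path) {
  first <- readLines(path, n = 1L)
  resolution <- NA_real_
  if (grepl("^#\\s*resolution_cm-1=", first)) {
    resolution <- as.numeric(sub("^#\\s*resolution_cm-1=", "", first))
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  list(data = df, resolution = resolution)
}

#' Read a dataset from CSV files
#'
#' Inverse of [write_dataset()]. Each sample must have exactly three
#' replicate columns `<id>:rep1..rep3` in the spectra file and one metadata
#' row; SUM is computed as QE + QI + RUT when the column is absent. All
#' dataset invariants (shared grid, known species, non-negative
#' concentrations) are validated with messages locating the offending sample
#' and field.
#'
#' @param spectra_file Path to `spectra.csv`.
#' @param metadata_file Path to `metadata.csv`.
#' @return An `ftir_dataset`.
#' @export
read_dataset <- function(spectra_file, metadata_file) {
  sp <- .read_csv_with_header(spectra_file)
  me <- .read_csv_with_header(metadata_file)
  spectra <- sp$data
  meta <- me$data
  if (names(spectra)[1L] != "wavenumber") {
    stop("spectra file must have 'wavenumber' as its first column",
         call. = FALSE)
  }
  g <- spectra$wavenumber
  resolution <- sp$resolution
  if (is.na(resolution)) resolution <- stats::median(diff(g))
  for (col in c("sample_id", "species", "plant_part", "prep", "QE", "QI", "RUT")) {
    if (!col %in% names(meta)) {
      stop(sprintf("metadata file lacks required column '%s'", col),
           call. = FALSE)
    }
  }
  for (f in c("QE", "QI", "RUT")) {
    bad <- which(is.na(meta[[f]]))
    if (length(bad)) {
      stop(sprintf("sample '%s': missing reference concentration '%s'",
                   meta$sample_id[bad[1L]], f), call. = FALSE)
    }
  }
  records <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    id <- meta$sample_id[i]
    repcols <- sprintf("%s:rep%d", id, 1:3)
    missing <- setdiff(repcols, names(spectra))
    if (length(missing)) {
      stop(sprintf("sample '%s': missing replicate column '%s'",
                   id, missing[1L]), call. = FALSE)
    }
    reps <- lapply(repcols, function(cn) ftir_spectrum(g, spectra[[cn]],
                                                       resolution))
    ref <- c(QE = meta$QE[i], QI = meta$QI[i], RUT = meta$RUT[i])
    if ("SUM" %in% names(meta) && !is.na(meta$SUM[i])) {
      ref <- c(ref, SUM = meta$SUM[i])
    }
    records[[i]] <- ftir_sample(id, meta$species[i], meta$plant_part[i],
                                meta$prep[i], reps, ref)
  }
  ftir_dataset(records, resolution,
               provenance = sprintf("read from %s", spectra_file))
}

#' Write pure-standard spectra to CSV
#'
#' One column per compound (QE, QI, RUT) plus the wavenumber column, with
#' the usual resolution header line.
#'
#' @param standards An `ftir_standards` object (see
#'   [generate_standard_spectra()]).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_standards <- function(standards, path) {
  stopifnot(inherits(standards, "ftir_standards"))
  g <- standards$QE$wavenumbers
  df <- data.frame(wavenumber = g, QE = standards$QE$absorbance,
                   QI = standards$QI$absorbance,
                   RUT = standards$RUT$absorbance)
  .write_csv_with_header(df, path, standards$QE$resolution)
  invisible(path)
}

#' Read pure-standard spectra from CSV
#'
#' @param path Path to a `standards.csv` written by [write_standards()].
#' @return An `ftir_standards` object.
#' @export
read_standards <- function(path) {
  x <- .read_csv_with_header(path)
  df <- x$data
  for (col in c("wavenumber", "QE", "QI", "RUT")) {
    if (!col %in% names(df)) {
      stop(sprintf("standards file lacks column '%s'", col), call. = FALSE)
    }
  }
  resolution <- x$resolution
  if (is.na(resolution)) resolution <- stats::median(diff(df$wavenumber))
  structure(
    list(QE = ftir_spectrum(df$wavenumber, df$QE, resolution),
         QI = ftir_spectrum(df$wavenumber, df$QI, resolution),
         RUT = ftir_spectrum(df$wavenumber, df$RUT, resolution)),
    class = "ftir_standards"
  )
}

#' Read a single spectrum from a JCAMP-DX file
#'
#' Minimal read-only support for AFFN-encoded `XYDATA=(X++(Y..Y))` blocks,
#' the common export format of FT-IR instrument software. The foreign grid
#' is immediately resampled onto the package's canonical grid for the given
#' resolution by linear interpolation, so instrument grids never leak into
#' the pipeline. Points outside the canonical range are dropped; the file
#' must cover the full 500--4000 cm^-1 range.
#'
#' @param path Path to a `.jdx`/`.dx` file.
#' @param resolution Target canonical resolution (4, 8 or 16 cm^-1).
#' @return An `ftir_spectrum` on the canonical grid.
#' @export
read_jcampdx <- function(path, resolution = 4) {
  lines <- readLines(path, warn = FALSE)
  ldr <- function(name) {
    hit <- grep(sprintf("^##%s=", name), lines, value = TRUE)
    if (length(hit)) as.numeric(sub(sprintf("^##%s=", name), "", hit[1L])) else NA_real_
  }
  xfactor <- ldr("XFACTOR"); if (is.na(xfactor)) xfactor <- 1
  yfactor <- ldr("YFACTOR"); if (is.na(yfactor)) yfactor <- 1
  deltax <- ldr("DELTAX")
  start <- grep("^##XYDATA=\\s*\\(X\\+\\+\\(Y\\.\\.Y\\)\\)", lines)
  if (!length(start)) stop("no (X++(Y..Y)) XYDATA block found", call. = FALSE)
  end <- grep("^##", lines)
  end <- end[end > start[1L]]
  end <- if (length(end)) end[1L] - 1L else length(lines)
  block <- trimws(lines[(start[1L] + 1L):end])
  block <- block[nzchar(block)]
  parsed <- lapply(block, function(ln) {
    vals <- as.numeric(strsplit(ln, "[,;[:space:]]+")[[1L]])
    if (anyNA(vals) || length(vals) < 2L) {
      stop(sprintf("cannot parse AFFN data line: '%s'", ln), call. = FALSE)
    }
    vals
  })
  x0 <- vapply(parsed, `[`, numeric(1), 1L)
  ny <- lengths(parsed) - 1L
  if (is.na(deltax)) {
    if (length(parsed) < 2L) {
      stop("cannot infer DELTAX from a single data line; add ##DELTAX=",
           call. = FALSE)
    }
    deltax <- (x0[2L] - x0[1L]) / ny[1L]
  }
  x <- unlist(lapply(seq_along(parsed),
                     function(l) x0[l] + deltax * (seq_len(ny[l]) - 1L)))
  y <- unlist(lapply(parsed, `[`, -1L))
  x <- x * xfactor
  y <- y * yfactor
  o <- order(x)
  x <- x[o]; y <- y[o]
  grid <- canonical_grid(resolution)
  if (min(x) > 500 + 1e-9 || max(x) < max(grid) - 1e-9) {
    stop("JCAMP-DX file does not cover the 500-4000 cm^-1 range",
         call. = FALSE)
  }
  a <- stats::approx(x, y, xout = grid, rule = 1)$y
  ftir_spectrum(grid, a, resolution)
}
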