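# Factorial model search: enumerate the 6912 pipeline configurations, run
# each end-to-end (subset -> average -> pretreat -> split -> reduce ->
# LOO factor selection -> fit -> metrics), and classify models against the
# reference-HPLC SD thresholds.

#' Reference HPLC variability (SD, mg/g) per plant part and flavonoid
#'
#' Default standard deviations of the reference HPLC determinations, the
#' yardstick of the model-acceptance rules: a model is *useful* when both
#' RMSEC and RMSEV are at most 3 SD and both correlation coefficients
#' exceed 0.9, and *HPLC-comparable* when additionally RMSEV is at most
#' 1 SD. Flower and leaf analyses use their part-specific row; the
#' combined analysis uses the pooled `"all"` row. (The pooled QI value,
#' 0.06 mg/g, is smaller than the flowers-only value, which a pooled SD
#' cannot arithmetically be; the defaults are nevertheless kept verbatim
#' -- see the methods vignette.)
#'
#' @return Data frame with columns `plant_part` (`flower`, `leaf`, `all`),
#'   `flavonoid`, `sd`.
#' @export
reference_sd_table <- function() {
  data.frame(
    plant_part = rep(c("flower", "leaf", "all"), each = 4),
    flavonoid = rep(c("QE", "QI", "RUT", "SUM"), 3),
    sd = c(0.1, 0.8, 3, 5,
           0.04, 0.3, 3, 4,
           0.4, 0.06, 3, 4),
    stringsAsFactors = FALSE
  )
}

.lookup_sd <- function(refstats, dataset_name, flavonoid) {
  part <- switch(dataset_name, flowers = "flower", leaves = "leaf",
                 combined = "all",
                 stop("unknown dataset name", call. = FALSE))
  row <- refstats[refstats$plant_part == part &
                    refstats$flavonoid == flavonoid, ]
  if (nrow(row) != 1L) {
    stop(sprintf("no reference SD for (%s, %s)", part, flavonoid),
         call. = FALSE)
  }
  row$sd
}

#' Enumerate the factorial grid of model configurations
#'
#' The full cross-product of the search factors -- 4 flavonoids x 3
#' dataset scopes x 2 preparations x 3 resolutions x 2 replicate handling
#' modes x 8 pretreatment chains x 3 reduction schemes x 2 auxiliary-
#' variable settings -- has exactly 6912 members. Any factor can be
#' restricted by passing the levels to keep.
#'
#' @param flavonoid,dataset,prep,resolution,replicates,chain,reduction,aux_vars
#'   Optional level subsets; `NULL` keeps all levels of that factor.
#' @return Data frame, one row per configuration, in a deterministic
#'   order.
#' @export
enumerate_grid <- function(flavonoid = NULL, dataset = NULL, prep = NULL,
                           resolution = NULL, replicates = NULL,
                           chain = NULL, reduction = NULL, aux_vars = NULL) {
  lv <- list(
    flavonoid = c("QE", "QI", "RUT", "SUM"),
    dataset = c("flowers", "leaves", "combined"),
    prep = c("whole", "ground"),
    resolution = c(4, 8, 16),
    replicates = c("separate", "averaged"),
    chain = pretreatment_chains()$label,
    reduction = c("RS1", "RS2", "RS3"),
    aux_vars = c(FALSE, TRUE)
  )
  pick <- function(name, sel) {
    if (is.null(sel)) return(lv[[name]])
    if (!all(sel %in% lv[[name]])) {
      stop(sprintf("unknown level for '%s'", name), call. = FALSE)
    }
    sel
  }
  grid <- expand.grid(
    flavonoid = pick("flavonoid", flavonoid),
    dataset = pick("dataset", dataset),
    prep = pick("prep", prep),
    resolution = pick("resolution", resolution),
    replicates = pick("replicates", replicates),
    chain = pick("chain", chain),
    reduction = pick("reduction", reduction),
    aux_vars = pick("aux_vars", aux_vars),
    stringsAsFactors = FALSE
  )
  grid
}

#' Deterministic rank-stratified calibration/validation split
#'
#' Samples are ranked by the reported reference concentration of the
#' target flavonoid; every fourth rank (starting at the second, for the
#' default quarter validation fraction) goes to validation. The extreme
#' samples (minimum and maximum concentration) always stay in calibration,
#' so validation never extrapolates. All replicate spectra of a sample
#' share its assignment.
#'
#' @param dataset An `ftir_dataset` with at least 8 samples.
#' @param flavonoid One of `"QE"`, `"QI"`, `"RUT"`, `"SUM"`.
#' @param validation_fraction Target share of validation samples.
#' @return List with character vectors `calibration` and `validation`
#'   (sample ids).
#' @export
split_calibration_validation <- function(dataset, flavonoid,
                                         validation_fraction = 0.25) {
  stopifnot(inherits(dataset, "ftir_dataset"))
  ids <- names(dataset$records)
  n <- length(ids)
  if (n < 8L) stop("the split needs at least 8 samples", call. = FALSE)
  y <- vapply(dataset$records, function(r) r$reference[[flavonoid]],
              numeric(1))
  rnk <- rank(y, ties.method = "first")
  step <- max(2L, round(1 / validation_fraction))
  val_ranks <- seq(2L, n - 1L, by = step)
  val <- ids[rnk %in% val_ranks]
  list(calibration = ids[!ids %in% val], validation = val)
}

# Build the model matrix for one (dataset, replicates, chain) choice:
# rows are samples (averaged) or replicate spectra (separate), columns the
# transformed variables; also returns the per-row sample id and the
# wavenumber labels of the columns.
.assemble_design <- function(dataset, replicates, chain) {
  if (is.character(chain)) chain <- pretreatment_chain(chain)
  grid <- dataset_grid(dataset)
  labels <- wavenumber_lineage(chain, grid)
  rows <- list(); row_ids <- character(0)
  for (rec in dataset$records) {
    specs <- if (replicates == "averaged") {
      list(average_replicates(rec))
    } else {
      rec$replicates
    }
    for (s in specs) {
      rows[[length(rows) + 1L]] <- apply_chain(chain, s$absorbance)
      row_ids <- c(row_ids, rec$sample_id)
    }
  }
  X <- do.call(rbind, rows)
  stopifnot(ncol(X) == length(labels))
  list(X = X, sample_id = row_ids, labels = labels)
}

# One-hot species dummies (all 7 levels), plus a plant-part dummy for the
# combined analysis; scaled to the median absolute magnitude of the kept
# spectral variables so they are neither dominant nor negligible.
.aux_columns <- function(dataset, row_ids, combined) {
  species <- vapply(dataset$records, `[[`, character(1), "species")
  part <- vapply(dataset$records, `[[`, character(1), "plant_part")
  lev <- fagopyrum_species()
  D <- matrix(0, length(row_ids), length(lev),
              dimnames = list(NULL, gsub("[^A-Za-z]", "", lev)))
  for (j in seq_along(lev)) D[species[row_ids] == lev[j], j] <- 1
  if (combined) D <- cbind(D, part_flower = as.numeric(part[row_ids] == "flower"))
  D
}

#' Classify a model against the reference-HPLC SD thresholds
#'
#' *Useful*: RMSEC and RMSEV both at most 3 SD of the reference HPLC data
#' and both R (calibration and validation) above 0.9. *HPLC-comparable*:
#' useful, and RMSEV at most 1 SD. RMSE comparisons are non-strict so
#' that a model printing exactly at the threshold is accepted.
#'
#' @param metrics Named list or vector with `r_cal`, `r_val`, `rmsec`,
#'   `rmsev`.
#' @param sd Reference HPLC standard deviation (mg/g), > 0.
#' @return List with logicals `useful` and `hplc_comparable`.
#' @export
evaluate_model <- function(metrics, sd) {
  if (!is.finite(sd) || sd <= 0) stop("sd must be > 0", call. = FALSE)
  m <- as.list(metrics)
  ok <- function(v) is.finite(v)
  useful <- ok(m$rmsec) && ok(m$rmsev) && ok(m$r_cal) && ok(m$r_val) &&
    m$rmsec <= 3 * sd && m$rmsev <= 3 * sd &&
    m$r_cal > 0.9 && m$r_val > 0.9
  list(useful = useful,
       hplc_comparable = useful && m$rmsev <= sd)
}

#' Run one configuration of the calibration pipeline end-to-end
#'
#' Executes, in order: dataset selection by resolution/part/prep ->
#' replicate averaging (if configured) -> pretreatment chain per spectrum
#' -> rank-stratified calibration/validation split -> variable reduction
#' to one quarter (fitted on calibration rows only; RS3 uses the
#' pretreated standards) -> optional auxiliary dummy variables ->
#' leave-one-out latent-factor selection -> final PLS1 fit -> calibration
#' and validation metrics -> verdict against the reference SD.
#'
#' @param bundle An `ftir_bundle` (datasets at 4, 8 and 16 cm^-1).
#' @param standards An `ftir_standards` object at 4 cm^-1.
#' @param config One row of [enumerate_grid()] (or an equivalent list).
#' @param refstats Reference SD table, defaults to [reference_sd_table()].
#' @param split Optional precomputed split (as returned by
#'   [split_calibration_validation()]); by default computed from the
#'   configuration's dataset and flavonoid.
#' @param max_lv Upper bound on candidate latent factors (default 20).
#' @return An object of class `ftir_model`: the fitted `pls1` model plus
#'   the mask, split, predictions, metrics and verdict; its `$row` element
#'   is the one-line summary data frame used by [run_search()].
#' @export
run_config <- function(bundle, standards, config,
                       refstats = reference_sd_table(), split = NULL,
                       max_lv = 20L) {
  stopifnot(inherits(bundle, "ftir_bundle"))
  config <- as.list(config)
  chain <- pretreatment_chain(config$chain)
  ds <- bundle[[as.character(config$resolution)]]
  if (is.null(ds)) stop("bundle lacks the requested resolution", call. = FALSE)
  part <- switch(config$dataset, flowers = "flower", leaves = "leaf",
                 combined = NULL)
  ds <- select_subset(ds, plant_part = part, prep = config$prep)
  des <- .assemble_design(ds, config$replicates, chain)
  yref <- vapply(ds$records, function(r) r$reference[[config$flavonoid]],
                 numeric(1))
  if (is.null(split)) {
    split <- split_calibration_validation(ds, config$flavonoid)
  }
  cal_rows <- des$sample_id %in% split$calibration
  val_rows <- des$sample_id %in% split$validation
  y_rows <- yref[des$sample_id]
  X <- des$X

  mask <- switch(config$reduction,
    RS1 = rs1_select(X[cal_rows, , drop = FALSE], y_rows[cal_rows]),
    RS2 = rs2_select(X[cal_rows, , drop = FALSE], y_rows[cal_rows],
                     des$labels),
    RS3 = {
      std <- if (config$resolution == 4) standards
             else degrade_standards(standards, config$resolution)
      rs3_select(cbind(QE = apply_chain(chain, std$QE$absorbance),
                       QI = apply_chain(chain, std$QI$absorbance),
                       RUT = apply_chain(chain, std$RUT$absorbance)))
    },
    stop("unknown reduction scheme", call. = FALSE))
  mask$wavenumbers <- des$labels
  Xr <- X[, mask$kept_indices, drop = FALSE]

  if (isTRUE(config$aux_vars)) {
    med <- stats::median(abs(Xr[cal_rows, ]))
    if (!is.finite(med) || med == 0) med <- 1
    Xr <- cbind(Xr, .aux_columns(ds, des$sample_id,
                                 combined = config$dataset == "combined") * med)
  }

  k <- loo_select_lv(Xr[cal_rows, , drop = FALSE], y_rows[cal_rows],
                     max_lv = max_lv)
  fit <- suppressWarnings(pls1(Xr[cal_rows, , drop = FALSE],
                               y_rows[cal_rows], as.integer(k)))
  pred_cal <- fit$fitted_values
  pred_val <- predict(fit, Xr[val_rows, , drop = FALSE])
  mc <- suppressWarnings(regression_metrics(y_rows[cal_rows], pred_cal))
  mv <- suppressWarnings(regression_metrics(y_rows[val_rows], pred_val))
  metrics <- list(r_cal = unname(mc["R"]), r_val = unname(mv["R"]),
                  rmsec = unname(mc["RMSE"]), rmsev = unname(mv["RMSE"]))
  sd <- .lookup_sd(refstats, config$dataset, config$flavonoid)
  verdict <- evaluate_model(metrics, sd)
  row <- data.frame(
    flavonoid = config$flavonoid, dataset = config$dataset,
    prep = config$prep, resolution = config$resolution,
    replicates = config$replicates, chain = chain$label,
    reduction = config$reduction, aux_vars = isTRUE(config$aux_vars),
    n_latent = fit$n_latent,
    r_cal = metrics$r_cal, r_val = metrics$r_val,
    rmsec = metrics$rmsec, rmsev = metrics$rmsev,
    sd_hplc = sd, useful = verdict$useful,
    hplc_comparable = verdict$hplc_comparable,
    error = NA_character_,
    stringsAsFactors = FALSE
  )
  structure(
    list(config = config, chain = chain, mask = mask, split = split,
         model = fit, rmsecv = attr(k, "rmsecv"),
         predictions = list(
           calibration = data.frame(sample_id = des$sample_id[cal_rows],
                                    reference = y_rows[cal_rows],
                                    predicted = pred_cal),
           validation = data.frame(sample_id = des$sample_id[val_rows],
                                   reference = y_rows[val_rows],
                                   predicted = pred_val)),
         metrics = metrics, sd_hplc = sd, verdict = verdict, row = row),
    class = "ftir_model"
  )
}

#' @export
print.ftir_model <- function(x, ...) {
  cfg <- x$row
  cat(sprintf("<ftir_model> %s | %s %s | %g cm^-1 | %s | %s | %s | aux: %s\n",
              cfg$flavonoid, cfg$dataset, cfg$prep, cfg$resolution,
              cfg$replicates, cfg$chain, cfg$reduction,
              ifelse(cfg$aux_vars, "yes", "no")))
  cat(sprintf("  %d latent factors; R cal %.3f, R val %.3f; RMSEC %.3g, RMSEV %.3g mg/g\n",
              cfg$n_latent, cfg$r_cal, cfg$r_val, cfg$rmsec, cfg$rmsev))
  cat(sprintf("  vs SD_HPLC %.3g mg/g: %s\n", cfg$sd_hplc,
              if (cfg$hplc_comparable) "HPLC-comparable"
              else if (cfg$useful) "useful" else "not useful"))
  invisible(x)
}

#' @export
summary.ftir_model <- function(object, ...) {
  print(object)
  cat(sprintf("  calibration n = %d rows, validation n = %d rows\n",
              nrow(object$predictions$calibration),
              nrow(object$predictions$validation)))
  cat(sprintf("  RMSECV curve: %s\n",
              paste(sprintf("%.3g", object$rmsecv), collapse = " ")))
  invisible(object)
}

#' @export
plot.ftir_model <- function(x, ...,
                            xlab = "Reference concentration (mg/g)",
                            ylab = "Predicted concentration (mg/g)") {
  cal <- x$predictions$calibration
  val <- x$predictions$validation
  rng <- range(cal$reference, cal$predicted, val$reference, val$predicted)
  graphics::plot(cal$reference, cal$predicted, pch = 1, xlim = rng,
                 ylim = rng, xlab = xlab, ylab = ylab, ...)
  graphics::points(val$reference, val$predicted, pch = 17)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", pch = c(1, 17),
                   legend = c("calibration", "validation"), bty = "n")
  invisible(x)
}

#' Run the factorial model search
#'
#' Runs [run_config()] for every row of the configuration grid, collecting
#' one report row per configuration. A failing configuration (for
#' example, a subset with no samples of the requested preparation) is
#' recorded with its error message and the search continues. The result is
#' deterministic for a given bundle.
#'
#' @param bundle An `ftir_bundle`.
#' @param standards An `ftir_standards` at 4 cm^-1.
#' @param grid Configuration grid, default the full 6912-row
#'   [enumerate_grid()].
#' @param refstats Reference SD table.
#' @param max_lv Upper bound on latent factors per model.
#' @param progress Print a line every `progress` configurations (0 = quiet).
#' @return Data frame of class `ftir_search`, one row per configuration,
#'   with columns for every configuration field plus `n_latent`, `r_cal`,
#'   `r_val`, `rmsec`, `rmsev`, `sd_hplc`, `useful`, `hplc_comparable`,
#'   `error`.
#' @export
run_search <- function(bundle, standards, grid = enumerate_grid(),
                       refstats = reference_sd_table(), max_lv = 20L,
                       progress = 0L) {
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- grid[i, ]
    rows[[i]] <- tryCatch(
      run_config(bundle, standards, cfg, refstats, max_lv = max_lv)$row,
      error = function(e) {
        data.frame(flavonoid = cfg$flavonoid, dataset = cfg$dataset,
                   prep = cfg$prep, resolution = cfg$resolution,
                   replicates = cfg$replicates, chain = cfg$chain,
                   reduction = cfg$reduction, aux_vars = cfg$aux_vars,
                   n_latent = NA_integer_, r_cal = NA_real_,
                   r_val = NA_real_, rmsec = NA_real_, rmsev = NA_real_,
                   sd_hplc = NA_real_, useful = FALSE,
                   hplc_comparable = FALSE,
                   error = conditionMessage(e), stringsAsFactors = FALSE)
      })
    if (progress > 0L && i %% progress == 0L) {
      message(sprintf("  ... %d / %d configurations", i, nrow(grid)))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ftir_search", "data.frame")
  out
}

#' @export
print.ftir_search <- function(x, ...) {
  cat(sprintf("<ftir_search> %d configurations: %d useful, %d HPLC-comparable, %d failed\n",
              nrow(x), sum(x$useful, na.rm = TRUE),
              sum(x$hplc_comparable, na.rm = TRUE),
              sum(!is.na(x$error))))
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' @export
summary.ftir_search <- function(object, ...) {
  df <- as.data.frame(object)
  marg <- function(f) {
    tab <- stats::aggregate(df$useful, by = list(level = df[[f]]),
                            FUN = sum, na.rm = TRUE)
    names(tab)[2L] <- "useful"
    tab$factor <- f
    tab[c("factor", "level", "useful")]
  }
  out <- list(
    n = nrow(df),
    useful = sum(df$useful, na.rm = TRUE),
    hplc_comparable = sum(df$hplc_comparable, na.rm = TRUE),
    failed = sum(!is.na(df$error)),
    marginals = do.call(rbind, lapply(
      c("flavonoid", "dataset", "prep", "resolution", "replicates",
        "chain", "reduction", "aux_vars"), marg))
  )
  class(out) <- "summary.ftir_search"
  out
}

#' @export
print.summary.ftir_search <- function(x, ...) {
  cat(sprintf("Model search: %d configurations (%d failed)\n", x$n, x$failed))
  cat(sprintf("  useful: %d, HPLC-comparable: %d\n", x$useful,
              x$hplc_comparable))
  cat("  useful models per factor level:\n")
  for (i in seq_len(nrow(x$marginals))) {
    cat(sprintf("    %-10s %-10s %d\n", x$marginals$factor[i],
                x$marginals$level[i], x$marginals$useful[i]))
  }
  invisible(x)
}

#' Write a search report to CSV and a JSON summary
#'
#' @param report An `ftir_search` data frame.
#' @param csv_path Path for the per-configuration CSV.
#' @param json_path Optional path for a JSON summary (useful and
#'   comparable counts plus per-factor marginals).
#' @return Invisibly, `csv_path`.
#' @export
write_search_report <- function(report, csv_path, json_path = NULL) {
  utils::write.csv(as.data.frame(report), csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    s <- summary(report)
    jsonlite::write_json(
      list(n_configurations = s$n, useful = s$useful,
           hplc_comparable = s$hplc_comparable, failed = s$failed,
           useful_by_factor = s$marginals),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(csv_path)
}
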