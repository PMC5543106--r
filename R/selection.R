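# Variable-selection schemes that reduce the transformed spectral
# variables to one quarter before PLS: RS1 (correlation ranking), RS2
# (band-region restriction then correlation), RS3 (pure-standard driven).

.selection_mask <- function(scheme, kept, p, wavenumbers = NULL,
                            implied_threshold = NA_real_) {
  structure(
    list(scheme = scheme, kept_indices = sort(as.integer(kept)),
         source_variable_count = as.integer(p),
         wavenumbers = wavenumbers,
         implied_threshold = implied_threshold),
    class = "selection_mask"
  )
}

#' @export
print.selection_mask <- function(x, ...) {
  cat(sprintf("<selection_mask> %s: kept %d of %d variables\n",
              x$scheme, length(x$kept_indices), x$source_variable_count))
  if (is.finite(x$implied_threshold)) {
    cat(sprintf("  implied normalized-intensity threshold: %.3f\n",
                x$implied_threshold))
  }
  invisible(x)
}

# Column-wise Pearson correlation with y; zero-variance columns (or a
# zero-variance y) get correlation 0, so ties resolve to the lowest index.
.col_correlations <- function(X, y) {
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  Xc <- sweep(X, 2L, colMeans(X))
  sx <- sqrt(colSums(Xc^2))
  r <- as.vector(crossprod(Xc, yc))
  denom <- sx * sy
  ifelse(denom > 0, r / denom, 0)
}

.top_quarter <- function(score, p) {
  k <- floor(p / 4)
  if (k < 1L) stop("fewer than 4 variables: nothing to select", call. = FALSE)
  order(-score, seq_along(score))[seq_len(k)]
}

#' RS1: correlation-ranked variable selection
#'
#' Keeps the `floor(p/4)` transformed variables with the largest absolute
#' Pearson correlation with the reference concentrations, computed on the
#' calibration rows only. Ties (including the all-zero correlations of a
#' constant response) are broken toward the lower column index.
#'
#' @param X_cal Calibration matrix, samples x transformed variables.
#' @param y_cal Reference concentration vector for the calibration rows.
#' @return A `selection_mask`.
#' @export
rs1_select <- function(X_cal, y_cal) {
  X_cal <- as.matrix(X_cal)
  if (nrow(X_cal) < 3L) {
    stop("rs1_select needs at least 3 calibration rows", call. = FALSE)
  }
  r <- .col_correlations(X_cal, y_cal)
  kept <- .top_quarter(abs(r), ncol(X_cal))
  .selection_mask("RS1", kept, ncol(X_cal))
}

#' Band-region mask for the standards' absorption regions
#'
#' Indices of grid points falling in the two regions where the pure
#' flavonoid standards show most of their absorption: 500--1700 cm^-1 and
#' 2950--3500 cm^-1 (closed intervals). Together the regions cover half of
#' the 500--4000 cm^-1 span.
#'
#' @param wavenumbers Ascending numeric vector of wavenumber labels.
#' @return Integer vector of indices into `wavenumbers`.
#' @export
region_mask <- function(wavenumbers) {
  which((wavenumbers >= 500 & wavenumbers <= 1700) |
          (wavenumbers >= 2950 & wavenumbers <= 3500))
}

#' RS2: region restriction followed by correlation ranking
#'
#' First restricts to variables whose wavenumber labels fall in the
#' standards' absorption regions (about half of the variables), then keeps
#' the `floor(p/4)` of them (p = total variable count) with the largest
#' absolute correlation with the calibration response. The kept set is
#' always a subset of the region.
#'
#' @inheritParams rs1_select
#' @param wavenumbers Wavenumber label per transformed variable (see
#'   [wavenumber_lineage()]).
#' @return A `selection_mask`.
#' @export
rs2_select <- function(X_cal, y_cal, wavenumbers) {
  X_cal <- as.matrix(X_cal)
  p <- ncol(X_cal)
  if (length(wavenumbers) != p) {
    stop("wavenumber labels must match the number of columns", call. = FALSE)
  }
  if (nrow(X_cal) < 3L) {
    stop("rs2_select needs at least 3 calibration rows", call. = FALSE)
  }
  region <- region_mask(wavenumbers)
  k <- floor(p / 4)
  if (length(region) < k) {
    stop("the absorption regions contain fewer variables than must be kept",
         call. = FALSE)
  }
  r <- .col_correlations(X_cal[, region, drop = FALSE], y_cal)
  kept <- region[order(-abs(r), seq_along(r))[seq_len(k)]]
  .selection_mask("RS2", kept, p)
}

#' RS3: selection from the normalized standard spectra
#'
#' Each pretreated standard spectrum is min-max normalized to \[0, 1\] (on
#' absolute values when the chain can produce negative variables, i.e.
#' derivative or wavelet-detail chains: peak magnitude, not sign, marks
#' analyte absorption). The score of a variable is the maximum over the
#' three standards, and the `floor(p/4)` top-scoring variables are kept.
#' The implied intensity threshold -- the score of the last variable kept
#' -- is reported; for raw spectra it falls near the conventional 0.4
#' normalized-intensity cutoff. The selection depends only on the
#' standards, never on sample spectra or reference values.
#'
#' @param standards_transformed Matrix (or list of 3 vectors) of the three
#'   standard spectra after the same pretreatment chain and resolution as
#'   the sample data; columns or elements named QE, QI, RUT in any order.
#' @return A `selection_mask` with `implied_threshold` set.
#' @export
rs3_select <- function(standards_transformed) {
  if (is.list(standards_transformed) && !is.matrix(standards_transformed)) {
    lens <- lengths(standards_transformed)
    if (length(unique(lens)) != 1L) {
      stop("standards are on mismatched grids", call. = FALSE)
    }
    standards_transformed <- do.call(cbind, standards_transformed)
  }
  S <- as.matrix(standards_transformed)
  if (ncol(S) != 3L) stop("exactly 3 standard spectra are required",
                          call. = FALSE)
  p <- nrow(S)
  norm01 <- function(v) {
    if (any(v < 0)) v <- abs(v)
    rng <- range(v)
    if (rng[2L] == rng[1L]) return(rep(0, length(v)))
    (v - rng[1L]) / (rng[2L] - rng[1L])
  }
  scores <- apply(S, 2L, norm01)
  score <- do.call(pmax, as.data.frame(scores))
  kept <- .top_quarter(score, p)
  .selection_mask("RS3", kept, p, implied_threshold = min(score[kept]))
}

#' Wavenumber labels of transformed variables
#'
#' Tracks which wavenumber each transformed variable represents through a
#' pretreatment chain, so region masks and reporting survive the index
#' shifts of derivatives and wavelet pairing: a derivative variable is
#' labeled by the midpoint of the two points it differences; a wavelet
#' variable by the midpoint of its input pair (the replicated edge pair of
#' an odd-length grid keeps the edge wavenumber). Composition follows the
#' chain order (base transform, then derivative).
#'
#' @param chain A `pretreatment_chain` or chain label.
#' @param grid Wavenumber grid of the raw spectra.
#' @return Numeric vector: one wavenumber label per transformed variable.
#' @export
wavenumber_lineage <- function(chain, grid) {
  if (is.character(chain)) chain <- pretreatment_chain(chain)
  labels <- grid
  if (chain$base %in% c("wavelet_approx", "wavelet_detail")) {
    n <- length(labels)
    if (n %% 2L == 1L) labels <- c(labels, labels[n])
    labels <- (labels[c(TRUE, FALSE)] + labels[c(FALSE, TRUE)]) / 2
  }
  if (chain$derivative) {
    labels <- (labels[-1L] + labels[-length(labels)]) / 2
  }
  labels
}

#' Serialize a selection mask to JSON
#'
#' Writes the scheme, kept indices, their wavenumber labels (when known)
#' and the implied RS3 threshold, enabling marked-wavenumber reports.
#'
#' @param mask A `selection_mask`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_mask_json <- function(mask, path) {
  stopifnot(inherits(mask, "selection_mask"))
  obj <- list(scheme = mask$scheme,
              source_variable_count = mask$source_variable_count,
              kept_indices = mask$kept_indices,
              implied_threshold = mask$implied_threshold)
  if (!is.null(mask$wavenumbers)) {
    obj$kept_wavenumbers <- mask$wavenumbers[mask$kept_indices]
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
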