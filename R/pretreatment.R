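# Per-spectrum pretreatment transforms and the eight chains built from
# them: {none, SNV, Haar approximation, Haar detail} x {with, without
# first derivative}.

#' Standard normal variate transform
#'
#' Per-spectrum standardization: subtract the mean and divide by the sample
#' (n-1) standard deviation. Removes multiplicative scatter and constant
#' offset: `snv(a*x + b) == snv(x)` for any `a > 0`.
#'
#' @param values Numeric vector (one spectrum), length >= 2, non-constant.
#' @return Numeric vector with mean 0 and sample SD 1.
#' @export
snv <- function(values) {
  if (length(values) < 2L) stop("snv needs at least 2 points", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("snv is undefined for a zero-variance (constant) spectrum",
         call. = FALSE)
  }
  (values - mean(values)) / s
}

#' First derivative by successive differences
#'
#' `x[k+1] - x[k]` over unit grid steps. The grid spacing is constant
#' within a resolution, so the omitted 1/spacing factor is a fixed scale
#' that mean-centered PLS is invariant to.
#'
#' @param values Numeric vector, length >= 2.
#' @return Numeric vector of length `length(values) - 1`.
#' @export
first_derivative <- function(values) {
  if (length(values) < 2L) {
    stop("first_derivative needs at least 2 points", call. = FALSE)
  }
  diff(values)
}

#' Single-level orthonormal Haar wavelet transform
#'
#' Pairs successive points and returns the approximation coefficients
#' `(a + b) / sqrt(2)` and detail coefficients `(a - b) / sqrt(2)`.
#' Odd-length input is padded by replicating the last point before
#' pairing. The transform conserves energy:
#' `sum(approx^2) + sum(detail^2)` equals the squared norm of the
#' (padded) input.
#'
#' @param values Numeric vector, length >= 2.
#' @return List with elements `approx`, `detail` (each of length
#'   `ceiling(length(values) / 2)`) and `original_length`.
#' @export
haar_transform <- function(values) {
  n <- length(values)
  if (n < 2L) stop("haar_transform needs at least 2 points", call. = FALSE)
  if (n %% 2L == 1L) values <- c(values, values[n])
  a <- values[c(TRUE, FALSE)]
  b <- values[c(FALSE, TRUE)]
  list(approx = (a + b) / sqrt(2), detail = (a - b) / sqrt(2),
       original_length = n)
}

#' Inverse of the single-level Haar transform
#'
#' @param approx,detail Coefficient vectors from [haar_transform()].
#' @param original_length Length of the original vector (drops the pad
#'   point for odd-length inputs); defaults to twice the coefficient
#'   length.
#' @return The reconstructed numeric vector.
#' @export
haar_inverse <- function(approx, detail, original_length = 2L * length(approx)) {
  if (length(approx) != length(detail)) {
    stop("approx and detail must have equal length", call. = FALSE)
  }
  out <- numeric(2L * length(approx))
  out[c(TRUE, FALSE)] <- (approx + detail) / sqrt(2)
  out[c(FALSE, TRUE)] <- (approx - detail) / sqrt(2)
  out[seq_len(original_length)]
}

#' The eight pretreatment chains
#'
#' Every chain is a base transform (`none`, `snv`, `wavelet_approx`,
#' `wavelet_detail`) optionally followed by the first derivative, giving
#' the untreated chain plus seven non-identity pretreatments. Labels follow
#' the reporting vocabulary: `none`, `deriv`, `SNV`, `SNV+deriv`, `WA`,
#' `WA+deriv`, `WD`, `WD+deriv`.
#'
#' @return Data frame with columns `label`, `base`, `derivative`.
#' @export
pretreatment_chains <- function() {
  base <- c("none", "snv", "wavelet_approx", "wavelet_detail")
  out <- expand.grid(base = base, derivative = c(FALSE, TRUE),
                     stringsAsFactors = FALSE)
  lab <- c(none = "none", snv = "SNV", wavelet_approx = "WA",
           wavelet_detail = "WD")
  out$label <- paste0(lab[out$base], ifelse(out$derivative, "+deriv", ""))
  out$label[out$label == "none+deriv"] <- "deriv"
  out[c("label", "base", "derivative")]
}

#' Construct a pretreatment chain
#'
#' @param base One of `"none"`, `"snv"`, `"wavelet_approx"`,
#'   `"wavelet_detail"`, or a chain label such as `"WA+deriv"` (in which
#'   case `derivative` is taken from the label).
#' @param derivative Logical: apply the first derivative after the base
#'   transform?
#' @return An object of class `pretreatment_chain`.
#' @export
pretreatment_chain <- function(base = "none", derivative = FALSE) {
  tab <- pretreatment_chains()
  if (base %in% tab$label && missing(derivative)) {
    row <- tab[tab$label == base, ]
    base <- row$base
    derivative <- row$derivative
  }
  if (!base %in% unique(tab$base)) {
    stop(sprintf("unknown pretreatment base '%s'", base), call. = FALSE)
  }
  label <- tab$label[tab$base == base & tab$derivative == derivative]
  structure(list(base = base, derivative = isTRUE(derivative), label = label),
            class = "pretreatment_chain")
}

#' @export
print.pretreatment_chain <- function(x, ...) {
  cat(sprintf("<pretreatment_chain> %s\n", x$label))
  invisible(x)
}

#' Apply a pretreatment chain to one spectrum
#'
#' The base transform is applied first, then (if configured) the first
#' derivative of its output -- the derivative always acts on the
#' transformed data, never the other way round. The `(none, FALSE)` chain
#' is the identity.
#'
#' @param chain A `pretreatment_chain` or a chain label string.
#' @param values Numeric vector (one spectrum's absorbances or transformed
#'   variables).
#' @return Numeric vector of transformed variables.
#' @export
apply_chain <- function(chain, values) {
  if (is.character(chain)) chain <- pretreatment_chain(chain)
  stopifnot(inherits(chain, "pretreatment_chain"))
  out <- switch(chain$base,
                none = values,
                snv = snv(values),
                wavelet_approx = haar_transform(values)$approx,
                wavelet_detail = haar_transform(values)$detail)
  if (chain$derivative) out <- first_derivative(out)
  out
}
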