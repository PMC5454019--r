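#' Spectral bleed-through correction factors
#'
#' The three-filter FRET correction needs two dimensionless fractions:
#' `d`, the fraction of donor fluorescence leaking into the raw FRET channel
#' (measured on a donor-only control), and `a`, the corresponding acceptor
#' fraction (acceptor-only control). Both are estimated from single-stain
#' control triples by regressing the raw FRET channel on the stained channel
#' over foreground pixels.
#'
#' @param d,a Non-negative fractions.
#' @param method Estimator label.
#' @param n_pixels_used Named integer vector (pixels behind each factor).
#' @return A `bleedthrough_factors` object.
#' @export
bleedthrough_factors <- function(d, a, method = "manual",
                                 n_pixels_used = c(d = NA_integer_, a = NA_integer_)) {
  if (d < 0 || a < 0) {
    abort("bleed-through factors must be non-negative.", class = "fretcoloc_value_error")
  }
  if (d >= 1 || a >= 1) {
    warn(sprintf("bleed-through factor >= 1 (d = %.3g, a = %.3g): check control images.", d, a))
  }
  structure(
    list(d = as.numeric(d), a = as.numeric(a), method = method,
         n_pixels_used = n_pixels_used),
    class = "bleedthrough_factors"
  )
}

#' @export
print.bleedthrough_factors <- function(x, ...) {
  cat(sprintf("<bleedthrough_factors> d = %.4f, a = %.4f (%s; n = %s/%s px)\n",
              x$d, x$a, x$method,
              format(x$n_pixels_used[["d"]]), format(x$n_pixels_used[["a"]])))
  invisible(x)
}

# Shared machinery: fit rawFRET against the single-stain channel over
# thresholded, unsaturated foreground pixels of a control triple.
estimate_bleedthrough <- function(control, stained = c("donor", "acceptor"),
                                  mask_method = "moments",
                                  estimator = c("slope", "median_ratio", "sum_ratio"),
                                  min_foreground = 50L) {
  stained <- match.arg(stained)
  estimator <- match.arg(estimator)
  stopifnot(inherits(control, "triple_stack"))
  ref <- control[[stained]]
  fg <- auto_threshold(ref, method = mask_method)$pixels
  sat <- stack_saturated_any(control)
  use <- fg & !sat
  n <- sum(use)
  if (n < min_foreground) {
    abort(sprintf(
      "calibration failed: only %d unsaturated foreground pixels in the %s channel (need >= %d)",
      n, stained, min_foreground), class = "fretcoloc_calibration_error")
  }
  x <- ref$pixels[use]
  y <- control$rawfret$pixels[use]
  value <- switch(estimator,
    slope = {
      sxx <- sum(x * x)
      if (sxx == 0) 0 else sum(x * y) / sxx
    },
    median_ratio = {
      pos <- x > 0
      if (!any(pos)) 0 else stats::median(y[pos] / x[pos])
    },
    sum_ratio = if (sum(x) == 0) 0 else sum(y) / sum(x)
  )
  if (value < 0) {
    warn(sprintf("fitted %s bleed-through slope was negative (%.4g); clipped to 0.",
                 stained, value))
    value <- 0
  }
  if (value >= 1) {
    warn(sprintf(
      "fitted %s bleed-through factor is >= 1 (%.4g): the control leaks as much as it emits; check the control images.",
      stained, value))
  }
  list(value = value, n_pixels_used = n, method = paste0(estimator, "/", mask_method),
       bit_depth = ref$bit_depth)
}

stack_saturated_any <- function(stack) {
  stack$saturation_masks$donor | stack$saturation_masks$acceptor |
    stack$saturation_masks$rawfret
}

#' Estimate the donor bleed-through factor from a donor-only control
#'
#' Fits the proportional bleed-through model `rawFRET = d * DF` over the
#' thresholded, unsaturated foreground of the donor channel. The default
#' estimator is the least-squares slope through the origin, matching the
#' proportional model of the Youvan correction; `median_ratio` (median of
#' per-pixel rawFRET/DF) and `sum_ratio` (ratio of summed intensities) are
#' offered as robust alternatives. No background subtraction is applied.
#'
#' @param control A [triple_stack()] of a donor-only stained sample.
#' @param mask_method Automated threshold method used to define foreground
#'   on the donor channel (see [auto_threshold()]).
#' @param estimator `"slope"` (default), `"median_ratio"` or `"sum_ratio"`.
#' @param min_foreground Minimum number of usable foreground pixels.
#' @return A list with `d`, `n_pixels_used`, `method`, `bit_depth`.
#' @export
estimate_donor_factor <- function(control, mask_method = "moments",
                                  estimator = "slope", min_foreground = 50L) {
  est <- estimate_bleedthrough(control, "donor", mask_method, estimator, min_foreground)
  list(d = est$value, n_pixels_used = est$n_pixels_used, method = est$method,
       bit_depth = est$bit_depth)
}

#' Estimate the acceptor bleed-through factor from an acceptor-only control
#'
#' Symmetric to [estimate_donor_factor()], with the acceptor channel (AF)
#' in place of the donor channel.
#'
#' @inheritParams estimate_donor_factor
#' @param control A [triple_stack()] of an acceptor-only stained sample.
#' @return A list with `a`, `n_pixels_used`, `method`, `bit_depth`.
#' @export
estimate_acceptor_factor <- function(control, mask_method = "moments",
                                     estimator = "slope", min_foreground = 50L) {
  est <- estimate_bleedthrough(control, "acceptor", mask_method, estimator, min_foreground)
  list(a = est$value, n_pixels_used = est$n_pixels_used, method = est$method,
       bit_depth = est$bit_depth)
}

#' Merge donor and acceptor calibration fragments
#'
#' @param d_fragment Result of [estimate_donor_factor()].
#' @param a_fragment Result of [estimate_acceptor_factor()].
#' @return A [bleedthrough_factors()] object.
#' @export
combine_factors <- function(d_fragment, a_fragment) {
  if (is.null(d_fragment$d) || is.null(a_fragment$a)) {
    abort("both a donor fragment (d) and an acceptor fragment (a) are required.",
          class = "fretcoloc_value_error")
  }
  bd <- d_fragment$bit_depth
  ba <- a_fragment$bit_depth
  if (!is.null(bd) && !is.null(ba) && !identical(bd, ba)) {
    warn(sprintf("calibration fragments come from different bit depths (%d vs %d).", bd, ba))
  }
  bleedthrough_factors(
    d = d_fragment$d, a = a_fragment$a,
    method = paste(unique(c(d_fragment$method, a_fragment$method)), collapse = ";"),
    n_pixels_used = c(d = d_fragment$n_pixels_used %||% NA_integer_,
                      a = a_fragment$n_pixels_used %||% NA_integer_)
  )
}

#' Write / read bleed-through factors as JSON
#'
#' Small sidecar format so `calibrate` runs can feed `analyze`/`batch` runs.
#'
#' @param factors A [bleedthrough_factors()].
#' @param path JSON file path.
#' @return `path` (write) or a [bleedthrough_factors()] (read).
#' @export
write_factors <- function(factors, path) {
  stopifnot(inherits(factors, "bleedthrough_factors"))
  jsonlite::write_json(
    list(d = factors$d, a = factors$a, method = factors$method,
         n_pixels_used = as.list(factors$n_pixels_used)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_factors
#' @export
read_factors <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  bleedthrough_factors(
    d = x$d, a = x$a, method = x$method %||% "file",
    n_pixels_used = c(d = x$n_pixels_used$d %||% NA_integer_,
                      a = x$n_pixels_used$a %||% NA_integer_))
}
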