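#' Bleed-through-corrected FRET image (Youvan FRETc)
#'
#' Subtracts the spectral bleed-through of donor and acceptor from the raw
#' FRET channel, pixel by pixel:
#'
#' \deqn{FRETc = rawFRET - d \cdot DF - a \cdot AF}
#'
#' Negative values are preserved — they are genuine noise excursions around
#' zero in non-interacting samples, and clipping them would bias object
#' means toward false-positive FRET. Clipping happens only at rendering
#' time ([render_fretc()]).
#'
#' @param stack A [triple_stack()], or a named list with numeric matrices
#'   `donor`, `acceptor`, `rawfret` (useful for synthetic float inputs).
#' @param factors A [bleedthrough_factors()].
#' @return Numeric matrix of FRETc values (may be negative).
#' @export
compute_fretc <- function(stack, factors) {
  stopifnot(inherits(factors, "bleedthrough_factors"))
  g <- stack_grids(stack)
  g$rawfret - factors$d * g$donor - factors$a * g$acceptor
}

stack_grids <- function(stack) {
  if (inherits(stack, "triple_stack")) {
    list(donor = stack$donor$pixels, acceptor = stack$acceptor$pixels,
         rawfret = stack$rawfret$pixels)
  } else if (is.list(stack) &&
             all(c("donor", "acceptor", "rawfret") %in% names(stack))) {
    grids <- stack[c("donor", "acceptor", "rawfret")]
    grids <- lapply(grids, function(m) if (inherits(m, "channel_image")) m$pixels else m)
    dims <- lapply(grids, dim)
    if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
      abort("donor, acceptor and rawfret grids must share dimensions.",
            class = "fretcoloc_shape_error")
    }
    grids
  } else {
    abort("`stack` must be a triple_stack or a list(donor=, acceptor=, rawfret=).",
          class = "fretcoloc_value_error")
  }
}

#' Normalized FRET image (Xia NFRET)
#'
#' Normalizes FRETc by the geometric mean of the fluorophore amounts,
#' \eqn{NFRET = FRETc / \sqrt{DF \cdot AF}}, making FRET levels comparable
#' between sites with different staining intensity. Pixels where `DF = 0`
#' or `AF = 0` carry no information about the ratio and are marked
#' undefined (`NA`), never coerced to 0 — a 0 would masquerade as a
#' measured negative result. Aggregation downstream skips `NA` pixels.
#'
#' @param fretc FRETc matrix from [compute_fretc()].
#' @param stack The [triple_stack()] (or grid list) the FRETc came from.
#' @return Numeric matrix of NFRET values with `NA` where undefined.
#' @export
compute_nfret <- function(fretc, stack) {
  g <- stack_grids(stack)
  if (!identical(dim(fretc), dim(g$donor))) {
    abort("`fretc` dimensions must match the stack.", class = "fretcoloc_shape_error")
  }
  defined <- g$donor > 0 & g$acceptor > 0
  out <- matrix(NA_real_, nrow(fretc), ncol(fretc))
  out[defined] <- fretc[defined] / sqrt(g$donor[defined] * g$acceptor[defined])
  out
}

#' FRETc + NFRET image pair
#'
#' Convenience constructor running both corrections and keeping the factors
#' used alongside the results.
#'
#' @inheritParams compute_fretc
#' @return A `fret_images` object: list with `fretc`, `nfret`,
#'   `factors_used`.
#' @export
fret_images <- function(stack, factors) {
  fretc <- compute_fretc(stack, factors)
  structure(
    list(fretc = fretc, nfret = compute_nfret(fretc, stack), factors_used = factors),
    class = "fret_images"
  )
}

#' @export
print.fret_images <- function(x, ...) {
  cat(sprintf("<fret_images> %dx%d px; FRETc range [%.1f, %.1f]; d = %.4f, a = %.4f\n",
              nrow(x$fretc), ncol(x$fretc), min(x$fretc), max(x$fretc),
              x$factors_used$d, x$factors_used$a))
  invisible(x)
}

fretc_palette <- function(colormap = c("fire", "jet", "gray"), n = 256L) {
  colormap <- match.arg(colormap)
  cols <- switch(colormap,
    fire = c("#000000", "#400080", "#B00000", "#FF8000", "#FFFF00", "#FFFFFF"),
    jet  = c("#00007F", "#0000FF", "#00FFFF", "#FFFF00", "#FF0000", "#7F0000"),
    gray = c("#000000", "#FFFFFF"))
  grDevices::colorRampPalette(cols)(n)
}

#' Pseudo-color rendering of a FRETc image
#'
#' Multiplies FRETc by a display gain (x10 by default, matching common
#' practice of amplifying weak sensitized-emission signals for display),
#' clips to `[0, display_max]`, and maps through a pseudo-color lookup
#' table. A vertical gradient color-bar strip is appended on the right;
#' the value breaks it spans are returned in the `"scale"` attribute (and
#' are drawn as labeled guides by [plot_fretc()]).
#'
#' Negative FRETc pixels render at the lowest color — display clipping
#' only, the underlying statistics keep the negatives.
#'
#' @param fretc FRETc matrix.
#' @param gain Positive display gain (default 10).
#' @param colormap `"fire"` (default), `"jet"` or `"gray"`.
#' @param display_max Ceiling of the display range after gain; defaults to
#'   4095 (12-bit display scale).
#' @param bar_width Width of the appended color-bar strip in pixels; 0
#'   suppresses it.
#' @return An `rows x (cols + bar) x 3` RGB array in `[0, 1]` with
#'   attributes `scale` (value breaks) and `gain`.
#' @export
render_fretc <- function(fretc, gain = 10, colormap = "fire", display_max = 4095,
                         bar_width = 12L) {
  if (gain <= 0) abort("`gain` must be positive.", class = "fretcoloc_config_error")
  pal <- fretc_palette(colormap)
  n <- length(pal)
  scaled <- pmin(pmax(fretc * gain, 0), display_max) / display_max
  idx <- pmin(floor(scaled * n) + 1L, n)
  rgbm <- grDevices::col2rgb(pal[idx]) / 255
  out <- array(0, dim = c(nrow(fretc), ncol(fretc), 3L))
  out[, , 1] <- matrix(rgbm[1, ], nrow(fretc), ncol(fretc))
  out[, , 2] <- matrix(rgbm[2, ], nrow(fretc), ncol(fretc))
  out[, , 3] <- matrix(rgbm[3, ], nrow(fretc), ncol(fretc))
  if (bar_width > 0) {
    # bar runs top (display_max) to bottom (0)
    bar_vals <- seq(1, 0, length.out = nrow(fretc))
    bar_idx <- pmin(floor(bar_vals * n) + 1L, n)
    bar_rgb <- grDevices::col2rgb(pal[bar_idx]) / 255
    bar <- array(0, dim = c(nrow(fretc), bar_width, 3L))
    for (k in 1:3) bar[, , k] <- matrix(bar_rgb[k, ], nrow(fretc), bar_width)
    full <- array(0, dim = c(nrow(fretc), ncol(fretc) + bar_width + 2L, 3L))
    full[, seq_len(ncol(fretc)), ] <- out
    full[, ncol(fretc) + 1:2, ] <- 1  # white gutter
    full[, (ncol(fretc) + 3L):(ncol(fretc) + 2L + bar_width), ] <- bar
    out <- full
  }
  breaks <- seq(0, display_max / gain, length.out = 5)
  structure(out, scale = breaks, gain = gain, colormap = colormap,
            display_max = display_max)
}

#' Write a pseudo-color FRETc rendering to PNG
#'
#' @param rendering RGB array from [render_fretc()] (or a FRETc matrix, in
#'   which case `...` is forwarded to [render_fretc()]).
#' @param path PNG output path.
#' @param ... Passed to [render_fretc()] when `rendering` is a matrix.
#' @return `path`, invisibly.
#' @export
write_fretc_png <- function(rendering, path, ...) {
  if (is.matrix(rendering)) rendering <- render_fretc(rendering, ...)
  png::writePNG(rendering, path)
  invisible(path)
}

#' Export a real-valued FRET map as scaled 32-bit TIFF + JSON sidecar
#'
#' FRETc/NFRET grids are real-valued (and can be negative), while baseline
#' TIFF containers here store scaled unsigned integers. The grid is mapped
#' affinely onto `[0, 1]`, written as a 32-bit TIFF (precision
#' `range / 2^32`), and the mapping (`offset`, `scale`) plus the undefined-
#' pixel mask are recorded in a JSON sidecar next to the image so
#' [read_float_tiff()] can invert it.
#'
#' @param grid Real-valued matrix (`NA` = undefined).
#' @param path Output TIFF path; the sidecar is `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_float_tiff <- function(grid, path) {
  finite <- is.finite(grid)
  rng <- if (any(finite)) range(grid[finite]) else c(0, 0)
  span <- if (diff(rng) > 0) diff(rng) else 1
  scaled <- (grid - rng[1]) / span
  scaled[!finite] <- 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(
    list(offset = rng[1], scale = span,
         na_index = which(!finite)),  # column-major indices
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_float_tiff
#' @export
read_float_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  scaled <- tiff::readTIFF(path)
  out <- scaled * meta$scale + meta$offset
  if (length(meta$na_index)) out[meta$na_index] <- NA_real_
  out
}
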