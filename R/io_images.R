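#' Single-channel microscopy image
#'
#' Wraps a 2-D grid of non-negative integer intensities together with the
#' detector bit depth and the channel role it plays in a three-filter FRET
#' acquisition: `donor` (donor emission at donor excitation, DF), `acceptor`
#' (acceptor emission at acceptor excitation, AF), or `rawfret` (acceptor
#' emission at donor excitation).
#'
#' The saturation ceiling is taken from the declared `bit_depth`, not from
#' the storage container: 12-bit data saved inside a 16-bit TIFF saturates
#' at 4095, and every pixel at `2^bit_depth - 1` is treated as clipped.
#'
#' @param pixels Numeric or integer matrix of non-negative intensities.
#' @param bit_depth Integer, one of 8, 12 or 16.
#' @param role One of `"donor"`, `"acceptor"`, `"rawfret"`.
#' @return A `channel_image` object.
#' @export
channel_image <- function(pixels, bit_depth, role = c("donor", "acceptor", "rawfret")) {
  role <- match.arg(role)
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L) {
    abort("`pixels` must be a matrix with at least one row and one column.",
          class = "fretcoloc_shape_error")
  }
  if (!bit_depth %in% c(8L, 12L, 16L)) {
    abort("`bit_depth` must be 8, 12 or 16.", class = "fretcoloc_config_error")
  }
  px <- pixels
  storage.mode(px) <- "double"
  if (anyNA(px) || any(px < 0) || any(px != floor(px))) {
    abort("`pixels` must contain non-negative integers only.",
          class = "fretcoloc_value_error")
  }
  ceiling_value <- 2^bit_depth - 1
  if (any(px > ceiling_value)) {
    abort(sprintf("pixel values exceed the %d-bit maximum of %d", bit_depth, ceiling_value),
          class = "fretcoloc_bitdepth_error")
  }
  structure(
    list(pixels = px, bit_depth = as.integer(bit_depth), role = role),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s, %dx%d px, %d-bit (max code %d), %d saturated px\n",
              x$role, nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              max_code(x), sum(saturation_mask(x))))
  invisible(x)
}

max_code <- function(channel) 2^channel$bit_depth - 1

#' Saturation mask of a channel
#'
#' Boolean grid, `TRUE` exactly where a pixel sits at the maximum code value
#' `2^bit_depth - 1` of the declared bit depth.
#'
#' @param channel A [channel_image()].
#' @return Logical matrix with the channel's dimensions.
#' @export
saturation_mask <- function(channel) {
  channel$pixels == max_code(channel)
}

#' Co-registered donor / acceptor / raw-FRET image triple
#'
#' The unit of analysis for three-filter FRET: the donor channel (DF), the
#' acceptor channel (AF) and the raw FRET channel imaged over the same field.
#' All three grids must share dimensions and bit depth; per-channel
#' saturation masks are computed on construction.
#'
#' @param donor,acceptor,rawfret [channel_image()] objects (roles are
#'   re-assigned to donor/acceptor/rawfret respectively).
#' @param source_id Character scalar identifying the field of view.
#' @return A `triple_stack` object with elements `donor`, `acceptor`,
#'   `rawfret`, `saturation_masks` (named list of logical matrices) and
#'   `source_id`.
#' @export
triple_stack <- function(donor, acceptor, rawfret, source_id = "stack") {
  chans <- list(donor = donor, acceptor = acceptor, rawfret = rawfret)
  for (nm in names(chans)) {
    if (!inherits(chans[[nm]], "channel_image")) {
      abort(sprintf("`%s` must be a channel_image.", nm), class = "fretcoloc_value_error")
    }
  }
  dims <- lapply(chans, function(ch) dim(ch$pixels))
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    abort("donor, acceptor and rawfret channels must share identical dimensions.",
          class = "fretcoloc_shape_error")
  }
  depths <- vapply(chans, function(ch) ch$bit_depth, integer(1))
  if (length(unique(depths)) != 1L) {
    abort("all channels of a triple must share one bit depth.",
          class = "fretcoloc_bitdepth_error")
  }
  chans$donor$role <- "donor"
  chans$acceptor$role <- "acceptor"
  chans$rawfret$role <- "rawfret"
  structure(
    list(
      donor = chans$donor,
      acceptor = chans$acceptor,
      rawfret = chans$rawfret,
      saturation_masks = lapply(chans, saturation_mask),
      source_id = as.character(source_id)
    ),
    class = "triple_stack"
  )
}

#' @export
print.triple_stack <- function(x, ...) {
  sat <- vapply(x$saturation_masks, sum, numeric(1))
  cat(sprintf("<triple_stack> '%s': %dx%d px, %d-bit; saturated px donor/acceptor/rawfret: %d/%d/%d\n",
              x$source_id, nrow(x$donor$pixels), ncol(x$donor$pixels),
              x$donor$bit_depth, sat[["donor"]], sat[["acceptor"]], sat[["rawfret"]]))
  invisible(x)
}

#' @export
dim.triple_stack <- function(x) dim(x$donor$pixels)

read_tiff_grid <- function(path, bit_depth, page = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("image file not found: %s", path), class = "fretcoloc_io_error")
  }
  img <- tiff::readTIFF(path, as.is = TRUE, all = !is.null(page))
  if (!is.null(page)) {
    if (page > length(img)) {
      abort(sprintf("%s has %d page(s); page %d requested", path, length(img), page),
            class = "fretcoloc_io_error")
    }
    img <- img[[page]]
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] != 1L) {
      abort(sprintf("%s is not single-plane grayscale", path), class = "fretcoloc_io_error")
    }
    img <- img[, , 1L]
  }
  if (any(img > 2^bit_depth - 1)) {
    abort(sprintf("pixels in '%s' exceed the declared %d-bit maximum (%d)",
                  path, bit_depth, 2^bit_depth - 1),
          class = "fretcoloc_bitdepth_error")
  }
  storage.mode(img) <- "double"
  img
}

#' Load a donor / acceptor / raw-FRET triple from TIFF files
#'
#' Reads three single-plane grayscale TIFFs (or three pages of one
#' multi-page TIFF, in donor, acceptor, rawfret page order) into a
#' [triple_stack()], validating dimensions against each other and pixel
#' values against the declared bit depth.
#'
#' @param donor_path,acceptor_path,rawfret_path TIFF file paths. For a
#'   multi-page file pass the same path three times with
#'   `pages = c(1, 2, 3)` (or the relevant page order).
#' @param bit_depth Declared A/D bit depth (8, 12 or 16); 12-bit data in a
#'   16-bit container is declared as 12.
#' @param pages Optional integer vector of length 3 selecting TIFF pages.
#' @param source_id Identifier; defaults to the donor file name stem.
#' @return A [triple_stack()].
#' @export
load_triple <- function(donor_path, acceptor_path, rawfret_path, bit_depth = 12,
                        pages = NULL, source_id = NULL) {
  if (!is.null(pages) && length(pages) != 3L) {
    abort("`pages` must have length 3 (donor, acceptor, rawfret).",
          class = "fretcoloc_config_error")
  }
  paths <- c(donor_path, acceptor_path, rawfret_path)
  grids <- lapply(seq_along(paths), function(i) {
    read_tiff_grid(paths[i], bit_depth, page = if (is.null(pages)) NULL else pages[i])
  })
  dims <- lapply(grids, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    abort(sprintf(
      "channel dimension mismatch: donor %s, acceptor %s, rawfret %s",
      paste(dims[[1]], collapse = "x"), paste(dims[[2]], collapse = "x"),
      paste(dims[[3]], collapse = "x")), class = "fretcoloc_shape_error")
  }
  if (is.null(source_id)) {
    source_id <- tools::file_path_sans_ext(basename(donor_path))
  }
  triple_stack(
    donor    = channel_image(grids[[1]], bit_depth, "donor"),
    acceptor = channel_image(grids[[2]], bit_depth, "acceptor"),
    rawfret  = channel_image(grids[[3]], bit_depth, "rawfret"),
    source_id = source_id
  )
}

#' Write a channel to a grayscale TIFF
#'
#' Stores the integer intensities bit-exactly in an 8- or 16-bit unsigned
#' container (16-bit for any bit depth above 8), so that reading the file
#' back yields the identical pixel grid.
#'
#' @param channel A [channel_image()] (or bare integer matrix plus
#'   `bit_depth`).
#' @param path Output file path.
#' @param bit_depth Required when `channel` is a bare matrix.
#' @return `path`, invisibly.
#' @export
write_channel_tiff <- function(channel, path, bit_depth = NULL) {
  if (!inherits(channel, "channel_image")) {
    if (is.null(bit_depth)) {
      abort("`bit_depth` is required when writing a bare matrix.",
            class = "fretcoloc_config_error")
    }
    channel <- channel_image(channel, bit_depth, "donor")
  }
  container_bits <- if (channel$bit_depth <= 8L) 8L else 16L
  denom <- 2^container_bits - 1
  tiff::writeTIFF(channel$pixels / denom, path, bits.per.sample = container_bits,
                  compression = "none")
  invisible(path)
}

#' Audit detector saturation of a triple
#'
#' Reports, per channel, the fraction of pixels at the maximum code value of
#' the declared bit depth, plus an overall overexposure verdict. Correct
#' acquisition excludes any saturation, hence the default tolerance of 0;
#' a nonzero tolerance supports deliberate-overexposure comparison runs.
#'
#' @param stack A [triple_stack()].
#' @param tolerance Maximum tolerated saturated-pixel fraction per channel.
#' @return A tibble with columns `source_id`, `channel`,
#'   `saturated_fraction`, `n_saturated`, `n_pixels`, and the logical
#'   `overexposed` verdict (identical in every row: `TRUE` iff any channel
#'   fraction exceeds `tolerance`).
#' @export
saturation_report <- function(stack, tolerance = 0) {
  stopifnot(inherits(stack, "triple_stack"))
  n_px <- prod(dim(stack))
  out <- purrr::map_dfr(c("donor", "acceptor", "rawfret"), function(ch) {
    n_sat <- sum(stack$saturation_masks[[ch]])
    tibble(
      source_id = stack$source_id,
      channel = ch,
      saturated_fraction = n_sat / n_px,
      n_saturated = n_sat,
      n_pixels = n_px
    )
  })
  out$overexposed <- any(out$saturated_fraction > tolerance)
  out
}
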