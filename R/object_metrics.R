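object_pixel_sets <- function(objects) {
  stopifnot(inherits(objects, "labeled_objects"))
  idx <- which(objects$labels > 0L)
  split(idx, objects$labels[idx])
}

as_grid <- function(x) if (inherits(x, "channel_image")) x$pixels else x

#' Pearson correlation of donor/acceptor intensities per object
#'
#' For each labeled object, the product-moment correlation of the (DF, AF)
#' pixel pairs restricted to that object's pixel set. Computed on the raw
#' stain channels (not FRETc): the sensitized-emission contribution to the
#' stain channels is negligible relative to the staining itself, and the
#' correlation is meant to measure colocalization of the two markers.
#'
#' Objects smaller than 2 px, or in which either channel is constant, have
#' no defined correlation and get `NA` (excluded from aggregates, never
#' reported as 0).
#'
#' @param objects A [labeled_objects()] map.
#' @param donor,acceptor [channel_image()]s (or matrices) matching the map.
#' @return Tibble with columns `object_id`, `pearson`.
#' @export
pearson_per_object <- function(objects, donor, acceptor) {
  df <- as_grid(donor); af <- as_grid(acceptor)
  sets <- object_pixel_sets(objects)
  vals <- vapply(sets, function(ix) {
    if (length(ix) < 2L) return(NA_real_)
    x <- df[ix]; y <- af[ix]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }, numeric(1))
  tibble(object_id = as.integer(names(sets)), pearson = unname(vals))
}

#' Whole-image Pearson correlation
#'
#' The classical global pixel-intensity correlation over the full frame,
#' with no object restriction. Provided as the contrast to the per-object
#' values: bright disjoint structures on a dark background can drive this
#' global coefficient to misleadingly high values even when no structure
#' contains both markers.
#'
#' @inheritParams pearson_per_object
#' @return A single numeric value (`NA` if either channel is constant).
#' @export
whole_image_pearson <- function(donor, acceptor) {
  x <- as.numeric(as_grid(donor)); y <- as.numeric(as_grid(acceptor))
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Color-mix coefficient per object
#'
#' Per pixel, the ratio of the weaker to the stronger channel
#' (`min(DF, AF) / max(DF, AF)`, 0 when both are 0); the object value is
#' the mean over the object's pixels (default) or, alternatively, the
#' min/max ratio of the object channel means. Values lie in `[0, 1]`:
#' 1 is a complete color-mix of the two channels (the "yellow" of perfectly
#' overlapping red and green), 0 a single marker.
#'
#' @inheritParams pearson_per_object
#' @param mode `"pixel_mean"` (default) or `"ratio_of_means"`.
#' @return Tibble with columns `object_id`, `colormix`.
#' @export
colormix_per_object <- function(objects, donor, acceptor,
                                mode = c("pixel_mean", "ratio_of_means")) {
  mode <- match.arg(mode)
  df <- as_grid(donor); af <- as_grid(acceptor)
  sets <- object_pixel_sets(objects)
  vals <- vapply(sets, function(ix) {
    x <- df[ix]; y <- af[ix]
    if (mode == "pixel_mean") {
      mean(pixel_colormix(x, y))
    } else {
      mx <- mean(x); my <- mean(y)
      if (mx == 0 && my == 0) 0 else min(mx, my) / max(mx, my)
    }
  }, numeric(1))
  tibble(object_id = as.integer(names(sets)), colormix = unname(vals))
}

pixel_colormix <- function(x, y) {
  lo <- pmin(x, y); hi <- pmax(x, y)
  ifelse(hi == 0, 0, lo / hi)
}

#' Acceptor:donor intensity ratio per object
#'
#' `mean(AF) / mean(DF)` over the object's pixels; undefined (`NA`,
#' flagged) when the donor mean is 0 while acceptor signal is present.
#'
#' @inheritParams pearson_per_object
#' @return Tibble with columns `object_id`, `ad_ratio`.
#' @export
ad_ratio_per_object <- function(objects, donor, acceptor) {
  df <- as_grid(donor); af <- as_grid(acceptor)
  sets <- object_pixel_sets(objects)
  vals <- vapply(sets, function(ix) {
    md <- mean(df[ix]); ma <- mean(af[ix])
    if (md == 0) {
      if (ma == 0) 0 else NA_real_
    } else {
      ma / md
    }
  }, numeric(1))
  tibble(object_id = as.integer(names(sets)), ad_ratio = unname(vals))
}

#' Mean NFRET per object
#'
#' Default mode averages the defined per-pixel NFRET values inside the
#' object (`pixel_mean`); the alternative computes the ratio of object
#' means, `mean(FRETc) / sqrt(mean(DF) * mean(AF))` (`ratio_of_means`).
#' The two coincide on uniform objects. Objects without a single defined
#' NFRET pixel (pixel-mean mode) or with a zero channel mean (ratio mode)
#' are `NA`.
#'
#' @param objects A [labeled_objects()] map.
#' @param fret A [fret_images()] result.
#' @param stack The source [triple_stack()]; required for
#'   `mode = "ratio_of_means"`.
#' @param mode `"pixel_mean"` (default) or `"ratio_of_means"`.
#' @return Tibble with columns `object_id`, `mean_NFRET`.
#' @export
nfret_per_object <- function(objects, fret, stack = NULL,
                             mode = c("pixel_mean", "ratio_of_means")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fret, "fret_images"))
  sets <- object_pixel_sets(objects)
  if (mode == "pixel_mean") {
    nf <- fret$nfret
    vals <- vapply(sets, function(ix) {
      v <- nf[ix]
      v <- v[!is.na(v)]
      if (!length(v)) NA_real_ else mean(v)
    }, numeric(1))
  } else {
    if (is.null(stack)) {
      abort("`stack` is required for mode = \"ratio_of_means\".",
            class = "fretcoloc_config_error")
    }
    g <- stack_grids(stack)
    fc <- fret$fretc
    vals <- vapply(sets, function(ix) {
      md <- mean(g$donor[ix]); ma <- mean(g$acceptor[ix])
      if (md <= 0 || ma <= 0) NA_real_ else mean(fc[ix]) / sqrt(md * ma)
    }, numeric(1))
  }
  tibble(object_id = as.integer(names(sets)), mean_NFRET = unname(vals))
}

#' Colocalization area fraction
#'
#' Quantifies the colocalizing (intersection) regions as a percentage of
#' the combined (union) regions: per image `100 * |intersection| / |union|`
#' (0 for an empty union), and per union object the percentage of that
#' object's area lying inside the intersection mask.
#'
#' @param union_mask,intersection_mask [binary_mask()]s from
#'   [combine_union()] / [combine_intersection()].
#' @param objects Optional [labeled_objects()] over the union mask for the
#'   per-object percentages.
#' @return A list with `per_image_pct` (scalar) and `per_object` (tibble
#'   with `object_id`, `coloc_area_fraction_pct`; empty when `objects` is
#'   `NULL`).
#' @export
coloc_area_fraction <- function(union_mask, intersection_mask, objects = NULL) {
  stopifnot(inherits(union_mask, "binary_mask"), inherits(intersection_mask, "binary_mask"))
  n_union <- sum(union_mask$pixels)
  n_int <- sum(intersection_mask$pixels)
  per_image <- if (n_union == 0) 0 else 100 * n_int / n_union
  per_object <- tibble(object_id = integer(0), coloc_area_fraction_pct = numeric(0))
  if (!is.null(objects)) {
    sets <- object_pixel_sets(objects)
    inter <- intersection_mask$pixels
    vals <- vapply(sets, function(ix) 100 * sum(inter[ix]) / length(ix), numeric(1))
    per_object <- tibble(object_id = as.integer(names(sets)),
                         coloc_area_fraction_pct = unname(vals))
  }
  list(per_image_pct = per_image, per_object = per_object)
}

#' Assemble the per-object statistics table
#'
#' One row per labeled object, carrying geometry (area, centroid in
#' 0-based row/col coordinates), mean channel intensities, mean FRETc,
#' mean NFRET, the object Pearson coefficient, acceptor:donor ratio,
#' color-mix coefficient, the colocalization area fraction of the object,
#' and a `saturated_flag` set for any object touching a saturated pixel in
#' any channel. Flagged objects are kept in the table but excluded from
#' aggregate statistics by default downstream.
#'
#' @param stack A [triple_stack()].
#' @param fret Matching [fret_images()].
#' @param objects A [labeled_objects()] map (typically union objects).
#' @param intersection_mask Optional [binary_mask()] for the per-object
#'   colocalization area fraction (NA column when absent).
#' @param nfret_mode Passed to [nfret_per_object()].
#' @param colormix_mode Passed to [colormix_per_object()].
#' @return A tibble with columns `source_id`, `object_id`, `provenance`,
#'   `area_px`, `centroid_row`, `centroid_col`, `mean_DF`, `mean_AF`,
#'   `mean_rawFRET`, `mean_FRETc`, `mean_NFRET`, `pearson`, `ad_ratio`,
#'   `colormix`, `coloc_area_fraction_pct`, `saturated_flag`.
#' @export
build_object_table <- function(stack, fret, objects, intersection_mask = NULL,
                               nfret_mode = "pixel_mean",
                               colormix_mode = "pixel_mean") {
  stopifnot(inherits(stack, "triple_stack"), inherits(fret, "fret_images"),
            inherits(objects, "labeled_objects"))
  sets <- object_pixel_sets(objects)
  if (!length(sets)) {
    return(tibble(
      source_id = character(0), object_id = integer(0), provenance = character(0),
      area_px = integer(0), centroid_row = numeric(0), centroid_col = numeric(0),
      mean_DF = numeric(0), mean_AF = numeric(0), mean_rawFRET = numeric(0),
      mean_FRETc = numeric(0), mean_NFRET = numeric(0), pearson = numeric(0),
      ad_ratio = numeric(0), colormix = numeric(0),
      coloc_area_fraction_pct = numeric(0), saturated_flag = logical(0)))
  }
  g <- stack_grids(stack)
  sat <- stack_saturated_any(stack)
  nr <- nrow(objects$labels)
  geom <- purrr::map_dfr(names(sets), function(id) {
    ix <- sets[[id]]
    tibble(
      object_id = as.integer(id),
      area_px = length(ix),
      centroid_row = mean((ix - 1L) %% nr),
      centroid_col = mean((ix - 1L) %/% nr),
      mean_DF = mean(g$donor[ix]),
      mean_AF = mean(g$acceptor[ix]),
      mean_rawFRET = mean(g$rawfret[ix]),
      mean_FRETc = mean(fret$fretc[ix]),
      saturated_flag = any(sat[ix]))
  })
  tab <- geom |>
    dplyr::left_join(nfret_per_object(objects, fret, stack, mode = nfret_mode),
                     by = "object_id") |>
    dplyr::left_join(pearson_per_object(objects, g$donor, g$acceptor), by = "object_id") |>
    dplyr::left_join(ad_ratio_per_object(objects, g$donor, g$acceptor), by = "object_id") |>
    dplyr::left_join(colormix_per_object(objects, g$donor, g$acceptor, mode = colormix_mode),
                     by = "object_id")
  if (!is.null(intersection_mask)) {
    dummy_union <- binary_mask(objects$labels > 0L, method = "union")
    caf <- coloc_area_fraction(dummy_union, intersection_mask, objects)$per_object
    tab <- dplyr::left_join(tab, caf, by = "object_id")
  } else {
    tab$coloc_area_fraction_pct <- NA_real_
  }
  tab$source_id <- stack$source_id
  tab$provenance <- objects$provenance
  tab[, c("source_id", "object_id", "provenance", "area_px", "centroid_row",
          "centroid_col", "mean_DF", "mean_AF", "mean_rawFRET", "mean_FRETc",
          "mean_NFRET", "pearson", "ad_ratio", "colormix",
          "coloc_area_fraction_pct", "saturated_flag")]
}
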