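#' Full FRET + colocalization analysis of one image triple
#'
#' The end-to-end pipeline for a single field of view:
#'
#' 1. audit detector saturation;
#' 2. threshold the donor and acceptor channels with one shared automated
#'    method and (optionally) split touching objects by distance-map
#'    watershed;
#' 3. combine the channel masks into union ("combined") and intersection
#'    ("colocalizing") regions;
#' 4. compute FRETc and NFRET images from the bleed-through factors;
#' 5. measure every union object (and, separately, the per-channel
#'    objects): area, centroid, mean intensities, mean FRETc/NFRET, object
#'    Pearson, acceptor:donor ratio, color-mix, colocalization area
#'    fraction, saturation flag;
#' 6. classify union objects into one-protein / two-combined /
#'    two-colocalizing using the channel thresholds as presence criteria.
#'
#' @param stack A [triple_stack()].
#' @param factors A [bleedthrough_factors()].
#' @param threshold_method Shared threshold method for both channels
#'   (see [auto_threshold()]).
#' @param manual_thresholds Named `c(donor=, acceptor=)` when
#'   `threshold_method = "manual"`.
#' @param min_size Minimum object area in px.
#' @param watershed Split touching objects per channel before combining
#'   (default `TRUE`).
#' @param saturation_tolerance Tolerated saturated-pixel fraction.
#' @param colormix_threshold Color-mix cutoff for the colocalizing call.
#' @param nfret_mode,colormix_mode Per-object aggregation modes (see
#'   [nfret_per_object()], [colormix_per_object()]).
#' @return A `fretcoloc_analysis` object; see [tidy.fretcoloc_analysis()]
#'   and [glance.fretcoloc_analysis()] for its tabular views.
#' @export
analyze_triple <- function(stack, factors, threshold_method = "moments",
                           manual_thresholds = NULL, min_size = 10L,
                           watershed = TRUE, saturation_tolerance = 0,
                           colormix_threshold = 0.5,
                           nfret_mode = "pixel_mean",
                           colormix_mode = "pixel_mean") {
  stopifnot(inherits(stack, "triple_stack"), inherits(factors, "bleedthrough_factors"))
  sat <- saturation_report(stack, tolerance = saturation_tolerance)

  thr_of <- function(channel_name) {
    if (threshold_method == "manual") {
      if (is.null(manual_thresholds) || !channel_name %in% names(manual_thresholds)) {
        abort("`manual_thresholds` must name donor and acceptor values.",
              class = "fretcoloc_config_error")
      }
      auto_threshold(stack[[channel_name]], "manual",
                     manual_value = manual_thresholds[[channel_name]])
    } else {
      auto_threshold(stack[[channel_name]], threshold_method)
    }
  }
  mask_d_raw <- thr_of("donor")
  mask_a_raw <- thr_of("acceptor")

  segment_channel <- function(mask, provenance) {
    if (watershed) {
      obj <- watershed_split(mask, provenance = provenance)
      obj <- filter_small(obj, min_size)
    } else {
      obj <- label_objects(mask, min_size = min_size, provenance = provenance)
    }
    obj
  }
  obj_d <- segment_channel(mask_d_raw, "donor")
  obj_a <- segment_channel(mask_a_raw, "acceptor")
  mask_d <- binary_mask(obj_d$labels > 0L, mask_d_raw$method, mask_d_raw$threshold_value)
  mask_a <- binary_mask(obj_a$labels > 0L, mask_a_raw$method, mask_a_raw$threshold_value)

  union_mask <- combine_union(mask_d, mask_a)
  intersection_mask <- combine_intersection(mask_d, mask_a)
  obj_union <- label_objects(union_mask, min_size = min_size, provenance = "union")

  fret <- fret_images(stack, factors)

  tab_union <- build_object_table(stack, fret, obj_union, intersection_mask,
                                  nfret_mode = nfret_mode, colormix_mode = colormix_mode)
  tab_union <- classify_objects(
    tab_union,
    presence_threshold = c(donor = mask_d_raw$threshold_value,
                           acceptor = mask_a_raw$threshold_value),
    colormix_threshold = colormix_threshold)
  tab_d <- build_object_table(stack, fret, obj_d, intersection_mask,
                              nfret_mode = nfret_mode, colormix_mode = colormix_mode)
  tab_a <- build_object_table(stack, fret, obj_a, intersection_mask,
                              nfret_mode = nfret_mode, colormix_mode = colormix_mode)

  caf <- coloc_area_fraction(union_mask, intersection_mask, obj_union)

  structure(list(
    source_id = stack$source_id,
    objects = tab_union,
    per_channel = list(donor = tab_d, acceptor = tab_a),
    saturation = sat,
    whole_image_pearson = whole_image_pearson(stack$donor, stack$acceptor),
    coloc_area_fraction_pct = caf$per_image_pct,
    thresholds = c(donor = mask_d_raw$threshold_value,
                   acceptor = mask_a_raw$threshold_value),
    factors = factors,
    fret = fret,
    masks = list(donor = mask_d, acceptor = mask_a, union = union_mask,
                 intersection = intersection_mask),
    labels = list(donor = obj_d, acceptor = obj_a, union = obj_union),
    params = list(threshold_method = threshold_method, min_size = min_size,
                  watershed = watershed, colormix_threshold = colormix_threshold,
                  nfret_mode = nfret_mode, colormix_mode = colormix_mode)),
    class = "fretcoloc_analysis")
}

# Drop labeled components below min_size px and relabel consecutively.
filter_small <- function(objects, min_size) {
  if (min_size <= 0L || objects$n_objects == 0L) return(objects)
  lab <- objects$labels
  sizes <- tabulate(lab[lab > 0L])
  drop <- which(sizes < min_size)
  if (length(drop)) lab[lab %in% drop] <- 0L
  labeled_objects(relabel_raster(lab), objects$provenance)
}

#' @export
print.fretcoloc_analysis <- function(x, ...) {
  cat(sprintf(
    "<fretcoloc_analysis> '%s': %d union object(s); whole-image Pearson %.3f; coloc area %.1f%%%s\n",
    x$source_id, nrow(x$objects), x$whole_image_pearson,
    x$coloc_area_fraction_pct,
    if (isTRUE(x$saturation$overexposed[1])) "; OVEREXPOSED" else ""))
  invisible(x)
}

#' Tidy the per-object results of an analysis
#'
#' @param x A `fretcoloc_analysis`.
#' @param provenance `"union"` (default), `"donor"` or `"acceptor"`.
#' @param ... Unused.
#' @return The per-object tibble (union objects carry the classification
#'   `label`).
#' @export
tidy.fretcoloc_analysis <- function(x, provenance = c("union", "donor", "acceptor"), ...) {
  provenance <- match.arg(provenance)
  if (provenance == "union") x$objects else x$per_channel[[provenance]]
}

#' One-row summary of an analysis
#'
#' @param x A `fretcoloc_analysis`.
#' @param exclude_saturated Exclude saturated-flagged objects from the
#'   aggregate means (default `TRUE`).
#' @param ... Unused.
#' @return A one-row tibble: object counts, aggregate object Pearson and
#'   NFRET means, whole-image Pearson, colocalization area fraction,
#'   overexposure verdict, factors used.
#' @export
glance.fretcoloc_analysis <- function(x, exclude_saturated = TRUE, ...) {
  tab <- x$objects
  if (exclude_saturated && nrow(tab)) tab <- tab[!tab$saturated_flag, ]
  tibble(
    source_id = x$source_id,
    n_objects = nrow(x$objects),
    n_unsaturated = nrow(tab),
    mean_object_pearson = mean(tab$pearson, na.rm = TRUE),
    mean_nfret = mean(tab$mean_NFRET, na.rm = TRUE),
    mean_colormix = mean(tab$colormix, na.rm = TRUE),
    whole_image_pearson = x$whole_image_pearson,
    coloc_area_fraction_pct = x$coloc_area_fraction_pct,
    overexposed = x$saturation$overexposed[1],
    d = x$factors$d, a = x$factors$a)
}
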