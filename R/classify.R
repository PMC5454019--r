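#' Truncate percentages to one decimal
#'
#' Percentages in the conventional deposition tables are truncated (not
#' rounded) to one decimal place, e.g. 25/267 -> 9.3 and 5/13 -> 38.4.
#'
#' @param x Numeric vector of percentages.
#' @return `x` truncated to one decimal.
#' @export
truncate_pct <- function(x) trunc(x * 10) / 10

#' Classify objects into conventional deposition categories
#'
#' Emulates the conventional visual call on double-labeled protein
#' deposits, made explicit: an object whose secondary channel (the weaker
#' of the two mean intensities) does not rise above `presence_threshold`
#' contains `one_protein`; otherwise it holds two proteins, and it is
#' `two_colocalizing` when its color-mix coefficient exceeds
#' `colormix_threshold` (the numeric stand-in for the "yellow color-mix"
#' call), else `two_combined`. Both thresholds are explicit parameters
#' because the original call was visual; by default the presence threshold
#' for each channel is its segmentation threshold.
#'
#' @param object_table Tibble from [build_object_table()] (data-frame
#'   first, pipeable).
#' @param presence_threshold Single intensity threshold, or named vector
#'   `c(donor = , acceptor = )` applied to whichever channel is secondary
#'   in each object.
#' @param colormix_threshold Color-mix cutoff in `[0, 1]` (default 0.5).
#' @param group Optional column name(s) in `object_table` to carry through
#'   as strata.
#' @return The input tibble with a `label` factor column
#'   (`one_protein`, `two_combined`, `two_colocalizing`).
#' @export
classify_objects <- function(object_table, presence_threshold,
                             colormix_threshold = 0.5, group = NULL) {
  stopifnot(is.data.frame(object_table))
  thr <- presence_threshold
  if (length(thr) == 1L && is.null(names(thr))) {
    thr <- c(donor = unname(thr), acceptor = unname(thr))
  }
  if (!all(c("donor", "acceptor") %in% names(thr))) {
    abort("`presence_threshold` must be a scalar or named c(donor=, acceptor=).",
          class = "fretcoloc_config_error")
  }
  secondary_is_donor <- object_table$mean_DF <= object_table$mean_AF
  secondary_mean <- ifelse(secondary_is_donor, object_table$mean_DF, object_table$mean_AF)
  secondary_thr <- ifelse(secondary_is_donor, thr[["donor"]], thr[["acceptor"]])
  label <- ifelse(secondary_mean <= secondary_thr, "one_protein",
                  ifelse(object_table$colormix > colormix_threshold,
                         "two_colocalizing", "two_combined"))
  object_table$label <- factor(label,
                               levels = c("one_protein", "two_combined", "two_colocalizing"))
  object_table
}

#' Tabulate deposition labels into counts and truncated percentages
#'
#' Builds the conventional summary: per stratum, the total number of
#' objects, the count in each category and its percentage of the total,
#' truncated to one decimal (so `25/267 -> 9.3`, `5/13 -> 38.4`).
#' Can also be fed pre-counted data via `n_one`, `n_combined`, `n_coloc`
#' columns instead of per-object labels.
#'
#' @param labels A data frame with a `label` column (from
#'   [classify_objects()]) and optional stratum columns, or a data frame of
#'   counts with columns `n_one`, `n_combined`, `n_coloc`.
#' @param strata Character vector of grouping column names (optional).
#' @return A tibble with one row per stratum: `n_total`, `n_one`,
#'   `n_combined`, `n_coloc`, `pct_one`, `pct_combined`, `pct_coloc`
#'   (percentages truncated to one decimal). Empty input gives an empty
#'   table.
#' @export
tabulate_depositions <- function(labels, strata = NULL) {
  stopifnot(is.data.frame(labels))
  if (!nrow(labels)) {
    return(tibble(n_total = integer(0), n_one = integer(0), n_combined = integer(0),
                  n_coloc = integer(0), pct_one = numeric(0), pct_combined = numeric(0),
                  pct_coloc = numeric(0)))
  }
  if (all(c("n_one", "n_combined", "n_coloc") %in% names(labels))) {
    counts <- as_tibble(labels)
  } else {
    if (!"label" %in% names(labels)) {
      abort("`labels` needs a `label` column or n_one/n_combined/n_coloc counts.",
            class = "fretcoloc_value_error")
    }
    grouped <- if (is.null(strata)) labels else
      dplyr::group_by(labels, dplyr::across(dplyr::all_of(strata)))
    counts <- dplyr::summarise(
      grouped,
      n_one = sum(.data$label == "one_protein"),
      n_combined = sum(.data$label == "two_combined"),
      n_coloc = sum(.data$label == "two_colocalizing"),
      .groups = "drop")
  }
  counts |>
    dplyr::mutate(
      n_total = .data$n_one + .data$n_combined + .data$n_coloc,
      pct_one = truncate_pct(100 * .data$n_one / .data$n_total),
      pct_combined = truncate_pct(100 * .data$n_combined / .data$n_total),
      pct_coloc = truncate_pct(100 * .data$n_coloc / .data$n_total)) |>
    dplyr::relocate("n_total", .before = "n_one")
}

#' Per-stratum mean and standard error of the object Pearson coefficient
#'
#' Arithmetic mean and SEM over the defined (non-`NA`) per-object Pearson
#' values; saturated-flagged objects are excluded by default. Strata with
#' a single defined value get an `NA` SEM; strata with none are flagged
#' empty.
#'
#' @param object_table Tibble with a `pearson` column (and optionally
#'   `saturated_flag`), e.g. from [build_object_table()].
#' @param strata Character vector of grouping column names (optional).
#' @param exclude_saturated Drop saturated-flagged objects first
#'   (default `TRUE`).
#' @return Tibble with `n`, `mean_pearson`, `sem_pearson`, `empty` per
#'   stratum.
#' @export
group_mean_pearson <- function(object_table, strata = NULL, exclude_saturated = TRUE) {
  stopifnot(is.data.frame(object_table))
  tab <- object_table
  if (exclude_saturated && "saturated_flag" %in% names(tab)) {
    tab <- dplyr::filter(tab, !.data$saturated_flag)
  }
  grouped <- if (is.null(strata)) tab else
    dplyr::group_by(tab, dplyr::across(dplyr::all_of(strata)))
  dplyr::summarise(
    grouped,
    n = sum(!is.na(.data$pearson)),
    mean_pearson = if (sum(!is.na(.data$pearson)) > 0)
      mean(.data$pearson, na.rm = TRUE) else NA_real_,
    sem_pearson = if (sum(!is.na(.data$pearson)) > 1)
      sd(.data$pearson, na.rm = TRUE) / sqrt(sum(!is.na(.data$pearson))) else NA_real_,
    empty = sum(!is.na(.data$pearson)) == 0,
    .groups = "drop")
}
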