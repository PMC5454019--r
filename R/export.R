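object_table_columns <- c(
  "source_id", "object_id", "provenance", "area_px", "centroid_row",
  "centroid_col", "mean_DF", "mean_AF", "mean_rawFRET", "mean_FRETc",
  "mean_NFRET", "pearson", "ad_ratio", "colormix",
  "coloc_area_fraction_pct", "saturated_flag")

#' Write an object table as CSV
#'
#' Comma separator, `.` decimal, one header row, UTF-8; undefined values
#' are written as empty fields, never as 0. The fixed column order of
#' [build_object_table()] is enforced so batch outputs concatenate
#' cleanly.
#'
#' @param table Object table tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_object_csv <- function(table, path) {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(object_table_columns, names(table))
  if (length(missing_cols)) {
    abort(sprintf("object table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "fretcoloc_value_error")
  }
  readr::write_csv(table[, object_table_columns], path, na = "")
  invisible(path)
}

#' Write numeric object data as an FCS 3.0 cytometry file
#'
#' Emits a single-dataset FCS 3.0 file with one event per object and one
#' parameter per selected numeric column, stored as little-endian float32
#' (`$DATATYPE F`, `$BYTEORD 1,2,3,4`). Float storage is chosen over
#' integer so negative FRETc values and sub-unit coefficients survive the
#' conversion. A numeric-only CSV twin is written alongside (same path
#' with `.csv`), since spreadsheet-based workflows consume CSV.
#'
#' Events with an undefined value in any selected column are dropped
#' (FCS has no missing-value representation); the number dropped is
#' reported via a warning.
#'
#' @param table Object table tibble.
#' @param path Output `.fcs` path.
#' @param numeric_columns Columns to export as FCS parameters; all must be
#'   numeric.
#' @return `path`, invisibly.
#' @export
write_cytometry <- function(table, path,
                            numeric_columns = c("area_px", "mean_NFRET", "pearson",
                                                "colormix")) {
  stopifnot(is.data.frame(table))
  bad <- numeric_columns[!numeric_columns %in% names(table)]
  if (length(bad)) {
    abort(sprintf("column(s) not in table: %s", paste(bad, collapse = ", ")),
          class = "fretcoloc_config_error")
  }
  non_num <- numeric_columns[!vapply(table[numeric_columns], is.numeric, logical(1))]
  if (length(non_num)) {
    abort(sprintf("non-numeric column(s) requested for cytometry export: %s",
                  paste(non_num, collapse = ", ")),
          class = "fretcoloc_config_error")
  }
  dat <- as.matrix(table[, numeric_columns, drop = FALSE])
  keep <- stats::complete.cases(dat)
  if (any(!keep)) {
    warn(sprintf("%d event(s) with undefined values dropped from FCS export.",
                 sum(!keep)))
  }
  dat <- dat[keep, , drop = FALSE]
  write_fcs3(dat, path)
  readr::write_csv(as_tibble(as.data.frame(dat)), paste0(tools::file_path_sans_ext(path), ".csv"),
                   na = "")
  invisible(path)
}

# Minimal single-dataset FCS 3.0 writer: 58-byte header with ASCII segment
# offsets, '/'-delimited TEXT segment, float32 little-endian DATA.
write_fcs3 <- function(dat, path) {
  stopifnot(is.matrix(dat))
  n_par <- ncol(dat)
  n_tot <- nrow(dat)
  ranges <- apply(dat, 2, function(x) if (length(x)) max(1, ceiling(max(abs(x)))) else 1)
  if (n_par == 0L) abort("at least one parameter is required.", class = "fretcoloc_config_error")
  kw <- c(
    "$MODE" = "L", "$DATATYPE" = "F", "$BYTEORD" = "1,2,3,4",
    "$NEXTDATA" = "0", "$PAR" = as.character(n_par), "$TOT" = as.character(n_tot),
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0")
  for (j in seq_len(n_par)) {
    kw[sprintf("$P%dN", j)] <- gsub("[/\\\\]", "_", colnames(dat)[j] %||% sprintf("P%d", j))
    kw[sprintf("$P%dB", j)] <- "32"
    kw[sprintf("$P%dE", j)] <- "0,0"
    kw[sprintf("$P%dR", j)] <- as.character(ranges[j])
  }
  data_bytes <- 4L * n_par * n_tot
  # fixed-width BEGINDATA/ENDDATA so the TEXT length is independent of the
  # offsets themselves
  text_of <- function(begin_data, end_data) {
    kw2 <- c(kw, "$BEGINDATA" = sprintf("%010d", begin_data),
             "$ENDDATA" = sprintf("%010d", end_data))
    paste0("/", paste0(names(kw2), "/", unname(kw2), "/", collapse = ""))
  }
  probe <- text_of(0, 0)
  header_len <- 58L
  text_start <- header_len
  text_end <- text_start + nchar(probe) - 1L
  data_start <- text_end + 1L
  data_end <- if (data_bytes > 0) data_start + data_bytes - 1L else 0L
  text <- text_of(data_start, data_end)
  stopifnot(nchar(text) == nchar(probe))
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_start, text_end,
                    if (data_bytes > 0) data_start else 0L, data_end,
                    0L, 0L)
  stopifnot(nchar(header) == header_len)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  if (data_bytes > 0) {
    writeBin(as.numeric(t(dat)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read back a minimal FCS 3.0 file
#'
#' Companion reader for [write_cytometry()] output (float32 list-mode,
#' single dataset). Intended for verification and downstream re-import.
#'
#' @param path `.fcs` file path.
#' @return A tibble with one column per FCS parameter.
#' @export
read_fcs <- function(path) {
  raw_all <- readBin(path, "raw", file.size(path))
  header <- rawToChar(raw_all[1:58])
  if (substr(header, 1, 6) != "FCS3.0") {
    abort("not an FCS 3.0 file.", class = "fretcoloc_io_error")
  }
  offs <- as.integer(substring(header, seq(11, 51, 8), seq(18, 58, 8)))
  text <- rawToChar(raw_all[(offs[1] + 1):(offs[2] + 1)])
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  keys <- parts[seq(1, length(parts), 2)]
  vals <- parts[seq(2, length(parts), 2)]
  kw <- setNames(vals, keys)
  n_par <- as.integer(kw[["$PAR"]])
  n_tot <- as.integer(kw[["$TOT"]])
  if (n_tot == 0L) {
    cols <- lapply(seq_len(n_par), function(j) numeric(0))
  } else {
    data_start <- as.integer(kw[["$BEGINDATA"]])
    vals <- readBin(raw_all[(data_start + 1):(data_start + 4 * n_par * n_tot)],
                    "numeric", n = n_par * n_tot, size = 4L, endian = "little")
    m <- matrix(vals, ncol = n_par, byrow = TRUE)
    cols <- lapply(seq_len(n_par), function(j) m[, j])
  }
  names(cols) <- vapply(seq_len(n_par), function(j) kw[[sprintf("$P%dN", j)]], character(1))
  as_tibble(cols)
}

#' Batch-process a set of image triples with one shared configuration
#'
#' Runs the full analysis (segmentation, FRET correction, per-object
#' statistics, classification) over every triple in a manifest with
#' identical parameters, writing one object table per image, a
#' concatenated table, a classification summary, and a plain-text log.
#' A failing item is logged and skipped; it does not abort the batch.
#' Missing calibration aborts up front.
#'
#' @param config A list (or path to a YAML file) with entries:
#'   `manifest` — data frame/list with columns `donor`, `acceptor`,
#'   `rawfret` (TIFF paths) and optional `source_id`; `factors` — a
#'   [bleedthrough_factors()], a factors JSON path, or `NULL` if
#'   `donor_control` and `acceptor_control` (each a 3-vector of TIFF
#'   paths) are given instead; `bit_depth` (default 12);
#'   `threshold_method` (default `"moments"`); `min_size` (default 10);
#'   `watershed` (default `TRUE`); `saturation_tolerance` (default 0);
#'   `colormix_threshold` (default 0.5); `out_dir` — output directory;
#'   `seed` — recorded in outputs (the analysis itself is deterministic).
#' @return Invisibly, a list with `tables` (per-image object tables),
#'   `combined` (concatenated table), `summary` (classification counts)
#'   and `log` (character vector); all also written under `out_dir`.
#' @export
run_batch <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- config
  cfg$bit_depth <- cfg$bit_depth %||% 12L
  cfg$threshold_method <- cfg$threshold_method %||% "moments"
  cfg$min_size <- cfg$min_size %||% 10L
  cfg$watershed <- cfg$watershed %||% TRUE
  cfg$saturation_tolerance <- cfg$saturation_tolerance %||% 0
  cfg$colormix_threshold <- cfg$colormix_threshold %||% 0.5
  out_dir <- cfg$out_dir %||% abort("`out_dir` is required.", class = "fretcoloc_config_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  factors <- cfg$factors
  if (is.character(factors)) factors <- read_factors(factors)
  if (is.null(factors)) {
    if (is.null(cfg$donor_control) || is.null(cfg$acceptor_control)) {
      abort("no calibration: supply `factors` or donor/acceptor control triples.",
            class = "fretcoloc_calibration_error")
    }
    dc <- cfg$donor_control; ac <- cfg$acceptor_control
    d_frag <- estimate_donor_factor(
      load_triple(dc[1], dc[2], dc[3], cfg$bit_depth),
      mask_method = cfg$threshold_method)
    a_frag <- estimate_acceptor_factor(
      load_triple(ac[1], ac[2], ac[3], cfg$bit_depth),
      mask_method = cfg$threshold_method)
    factors <- combine_factors(d_frag, a_frag)
  }
  if (!inherits(factors, "bleedthrough_factors")) {
    abort("`factors` must be a bleedthrough_factors object or a JSON path.",
          class = "fretcoloc_calibration_error")
  }
  write_factors(factors, file.path(out_dir, "factors.json"))

  manifest <- cfg$manifest
  if (is.null(manifest) || !length(manifest$donor %||% manifest[["donor"]])) {
    warn("empty manifest: nothing to process.")
    manifest <- list(donor = character(0), acceptor = character(0),
                     rawfret = character(0))
  }
  manifest <- as_tibble(as.data.frame(manifest, stringsAsFactors = FALSE))
  n_items <- nrow(manifest)
  log_lines <- c(sprintf("# fretcoloc batch | %d item(s) | threshold=%s min_size=%d seed=%s",
                         n_items, cfg$threshold_method, cfg$min_size,
                         format(cfg$seed %||% NA)))
  tables <- list()
  for (i in seq_len(n_items)) {
    sid <- manifest$source_id[i] %||%
      tools::file_path_sans_ext(basename(manifest$donor[i]))
    res <- tryCatch({
      stack <- load_triple(manifest$donor[i], manifest$acceptor[i],
                           manifest$rawfret[i], cfg$bit_depth, source_id = sid)
      ana <- analyze_triple(
        stack, factors,
        threshold_method = cfg$threshold_method, min_size = cfg$min_size,
        watershed = cfg$watershed,
        saturation_tolerance = cfg$saturation_tolerance,
        colormix_threshold = cfg$colormix_threshold)
      tab <- ana$objects
      write_object_csv(tab, file.path(out_dir, paste0(sid, "_objects.csv")))
      log_lines <<- c(log_lines, sprintf(
        "%s | OK | %s: %d object(s), overexposed=%s",
        format(Sys.time(), "%Y-%m-%d %H:%M:%S"), sid, nrow(tab),
        ana$saturation$overexposed[1]))
      tab
    }, error = function(e) {
      log_lines <<- c(log_lines, sprintf(
        "%s | SKIP | %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), sid,
        conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) tables[[sid]] <- res
  }
  combined <- if (length(tables)) dplyr::bind_rows(tables) else
    build_object_table_empty()
  write_object_csv(combined, file.path(out_dir, "objects_combined.csv"))
  # analyze_triple() already classified each image's union objects with its
  # own channel thresholds
  summary_tab <- if (nrow(combined) && "label" %in% names(combined)) {
    tabulate_depositions(combined, strata = "source_id")
  } else {
    tabulate_depositions(build_object_table_empty())
  }
  readr::write_csv(summary_tab, file.path(out_dir, "summary.csv"), na = "")
  writeLines(log_lines, file.path(out_dir, "batch.log"))
  invisible(list(tables = tables, combined = combined, summary = summary_tab,
                 log = log_lines))
}

build_object_table_empty <- function() {
  tibble(
    source_id = character(0), object_id = integer(0), provenance = character(0),
    area_px = integer(0), centroid_row = numeric(0), centroid_col = numeric(0),
    mean_DF = numeric(0), mean_AF = numeric(0), mean_rawFRET = numeric(0),
    mean_FRETc = numeric(0), mean_NFRET = numeric(0), pearson = numeric(0),
    ad_ratio = numeric(0), colormix = numeric(0),
    coloc_area_fraction_pct = numeric(0), saturated_flag = logical(0))
}
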