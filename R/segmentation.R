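#' Binary foreground mask
#'
#' @param pixels Logical matrix.
#' @param method Threshold-method label that produced it.
#' @param threshold_value The threshold used (mask is `intensity > threshold`).
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(pixels, method = "manual", threshold_value = NA_real_) {
  stopifnot(is.matrix(pixels), is.logical(pixels))
  structure(list(pixels = pixels, method = method, threshold_value = threshold_value),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %dx%d, %d foreground px (method %s, threshold %s)\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels), x$method,
              format(x$threshold_value)))
  invisible(x)
}

channel_histogram <- function(channel) {
  nbins <- max_code(channel) + 1
  tabulate(as.integer(channel$pixels) + 1L, nbins = nbins)
}

threshold_otsu <- function(counts) {
  # maximize between-class variance of the split {<= t} / {> t}
  n <- sum(counts)
  levels <- seq_along(counts) - 1
  w0 <- cumsum(counts)
  w1 <- n - w0
  s0 <- cumsum(counts * levels)
  mu_total <- s0[length(s0)]
  mu0 <- ifelse(w0 > 0, s0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (mu_total - s0) / w1, 0)
  bcv <- w0 * w1 * (mu0 - mu1)^2
  bcv[length(bcv)] <- -Inf  # all-background split is not a threshold
  levels[which.max(bcv)]
}

threshold_mean <- function(counts) {
  levels <- seq_along(counts) - 1
  floor(sum(counts * levels) / sum(counts))
}

threshold_moments <- function(counts) {
  # Tsai moment-preserving thresholding: pick the threshold whose two-level
  # image preserves the first three gray-level moments of the input.
  p <- counts / sum(counts)
  levels <- seq_along(counts) - 1
  m1 <- sum(levels * p)
  m2 <- sum(levels^2 * p)
  m3 <- sum(levels^3 * p)
  cd <- m2 - m1^2
  if (cd <= 0) return(max(levels[counts > 0]))
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (m1 * m2 - m3) / cd
  disc <- c1^2 - 4 * c0
  if (disc < 0) return(max(levels[counts > 0]))
  z0 <- 0.5 * (-c1 - sqrt(disc))
  z1 <- 0.5 * (-c1 + sqrt(disc))
  p0 <- (z1 - m1) / (z1 - z0)  # fraction of pixels assigned to the dark level
  cum <- cumsum(p)
  idx <- which(cum >= p0)
  if (!length(idx)) return(max(levels[counts > 0]))
  levels[idx[1]]
}

threshold_triangle <- function(counts) {
  # Zack's triangle method: drop a line from the histogram peak to the far
  # tail end and take the level with maximum distance below that line.
  nz <- which(counts > 0)
  if (!length(nz)) return(0)
  peak <- which.max(counts)
  lo <- nz[1]
  hi <- nz[length(nz)]
  flipped <- (peak - lo) > (hi - peak)  # longer tail on the left: mirror
  h <- as.numeric(counts)
  if (flipped) {
    h <- rev(h)
    peak <- length(h) - peak + 1
    hi <- length(h) - lo + 1
  }
  if (hi <= peak) {
    t <- peak - 1
  } else {
    xs <- peak:hi
    # line from (peak, h[peak]) to (hi, h[hi]); distance ∝ cross product
    d <- (h[peak] - h[hi]) * (xs - peak) - (peak - hi) * (h[xs] - h[peak])
    t <- xs[which.max(d)] - 1
  }
  if (flipped) t <- (length(h) - 1) - t
  t
}

#' Automated (or manual) histogram thresholding
#'
#' Computes a global threshold from the full-image histogram at native bit
#' depth and returns the mask of pixels strictly above it. Supported
#' automated methods are the moment-preserving `"moments"` method (the
#' default, matching common practice for bright aggregates on dark
#' background), `"otsu"`, `"mean"` and `"triangle"`; `"manual"` uses
#' `manual_value`. Use one and the same method for the donor and acceptor
#' channels of an analysis (the pipeline enforces this) so the two masks
#' are comparable.
#'
#' @param image A [channel_image()].
#' @param method One of `"moments"`, `"otsu"`, `"mean"`, `"triangle"`,
#'   `"manual"`.
#' @param manual_value Threshold when `method = "manual"`.
#' @return A [binary_mask()] carrying the threshold used.
#' @export
auto_threshold <- function(image, method = c("moments", "otsu", "mean", "triangle", "manual"),
                           manual_value = NULL) {
  if (!inherits(image, "channel_image")) {
    abort("`image` must be a channel_image.", class = "fretcoloc_value_error")
  }
  method <- tryCatch(match.arg(method),
                     error = function(e) abort(
                       sprintf("unknown threshold method '%s'", method[1]),
                       class = "fretcoloc_config_error"))
  if (method == "manual") {
    if (is.null(manual_value)) {
      abort("`manual_value` is required for method = \"manual\".",
            class = "fretcoloc_config_error")
    }
    thr <- manual_value
  } else {
    px <- image$pixels
    if (min(px) == max(px)) {
      warn(sprintf("constant image: '%s' threshold degenerates, returning an empty mask.",
                   method))
      thr <- max(px)
    } else {
      counts <- channel_histogram(image)
      thr <- switch(method,
        moments  = threshold_moments(counts),
        otsu     = threshold_otsu(counts),
        mean     = threshold_mean(counts),
        triangle = threshold_triangle(counts))
    }
  }
  binary_mask(image$pixels > thr, method = method, threshold_value = thr)
}

#' Labeled object map
#'
#' @param labels Non-negative integer matrix; 0 is background, objects are
#'   labeled consecutively `1..n_objects`.
#' @param provenance Which mask the objects come from: `"donor"`,
#'   `"acceptor"`, `"union"` or `"intersection"`.
#' @return A `labeled_objects` object.
#' @export
labeled_objects <- function(labels, provenance = c("donor", "acceptor", "union", "intersection")) {
  provenance <- match.arg(provenance)
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  n <- if (length(labels)) max(labels) else 0L
  structure(list(labels = labels, n_objects = as.integer(n), provenance = provenance),
            class = "labeled_objects")
}

#' @export
print.labeled_objects <- function(x, ...) {
  cat(sprintf("<labeled_objects> %s: %d object(s) in %dx%d px\n",
              x$provenance, x$n_objects, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

# 8-connected component labeling: 4-connected pass (EBImage::bwlabel) then
# union-find merging of labels that touch diagonally.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1L)
  storage.mode(lab) <- "integer"
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  if (nrow(pairs)) {
    parent <- seq_len(nlab)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    roots <- vapply(seq_len(nlab), find, integer(1))
    lab[lab > 0L] <- roots[lab[lab > 0L]]
  }
  lab
}

# Relabel positive labels consecutively 1..n in raster-scan order (row-major)
# of each label's first pixel.
relabel_raster <- function(labels) {
  pos <- which(labels > 0L)
  if (!length(pos)) return(labels)
  nr <- nrow(labels)
  r <- (pos - 1L) %% nr
  c <- (pos - 1L) %/% nr
  raster_key <- r * ncol(labels) + c
  first_key <- tapply(raster_key, labels[pos], min)
  old <- as.integer(names(first_key))
  new <- integer(max(old))
  new[old[order(first_key)]] <- seq_along(old)
  labels[pos] <- new[labels[pos]]
  labels
}

#' Split touching objects by distance-map watershed
#'
#' Implements the standard binary-object splitting scheme: the Euclidean
#' distance map of the mask is computed, its regional maxima (the ultimate
#' eroded points) seed a watershed flood, and wherever two catchment basins
#' meet the touching objects are cut apart by a one-pixel-wide background
#' separation line. A single convex object passes through unchanged (one
#' label, no line).
#'
#' Maxima whose distance-map depth difference is below `tolerance` are
#' merged into one seed before flooding, so shallow plateau ripples do not
#' oversegment; the flood itself is deterministic.
#'
#' @param mask A [binary_mask()] (or logical matrix).
#' @param tolerance Seed-merging tolerance in distance-map units
#'   (default 0.5 px).
#' @param provenance Carried through to the result.
#' @return A [labeled_objects()]; labels are consecutive in raster-scan
#'   order and any two labels that were connected in `mask` are separated
#'   by a one-pixel (4-connectivity) background line.
#' @export
watershed_split <- function(mask, tolerance = 0.5, provenance = "union") {
  px <- if (inherits(mask, "binary_mask")) mask$pixels else mask
  stopifnot(is.logical(px))
  if (!any(px)) {
    return(labeled_objects(matrix(0L, nrow(px), ncol(px)), provenance))
  }
  dm <- EBImage::distmap(px * 1)
  ws <- EBImage::watershed(dm, tolerance = tolerance, ext = 1L)
  lab <- matrix(as.integer(EBImage::imageData(ws)), nrow(px), ncol(px))
  # carve a one-pixel separation line: of two 4-adjacent differing labels,
  # background the pixel belonging to the larger label
  nr <- nrow(lab); nc <- ncol(lab)
  collect_cuts <- function(ai, bi) {
    a <- lab[ai]; b <- lab[bi]
    both <- a > 0L & b > 0L
    c(ai[both & a > b], bi[both & b > a])
  }
  cut_idx <- integer(0)
  if (nr > 1) {
    idx_top <- which(matrix(rep(seq_len(nr) < nr, nc), nr, nc))
    cut_idx <- c(cut_idx, collect_cuts(idx_top, idx_top + 1L))
  }
  if (nc > 1) {
    idx_left <- which(matrix(rep(seq_len(nc) < nc, each = nr), nr, nc))
    cut_idx <- c(cut_idx, collect_cuts(idx_left, idx_left + nr))
  }
  lab[unique(cut_idx)] <- 0L
  labeled_objects(relabel_raster(lab), provenance)
}

#' Combine two channel masks into the union ("combined regions")
#'
#' Pixel-wise OR of the donor and acceptor masks: every region occupied by
#' either marker.
#'
#' @param mask_d,mask_a [binary_mask()] objects of identical dimensions.
#' @return A [binary_mask()] with method `"union"`.
#' @export
combine_union <- function(mask_d, mask_a) {
  check_same_shape(mask_d, mask_a)
  binary_mask(mask_d$pixels | mask_a$pixels, method = "union")
}

#' Combine two channel masks into the intersection (colocalizing regions)
#'
#' Pixel-wise AND: only the regions where both markers exceed their
#' thresholds.
#'
#' @inheritParams combine_union
#' @return A [binary_mask()] with method `"intersection"`.
#' @export
combine_intersection <- function(mask_d, mask_a) {
  check_same_shape(mask_d, mask_a)
  binary_mask(mask_d$pixels & mask_a$pixels, method = "intersection")
}

check_same_shape <- function(mask_d, mask_a) {
  stopifnot(inherits(mask_d, "binary_mask"), inherits(mask_a, "binary_mask"))
  if (!identical(dim(mask_d$pixels), dim(mask_a$pixels))) {
    abort("masks must share identical dimensions.", class = "fretcoloc_shape_error")
  }
}

#' Label connected components of a mask, dropping specks
#'
#' 8-connected components smaller than `min_size` pixels are removed; the
#' remaining components are labeled `1..n` in raster-scan order of their
#' top-left pixel.
#'
#' @param mask A [binary_mask()] (or logical matrix).
#' @param min_size Minimum component area in pixels (default 10).
#' @param provenance Carried through to the result.
#' @return A [labeled_objects()].
#' @export
label_objects <- function(mask, min_size = 10L, provenance = "union") {
  px <- if (inherits(mask, "binary_mask")) mask$pixels else mask
  stopifnot(is.logical(px), min_size >= 0)
  lab <- label_components8(px)
  if (min_size > 0L && any(lab > 0L)) {
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(sizes < min_size)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  labeled_objects(relabel_raster(lab), provenance)
}
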