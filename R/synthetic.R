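#' Specification of a synthetic FRET microscopy scene
#'
#' Describes a field of smooth-edged disc-shaped fluorescent aggregates
#' (tissue-deposit-like blobs) on a low uniform background, imaged through
#' the three-filter FRET scheme. A fraction of donor/acceptor object pairs
#' can be placed co-located with a controlled pixel-intensity correlation
#' `rho`; the raw FRET channel is built from the forward model
#' `rawFRET = d_true * DF + a_true * AF + s_true * (co-located indicator)`,
#' i.e. pure spectral bleed-through plus an additive sensitized-emission
#' term where donor and acceptor coincide. Shot noise is Poisson, optional
#' Gaussian read noise can be added, and the result is quantized and
#' clipped at `clip_ceiling` (lowering the ceiling below `2^bit_depth - 1`
#' emulates detector overexposure). Generation is a pure function of the
#' spec (including its `seed`).
#'
#' @param shape `c(rows, cols)` image size.
#' @param n_donor,n_acceptor Number of objects carrying each fluorophore;
#'   co-located pairs count toward both.
#' @param radius_range `c(min, max)` object radius in px.
#' @param overlap_fraction Fraction of object pairs placed co-located
#'   (same center and radius in both channels).
#' @param rho Target pixel-intensity correlation within co-located pairs.
#' @param donor_mean,donor_sd,acceptor_mean,acceptor_sd Object intensity
#'   distribution per channel (intensity units above background).
#' @param background Uniform background fluorescence level (both channels).
#' @param d_true,a_true True bleed-through fractions of the forward model.
#' @param s_true Sensitized-emission amplitude added to rawFRET inside
#'   co-located objects (0 = no interaction).
#' @param poisson Apply Poisson shot noise (default `TRUE`).
#' @param gaussian_sd Additional Gaussian read-noise sd (0 = none).
#' @param glow_amplitude,glow_sigma Diffuse out-of-focus glow: a Gaussian-
#'   blurred copy (sd `glow_sigma` px) of each channel's structure is added
#'   back scaled by `glow_amplitude`.
#' @param texture_sd,texture_sigma Shared tissue texture: a smooth random
#'   field (correlation length `texture_sigma` px, standard deviation
#'   `texture_sd` intensity units) added to both channels' background,
#'   mimicking nonspecific staining and autofluorescence of the tissue
#'   itself. Because both channels see the same tissue, this component is
#'   what overexposure amplifies into apparent colocalization; its long
#'   correlation length keeps it nearly constant within any one object, so
#'   it does not disturb per-object correlations.
#' @param bit_depth Detector A/D bit depth.
#' @param clip_ceiling Overexposure ceiling; defaults to `2^bit_depth - 1`
#'   (correct exposure). A lower value emulates acquiring the same field at
#'   a detector gain of `(2^bit_depth - 1) / clip_ceiling`: intensities are
#'   clipped at the ceiling and rescaled to the full code range, so clipped
#'   pixels sit at the detector maximum and are seen by the saturation
#'   audit.
#' @param edge_softness Logistic edge falloff scale in px.
#' @param seed RNG seed; generation is reproducible given the full spec.
#' @return A `scene_spec` object (a validated list).
#' @export
scene_spec <- function(shape = c(320L, 320L), n_donor = 25L, n_acceptor = 25L,
                       radius_range = c(5, 9), overlap_fraction = 0, rho = 0,
                       donor_mean = 1500, donor_sd = 250,
                       acceptor_mean = 1500, acceptor_sd = 250,
                       background = 20, d_true = 0.15, a_true = 0.05,
                       s_true = 0, poisson = TRUE, gaussian_sd = 0,
                       glow_amplitude = 0.15, glow_sigma = 8,
                       texture_sd = 15, texture_sigma = 40,
                       bit_depth = 12L, clip_ceiling = NULL,
                       edge_softness = 0.3, seed = 1L) {
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    abort("`overlap_fraction` must lie in [0, 1].", class = "fretcoloc_config_error")
  }
  if (rho < -1 || rho > 1) {
    abort("`rho` must lie in [-1, 1].", class = "fretcoloc_config_error")
  }
  if (is.null(clip_ceiling)) clip_ceiling <- 2^bit_depth - 1
  structure(list(
    shape = as.integer(shape), n_donor = as.integer(n_donor),
    n_acceptor = as.integer(n_acceptor), radius_range = radius_range,
    overlap_fraction = overlap_fraction, rho = rho,
    donor_mean = donor_mean, donor_sd = donor_sd,
    acceptor_mean = acceptor_mean, acceptor_sd = acceptor_sd,
    background = background, d_true = d_true, a_true = a_true,
    s_true = s_true, poisson = poisson, gaussian_sd = gaussian_sd,
    glow_amplitude = glow_amplitude, glow_sigma = glow_sigma,
    texture_sd = texture_sd, texture_sigma = texture_sigma,
    bit_depth = as.integer(bit_depth), clip_ceiling = clip_ceiling,
    edge_softness = edge_softness, seed = as.integer(seed)),
    class = "scene_spec")
}

# Random sequential placement of n centers with a minimum pairwise distance,
# inside a margin. Errors when the field cannot accommodate the request.
place_centers <- function(n, shape, min_dist, margin, max_attempts = 20000L) {
  if (n == 0L) return(cbind(row = numeric(0), col = numeric(0)))
  rows <- numeric(n); cols <- numeric(n)
  placed <- 0L
  lo_r <- 1 + margin; hi_r <- shape[1] - margin
  lo_c <- 1 + margin; hi_c <- shape[2] - margin
  if (hi_r <= lo_r || hi_c <= lo_c) {
    abort("objects do not fit: image too small for the radius range.",
          class = "fretcoloc_generation_error")
  }
  attempts <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      abort(sprintf("infeasible packing: placed %d of %d objects after %d attempts",
                    placed, n, max_attempts), class = "fretcoloc_generation_error")
    }
    r <- stats::runif(1, lo_r, hi_r)
    c <- stats::runif(1, lo_c, hi_c)
    if (placed == 0L ||
        min((rows[seq_len(placed)] - r)^2 + (cols[seq_len(placed)] - c)^2) >= min_dist^2) {
      placed <- placed + 1L
      rows[placed] <- r; cols[placed] <- c
    }
  }
  cbind(row = rows, col = cols)
}

# Gaussian blur whose kernel never exceeds the image (EBImage's brush is
# 2*ceiling(3*sigma)+1 wide); small fields get a correspondingly shorter
# correlation length.
gblur_safe <- function(x, sigma) {
  max_sigma <- (min(dim(x)) - 3) / 6.5
  EBImage::gblur(x, sigma = max(min(sigma, max_sigma), 0.5))
}

# Mixing weight for the shared latent field, solved so that the realized
# pixel correlation of the emitted (noisy, edge-faded) images matches rho.
# W: edge-falloff weights over the object's true-mask pixels.
solve_mixing <- function(rho, W, m_d, s_d, m_a, s_a, background, poisson, gaussian_sd) {
  vW <- mean(W^2) - mean(W)^2
  eW2 <- mean(W^2)
  quant <- 1 / 12  # quantization noise
  n_d <- (if (poisson) background + m_d * mean(W) else 0) + gaussian_sd^2 + quant
  n_a <- (if (poisson) background + m_a * mean(W) else 0) + gaussian_sd^2 + quant
  A <- m_d * m_a * vW
  B <- s_d * s_a * eW2
  Dd <- m_d^2 * vW + s_d^2 * eW2 + n_d
  Da <- m_a^2 * vW + s_a^2 * eW2 + n_a
  if (B <= 0) return(0)
  c <- (rho * sqrt(Dd * Da) - A) / B
  max(-1, min(1, c))
}

#' Generate a synthetic image triple with ground truth
#'
#' Renders the scene described by a [scene_spec()] and returns both the
#' quantized [triple_stack()] (as a microscope would deliver it) and the
#' generating ground truth: object geometry, the co-location pairing, the
#' true channel masks, the realized per-pair intensity correlations
#' measured on the emitted pixels over each pair object's flat-top core
#' (edge weight >= 0.6 — the area a threshold-based measurement selects;
#' the sub-threshold edge skirt carries a shared geometric gradient, not
#' stain correlation), the noise-free sensitized-emission field (the true
#' FRETc), and the true bleed-through factors.
#'
#' @param spec A [scene_spec()].
#' @return A list with elements `stack` ([triple_stack()]) and `truth`
#'   (list: `objects` tibble, `true_masks`, `pair_correlations` tibble,
#'   `true_fretc` matrix, `d_true`, `a_true`, `spec`).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)
  nr <- spec$shape[1]; nc <- spec$shape[2]
  texture <- matrix(0, nr, nc)
  if (spec$texture_sd > 0) {
    texture <- gblur_safe(matrix(rnorm(nr * nc), nr, nc), spec$texture_sigma)
    texture <- texture / sd(texture) * spec$texture_sd
  }
  rmax <- max(spec$radius_range)
  n_pair <- round(spec$overlap_fraction * min(spec$n_donor, spec$n_acceptor))
  n_donly <- spec$n_donor - n_pair
  n_aonly <- spec$n_acceptor - n_pair
  n_total <- n_pair + n_donly + n_aonly
  centers <- place_centers(n_total, spec$shape, min_dist = 2 * rmax + 2, margin = rmax + 2)
  radii <- stats::runif(n_total, spec$radius_range[1], spec$radius_range[2])
  kind <- rep(c("pair", "donor", "acceptor"), c(n_pair, n_donly, n_aonly))

  mask_d <- matrix(FALSE, nr, nc)
  mask_a <- matrix(FALSE, nr, nc)
  obj_rows <- vector("list", n_total)
  obj_geom <- vector("list", n_total)   # per-object W, indices, latent draws
  pair_pixels <- vector("list", n_total)

  for (k in seq_len(n_total)) {
    cr <- centers[k, "row"]; cc <- centers[k, "col"]; rad <- radii[k]
    ext <- ceiling(rad + 4)
    r0 <- max(1L, floor(cr) - ext); r1 <- min(nr, ceiling(cr) + ext)
    c0 <- max(1L, floor(cc) - ext); c1 <- min(nc, ceiling(cc) + ext)
    rr <- r0:r1; cczz <- c0:c1
    dist <- sqrt(outer((rr - cr)^2, (cczz - cc)^2, `+`))
    W <- 1 / (1 + exp((dist - rad) / spec$edge_softness))
    inside <- dist <= rad
    core <- W >= 0.6  # flat-top region a threshold-based measurement selects
    box_idx <- outer(rr, (cczz - 1L) * nr, `+`)  # linear indices of the box
    npx <- length(W)
    g <- list(W = W, box_idx = box_idx, core = core,
              near = dist <= rad + 2)  # excludes neighbours entering the box
    if (kind[k] == "pair") {
      g$z <- rnorm(npx); g$e1 <- rnorm(npx); g$e2 <- rnorm(npx)
      mask_d[box_idx[inside]] <- TRUE
      mask_a[box_idx[inside]] <- TRUE
    } else if (kind[k] == "donor") {
      g$u <- rnorm(npx)
      mask_d[box_idx[inside]] <- TRUE
    } else {
      g$v <- rnorm(npx)
      mask_a[box_idx[inside]] <- TRUE
    }
    obj_geom[[k]] <- g
    obj_rows[[k]] <- tibble(
      object = k, kind = kind[k], center_row = cr - 1, center_col = cc - 1,
      radius = rad)
  }

  # Build the mean (expected-photon) fields for a given per-object mixing
  # weight vector, then sample the detector; the sampling RNG stream is
  # re-seeded identically on every call so the only difference between
  # renders is the mixing.
  build_mu <- function(cmix) {
    mu_d <- pmax(spec$background + texture, 0)
    mu_a <- pmax(spec$background + texture, 0)
    pair_field <- matrix(0, nr, nc)
    for (k in seq_len(n_total)) {
      g <- obj_geom[[k]]
      if (kind[k] == "pair") {
        alpha <- sqrt(abs(cmix[k])); sgn <- if (cmix[k] < 0) -1 else 1
        u <- alpha * g$z + sqrt(1 - alpha^2) * g$e1
        v <- sgn * alpha * g$z + sqrt(1 - alpha^2) * g$e2
        mu_d[g$box_idx] <- mu_d[g$box_idx] +
          g$W * pmax(spec$donor_mean + spec$donor_sd * u, 0)
        mu_a[g$box_idx] <- mu_a[g$box_idx] +
          g$W * pmax(spec$acceptor_mean + spec$acceptor_sd * v, 0)
        pair_field[g$box_idx] <- pmin(pair_field[g$box_idx] + g$W, 1)
      } else if (kind[k] == "donor") {
        mu_d[g$box_idx] <- mu_d[g$box_idx] +
          g$W * pmax(spec$donor_mean + spec$donor_sd * g$u, 0)
      } else {
        mu_a[g$box_idx] <- mu_a[g$box_idx] +
          g$W * pmax(spec$acceptor_mean + spec$acceptor_sd * g$v, 0)
      }
    }
    if (spec$glow_amplitude > 0) {
      mu_d <- pmax(mu_d + spec$glow_amplitude *
        gblur_safe(mu_d - spec$background, spec$glow_sigma), 0)
      mu_a <- pmax(mu_a + spec$glow_amplitude *
        gblur_safe(mu_a - spec$background, spec$glow_sigma), 0)
    }
    true_fretc <- spec$s_true * pair_field
    list(mu_d = mu_d, mu_a = mu_a,
         mu_r = spec$d_true * mu_d + spec$a_true * mu_a + true_fretc,
         true_fretc = true_fretc)
  }

  max_code_value <- 2^spec$bit_depth - 1
  ceiling_value <- min(spec$clip_ceiling, max_code_value)
  gain <- max_code_value / ceiling_value  # overexposure = gain then clip at max
  samp_seed <- (spec$seed + 1000003L) %% .Machine$integer.max
  render <- function(mu) {
    set.seed(samp_seed)
    sample_channel <- function(m) {
      x <- if (spec$poisson) as.numeric(rpois(length(m), m)) else as.numeric(m)
      if (spec$gaussian_sd > 0) x <- x + rnorm(length(x), 0, spec$gaussian_sd)
      x <- pmin(pmax(round(x), 0), ceiling_value)
      if (gain > 1) x <- round(x * gain)
      matrix(x, nr, nc)
    }
    list(df = sample_channel(mu$mu_d), af = sample_channel(mu$mu_a),
         rf = sample_channel(mu$mu_r))
  }

  # Solve the latent mixing weight of each pair so the correlation a
  # threshold-based measurement sees equals rho. An analytic variance-
  # component solve on the flat-top core seeds the value; a pilot render
  # then determines the pixel set an automated threshold actually selects,
  # and because the realized correlation over a fixed pixel set is linear
  # in the mixing weight, one secant step on two renders lands on the
  # target. All renders draw the same noise stream, so generation stays a
  # pure function of the spec.
  cmix <- numeric(n_total)
  is_pair <- kind == "pair"
  for (k in which(is_pair)) {
    g <- obj_geom[[k]]
    cmix[k] <- solve_mixing(spec$rho, g$W[g$core],
                            spec$donor_mean, spec$donor_sd,
                            spec$acceptor_mean, spec$acceptor_sd,
                            spec$background, spec$poisson, spec$gaussian_sd)
    pair_pixels[[k]] <- g$box_idx[g$core]
  }
  mu <- build_mu(cmix)
  imgs <- render(mu)
  if (any(is_pair)) {
    t_d <- auto_threshold(channel_image(imgs$df, spec$bit_depth, "donor"),
                          "moments")$threshold_value
    t_a <- auto_threshold(channel_image(imgs$af, spec$bit_depth, "acceptor"),
                          "moments")$threshold_value
    pair_ids <- which(is_pair)
    for (k in pair_ids) {
      g <- obj_geom[[k]]
      measured <- (imgs$df[g$box_idx] > t_d | imgs$af[g$box_idx] > t_a) & g$near
      if (sum(measured) >= 20L) pair_pixels[[k]] <- g$box_idx[measured]
    }
    corr_on_sets <- function(im) {
      vapply(pair_ids, function(k) {
        ix <- pair_pixels[[k]]
        if (length(ix) >= 3) cor(im$df[ix], im$af[ix]) else NA_real_
      }, numeric(1))
    }
    r0 <- corr_on_sets(imgs)
    c0 <- cmix[pair_ids]
    c1 <- pmax(pmin(c0 + 0.25, 1), -1)
    flip <- abs(c1 - c0) < 0.05  # already at the upper bound: probe downward
    c1[flip] <- pmax(pmin(c0[flip] - 0.25, 1), -1)
    cmix[pair_ids] <- c1
    r1 <- corr_on_sets(render(build_mu(cmix)))
    slope <- (r1 - r0) / (c1 - c0)
    slope[is.na(slope) | abs(slope) < 1e-6] <- 1
    # fixed-point polish: re-derive the measured sets from each new render
    # (threshold shifts, watershed and merging move the set slightly) and
    # step along the known slope
    c_cur <- c0
    r_cur <- r0
    for (it in 1:3) {
      c_cur <- pmax(pmin(c_cur + (spec$rho - r_cur) / slope, 1), -1)
      cmix[pair_ids] <- c_cur
      mu <- build_mu(cmix)
      imgs <- render(mu)
      t_d <- auto_threshold(channel_image(imgs$df, spec$bit_depth, "donor"),
                            "moments")$threshold_value
      t_a <- auto_threshold(channel_image(imgs$af, spec$bit_depth, "acceptor"),
                            "moments")$threshold_value
      for (k in pair_ids) {
        g <- obj_geom[[k]]
        measured <- (imgs$df[g$box_idx] > t_d | imgs$af[g$box_idx] > t_a) & g$near
        if (sum(measured) >= 20L) pair_pixels[[k]] <- g$box_idx[measured]
      }
      r_cur <- corr_on_sets(imgs)
    }
  }
  df <- imgs$df; af <- imgs$af; rf <- imgs$rf
  true_fretc <- mu$true_fretc

  stack <- triple_stack(
    donor    = channel_image(df, spec$bit_depth, "donor"),
    acceptor = channel_image(af, spec$bit_depth, "acceptor"),
    rawfret  = channel_image(rf, spec$bit_depth, "rawfret"),
    source_id = sprintf("synthetic_seed%d", spec$seed))

  pair_cors <- purrr::map_dfr(which(is_pair), function(k) {
    ix <- pair_pixels[[k]]
    tibble(object = k,
           realized_correlation = if (length(ix) >= 3) cor(df[ix], af[ix]) else NA_real_)
  })

  list(
    stack = stack,
    truth = list(
      objects = dplyr::bind_rows(obj_rows),
      true_masks = list(donor = mask_d, acceptor = mask_a),
      pair_correlations = pair_cors,
      true_fretc = true_fretc,
      d_true = spec$d_true, a_true = spec$a_true,
      spec = spec))
}

#' Named library of study-condition scenarios
#'
#' Fixed scene specifications mirroring the experimental conditions the
#' analysis is designed to discriminate:
#'
#' * `distinct_localization` — donor and acceptor aggregates spatially
#'   disjoint, no sensitized emission, correctly exposed: the
#'   negative-result condition (expect object Pearson and NFRET near 0).
#' * `true_interaction` — fully co-located pairs, intensity correlation
#'   0.7, positive sensitized emission: the positive-control condition.
#' * `overexposed` — identical to `distinct_localization` (same seed,
#'   same draws) except acquired at roughly 100-fold detector gain
#'   (ceiling 30 of 4095), deep enough that the shared diffuse tissue
#'   signal saturates in both channels: the condition that produces
#'   broad false-positive colocalization.
#' * `donor_only` / `acceptor_only` — single-fluorophore calibration
#'   controls with true factors d = 0.15, a = 0.05.
#'
#' @param base_seed Integer from which the per-scenario seeds are derived;
#'   scenario parameters themselves are fixed.
#' @return Named list of [scene_spec()]s.
#' @export
scenario_library <- function(base_seed = 1951L) {
  base_seed <- as.integer(base_seed)
  distinct <- scene_spec(
    shape = c(320L, 320L), n_donor = 55L, n_acceptor = 55L,
    radius_range = c(5, 9), overlap_fraction = 0, rho = 0,
    s_true = 0, glow_amplitude = 0.15, glow_sigma = 8,
    seed = base_seed + 1L)
  overexposed <- distinct
  overexposed$clip_ceiling <- 30
  list(
    distinct_localization = distinct,
    true_interaction = scene_spec(
      shape = c(320L, 320L), n_donor = 100L, n_acceptor = 100L,
      radius_range = c(5, 9), overlap_fraction = 1, rho = 0.7,
      s_true = 150, glow_amplitude = 0.05, glow_sigma = 8,
      seed = base_seed + 2L),
    overexposed = overexposed,
    donor_only = scene_spec(
      shape = c(320L, 320L), n_donor = 40L, n_acceptor = 0L,
      radius_range = c(8, 14), overlap_fraction = 0, rho = 0,
      s_true = 0, glow_amplitude = 0.05, glow_sigma = 8,
      seed = base_seed + 3L),
    acceptor_only = scene_spec(
      shape = c(320L, 320L), n_donor = 0L, n_acceptor = 40L,
      radius_range = c(8, 14), overlap_fraction = 0, rho = 0,
      s_true = 0, glow_amplitude = 0.05, glow_sigma = 8,
      seed = base_seed + 4L))
}

#' Write a synthetic scene to disk as TIFF triple + ground-truth JSON
#'
#' @param scene Result of [generate_scene()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_scene <- function(scene, dir, prefix = "scene") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    donor = file.path(dir, paste0(prefix, "_donor.tif")),
    acceptor = file.path(dir, paste0(prefix, "_acceptor.tif")),
    rawfret = file.path(dir, paste0(prefix, "_rawfret.tif")),
    truth = file.path(dir, paste0(prefix, "_truth.json")))
  write_channel_tiff(scene$stack$donor, paths[["donor"]])
  write_channel_tiff(scene$stack$acceptor, paths[["acceptor"]])
  write_channel_tiff(scene$stack$rawfret, paths[["rawfret"]])
  truth <- scene$truth
  jsonlite::write_json(list(
    objects = truth$objects,
    pair_correlations = truth$pair_correlations,
    d_true = truth$d_true, a_true = truth$a_true,
    spec = unclass(truth$spec)),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
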