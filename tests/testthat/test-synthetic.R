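test_that("generation is a pure function of the spec", {
  spec <- small_scene_spec(91)
  a <- generate_scene(spec)
  b <- generate_scene(spec)
  expect_identical(a$stack$donor$pixels, b$stack$donor$pixels)
  expect_identical(a$stack$rawfret$pixels, b$stack$rawfret$pixels)
  expect_equal(a$truth$pair_correlations, b$truth$pair_correlations)
})

test_that("an empty spec yields a background-only triple", {
  spec <- scene_spec(shape = c(64L, 64L), n_donor = 0L, n_acceptor = 0L, seed = 92)
  scene <- generate_scene(spec)
  expect_false(any(scene$truth$true_masks$donor))
  expect_lt(max(scene$stack$donor$pixels), 200)  # background + texture only
  expect_equal(nrow(scene$truth$pair_correlations), 0)
})

test_that("noise-free fully correlated pairs give object Pearson 1", {
  spec <- scene_spec(shape = c(128L, 128L), n_donor = 8L, n_acceptor = 8L,
                     overlap_fraction = 1, rho = 1, poisson = FALSE,
                     gaussian_sd = 0, texture_sd = 0, glow_amplitude = 0,
                     seed = 93)
  scene <- generate_scene(spec)
  tab <- tidy(analyze_triple(scene$stack, true_factors(), min_size = 5))
  expect_gte(nrow(tab), 8)
  expect_true(all(tab$pearson > 0.999))
})

test_that("noise-free non-interacting scenes cancel exactly under true factors", {
  spec <- scene_spec(shape = c(128L, 128L), n_donor = 6L, n_acceptor = 6L,
                     d_true = 0.1, a_true = 0.05, s_true = 0,
                     poisson = FALSE, gaussian_sd = 0, seed = 94)
  scene <- generate_scene(spec)
  fretc <- compute_fretc(scene$stack, bleedthrough_factors(0.1, 0.05))
  # only quantization ripple remains; its mean vanishes
  expect_lt(max(abs(fretc)), 1.5)
  expect_lt(abs(mean(fretc)), 0.01)
})

test_that("realized pair correlation converges to rho for large objects", {
  for (rho in c(0.3, 0.7)) {
    spec <- scene_spec(shape = c(160L, 160L), n_donor = 4L, n_acceptor = 4L,
                       radius_range = c(14, 16), overlap_fraction = 1,
                       rho = rho, s_true = 100, seed = 95 + round(10 * rho))
    scene <- generate_scene(spec)
    cors <- scene$truth$pair_correlations$realized_correlation
    areas <- pi * scene$truth$objects$radius^2
    expect_true(all(areas >= 500))
    expect_lt(max(abs(cors - rho)), 0.05)
  }
})

test_that("no saturation occurs when intensities stay below the ceiling", {
  scene <- cached_scene("distinct_localization")
  expect_equal(sum(unlist(scene$stack$saturation_masks)), 0)
  rep <- saturation_report(scene$stack)
  expect_false(any(rep$overexposed))
})

test_that("scenario library encodes the study conditions", {
  lib <- scenario_library(1951)
  expect_gte(length(lib), 5)
  expect_named(lib, c("distinct_localization", "true_interaction", "overexposed",
                      "donor_only", "acceptor_only"))

  don <- cached_scene("donor_only")
  expect_false(any(don$truth$true_masks$acceptor))
  expect_lt(mean(don$stack$acceptor$pixels), 100)  # background only
  expect_gt(mean(don$stack$donor$pixels > 500), 0.05)

  ti <- lib$true_interaction
  expect_gte(ti$overlap_fraction, 0.9)
  expect_gte(ti$rho, 0.7)
  expect_gt(ti$s_true, 0)

  # overexposed differs from distinct_localization only in the clip ceiling
  d <- lib$distinct_localization
  o <- lib$overexposed
  d$clip_ceiling <- o$clip_ceiling
  expect_identical(unclass(d), unclass(o))
  # ... and the emitted image is the gain-amplified clip of the same draws
  di <- cached_scene("distinct_localization")$stack$donor$pixels
  ov <- cached_scene("overexposed")$stack$donor$pixels
  gain <- 4095 / 30
  low <- di <= 30
  expect_identical(ov[low], round(di[low] * gain))
  expect_true(all(ov[!low] == 4095))
})

test_that("impossible packings fail loudly", {
  spec <- scene_spec(shape = c(64L, 64L), n_donor = 200L, n_acceptor = 200L,
                     radius_range = c(8, 10), seed = 96)
  expect_error(generate_scene(spec), class = "fretcoloc_generation_error")
  expect_error(
    generate_scene(scene_spec(shape = c(16L, 16L), n_donor = 1L,
                              n_acceptor = 0L, radius_range = c(8, 10), seed = 97)),
    class = "fretcoloc_generation_error")
})

test_that("scenes written to disk reload identically", {
  dir <- withr::local_tempdir()
  scene <- generate_scene(small_scene_spec(98))
  paths <- write_scene(scene, dir, prefix = "sc")
  st <- load_triple(paths[["donor"]], paths[["acceptor"]], paths[["rawfret"]],
                    bit_depth = 12)
  expect_identical(st$donor$pixels, scene$stack$donor$pixels)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$d_true, scene$truth$d_true)
})
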