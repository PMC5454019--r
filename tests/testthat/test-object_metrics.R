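one_object <- function(df_vals, af_vals) {
  n <- length(df_vals)
  lab <- matrix(0L, 1, n + 1)
  lab[1, seq_len(n)] <- 1L
  objects <- labeled_objects(lab, "union")
  donor <- matrix(c(df_vals, 0), 1, n + 1)
  acceptor <- matrix(c(af_vals, 0), 1, n + 1)
  list(objects = objects, donor = donor, acceptor = acceptor)
}

test_that("object Pearson matches hand and brute-force values", {
  o <- one_object(c(10, 20, 30, 40), 2 * c(10, 20, 30, 40) + 5)
  expect_equal(pearson_per_object(o$objects, o$donor, o$acceptor)$pearson, 1)

  o2 <- one_object(c(10, 20, 30, 40), 100 - c(10, 20, 30, 40))
  expect_equal(pearson_per_object(o2$objects, o2$donor, o2$acceptor)$pearson, -1)

  o3 <- one_object(c(1, 2, 3, 4), c(2, 1, 4, 3))
  got <- pearson_per_object(o3$objects, o3$donor, o3$acceptor)$pearson
  expect_equal(got, 0.6)
  expect_equal(got, naive_pearson(c(1, 2, 3, 4), c(2, 1, 4, 3)))

  # zero variance in one channel: undefined, not 0
  o4 <- one_object(c(5, 5, 5), c(1, 2, 3))
  expect_true(is.na(pearson_per_object(o4$objects, o4$donor, o4$acceptor)$pearson))
})

test_that("color-mix coefficient spans single-marker to complete mix", {
  o <- one_object(c(40, 80), c(40, 80))
  expect_equal(colormix_per_object(o$objects, o$donor, o$acceptor)$colormix, 1)

  o2 <- one_object(c(40, 80), c(0, 0))
  expect_equal(colormix_per_object(o2$objects, o2$donor, o2$acceptor)$colormix, 0)

  o3 <- one_object(c(50, 100), c(100, 50))
  expect_equal(colormix_per_object(o3$objects, o3$donor, o3$acceptor)$colormix, 0.5)
  expect_equal(
    colormix_per_object(o3$objects, o3$donor, o3$acceptor, mode = "ratio_of_means")$colormix,
    1)  # equal channel means
})

test_that("acceptor:donor ratio handles zero denominators per contract", {
  o <- one_object(c(200, 200), c(400, 400))
  expect_equal(ad_ratio_per_object(o$objects, o$donor, o$acceptor)$ad_ratio, 2)

  o2 <- one_object(c(200, 200), c(0, 0))
  expect_equal(ad_ratio_per_object(o2$objects, o2$donor, o2$acceptor)$ad_ratio, 0)

  o3 <- one_object(c(0, 0), c(10, 10))
  expect_true(is.na(ad_ratio_per_object(o3$objects, o3$donor, o3$acceptor)$ad_ratio))
})

test_that("per-object NFRET modes coincide on uniform objects", {
  st <- make_stack(const_mat(200, 2, 3), const_mat(400, 2, 3), const_mat(100, 2, 3))
  fac <- bleedthrough_factors(0.1, 0.05)
  fr <- fret_images(st, fac)
  obj <- labeled_objects(matrix(1L, 2, 3), "union")
  pm <- nfret_per_object(obj, fr)$mean_NFRET
  rm_ <- nfret_per_object(obj, fr, st, mode = "ratio_of_means")$mean_NFRET
  expect_equal(pm, 60 / sqrt(200 * 400))
  expect_equal(pm, rm_)

  # pure bleed-through: zero NFRET
  raw0 <- 0.1 * const_mat(200, 2, 3) + 0.05 * const_mat(400, 2, 3)
  st0 <- make_stack(const_mat(200, 2, 3), const_mat(400, 2, 3), raw0)
  fr0 <- fret_images(st0, fac)
  expect_equal(nfret_per_object(obj, fr0)$mean_NFRET, 0)

  # non-uniform object: pixel-mean mode equals the brute-force average
  set.seed(41)
  df <- matrix(sample(100:400, 12), 3, 4)
  af <- matrix(sample(100:400, 12), 3, 4)
  raw <- matrix(sample(50:150, 12), 3, 4)
  stn <- make_stack(df, af, raw)
  frn <- fret_images(stn, fac)
  objn <- labeled_objects(matrix(1L, 3, 4), "union")
  expect_equal(nfret_per_object(objn, frn)$mean_NFRET,
               naive_nfret_mean(frn$fretc, df, af))
})

test_that("colocalization area fraction counts intersection over union", {
  a <- binary_mask(disc_mask(30, 30, c(15, 15), 8))
  expect_equal(coloc_area_fraction(a, a)$per_image_pct, 100)

  b <- binary_mask(disc_mask(30, 30, c(8, 8), 4))
  c2 <- binary_mask(disc_mask(30, 30, c(22, 22), 4))
  u <- combine_union(b, c2)
  x <- combine_intersection(b, c2)
  expect_equal(coloc_area_fraction(u, x)$per_image_pct, 0)

  # constructed counts: |union| = 200, |intersection| = 50
  um <- matrix(FALSE, 20, 20); um[1:200] <- TRUE
  im <- matrix(FALSE, 20, 20); im[1:50] <- TRUE
  expect_equal(coloc_area_fraction(binary_mask(um), binary_mask(im))$per_image_pct, 25)

  obj <- label_objects(binary_mask(um), min_size = 0)
  per_obj <- coloc_area_fraction(binary_mask(um), binary_mask(im), obj)$per_object
  expect_equal(per_obj$coloc_area_fraction_pct, 25)
})

test_that("object table is complete, conserving and saturation-flagged", {
  set.seed(42)
  df <- const_mat(10, 40, 40)
  df[disc_mask(40, 40, c(10, 10), 5)] <- 1000
  df[disc_mask(40, 40, c(10, 30), 5)] <- 1200
  df[disc_mask(40, 40, c(30, 20), 5)] <- 900
  af <- const_mat(10, 40, 40)
  af[disc_mask(40, 40, c(30, 20), 5)] <- 800
  af[15, 15] <- 4095  # one saturated acceptor pixel outside any object
  raw <- const_mat(5, 40, 40)
  st <- make_stack(df, af, raw)
  fac <- bleedthrough_factors(0.1, 0.05)
  ana <- analyze_triple(st, fac, threshold_method = "manual",
                        manual_thresholds = c(donor = 400, acceptor = 400),
                        min_size = 5)
  tab <- tidy(ana)
  expect_equal(nrow(tab), 3)
  expect_equal(sum(tab$area_px), sum(ana$masks$union$pixels))
  expect_named(tab, c("source_id", "object_id", "provenance", "area_px",
                      "centroid_row", "centroid_col", "mean_DF", "mean_AF",
                      "mean_rawFRET", "mean_FRETc", "mean_NFRET", "pearson",
                      "ad_ratio", "colormix", "coloc_area_fraction_pct",
                      "saturated_flag", "label"))
  expect_false(any(tab$saturated_flag))

  # move the saturated pixel into an object: that object gets flagged
  af2 <- af; af2[15, 15] <- 10; af2[10, 10] <- 4095
  st2 <- make_stack(df, af2, raw)
  tab2 <- tidy(analyze_triple(st2, fac, threshold_method = "manual",
                              manual_thresholds = c(donor = 400, acceptor = 400),
                              min_size = 5, saturation_tolerance = 1))
  flagged <- tab2[tab2$saturated_flag, ]
  expect_equal(nrow(flagged), 1)
  expect_lt(abs(flagged$centroid_row - 9), 2)  # 0-based centroid near (9, 9)

  # empty label map: empty table
  fr <- fret_images(st, fac)
  empty <- build_object_table(st, fr, labeled_objects(matrix(0L, 40, 40), "union"))
  expect_equal(nrow(empty), 0)
})

test_that("mean object Pearson recovers the generating correlation", {
  base <- scenario_library(1951)$true_interaction
  for (rho in c(0, 0.5, 0.9)) {
    spec <- base
    spec$rho <- rho
    spec$seed <- base$seed + round(100 * rho)
    scene <- generate_scene(spec)
    tab <- tidy(analyze_triple(scene$stack, true_factors()))
    ok <- !is.na(tab$pearson)
    expect_gte(sum(ok), 100)
    m <- mean(tab$pearson[ok])
    sem <- sd(tab$pearson[ok]) / sqrt(sum(ok))
    expect_lt(abs(m - rho), 3 * sem)
  }
})

test_that("whole-image Pearson is defined and bounded", {
  sc <- cached_scene("distinct_localization")
  r <- whole_image_pearson(sc$stack$donor, sc$stack$acceptor)
  expect_true(is.finite(r) && abs(r) <= 1)
  expect_true(is.na(whole_image_pearson(const_mat(3), const_mat(7))))
})
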