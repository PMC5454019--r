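test_that("FRETc reproduces hand-substituted values and identities", {
  st <- make_stack(const_mat(200), const_mat(400), const_mat(100))
  fac <- bleedthrough_factors(0.1, 0.05)
  expect_equal(compute_fretc(st, fac), const_mat(60))

  none <- bleedthrough_factors(0, 0)
  expect_equal(compute_fretc(st, none), st$rawfret$pixels)

  # pure bleed-through scene cancels exactly
  raw <- 0.1 * const_mat(200) + 0.05 * const_mat(400)
  st2 <- make_stack(const_mat(200), const_mat(400), raw)
  expect_equal(compute_fretc(st2, fac), const_mat(0))

  # negative values are preserved, not clipped
  st3 <- make_stack(const_mat(1000), const_mat(1000), const_mat(0))
  expect_true(all(compute_fretc(st3, fac) == -150))
})

test_that("NFRET divides by the geometric fluorophore mean, undefined at zero", {
  st <- make_stack(const_mat(200), const_mat(400), const_mat(100))
  fac <- bleedthrough_factors(0.1, 0.05)
  nf <- compute_nfret(compute_fretc(st, fac), st)
  expect_equal(nf[1, 1], 60 / sqrt(200 * 400))
  expect_equal(round(nf[1, 1], 4), 0.2121)

  donor0 <- const_mat(200); donor0[3, 3] <- 0
  st0 <- make_stack(donor0, const_mat(400), const_mat(100))
  nf0 <- compute_nfret(compute_fretc(st0, fac), st0)
  expect_true(is.na(nf0[3, 3]))
  expect_false(anyNA(nf0[-19]))  # linear index of (3, 3) in 8x8
})

test_that("NFRET is invariant under joint fluorophore-amount scaling", {
  set.seed(21)
  d <- 0.1; a <- 0.05; s_amp <- 30
  df <- matrix(runif(400, 50, 500), 20, 20)
  af <- matrix(runif(400, 50, 500), 20, 20)
  s_field <- matrix(runif(400, 0, s_amp), 20, 20)
  raw <- d * df + a * af + s_field
  fac <- bleedthrough_factors(d, a)
  nf1 <- compute_nfret(compute_fretc(list(donor = df, acceptor = af, rawfret = raw), fac),
                       list(donor = df, acceptor = af, rawfret = raw))
  k <- 4
  scaled <- list(donor = k * df, acceptor = k * af, rawfret = d * k * df + a * k * af + k * s_field)
  nf4 <- compute_nfret(compute_fretc(scaled, fac), scaled)
  expect_lt(max(abs(nf4 - nf1) / abs(nf1)), 1e-6)
})

test_that("FRETc is linear in each channel", {
  set.seed(22)
  g <- list(donor = matrix(runif(100, 0, 1000), 10, 10),
            acceptor = matrix(runif(100, 0, 1000), 10, 10),
            rawfret = matrix(runif(100, 0, 1000), 10, 10))
  fac <- bleedthrough_factors(0.12, 0.07)
  f1 <- compute_fretc(g, fac)
  g2 <- g; g2$rawfret <- 2 * g$rawfret
  expect_equal(compute_fretc(g2, fac),
               2 * f1 + fac$d * g$donor + fac$a * g$acceptor)
})

test_that("foreground FRETc is unbiased on simulated scenes", {
  fac <- true_factors()
  # non-interacting: mean foreground FRETc compatible with 0 at 3 SE
  distinct <- cached_scene("distinct_localization")
  ana <- analyze_triple(distinct$stack, fac)
  fg <- ana$masks$union$pixels
  vals <- ana$fret$fretc[fg]
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)))

  # interacting: mean FRETc over co-located cores estimates the sensitized
  # emission actually injected there
  inter <- cached_scene("true_interaction")
  ana2 <- analyze_triple(inter$stack, fac)
  co <- ana2$masks$intersection$pixels
  vals2 <- ana2$fret$fretc[co]
  s_local <- inter$truth$true_fretc[co]
  expect_lt(abs(mean(vals2) - mean(s_local)), 3 * sd(vals2) / sqrt(length(vals2)))
})

test_that("pseudo-color rendering clips for display only", {
  z <- render_fretc(const_mat(0, 6, 6), bar_width = 0)
  expect_equal(dim(z), c(6, 6, 3))
  expect_true(all(z == z[1, 1, 1] | z == z[1, 1, 2] | z == z[1, 1, 3]))

  m <- const_mat(0, 6, 6); m[1, 1] <- -50; m[2, 2] <- 1e6
  z2 <- render_fretc(m, gain = 10, display_max = 4095, bar_width = 0)
  expect_equal(z2[1, 1, ], z2[3, 3, ])            # negative renders as zero
  expect_false(isTRUE(all.equal(z2[2, 2, ], z2[1, 1, ])))  # saturated top color

  with_bar <- render_fretc(m, bar_width = 10)
  expect_equal(dim(with_bar)[2], 6 + 12)
  expect_length(attr(with_bar, "scale"), 5)
  expect_error(render_fretc(m, gain = 0), class = "fretcoloc_config_error")
})

test_that("float map TIFF sidecar round-trips FRETc values", {
  dir <- withr::local_tempdir()
  set.seed(23)
  m <- matrix(rnorm(100, 0, 50), 10, 10)
  m[1, 5] <- NA
  path <- file.path(dir, "fretc.tif")
  write_float_tiff(m, path)
  back <- read_float_tiff(path)
  expect_equal(which(is.na(back)), which(is.na(m)))
  expect_lt(max(abs(back - m), na.rm = TRUE), 1e-5)
})
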