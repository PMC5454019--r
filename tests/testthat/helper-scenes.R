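# Shared fixtures: scenes are generated once per test run and cached, since
# several test files exercise the same study-condition scenarios.

.scene_cache <- new.env(parent = emptyenv())

cached_scene <- function(name, base_seed = 1951L) {
  key <- paste(name, base_seed, sep = "@")
  if (is.null(.scene_cache[[key]])) {
    .scene_cache[[key]] <- generate_scene(scenario_library(base_seed)[[name]])
  }
  .scene_cache[[key]]
}

true_factors <- function() bleedthrough_factors(0.15, 0.05, method = "truth")

# Build a triple_stack directly from integer matrices.
make_stack <- function(donor, acceptor, rawfret, bit_depth = 12, id = "test") {
  triple_stack(
    donor = channel_image(donor, bit_depth, "donor"),
    acceptor = channel_image(acceptor, bit_depth, "acceptor"),
    rawfret = channel_image(rawfret, bit_depth, "rawfret"),
    source_id = id)
}

const_mat <- function(value, nr = 8, nc = 8) matrix(value, nr, nc)

# Small mixed scene used for oracle comparisons and batch tests.
small_scene_spec <- function(seed) {
  scene_spec(shape = c(96L, 96L), n_donor = 6L, n_acceptor = 6L,
             radius_range = c(4, 7), overlap_fraction = 0.5, rho = 0.5,
             s_true = 100, glow_amplitude = 0.1, texture_sd = 10,
             seed = seed)
}

# Naive reference implementations (independent oracles, plain loops).
naive_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  if (dx == 0 || dy == 0) return(NA_real_)
  num / sqrt(dx * dy)
}

naive_colormix <- function(x, y) {
  acc <- 0
  for (i in seq_along(x)) {
    hi <- max(x[i], y[i])
    acc <- acc + if (hi == 0) 0 else min(x[i], y[i]) / hi
  }
  acc / length(x)
}

naive_nfret_mean <- function(fretc, df, af) {
  vals <- c()
  for (i in seq_along(fretc)) {
    if (df[i] > 0 && af[i] > 0) {
      vals <- c(vals, fretc[i] / sqrt(df[i] * af[i]))
    }
  }
  if (!length(vals)) NA_real_ else sum(vals) / length(vals)
}

disc_mask <- function(nr, nc, center, radius) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  sqrt((rows - center[1])^2 + (cols - center[2])^2) <= radius
}
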