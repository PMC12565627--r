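test_that("binning counts every positive event and averages across cells", {
  # one cell, repeated value: a single occupied bin
  prof <- build_profile(list(rep(3.5, 12)), n_bins = 50)
  expect_equal(sum(prof$mean_counts), 12)
  expect_equal(sum(prof$mean_counts > 0), 1)

  # identical cells: mean equals either cell's counts
  v <- c(1, 2, 4, 8, 16)
  p1 <- build_profile(list(v), n_bins = 40)
  p2 <- build_profile(list(v, v), n_bins = 40)
  expect_equal(p2$mean_counts, p1$mean_counts)
  expect_equal(p2$n_cells, 2L)

  # conservation with unequal cells and zeros excluded
  set.seed(8)
  cells <- lapply(1:7, function(i) c(rlnorm(sample(20:60, 1)), 0, 0))
  prof <- build_profile(cells, n_bins = 200)
  expect_equal(sum(prof$mean_counts) * prof$n_cells,
               sum(unlist(cells) > 0))
  expect_equal(prof$n_zero_excluded, 14L)
  expect_true(all(diff(prof$bin_edges) > 0))
  expect_error(build_profile(list(c(0, 0))), "positive")
})

test_that("peak detection matches the exhaustive oracle on short profiles", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(20:200, 1)
    y <- abs(stats::filter(rnorm(n), rep(1, 5), circular = TRUE))
    y <- as.numeric(y)
    if (rep %% 3 == 0) y[sample(n, 4)] <- y[sample(n, 4)] # inject ties
    prom <- runif(1, 0, 0.5) * max(y)
    dist <- sample(1:8, 1)
    got <- find_peaks_core(y, prominence_min = prom, min_distance = dist)
    expect_identical(got$index, oracle_peaks(y, prom, dist),
                     label = sprintf("rep %d (n=%d)", rep, n))
  }
})

test_that("plateaus report their left-most index", {
  y <- c(0, 1, 3, 3, 3, 1, 0)
  got <- find_peaks_core(y)
  expect_identical(got$index, 3L)
})

test_that("a constant profile has no peaks", {
  prof <- build_profile(list(rep(2, 5)), n_bins = 30)
  flat <- prof
  flat$mean_counts <- rep(1, 30)
  expect_identical(nrow(detect_peaks(flat)), 0L)
})

test_that("peak positions are invariant under vertical rescaling", {
  spec <- scenario_spec(seed = 13)
  g <- generate_intensity_population(spec, "YD", "C10", n_cells = 40,
                                     events_per_cell = 300)
  prof <- build_profile(g$cells, n_bins = 400)
  pk1 <- detect_peaks(prof, prominence = 0.05 * max(prof$mean_counts),
                      min_distance = 10, smooth_window = 9)
  # power-of-two factor: exact in floating point, so the check isolates the
  # design property from rounding at the prominence threshold
  scaled <- prof
  scaled$mean_counts <- prof$mean_counts * 32
  pk2 <- detect_peaks(scaled, prominence = 32 * 0.05 * max(prof$mean_counts),
                      min_distance = 10, smooth_window = 9)
  expect_equal(pk1$log10_position, pk2$log10_position)
})

test_that("detected peak positions increase strictly with peak ordinal", {
  for (s in 1:5) {
    spec <- scenario_spec(seed = s, n_components = 3L)
    g <- generate_intensity_population(spec, "RS", "Bleo", n_cells = 60,
                                       events_per_cell = 400)
    prof <- build_profile(g$cells, n_bins = 1000)
    pk <- detect_peaks(prof, smooth_window = 31,
                       prominence = 0.05 * max(prof$mean_counts),
                       min_distance = 30)
    if (nrow(pk) > 1) expect_true(all(diff(pk$log10_position) > 0))
    expect_identical(pk$peak_id, seq_len(nrow(pk)))
  }
})

test_that("unimodal and well-separated bimodal mixtures are recovered near their modes", {
  spec <- scenario_spec(seed = 3, n_components = 1L)
  g <- generate_intensity_population(spec, "YD", "C10", n_cells = 100,
                                     events_per_cell = 1000)
  prof <- build_profile(g$cells, n_bins = spec$profile_n_bins)
  pk <- detect_peaks(prof, smooth_window = spec$profile_smooth_window,
                     prominence = spec$profile_prominence_frac *
                       max(prof$mean_counts),
                     min_distance = round(0.01 * spec$profile_n_bins))
  expect_identical(nrow(pk), 1L)
  expect_lt(abs(pk$log10_position - g$truth$modes_log10), 0.05)

  spec2 <- scenario_spec(seed = 4, peak_slope = 1.5)
  g2 <- generate_intensity_population(spec2, "YD", "C10", n_cells = 100,
                                      events_per_cell = 1000)
  prof2 <- build_profile(g2$cells, n_bins = spec2$profile_n_bins)
  pk2 <- detect_peaks(prof2, smooth_window = spec2$profile_smooth_window,
                      prominence = spec2$profile_prominence_frac *
                        max(prof2$mean_counts),
                      min_distance = round(0.01 * spec2$profile_n_bins))
  expect_identical(nrow(pk2), 2L)
  expect_true(all(abs(pk2$log10_position - g2$truth$modes_log10) < 0.05))
})
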