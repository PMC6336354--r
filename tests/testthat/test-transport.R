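test_that("tracks decompose into runs and pauses framed by reversals", {
  # monotone anterograde run
  s <- segment_track(seq(0, 4, by = 0.2), dt = 0.2)
  expect_equal(nrow(s), 1L)
  expect_equal(s$direction, "anterograde")
  expect_equal(s$velocity, 1.0, tolerance = 1e-12)

  # constant position: one pause spanning the track
  sp <- segment_track(rep(5, 15), dt = 0.2)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$direction, "pause")
  expect_equal(sp$run_length, 0)

  # reversal: boundary within the smoothing half-width of frame 11
  pos <- c(seq(0, 2, by = 0.2), seq(1.8, 0, by = -0.2))
  sr <- segment_track(pos, dt = 0.2)
  expect_equal(sr$direction, c("anterograde", "retrograde"))
  expect_lte(abs(sr$end_frame[1] - 11), 1)
})

test_that("segmentation is offset-invariant and reflects direction labels
           under coordinate reflection", {
  set.seed(4)
  tr <- gen_tracks(5, duration = 20, dt = 0.2, seed = 31)
  for (p in tr) {
    a <- segment_track(p, dt = 0.2)
    b <- segment_track(p + 123.4, dt = 0.2)
    expect_equal(a$velocity, b$velocity, tolerance = 1e-9)
    expect_equal(a$direction, b$direction)
    r <- segment_track(-p, dt = 0.2)
    flip <- c(anterograde = "retrograde", retrograde = "anterograde",
              pause = "pause")
    expect_equal(r$direction, unname(flip[a$direction]))
  }
})

test_that("transport summaries classify particles by net displacement and
           fractions sum to one", {
  const <- replicate(5, rep(2, 20), simplify = FALSE)
  su <- summarize_transport(const, dt = 0.2)
  expect_equal(unname(su$particle_fractions["stationary"]), 1)

  retro <- list(seq(10, 4, length.out = 31))
  sr <- summarize_transport(retro, dt = 0.2)
  expect_equal(unname(sr$particle_fractions["retrograde"]), 1)

  tr <- gen_tracks(60, duration = 20, dt = 0.2, seed = 77)
  st <- summarize_transport(tr, dt = 0.2)
  expect_equal(sum(st$particle_fractions), 1, tolerance = 1e-12)
  expect_equal(sum(st$time_fractions), 1, tolerance = 1e-12)
})

test_that("a retrograde-biased state model yields a retrograde particle
           fraction inside the binomial 99% interval", {
  # strong retrograde bias: particles mostly move toward the cell body
  P <- matrix(c(0.85, 0.05, 0.10,
                0.02, 0.88, 0.10,
                0.10, 0.30, 0.60), 3, 3, byrow = TRUE)
  tr <- gen_tracks(100, duration = 30, dt = 0.2,
                   velocities = c(anterograde = 1, retrograde = -1),
                   transition = P, seed = 55)
  su <- summarize_transport(tr, dt = 0.2)
  # truth estimated from the net-displacement sign distribution of the
  # generating chain: simulate the classifier on an independent replicate
  tr2 <- gen_tracks(2000, duration = 30, dt = 0.2,
                    velocities = c(anterograde = 1, retrograde = -1),
                    transition = P, seed = 56)
  p_true <- summarize_transport(tr2, dt = 0.2)$particle_fractions["retrograde"]
  ci <- qnorm(0.995) * sqrt(p_true * (1 - p_true) / 100)
  expect_lt(abs(su$particle_fractions["retrograde"] - p_true), ci + 0.02)
})

test_that("axon maps normalize to axon length and bin uniformly", {
  a <- axon_spatial_stats(seq(10, 290, length.out = 30), 300)
  expect_equal(a$density_per_100um, 10)
  expect_equal(axon_spatial_stats(300, 300)$relative_pct, 100)
  expect_error(axon_spatial_stats(301, 300), "outside")

  set.seed(10)
  pos <- runif(1000, 0, 200)
  b <- axon_spatial_stats(pos, 200, n_bins = 10)
  expect_equal(sum(b$bins$count), 1000L)
  # multinomial 99% band per bin around the uniform expectation
  expected <- 100
  band <- qnorm(0.995) * sqrt(1000 * 0.1 * 0.9)
  expect_true(all(abs(b$bins$count - expected) < band + 1))
})

test_that("ROI background subtraction is exact on constructions", {
  # uniform image: pure background, zero final signal
  m <- matrix(FALSE, 20, 20); m[8:12, 8:12] <- TRUE
  u <- roi_integrated_intensity(matrix(3, 20, 20), m)
  expect_equal(u$final, 0, tolerance = 1e-9)
  expect_equal(u$background_per_px, 3, tolerance = 1e-12)

  # punctum of known integral wholly inside the inner mask
  g <- gen_roi_image(c(61, 61), background_level = 2,
                     puncta = data.frame(x = 31, y = 31,
                                         integrated_intensity = 500,
                                         width = 1.5),
                     noise_sd = 0, seed = 1)
  r <- roi_integrated_intensity(g$image, g$masks[[1]], dilation_px = 2)
  expect_equal(r$final, 500, tolerance = 1e-2)
  expect_gt(r$area_out, r$area_in)

  expect_error(roi_integrated_intensity(matrix(1, 5, 5),
                                        matrix(FALSE, 5, 5)), "empty")
  expect_error(roi_integrated_intensity(matrix(1, 5, 5),
                                        matrix(TRUE, 5, 5)), "ring")
})

test_that("ROI estimates are unbiased on pure-noise images", {
  m <- matrix(FALSE, 30, 30); m[12:18, 12:18] <- TRUE
  finals <- vapply(1:40, function(s) {
    g <- gen_roi_image(c(30, 30), background_level = 10, noise_sd = 2,
                       seed = 1000 + s)
    roi_integrated_intensity(g$image, m)$final
  }, numeric(1))
  expect_lt(abs(mean(finals)), 3 * sd(finals) / sqrt(length(finals)))
})

test_that("spindle tilt is the axis angle folded to [0, 90] degrees", {
  expect_equal(spindle_tilt_angle(c(0, 0), c(1, 0), c(0, 0), c(2, 0)), 0)
  expect_equal(spindle_tilt_angle(c(0, 0), c(1, 1), c(0, 0), c(1, 0)), 45)
  expect_equal(spindle_tilt_angle(c(0, 0), c(1, 3), c(0, 0), c(1, 0)),
               atan(3) * 180 / pi, tolerance = 1e-10)
  # axis symmetry: swapping centrosomes changes nothing
  expect_equal(spindle_tilt_angle(c(1, 3), c(0, 0), c(0, 0), c(1, 0)),
               spindle_tilt_angle(c(0, 0), c(1, 3), c(0, 0), c(1, 0)))
  expect_error(spindle_tilt_angle(c(1, 1), c(1, 1), c(0, 0), c(1, 0)),
               "coincident")

  rb <- rose_bins(c(3, 17, 44, 46, 89))
  expect_equal(sum(rb$count), 5L)
  expect_equal(nrow(rb), 6L)
})

test_that("the exact 2x2 test reproduces the spindle-tilt contingency
           p-value and agrees with stats::fisher.test", {
  p <- fisher_exact_2x2(7, 14, 0, 13)
  expect_equal(signif(p, 2), 0.029)
  expect_equal(p, stats::fisher.test(matrix(c(7, 14, 0, 13), 2,
                                            byrow = TRUE))$p.value,
               tolerance = 1e-10)
  # degenerate column: the only table with these margins
  expect_equal(fisher_exact_2x2(0, 5, 0, 8), 1)
  # full enumeration hand value for the 3,1 / 1,3 table
  expect_equal(fisher_exact_2x2(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)
  # one-sided is the upper tail
  expect_equal(fisher_exact_2x2(3, 1, 1, 3, sided = "one"),
               stats::fisher.test(matrix(c(3, 1, 1, 3), 2, byrow = TRUE),
                                  alternative = "greater")$p.value,
               tolerance = 1e-12)

  # spot agreement with the brute-force oracle on moderate tables
  set.seed(5)
  for (i in 1:50) {
    cells <- as.vector(stats::rmultinom(1, sample(8:20, 1), rep(0.25, 4)))
    if (cells[1] + cells[2] == 0 || cells[3] + cells[4] == 0) next
    expect_equal(fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4]),
                 brute_force_fisher(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-10)
  }
})
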