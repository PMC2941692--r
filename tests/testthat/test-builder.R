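# Nuclear giant-loop walk, fiber subdivision, nucleosome placement and
# bp -> element mapping.

test_that("a chromosome of exactly one loop closes on its anchor", {
  p <- nuclear_params(loop_size_bp = 3e6, step_bp = 3e4,
                      step_length_nm = 150, nucleus_radius_nm = 5000,
                      seed = 9)
  walk <- build_nuclear_walk(3e6, p)
  expect_equal(nrow(walk), 101)  # 100 steps + origin
  expect_equal(attr(walk, "loop_boundaries"), 1L)
  closure <- sqrt(sum((as.numeric(walk[101, c("x", "y", "z")]) -
                         as.numeric(walk[1, c("x", "y", "z")]))^2))
  expect_lt(closure, 1e-6)
  # every step has the prescribed length
  steps <- sqrt(rowSums(diff(as.matrix(walk[, c("x", "y", "z")]))^2))
  expect_equal(steps, rep(150, 100), tolerance = 1e-6)
  expect_true(all(point_radii(walk) <= 5000 + 1e-9))
  expect_true(all(diff(walk$bp) > 0))
})

test_that("step count, loops and determinism follow the parameters", {
  p <- nuclear_params(loop_size_bp = 6e4, step_bp = 6e3,
                      nucleus_radius_nm = 2000, seed = 4)
  # 20 kbp / 6 kbp steps -> ceil = 4 steps, no full 10-step loop fits
  w1 <- build_nuclear_walk(2e4, p)
  expect_equal(nrow(w1), 5)
  # 126 kbp -> 21 steps: one 10-step loop + backbone + partial
  w2 <- build_nuclear_walk(1.26e5, p)
  expect_equal(nrow(w2), 22)
  expect_equal(sum(!is.na(unique(w2$loop))), 2)

  expect_identical(build_nuclear_walk(1.26e5, p),
                   build_nuclear_walk(1.26e5, p))
  p2 <- p; p2$seed <- 5L
  expect_false(identical(build_nuclear_walk(1.26e5, p),
                         build_nuclear_walk(1.26e5, p2)))

  expect_error(build_nuclear_walk(100, p),
               class = "chromo3d_error_argument")
})

test_that("unconfined open walk recovers ideal-chain statistics", {
  n_steps <- 1000
  reps <- 200
  b <- 150
  r2 <- vapply(seq_len(reps), function(i) {
    p <- nuclear_params(loop_size_bp = 1e12, step_bp = 3e4,
                        step_length_nm = b, nucleus_radius_nm = 1e9,
                        seed = 1e5 + i)
    w <- build_nuclear_walk(n_steps * 3e4, p)
    sum((as.numeric(w[nrow(w), c("x", "y", "z")]) -
           as.numeric(w[1, c("x", "y", "z")]))^2)
  }, numeric(1))
  expected <- n_steps * b^2
  se <- stats::sd(r2) / sqrt(reps)
  expect_lt(abs(mean(r2) - expected), 3 * se)
})

test_that("fiber subdivision covers the chromosome and respects jitter", {
  p <- nuclear_params(loop_size_bp = 6e4, step_bp = 3e4,
                      nucleus_radius_nm = 2000, seed = 8)
  nuc <- build_nuclear_walk(9e4, p)
  fib <- build_fiber_path(nuc, bp_per_point = 1200, jitter_nm = 3)
  # 30000 / 1200 = 25 points per nuclear step
  expect_equal(nrow(fib), 3 * 25 + 1)
  expect_true(all(diff(fib$bp) > 0))
  expect_equal(fib$bp[1], 0)
  expect_equal(fib$bp[nrow(fib)], 9e4)
  expect_true(all(point_radii(fib) <= 2000 + 1e-9))

  # zero jitter degenerates to the interpolated nuclear polyline
  f0 <- build_fiber_path(nuc, bp_per_point = 1200, jitter_nm = 0)
  seg <- findInterval(f0$bp, nuc$bp, rightmost.closed = TRUE)
  seg <- pmin(seg, nrow(nuc) - 1)
  t <- (f0$bp - nuc$bp[seg]) / (nuc$bp[seg + 1] - nuc$bp[seg])
  expect_equal(f0$x, nuc$x[seg] + t * (nuc$x[seg + 1] - nuc$x[seg]),
               tolerance = 1e-9)
  expect_equal(f0$z, nuc$z[seg] + t * (nuc$z[seg + 1] - nuc$z[seg]),
               tolerance = 1e-9)

  expect_identical(build_fiber_path(nuc, 1200, 3, seed = 2),
                   build_fiber_path(nuc, 1200, 3, seed = 2))
  expect_error(build_fiber_path(nuc, bp_per_point = 3e4),
               class = "chromo3d_error_argument")
})

test_that("default nucleosome tiling conserves bp exactly", {
  m <- tiny_model(len = 2000)
  recs <- m$chromosomes$chr1$nucleosomes
  expect_equal(nrow(recs), 10)
  expect_true(all(recs$wrap_bp == 147))
  expect_equal(unique(recs$linker_bp_after[-10]), 53)
  expect_identical(sum(recs$wrap_bp + recs$linker_bp_after), 2000)
  validate_frames(recs)
})

test_that("explicit positions reproduce browser-style coordinates", {
  # the 1-based inclusive interval 7602872-7603018 is the 0-based start
  # 7602871 with an inclusive length of 147 bp
  rng <- parse_range("chr1:7602872-7603018")
  expect_equal(rng$start, 7602871)
  expect_equal(rng$end - rng$start, 147)

  g <- synth_genome(lengths = 7.7e6, seed = 2)
  m <- build_genome_model(g, seed = 2,
                          positions = list(chr1 = 7602871))
  recs <- m$chromosomes$chr1$nucleosomes
  expect_equal(nrow(recs), 1)
  expect_equal(recs$start, 7602871)
  expect_equal(recs$wrap_bp, 147L)

  hit <- map_bp_to_scale(m, "chr1", 7602871, "nucleosome")
  expect_equal(hit$type, "nucleosome")
  expect_equal(hit$index, 1L)
})

test_that("invalid explicit positions are rejected with offenders named", {
  m <- tiny_model(len = 2000)
  fib <- m$chromosomes$chr1$fiber
  expect_error(place_nucleosomes(fib, positions = c(100, 150)),
               "100\\+147 > 150",
               class = "chromo3d_error_validation")
  expect_error(place_nucleosomes(fib, positions = c(150, 100)),
               class = "chromo3d_error_validation")
  expect_error(place_nucleosomes(fib, positions = c(1900)),
               class = "chromo3d_error_validation")
})

test_that("bp map returns the containing element at every scale", {
  m <- tiny_model(len = 2000)
  for (scale in c("nuclear", "fiber", "nucleosome")) {
    first <- map_bp_to_scale(m, "chr1", 0, scale)
    expect_equal(first$index, 1L)
    expect_equal(first$bp_start, 0)
  }
  wrap <- map_bp_to_scale(m, "chr1", 146, "nucleosome")
  expect_equal(wrap$type, "nucleosome")
  link <- map_bp_to_scale(m, "chr1", 147, "nucleosome")
  expect_equal(link$type, "linker")
  expect_equal(link$index, 1L)
  expect_equal(link$next_index, 2L)
  expect_error(map_bp_to_scale(m, "chr1", 2000, "fiber"),
               class = "chromo3d_error_range")
  expect_error(map_bp_to_scale(m, "chrX", 0, "fiber"),
               class = "chromo3d_error_range")
})
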