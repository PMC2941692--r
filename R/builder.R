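# Construction of the coarse scales: nuclear-scale giant-loop random walk,
# 30 nm fiber path, and nucleosome placement along the fiber.

#' Nuclear-scale random-walk parameters
#'
#' Parameters of the giant-loop random-walk representation of a chromosome
#' inside the nucleus: chromatin forms Mbp-scale closed loops attached to a
#' backbone, each loop modelled as a closed equal-step random walk confined
#' to the nuclear sphere.
#'
#' @param loop_size_bp Giant-loop size in bp (default 3 Mbp).
#' @param step_bp Genomic bp per walk step (default 30 kbp).
#' @param step_length_nm Spatial step length in nm (default 150).
#' @param nucleus_radius_nm Confining sphere radius in nm (default 5000).
#' @param seed Integer RNG seed.
#' @return A `nuclear_params` list.
#' @export
nuclear_params <- function(loop_size_bp = 3e6, step_bp = 3e4,
                           step_length_nm = 150, nucleus_radius_nm = 5000,
                           seed = 1L) {
  check_count(loop_size_bp, "loop_size_bp", 1)
  check_count(step_bp, "step_bp", 1)
  if (loop_size_bp < step_bp) {
    abort_argument("`loop_size_bp` must be >= `step_bp`")
  }
  check_number(step_length_nm, "step_length_nm", 0, strict = TRUE)
  check_number(nucleus_radius_nm, "nucleus_radius_nm", step_length_nm,
               strict = TRUE)
  check_count(seed, "seed")
  structure(
    list(loop_size_bp = loop_size_bp, step_bp = step_bp,
         step_length_nm = step_length_nm,
         nucleus_radius_nm = nucleus_radius_nm, seed = as.integer(seed)),
    class = "nuclear_params"
  )
}

# Random unit vectors, n x 3.
runif_sphere <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Uniform point in a sphere of radius R.
runif_ball <- function(radius) {
  as.numeric(runif_sphere(1L)) * radius * stats::runif(1L)^(1 / 3)
}

# Closed equilateral random polygon: m steps of length b summing to zero.
# Alternating projection between the zero-sum hyperplane and the product of
# spheres; converges to closure residual < 1e-9 * b.
closed_loop_steps <- function(m, b) {
  u <- runif_sphere(m)
  for (iter in seq_len(400L)) {
    u <- sweep(u, 2L, colMeans(u))
    len <- sqrt(rowSums(u^2))
    if (any(len == 0)) u[len == 0, ] <- runif_sphere(sum(len == 0))
    u <- u / sqrt(rowSums(u^2))
    if (vec_norm(colSums(u)) < 1e-10) break
  }
  u <- sweep(u, 2L, colMeans(u))
  u <- u / sqrt(rowSums(u^2))  # exact unit steps; closure residual ~1e-10
  u * b
}

# One confined step from `from`: resample direction up to `tries` times,
# then reflect radially back into the sphere (preserving direction, not
# necessarily step length, in that rare fallback).
confined_step <- function(from, b, radius, tries = 100L) {
  for (k in seq_len(tries)) {
    p <- from + as.numeric(runif_sphere(1L)) * b
    if (vec_norm(p) <= radius) return(p)
  }
  p <- from + as.numeric(runif_sphere(1L)) * b
  p * (2 * radius - vec_norm(p)) / vec_norm(p)
}

#' Build the nuclear-scale giant-loop random walk for a chromosome
#'
#' The chromosome is traversed as a sequence of closed giant loops of
#' `loop_size_bp` attached to a backbone: each full loop is a closed
#' equal-step random walk (all steps exactly `step_length_nm`, returning to
#' its anchor), consecutive loop anchors are joined by one backbone step, and
#' any trailing remainder of the chromosome forms an open partial walk. All
#' points are confined to the nuclear sphere (loops are resampled whole if
#' they leave it). The walk is a pure function of `(chrom_length_bp, params)`.
#'
#' @param chrom_length_bp Chromosome length in bp (>= `step_bp`).
#' @param params A [nuclear_params()] object.
#' @return A `nuclear_path` tibble with columns `point` (1-based), `bp`
#'   (anchor, 0-based, strictly increasing), `x`, `y`, `z` (nm) and `loop`
#'   (loop id, `NA` for backbone/tail points). Attributes: `params`,
#'   `chrom_length_bp`, `loop_boundaries` (point indices of loop anchors).
#' @export
build_nuclear_walk <- function(chrom_length_bp, params = nuclear_params()) {
  check_count(chrom_length_bp, "chrom_length_bp", 1)
  if (chrom_length_bp < params$step_bp) {
    abort_argument("`chrom_length_bp` must be >= `step_bp`")
  }
  n_steps <- ceiling(chrom_length_bp / params$step_bp)
  m <- max(3L, round(params$loop_size_bp / params$step_bp))
  b <- params$step_length_nm
  radius <- params$nucleus_radius_nm

  with_seed(params$seed, {
    # how many full loops fit: K loops + (K-1) backbone steps <= n_steps
    n_loops <- 0L
    while ((n_loops + 1L) * m + n_loops <= n_steps) n_loops <- n_loops + 1L
    pts <- matrix(NA_real_, nrow = n_steps + 1L, ncol = 3L)
    loop_id <- rep(NA_integer_, n_steps + 1L)
    loop_boundaries <- integer(0)

    anchor <- runif_ball(radius)
    pos <- 1L
    pts[1L, ] <- anchor
    for (lp in seq_len(n_loops)) {
      loop_boundaries <- c(loop_boundaries, pos)
      # resample the whole loop until it fits in the nucleus
      ok <- FALSE
      for (try in seq_len(60L)) {
        steps <- closed_loop_steps(m, b)
        walk <- sweep(apply(steps, 2L, cumsum), 2L, anchor, "+")
        if (all(rowSums(walk^2) <= radius^2)) { ok <- TRUE; break }
      }
      if (!ok) {
        # contract the loop about its anchor until confined
        for (f in c(0.8, 0.6, 0.4, 0.2, 0.1)) {
          walk <- sweep(apply(steps * f, 2L, cumsum), 2L, anchor, "+")
          if (all(rowSums(walk^2) <= radius^2)) break
        }
      }
      pts[pos + seq_len(m), ] <- walk
      loop_id[pos:(pos + m)] <- lp
      pos <- pos + m
      # backbone step to the next anchor (if another loop follows)
      if (lp < n_loops) {
        anchor <- confined_step(pts[pos, ], b, radius)
        pos <- pos + 1L
        pts[pos, ] <- anchor
        loop_id[pos] <- NA_integer_
      }
    }
    # open tail for the remainder
    while (pos < n_steps + 1L) {
      pts[pos + 1L, ] <- confined_step(pts[pos, ], b, radius)
      pos <- pos + 1L
    }
  })

  bp <- (seq_len(n_steps + 1L) - 1L) * params$step_bp
  bp[n_steps + 1L] <- min(bp[n_steps + 1L], chrom_length_bp)
  out <- tibble(
    point = seq_len(n_steps + 1L),
    bp = as.numeric(bp),
    x = pts[, 1L], y = pts[, 2L], z = pts[, 3L],
    loop = loop_id
  )
  structure(
    out,
    params = params,
    chrom_length_bp = as.numeric(chrom_length_bp),
    loop_boundaries = loop_boundaries,
    class = c("nuclear_path", class(out))
  )
}

# Interpolate positions along a bp-parameterized polyline (tibble with bp,
# x, y, z) at bp values `at`. Returns n x 3 matrix.
polyline_at_bp <- function(path, at) {
  xs <- stats::approx(path$bp, path$x, xout = at, rule = 2)$y
  ys <- stats::approx(path$bp, path$y, xout = at, rule = 2)$y
  zs <- stats::approx(path$bp, path$z, xout = at, rule = 2)$y
  cbind(xs, ys, zs)
}

#' Build the 30 nm fiber path by subdividing the nuclear walk
#'
#' Fiber points are placed every `bp_per_point` bp by linear interpolation
#' along the nuclear polyline, then perturbed by seeded isotropic Gaussian
#' jitter. Points that coincide with nuclear anchors are left unjittered so
#' the fiber passes exactly through every nuclear point; all points are kept
#' inside the nuclear sphere.
#'
#' @param nuclear A [build_nuclear_walk()] result.
#' @param bp_per_point Genomic bp per fiber point (default 1200, about six
#'   nucleosome repeats). Must be < the nuclear `step_bp`.
#' @param jitter_nm Isotropic jitter standard deviation in nm (default 3,
#'   small against the 15 nm fiber radius so each fiber point stays a
#'   representative anchor for the nucleosomes of its segment).
#' @param seed Integer seed (default: nuclear seed + 1).
#' @return A `fiber_path` tibble: `point`, `bp`, `x`, `y`, `z`. Attributes:
#'   `bp_per_point`, `jitter_nm`, `seed`, `chrom_length_bp`,
#'   `nucleus_radius_nm`.
#' @export
build_fiber_path <- function(nuclear, bp_per_point = 1200, jitter_nm = 3,
                             seed = NULL) {
  params <- attr(nuclear, "params")
  check_count(bp_per_point, "bp_per_point", 1)
  if (bp_per_point >= params$step_bp) {
    abort_argument("`bp_per_point` must be < the nuclear `step_bp`")
  }
  check_number(jitter_nm, "jitter_nm", 0)
  seed <- seed %||% (params$seed + 1L)
  chrom_length_bp <- attr(nuclear, "chrom_length_bp")
  bp <- seq(0, chrom_length_bp, by = bp_per_point)
  if (bp[length(bp)] < chrom_length_bp) bp <- c(bp, chrom_length_bp)
  pts <- polyline_at_bp(nuclear, bp)
  on_anchor <- bp %in% nuclear$bp
  radius <- params$nucleus_radius_nm
  if (jitter_nm > 0) {
    with_seed(seed, {
      jit <- matrix(stats::rnorm(length(bp) * 3L, sd = jitter_nm), ncol = 3L)
    })
    jit[on_anchor, ] <- 0
    pts <- pts + jit
    # clamp back inside the nuclear sphere
    rr <- sqrt(rowSums(pts^2))
    over <- rr > radius
    if (any(over)) pts[over, ] <- pts[over, ] * (radius / rr[over])
  }
  out <- tibble(
    point = seq_along(bp), bp = as.numeric(bp),
    x = pts[, 1L], y = pts[, 2L], z = pts[, 3L]
  )
  structure(
    out,
    bp_per_point = bp_per_point, jitter_nm = jitter_nm, seed = seed,
    chrom_length_bp = chrom_length_bp, nucleus_radius_nm = radius,
    class = c("fiber_path", class(out))
  )
}

#' Place nucleosomes along the fiber path
#'
#' Without explicit positions, nucleosome core particles tile the chromosome
#' with period `repeat_bp` (147 bp wrap + `repeat_bp - 147` linker); the last
#' linker absorbs the remainder so that bp are conserved exactly. Each
#' record's frame puts the NCP axis (`e3`) along the local fiber tangent and
#' rotates the reference azimuth about it in a solenoidal arrangement
#' (default 6 nucleosomes per turn).
#'
#' @param fiber A [build_fiber_path()] result.
#' @param positions Optional explicit 0-based start positions (sorted,
#'   non-overlapping, each `+147` within the chromosome).
#' @param repeat_bp Nucleosome repeat length in bp (default 200; >= 147).
#' @param superhelix [superhelix_params()] (supplies `wrap_bp`).
#' @param nucleosomes_per_turn Solenoid density (default 6).
#' @return A `nucleosome_set` tibble: `record` (1-based), `start` (0-based
#'   bp), `wrap_bp`, `linker_bp_after`, and frame columns `x..e3z`.
#' @export
place_nucleosomes <- function(fiber, positions = NULL, repeat_bp = 200,
                              superhelix = superhelix_params(),
                              nucleosomes_per_turn = 6) {
  chrom_length_bp <- attr(fiber, "chrom_length_bp")
  wrap <- superhelix$wrap_bp
  if (is.null(positions)) {
    check_count(repeat_bp, "repeat_bp", wrap)
    starts <- seq(0, chrom_length_bp - wrap, by = repeat_bp)
  } else {
    if (any(positions != round(positions)) || any(positions < 0)) {
      abort_argument("explicit `positions` must be non-negative integers")
    }
    if (is.unsorted(positions, strictly = TRUE)) {
      abort_validation("explicit `positions` must be strictly sorted")
    }
    ends <- positions + wrap
    if (any(ends > chrom_length_bp)) {
      bad <- positions[ends > chrom_length_bp]
      abort_validation(paste0(
        "positions extend past the chromosome end: ",
        paste(bad, collapse = ", ")
      ))
    }
    overlap <- which(utils::head(ends, -1) > positions[-1])
    if (length(overlap) > 0L) {
      abort_validation(paste0(
        "overlapping nucleosome positions: ",
        paste(sprintf("%d+%d > %d", positions[overlap], wrap,
                      positions[overlap + 1L]), collapse = "; ")
      ))
    }
    starts <- as.numeric(positions)
  }
  n <- length(starts)
  if (n == 0L) abort_argument("no nucleosomes fit in the chromosome")
  linker <- c(diff(starts) - wrap, chrom_length_bp - (starts[n] + wrap))

  mid <- starts + wrap / 2
  origins <- polyline_at_bp(fiber, mid)
  # local fiber tangent at each midpoint
  seg <- pmin(pmax(findInterval(mid, fiber$bp), 1L), nrow(fiber) - 1L)
  tv <- cbind(
    fiber$x[seg + 1L] - fiber$x[seg],
    fiber$y[seg + 1L] - fiber$y[seg],
    fiber$z[seg + 1L] - fiber$z[seg]
  )
  tn <- sqrt(rowSums(tv^2))
  tn[tn == 0] <- 1
  t3 <- tv / tn
  # stable perpendicular reference, then solenoid rotation about the tangent
  refz <- abs(t3[, 3L]) < 0.9
  a <- cbind(
    ifelse(refz, 0, 1), 0, ifelse(refz, 1, 0)
  )
  e1 <- cbind(
    a[, 2L] * t3[, 3L] - a[, 3L] * t3[, 2L],
    a[, 3L] * t3[, 1L] - a[, 1L] * t3[, 3L],
    a[, 1L] * t3[, 2L] - a[, 2L] * t3[, 1L]
  )
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(
    t3[, 2L] * e1[, 3L] - t3[, 3L] * e1[, 2L],
    t3[, 3L] * e1[, 1L] - t3[, 1L] * e1[, 3L],
    t3[, 1L] * e1[, 2L] - t3[, 2L] * e1[, 1L]
  )
  ang <- (seq_len(n) - 1L) * 2 * pi / nucleosomes_per_turn
  ca <- cos(ang); sa <- sin(ang)
  e1r <- e1 * ca + e2 * sa
  e2r <- e2 * ca - e1 * sa
  out <- dplyr::bind_cols(
    tibble(
      record = seq_len(n), start = starts,
      wrap_bp = as.integer(wrap), linker_bp_after = as.numeric(linker)
    ),
    mats_to_frames(origins, cbind(e1r, e2r, t3))
  )
  structure(
    out,
    chrom_length_bp = chrom_length_bp,
    superhelix = superhelix,
    nucleosomes_per_turn = nucleosomes_per_turn,
    class = c("nucleosome_set", class(out))
  )
}
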