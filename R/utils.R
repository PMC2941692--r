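# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
NULL

abort_argument <- function(msg, ...) {
  abort(msg, class = c("chromo3d_error_argument", "chromo3d_error"), ...)
}

abort_range <- function(msg, ...) {
  abort(msg, class = c("chromo3d_error_range", "chromo3d_error"), ...)
}

abort_io <- function(msg, ...) {
  abort(msg, class = c("chromo3d_error_io", "chromo3d_error"), ...)
}

abort_format <- function(msg, ...) {
  abort(msg, class = c("chromo3d_error_format", "chromo3d_error"), ...)
}

abort_validation <- function(msg, ...) {
  abort(msg, class = c("chromo3d_error_validation", "chromo3d_error"), ...)
}

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_argument(sprintf("`%s` must be a single finite number", name))
  }
  if (strict && x <= lower) {
    abort_argument(sprintf("`%s` must be > %s", name, format(lower)))
  }
  if (!strict && x < lower) {
    abort_argument(sprintf("`%s` must be >= %s", name, format(lower)))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  check_number(x, name, lower = lower)
  if (x != round(x)) {
    abort_argument(sprintf("`%s` must be an integer", name))
  }
  invisible(as.numeric(x))
}

# Run code with a temporary RNG state seeded by `seed`, restoring the caller's
# stream afterwards so model building never perturbs user RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

vec_norm <- function(v) sqrt(sum(v * v))

normalize <- function(v) {
  n <- vec_norm(v)
  if (n == 0) abort_argument("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(
    a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L]
  )
}

# Rotation matrix (3x3, columns e1,e2,e3) <-> unit quaternion (w,x,y,z).
rot_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / vec_norm(q)
}

quat_to_rot <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L)
}

# Spherical linear interpolation between two unit quaternions at fractions t
# (vectorized over t); returns a length(t) list of quaternions.
quat_slerp <- function(qa, qb, t) {
  d <- sum(qa * qb)
  if (d < 0) { qb <- -qb; d <- -d }
  if (d > 1 - 1e-10) {
    lapply(t, function(ti) {
      q <- (1 - ti) * qa + ti * qb
      q / vec_norm(q)
    })
  } else {
    th <- acos(min(d, 1))
    s <- sin(th)
    lapply(t, function(ti) {
      (sin((1 - ti) * th) * qa + sin(ti * th) * qb) / s
    })
  }
}
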