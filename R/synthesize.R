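# On-demand DNA-scale synthesis: per-bp frames and atoms for a genomic
# range. Nothing at this scale is ever stored; coordinates are a pure
# function of (model, range, template), so chunked queries concatenate to
# identical results.

# Axes (n x 9) for frames Ra composed with a relative rotation about unit
# axis `u` (in Ra's local coordinates) by angles `ang` (vectorized).
compose_rotation <- function(Ra, u, ang) {
  ca <- cos(ang); sa <- sin(ang); vc <- 1 - ca
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  # relative rotation columns (local coords), each length(ang)
  r11 <- ca + ux^2 * vc;      r21 <- uy * ux * vc + uz * sa
  r31 <- uz * ux * vc - uy * sa
  r12 <- ux * uy * vc - uz * sa; r22 <- ca + uy^2 * vc
  r32 <- uz * uy * vc + ux * sa
  r13 <- ux * uz * vc + uy * sa; r23 <- uy * uz * vc - ux * sa
  r33 <- ca + uz^2 * vc
  glob <- function(c1, c2, c3) {
    cbind(
      c1 * Ra[1L, 1L] + c2 * Ra[1L, 2L] + c3 * Ra[1L, 3L],
      c1 * Ra[2L, 1L] + c2 * Ra[2L, 2L] + c3 * Ra[2L, 3L],
      c1 * Ra[3L, 1L] + c2 * Ra[3L, 2L] + c3 * Ra[3L, 3L]
    )
  }
  cbind(glob(r11, r21, r31), glob(r12, r22, r32), glob(r13, r23, r33))
}

# Twist frames (axes n x 9 about their own e3) by angles `ang`.
twist_axes <- function(axes, ang) {
  ca <- cos(ang); sa <- sin(ang)
  e1 <- axes[, 1:3, drop = FALSE]
  e2 <- axes[, 4:6, drop = FALSE]
  cbind(e1 * ca + e2 * sa, e2 * ca - e1 * sa, axes[, 7:9, drop = FALSE])
}

# Straight B-DNA from an endpoint frame: offsets is a vector of signed bp
# steps relative to the endpoint (negative = upstream).
straight_from <- function(endpoint_origin, endpoint_axes, offsets, helix) {
  e3 <- endpoint_axes[7:9]
  origins <- cbind(
    endpoint_origin[1L] + offsets * helix$rise_nm * e3[1L],
    endpoint_origin[2L] + offsets * helix$rise_nm * e3[2L],
    endpoint_origin[3L] + offsets * helix$rise_nm * e3[3L]
  )
  sgn <- if (helix$handedness == "right") 1 else -1
  axes <- twist_axes(
    matrix(endpoint_axes, nrow = length(offsets), ncol = 9L, byrow = TRUE),
    sgn * offsets * 2 * pi / helix$bp_per_turn
  )
  list(origins = origins, axes = axes)
}

# Blended linker between exit frame A and entry frame B: interior bp j in
# `js` (1..g), fractions t = j/(g+1); origins linearly interpolated,
# orientations spherically interpolated.
linker_frames <- function(A, B, g, js) {
  t <- js / (g + 1)
  origins <- cbind(
    A$origin[1L] + t * (B$origin[1L] - A$origin[1L]),
    A$origin[2L] + t * (B$origin[2L] - A$origin[2L]),
    A$origin[3L] + t * (B$origin[3L] - A$origin[3L])
  )
  q <- rot_to_quat(t(A$R) %*% B$R)
  vn <- vec_norm(q[2:4])
  if (vn < 1e-12) {
    axes <- matrix(as.numeric(A$R), nrow = length(js), ncol = 9L,
                   byrow = TRUE)
  } else {
    theta <- 2 * atan2(vn, q[1L])
    u <- q[2:4] / vn
    axes <- compose_rotation(A$R, u, t * theta)
  }
  list(origins = origins, axes = axes)
}

row_to_mat <- function(origins, axes, i) {
  list(origin = origins[i, ], R = matrix(axes[i, ], nrow = 3L))
}

#' Synthesize per-bp DNA frames for a genomic range
#'
#' Base pairs inside a nucleosome wrap follow the superhelical path around
#' that record's frame (centered so the 147-bp centroid coincides with the
#' stored origin); linker bp follow a straight blend between the flanking
#' wrap endpoints with spherically interpolated orientation; bp before the
#' first / after the last nucleosome extend as straight B-DNA. The result
#' depends only on `(model, range)`.
#'
#' @param model A `genome_model`.
#' @param range A [genomic_range()].
#' @return A frame tibble with a 0-based `bp` column covering
#'   `[start, end)` in order.
#' @export
synthesize_frames <- function(model, range) {
  check_range(model, range)
  ch <- model$chromosomes[[range$chrom]]
  recs <- ch$nucleosomes
  pars <- model$manifest$params
  helix <- pars$helix
  sh <- pars$superhelix
  L <- attr(recs, "chrom_length_bp") %||%
    model$manifest$chromosomes$length[
      model$manifest$chromosomes$chrom == range$chrom
    ]
  S <- recs$start
  w <- recs$wrap_bp[1L]
  n <- nrow(recs)

  # segment table covering [0, L)
  segs <- dplyr::bind_rows(
    if (S[1L] > 0) tibble(type = "lead", k = 0L, s = 0, e = S[1L]),
    tibble(type = "wrap", k = seq_len(n), s = S, e = S + w),
    if (n > 1L) tibble(type = "linker", k = seq_len(n - 1L),
                       s = S[-n] + w, e = S[-1L]),
    if (S[n] + w < L) tibble(type = "tail", k = n, s = S[n] + w, e = L)
  )
  segs <- segs[segs$e > range$start & segs$s < range$end, , drop = FALSE]
  segs <- segs[segs$e > segs$s, , drop = FALSE]
  segs <- segs[order(segs$s), , drop = FALSE]
  seg_type <- segs$type
  seg_k <- segs$k
  seg_s <- segs$s
  seg_e <- segs$e

  # canonical centroid-centered wrap in record-local coordinates, shared by
  # all records; per-record wraps are affine transforms of it
  loc <- superhelix_local(sh, helix, center = "centroid")
  rec_o <- as.matrix(recs[c("x", "y", "z")])
  rec_R <- as.matrix(recs[frame_axis_cols])  # rows: e1,e2,e3 components

  wrap_cache <- vector("list", n)
  get_wrap <- function(k) {
    if (!is.null(wrap_cache[[k]])) return(wrap_cache[[k]])
    R <- matrix(rec_R[k, ], nrow = 3L)  # columns e1, e2, e3
    origins <- loc$origins %*% t(R)
    origins[, 1L] <- origins[, 1L] + rec_o[k, 1L]
    origins[, 2L] <- origins[, 2L] + rec_o[k, 2L]
    origins[, 3L] <- origins[, 3L] + rec_o[k, 3L]
    axes <- cbind(
      loc$axes[, 1:3] %*% t(R),
      loc$axes[, 4:6] %*% t(R),
      loc$axes[, 7:9] %*% t(R)
    )
    val <- list(origins = origins, axes = axes)
    wrap_cache[[k]] <<- val
    val
  }

  nseg <- length(seg_type)
  po <- vector("list", nseg)
  pa <- vector("list", nseg)
  pb <- vector("list", nseg)
  for (i in seq_len(nseg)) {
    lo <- max(seg_s[i], range$start)
    hi <- min(seg_e[i], range$end)
    bps <- seq(lo, hi - 1)
    k <- seg_k[i]
    if (seg_type[i] == "wrap") {
      wfk <- get_wrap(k)
      idx <- bps - S[k] + 1
      origins <- wfk$origins[idx, , drop = FALSE]
      axes <- wfk$axes[idx, , drop = FALSE]
    } else if (seg_type[i] == "linker") {
      Aw <- get_wrap(k)
      A <- row_to_mat(Aw$origins, Aw$axes, w)
      Bw <- get_wrap(k + 1L)
      B <- row_to_mat(Bw$origins, Bw$axes, 1L)
      lf <- linker_frames(A, B, g = seg_e[i] - seg_s[i],
                          js = bps - seg_s[i] + 1)
      origins <- lf$origins
      axes <- lf$axes
    } else if (seg_type[i] == "lead") {
      Bw <- get_wrap(1L)
      B <- row_to_mat(Bw$origins, Bw$axes, 1L)
      sf <- straight_from(B$origin, as.numeric(B$R), bps - S[1L], helix)
      origins <- sf$origins
      axes <- sf$axes
    } else {  # tail
      Aw <- get_wrap(k)
      A <- row_to_mat(Aw$origins, Aw$axes, w)
      sf <- straight_from(A$origin, as.numeric(A$R),
                          bps - (S[k] + w - 1), helix)
      origins <- sf$origins
      axes <- sf$axes
    }
    po[[i]] <- origins
    pa[[i]] <- axes
    pb[[i]] <- bps
  }
  mats_to_frames(do.call(rbind, po), do.call(rbind, pa),
                 bp = unlist(pb))
}

#' Synthesize atomic DNA coordinates for a genomic range
#'
#' Computes per-bp frames with [synthesize_frames()] and expands them
#' through the per-bp pseudo-atom template. Atomic coordinates are computed
#' on demand and never stored.
#'
#' @inheritParams synthesize_frames
#' @param template Per-bp atom template (default [atom_template()], 20
#'   pseudo-atoms per bp).
#' @param bases Optional base sequence for the range (one character per bp).
#' @return An atom tibble (see [place_atoms()]); `bp_index` is the genomic
#'   bp coordinate.
#' @examples
#' g <- synth_genome(lengths = 4000, seed = 1)
#' m <- build_genome_model(g, seed = 1)
#' a <- synthesize_dna(m, genomic_range("chr1", 0, 100))
#' nrow(a)  # 2000
#' @export
synthesize_dna <- function(model, range, template = atom_template(),
                           bases = NULL) {
  frames <- synthesize_frames(model, range)
  place_atoms(frames, template = template, bases = bases)
}
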