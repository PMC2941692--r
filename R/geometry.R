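# Pure geometry: local orthonormal frames, B-DNA helical frame propagation,
# nucleosome superhelical wrapping, atom placement and rotational phasing.
#
# A "frame" is one row of a tibble with columns
#   x, y, z           origin (nm)
#   e1x..e1z, e2x..e2z, e3x..e3z   right-handed orthonormal triad
# e3 is the local helix axis / path tangent; e1 points at the reference
# (major-groove) azimuth from which rotational phase is measured.

frame_axis_cols <- c(
  "e1x", "e1y", "e1z",
  "e2x", "e2y", "e2z",
  "e3x", "e3y", "e3z"
)
frame_cols <- c("x", "y", "z", frame_axis_cols)

#' Construct a local coordinate frame
#'
#' A frame is the geometric currency passed between scales of the model: an
#' origin in nm plus a right-handed orthonormal triad `e1`, `e2`, `e3`.
#'
#' @param origin Numeric length-3 origin in nm.
#' @param e1,e2,e3 Numeric length-3 axis vectors. They are checked for unit
#'   length, orthogonality and right-handedness (determinant +1) to 1e-9.
#' @return A one-row tibble with columns `x, y, z, e1x..e3z`.
#' @examples
#' frame()                      # identity frame at the origin
#' frame(origin = c(1, 2, 3))
#' @export
frame <- function(origin = c(0, 0, 0),
                  e1 = c(1, 0, 0), e2 = c(0, 1, 0), e3 = c(0, 0, 1)) {
  f <- tibble(
    x = origin[1L], y = origin[2L], z = origin[3L],
    e1x = e1[1L], e1y = e1[2L], e1z = e1[3L],
    e2x = e2[1L], e2y = e2[2L], e2z = e2[3L],
    e3x = e3[1L], e3y = e3[2L], e3z = e3[3L]
  )
  validate_frames(f)
  f
}

#' Validate frame orthonormality and handedness
#'
#' Checks, for every row, that the triad is orthonormal to `tol` and that
#' `det[e1 e2 e3] = +1` (right-handed).
#'
#' @param frames A tibble with frame columns.
#' @param tol Numeric tolerance (default 1e-9).
#' @return `frames`, invisibly. Errors on the first violation.
#' @export
validate_frames <- function(frames, tol = 1e-9) {
  missing_cols <- setdiff(frame_cols, names(frames))
  if (length(missing_cols) > 0L) {
    abort_argument(paste0(
      "frame tibble is missing columns: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  m <- as.matrix(frames[frame_axis_cols])
  e1 <- m[, 1:3, drop = FALSE]
  e2 <- m[, 4:6, drop = FALSE]
  e3 <- m[, 7:9, drop = FALSE]
  nrm <- cbind(rowSums(e1^2), rowSums(e2^2), rowSums(e3^2))
  if (any(abs(nrm - 1) > 2 * tol)) {
    abort_validation("frame axes are not unit length")
  }
  dots <- cbind(
    rowSums(e1 * e2), rowSums(e1 * e3), rowSums(e2 * e3)
  )
  if (any(abs(dots) > tol)) {
    abort_validation("frame axes are not orthogonal")
  }
  # det[e1 e2 e3] = e1 . (e2 x e3)
  cx <- cbind(
    e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2],
    e2[, 3] * e3[, 1] - e2[, 1] * e3[, 3],
    e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1]
  )
  det <- rowSums(e1 * cx)
  if (any(abs(det - 1) > 10 * tol)) {
    abort_validation("frame triad is not right-handed (det != +1)")
  }
  invisible(frames)
}

# Internal: one frame row -> list(origin, R) with R columns e1,e2,e3.
frame_to_mat <- function(frames, i = 1L) {
  r <- as.numeric(frames[i, frame_cols])
  list(
    origin = r[1:3],
    R = matrix(r[4:12], nrow = 3L)
  )
}

# Internal: origins (n x 3) + rotation arrays (n x 9, columns of e1,e2,e3)
# -> frame tibble.
mats_to_frames <- function(origins, axes, bp = NULL) {
  out <- as_tibble(as.data.frame(cbind(origins, axes)))
  names(out) <- frame_cols
  if (!is.null(bp)) out <- dplyr::bind_cols(tibble(bp = bp), out)
  out
}

#' B-DNA helical step parameters
#'
#' Canonical solution-state B-DNA values: 0.34 nm rise per bp and 10.5 bp per
#' helical turn, right-handed.
#'
#' @param rise_nm Rise per bp step in nm (> 0).
#' @param bp_per_turn Base pairs per full helical turn (> 0).
#' @param handedness `"right"` or `"left"`.
#' @return A `helix_params` list.
#' @export
helix_params <- function(rise_nm = 0.34, bp_per_turn = 10.5,
                         handedness = c("right", "left")) {
  check_number(rise_nm, "rise_nm", 0, strict = TRUE)
  check_number(bp_per_turn, "bp_per_turn", 0, strict = TRUE)
  handedness <- match.arg(handedness)
  structure(
    list(rise_nm = rise_nm, bp_per_turn = bp_per_turn,
         handedness = handedness),
    class = "helix_params"
  )
}

#' Nucleosome superhelix parameters
#'
#' Canonical nucleosome core particle values: 147 bp wrapped in 1.65
#' left-handed superhelical turns of radius 4.18 nm and pitch 2.39 nm.
#'
#' @param radius_nm Superhelix radius in nm (> 0).
#' @param pitch_nm Axial advance per superhelical turn in nm.
#' @param turns Number of superhelical turns (> 0).
#' @param wrap_bp Wrapped bp count (integer >= 2).
#' @param handedness `"left"` or `"right"`.
#' @return A `superhelix_params` list.
#' @export
superhelix_params <- function(radius_nm = 4.18, pitch_nm = 2.39,
                              turns = 1.65, wrap_bp = 147L,
                              handedness = c("left", "right")) {
  check_number(radius_nm, "radius_nm", 0, strict = TRUE)
  check_number(pitch_nm, "pitch_nm", 0)
  check_number(turns, "turns", 0, strict = TRUE)
  check_count(wrap_bp, "wrap_bp", 2)
  handedness <- match.arg(handedness)
  structure(
    list(radius_nm = radius_nm, pitch_nm = pitch_nm, turns = turns,
         wrap_bp = as.integer(wrap_bp), handedness = handedness),
    class = "superhelix_params"
  )
}

#' Propagate B-DNA frames along a straight helical axis
#'
#' Generates one frame per bp along `start`'s `e3` axis: origins advance by
#' `rise_nm` per step and the (`e1`, `e2`) pair twists by 360/`bp_per_turn`
#' degrees per bp.
#'
#' @param n_bp Number of bp (>= 1).
#' @param start Starting frame (one-row frame tibble). Frame 0 of the output
#'   equals `start`.
#' @param params A [helix_params()] object.
#' @return A tibble of `n_bp` frames with a 0-based `bp` column.
#' @examples
#' f <- propagate_bdna_frames(10, frame())
#' @export
propagate_bdna_frames <- function(n_bp, start = frame(),
                                  params = helix_params()) {
  check_count(n_bp, "n_bp", 1)
  validate_frames(start)
  fm <- frame_to_mat(start)
  i <- seq_len(n_bp) - 1
  sgn <- if (params$handedness == "right") 1 else -1
  ang <- sgn * i * 2 * pi / params$bp_per_turn
  e1 <- fm$R[, 1L]; e2 <- fm$R[, 2L]; e3 <- fm$R[, 3L]
  origins <- cbind(
    fm$origin[1L] + i * params$rise_nm * e3[1L],
    fm$origin[2L] + i * params$rise_nm * e3[2L],
    fm$origin[3L] + i * params$rise_nm * e3[3L]
  )
  ca <- cos(ang); sa <- sin(ang)
  # rotation of e1/e2 about e3 (e2 = e3 x e1)
  e1r <- cbind(ca * e1[1L] + sa * e2[1L],
               ca * e1[2L] + sa * e2[2L],
               ca * e1[3L] + sa * e2[3L])
  e2r <- cbind(ca * e2[1L] - sa * e1[1L],
               ca * e2[2L] - sa * e1[2L],
               ca * e2[3L] - sa * e1[3L])
  e3r <- matrix(e3, nrow = n_bp, ncol = 3L, byrow = TRUE)
  mats_to_frames(origins, cbind(e1r, e2r, e3r), bp = as.integer(i))
}

# Internal: superhelix frames in the anchor's local coordinates (anchor =
# identity frame at the origin, axis = +z). Returns list(origins, axes),
# n x 3 and n x 9.
superhelix_local <- function(params, helix, center) {
  n <- params$wrap_bp
  i <- seq_len(n) - 1
  sweep <- params$turns * 2 * pi
  sgn <- if (params$handedness == "left") -1 else 1
  phi <- sgn * i * sweep / (n - 1)
  zext <- params$turns * params$pitch_nm
  zz <- i * zext / (n - 1) - zext / 2
  r <- params$radius_nm
  origins <- cbind(r * cos(phi), r * sin(phi), zz)
  # path tangent d/di, normalized
  dphi <- sgn * sweep / (n - 1)
  dz <- zext / (n - 1)
  tx <- -r * sin(phi) * dphi
  ty <- r * cos(phi) * dphi
  tz <- rep(dz, n)
  tn <- sqrt(tx^2 + ty^2 + tz^2)
  t3 <- cbind(tx / tn, ty / tn, tz / tn)
  # radial outward direction, projected perpendicular to the tangent
  ux <- cos(phi); uy <- sin(phi); uz <- rep(0, n)
  dot <- ux * t3[, 1] + uy * t3[, 2] + uz * t3[, 3]
  f1 <- cbind(ux - dot * t3[, 1], uy - dot * t3[, 2], uz - dot * t3[, 3])
  f1 <- f1 / sqrt(rowSums(f1^2))
  f2 <- cbind(
    t3[, 2] * f1[, 3] - t3[, 3] * f1[, 2],
    t3[, 3] * f1[, 1] - t3[, 1] * f1[, 3],
    t3[, 1] * f1[, 2] - t3[, 2] * f1[, 1]
  )
  # helical twist about the path tangent
  tsgn <- if (helix$handedness == "right") 1 else -1
  tau <- tsgn * i * 2 * pi / helix$bp_per_turn
  ct <- cos(tau); st <- sin(tau)
  g1 <- f1 * ct + f2 * st
  g2 <- f2 * ct - f1 * st
  if (center == "centroid") {
    origins <- sweep(origins, 2L, colMeans(origins))
  }
  list(origins = origins, axes = cbind(g1, g2, t3))
}

#' Wrap DNA frames onto the nucleosome superhelix
#'
#' Places `wrap_bp` frames on the left-handed superhelical path that DNA
#' follows around a nucleosome core particle. The anchor frame's `e3` is the
#' NCP cylinder axis; bp are uniformly spaced in arc length, sweep
#' `turns * 360` degrees in total and span `turns * pitch_nm` axially. Each
#' frame's `e3` is the local path tangent and carries a helical twist of
#' 360/`bp_per_turn` degrees per bp.
#'
#' @param params A [superhelix_params()] object.
#' @param anchor Anchor frame; its origin is the NCP center.
#' @param helix [helix_params()] supplying the twist rate.
#' @param center `"axis"` (anchor origin on the cylinder axis, the default)
#'   or `"centroid"` (path translated so the mean bp origin coincides with
#'   the anchor origin, which is what on-demand DNA synthesis uses so that
#'   stored record origins equal bp centroids).
#' @return A tibble of `wrap_bp` frames with a 0-based `bp` column.
#' @examples
#' w <- wrap_superhelix()
#' nrow(w)  # 147
#' @export
wrap_superhelix <- function(params = superhelix_params(), anchor = frame(),
                            helix = helix_params(),
                            center = c("axis", "centroid")) {
  if (!inherits(params, "superhelix_params")) {
    params <- do.call(superhelix_params, params)
  }
  center <- match.arg(center)
  validate_frames(anchor)
  loc <- superhelix_local(params, helix, center)
  fm <- frame_to_mat(anchor)
  origins <- loc$origins %*% t(fm$R)
  origins <- sweep(origins, 2L, fm$origin, "+")
  axes <- cbind(
    loc$axes[, 1:3] %*% t(fm$R),
    loc$axes[, 4:6] %*% t(fm$R),
    loc$axes[, 7:9] %*% t(fm$R)
  )
  mats_to_frames(origins, axes, bp = seq_len(params$wrap_bp) - 1L)
}

#' Default per-bp pseudo-atom template
#'
#' A reduced representation of one bp: 10 pseudo-atoms per strand (20 total),
#' tracing phosphate, sugar-ring and base positions on the Watson (`W`) and
#' Crick (`C`) strands. Offsets are expressed in the bp local frame, in nm,
#' with the two backbones at canonical B-DNA radius and groove asymmetry.
#' The template is plain data and fully user-replaceable.
#'
#' @return A tibble with columns `name`, `element`, `ox`, `oy`, `oz`,
#'   `strand` (20 rows).
#' @export
atom_template <- function() {
  # radial stations from backbone (0.94 nm) in toward the helix axis
  names10 <- c("P", "OP1", "O5'", "C5'", "C4'", "C3'", "C1'", "N1", "C2", "C4")
  elem10 <- c("P", "O", "O", "C", "C", "C", "C", "N", "C", "C")
  radii <- c(0.94, 0.90, 0.84, 0.78, 0.72, 0.66, 0.55, 0.40, 0.28, 0.15)
  build_strand <- function(strand) {
    # strand azimuths straddle the minor groove: +/- 77 degrees from e1
    az <- if (strand == "W") 77 else -77
    a <- az * pi / 180
    tibble(
      name = names10,
      element = elem10,
      ox = radii * cos(a),
      oy = radii * sin(a),
      oz = 0,
      strand = strand
    )
  }
  w <- build_strand("W")
  c_ <- build_strand("C")
  dplyr::bind_rows(w, c_)
}

#' Place template atoms into a list of bp frames
#'
#' Expands each bp frame into the template's pseudo-atoms: each atom position
#' is `origin + ox*e1 + oy*e2 + oz*e3` of its frame. Output order is
#' bp-major, template-order minor.
#'
#' @param frames Frame tibble (one row per bp). A `bp` column, if present,
#'   is carried through as `bp_index`; otherwise 0-based row order is used.
#' @param template An atom template tibble (see [atom_template()]).
#' @param bases Optional character vector / string of bases, one per frame;
#'   `NULL` labels every bp `N`.
#' @return A tibble of atoms: `serial`, `name`, `element`, `x`, `y`, `z`
#'   (nm), `bp_index`, `strand`, `base`.
#' @examples
#' a <- place_atoms(propagate_bdna_frames(3, frame()))
#' nrow(a)  # 60
#' @export
place_atoms <- function(frames, template = atom_template(), bases = NULL) {
  if (nrow(frames) == 0L) {
    return(tibble(
      serial = integer(), name = character(), element = character(),
      x = numeric(), y = numeric(), z = numeric(),
      bp_index = integer(), strand = character(), base = character()
    ))
  }
  validate_frames(frames)
  if (!is.null(bases)) {
    if (length(bases) == 1L && nchar(bases[1L]) > 1L) {
      bases <- strsplit(bases, "")[[1L]]
    }
    if (length(bases) != nrow(frames)) {
      abort_argument(sprintf(
        "`bases` has %d entries for %d frames", length(bases), nrow(frames)
      ))
    }
  } else {
    bases <- rep("N", nrow(frames))
  }
  bp_index <- if ("bp" %in% names(frames)) {
    as.integer(frames$bp)
  } else {
    seq_len(nrow(frames)) - 1L
  }
  nf <- nrow(frames)
  nt <- nrow(template)
  m <- as.matrix(frames[frame_cols])
  off <- as.matrix(template[c("ox", "oy", "oz")])
  # positions: for each frame i, origin_i + R_i %*% off_j for all template j
  idx_f <- rep(seq_len(nf), each = nt)
  idx_t <- rep(seq_len(nt), times = nf)
  ox <- off[idx_t, 1L]; oy <- off[idx_t, 2L]; oz <- off[idx_t, 3L]
  px <- m[idx_f, "x"] + ox * m[idx_f, "e1x"] + oy * m[idx_f, "e2x"] +
    oz * m[idx_f, "e3x"]
  py <- m[idx_f, "y"] + ox * m[idx_f, "e1y"] + oy * m[idx_f, "e2y"] +
    oz * m[idx_f, "e3y"]
  pz <- m[idx_f, "z"] + ox * m[idx_f, "e1z"] + oy * m[idx_f, "e2z"] +
    oz * m[idx_f, "e3z"]
  tibble(
    serial = seq_len(nf * nt),
    name = template$name[idx_t],
    element = template$element[idx_t],
    x = as.numeric(px), y = as.numeric(py), z = as.numeric(pz),
    bp_index = bp_index[idx_f],
    strand = template$strand[idx_t],
    base = bases[idx_f]
  )
}

#' Rotational phase angle of a bp offset
#'
#' The angular position of a bp around the DNA double helix relative to
#' position 0 (e.g. the first wrapped bp of a nucleosome), in degrees:
#' `(bp_offset * 360 / bp_per_turn) mod 360`. This is the quantity that
#' determines which face of the helix a SNP presents to the histone surface.
#'
#' @param bp_offset Integer bp offset(s) >= 0.
#' @param params A [helix_params()] object.
#' @return Angle(s) in degrees, in `[0, 360)`.
#' @examples
#' phase_angle(5)  # 171.43 degrees for 10.5 bp/turn
#' @export
phase_angle <- function(bp_offset, params = helix_params()) {
  if (any(!is.finite(bp_offset)) || any(bp_offset < 0) ||
      any(bp_offset != round(bp_offset))) {
    abort_argument("`bp_offset` must be non-negative integers")
  }
  (bp_offset * 360 / params$bp_per_turn) %% 360
}

#' Arc length of the superhelical wrap path
#'
#' Closed form: `turns * sqrt((2 * pi * radius)^2 + pitch^2)`.
#'
#' @param params A [superhelix_params()] object.
#' @return Arc length in nm.
#' @export
superhelix_arc_length <- function(params = superhelix_params()) {
  params$turns * sqrt((2 * pi * params$radius_nm)^2 + params$pitch_nm^2)
}
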