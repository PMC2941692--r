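# Export of atomic selections to fixed-column PDB, scenes to PovRay SDL,
# and atoms to plain XYZ. Internal lengths are nm; PDB and XYZ convert to
# Angstrom (x10).

PDB_MAX_ATOMS <- 99999L

#' Write atoms as a fixed-column PDB file
#'
#' Emits v3.3-style `ATOM` records: serial in columns 7-11, atom name
#' 13-16, residue name `DN` 18-20, chain `A`, residue number 23-26 (the
#' genomic bp index + 1, wrapped at 9999), coordinates in Angstrom (nm x
#' 10) as 8.3 fixed decimals in columns 31-54, element symbol 77-78;
#' terminated by `END`. Serials are capped at 99999 with a hard error (no
#' silent wrapping): subdivide the region instead.
#'
#' @param atoms An atom tibble from [place_atoms()] / [synthesize_dna()].
#' @param path Output file path or connection.
#' @param center Translate the selection to its centroid before writing
#'   (default `TRUE`): model coordinates live in nuclear space (thousands
#'   of nm), which would overflow PDB's fixed 8.3 coordinate columns.
#' @return The number of ATOM records written, invisibly.
#' @export
write_pdb <- function(atoms, path, center = TRUE) {
  n <- nrow(atoms)
  if (n > PDB_MAX_ATOMS) {
    abort_argument(sprintf(
      paste0("%d atoms exceed the PDB serial limit of %d; ",
             "subdivide the region into smaller selections"),
      n, PDB_MAX_ATOMS
    ))
  }
  xyz <- cbind(atoms$x, atoms$y, atoms$z) * 10  # nm -> Angstrom
  if (center && n > 0L) xyz <- sweep(xyz, 2L, colMeans(xyz))
  if (n > 0L && any(abs(xyz) > 9999.999)) {
    abort_argument(paste0(
      "coordinates overflow the fixed 8.3 PDB columns (|x| > 9999.999 A);",
      " subdivide the region or keep `center = TRUE`"
    ))
  }
  chain <- "A"
  resseq <- (atoms$bp_index %% 9999L) + 1L
  name4 <- sprintf("%-4s", substr(atoms$name, 1L, 4L))
  lines <- sprintf(
    "ATOM  %5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(n), name4, "DN", chain, resseq,
    xyz[, 1L], xyz[, 2L], xyz[, 3L], 1, 0,
    sprintf("%2s", substr(atoms$element, 1L, 2L))
  )
  writeLines(c(lines, "END"), path)
  invisible(n)
}

#' Write atoms as a plain XYZ file
#'
#' Standard XYZ: atom count, comment line, then `element x y z` in
#' Angstrom.
#'
#' @inheritParams write_pdb
#' @param comment Comment line content.
#' @return The number of atom lines written, invisibly.
#' @export
write_xyz <- function(atoms, path, comment = "chromo3d atomic selection") {
  lines <- c(
    sprintf("%d", nrow(atoms)),
    comment,
    sprintf("%s %.3f %.3f %.3f", atoms$element,
            atoms$x * 10, atoms$y * 10, atoms$z * 10)
  )
  writeLines(lines, path)
  invisible(nrow(atoms))
}

new_scene <- function(primitives, camera, lights) {
  structure(
    list(primitives = primitives, camera = camera, lights = lights),
    class = "scene"
  )
}

scene_primitive_row <- function(type, p1, p2 = c(NA, NA, NA), radius = 1,
                                color = c(0.5, 0.5, 0.5), points = NULL) {
  p1 <- unname(p1); p2 <- unname(p2); color <- unname(color)
  tibble(
    type = type,
    x1 = p1[1L], y1 = p1[2L], z1 = p1[3L],
    x2 = p2[1L], y2 = p2[2L], z2 = p2[3L],
    radius = radius,
    r = color[1L], g = color[2L], b = color[3L],
    points = list(points)
  )
}

validate_scene <- function(scene) {
  pr <- scene$primitives
  num <- as.matrix(pr[c("x1", "y1", "z1", "radius", "r", "g", "b")])
  if (any(!is.finite(num))) {
    abort_validation("scene contains non-finite coordinates or colors")
  }
  if (any(pr$radius <= 0)) {
    abort_validation("scene primitive radii must be > 0")
  }
  invisible(scene)
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %d primitives (%s)\n", nrow(x$primitives),
              paste(sprintf("%d %s", table(x$primitives$type),
                            names(table(x$primitives$type))),
                    collapse = ", ")))
  invisible(x)
}

pov_vec <- function(p) sprintf("<%.3f, %.3f, %.3f>", p[1L], p[2L], p[3L])

#' Write a scene as a PovRay scene-description file
#'
#' Emits camera, light sources and one object per primitive with `rgb`
#' pigments. Degenerate cylinders (coincident endpoints) are replaced by
#' spheres with a warning. The number of emitted objects equals the scene
#' primitive count.
#'
#' @param scene A scene from [scene_from_model()].
#' @param path Output file path.
#' @return The primitive count, invisibly.
#' @export
write_povray <- function(scene, path) {
  if (!inherits(scene, "scene")) abort_argument("`scene` must be a scene")
  if (nrow(scene$primitives) == 0L) {
    abort_argument("cannot export an empty scene")
  }
  validate_scene(scene)
  out <- c(
    "// chromo3d scene export",
    "#version 3.7;",
    'global_settings { assumed_gamma 1.0 }',
    "background { color rgb <1, 1, 1> }",
    sprintf("camera { location %s look_at %s }",
            pov_vec(scene$camera$position), pov_vec(scene$camera$look_at)),
    purrr::map_chr(scene$lights, function(l) {
      sprintf("light_source { %s color rgb <1, 1, 1> }", pov_vec(l))
    })
  )
  degenerate <- 0L
  body <- purrr::map_chr(seq_len(nrow(scene$primitives)), function(i) {
    p <- scene$primitives[i, ]
    pig <- sprintf("pigment { color rgb <%.3f, %.3f, %.3f> }",
                   p$r, p$g, p$b)
    if (p$type == "sphere") {
      sprintf("sphere { %s, %.3f %s }",
              pov_vec(c(p$x1, p$y1, p$z1)), p$radius, pig)
    } else if (p$type == "cylinder") {
      a <- c(p$x1, p$y1, p$z1); b <- c(p$x2, p$y2, p$z2)
      if (vec_norm(a - b) < 1e-9) {
        degenerate <<- degenerate + 1L
        sprintf("sphere { %s, %.3f %s }", pov_vec(a), p$radius, pig)
      } else {
        sprintf("cylinder { %s, %s, %.3f %s }",
                pov_vec(a), pov_vec(b), p$radius, pig)
      }
    } else if (p$type == "box") {
      sprintf("box { %s, %s %s }",
              pov_vec(c(p$x1, p$y1, p$z1)), pov_vec(c(p$x2, p$y2, p$z2)),
              pig)
    } else if (p$type == "polyline") {
      pts <- p$points[[1L]]
      sprintf("sphere_sweep { linear_spline %d, %s, %.3f %s }",
              nrow(pts),
              paste(sprintf("%s, ", apply(pts, 1L, pov_vec)),
                    collapse = ""),
              p$radius, pig)
    } else {
      abort_argument(sprintf("unknown primitive type '%s'", p$type))
    }
  })
  if (degenerate > 0L) {
    warn(sprintf("replaced %d degenerate cylinder(s) by spheres",
                 degenerate))
  }
  writeLines(c(out, body), path)
  invisible(nrow(scene$primitives))
}

default_camera <- function(pts) {
  ctr <- colMeans(pts)
  span <- max(apply(pts, 2L, function(v) diff(range(v))), 1)
  list(position = ctr + c(0, 0, 2.5 * span), look_at = ctr)
}

annotation_colors <- function(els, annotation, rule) {
  cols <- matrix(0.5, nrow = nrow(els), ncol = 3L)
  if (is.null(annotation)) {
    return(cols)
  }
  key_el <- paste(els$type, els$element)
  ann_type <- if ("type" %in% names(annotation)) annotation$type else
    rep(els$type[1L], nrow(annotation))
  key_ann <- paste(ann_type, annotation$element)
  rgb <- as.matrix(colorize(annotation$value, rule))
  idx <- match(key_el, key_ann)
  ok <- !is.na(idx)
  cols[ok, ] <- rgb[idx[ok], , drop = FALSE]
  cols
}

#' Build a renderable scene from a model range
#'
#' Nuclear and fiber scales render as a polyline through the path points
#' plus a sphere per point; the nucleosome scale renders one cylinder per
#' NCP (11 nm diameter, 5.5 nm height by default) with polyline linkers;
#' the DNA scale renders one sphere per synthesized atom. A projected
#' annotation colors elements via [colorize()]; optional TSS tables add
#' expression-colored spheres and binding-site tables add cubes colored
#' orange/yellow by the proximity rule.
#'
#' @param model A `genome_model`.
#' @param range A [genomic_range()].
#' @param scale `"nuclear"`, `"fiber"`, `"nucleosome"` or `"dna"`.
#' @param annotation Optional `scale_annotation` (from [project()]) at the
#'   same scale.
#' @param rule [color_rule()] used for annotation colors.
#' @param tss Optional TSS tibble with optional `value` column (signed
#'   expression) to draw as spheres.
#' @param sites Optional binding-site tibble, classified against `tss` by
#'   [proximity_classify()], drawn as cubes (orange near / yellow far).
#' @param ncp_diameter_nm,ncp_height_nm NCP cylinder display dimensions.
#' @param max_dna_bp Largest range allowed at DNA scale (default 100000).
#' @return A `scene` object.
#' @export
scene_from_model <- function(model, range,
                             scale = c("nuclear", "fiber", "nucleosome",
                                       "dna"),
                             annotation = NULL,
                             rule = color_rule("signed"),
                             tss = NULL, sites = NULL,
                             ncp_diameter_nm = 11, ncp_height_nm = 5.5,
                             max_dna_bp = 100000) {
  scale <- match.arg(scale)
  check_range(model, range)
  ch <- model$chromosomes[[range$chrom]]
  prim <- list()
  if (scale %in% c("nuclear", "fiber")) {
    path <- if (scale == "nuclear") ch$nuclear else ch$fiber
    sel <- path$bp >= range$start & path$bp <= range$end
    sub <- path[sel, , drop = FALSE]
    if (nrow(sub) == 0L) abort_range("range contains no path points")
    pts <- as.matrix(sub[c("x", "y", "z")])
    els <- tibble(element = sub$point, type = "point")
    cols <- annotation_colors(els, annotation, rule)
    radius <- if (scale == "nuclear") 30 else 15
    if (nrow(sub) > 1L) {
      prim <- c(prim, list(scene_primitive_row(
        "polyline", pts[1L, ], radius = radius / 3,
        color = c(0.7, 0.7, 0.7), points = pts
      )))
    }
    prim <- c(prim, purrr::map(seq_len(nrow(sub)), function(i) {
      scene_primitive_row("sphere", pts[i, ], radius = radius,
                          color = cols[i, ])
    }))
  } else if (scale == "nucleosome") {
    recs <- ch$nucleosomes
    sel <- recs$start + recs$wrap_bp > range$start & recs$start < range$end
    sub <- recs[sel, , drop = FALSE]
    if (nrow(sub) == 0L) abort_range("range contains no nucleosomes")
    els <- tibble(element = sub$record, type = "nucleosome")
    cols <- annotation_colors(els, annotation, rule)
    h2 <- ncp_height_nm / 2
    o <- as.matrix(sub[c("x", "y", "z")])
    e3 <- as.matrix(sub[c("e3x", "e3y", "e3z")])
    prim <- c(prim, purrr::map(seq_len(nrow(sub)), function(i) {
      scene_primitive_row(
        "cylinder", o[i, ] - h2 * e3[i, ], o[i, ] + h2 * e3[i, ],
        radius = ncp_diameter_nm / 2, color = cols[i, ]
      )
    }))
    if (nrow(sub) > 1L) {
      prim <- c(prim, purrr::map(seq_len(nrow(sub) - 1L), function(i) {
        seg <- rbind(o[i, ] + h2 * e3[i, ], o[i + 1L, ] - h2 * e3[i + 1L, ])
        scene_primitive_row("polyline", seg[1L, ], radius = 1,
                            color = c(0.6, 0.6, 0.6), points = seg)
      }))
    }
    pts <- o
  } else {
    if (range$end - range$start > max_dna_bp) {
      abort_range(sprintf(
        "DNA-scale range of %s bp exceeds the configured maximum of %s bp",
        fmt_bp(range$end - range$start), fmt_bp(max_dna_bp)
      ))
    }
    atoms <- synthesize_dna(model, range)
    pts <- as.matrix(atoms[c("x", "y", "z")])
    prim <- purrr::map(seq_len(nrow(atoms)), function(i) {
      scene_primitive_row("sphere", pts[i, ], radius = 0.15,
                          color = c(0.4, 0.4, 0.75))
    })
  }
  # Fig-3-style overlays: TSS spheres (signed expression) + site cubes
  if (!is.null(tss) && nrow(tss) > 0L) {
    tpos <- polyline_at_bp(ch$fiber, floor((tss$start + tss$end) / 2))
    tcol <- if ("value" %in% names(tss)) {
      as.matrix(colorize(tss$value, color_rule("signed")))
    } else {
      matrix(0.5, nrow(tss), 3L)
    }
    prim <- c(prim, purrr::map(seq_len(nrow(tss)), function(i) {
      scene_primitive_row("sphere", tpos[i, ], radius = 20,
                          color = tcol[i, ])
    }))
  }
  if (!is.null(sites) && nrow(sites) > 0L) {
    cl <- proximity_classify(sites, tss %||% sites[0, ])
    spos <- polyline_at_bp(ch$fiber, cl$midpoint)
    orange <- c(1.0, 0.55, 0.0)
    yellow <- c(1.0, 0.9, 0.1)
    prim <- c(prim, purrr::map(seq_len(nrow(cl)), function(i) {
      col <- if (cl$class[i] == "near") orange else yellow
      scene_primitive_row("box", spos[i, ] - 15, spos[i, ] + 15,
                          radius = 15, color = col)
    }))
  }
  primitives <- purrr::list_rbind(prim)
  scene <- new_scene(
    primitives,
    camera = default_camera(pts),
    lights = list(c(0, 0, 2e4), c(2e4, 2e4, 2e4))
  )
  validate_scene(scene)
  scene
}
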