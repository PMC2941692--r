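# Projection of annotation tracks onto model elements at any scale, and
# the demonstration statistics: SNP rotational phasing on nucleosomes,
# TSS-binding-site proximity classification, and signed coloring.

#' Enumerate the bp spans of model elements at a scale
#'
#' Point scales (nuclear, fiber) assign each point the bp segment it
#' starts; the nucleosome scale alternates wrap and linker elements
#' (including a leading linker when the first record does not start at 0).
#' Spans tile `[0, chromosome length)` without gaps.
#'
#' @param model A `genome_model`.
#' @param chrom Chromosome name.
#' @param scale `"nuclear"`, `"fiber"` or `"nucleosome"`.
#' @return A tibble: `element` (id at that scale), `type`, `bp_start`,
#'   `bp_end`.
#' @export
scale_elements <- function(model, chrom,
                           scale = c("nuclear", "fiber", "nucleosome")) {
  scale <- match.arg(scale)
  if (!chrom %in% names(model$chromosomes)) {
    abort_range(sprintf("unknown chromosome '%s'", chrom))
  }
  len <- model$manifest$chromosomes$length[
    model$manifest$chromosomes$chrom == chrom
  ]
  ch <- model$chromosomes[[chrom]]
  if (scale %in% c("nuclear", "fiber")) {
    path <- if (scale == "nuclear") ch$nuclear else ch$fiber
    bp <- path$bp
    n <- length(bp)
    ends <- c(bp[-1L], len)
    out <- tibble(
      element = seq_len(n), type = "point",
      bp_start = bp, bp_end = ends
    )
    return(out[out$bp_end > out$bp_start, , drop = FALSE])
  }
  recs <- ch$nucleosomes
  n <- nrow(recs)
  wrap <- recs$wrap_bp
  rows <- list()
  if (recs$start[1L] > 0) {
    rows[[1L]] <- tibble(element = 0L, type = "linker",
                         bp_start = 0, bp_end = recs$start[1L])
  }
  wrap_tab <- tibble(
    element = seq_len(n), type = "nucleosome",
    bp_start = recs$start, bp_end = recs$start + wrap
  )
  link_tab <- tibble(
    element = seq_len(n), type = "linker",
    bp_start = recs$start + wrap,
    bp_end = recs$start + wrap + recs$linker_bp_after
  )
  out <- dplyr::bind_rows(c(rows, list(wrap_tab, link_tab)))
  out <- out[out$bp_end > out$bp_start, , drop = FALSE]
  dplyr::arrange(out, .data$bp_start)
}

#' Project an annotation track onto model elements
#'
#' Assigns per-bp track values to the containing element at the target
#' scale and aggregates. `coverage` counts annotated bp per element with
#' multiplicity, so coverage totals equal the summed interval lengths
#' clipped to the chromosome; `sum` adds `value * bp`; `mean` is the
#' bp-weighted mean over annotated bp; `max` is the largest overlapping
#' value. BED intervals use their `score` as value (1 when absent); WIG
#' tables use `value`.
#'
#' @param track A [parse_bed()] or [parse_wig()] tibble.
#' @param model A `genome_model`.
#' @param chrom Chromosome to project (default: the track's single
#'   chromosome).
#' @param scale Target scale.
#' @param aggregation `"mean"`, `"max"`, `"sum"` or `"coverage"`.
#' @return A `scale_annotation` tibble: element spans plus `coverage_bp`
#'   and `value`. Attributes: `scale`, `aggregation`, `chrom`.
#' @export
project <- function(track, model, chrom = NULL,
                    scale = c("nuclear", "fiber", "nucleosome"),
                    aggregation = c("mean", "max", "sum", "coverage")) {
  scale <- match.arg(scale)
  if (!is.character(aggregation) ||
      !aggregation[1L] %in% c("mean", "max", "sum", "coverage")) {
    abort_argument(sprintf("unknown aggregation '%s'",
                           as.character(aggregation)[1L]))
  }
  aggregation <- aggregation[1L]
  chrom <- chrom %||% unique(track$chrom)
  if (length(chrom) != 1L) {
    abort_argument("track covers multiple chromosomes; supply `chrom`")
  }
  if (!chrom %in% names(model$chromosomes)) {
    abort_range(sprintf("unknown chromosome '%s'", chrom))
  }
  len <- model$manifest$chromosomes$length[
    model$manifest$chromosomes$chrom == chrom
  ]
  els <- scale_elements(model, chrom, scale)
  track <- track[track$chrom == chrom, , drop = FALSE]
  value <- if ("value" %in% names(track)) {
    track$value
  } else if ("score" %in% names(track)) {
    dplyr::coalesce(track$score, 1)
  } else {
    rep(1, nrow(track))
  }
  # clip to the modeled span
  s <- pmax(track$start, 0)
  e <- pmin(track$end, len)
  ok <- e > s
  s <- s[ok]; e <- e[ok]; value <- value[ok]
  els$coverage_bp <- 0
  els$value <- NA_real_
  if (length(s) > 0L) {
    q <- IRanges::IRanges(start = s + 1, end = e)
    subj <- IRanges::IRanges(start = els$bp_start + 1, end = els$bp_end)
    hits <- IRanges::findOverlaps(q, subj)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(q[qh], subj[sh]))
    cov <- tapply(ov, sh, sum)
    els$coverage_bp[as.integer(names(cov))] <- as.numeric(cov)
    agg <- switch(aggregation,
      coverage = cov,
      sum = tapply(ov * value[qh], sh, sum),
      mean = tapply(ov * value[qh], sh, sum) / cov,
      max = tapply(value[qh], sh, max)
    )
    els$value[as.integer(names(agg))] <- as.numeric(agg)
  }
  if (aggregation == "coverage") els$value[is.na(els$value)] <- 0
  structure(
    els,
    scale = scale, aggregation = aggregation, chrom = chrom,
    class = c("scale_annotation", class(els))
  )
}

#' Rotational phasing report for SNPs on nucleosomes
#'
#' For each single-bp SNP, locates the containing nucleosome record and
#' reports the bp offset from the wrap start, the rotational phase angle
#' around the DNA helix, and the axial position along the NCP superhelix
#' axis. SNPs that fall in linker DNA are reported with
#' `location = "linker"` and the nearest record.
#'
#' @param snps A BED tibble of single-bp intervals (`end - start = 1`).
#' @param nucleosomes A `nucleosome_set` (or the nucleosome table of one
#'   chromosome of a model).
#' @param helix [helix_params()] for the phase calculation.
#' @param superhelix [superhelix_params()] for the axial coordinate.
#' @return A tibble: `name`, `chrom`, `pos`, `location`
#'   (`"wrap"`/`"linker"`), `record`, `offset_bp`, `phase_deg`, `axial_nm`.
#' @export
snp_phase_report <- function(snps, nucleosomes, helix = helix_params(),
                             superhelix = superhelix_params()) {
  widths <- snps$end - snps$start
  if (any(widths != 1)) {
    abort_validation(sprintf(
      "SNP intervals must be single-bp; %d offending row(s), first width %s",
      sum(widths != 1), fmt_bp(widths[widths != 1][1L])
    ))
  }
  wrap <- superhelix$wrap_bp
  zext <- superhelix$turns * superhelix$pitch_nm
  starts <- nucleosomes$start
  n <- nrow(nucleosomes)
  snp_names <- if ("name" %in% names(snps)) snps$name else
    rep(NA_character_, nrow(snps))
  purrr::pmap(list(snp_names, snps$chrom, snps$start),
              function(nm, ch, pos) {
    idx <- findInterval(pos, starts)
    if (idx >= 1L && pos < starts[idx] + wrap) {
      off <- pos - starts[idx]
      tibble(
        name = nm, chrom = ch, pos = pos, location = "wrap",
        record = idx, offset_bp = off,
        phase_deg = phase_angle(off, helix),
        axial_nm = off / (wrap - 1) * zext - zext / 2
      )
    } else {
      # nearest record: previous wrap end vs next wrap start
      d_prev <- if (idx >= 1L) pos - (starts[idx] + wrap - 1) else Inf
      d_next <- if (idx < n) starts[idx + 1L] - pos else Inf
      nearest <- if (d_prev <= d_next) idx else idx + 1L
      tibble(
        name = nm, chrom = ch, pos = pos, location = "linker",
        record = nearest, offset_bp = NA_real_,
        phase_deg = NA_real_, axial_nm = NA_real_
      )
    }
  }) |>
    purrr::list_rbind()
}

#' Classify binding sites by proximity to transcription start sites
#'
#' Distance is the minimum bp gap between the site midpoint and any TSS
#' position on the same chromosome; a site is `"near"` iff its distance is
#' strictly below `threshold_bp` (the `< 10 kbp` rule), `"far"` otherwise.
#' With no TSS on a site's chromosome the distance is `Inf` and the site
#' is `"far"`.
#'
#' @param sites BED tibble of binding sites.
#' @param tss BED tibble of TSS positions (midpoints are used).
#' @param threshold_bp Strict proximity threshold in bp (default 10000).
#' @return `sites` plus `midpoint`, `distance_bp` and `class`
#'   (`"near"`/`"far"`).
#' @export
proximity_classify <- function(sites, tss, threshold_bp = 10000) {
  check_number(threshold_bp, "threshold_bp", 0, strict = TRUE)
  mid <- floor((sites$start + sites$end) / 2)
  tss_mid <- if (nrow(tss) > 0L) floor((tss$start + tss$end) / 2) else
    numeric(0)
  dist <- purrr::map_dbl(seq_len(nrow(sites)), function(i) {
    cand <- tss_mid[tss$chrom == sites$chrom[i]]
    if (length(cand) == 0L) return(Inf)
    min(abs(mid[i] - cand))
  })
  dplyr::mutate(
    as_tibble(sites),
    midpoint = mid,
    distance_bp = dist,
    class = ifelse(dist < threshold_bp, "near", "far")
  )
}

#' Color mapping rule
#'
#' @param scheme `"signed"` (positive green, negative red, zero neutral
#'   gray), `"sequential"` (gray to blue) or `"categorical"`.
#' @return A `color_rule` list.
#' @export
color_rule <- function(scheme = c("signed", "sequential", "categorical")) {
  scheme <- match.arg(scheme)
  structure(list(scheme = scheme), class = "color_rule")
}

#' Map values to RGB colors
#'
#' The signed scheme maps `max(|value|)` to fully saturated green (positive)
#' or red (negative) and 0 to neutral gray; saturation is monotone in
#' `|value|`. All-zero input yields all-neutral output.
#'
#' @param values Finite numeric values (NA allowed, colored neutral).
#' @param rule A [color_rule()].
#' @return A tibble with columns `r`, `g`, `b` in `[0, 1]`.
#' @export
colorize <- function(values, rule = color_rule("signed")) {
  neutral <- c(0.5, 0.5, 0.5)
  n <- length(values)
  out <- matrix(rep(neutral, each = n), nrow = n)
  if (rule$scheme == "categorical") {
    ok <- !is.na(values)
    pal <- matrix(c(
      0.90, 0.10, 0.10,
      0.10, 0.60, 0.90,
      0.10, 0.70, 0.20,
      0.95, 0.65, 0.10,
      0.60, 0.30, 0.80,
      0.80, 0.80, 0.20
    ), ncol = 3L, byrow = TRUE)
    idx <- (as.integer(factor(values)) - 1L) %% nrow(pal) + 1L
    out[ok, ] <- pal[idx[ok], , drop = FALSE]
    colnames(out) <- c("r", "g", "b")
    return(as_tibble(as.data.frame(out)))
  }
  v <- as.numeric(values)
  if (any(!is.na(v) & !is.finite(v))) {
    abort_argument("`values` must be finite (or NA)")
  }
  ok <- !is.na(v)
  if (rule$scheme == "signed") {
    m <- if (any(ok)) max(abs(v[ok])) else 0
    if (m > 0) {
      s <- abs(v) / m
      pos <- ok & v >= 0
      neg <- ok & v < 0
      # neutral gray -> full green (0, 0.8, 0) / full red (0.8, 0, 0)
      out[pos, 1L] <- 0.5 * (1 - s[pos])
      out[pos, 2L] <- 0.5 + 0.3 * s[pos]
      out[pos, 3L] <- 0.5 * (1 - s[pos])
      out[neg, 1L] <- 0.5 + 0.3 * s[neg]
      out[neg, 2L] <- 0.5 * (1 - s[neg])
      out[neg, 3L] <- 0.5 * (1 - s[neg])
    }
  } else if (rule$scheme == "sequential") {
    rng <- range(v[ok])
    s <- if (diff(rng) > 0) (v - rng[1L]) / diff(rng) else rep(0, n)
    out[ok, 1L] <- 0.9 * (1 - s[ok])
    out[ok, 2L] <- 0.9 * (1 - s[ok]) + 0.1
    out[ok, 3L] <- 0.5 + 0.5 * s[ok]
  }
  colnames(out) <- c("r", "g", "b")
  as_tibble(as.data.frame(out))
}
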