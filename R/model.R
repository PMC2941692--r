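# The genome_model container: manifest + per-chromosome layered scales
# (nuclear, fiber, nucleosome). The atomic scale is always derived on
# demand, never stored.

#' Genomic range in 0-based half-open coordinates
#'
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open bp bounds (`start < end`).
#' @return A `genomic_range` list.
#' @export
genomic_range <- function(chrom, start, end) {
  check_count(start, "start")
  check_count(end, "end")
  if (start >= end) {
    abort_argument("`start` must be < `end` (0-based half-open)")
  }
  structure(
    list(chrom = as.character(chrom), start = as.numeric(start),
         end = as.numeric(end)),
    class = "genomic_range"
  )
}

#' Parse a UCSC-style range string
#'
#' Accepts `"chrom:start-end"` in the 1-based inclusive convention used by
#' genome browsers and figure legends, and converts it to the package's
#' internal 0-based half-open [genomic_range()]. Commas in numbers are
#' allowed.
#'
#' @param text Range string, e.g. `"chr20:7602872-7603018"`.
#' @return A [genomic_range()].
#' @export
parse_range <- function(text) {
  m <- regmatches(text, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", text))[[1L]]
  if (length(m) != 4L) {
    abort_argument(sprintf("cannot parse range string '%s'", text))
  }
  s1 <- as.numeric(gsub(",", "", m[3L]))
  e1 <- as.numeric(gsub(",", "", m[4L]))
  if (s1 < 1 || e1 < s1) {
    abort_argument(sprintf("invalid 1-based range '%s'", text))
  }
  genomic_range(m[2L], s1 - 1, e1)
}

check_range <- function(model, range) {
  if (!range$chrom %in% names(model$chromosomes)) {
    abort_range(sprintf("unknown chromosome '%s'", range$chrom))
  }
  len <- model$manifest$chromosomes$length[
    model$manifest$chromosomes$chrom == range$chrom
  ]
  if (range$end > len) {
    abort_range(sprintf(
      "range [%s, %s) exceeds chromosome '%s' length %s",
      format(range$start, scientific = FALSE),
      format(range$end, scientific = FALSE), range$chrom,
      format(len, scientific = FALSE)
    ))
  }
  invisible(len)
}

#' Build a hierarchical multi-scale genome model
#'
#' For each chromosome in `chrom_table` this constructs the three stored
#' scales: the nuclear giant-loop random walk, the 30 nm fiber path, and the
#' nucleosome records along it. Per-chromosome seeds are derived from the
#' master seed, so equal inputs give bitwise-equal models.
#'
#' @param chrom_table Data frame with columns `chrom` and `length` (bp), as
#'   produced by [synth_genome()] or [read_chrom_table()].
#' @param genome Genome name recorded in the manifest.
#' @param seed Master integer seed.
#' @param nuclear [nuclear_params()] (its seed field is overridden by the
#'   derived per-chromosome seed).
#' @param bp_per_point Fiber resolution in bp per point.
#' @param jitter_nm Fiber jitter sd in nm.
#' @param repeat_bp Nucleosome repeat length in bp.
#' @param positions Optional named list of explicit nucleosome start vectors
#'   per chromosome.
#' @param superhelix [superhelix_params()].
#' @param helix [helix_params()].
#' @param nucleosomes_per_turn Solenoid density along the fiber.
#' @return A `genome_model`: list with `manifest` (genome, chromosome table,
#'   parameters, seed) and `chromosomes` (per chromosome: `nuclear`,
#'   `fiber`, `nucleosomes`).
#' @examples
#' g <- synth_genome(lengths = 20000, seed = 1)
#' m <- build_genome_model(g, seed = 1)
#' glance(m)
#' @export
build_genome_model <- function(chrom_table, genome = "synthetic",
                               seed = 1L,
                               nuclear = nuclear_params(),
                               bp_per_point = 1200, jitter_nm = 3,
                               repeat_bp = 200, positions = NULL,
                               superhelix = superhelix_params(),
                               helix = helix_params(),
                               nucleosomes_per_turn = 6) {
  if (!all(c("chrom", "length") %in% names(chrom_table))) {
    abort_argument("`chrom_table` needs columns `chrom` and `length`")
  }
  check_count(seed, "seed")
  chrom_table <- as_tibble(chrom_table[c("chrom", "length")])
  chroms <- purrr::imap(
    stats::setNames(chrom_table$length, chrom_table$chrom),
    function(len, nm) {
      i <- match(nm, chrom_table$chrom)
      np <- nuclear
      np$seed <- as.integer((seed * 1009L + i * 7L) %% 2147483647L)
      nuc <- build_nuclear_walk(len, np)
      fib <- build_fiber_path(nuc, bp_per_point = bp_per_point,
                              jitter_nm = jitter_nm,
                              seed = (np$seed + 1L) %% 2147483647L)
      pos <- if (!is.null(positions)) positions[[nm]] else NULL
      ncl <- place_nucleosomes(fib, positions = pos, repeat_bp = repeat_bp,
                               superhelix = superhelix,
                               nucleosomes_per_turn = nucleosomes_per_turn)
      list(nuclear = nuc, fiber = fib, nucleosomes = ncl)
    }
  )
  structure(
    list(
      manifest = list(
        genome = genome,
        chromosomes = chrom_table,
        seed = as.integer(seed),
        params = list(
          nuclear = nuclear, bp_per_point = bp_per_point,
          jitter_nm = jitter_nm, repeat_bp = repeat_bp,
          superhelix = superhelix, helix = helix,
          nucleosomes_per_turn = nucleosomes_per_turn
        )
      ),
      chromosomes = chroms
    ),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf(
    "<genome_model> genome '%s', %d chromosome(s), %s bp, seed %d\n",
    x$manifest$genome, nrow(x$manifest$chromosomes),
    format(sum(x$manifest$chromosomes$length), big.mark = ",",
           scientific = FALSE),
    x$manifest$seed
  ))
  for (nm in names(x$chromosomes)) {
    ch <- x$chromosomes[[nm]]
    cat(sprintf(
      "  %s: %d nuclear points, %d fiber points, %d nucleosomes\n",
      nm, nrow(ch$nuclear), nrow(ch$fiber), nrow(ch$nucleosomes)
    ))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a genome model into its nucleosome record table
#'
#' @param x A `genome_model`.
#' @param ... Unused.
#' @return A tibble of all nucleosome records with a leading `chrom` column.
#' @export
tidy.genome_model <- function(x, ...) {
  purrr::imap(x$chromosomes, function(ch, nm) {
    dplyr::bind_cols(tibble(chrom = nm), as_tibble(ch$nucleosomes))
  }) |>
    purrr::list_rbind()
}

#' One-row summary of a genome model
#'
#' @param x A `genome_model`.
#' @param ... Unused.
#' @return A one-row tibble: chromosome count, modeled bp, element counts
#'   per scale.
#' @export
glance.genome_model <- function(x, ...) {
  tibble(
    genome = x$manifest$genome,
    n_chromosomes = nrow(x$manifest$chromosomes),
    total_bp = sum(x$manifest$chromosomes$length),
    nuclear_points = sum(purrr::map_int(x$chromosomes,
                                        ~ nrow(.x$nuclear))),
    fiber_points = sum(purrr::map_int(x$chromosomes, ~ nrow(.x$fiber))),
    nucleosomes = sum(purrr::map_int(x$chromosomes,
                                     ~ nrow(.x$nucleosomes))),
    seed = x$manifest$seed
  )
}

#' Map a bp coordinate to the containing element at a scale
#'
#' The drill-down primitive: given a genomic position, return the unique
#' model element whose bp span contains it at the requested scale. At the
#' nucleosome scale, positions that fall between wraps return a linker
#' designation with the flanking record indices.
#'
#' @param model A `genome_model`.
#' @param chrom Chromosome name.
#' @param bp 0-based position within the chromosome.
#' @param scale `"nuclear"`, `"fiber"` or `"nucleosome"`.
#' @return A one-row tibble: `scale`, `type` (`"point"`, `"nucleosome"` or
#'   `"linker"`), `index` (element index; for linkers the preceding record,
#'   0 before the first), `next_index` (linkers only), `bp_start`, `bp_end`.
#' @export
map_bp_to_scale <- function(model, chrom, bp,
                            scale = c("nuclear", "fiber", "nucleosome")) {
  scale <- match.arg(scale)
  len <- check_range(model, genomic_range(chrom, bp, bp + 1))
  ch <- model$chromosomes[[chrom]]
  if (scale %in% c("nuclear", "fiber")) {
    path <- if (scale == "nuclear") ch$nuclear else ch$fiber
    idx <- findInterval(bp, path$bp)
    idx <- min(idx, nrow(path) - 1L)  # last segment owns its end
    return(tibble(
      scale = scale, type = "point", index = idx, next_index = NA_integer_,
      bp_start = path$bp[idx], bp_end = path$bp[idx + 1L]
    ))
  }
  recs <- ch$nucleosomes
  idx <- findInterval(bp, recs$start)
  if (idx == 0L) {
    return(tibble(
      scale = scale, type = "linker", index = 0L, next_index = 1L,
      bp_start = 0, bp_end = recs$start[1L]
    ))
  }
  s <- recs$start[idx]
  if (bp < s + recs$wrap_bp[idx]) {
    tibble(
      scale = scale, type = "nucleosome", index = idx,
      next_index = NA_integer_,
      bp_start = s, bp_end = s + recs$wrap_bp[idx]
    )
  } else {
    nxt <- if (idx < nrow(recs)) idx + 1L else NA_integer_
    tibble(
      scale = scale, type = "linker", index = idx, next_index = nxt,
      bp_start = s + recs$wrap_bp[idx],
      bp_end = if (!is.na(nxt)) recs$start[nxt] else len
    )
  }
}
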