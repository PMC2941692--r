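# UCSC BED / WIG track parsing and writing. BED is 0-based half-open; WIG
# declarations are 1-based (converted to 0-based internally); bedGraph is
# accepted as a WIG dialect variant, auto-detected by its 4-column value
# lines. All parse errors carry the offending 1-based line number.

read_track_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else if (length(x) == 1L && grepl("\n", x)) {
    strsplit(x, "\n", fixed = TRUE)[[1L]]
  } else {
    as.character(x)
  }
}

is_skip_line <- function(line) {
  grepl("^\\s*$", line) | grepl("^(track|browser|#)", line)
}

parse_int_field <- function(x, what, lineno) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) | v != floor(v)
  if (any(bad)) {
    abort_format(sprintf(
      "line %d: non-integer %s '%s'", lineno[bad][1L], what, x[bad][1L]
    ))
  }
  v
}

#' Parse a UCSC BED track
#'
#' Columns 1-3 (`chrom`, `start`, `end`) are mandatory; 4-6 (`name`,
#' `score`, `strand`) optional. Coordinates are 0-based half-open; `track`,
#' `browser`, comment and blank lines are skipped. Validation failures
#' report the 1-based line number.
#'
#' @param x A file path, a single string with embedded newlines, or a
#'   character vector of lines.
#' @return A tibble: `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @examples
#' parse_bed("chr1\t0\t100\tfeat")
#' @export
parse_bed <- function(x) {
  lines <- read_track_lines(x)
  lineno <- seq_along(lines)
  keep <- !is_skip_line(lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (length(lines) == 0L) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  name = character(), score = numeric(),
                  strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    abort_format(sprintf("line %d: fewer than 3 BED columns",
                         lineno[nf < 3L][1L]))
  }
  col <- function(i) purrr::map_chr(fields, ~ if (length(.x) >= i) .x[i]
                                    else NA_character_)
  start <- parse_int_field(col(2L), "start coordinate", lineno)
  end <- parse_int_field(col(3L), "end coordinate", lineno)
  bad <- start >= end
  if (any(bad)) {
    abort_format(sprintf(
      "line %d: empty or inverted interval (start %s >= end %s)",
      lineno[bad][1L], fmt_bp(start[bad][1L]), fmt_bp(end[bad][1L])
    ))
  }
  if (any(start < 0)) {
    abort_format(sprintf("line %d: negative start", lineno[start < 0][1L]))
  }
  score_chr <- col(5L)
  score <- suppressWarnings(as.numeric(score_chr))
  bad_score <- !is.na(score_chr) & is.na(score)
  if (any(bad_score)) {
    abort_format(sprintf("line %d: non-numeric score '%s'",
                         lineno[bad_score][1L], score_chr[bad_score][1L]))
  }
  strand <- col(6L)
  bad_strand <- !is.na(strand) & !strand %in% c("+", "-", ".")
  if (any(bad_strand)) {
    abort_format(sprintf("line %d: invalid strand '%s'",
                         lineno[bad_strand][1L], strand[bad_strand][1L]))
  }
  tibble(
    chrom = col(1L), start = start, end = end,
    name = col(4L), score = score,
    strand = dplyr::coalesce(strand, ".")
  )
}

#' Write intervals as a BED file
#'
#' Canonical tab-separated BED; emits only the rightmost optional columns
#' that carry any data. `parse_bed(write_bed(x, f))` is the identity.
#'
#' @param intervals A tibble as returned by [parse_bed()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  has_name <- "name" %in% names(intervals) && any(!is.na(intervals$name))
  has_score <- "score" %in% names(intervals) && any(!is.na(intervals$score))
  has_strand <- "strand" %in% names(intervals) &&
    any(!intervals$strand %in% c(NA, "."))
  cols <- list(
    intervals$chrom, fmt_bp(intervals$start), fmt_bp(intervals$end)
  )
  if (has_name || has_score || has_strand) {
    cols <- c(cols, list(dplyr::coalesce(intervals$name, ".")))
  }
  if (has_score || has_strand) {
    sc <- intervals$score %||% rep(NA_real_, nrow(intervals))
    cols <- c(cols, list(ifelse(is.na(sc), "0", format(sc, trim = TRUE))))
  }
  if (has_strand) cols <- c(cols, list(intervals$strand))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

parse_wig_declaration <- function(line, lineno) {
  toks <- strsplit(trimws(line), "\\s+")[[1L]]
  mode <- toks[1L]
  kv <- strsplit(toks[-1L], "=", fixed = TRUE)
  vals <- stats::setNames(
    purrr::map_chr(kv, 2L), purrr::map_chr(kv, 1L)
  )
  if (is.na(vals["chrom"])) {
    abort_format(sprintf("line %d: %s declaration without chrom",
                         lineno, mode))
  }
  list(
    mode = mode,
    chrom = unname(vals["chrom"]),
    start = if (!is.na(vals["start"])) as.numeric(vals["start"]) else NA,
    step = if (!is.na(vals["step"])) as.numeric(vals["step"]) else 1,
    span = if (!is.na(vals["span"])) as.numeric(vals["span"]) else 1
  )
}

#' Parse a UCSC WIG (or bedGraph) track
#'
#' Supports `fixedStep` and `variableStep` declarations (1-based starts,
#' converted to 0-based internally) and auto-detects bedGraph by 4-column
#' data lines. Each value covers `span` bp.
#'
#' @param x A file path, a single string with newlines, or lines.
#' @return A tibble of per-position values: `chrom`, `start` (0-based),
#'   `end` (`start + span`), `value`, `mode`.
#' @examples
#' parse_wig("fixedStep chrom=chr1 start=1 step=1\n1.0\n2.0\n3.0")
#' @export
parse_wig <- function(x) {
  lines <- read_track_lines(x)
  out <- list()
  decl <- NULL
  fixed_i <- 0
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (is_skip_line(line)) next
    if (grepl("^(fixedStep|variableStep)\\b", line)) {
      decl <- parse_wig_declaration(line, i)
      if (decl$mode == "fixedStep" && is.na(decl$start)) {
        abort_format(sprintf("line %d: fixedStep without start", i))
      }
      fixed_i <- 0
      next
    }
    toks <- strsplit(trimws(line), "\\s+")[[1L]]
    if (length(toks) == 4L && is.null(decl)) {
      # bedGraph variant: chrom start end value (0-based half-open)
      start <- parse_int_field(toks[2L], "start coordinate", i)
      end <- parse_int_field(toks[3L], "end coordinate", i)
      value <- suppressWarnings(as.numeric(toks[4L]))
      if (is.na(value)) {
        abort_format(sprintf("line %d: non-numeric value '%s'", i, toks[4L]))
      }
      if (start >= end) {
        abort_format(sprintf("line %d: empty bedGraph interval", i))
      }
      out[[length(out) + 1L]] <- tibble(
        chrom = toks[1L], start = start, end = end, value = value,
        mode = "bedGraph"
      )
      next
    }
    if (is.null(decl)) {
      abort_format(sprintf(
        "line %d: value line before any fixedStep/variableStep declaration",
        i
      ))
    }
    if (decl$mode == "variableStep") {
      if (length(toks) != 2L) {
        abort_format(sprintf("line %d: variableStep line needs 2 fields", i))
      }
      pos1 <- parse_int_field(toks[1L], "position", i)
      value <- suppressWarnings(as.numeric(toks[2L]))
      if (is.na(value)) {
        abort_format(sprintf("line %d: non-numeric value '%s'", i, toks[2L]))
      }
      start <- pos1 - 1  # 1-based -> 0-based
      out[[length(out) + 1L]] <- tibble(
        chrom = decl$chrom, start = start, end = start + decl$span,
        value = value, mode = "variableStep"
      )
    } else {
      value <- suppressWarnings(as.numeric(toks[1L]))
      if (is.na(value)) {
        abort_format(sprintf("line %d: non-numeric value '%s'", i, toks[1L]))
      }
      start <- (decl$start - 1) + fixed_i * decl$step
      out[[length(out) + 1L]] <- tibble(
        chrom = decl$chrom, start = start, end = start + decl$span,
        value = value, mode = "fixedStep"
      )
      fixed_i <- fixed_i + 1
    }
  }
  if (length(out) == 0L) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  value = numeric(), mode = character()))
  }
  purrr::list_rbind(out)
}

#' Write per-position values as a variableStep WIG file
#'
#' Emits one `variableStep` declaration per (chromosome, span) run, with
#' 1-based positions. `parse_wig(write_wig(x, f))` reproduces `chrom`,
#' `start`, `end`, `value`.
#'
#' @param wig A tibble as returned by [parse_wig()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wig <- function(wig, path) {
  if (nrow(wig) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  wig <- dplyr::arrange(wig, .data$chrom, .data$start)
  span <- wig$end - wig$start
  grp <- cumsum(
    c(TRUE, wig$chrom[-1L] != wig$chrom[-nrow(wig)] |
        span[-1L] != span[-nrow(wig)])
  )
  lines <- unlist(purrr::map(split(seq_len(nrow(wig)), grp), function(idx) {
    c(
      sprintf("variableStep chrom=%s span=%s",
              wig$chrom[idx[1L]], fmt_bp(span[idx[1L]])),
      sprintf("%s\t%s", fmt_bp(wig$start[idx] + 1), # 0-based -> 1-based
              format(wig$value[idx], trim = TRUE, scientific = FALSE))
    )
  }))
  writeLines(lines, path)
  invisible(path)
}
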