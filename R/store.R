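# Compressed-XML persistence of the three stored scales per chromosome,
# with block-structured lazy range loading and storage accounting.
#
# Layout: <dir>/manifest.xml (uncompressed) + <chrom>.<scale>.xml.gz.
# Each payload file is a concatenation of independently gzip-compressed
# blocks of at most `block_size` elements; the manifest records each
# block's byte offset and bp span, so a range query decompresses only the
# blocks it needs. No timestamps are embedded anywhere, so writing the
# same model twice is byte-identical.

STORE_VERSION <- "1.0"
STORE_BLOCK_SIZE <- 10000L

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

fmt_bp <- function(x) sprintf("%.0f", x)

#' Naive atomic-storage parameters
#'
#' The constants of the naive storage estimate for an all-atom genome model:
#' one 3D position per atom, `atoms_per_bp` atoms per bp, 4-byte floats.
#'
#' @param genome_bp Genome size in bp (default 3e9, human).
#' @param atoms_per_bp Atoms stored per bp (default 20).
#' @param coords_per_atom Coordinates per atom (default 3).
#' @param bytes_per_coord Bytes per coordinate (default 4).
#' @return A `storage_params` list. All fields must be positive integers.
#' @export
storage_params <- function(genome_bp = 3e9, atoms_per_bp = 20,
                           coords_per_atom = 3, bytes_per_coord = 4) {
  for (nm in c("genome_bp", "atoms_per_bp", "coords_per_atom",
               "bytes_per_coord")) {
    v <- get(nm)
    check_count(v, nm, 1)
  }
  structure(
    list(genome_bp = genome_bp, atoms_per_bp = atoms_per_bp,
         coords_per_atom = coords_per_atom,
         bytes_per_coord = bytes_per_coord),
    class = "storage_params"
  )
}

#' Naive atomic-representation byte count
#'
#' `genome_bp * atoms_per_bp * coords_per_atom * bytes_per_coord` - the cost
#' of storing every atom coordinate explicitly (about 7.2e11 bytes, i.e.
#' more than 600 decimal GB, for a human genome at 20 atoms/bp).
#'
#' @param params A [storage_params()] object.
#' @return Byte count (numeric, exact).
#' @examples
#' naive_bytes()  # 7.2e11
#' @export
naive_bytes <- function(params = storage_params()) {
  params$genome_bp * params$atoms_per_bp * params$coords_per_atom *
    params$bytes_per_coord
}

# --- serialization -------------------------------------------------------

element_lines <- function(scale, tab) {
  if (scale == "nucleosome") {
    axes <- as.matrix(tab[frame_axis_cols])
    sprintf(
      '<n s="%s" k="%s" x="%.3f" y="%.3f" z="%.3f" a="%s"/>',
      fmt_bp(tab$start), fmt_bp(tab$linker_bp_after),
      tab$x, tab$y, tab$z,
      apply(axes, 1L, function(r) paste(sprintf("%.6f", r), collapse = " "))
    )
  } else {
    loop_attr <- if ("loop" %in% names(tab)) {
      ifelse(is.na(tab$loop), "", sprintf(' l="%d"', tab$loop))
    } else ""
    sprintf(
      '<p b="%s" x="%.3f" y="%.3f" z="%.3f"%s/>',
      fmt_bp(tab$bp), tab$x, tab$y, tab$z, loop_attr
    )
  }
}

element_anchors <- function(scale, tab) {
  if (scale == "nucleosome") tab$start else tab$bp
}

#' Write a genome model to a compressed-XML store directory
#'
#' One uncompressed `manifest.xml` plus one `<chrom>.<scale>.xml.gz` file
#' per chromosome and stored scale (nuclear, fiber, nucleosome). Positions
#' are written at fixed 3-decimal precision in nm (orientation unit vectors
#' at 6 decimals); payloads are chunked into independently decompressible
#' gzip blocks indexed in the manifest. Output is deterministic: writing
#' the same model twice gives byte-identical files.
#'
#' @param model A `genome_model`.
#' @param directory Target directory (created if needed).
#' @param block_size Elements per compressed block (default 10000).
#' @return The store manifest (list), invisibly.
#' @export
write_model <- function(model, directory, block_size = STORE_BLOCK_SIZE) {
  ok <- dir.exists(directory) ||
    dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(directory, 2L) != 0L) {
    abort_io(sprintf("directory '%s' is not writable", directory))
  }
  scales <- c("nuclear", "fiber", "nucleosome")
  chrom_entries <- character(0)
  for (ci in seq_len(nrow(model$manifest$chromosomes))) {
    nm <- model$manifest$chromosomes$chrom[ci]
    len <- model$manifest$chromosomes$length[ci]
    ch <- model$chromosomes[[nm]]
    scale_entries <- character(0)
    for (scale in scales) {
      tab <- switch(scale, nuclear = ch$nuclear, fiber = ch$fiber,
                    nucleosome = ch$nucleosomes)
      lines <- element_lines(scale, tab)
      anchors <- element_anchors(scale, tab)
      nblk <- max(1L, ceiling(length(lines) / block_size))
      starts <- (seq_len(nblk) - 1L) * block_size + 1L
      raws <- vector("list", nblk)
      blk_meta <- vector("list", nblk)
      offset <- 0
      for (b in seq_len(nblk)) {
        idx <- starts[b]:min(starts[b] + block_size - 1L, length(lines))
        bp_start <- anchors[idx[1L]]
        bp_end <- if (b < nblk) anchors[starts[b + 1L]] else len
        txt <- paste0(
          sprintf('<block n="%d" s="%s" e="%s">\n', length(idx),
                  fmt_bp(bp_start), fmt_bp(bp_end)),
          paste(lines[idx], collapse = "\n"),
          "\n</block>\n"
        )
        raws[[b]] <- memCompress(charToRaw(txt), type = "gzip")
        blk_meta[[b]] <- sprintf(
          '      <block offset="%s" bytes="%d" s="%s" e="%s" n="%d"/>',
          fmt_bp(offset), length(raws[[b]]), fmt_bp(bp_start),
          fmt_bp(bp_end), length(idx)
        )
        offset <- offset + length(raws[[b]])
      }
      fname <- sprintf("%s.%s.xml.gz", nm, scale)
      con <- file(file.path(directory, fname), "wb")
      writeBin(unlist(lapply(raws, as.vector)), con)
      close(con)
      scale_entries <- c(scale_entries, paste0(
        sprintf('    <scale name="%s" file="%s" bytes="%s" n="%d">\n',
                scale, xml_escape(fname), fmt_bp(offset), length(lines)),
        paste(unlist(blk_meta), collapse = "\n"),
        "\n    </scale>"
      ))
    }
    chrom_entries <- c(chrom_entries, paste0(
      sprintf('  <chromosome name="%s" length="%s">\n',
              xml_escape(nm), fmt_bp(len)),
      paste(scale_entries, collapse = "\n"),
      "\n  </chromosome>"
    ))
  }
  params_yaml <- yaml::as.yaml(rapply(
    model$manifest$params, unclass, how = "replace"
  ))
  manifest_txt <- paste0(
    sprintf('<chromo3d_store version="%s" genome="%s" seed="%d">\n',
            STORE_VERSION, xml_escape(model$manifest$genome),
            model$manifest$seed),
    "  <params>", xml_escape(params_yaml), "</params>\n",
    paste(chrom_entries, collapse = "\n"),
    if (length(chrom_entries) > 0L) "\n" else "",
    "</chromo3d_store>\n"
  )
  writeLines(manifest_txt, file.path(directory, "manifest.xml"), sep = "")
  invisible(read_manifest(directory))
}

read_manifest <- function(directory) {
  path <- file.path(directory, "manifest.xml")
  if (!file.exists(path)) {
    abort_io(sprintf("missing manifest file '%s'", path))
  }
  doc <- xml2::read_xml(path)
  version <- xml2::xml_attr(doc, "version")
  if (!identical(version, STORE_VERSION)) {
    abort_format(sprintf(
      "incompatible store version '%s' (expected '%s')",
      version, STORE_VERSION
    ))
  }
  params_raw <- yaml::yaml.load(
    xml2::xml_text(xml2::xml_find_first(doc, "./params"))
  )
  params <- params_raw
  if (!is.null(params$nuclear)) {
    params$nuclear <- do.call(nuclear_params, params$nuclear)
  }
  if (!is.null(params$superhelix)) {
    params$superhelix <- do.call(superhelix_params, params$superhelix)
  }
  if (!is.null(params$helix)) {
    params$helix <- do.call(helix_params, params$helix)
  }
  chrom_nodes <- xml2::xml_find_all(doc, "./chromosome")
  chromosomes <- tibble(
    chrom = xml2::xml_attr(chrom_nodes, "name"),
    length = as.numeric(xml2::xml_attr(chrom_nodes, "length"))
  )
  files <- purrr::map(chrom_nodes, function(cn) {
    scale_nodes <- xml2::xml_find_all(cn, "./scale")
    stats::setNames(
      purrr::map(scale_nodes, function(sn) {
        bn <- xml2::xml_find_all(sn, "./block")
        list(
          file = xml2::xml_attr(sn, "file"),
          bytes = as.numeric(xml2::xml_attr(sn, "bytes")),
          n = as.integer(xml2::xml_attr(sn, "n")),
          blocks = tibble(
            offset = as.numeric(xml2::xml_attr(bn, "offset")),
            bytes = as.numeric(xml2::xml_attr(bn, "bytes")),
            s = as.numeric(xml2::xml_attr(bn, "s")),
            e = as.numeric(xml2::xml_attr(bn, "e")),
            n = as.integer(xml2::xml_attr(bn, "n"))
          )
        )
      }),
      xml2::xml_attr(scale_nodes, "name")
    )
  })
  names(files) <- chromosomes$chrom
  list(
    version = version,
    genome = xml2::xml_attr(doc, "genome"),
    seed = as.integer(xml2::xml_attr(doc, "seed")),
    params = params,
    chromosomes = chromosomes,
    files = files
  )
}

#' Open a model store for lazy reading
#'
#' Loads only the manifest eagerly; scale payloads are decompressed on
#' first access per (chromosome, scale) or per range via [load_range()].
#' The store records every payload file it opens in `store$access_log`.
#'
#' @param directory A directory written by [write_model()].
#' @return A `genome_store` environment: `manifest`, `directory`, `cache`,
#'   `access_log`.
#' @export
read_model <- function(directory) {
  manifest <- read_manifest(directory)
  store <- new.env(parent = emptyenv())
  store$manifest <- manifest
  store$directory <- directory
  store$cache <- new.env(parent = emptyenv())
  store$access_log <- character(0)
  class(store) <- "genome_store"
  store
}

#' @export
print.genome_store <- function(x, ...) {
  cat(sprintf(
    "<genome_store> '%s': genome '%s', %d chromosome(s), %s payload bytes\n",
    x$directory, x$manifest$genome, nrow(x$manifest$chromosomes),
    format(store_payload_bytes(x), big.mark = ",", scientific = FALSE)
  ))
  invisible(x)
}

store_payload_bytes <- function(store) {
  sum(purrr::map_dbl(store$manifest$files, function(sc) {
    sum(purrr::map_dbl(sc, "bytes"))
  }))
}

# Read raw bytes of one payload file, logging the access.
store_read_raw <- function(store, chrom, scale) {
  entry <- store$manifest$files[[chrom]][[scale]]
  if (is.null(entry)) {
    abort_range(sprintf("unknown chromosome '%s' or scale '%s'",
                        chrom, scale))
  }
  path <- file.path(store$directory, entry$file)
  if (!file.exists(path)) {
    abort_io(sprintf("missing payload file '%s'", path))
  }
  store$access_log <- c(store$access_log, entry$file)
  readBin(path, "raw", n = file.size(path))
}

decode_block <- function(raw, meta, chrom, scale) {
  if (meta$offset + meta$bytes > length(raw)) {
    abort_io(sprintf(
      "corrupt payload for chromosome '%s' scale '%s': file truncated (%d bytes, block needs %s)",
      chrom, scale, length(raw), fmt_bp(meta$offset + meta$bytes)
    ))
  }
  bytes <- tryCatch(
    memDecompress(raw[(meta$offset + 1):(meta$offset + meta$bytes)],
                  type = "gzip"),
    error = function(e) {
      abort_io(sprintf(
        "corrupt payload block for chromosome '%s' scale '%s': %s",
        chrom, scale, conditionMessage(e)
      ))
    }
  )
  doc <- tryCatch(
    xml2::read_xml(bytes),
    error = function(e) {
      abort_io(sprintf(
        "unparseable payload block for chromosome '%s' scale '%s'",
        chrom, scale
      ))
    }
  )
  doc
}

orthonormalize <- function(axes) {
  e1 <- axes[, 1:3, drop = FALSE]
  e2 <- axes[, 4:6, drop = FALSE]
  e1 <- e1 / sqrt(rowSums(e1^2))
  d <- rowSums(e1 * e2)
  e2 <- e2 - e1 * d
  e2 <- e2 / sqrt(rowSums(e2^2))
  e3 <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  cbind(e1, e2, e3)
}

parse_block_elements <- function(doc, scale) {
  if (scale == "nucleosome") {
    nodes <- xml2::xml_find_all(doc, "./n")
    axes_txt <- xml2::xml_attr(nodes, "a")
    axes <- do.call(rbind, lapply(strsplit(axes_txt, " ", fixed = TRUE),
                                  as.numeric))
    dplyr::bind_cols(
      tibble(
        start = as.numeric(xml2::xml_attr(nodes, "s")),
        linker_bp_after = as.numeric(xml2::xml_attr(nodes, "k")),
        x = as.numeric(xml2::xml_attr(nodes, "x")),
        y = as.numeric(xml2::xml_attr(nodes, "y")),
        z = as.numeric(xml2::xml_attr(nodes, "z"))
      ),
      stats::setNames(
        as_tibble(as.data.frame(orthonormalize(axes))), frame_axis_cols
      )
    )
  } else {
    nodes <- xml2::xml_find_all(doc, "./p")
    loop <- xml2::xml_attr(nodes, "l")
    tibble(
      bp = as.numeric(xml2::xml_attr(nodes, "b")),
      x = as.numeric(xml2::xml_attr(nodes, "x")),
      y = as.numeric(xml2::xml_attr(nodes, "y")),
      z = as.numeric(xml2::xml_attr(nodes, "z")),
      loop = as.integer(loop)
    )
  }
}

# Decode a full (chromosome, scale) payload into its element tibble,
# memoizing in the store cache.
store_scale <- function(store, chrom, scale) {
  key <- paste(chrom, scale, sep = "\r")
  cached <- store$cache[[key]]
  if (!is.null(cached)) return(cached)
  entry <- store$manifest$files[[chrom]][[scale]]
  raw <- store_read_raw(store, chrom, scale)
  parts <- purrr::map(seq_len(nrow(entry$blocks)), function(b) {
    parse_block_elements(
      decode_block(raw, entry$blocks[b, ], chrom, scale), scale
    )
  })
  tab <- purrr::list_rbind(parts)
  tab <- finalize_scale_tab(store, chrom, scale, tab)
  store$cache[[key]] <- tab
  tab
}

finalize_scale_tab <- function(store, chrom, scale, tab) {
  len <- store$manifest$chromosomes$length[
    store$manifest$chromosomes$chrom == chrom
  ]
  params <- store$manifest$params
  if (scale == "nucleosome") {
    tab <- dplyr::bind_cols(
      tibble(record = seq_len(nrow(tab)), start = tab$start,
             wrap_bp = params$superhelix$wrap_bp,
             linker_bp_after = tab$linker_bp_after),
      tab[c("x", "y", "z", frame_axis_cols)]
    )
    structure(tab, chrom_length_bp = len, superhelix = params$superhelix,
              nucleosomes_per_turn = params$nucleosomes_per_turn,
              class = c("nucleosome_set", class(tab)))
  } else if (scale == "nuclear") {
    tab <- dplyr::bind_cols(tibble(point = seq_len(nrow(tab))), tab)
    structure(tab, chrom_length_bp = len, params = params$nuclear,
              class = c("nuclear_path", class(tab)))
  } else {
    tab <- dplyr::bind_cols(tibble(point = seq_len(nrow(tab))),
                            tab[setdiff(names(tab), "loop")])
    structure(tab, chrom_length_bp = len,
              bp_per_point = params$bp_per_point,
              jitter_nm = params$jitter_nm,
              nucleus_radius_nm = params$nuclear$nucleus_radius_nm,
              class = c("fiber_path", class(tab)))
  }
}

#' Materialize a lazily-read store as a genome model
#'
#' Loads every scale of every chromosome and reassembles a `genome_model`
#' equal (to the store's stated precision) to the model that was written.
#'
#' @param store A [read_model()] result.
#' @return A `genome_model`.
#' @export
as_genome_model <- function(store) {
  chroms <- stats::setNames(
    purrr::map(store$manifest$chromosomes$chrom, function(nm) {
      list(
        nuclear = store_scale(store, nm, "nuclear"),
        fiber = store_scale(store, nm, "fiber"),
        nucleosomes = store_scale(store, nm, "nucleosome")
      )
    }),
    store$manifest$chromosomes$chrom
  )
  structure(
    list(
      manifest = list(
        genome = store$manifest$genome,
        chromosomes = store$manifest$chromosomes,
        seed = store$manifest$seed,
        params = store$manifest$params
      ),
      chromosomes = chroms
    ),
    class = "genome_model"
  )
}

#' Load the elements of one scale overlapping a range
#'
#' Uses the manifest's block index to decompress only the blocks whose bp
#' span intersects the query. Returns exactly the elements whose bp span
#' intersects `[start, end)`: nucleosome records own
#' `[start, start + wrap + linker)`; for point scales, the points bounding
#' any intersected path segment are returned.
#'
#' @param store A [read_model()] result.
#' @param range A [genomic_range()].
#' @param scale `"nuclear"`, `"fiber"` or `"nucleosome"`.
#' @return Element tibble (subset of the eager [store_scale] table).
#' @export
load_range <- function(store, range,
                       scale = c("nuclear", "fiber", "nucleosome")) {
  scale <- match.arg(scale)
  entry <- store$manifest$files[[range$chrom]][[scale]]
  if (is.null(entry)) {
    abort_range(sprintf("unknown chromosome '%s'", range$chrom))
  }
  len <- store$manifest$chromosomes$length[
    store$manifest$chromosomes$chrom == range$chrom
  ]
  if (range$end > len) {
    abort_range(sprintf("range end %s exceeds chromosome length %s",
                        fmt_bp(range$end), fmt_bp(len)))
  }
  blocks <- entry$blocks
  sel <- which(blocks$e > range$start & blocks$s < range$end)
  if (length(sel) == 0L) {
    full <- store_scale(store, range$chrom, scale)
    return(full[0, ])
  }
  # include one block either side so flanking point elements are available
  sel <- unique(pmin(pmax(c(min(sel) - 1L, sel, max(sel) + 1L), 1L),
                     nrow(blocks)))
  raw <- store_read_raw(store, range$chrom, scale)
  parts <- purrr::map(sel, function(b) {
    parse_block_elements(decode_block(raw, blocks[b, ], range$chrom, scale),
                         scale)
  })
  tab <- purrr::list_rbind(parts)
  first_index <- sum(blocks$n[seq_len(min(sel) - 1L)])
  if (scale == "nucleosome") {
    span_end <- tab$start + store$manifest$params$superhelix$wrap_bp +
      tab$linker_bp_after
    keep <- span_end > range$start & tab$start < range$end
  } else {
    anchors <- tab$bp
    nn <- length(anchors)
    seg_hit <- anchors[-nn] < range$end & anchors[-1L] > range$start
    keep <- c(seg_hit, FALSE) | c(FALSE, seg_hit)
  }
  tab <- tab[keep, , drop = FALSE]
  full <- finalize_scale_tab(store, range$chrom, scale, tab)
  idcol <- if (scale == "nucleosome") "record" else "point"
  full[[idcol]] <- full[[idcol]] + first_index + which(keep)[1L] - 1L
  full
}

#' Storage accounting against the naive atomic representation
#'
#' Measures the compressed store, extrapolates its per-bp cost to a full
#' genome, and reports the compression ratio relative to [naive_bytes()].
#'
#' @param store A [read_model()] result (or a store directory path).
#' @param params A [storage_params()] object.
#' @return A one-row tibble: `stored_bytes`, `modeled_bp`,
#'   `stored_bytes_per_bp`, `extrapolated_genome_bytes`,
#'   `compression_ratio`, `naive_bytes`.
#' @export
storage_stats <- function(store, params = storage_params()) {
  if (is.character(store)) store <- read_model(store)
  if (nrow(store$manifest$chromosomes) == 0L) {
    abort_argument("store contains no chromosomes")
  }
  stored <- store_payload_bytes(store)
  modeled_bp <- sum(store$manifest$chromosomes$length)
  per_bp <- stored / modeled_bp
  extrapolated <- per_bp * params$genome_bp
  tibble(
    stored_bytes = stored,
    modeled_bp = modeled_bp,
    stored_bytes_per_bp = per_bp,
    extrapolated_genome_bytes = extrapolated,
    compression_ratio = naive_bytes(params) / extrapolated,
    naive_bytes = naive_bytes(params)
  )
}

#' @export
glance.genome_store <- function(x, ...) storage_stats(x)
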