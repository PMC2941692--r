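# Seeded generators for every input the toolkit consumes: chromosome
# length tables (+ optional FASTA), statistically plausible nucleosome
# position lists, and annotation tracks (SNPs, TSSs, binding sites, WIG
# scores, signed expression). Every generator is a pure function of its
# arguments and seed, so tests and demos run fully offline.

#' Generate a synthetic chromosome length table
#'
#' @param n_chrom Number of chromosomes (0 gives an empty table).
#' @param length_mean,length_sd Lognormal-ish length distribution in bp
#'   (draws are `round(rnorm)` clamped to `min_length`).
#' @param min_length Smallest allowed chromosome (default one nucleosome
#'   repeat plus wrap).
#' @param lengths Optional explicit length vector (overrides the draw).
#' @param seed Integer seed.
#' @param fasta Optional path: writes a random-sequence FASTA whose
#'   sequence lengths equal the table lengths (requires Biostrings).
#' @return A tibble: `chrom` (`chr1`, `chr2`, ...), `length` (bp).
#' @export
synth_genome <- function(n_chrom = 1L, length_mean = 1e6, length_sd = 0,
                         min_length = 400, lengths = NULL, seed = 1L,
                         fasta = NULL) {
  check_count(n_chrom, "n_chrom")
  check_count(seed, "seed")
  if (!is.null(lengths)) {
    n_chrom <- length(lengths)
    lens <- as.numeric(lengths)
  } else if (n_chrom == 0L) {
    lens <- numeric(0)
  } else {
    lens <- with_seed(seed, {
      pmax(round(stats::rnorm(n_chrom, length_mean, length_sd)), min_length)
    })
  }
  tab <- tibble(chrom = paste0("chr", seq_len(n_chrom)), length = lens)
  if (!is.null(fasta) && n_chrom > 0L) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      abort_argument("FASTA output requires the Biostrings package")
    }
    seqs <- with_seed(seed + 1L, {
      purrr::map_chr(lens, function(L) {
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              collapse = "")
      })
    })
    ss <- Biostrings::DNAStringSet(seqs)
    names(ss) <- tab$chrom
    Biostrings::writeXStringSet(ss, fasta)
  }
  tab
}

#' Read / write a chromosome length table
#'
#' Two-column tab-separated text: chromosome name, length in bp.
#'
#' @param path File path.
#' @return A tibble with `chrom` and `length`.
#' @export
read_chrom_table <- function(path) {
  if (!file.exists(path)) {
    abort_io(sprintf("missing chromosome length table '%s'", path))
  }
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  as_tibble(df)
}

#' @rdname read_chrom_table
#' @param tab A chromosome table tibble.
#' @export
write_chrom_table <- function(tab, path) {
  writeLines(sprintf("%s\t%s", tab$chrom, fmt_bp(tab$length)), path)
  invisible(path)
}

#' Generate statistically plausible nucleosome start positions
#'
#' Successive repeat lengths are drawn from a truncated normal
#' (`max(157, round(rnorm(repeat_mean, jitter_sd)))`), which keeps
#' nucleosomes non-overlapping with at least a 10 bp linker while the mean
#' repeat stays at `repeat_mean` for modest jitter.
#'
#' @param chrom_length Chromosome length in bp.
#' @param repeat_mean Mean repeat length in bp (>= 157).
#' @param jitter_sd Repeat-length standard deviation in bp.
#' @param seed Integer seed.
#' @param chrom Chromosome name for the output.
#' @return A BED3 tibble of 147 bp wrap intervals: `chrom`, `start`, `end`.
#' @export
synth_nucleosome_positions <- function(chrom_length, repeat_mean = 200,
                                       jitter_sd = 0, seed = 1L,
                                       chrom = "chr1") {
  check_count(chrom_length, "chrom_length", 147)
  if (repeat_mean < 157) {
    abort_argument("`repeat_mean` must be >= 157 (147 bp wrap + linker)")
  }
  check_number(jitter_sd, "jitter_sd", 0)
  n_max <- ceiling(chrom_length / 157) + 1L
  starts <- with_seed(seed, {
    reps <- if (jitter_sd > 0) {
      pmax(157, round(stats::rnorm(n_max, repeat_mean, jitter_sd)))
    } else {
      rep(repeat_mean, n_max)
    }
    cumsum(c(0, reps))
  })
  starts <- starts[starts + 147 <= chrom_length]
  tibble(chrom = chrom, start = starts, end = starts + 147)
}

#' Generate synthetic annotation tracks
#'
#' Emulates the demonstration inputs: single-bp SNPs, TSS positions with
#' signed expression values (zero-mean normal log-ratios), binding sites a
#' configurable fraction of which is planted within the proximity
#' threshold of a TSS, and a fixedStep WIG score track.
#'
#' @param chrom_length Chromosome length in bp.
#' @param chrom Chromosome name.
#' @param n_snps,n_tss,n_sites Feature counts.
#' @param near_fraction Expected fraction of binding sites planted within
#'   `threshold_bp` of a TSS (per-site Bernoulli draw).
#' @param threshold_bp Proximity threshold used for planting.
#' @param site_width Binding-site width in bp.
#' @param expr_sd Standard deviation of the signed expression log-ratios.
#' @param wig_step,wig_n fixedStep geometry of the score track.
#' @param seed Integer seed.
#' @return A list of tibbles: `snps`, `tss`, `sites`, `wig`, `expression`.
#' @export
synth_tracks <- function(chrom_length, chrom = "chr1",
                         n_snps = 10L, n_tss = 20L, n_sites = 40L,
                         near_fraction = 0.5, threshold_bp = 10000,
                         site_width = 20L, expr_sd = 1,
                         wig_step = 1000, wig_n = 50L, seed = 1L) {
  check_count(chrom_length, "chrom_length", 1)
  check_number(near_fraction, "near_fraction", 0)
  if (near_fraction > 1) abort_argument("`near_fraction` must be <= 1")
  with_seed(seed, {
    snp_pos <- sort(sample.int(chrom_length, n_snps)) - 1
    snps <- tibble(
      chrom = chrom, start = as.numeric(snp_pos), end = snp_pos + 1,
      name = sprintf("rs%06d", sample.int(999999L, n_snps)),
      score = NA_real_, strand = "."
    )
    tss_pos <- sort(sample.int(chrom_length, n_tss)) - 1
    expression <- tibble(
      gene = sprintf("gene%03d", seq_len(n_tss)),
      chrom = chrom,
      tss = as.numeric(tss_pos),
      log_ratio = stats::rnorm(n_tss, 0, expr_sd)
    )
    tss <- tibble(
      chrom = chrom, start = as.numeric(tss_pos), end = tss_pos + 1,
      name = expression$gene, score = expression$log_ratio, strand = "."
    )
    near <- stats::runif(n_sites) < near_fraction
    site_mid <- numeric(n_sites)
    for (i in seq_len(n_sites)) {
      # margins of one site width keep the planted class stable against
      # midpoint shifts from width rounding and chromosome-end clamping
      if (near[i] && n_tss > 0L) {
        anchor <- sample(tss_pos, 1L)
        site_mid[i] <- anchor +
          sample((-threshold_bp + site_width):(threshold_bp - site_width),
                 1L)
        site_mid[i] <- min(max(site_mid[i], 0), chrom_length - 1)
      } else {
        ok <- FALSE
        for (try in seq_len(200L)) {
          cand <- sample.int(chrom_length, 1L) - 1
          if (n_tss == 0L ||
              min(abs(cand - tss_pos)) >= threshold_bp + site_width) {
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          # farthest midpoint between sorted TSSs as a deterministic
          # fallback on short chromosomes
          gaps <- diff(c(0, tss_pos, chrom_length - 1))
          gi <- which.max(gaps)
          cand <- round(c(0, tss_pos, chrom_length - 1)[gi] + gaps[gi] / 2)
        }
        site_mid[i] <- cand
      }
    }
    site_start <- pmax(0, round(site_mid - site_width / 2))
    sites <- tibble(
      chrom = chrom, start = site_start,
      end = pmin(site_start + site_width, chrom_length),
      name = sprintf("site%03d", seq_len(n_sites)),
      score = NA_real_, strand = "."
    )
    wig_n <- min(wig_n, floor(chrom_length / wig_step))
    wstart <- (seq_len(wig_n) - 1) * wig_step
    wig <- tibble(
      chrom = chrom, start = wstart, end = wstart + wig_step,
      value = round(stats::rnorm(wig_n, 0, 1), 4),
      mode = "fixedStep"
    )
    list(snps = snps, tss = tss, sites = sites, wig = wig,
         expression = expression)
  })
}
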