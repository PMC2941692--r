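# Compressed-XML store: round trips, determinism, lazy/range loading and
# storage accounting.

write_tmp_store <- function(model) {
  d <- withr::local_tempdir(.local_envir = parent.frame())
  write_model(model, d)
  d
}

expect_model_roundtrip <- function(m) {
  d <- withr::local_tempdir()
  write_model(m, d)
  m2 <- as_genome_model(read_model(d))
  for (nm in names(m$chromosomes)) {
    a <- m$chromosomes[[nm]]
    b <- m2$chromosomes[[nm]]
    # coordinates at the stated 3-decimal nm precision
    for (sc in c("nuclear", "fiber")) {
      expect_equal(a[[sc]]$bp, b[[sc]]$bp)
      expect_lt(max(abs(as.matrix(a[[sc]][, c("x", "y", "z")]) -
                          as.matrix(b[[sc]][, c("x", "y", "z")]))), 5e-4)
    }
    expect_identical(a$nucleosomes$start, b$nucleosomes$start)
    expect_identical(a$nucleosomes$linker_bp_after,
                     b$nucleosomes$linker_bp_after)
    expect_lt(max(abs(as.matrix(a$nucleosomes[, c("x", "y", "z")]) -
                        as.matrix(b$nucleosomes[, c("x", "y", "z")]))),
              5e-4)
    expect_lt(max(abs(as.matrix(a$nucleosomes[, frame_cols()[-(1:3)]]) -
                        as.matrix(b$nucleosomes[, frame_cols()[-(1:3)]]))),
              5e-3)
    validate_frames(b$nucleosomes)
  }
  expect_equal(m$manifest$chromosomes, m2$manifest$chromosomes)
  expect_equal(m$manifest$seed, m2$manifest$seed)
}

test_that("write then read reproduces generated models", {
  expect_model_roundtrip(small_model(seed = 1))
  expect_model_roundtrip(tiny_model(seed = 31))
  # two chromosomes of different lengths
  g <- synth_genome(lengths = c(15000, 24000), seed = 12)
  m <- build_genome_model(
    g, seed = 12,
    nuclear = nuclear_params(loop_size_bp = 6e4, step_bp = 6e3,
                             nucleus_radius_nm = 2000)
  )
  expect_model_roundtrip(m)
})

test_that("writing the same model twice is byte-identical", {
  m <- small_model(seed = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_model(m, d1)
  write_model(m, d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     label = f)
  }
})

test_that("an empty chromosome list yields a valid empty manifest", {
  d <- withr::local_tempdir()
  m <- build_genome_model(synth_genome(n_chrom = 0), seed = 1)
  write_model(m, d)
  st <- read_model(d)
  expect_equal(nrow(st$manifest$chromosomes), 0)
  expect_error(storage_stats(st), class = "chromo3d_error_argument")
})

test_that("scale payloads load lazily and are access-logged", {
  m <- small_model(seed = 6)
  d <- write_tmp_store(m)
  st <- read_model(d)
  expect_length(st$access_log, 0)
  invisible(load_range(st, genomic_range("chr1", 0, 200), "nucleosome"))
  expect_identical(unique(st$access_log), "chr1.nucleosome.xml.gz")
})

test_that("range loading matches eager loading", {
  m <- small_model(seed = 6, repeat_bp = 200)
  d <- write_tmp_store(m)
  st <- read_model(d)
  len <- st$manifest$chromosomes$length

  one <- load_range(st, genomic_range("chr1", 0, 200), "nucleosome")
  expect_equal(nrow(one), 1)
  expect_equal(one$record, 1L)

  mid <- load_range(st, genomic_range("chr1", 1000, 1200), "nucleosome")
  expect_equal(nrow(mid), 1)
  expect_equal(mid$start, 1000)

  st2 <- read_model(d)
  for (sc in c("nuclear", "fiber", "nucleosome")) {
    full <- load_range(st2, genomic_range("chr1", 0, len), sc)
    eager <- as_genome_model(read_model(d))$chromosomes$chr1[[
      switch(sc, nucleosome = "nucleosomes", nuclear = "nuclear",
             fiber = "fiber")
    ]]
    expect_equal(as.data.frame(full), as.data.frame(eager), tolerance = 0)
  }
})

test_that("corrupt and missing payloads fail with named errors", {
  m <- small_model(seed = 8)
  d <- write_tmp_store(m)
  # truncate the nucleosome payload mid-stream
  f <- file.path(d, "chr1.nucleosome.xml.gz")
  raw <- readBin(f, "raw", file.size(f))
  writeBin(raw[1:(length(raw) %/% 2)], f)
  st <- read_model(d)
  expect_error(load_range(st, genomic_range("chr1", 0, 2e4), "nucleosome"),
               "chr1.*nucleosome", class = "chromo3d_error_io")

  file.remove(f)
  st2 <- read_model(d)
  err <- tryCatch(load_range(st2, genomic_range("chr1", 0, 100),
                             "nucleosome"),
                  error = function(e) conditionMessage(e))
  expect_match(err, "chr1.nucleosome.xml.gz", fixed = TRUE)
})

test_that("incompatible store versions are refused", {
  m <- tiny_model(seed = 9)
  d <- write_tmp_store(m)
  mf <- file.path(d, "manifest.xml")
  txt <- sub('version="1.0"', 'version="9.9"', readLines(mf))
  writeLines(txt, mf)
  expect_error(read_model(d), "9\\.9", class = "chromo3d_error_format")
  expect_error(read_model(withr::local_tempdir()),
               class = "chromo3d_error_io")
})

test_that("naive storage arithmetic multiplies the stated factors", {
  expect_equal(naive_bytes(), 7.2e11)
  expect_equal(naive_bytes(storage_params(genome_bp = 1)), 240)
  expect_error(storage_params(atoms_per_bp = 0),
               class = "chromo3d_error_argument")
  expect_error(storage_params(genome_bp = 2.5),
               class = "chromo3d_error_argument")
})

test_that("storage statistics are internally consistent", {
  m <- small_model(seed = 10)
  d <- write_tmp_store(m)
  st <- read_model(d)
  s <- storage_stats(st)
  # manifest byte totals equal the on-disk payload sizes
  payloads <- setdiff(list.files(d), "manifest.xml")
  expect_equal(s$stored_bytes,
               sum(file.size(file.path(d, payloads))))
  expect_equal(s$stored_bytes_per_bp, s$stored_bytes / s$modeled_bp)
  expect_equal(s$extrapolated_genome_bytes,
               s$stored_bytes_per_bp * 3e9)
  expect_equal(s$compression_ratio,
               naive_bytes() / s$extrapolated_genome_bytes)
  # ratio is inversely proportional to the stored cost: doubling the
  # naive atom budget doubles it
  s2 <- storage_stats(st, storage_params(genome_bp = 3e9,
                                         atoms_per_bp = 40))
  expect_equal(s2$compression_ratio, 2 * s$compression_ratio)
})
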