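# Projection onto model elements, SNP phasing, proximity rule, colors.

test_that("coverage projection conserves annotated bp exactly", {
  m <- tiny_model(len = 2000)
  bed <- tibble::tibble(chrom = "chr1", start = 100, end = 1100)
  for (scale in c("nuclear", "fiber", "nucleosome")) {
    ann <- project(bed, m, scale = scale, aggregation = "coverage")
    expect_identical(sum(ann$coverage_bp), 1000)
  }
  # randomized interval sets, clipped to the model span
  for (seed in c(2, 5)) {
    set.seed(seed)
    n <- 20
    s <- sample(0:2100, n, replace = TRUE)
    bed <- tibble::tibble(chrom = "chr1", start = s,
                          end = s + sample(1:400, n, replace = TRUE))
    clipped <- sum(pmin(bed$end, 2000) - pmin(bed$start, 2000))
    ann <- project(bed, m, scale = "nucleosome",
                   aggregation = "coverage")
    expect_identical(sum(ann$coverage_bp), clipped)
  }
})

test_that("projection matches a per-bp brute-force oracle", {
  m <- tiny_model(len = 2000)
  set.seed(13)
  s <- sample(0:1900, 8)
  bed <- tibble::tibble(chrom = "chr1", start = s, end = s + 60,
                        score = rnorm(8))
  els <- scale_elements(m, "chr1", "nucleosome")
  # oracle: assign every bp its summed score, then aggregate per element
  per_bp_cov <- integer(2000)
  per_bp_val <- numeric(2000)
  for (i in seq_len(nrow(bed))) {
    idx <- (bed$start[i] + 1):min(bed$end[i], 2000)
    per_bp_cov[idx] <- per_bp_cov[idx] + 1L
    per_bp_val[idx] <- per_bp_val[idx] + bed$score[i]
  }
  cov <- project(bed, m, scale = "nucleosome", aggregation = "coverage")
  sums <- project(bed, m, scale = "nucleosome", aggregation = "sum")
  for (j in seq_len(nrow(els))) {
    idx <- (els$bp_start[j] + 1):els$bp_end[j]
    expect_equal(cov$coverage_bp[j], sum(per_bp_cov[idx]))
    expect_equal(sums$value[j],
                 if (sum(per_bp_cov[idx]) == 0) NA_real_ else
                   sum(per_bp_val[idx]),
                 tolerance = 1e-12)
  }
})

test_that("an interval spanning one wrap covers exactly its 147 bp", {
  m <- tiny_model(len = 2000)
  recs <- m$chromosomes$chr1$nucleosomes
  bed <- tibble::tibble(chrom = "chr1", start = recs$start[3],
                        end = recs$start[3] + 147)
  ann <- project(bed, m, scale = "nucleosome", aggregation = "coverage")
  wrap_row <- ann[ann$type == "nucleosome" & ann$element == 3, ]
  expect_identical(wrap_row$coverage_bp, 147)
  expect_identical(sum(ann$coverage_bp), 147)
})

test_that("WIG values project with bp-weighted aggregation", {
  m <- tiny_model(len = 2000)
  wig <- parse_wig("fixedStep chrom=chr1 start=1 step=100 span=100\n1\n2\n3\n4")
  mean_ann <- project(wig, m, scale = "nucleosome", aggregation = "mean")
  max_ann <- project(wig, m, scale = "nucleosome", aggregation = "max")
  # first wrap [0,147) sees values 1 (100 bp) and 2 (47 bp)
  w1 <- mean_ann[mean_ann$type == "nucleosome" & mean_ann$element == 1, ]
  expect_equal(w1$value, (100 * 1 + 47 * 2) / 147)
  m1 <- max_ann[max_ann$type == "nucleosome" & max_ann$element == 1, ]
  expect_equal(m1$value, 2)
  expect_error(project(wig, m, scale = "nucleosome", aggregation = "mode"),
               class = "chromo3d_error_argument")
  expect_error(project(wig, m, chrom = "chrZ", scale = "fiber"),
               class = "chromo3d_error_range")
})

test_that("SNP phasing locates offsets, angles and linkers", {
  m <- tiny_model(len = 2000)
  recs <- m$chromosomes$chr1$nucleosomes
  snps <- tibble::tibble(
    chrom = "chr1",
    start = c(recs$start[2], recs$start[2] + 5, recs$start[2] + 150),
    end = start + 1,
    name = c("s0", "s5", "slink")
  )
  rep <- snp_phase_report(snps, recs)
  expect_equal(rep$location, c("wrap", "wrap", "linker"))
  expect_equal(rep$offset_bp[1:2], c(0, 5))
  expect_equal(rep$phase_deg[1:2], c(0, phase_angle(5)))
  expect_equal(rep$record[1:2], c(2, 2))
  # axial position spans the superhelix extent symmetrically
  expect_equal(rep$axial_nm[1], -1.65 * 2.39 / 2)
  expect_error(
    snp_phase_report(tibble::tibble(chrom = "chr1", start = 0, end = 2,
                                    name = "bad"), recs),
    class = "chromo3d_error_validation"
  )
})

test_that("four SNPs inside one wrap report the same record", {
  g <- synth_genome(lengths = 7.7e6, seed = 2)
  m <- build_genome_model(g, seed = 2, positions = list(chr1 = 7602871))
  snps <- tibble::tibble(
    chrom = "chr1",
    start = 7602871 + c(10, 40, 90, 130),
    end = start + 1,
    name = paste0("snp", 1:4)
  )
  rep <- snp_phase_report(snps, m$chromosomes$chr1$nucleosomes)
  expect_equal(nrow(rep), 4)
  expect_equal(unique(rep$record), 1)
  expect_true(all(rep$location == "wrap"))
  expect_true(all(rep$phase_deg >= 0 & rep$phase_deg < 360))
})

test_that("the proximity rule is strict at the threshold", {
  tss <- tibble::tibble(chrom = "chr1", start = 50000, end = 50001)
  sites <- tibble::tibble(
    chrom = "chr1",
    start = c(55000, 60000, 50000, 39999) - 10,
    end = c(55000, 60000, 50000, 39999) + 10
  )
  cl <- proximity_classify(sites, tss)
  expect_equal(cl$distance_bp, c(5000, 10000, 0, 10001))
  expect_equal(cl$class, c("near", "far", "near", "far"))

  none <- proximity_classify(sites, tss[0, ])
  expect_true(all(none$class == "far"))
  expect_true(all(is.infinite(none$distance_bp)))

  # a TSS on another chromosome does not count
  cl2 <- proximity_classify(sites,
                            tibble::tibble(chrom = "chr9", start = 55000,
                                           end = 55001))
  expect_true(all(cl2$class == "far"))
})

test_that("signed colors are symmetric, monotone and neutral at zero", {
  v <- c(-4, -2, 0, 2, 4, NA)
  cols <- colorize(v, color_rule("signed"))
  expect_true(all(as.matrix(cols) >= 0 & as.matrix(cols) <= 1))
  expect_equal(as.numeric(cols[3, ]), c(0.5, 0.5, 0.5))
  expect_equal(as.numeric(cols[6, ]), c(0.5, 0.5, 0.5))
  # +v and -v mirror green/red at equal intensity
  expect_equal(cols$g[4], cols$r[2])
  expect_equal(cols$r[4], cols$g[2])
  # saturation monotone in |value|
  sat <- abs(cols$g - cols$r)
  expect_true(all(diff(sat[c(3, 4, 5)]) > 0))
  expect_equal(sat[1], sat[5])

  allz <- colorize(c(0, 0, 0))
  expect_true(all(as.matrix(allz) == 0.5))
  expect_error(colorize(c(1, Inf)), class = "chromo3d_error_argument")

  seqc <- colorize(1:5, color_rule("sequential"))
  expect_true(all(diff(seqc$b) > 0))
  catc <- colorize(c("a", "b", "a"), color_rule("categorical"))
  expect_equal(catc[1, ], catc[3, ])
})
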