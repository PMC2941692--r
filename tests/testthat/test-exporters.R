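# PDB / PovRay / XYZ emission: fixed columns, parse-back equivalence,
# primitive-count conservation.

test_that("a 147 bp selection yields 2940 fixed-column ATOM records", {
  m <- small_model()
  atoms <- synthesize_dna(m, genomic_range("chr1", 0, 147))
  f <- withr::local_tempfile(fileext = ".pdb")
  n <- write_pdb(atoms, f)
  expect_equal(n, 2940)
  lines <- readLines(f)
  expect_equal(length(lines), 2941)
  expect_identical(lines[length(lines)], "END")
  expect_true(all(substr(lines[-length(lines)], 1, 6) == "ATOM  "))
  expect_true(all(substr(lines[-length(lines)], 18, 19) == "DN"))
  expect_true(all(nchar(lines[-length(lines)]) == 78))
})

test_that("PDB coordinates are Angstrom at fixed 8.3 width", {
  atoms <- tibble::tibble(
    serial = 1L, name = "P", element = "P",
    x = 1, y = 2, z = 3, bp_index = 0L, strand = "W", base = "N"
  )
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(atoms, f, center = FALSE)
  line <- readLines(f)[1]
  expect_identical(substr(line, 31, 38), "  10.000")
  expect_identical(substr(line, 39, 46), "  20.000")
  expect_identical(substr(line, 47, 54), "  30.000")
  expect_identical(substr(line, 23, 26), "   1")
  expect_identical(substr(line, 77, 78), " P")
})

test_that("an independent PDB reader reproduces the coordinates", {
  m <- small_model(seed = 21)
  set.seed(2)
  for (i in 1:3) {
    s <- sample(0:1000, 1)
    atoms <- synthesize_dna(m, genomic_range("chr1", s, s + 80))
    f <- withr::local_tempfile(fileext = ".pdb")
    write_pdb(atoms, f)
    pdb <- bio3d::read.pdb(f)
    ctr <- colMeans(cbind(atoms$x, atoms$y, atoms$z)) * 10
    expect_equal(pdb$atom$x, atoms$x * 10 - ctr[1], tolerance = 6e-4)
    expect_equal(pdb$atom$y, atoms$y * 10 - ctr[2], tolerance = 6e-4)
    expect_equal(pdb$atom$z, atoms$z * 10 - ctr[3], tolerance = 6e-4)
    expect_equal(pdb$atom$elesy, atoms$element)
    expect_equal(unique(pdb$atom$resid), "DN")
  }
})

test_that("over-long selections refuse to overflow PDB serials", {
  frames <- propagate_bdna_frames(5001, frame())
  atoms <- place_atoms(frames)  # 100020 atoms
  expect_error(write_pdb(atoms, withr::local_tempfile()),
               "subdivide", class = "chromo3d_error_argument")
})

test_that("XYZ export round-trips through a plain reader", {
  m <- small_model()
  atoms <- synthesize_dna(m, genomic_range("chr1", 0, 10))
  f <- withr::local_tempfile(fileext = ".xyz")
  n <- write_xyz(atoms, f)
  expect_equal(n, 200)
  expect_equal(as.integer(readLines(f, 1)), 200)
  tab <- utils::read.table(f, skip = 2)
  expect_equal(tab$V2, round(atoms$x * 10, 3), tolerance = 1e-9)
  expect_equal(tab$V1, atoms$element)
})

test_that("PovRay output conserves primitive counts by type", {
  m <- tiny_model(len = 2000)
  scene <- scene_from_model(m, genomic_range("chr1", 0, 2000),
                            scale = "nucleosome")
  expect_equal(sum(scene$primitives$type == "cylinder"), 10)
  f <- withr::local_tempfile(fileext = ".pov")
  n <- write_povray(scene, f)
  expect_equal(n, nrow(scene$primitives))
  lines <- readLines(f)
  expect_equal(sum(grepl("cylinder {", lines, fixed = TRUE)), 10)
  expect_equal(sum(grepl("sphere {", lines, fixed = TRUE)), 0)
  expect_equal(sum(grepl("sphere_sweep {", lines, fixed = TRUE)), 9)
  expect_equal(sum(grepl("camera {", lines, fixed = TRUE)), 1)

  # determinism: identical text on re-export
  f2 <- withr::local_tempfile(fileext = ".pov")
  write_povray(scene_from_model(m, genomic_range("chr1", 0, 2000),
                                scale = "nucleosome"), f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("a 200 bp range renders exactly one NCP cylinder", {
  m <- tiny_model(len = 2000)
  scene <- scene_from_model(m, genomic_range("chr1", 0, 200),
                            scale = "nucleosome")
  expect_equal(sum(scene$primitives$type == "cylinder"), 1)
})

test_that("ten spheres emit exactly ten sphere tokens", {
  m <- tiny_model(len = 2000)
  scene <- scene_from_model(m, genomic_range("chr1", 0, 2000),
                            scale = "fiber")
  spheres <- sum(scene$primitives$type == "sphere")
  f <- withr::local_tempfile(fileext = ".pov")
  write_povray(scene, f)
  expect_equal(sum(grepl("sphere {", readLines(f), fixed = TRUE)), spheres)
})

test_that("degenerate cylinders fall back to spheres with a warning", {
  scene <- structure(
    list(
      primitives = dplyr::bind_rows(
        tibble::tibble(type = "cylinder", x1 = 0, y1 = 0, z1 = 0,
                       x2 = 0, y2 = 0, z2 = 0, radius = 1,
                       r = 0.5, g = 0.5, b = 0.5, points = list(NULL))
      ),
      camera = list(position = c(0, 0, 10), look_at = c(0, 0, 0)),
      lights = list(c(0, 0, 10))
    ),
    class = "scene"
  )
  f <- withr::local_tempfile(fileext = ".pov")
  expect_warning(write_povray(scene, f), "degenerate")
  expect_equal(sum(grepl("sphere {", readLines(f), fixed = TRUE)), 1)

  empty <- scene
  empty$primitives <- empty$primitives[0, ]
  expect_error(write_povray(empty, f), class = "chromo3d_error_argument")
})

test_that("annotation colors pass through to scene primitives", {
  m <- tiny_model(len = 2000)
  wig <- tibble::tibble(chrom = "chr1", start = 0, end = 2000,
                        value = 2)
  ann <- project(wig, m, scale = "nucleosome", aggregation = "mean")
  scene <- scene_from_model(m, genomic_range("chr1", 0, 2000),
                            scale = "nucleosome", annotation = ann)
  cyl <- scene$primitives[scene$primitives$type == "cylinder", ]
  wraps <- ann[ann$type == "nucleosome", ]
  expected <- colorize(wraps$value, color_rule("signed"))
  expect_equal(cyl$r, expected$r)
  expect_equal(cyl$g, expected$g)
  expect_equal(cyl$b, expected$b)
})

test_that("DNA-scale scenes enforce the range cap", {
  m <- small_model()
  expect_error(
    scene_from_model(m, genomic_range("chr1", 0, 5000), scale = "dna",
                     max_dna_bp = 1000),
    "1000", class = "chromo3d_error_range"
  )
  sc <- scene_from_model(m, genomic_range("chr1", 0, 20), scale = "dna")
  expect_equal(sum(sc$primitives$type == "sphere"), 400)
})

test_that("TSS and binding-site overlays follow the proximity colors", {
  m <- small_model(len = 5e4)
  tss <- tibble::tibble(chrom = "chr1", start = 25000, end = 25001,
                        value = 1.5)
  sites <- tibble::tibble(chrom = "chr1",
                          start = c(26000, 45000), end = c(26020, 45020))
  scene <- scene_from_model(m, genomic_range("chr1", 0, 5e4),
                            scale = "nucleosome", tss = tss, sites = sites)
  boxes <- scene$primitives[scene$primitives$type == "box", ]
  expect_equal(nrow(boxes), 2)
  # near site orange, far site yellow
  expect_equal(boxes$r, c(1, 1))
  expect_lt(boxes$g[1], boxes$g[2])
})
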