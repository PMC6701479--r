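test_that("bead PDB + sidecar round-trips coordinates, labels and bonds", {
  m <- default_full()
  pdb <- tempfile(fileext = ".pdb")
  sc <- tempfile(fileext = ".csv")
  write_bead_pdb(m, pdb, sc)
  m2 <- read_bead_pdb(pdb, sc)
  expect_lt(max(abs(m2$xyz - unname(m$xyz))), 1e-3)
  expect_identical(m2$chain, m$chain)
  expect_identical(m2$domain, m$domain)
  expect_identical(m2$rigid, m$rigid)
  expect_identical(bond_list(m2), bond_list(m))
})

test_that("minimal two-bead PDB reads into a one-domain model", {
  pdb <- tempfile(fileext = ".pdb")
  sc <- tempfile(fileext = ".csv")
  write_bead_pdb(toy_two_beads(), pdb, sc)
  m <- read_bead_pdb(pdb, sc)
  expect_equal(nrow(m$xyz), 2)
  expect_equal(nrow(m$domains), 1)
  expect_true(m$domains$rigid[1])
})

test_that("incomplete sidecar coverage raises a labeling error", {
  m <- toy_two_beads()
  pdb <- tempfile(fileext = ".pdb")
  sc <- tempfile(fileext = ".csv")
  write_bead_pdb(m, pdb, sc)
  tab <- read.csv(sc)
  tab$end <- 1 # covers only the first of two residues
  write.csv(tab, sc, row.names = FALSE)
  expect_error(read_bead_pdb(pdb, sc), "labeling error")
})

test_that("non-monotone residue numbering raises a format error", {
  pdb <- tempfile(fileext = ".pdb")
  sc <- tempfile(fileext = ".csv")
  write_bead_pdb(toy_two_beads(), pdb, sc)
  lines <- readLines(pdb)
  substr(lines[2], 23, 26) <- "   1" # duplicate residue number
  writeLines(lines, pdb)
  expect_error(read_bead_pdb(pdb, sc), "format error")
})

test_that("center of mass matches closed forms and a sampling bound", {
  m <- toy_two_beads(d = 2)
  expect_equal(center_of_mass(m), c(1, 0, 0))
  one <- bead_model(matrix(c(3, -1, 7), 1), "A", "D", c(D = TRUE))
  expect_equal(center_of_mass(one), c(3, -1, 7))
  expect_error(center_of_mass(m, domain = "missing"), "selection error")
  x <- sphere_beads(n = 1000, R = 50)
  expect_lt(sqrt(sum(colMeans(x)^2)), 3 * 50 / sqrt(1000))
})

test_that("radius of gyration matches closed forms and is rigid-invariant", {
  expect_equal(radius_of_gyration(toy_two_beads(d = 2)), 1.0)
  # uniform solid sphere: Rg = sqrt(3/5) R
  x <- sphere_beads(n = 4000, R = 50)
  expect_equal(radius_of_gyration(x), sqrt(3 / 5) * 50, tolerance = 0.02)
  m <- default_core()
  R <- random_rotation(3)
  moved <- set_coords(m, sweep(m$xyz %*% t(R), 2, c(11, -5, 2), "+"))
  expect_equal(radius_of_gyration(moved), radius_of_gyration(m),
               tolerance = 1e-9)
  com0 <- center_of_mass(m)
  expect_equal(center_of_mass(moved), drop(R %*% com0) + c(11, -5, 2),
               tolerance = 1e-9)
})

test_that("domain partition invariants are enforced", {
  expect_error(
    bead_model(matrix(0, 3, 3), c("A", "A", "A"), c("D1", "D2", "D1"),
               rigid = c(D1 = TRUE, D2 = TRUE)),
    "not contiguous")
  expect_error(
    bead_model(matrix(0, 2, 3), c("A", "A"), c("D1", "D1"),
               rigid = c(OTHER = TRUE)),
    "labeling error")
})
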