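test_that("quality filters enforce R-free, canonical residues, one chain", {
  ok <- list(r_free = 0.20, canonical = TRUE, n_chains = 1L)
  expect_true(passes_filters(ok))
  expect_false(passes_filters(modifyList(ok, list(r_free = 0.21))))
  expect_false(passes_filters(modifyList(ok, list(n_chains = 2L))))
  expect_false(passes_filters(modifyList(ok, list(canonical = FALSE))))
  expect_message(
    expect_false(passes_filters(modifyList(ok, list(r_free = NA)))),
    "R-free")
})

test_that("PDB loading extracts the C-alpha trace, annotations and metadata", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_fixture(f)
  tr <- load_atomistic(f, "A")
  expect_equal(tr$sequence, c("A", "G", "L", "V", "S"))
  expect_equal(nrow(tr$xyz), 5L)
  expect_equal(tr$ss, c("C", "H", "H", "H", "C"))
  expect_equal(tr$meta$r_free, 0.195)
  expect_true(tr$meta$canonical)
  expect_equal(tr$meta$n_chains, 1L)

  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_fixture(f2, selenomet = TRUE)
  tr2 <- load_atomistic(f2, "A")
  expect_false(tr2$meta$canonical)
  expect_equal(tr2$sequence[3L], "X")

  f3 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_fixture(f3, two_chains = TRUE)
  expect_equal(load_atomistic(f3, "A")$meta$n_chains, 2L)
})

test_that("a straight 3.8 A trace maps to a collinear lattice chain", {
  n <- 8L
  xyz <- cbind(3.8 * (0:(n - 1)) / sqrt(3), 3.8 * (0:(n - 1)) / sqrt(3),
               3.8 * (0:(n - 1)) / sqrt(3))
  tr <- list(sequence = rep("A", n), xyz = xyz, ss = rep("C", n))
  s <- fit_to_lattice(tr)
  expect_true(validate_structure(s))
  expect_equal(s$coords, matrix(rep(0:(n - 1), 3), n), ignore_attr = TRUE)
  expect_lt(attr(s, "rmsd"), 1e-6)
})

test_that("lattice fitting preserves sequence and bounds the RMSD", {
  set.seed(11)
  ref <- random_saw(20L)
  xyz <- ref$coords * lattice_scale()
  xyz <- xyz + matrix(rnorm(length(xyz), 0, 0.6), ncol = 3L)  # ~0.6 A jitter
  tr <- list(sequence = ref$sequence, xyz = xyz, ss = rep("C", 20L))
  s <- fit_to_lattice(tr)
  expect_true(validate_structure(s))
  expect_equal(s$sequence, ref$sequence)
  expect_equal(s$n_res, 20L)
  expect_lt(attr(s, "rmsd"), 2 * 3.8)
})

test_that("helical segments are fitted as intact lattice helices", {
  # atomistic positions: an exact lattice helix in physical units
  n <- 9L
  hc <- lattice_helix(n)
  tr <- list(sequence = rep("A", n), xyz = hc * lattice_scale(),
             ss = rep("H", n))
  s <- fit_to_lattice(tr)
  expect_true(validate_structure(s))
  # one regular turn per five residues: i and i+4 differ by a pure axis
  # translation of 4 lattice units
  for (i in seq_len(n - 4L)) {
    d <- s$coords[i + 4L, ] - s$coords[i, ]
    expect_equal(sort(abs(d)), c(0L, 0L, 4L))
  }
  expect_lt(attr(s, "rmsd"), 1e-6)
  # and the helix windows earn the secondary-structure bonus
  expect_equal(secondary_structure_energy(s, energy_params()),
               -25 * (n - 4L))
})

test_that("stretched peptides are maximally extended zig-zags", {
  s1 <- stretched_peptide("A")
  expect_equal(s1$coords, matrix(0L, 1L, 3L))
  s <- stretched_peptide(strrep("A", 40L))
  expect_true(validate_structure(s))
  expect_true(all(s$native_ss == "C"))
  # end-to-end distance of the alternating (1,1,1)/(1,1,-1) zig-zag
  n_bonds <- 39L
  up <- ceiling(n_bonds / 2)
  expected <- sqrt(n_bonds^2 + n_bonds^2 + (up - (n_bonds - up))^2) *
    lattice_scale()
  expect_equal(physical_distance(s$coords[1L, ], s$coords[40L, ]), expected)
  expect_error(stretched_peptide(character(0)), "empty")
})

test_that("structures round-trip through JSON and export to PDB", {
  s <- label_structure(stretched_peptide("KACDEFGHIK"), default_scheme("C"))
  f <- withr::local_tempfile(fileext = ".json")
  write_structure_json(s, f)
  s2 <- read_structure_json(f)
  expect_equal(s2$coords, s$coords)
  expect_equal(s2$sequence, s$sequence)
  expect_equal(s2$tags, s$tags)

  fp <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(s, fp)
  tr <- load_atomistic(fp, "A")
  expect_equal(tr$sequence, s$sequence)
  expect_equal(tr$xyz, s$coords * lattice_scale(), ignore_attr = TRUE,
               tolerance = 1e-3)
})
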