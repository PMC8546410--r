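test_that("FRET efficiency matches the Forster relation exactly", {
  cst <- fret_constants()
  expect_equal(fret_efficiency(54, cst), 0.5)
  expect_equal(fret_efficiency(27, cst), 64 / 65)
  expect_equal(fret_efficiency(108, cst), 1 / 65)
  r <- seq(1, 150, by = 0.5)
  expect_true(all(diff(fret_efficiency(r, cst)) < 0))
  expect_error(fret_efficiency(-1, cst), "non-negative")
})

test_that("snapshot sampling yields 100 valid conformations", {
  s <- label_structure(stretched_peptide("KAAAAAAAAAAAAAAC"),
                       default_scheme("C"))
  res <- fold(s, energy_params(), folding_config(max_iterations = 1000L),
              seed = 4)
  snaps <- sample_snapshots(res, seed = 5)
  expect_length(snaps, 100L)
  expect_true(all(vapply(snaps, validate_structure, logical(1))))
  bad <- res
  bad$hindrance_free <- FALSE
  expect_error(sample_snapshots(bad), "hindrance")
})

test_that("dye orientations are uniform over accessible directions", {
  s <- label_structure(stretched_peptide("KAC"), default_scheme("C"))
  cst <- fret_constants()
  set.seed(8)
  picks <- replicate(600, {
    p <- place_dyes(s, cst)
    off <- p$dye[p$channel == "C", ] - s$coords[3L, ] * lattice_scale()
    paste(sign(off), collapse = ",")
  })
  tab <- table(picks)
  expect_gte(length(tab), 4L)    # several directions actually used
  expect_gt(stats::chisq.test(tab)$p.value, 1e-4)
  # the dye sits exactly dye_offset from the residue
  p <- place_dyes(s, cst)
  off <- p$dye[p$channel == "C", ] - s$coords[3L, ] * lattice_scale()
  expect_equal(sqrt(sum(off^2)), cst$dye_offset)
})

test_that("fingerprints concentrate at E = 0.5 when R equals R0", {
  # straight chain, ref at residue 1 and C at residue 16, dye offset 0:
  # donor-acceptor distance is the fixed backbone distance; set R0 to it
  s <- label_structure(stretched_peptide(paste0("K", strrep("A", 14), "C")),
                       default_scheme("C"))
  d <- physical_distance(s$coords[1L, ], s$coords[16L, ])
  cst <- fret_constants(r0 = d, dye_offset = 0)
  snaps <- rep(list(s), 100L)
  fp <- build_fingerprint(snaps, cst, seed = 12)
  expect_equal(fp$n_frames, 10L)
  expect_equal(unname(fp$channels$C$values), rep(0.5, 10L))
  expect_equal(sum(fp$channels$C$counts), 1)
  hot_bin <- which(fp$channels$C$counts > 0)
  expect_length(hot_bin, 1L)
  expect_equal(fp$channels$C$breaks[hot_bin + 1L], 0.5)  # right bin edge
})

test_that("distances are averaged before the FRET transform", {
  # two alternating conformations with different donor-acceptor distances:
  # the frame value is E(mean R), not mean E(R)
  sA <- label_structure(stretched_peptide(paste0("K", strrep("A", 14), "C")),
                        default_scheme("C"))
  sB <- NULL
  for (rot in lattice_rotations()) {
    prop <- propose_move(sA, kind = "branch_rotation", index = 8L,
                         rotation = rot)
    if (!prop$valid) next
    cand <- apply_move(sA, prop)
    if (!isTRUE(all.equal(cand$coords[16L, ], sA$coords[16L, ]))) {
      sB <- cand
      break
    }
  }
  expect_false(is.null(sB))
  dA <- physical_distance(sA$coords[1L, ], sA$coords[16L, ])
  dB <- physical_distance(sB$coords[1L, ], sB$coords[16L, ])
  expect_false(isTRUE(all.equal(dA, dB)))
  cst <- fret_constants(dye_offset = 0)
  snaps <- rep(list(sA, sB), 10L)    # 5 of each per block of 10
  fp <- build_fingerprint(snaps, cst, seed = 13)
  expected <- fret_efficiency((dA + dB) / 2, cst)
  expect_equal(unname(fp$channels$C$values), rep(expected, 2L))
  expect_false(isTRUE(all.equal(
    expected, mean(fret_efficiency(c(dA, dB), cst)))))
})

test_that("fingerprint weights normalize to one and honour the resolution", {
  s <- label_structure(stretched_peptide("KAAAAAAAAAAAAAAC"),
                       default_scheme("C"))
  res <- fold(s, energy_params(), folding_config(max_iterations = 1000L),
              seed = 6)
  snaps <- sample_snapshots(res, seed = 7)
  fp <- build_fingerprint(snaps, fret_constants(resolution = 0.05), seed = 8)
  expect_equal(sum(fp$channels$C$counts), 1)
  expect_length(fp$channels$C$counts, 20L)
  expect_true(all(fp$channels$C$values >= 0 & fp$channels$C$values <= 1))
})

test_that("fingerprint simulation is reproducible for a fixed seed", {
  pep <- make_peptide(16L, 9L)
  scheme <- default_scheme("C")
  cfg <- folding_config(max_iterations = 1000L)
  f1 <- simulate_fingerprint(pep$structure, scheme, "optimal",
                             energy_params(), cfg, seed = 42)
  f2 <- simulate_fingerprint(pep$structure, scheme, "optimal",
                             energy_params(), cfg, seed = 42)
  expect_equal(f1$channels$C$values, f2$channels$C$values)
})

test_that("fingerprints round-trip through TSV for classification", {
  ds <- make_fingerprint_classes(2L, 3L, channels = c("C", "K"), seed = 21)
  fp <- ds$proteins[[1L]][[1L]]
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fingerprint_tsv(fp, f)
  fp2 <- read_fingerprint_tsv(f)
  expect_equal(fp2$resolution, fp$resolution)
  expect_equal(fp2$channels$C$counts, unname(fp$channels$C$counts))
  expect_equal(to_features(fp2, c("C", "K"), 0.05),
               to_features(fp, c("C", "K"), 0.05))
})
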