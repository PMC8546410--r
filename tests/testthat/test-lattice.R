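test_that("BCC neighbourhood has the eight body-diagonal vertices", {
  nb <- bcc_neighbors(c(0, 0, 0))
  expect_equal(nrow(nb), 8L)
  expect_true(all(abs(nb) == 1L))
  expect_equal(nrow(unique(nb)), 8L)
  # all on the opposite sublattice, all at sqrt(3) lattice units
  expect_true(all(apply(nb, 1L, function(v) all(v %% 2 == 1))))
  expect_equal(unname(apply(nb, 1L, function(v) sqrt(sum(v^2)))),
               rep(sqrt(3), 8))
  nb1 <- bcc_neighbors(c(1, 1, 1))
  expect_true(any(apply(nb1, 1L, function(v) all(v == c(0, 0, 0)))))
  expect_true(any(apply(nb1, 1L, function(v) all(v == c(2, 2, 2)))))
  expect_error(bcc_neighbors(c(1, 0, 0)), "parity|invalid")
})

test_that("physical distance is calibrated to 3.8 A per bond", {
  expect_equal(physical_distance(c(0, 0, 0), c(1, 1, 1)), 3.8)
  expect_equal(physical_distance(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(physical_distance(c(0, 0, 0), c(2, 2, 2)), 7.6)
})

test_that("structure validation catches broken invariants", {
  s <- stretched_peptide("ACDEF")
  expect_true(validate_structure(s))
  bad <- s
  bad$coords[3L, ] <- bad$coords[1L, ]          # duplicate vertex
  expect_false(validate_structure(bad))
  bad2 <- s
  bad2$coords[2L, ] <- c(2L, 0L, 0L)            # not a bond vector
  expect_false(validate_structure(bad2))
  expect_error(lattice_structure("AB", rbind(c(0, 0, 0), c(1, 1, 1))),
               "non-canonical")
})

test_that("corner flip relocates to the other common neighbour", {
  # straight 3-mer (0,0,0)-(1,1,1)-(2,2,0): endpoints share exactly two
  # common neighbours, (1,1,1) and (1,1,-1)
  s <- lattice_structure(c("G", "G", "G"),
                         rbind(c(0L, 0L, 0L), c(1L, 1L, 1L), c(2L, 2L, 0L)))
  set.seed(1)
  prop <- propose_move(s, kind = "corner_flip", index = 2L)
  expect_true(prop$valid)
  expect_equal(prop$new_coords[2L, ], c(1L, 1L, -1L))
  expect_equal(prop$new_coords[c(1L, 3L), ], s$coords[c(1L, 3L), ])
})

test_that("branch rotation with the identity leaves coordinates unchanged", {
  s <- stretched_peptide("ACDEFG")
  prop <- propose_move(s, kind = "branch_rotation", index = 3L,
                       rotation = diag(3L))
  expect_true(prop$valid)
  expect_equal(prop$new_coords, s$coords)
})

test_that("chains shorter than 3 residues admit no moves", {
  s <- stretched_peptide("AC")
  expect_error(propose_move(s), "length < 3")
})

test_that("the lattice rotation group has 24 proper elements", {
  rots <- lattice_rotations()
  expect_length(rots, 24L)
  expect_true(all(vapply(rots, function(m) abs(det(m) - 1) < 1e-9,
                         logical(1))))
  expect_equal(length(unique(lapply(rots, as.vector))), 24L)
})

test_that("accepted moves preserve validity and bond lengths (property)", {
  set.seed(42)
  for (case in 1:8) {
    s <- random_saw(12L)
    for (m in 1:40) {
      prop <- propose_move(s)
      if (prop$valid) {
        s2 <- apply_move(s, prop)
        expect_true(validate_structure(s2))
        b <- diff(s2$coords)
        expect_true(all(rowSums(b^2) == 3))
        s <- s2
      }
    }
  }
})

test_that("corner flips and crankshafts are reversible", {
  set.seed(7)
  for (case in 1:5) {
    s <- random_saw(10L)
    for (kind in c("corner_flip", "crankshaft")) {
      prop <- propose_move(s, kind = kind)
      if (!prop$valid) next
      s2 <- apply_move(s, prop)
      # an inverse proposal at the same position can restore the coordinates
      restored <- FALSE
      for (tries in 1:200) {
        back <- propose_move(s2, kind = kind, index = prop$indices[1L])
        if (back$valid && all(back$new_coords == s$coords)) {
          restored <- TRUE
          break
        }
      }
      expect_true(restored)
    }
  }
})
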