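# Shared fixture builders (all generated in code; nothing on disk).

# Random self-avoiding walk on the BCC lattice, grown by rejection.
random_saw <- function(n, seed = NULL, sequence = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sequence)) {
    sequence <- sample(c("A", "G", "S", "L", "K", "F"), n, replace = TRUE)
  }
  repeat {
    coords <- matrix(0L, n, 3L)
    ok <- TRUE
    for (i in seq_len(n - 1L)) {
      nb <- bcc_neighbors(coords[i, ])
      taken <- apply(nb, 1L, function(v) {
        any(colSums(abs(t(coords[seq_len(i), , drop = FALSE]) - v)) == 0L)
      })
      free <- which(!taken)
      if (!length(free)) {
        ok <- FALSE
        break
      }
      coords[i + 1L, ] <- nb[free[sample.int(length(free), 1L)], ]
    }
    if (ok) return(lattice_structure(sequence, coords))
  }
}

# 4-mer U-turn: residues 1 and 4 in lattice contact (non-chain neighbours).
uturn_4mer <- function(sequence = c("A", "G", "G", "W")) {
  coords <- rbind(c(0L, 0L, 0L), c(1L, 1L, 1L), c(2L, 0L, 0L),
                  c(1L, -1L, 1L))
  lattice_structure(sequence, coords)
}

# 6-mer whose cysteines at positions 1, 4 and 6 form a contact star
# (1-4 and 1-6 in contact, 4-6 not): maximum disulfide matching is 1.
cys_star_6mer <- function() {
  coords <- rbind(c(0L, 0L, 0L), c(1L, 1L, 1L), c(2L, 2L, 0L),
                  c(1L, 1L, -1L), c(0L, 0L, -2L), c(-1L, -1L, -1L))
  lattice_structure(c("C", "G", "A", "C", "G", "C"), coords)
}

# Caged tag: a tagged residue at the origin surrounded by a closed shell of
# residues (every vertex with all-odd coordinates and Chebyshev norm 3), so
# that every periphery route is blocked. Geometry-only fixture: chain
# connectivity is irrelevant to clearance, so validation is skipped.
caged_tag <- function() {
  g <- as.matrix(expand.grid(c(-3L, -1L, 1L, 3L), c(-3L, -1L, 1L, 3L),
                             c(-3L, -1L, 1L, 3L)))
  shell <- g[apply(abs(g), 1L, max) == 3L, ]
  coords <- rbind(c(0L, 0L, 0L), shell)
  n <- nrow(coords)
  s <- structure(list(
    sequence = rep("G", n),
    coords = coords,
    native_ss = rep("C", n),
    tags = c("C", rep(NA_character_, n - 1L)),
    seq_idx = rep(match("G", c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
                               "I", "L", "K", "M", "F", "P", "S", "T", "W",
                               "Y", "V")), n),
    n_res = n
  ), class = "lattice_structure")
  s
}

# Minimal PDB text fixture: 5 residues, helix annotation over 2-4, R-free in
# REMARK 3. `selenomet` swaps residue 3 for MSE (non-canonical).
write_pdb_fixture <- function(path, r_free = 0.195, selenomet = FALSE,
                              two_chains = FALSE) {
  res <- c("ALA", "GLY", if (selenomet) "MSE" else "LEU", "VAL", "SER")
  xyz <- cbind(3.8 * (0:4) / sqrt(3), 3.8 * (0:4) / sqrt(3),
               3.8 * (0:4) / sqrt(3))
  lines <- c(
    sprintf("REMARK   3   FREE R VALUE                     : %.3f", r_free),
    "HELIX    1   1 GLY A    2  VAL A    4  1                                   3")
  for (i in 1:5) {
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      i, res[i], i, xyz[i, 1], xyz[i, 2], xyz[i, 3]))
  }
  if (two_chains) {
    for (i in 1:3) {
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  GLY B%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        5 + i, i, 30 + i * 2.2, 30.0, 30.0))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# Exhaustive enumeration of n-residue self-avoiding BCC chains with the
# first bond fixed (energies are rotation invariant), returning the minimum
# structural E_tot. Oracle for the folding engine.
enumerate_min_energy <- function(sequence, params) {
  n <- length(sequence)
  bonds <- as.matrix(expand.grid(c(-1L, 1L), c(-1L, 1L), c(-1L, 1L)))
  best <- Inf
  coords <- matrix(0L, n, 3L)
  coords[2L, ] <- c(1L, 1L, 1L)
  recurse <- function(i) {
    if (i > n) {
      s <- lattice_structure(sequence, coords, validate = FALSE)
      e <- total_energy(s, NULL, params)$E_tot
      if (e < best) best <<- e
      return(invisible(NULL))
    }
    for (k in seq_len(8L)) {
      cand <- coords[i - 1L, ] + bonds[k, ]
      clash <- any(colSums(abs(t(coords[seq_len(i - 1L), , drop = FALSE]) -
                                 cand)) == 0L)
      if (!clash) {
        coords[i, ] <<- cand
        recurse(i + 1L)
      }
    }
  }
  recurse(3L)
  best
}
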