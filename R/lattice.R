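# The eight BCC bond vectors (rows): every (+/-1, +/-1, +/-1) triple.
.bond_vectors <- as.matrix(expand.grid(x = c(-1L, 1L), y = c(-1L, 1L),
                                       z = c(-1L, 1L)))[, 3:1]
dimnames(.bond_vectors) <- NULL
storage.mode(.bond_vectors) <- "integer"

# Precomputed first-leg offsets for single-bend tag periphery routes:
# .bend_legs[[direction]][[steps]] is a steps x 3 offset matrix.
.bend_legs <- lapply(seq_len(8L), function(k1) {
  lapply(1:3, function(steps) seq_len(steps) %o% .bond_vectors[k1, ])
})

# One-letter codes of the 20 canonical amino acids.
.aa_codes <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Physical scale: one bond (sqrt(3) lattice units) = 3.8 Angstrom, the
# canonical C-alpha virtual bond length.
.lattice_scale <- 3.8 / sqrt(3)

#' Physical scale of the lattice
#'
#' One lattice unit expressed in Angstrom. The scale is fixed so that one
#' bond (length \eqn{\sqrt{3}} lattice units) equals 3.8 Å, the canonical
#' C\eqn{\alpha}–C\eqn{\alpha} virtual bond length.
#'
#' @return Scalar, Å per lattice unit.
#' @export
lattice_scale <- function() .lattice_scale

.is_bcc_vertex <- function(v) {
  all(v %% 2L == v[1] %% 2L)
}

#' Nearest neighbours of a BCC lattice vertex
#'
#' On the body-centered cubic lattice used here, valid vertices are integer
#' triples whose coordinates are all even or all odd (the two interpenetrating
#' cubic sublattices), and each vertex has exactly eight nearest neighbours at
#' displacement \eqn{(\pm 1, \pm 1, \pm 1)}.
#'
#' @param v Integer vector of length 3, a valid BCC vertex.
#' @return An 8 x 3 integer matrix of neighbouring vertices, all on the
#'   opposite sublattice, each at Euclidean distance \eqn{\sqrt{3}} lattice
#'   units.
#' @export
bcc_neighbors <- function(v) {
  v <- as.integer(v)
  if (length(v) != 3L) stop("vertex must have 3 coordinates")
  if (!.is_bcc_vertex(v)) {
    stop("invalid BCC vertex: coordinates must be all even or all odd")
  }
  sweep(.bond_vectors, 2L, v, "+")
}

#' Physical distance between lattice vertices
#'
#' Euclidean distance in Å, using the calibration of
#' \code{\link{lattice_scale}} (one bond = 3.8 Å).
#'
#' @param a,b Integer vectors of length 3 (lattice vertices).
#' @return Distance in Å.
#' @export
physical_distance <- function(a, b) {
  sqrt(sum((as.numeric(a) - as.numeric(b))^2)) * .lattice_scale
}

#' Construct a lattice protein structure
#'
#' A coarse-grained chain of residues, one pseudo-atom per residue, each on a
#' vertex of the BCC lattice. Consecutive residues occupy bonded vertices
#' (displacement one of the eight \eqn{(\pm 1,\pm 1,\pm 1)} vectors) and no
#' two residues share a vertex.
#'
#' @param sequence Character vector of one-letter amino-acid codes (or a
#'   single string).
#' @param coords Integer matrix, n x 3, lattice coordinates in chain order.
#' @param native_ss Per-residue native secondary structure, characters in
#'   \code{c("H", "E", "C")} (helix, sheet, coil). Default all coil.
#' @param tags Character vector of tag channels per residue (\code{NA} =
#'   untagged); the N-terminal reference channel is conventionally
#'   \code{"ref"} at residue 1.
#' @param validate Check structural invariants (default TRUE).
#' @return An object of class \code{lattice_structure}.
#' @export
lattice_structure <- function(sequence, coords, native_ss = NULL, tags = NULL,
                              validate = TRUE) {
  if (length(sequence) == 1L && nchar(sequence[1]) > 1L) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  sequence <- toupper(sequence)
  bad <- setdiff(unique(sequence), .aa_codes)
  if (length(bad)) stop("non-canonical residue code(s): ",
                        paste(bad, collapse = ", "))
  coords <- matrix(as.integer(coords), ncol = 3L)
  n <- length(sequence)
  if (nrow(coords) != n) stop("coords must have one row per residue")
  if (is.null(native_ss)) native_ss <- rep("C", n)
  if (is.null(tags)) tags <- rep(NA_character_, n)
  stopifnot(length(native_ss) == n, length(tags) == n)
  s <- structure(list(
    sequence = sequence,
    coords = coords,
    native_ss = native_ss,
    tags = tags,
    seq_idx = match(sequence, .aa_codes),
    n_res = n
  ), class = "lattice_structure")
  if (validate && !validate_structure(s)) {
    stop("invalid lattice structure: connectivity or self-avoidance violated")
  }
  s
}

#' Validate a lattice structure
#'
#' Checks chain connectivity (all consecutive displacements are bond vectors,
#' i.e. every component is \eqn{\pm 1}) and self-avoidance (no two residues on
#' one vertex). Vertex parity follows from connectivity given a valid start.
#'
#' @param s A \code{lattice_structure} (or a list with a \code{coords}
#'   matrix).
#' @return Logical.
#' @export
validate_structure <- function(s) {
  coords <- s$coords
  n <- nrow(coords)
  if (n == 0L) return(FALSE)
  if (!.is_bcc_vertex(coords[1L, ])) return(FALSE)
  if (n > 1L) {
    d <- diff(coords)
    if (!all(abs(d) == 1L)) return(FALSE)
  }
  !anyDuplicated(.vertex_key(coords)) > 0L
}

# Collision-free scalar key for vertices (coordinates stay far below 1e6).
.vertex_key <- function(coords) {
  coords[, 1L] * 4e12 + coords[, 2L] * 2e6 + coords[, 3L]
}

# ---- lattice rotation group --------------------------------------------

# The 24 proper rotations of the cubic/BCC lattice: signed permutation
# matrices with determinant +1. They preserve sublattice parity.
.make_rotations <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  signs <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
  rots <- list()
  for (p in perms) {
    pm <- diag(3)[p, , drop = FALSE]
    for (i in seq_len(nrow(signs))) {
      m <- diag(signs[i, ]) %*% pm
      if (abs(det(m) - 1) < 1e-9) rots[[length(rots) + 1L]] <- m
    }
  }
  lapply(rots, function(m) {
    storage.mode(m) <- "integer"
    m
  })
}
.lattice_rotations <- .make_rotations()

#' The 24 proper rotations of the lattice
#'
#' @return A list of 24 integer 3 x 3 rotation matrices (the proper signed
#'   permutation matrices), used by branch-rotation moves.
#' @export
lattice_rotations <- function() .lattice_rotations

# ---- Monte-Carlo move generators ---------------------------------------

# Enumerate vertices simultaneously bonded to both a and b.
.common_neighbors <- function(a, b) {
  na <- sweep(.bond_vectors, 2L, as.integer(a), "+")
  d <- sweep(na, 2L, as.integer(b), "-")
  na[rowSums(abs(d) == 1L) == 3L, , drop = FALSE]
}

#' Propose a Monte-Carlo move on a lattice structure
#'
#' One of three move kinds, chosen uniformly at random at a uniformly random
#' position: \emph{branch rotation} applies a random proper lattice rotation
#' (24-element group) to all residues after a pivot; \emph{corner flip}
#' relocates one internal residue to another vertex simultaneously bonded to
#' both its chain neighbours; \emph{crankshaft} relocates two consecutive
#' internal residues, preserving bonding to their flanking residues and to
#' each other. Proposals that would break self-avoidance are returned flagged
#' invalid (an MCMC driver counts them as rejections).
#'
#' Uses the R session RNG; seed with \code{set.seed()} for reproducibility.
#'
#' @param s A valid \code{lattice_structure} with at least 3 residues.
#' @param kind Optional move kind (\code{"branch_rotation"},
#'   \code{"corner_flip"}, \code{"crankshaft"}); random if \code{NULL}.
#' @param index Optional position (pivot residue for branch rotation, moved
#'   residue for corner flip, first of the moved pair for crankshaft).
#' @param rotation Optional 3 x 3 rotation matrix for branch rotation.
#' @return A list of class \code{move_proposal}: \code{kind}, \code{indices}
#'   (residues whose coordinates change), \code{new_coords} (full n x 3
#'   matrix), \code{valid}.
#' @export
propose_move <- function(s, kind = NULL, index = NULL, rotation = NULL) {
  n <- s$n_res
  if (n < 3L) stop("no valid moves for chains of length < 3")
  if (is.null(kind)) {
    kind <- c("branch_rotation", "corner_flip", "crankshaft")[
      sample.int(3L, 1L)]
  }
  coords <- s$coords
  prop <- switch(kind,
    branch_rotation = {
      pivot <- if (is.null(index)) sample.int(n - 1L, 1L) else as.integer(index)
      rot <- if (is.null(rotation)) {
        .lattice_rotations[[sample.int(24L, 1L)]]
      } else rotation
      idx <- (pivot + 1L):n
      p <- coords[pivot, ]
      moved <- sweep(coords[idx, , drop = FALSE], 2L, p, "-") %*% t(rot)
      new_coords <- coords
      new_coords[idx, ] <- sweep(moved, 2L, p, "+")
      list(indices = idx, new_coords = new_coords)
    },
    corner_flip = {
      i <- if (is.null(index)) sample.int(n - 2L, 1L) + 1L else as.integer(index)
      cand <- .common_neighbors(coords[i - 1L, ], coords[i + 1L, ])
      cur <- coords[i, ]
      keep <- rowSums(cand != matrix(cur, nrow(cand), 3L, byrow = TRUE)) > 0L
      cand <- cand[keep, , drop = FALSE]
      if (nrow(cand) == 0L) return(.invalid_proposal(kind, i, coords))
      new_coords <- coords
      new_coords[i, ] <- cand[sample.int(nrow(cand), 1L), ]
      list(indices = i, new_coords = new_coords)
    },
    crankshaft = {
      if (n < 4L) return(.invalid_proposal(kind, NA_integer_, coords))
      i <- if (is.null(index)) sample.int(n - 3L, 1L) + 1L else as.integer(index)
      left <- sweep(.bond_vectors, 2L, coords[i - 1L, ], "+")
      right <- sweep(.bond_vectors, 2L, coords[i + 2L, ], "+")
      adj <- abs(outer(left[, 1L], right[, 1L], "-")) == 1L &
        abs(outer(left[, 2L], right[, 2L], "-")) == 1L &
        abs(outer(left[, 3L], right[, 3L], "-")) == 1L
      cur_a <- which(rowSums(left == matrix(coords[i, ], 8L, 3L,
                                            byrow = TRUE)) == 3L)
      cur_b <- which(rowSums(right == matrix(coords[i + 1L, ], 8L, 3L,
                                             byrow = TRUE)) == 3L)
      if (length(cur_a) && length(cur_b)) adj[cur_a, cur_b] <- FALSE
      cand <- which(adj, arr.ind = TRUE, useNames = FALSE)
      if (nrow(cand) == 0L) return(.invalid_proposal(kind, i, coords))
      p <- cand[sample.int(nrow(cand), 1L), ]
      new_coords <- coords
      new_coords[i, ] <- left[p[1L], ]
      new_coords[i + 1L, ] <- right[p[2L], ]
      list(indices = c(i, i + 1L), new_coords = new_coords)
    },
    stop("unknown move kind: ", kind)
  )
  if (inherits(prop, "move_proposal")) return(prop)
  valid <- !(anyDuplicated(.vertex_key(prop$new_coords)) > 0L)
  structure(list(kind = kind, indices = prop$indices,
                 new_coords = prop$new_coords, valid = valid),
            class = "move_proposal")
}

.invalid_proposal <- function(kind, index, coords) {
  structure(list(kind = kind, indices = index, new_coords = coords,
                 valid = FALSE),
            class = "move_proposal")
}

#' Apply an accepted move proposal
#'
#' @param s A \code{lattice_structure}.
#' @param proposal A valid \code{move_proposal} from
#'   \code{\link{propose_move}}.
#' @return The structure with updated coordinates.
#' @export
apply_move <- function(s, proposal) {
  if (!isTRUE(proposal$valid)) stop("cannot apply an invalid move proposal")
  s$coords <- proposal$new_coords
  s
}

#' @export
print.lattice_structure <- function(x, ...) {
  cat("lattice_structure:", x$n_res, "residues\n")
  cat("  sequence:", paste(x$sequence, collapse = ""), "\n")
  nt <- sum(!is.na(x$tags))
  cat("  tags:", nt, if (nt) paste0("(",
      paste(unique(stats::na.omit(x$tags)), collapse = ", "), ")") else "",
      "\n")
  invisible(x)
}
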