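# Canonical lattice helix: a period-4 bond cycle whose residues i and i+4
# differ by a pure axis translation of 4 lattice units -- one regular turn
# per five residues. Base cycle about +z, right-handed:
.helix_base_cycle <- rbind(c(1L, 1L, 1L), c(1L, -1L, 1L),
                           c(-1L, -1L, 1L), c(-1L, 1L, 1L))

# All realizations of the lattice helix: 24 rotations x 4 phases x 2
# handedness (reversal of the cycle), as bond-vector cycles.
.helix_cycles <- local({
  out <- list()
  for (rot in .make_rotations()) {
    for (rev in c(FALSE, TRUE)) {
      cyc <- .helix_base_cycle %*% t(rot)
      if (rev) cyc <- cyc[4:1, , drop = FALSE]
      for (phase in 0:3) {
        out[[length(out) + 1L]] <- cyc[((0:3 + phase) %% 4L) + 1L, ,
                                       drop = FALSE]
      }
    }
  }
  unique(out)
})

#' Canonical lattice helix coordinates
#'
#' Generates \code{n} residues of the canonical BCC lattice helix starting at
#' \code{start}: a repeating cycle of four bond vectors all sharing one axis
#' direction, each the 90-degree rotation of its predecessor about that axis,
#' so that residues \eqn{i} and \eqn{i+4} differ by a translation of 4 lattice
#' units along the axis (one regular turn per five residues).
#'
#' @param n Number of residues.
#' @param start Starting vertex (default origin).
#' @param cycle A 4 x 3 bond-vector cycle; default the base cycle about +z.
#' @return n x 3 integer coordinate matrix.
#' @export
lattice_helix <- function(n, start = c(0L, 0L, 0L),
                          cycle = .helix_base_cycle) {
  coords <- matrix(0L, n, 3L)
  coords[1L, ] <- as.integer(start)
  if (n > 1L) for (i in 2L:n) {
    coords[i, ] <- coords[i - 1L, ] + cycle[((i - 2L) %% 4L) + 1L, ]
  }
  coords
}

#' Quality filters for atomistic input structures
#'
#' A structure is usable for lattice modelling when its refinement quality is
#' adequate and it needs no energy terms the model lacks: R-free strictly
#' below 0.21, only canonical residues, and a single chain (quaternary
#' structure is lost during single-molecule sample preparation and is not
#' modelled).
#'
#' @param meta List with fields \code{r_free} (numeric or NA),
#'   \code{canonical} (logical), \code{n_chains} (integer).
#' @return Logical. A missing R-free fails (with a message).
#' @export
passes_filters <- function(meta) {
  if (is.null(meta$r_free) || is.na(meta$r_free)) {
    message("structure rejected: R-free value missing")
    return(FALSE)
  }
  isTRUE(meta$r_free < 0.21) && isTRUE(meta$canonical) &&
    isTRUE(meta$n_chains == 1L)
}

.aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Load a C-alpha trace from a PDB file
#'
#' Reads a single chain with \code{bio3d::read.pdb}, reduces it to its
#' C\eqn{\alpha} positions, and annotates per-residue secondary structure from
#' the file's HELIX/SHEET records. Metadata needed by
#' \code{\link{passes_filters}} (R-free from REMARK 3, chain count,
#' canonical-residue flag) is collected alongside.
#'
#' @param pdb_file Path to a PDB file.
#' @param chain_id Chain to extract (default: first chain in the file).
#' @return A list of class \code{atomistic_trace}: \code{sequence} (one-letter
#'   codes, \code{"X"} for non-canonical), \code{xyz} (n x 3 Å matrix),
#'   \code{ss} (\code{"H"}/\code{"E"}/\code{"C"}), \code{meta}.
#' @export
load_atomistic <- function(pdb_file, chain_id = NULL) {
  pdb <- bio3d::read.pdb(pdb_file)
  atoms <- pdb$atom
  chains <- unique(atoms$chain[atoms$type == "ATOM"])
  if (is.null(chain_id)) chain_id <- chains[1L]
  if (!chain_id %in% atoms$chain) stop("chain not found: ", chain_id)
  ca <- atoms[atoms$elety == "CA" & atoms$chain == chain_id &
                atoms$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  if (nrow(ca) == 0L) stop("no C-alpha atoms found for chain ", chain_id)
  # gap check: residue numbering must be consecutive
  if (nrow(ca) > 1L && any(diff(ca$resno) != 1L)) {
    stop("C-alpha gap detected in chain ", chain_id)
  }
  seq1 <- unname(.aa3to1[ca$resid])
  canonical <- !any(is.na(seq1))
  seq1[is.na(seq1)] <- "X"
  ss <- rep("C", nrow(ca))
  hel <- pdb$helix
  if (!is.null(hel) && length(hel$start)) {
    for (k in seq_along(hel$start)) {
      if (!is.null(hel$chain) && length(hel$chain) &&
          hel$chain[k] != chain_id) next
      ss[ca$resno >= hel$start[k] & ca$resno <= hel$end[k]] <- "H"
    }
  }
  sht <- pdb$sheet
  if (!is.null(sht) && length(sht$start)) {
    for (k in seq_along(sht$start)) {
      if (!is.null(sht$chain) && length(sht$chain) &&
          sht$chain[k] != chain_id) next
      ss[ca$resno >= sht$start[k] & ca$resno <= sht$end[k]] <- "E"
    }
  }
  r_free <- .parse_r_free(pdb_file)
  structure(list(
    sequence = seq1,
    xyz = as.matrix(ca[, c("x", "y", "z")]),
    ss = ss,
    meta = list(r_free = r_free, n_chains = length(chains),
                canonical = canonical)
  ), class = "atomistic_trace")
}

# REMARK   3   FREE R VALUE                     : 0.205
.parse_r_free <- function(pdb_file) {
  lines <- readLines(pdb_file, warn = FALSE)
  rl <- grep("^REMARK   3   FREE R VALUE\\s*:", lines, value = TRUE)
  if (!length(rl)) return(NA_real_)
  val <- sub(".*:\\s*", "", rl[1L])
  suppressWarnings(as.numeric(val))
}

#' Fit an atomistic C-alpha trace to the BCC lattice
#'
#' Places residue 1 on the nearest lattice vertex and every subsequent
#' residue on the bonded neighbour of its predecessor closest to the scaled
#' atomistic position, subject to self-avoidance, with depth-limited
#' backtracking over ranked candidates when a placement dead-ends. Residues
#' inside helical segments of five or more residues are first replaced by the
#' canonical lattice helix (\code{\link{lattice_helix}}): the helix
#' realization (axis, phase, handedness) and anchor minimizing the summed
#' squared deviation from the scaled atomistic positions is chosen among
#' those that keep the chain bonded and self-avoiding.
#'
#' @param trace An \code{atomistic_trace} from \code{\link{load_atomistic}}
#'   (or any list with \code{sequence}, \code{xyz}, \code{ss}).
#' @param max_backtrack Backtracking depth on steric dead-ends (default 50).
#' @return A valid \code{lattice_structure} carrying the native secondary
#'   structure annotations, with attribute \code{"rmsd"}: the RMSD (Å)
#'   between scaled atomistic and fitted positions.
#' @export
fit_to_lattice <- function(trace, max_backtrack = 50L) {
  n <- length(trace$sequence)
  if (n < 2L) stop("trace must have at least 2 residues")
  target <- trace$xyz / .lattice_scale   # lattice units
  ss <- trace$ss
  if (is.null(ss)) ss <- rep("C", n)

  # helical runs of length >= 5 are placed as rigid lattice helices
  runs <- rle(ss == "H")
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  helix_runs <- which(runs$values & runs$lengths >= 5L)
  helix_of <- integer(n)                  # 0 = free residue
  for (h in seq_along(helix_runs)) {
    r <- helix_runs[h]
    helix_of[run_start[r]:run_end[r]] <- h
  }

  coords <- matrix(NA_integer_, n, 3L)
  occupied <- new.env(hash = TRUE, parent = emptyenv())
  occupy <- function(v) assign(as.character(.vertex_key(matrix(v, 1L))),
                               TRUE, envir = occupied)
  free_v <- function(v) rm(list = as.character(.vertex_key(matrix(v, 1L))),
                           envir = occupied)
  is_occ <- function(v) {
    exists(as.character(.vertex_key(matrix(v, 1L))), envir = occupied)
  }

  place_helix <- function(i) {
    # residues i .. e form one helix run
    h <- helix_of[i]
    r <- helix_runs[h]
    e <- run_end[r]
    len <- e - i + 1L
    best <- NULL
    best_cost <- Inf
    starts <- if (i == 1L) list(.nearest_vertex(target[1L, ])) else {
      prev <- coords[i - 1L, ]
      lapply(seq_len(8L), function(k) prev + .bond_vectors[k, ])
    }
    for (st in starts) {
      for (cyc in .helix_cycles) {
        hc <- lattice_helix(len, st, cyc)
        if (any(apply(hc, 1L, is_occ))) next
        if (anyDuplicated(.vertex_key(hc))) next
        cost <- sum((hc - target[i:e, , drop = FALSE])^2)
        if (cost < best_cost) {
          best_cost <- cost
          best <- hc
        }
      }
    }
    if (is.null(best)) return(NA_integer_)
    coords[i:e, ] <<- best
    for (k in i:e) occupy(best[k - i + 1L, ])
    e
  }

  # iterative placement with backtracking over ranked candidates
  cand_stack <- vector("list", n)
  seg_end <- integer(n)  # last residue placed by the step that started at i
  i <- 1L
  backtracks <- 0L
  while (i <= n) {
    if (helix_of[i] > 0L && (i == 1L || helix_of[i] != helix_of[i - 1L])) {
      e <- place_helix(i)
      if (is.na(e)) {
        stop("lattice fitting failed: no helix placement at residue ", i)
      }
      seg_end[i] <- e
      cand_stack[[i]] <- matrix(integer(0), 0L, 3L)  # helix: no alternatives
      i <- e + 1L
      next
    }
    if (is.null(cand_stack[[i]]) || nrow(cand_stack[[i]]) == 0L) {
      cands <- if (i == 1L) {
        matrix(.nearest_vertex(target[1L, ]), 1L)
      } else {
        nb <- sweep(.bond_vectors, 2L, coords[i - 1L, ], "+")
        nb[order(rowSums((nb - matrix(target[i, ], 8L, 3L,
                                      byrow = TRUE))^2)), , drop = FALSE]
      }
      cands <- cands[!apply(cands, 1L, is_occ), , drop = FALSE]
      cand_stack[[i]] <- cands
    }
    if (nrow(cand_stack[[i]]) == 0L) {
      # dead end: backtrack to the previous free residue
      cand_stack[i] <- list(NULL)
      j <- i - 1L
      while (j >= 1L && helix_of[j] > 0L) j <- j - 1L
      if (j < 1L || backtracks >= max_backtrack) {
        stop("lattice fitting failed: steric dead-end at residue ", i)
      }
      backtracks <- backtracks + 1L
      for (k in j:(i - 1L)) if (!is.na(coords[k, 1L])) {
        free_v(coords[k, ])
        coords[k, ] <- NA_integer_
      }
      if (j + 1L <= i) for (k in (j + 1L):i) cand_stack[k] <- list(NULL)
      i <- j
      next
    }
    coords[i, ] <- cand_stack[[i]][1L, ]
    cand_stack[[i]] <- cand_stack[[i]][-1L, , drop = FALSE]
    occupy(coords[i, ])
    seg_end[i] <- i
    i <- i + 1L
  }

  s <- lattice_structure(trace$sequence, coords, native_ss = ss)
  attr(s, "rmsd") <- sqrt(mean(rowSums(
    (coords - target)^2))) * .lattice_scale
  s
}

# Nearest valid BCC vertex to a fractional position (lattice units).
.nearest_vertex <- function(p) {
  even <- 2L * as.integer(round(p / 2))
  odd <- 2L * as.integer(round((p - 1) / 2)) + 1L
  if (sum((even - p)^2) <= sum((odd - p)^2)) even else odd
}

#' Stretched (maximally extended) starting structure from a sequence
#'
#' Places residues along alternating bond vectors \eqn{(1,1,1)} and
#' \eqn{(1,1,-1)}, the maximally extended zig-zag on the BCC lattice; all
#' native secondary structure is set to coil. Used as the starting
#' configuration for peptides without an experimental structure.
#'
#' @param sequence Character vector of one-letter codes or a single string.
#' @return A valid \code{lattice_structure}.
#' @export
stretched_peptide <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence[1]) > 1L) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  if (length(sequence) == 0L) stop("empty sequence")
  n <- length(sequence)
  coords <- matrix(0L, n, 3L)
  if (n > 1L) for (i in 2L:n) {
    b <- if (i %% 2L == 0L) c(1L, 1L, 1L) else c(1L, 1L, -1L)
    coords[i, ] <- coords[i - 1L, ] + b
  }
  lattice_structure(sequence, coords)
}

# ---- serialization ------------------------------------------------------

#' Write / read a lattice structure as JSON
#'
#' The layout is \code{{sequence, coords, native_ss, tags}} with coords as an
#' n x 3 integer array.
#'
#' @param s A \code{lattice_structure}.
#' @param path Output / input file path.
#' @return \code{read_structure_json} returns a \code{lattice_structure};
#'   \code{write_structure_json} returns \code{path} invisibly.
#' @export
write_structure_json <- function(s, path) {
  jsonlite::write_json(list(sequence = s$sequence,
                            coords = s$coords,
                            native_ss = s$native_ss,
                            tags = s$tags),
                       path, auto_unbox = FALSE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_structure_json
#' @export
read_structure_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tags <- as.character(x$tags)
  tags[tags == "NULL" | tags == "NA"] <- NA_character_
  lattice_structure(x$sequence, x$coords, x$native_ss, tags)
}

#' Export a lattice structure to PDB (pseudo C-alpha trace)
#'
#' Writes one CA atom per residue at the physical (Å) position of its lattice
#' vertex, for visualization.
#'
#' @param s A \code{lattice_structure}.
#' @param path Output path.
#' @export
write_structure_pdb <- function(s, path) {
  xyz <- s$coords * .lattice_scale
  aa1to3 <- names(.aa3to1)
  res3 <- aa1to3[match(s$sequence, unname(.aa3to1))]
  lines <- sprintf(
    "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(s$n_res), res3, seq_len(s$n_res),
    xyz[, 1L], xyz[, 2L], xyz[, 3L])
  writeLines(c(lines, "END"), path)
  invisible(path)
}
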