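#' Load the bundled residue contact-potential table
#'
#' A symmetric 20 x 20 matrix of pairwise contact energies (dimensionless
#' model units), derived from an empirical per-residue contact-energy scale
#' via a one-body approximation; see the header of
#' \code{inst/extdata/contact_potential.csv} for provenance and derivation.
#' The table is solvent-referenced, so the default per-exposed-vertex solvent
#' energy is zero.
#'
#' @param path Optional path to an alternative CSV (first column and header
#'   row are one-letter residue codes; \code{#} comment lines allowed).
#' @return Named 20 x 20 numeric matrix.
#' @export
contact_potential <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "contact_potential.csv",
                        package = "latticefret")
  }
  tab <- utils::read.csv(path, comment.char = "#", row.names = 1L,
                         check.names = FALSE)
  m <- as.matrix(tab)
  if (!isTRUE(all.equal(m, t(m)))) stop("contact table must be symmetric")
  m
}

#' Energy-model parameters
#'
#' Bundles the constants of the six-term model energy
#' \eqn{E_{tot} = E_{AA} + E_{sol} + E_{ss} + E_{dsb} + E_{tag} + E_{reg}}:
#' the pairwise contact table, per-residue-type solvent energy per exposed
#' vertex, the secondary-structure bonus (-25 per qualifying residue), the
#' disulfide bonus (-50 per contacting cysteine pair, maximum matching), the
#' tag steric penalty (+100 per blocking residue) and the single-step
#' reorganization penalty (weight x excess displacement).
#'
#' @param contact_table Symmetric 20 x 20 matrix (default:
#'   \code{\link{contact_potential}()}).
#' @param solvent Named numeric, residue-type energy per solvent-exposed
#'   neighbour vertex (default all 0; the bundled contact table is
#'   solvent-referenced).
#' @param ss_bonus Secondary-structure bonus per qualifying residue
#'   (default -25).
#' @param dsb_bonus Disulfide bonus per contacting cysteine pair
#'   (default -50).
#' @param tag_penalty Penalty per residue blocking a tag's periphery route
#'   (default +100).
#' @param reg_weight,reg_threshold Reorganization penalty: \code{reg_weight *
#'   max(0, total displacement - reg_threshold)}, displacement summed over
#'   residues in lattice units (defaults 1 and 1000: the penalty targets
#'   reorganizations far beyond the displacement scale of ordinary
#'   peptide-length branch rotations; see the methods vignette).
#' @param inert_types Residue types modelled as non-interacting (all their
#'   pairwise contact energies set to 0), used to represent designed inert
#'   linkers/fillers in synthetic model peptides (default none).
#' @return An object of class \code{energy_params}.
#' @export
energy_params <- function(contact_table = NULL,
                          solvent = NULL,
                          ss_bonus = -25,
                          dsb_bonus = -50,
                          tag_penalty = 100,
                          reg_weight = 1,
                          reg_threshold = 1000,
                          inert_types = character(0)) {
  if (is.null(contact_table)) contact_table <- contact_potential()
  if (is.null(solvent)) solvent <- stats::setNames(rep(0, 20L), .aa_codes)
  stopifnot(ss_bonus <= 0, dsb_bonus <= 0, tag_penalty >= 0,
            reg_weight >= 0, reg_threshold >= 0)
  if (length(inert_types)) {
    contact_table[inert_types, ] <- 0
    contact_table[, inert_types] <- 0
  }
  structure(list(contact_table = contact_table,
                 contact_idx = contact_table[.aa_codes, .aa_codes],
                 solvent = solvent[.aa_codes],
                 ss_bonus = ss_bonus,
                 dsb_bonus = dsb_bonus,
                 tag_penalty = tag_penalty,
                 reg_weight = reg_weight,
                 reg_threshold = reg_threshold),
            class = "energy_params")
}

# Non-bonded lattice contacts: pairs (i, j), j > i + 1, at squared lattice
# distance 3 (one bond). Returns a 2-column index matrix.
.contact_pairs <- function(coords) {
  n <- nrow(coords)
  if (n < 3L) return(matrix(integer(0), 0L, 2L))
  sq <- rowSums(coords * coords)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(coords)
  hit <- d2 == 3 & upper.tri(d2)
  idx <- which(hit, arr.ind = TRUE, useNames = FALSE)
  idx[idx[, 2L] - idx[, 1L] > 1L, , drop = FALSE]
}

#' Residue-residue and residue-solvent contact energy
#'
#' \code{E_AA} sums the contact-table entry over every unordered pair of
#' residues that are adjacent on the lattice but not neighbours in the chain;
#' pairs involving a tagged residue contribute nothing (the DNA tag obstructs
#' the residue's interactions). \code{E_sol} sums the per-type solvent energy
#' over every unoccupied neighbour vertex of every untagged residue.
#'
#' @param s A valid, possibly tagged \code{lattice_structure}.
#' @param params An \code{\link{energy_params}}.
#' @return Named numeric vector \code{c(E_AA, E_sol)}.
#' @export
contact_energy <- function(s, params) {
  tagged <- !is.na(s$tags)
  pairs <- .contact_pairs(s$coords)
  e_aa <- 0
  occ_contacts <- integer(s$n_res)
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      occ_contacts[i] <- occ_contacts[i] + 1L
      occ_contacts[j] <- occ_contacts[j] + 1L
      if (!tagged[i] && !tagged[j]) {
        e_aa <- e_aa + params$contact_idx[s$seq_idx[i], s$seq_idx[j]]
      }
    }
  }
  # exposed vertices: 8 minus chain neighbours minus residue contacts
  chain_nb <- rep(2L, s$n_res)
  chain_nb[c(1L, s$n_res)] <- 1L
  if (s$n_res == 1L) chain_nb <- 0L
  exposed <- 8L - chain_nb - occ_contacts
  e_sol <- sum(params$solvent[s$seq_idx[!tagged]] * exposed[!tagged])
  c(E_AA = e_aa, E_sol = as.numeric(e_sol))
}

# Does the 5-residue window starting at i match the lattice-helix pattern?
# All 4 bonds share one axis component of constant sign and each bond is the
# same +/-90 degree rotation of its predecessor about that axis.
.helix_window_ok <- function(bonds) {
  for (ax in 1:3) {
    sgn <- bonds[1L, ax]
    if (any(bonds[, ax] != sgn)) next
    tr <- (1:3)[-ax]
    # rotation about axis: (u, v) -> (-v, u) or (v, -u), consistent over steps
    u <- bonds[, tr[1L]]; v <- bonds[, tr[2L]]
    cw <- all(u[-1L] == -v[-4L]) && all(v[-1L] == u[-4L])
    ccw <- all(u[-1L] == v[-4L]) && all(v[-1L] == -u[-4L])
    if (cw || ccw) return(TRUE)
  }
  FALSE
}

#' Secondary-structure formation energy
#'
#' A bonus (default -25) per untagged residue that re-forms its native
#' secondary structure on the lattice: a natively helical residue whose
#' window \eqn{i..i+4} realizes the canonical lattice helix (all four bonds
#' share an axis sign and each is the same 90-degree rotation of its
#' predecessor — one regular turn per five residues); a natively sheet
#' residue adjacent on the lattice to another natively sheet residue that is
#' not its chain neighbour.
#'
#' @inheritParams contact_energy
#' @return Scalar \code{E_ss}.
#' @export
secondary_structure_energy <- function(s, params) {
  n <- s$n_res
  tagged <- !is.na(s$tags)
  e <- 0
  helical <- which(s$native_ss == "H" & !tagged)
  helical <- helical[helical <= n - 4L]
  if (length(helical)) {
    bonds_all <- diff(s$coords)
    for (i in helical) {
      if (!all(s$native_ss[i:(i + 4L)] == "H")) next
      if (.helix_window_ok(bonds_all[i:(i + 3L), , drop = FALSE])) {
        e <- e + params$ss_bonus
      }
    }
  }
  sheet <- which(s$native_ss == "E")
  if (length(sheet) > 1L) {
    pairs <- .contact_pairs(s$coords)
    if (nrow(pairs)) {
      both_sheet <- s$native_ss[pairs[, 1L]] == "E" &
        s$native_ss[pairs[, 2L]] == "E"
      pr <- pairs[both_sheet, , drop = FALSE]
      qualifies <- logical(n)
      if (nrow(pr)) qualifies[unique(as.vector(pr))] <- TRUE
      e <- e + params$ss_bonus * sum(qualifies & !tagged)
    }
  }
  e
}

# Maximum matching size on a small graph given as a 2-column edge matrix.
.max_matching <- function(edges, used = integer(0)) {
  if (nrow(edges) == 0L) return(0L)
  e <- edges[1L, ]
  rest <- edges[-1L, , drop = FALSE]
  skip <- .max_matching(rest, used)
  if (e[1L] %in% used || e[2L] %in% used) return(skip)
  keep_rest <- rest[rest[, 1L] != e[1L] & rest[, 2L] != e[1L] &
                      rest[, 1L] != e[2L] & rest[, 2L] != e[2L], ,
                    drop = FALSE]
  max(skip, 1L + .max_matching(keep_rest, used))
}

#' Disulfide-bridge energy
#'
#' A bonus (default -50) per pair of lattice-contacting, untagged cysteines
#' in a maximum matching: each cysteine contributes to at most one bridge.
#'
#' @inheritParams contact_energy
#' @return Scalar \code{E_dsb}.
#' @export
disulfide_energy <- function(s, params) {
  cys <- which(s$sequence == "C" & is.na(s$tags))
  if (length(cys) < 2L) return(0)
  pairs <- .contact_pairs(s$coords)
  if (nrow(pairs) == 0L) return(0)
  keep <- pairs[, 1L] %in% cys & pairs[, 2L] %in% cys
  edges <- pairs[keep, , drop = FALSE]
  if (nrow(edges) == 0L) return(0)
  params$dsb_bonus * .max_matching(edges)
}

#' Tag steric-hindrance energy
#'
#' \code{tag_penalty} (default +100) per residue blocking the best periphery
#' route of each tagged residue (see \code{\link{clearance_blockers}});
#' 0 exactly when every tag fits without steric hindrance.
#'
#' @inheritParams contact_energy
#' @return Scalar \code{E_tag}.
#' @export
tag_energy <- function(s, params) {
  tagged <- which(!is.na(s$tags))
  if (!length(tagged)) return(0)
  params$tag_penalty *
    sum(vapply(tagged, function(i) clearance_blockers(s, i), integer(1)))
}

#' Single-step reorganization penalty
#'
#' Penalizes large structural reorganizations within one MCMC step:
#' \code{reg_weight * max(0, D - reg_threshold)} where \code{D} is the total
#' per-residue Euclidean displacement (lattice units) between the structure
#' and the pre-move reference coordinates. Zero for the identity move; it
#' enters the Metropolis acceptance only, never the recorded structure
#' energy.
#'
#' @inheritParams contact_energy
#' @param reference n x 3 coordinate matrix before the proposed move (or
#'   \code{NULL} for zero).
#' @return Scalar \code{E_reg}.
#' @export
regularization_energy <- function(s, reference, params) {
  if (is.null(reference)) return(0)
  d <- sqrt(rowSums((s$coords - reference)^2))
  params$reg_weight * max(0, sum(d) - params$reg_threshold)
}

#' Total model energy with per-term breakdown
#'
#' @inheritParams regularization_energy
#' @return A named list of class \code{energy_breakdown} with elements
#'   \code{E_AA}, \code{E_sol}, \code{E_ss}, \code{E_dsb}, \code{E_tag},
#'   \code{E_reg} and their exact sum \code{E_tot}.
#' @export
total_energy <- function(s, reference = NULL, params = energy_params()) {
  ct <- contact_energy(s, params)
  out <- list(E_AA = unname(ct["E_AA"]),
              E_sol = unname(ct["E_sol"]),
              E_ss = secondary_structure_energy(s, params),
              E_dsb = disulfide_energy(s, params),
              E_tag = tag_energy(s, params),
              E_reg = regularization_energy(s, reference, params))
  out$E_tot <- out$E_AA + out$E_sol + out$E_ss + out$E_dsb + out$E_tag +
    out$E_reg
  structure(out, class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(
    "E_tot = %.3f (AA %.3f | sol %.3f | ss %.1f | dsb %.1f | tag %.1f | reg %.3f)\n",
    x$E_tot, x$E_AA, x$E_sol, x$E_ss, x$E_dsb, x$E_tag, x$E_reg))
  invisible(x)
}
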