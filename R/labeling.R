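#' Define a residue-labeling scheme
#'
#' A scheme maps tag channels to target residue types, with a per-channel
#' labeling efficiency (probability that a target residue actually receives
#' its tag under error-prone chemistry) and an off-target table (probability
#' that a non-target residue of a given type receives the channel's tag).
#' Defaults follow the error-prone scenario used throughout: 90% efficiency
#' and off-target rates C 1%, K 1%, R 0.5%.
#'
#' @param channels Named list; each element is a list with fields
#'   \code{targets} (character vector of residue types), \code{efficiency}
#'   (default 1), \code{off_target} (named numeric, default none). Residue
#'   types absent from \code{off_target} are never mislabeled.
#' @return An object of class \code{labeling_scheme}.
#' @examples
#' scheme_ck <- labeling_scheme(list(
#'   C = list(targets = "C", efficiency = 0.9, off_target = c(K = 0.01)),
#'   K = list(targets = "K", efficiency = 0.9, off_target = c(C = 0.01))))
#' @export
labeling_scheme <- function(channels) {
  stopifnot(is.list(channels), length(names(channels)) == length(channels))
  channels <- lapply(channels, function(ch) {
    if (is.null(ch$efficiency)) ch$efficiency <- 1
    if (is.null(ch$off_target)) ch$off_target <- numeric(0)
    stopifnot(ch$efficiency >= 0, ch$efficiency <= 1,
              all(ch$off_target >= 0), all(ch$off_target <= 1))
    ch
  })
  structure(list(channels = channels), class = "labeling_scheme")
}

#' Default labeling schemes for C / C+K / C+K+R chemistries
#'
#' @param residues Character vector among \code{c("C","K","R")} naming the
#'   targeted residue types (one channel each).
#' @param efficiency Labeling efficiency under the error-prone scenario
#'   (default 0.9).
#' @param off_target Named numeric of off-target probabilities per residue
#'   type (defaults C 1%, K 1%, R 0.5%); a channel never mislabels its own
#'   target type.
#' @return A \code{labeling_scheme}.
#' @export
default_scheme <- function(residues = c("C", "K", "R"), efficiency = 0.9,
                           off_target = c(C = 0.01, K = 0.01, R = 0.005)) {
  chans <- lapply(residues, function(r) {
    list(targets = r, efficiency = efficiency,
         off_target = off_target[setdiff(names(off_target), r)])
  })
  names(chans) <- residues
  labeling_scheme(chans)
}

#' Assign tag channels to residues
#'
#' Under the \code{optimal} scenario every target residue is tagged and no
#' off-target labeling occurs. Under the \code{suboptimal} scenario each
#' target residue is tagged with the channel's efficiency and each non-target
#' residue of a type listed in the channel's off-target table with the listed
#' probability. Residue 1 (the N terminus) always carries the reference
#' channel \code{"ref"}; a residue carries at most one channel, the
#' first-drawn winning (channels are drawn in scheme definition order).
#'
#' Uses the R session RNG; seed with \code{set.seed()} for reproducibility.
#'
#' @param sequence Character vector of one-letter codes or a single string.
#' @param scheme A \code{\link{labeling_scheme}}.
#' @param mode \code{"optimal"} or \code{"suboptimal"}.
#' @return Character vector of per-residue channels (\code{NA} = untagged),
#'   suitable as the \code{tags} field of a \code{lattice_structure}.
#' @export
apply_labeling <- function(sequence, scheme, mode = c("optimal", "suboptimal")) {
  mode <- match.arg(mode)
  if (length(sequence) == 1L && nchar(sequence[1]) > 1L) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  if (length(sequence) == 0L) stop("empty sequence")
  n <- length(sequence)
  tags <- rep(NA_character_, n)
  tags[1L] <- "ref"
  for (cname in names(scheme$channels)) {
    ch <- scheme$channels[[cname]]
    is_target <- sequence %in% ch$targets
    hit <- logical(n)
    if (mode == "optimal") {
      hit <- is_target
    } else {
      hit[is_target] <- stats::runif(sum(is_target)) < ch$efficiency
      for (rt in names(ch$off_target)) {
        ot <- which(!is_target & sequence == rt)
        if (length(ot)) {
          hit[ot] <- stats::runif(length(ot)) < ch$off_target[[rt]]
        }
      }
    }
    take <- hit & is.na(tags)
    tags[take] <- cname
  }
  tags
}

#' Tag a structure
#'
#' Convenience wrapper: runs \code{\link{apply_labeling}} on the structure's
#' sequence and stores the result in its \code{tags} field.
#'
#' @inheritParams apply_labeling
#' @param s A \code{lattice_structure}.
#' @return The tagged structure.
#' @export
label_structure <- function(s, scheme, mode = "optimal") {
  s$tags <- apply_labeling(s$sequence, scheme, mode)
  s
}

# ---- tag steric geometry -------------------------------------------------

# TRUE where vertex-difference rows are reachable in <= 2 lattice bonds:
# either a bond vector, or a sum of two bonds (all components even, max
# |component| <= 2), or zero.
.within_two_bonds <- function(delta) {
  a1 <- abs(delta[, 1L]); a2 <- abs(delta[, 2L]); a3 <- abs(delta[, 3L])
  one <- a1 == 1L & a2 == 1L & a3 == 1L
  two <- a1 + a2 + a3 <= 2L            # zero or a single axial two-step
  one | two
}

# Blockers along one route (matrix of route vertices): chain residues whose
# vertex lies in the tag's swept volume -- within Euclidean distance 2
# lattice units of a route vertex, i.e. a bond vector (all components +/-1)
# or an axial two-step (a single component +/-2). `others` excludes the
# tagged residue and its bonded chain neighbours.
.route_blockers <- function(route, others) {
  n <- nrow(others)
  if (n == 0L) return(0L)
  a1 <- abs(outer(others[, 1L], route[, 1L], "-"))
  a2 <- abs(outer(others[, 2L], route[, 2L], "-"))
  a3 <- abs(outer(others[, 3L], route[, 3L], "-"))
  one <- a1 == 1L & a2 == 1L & a3 == 1L
  sum(rowSums(one | (a1 + a2 + a3 <= 2L)) > 0L)
}

#' Count residues blocking a tag's route to the periphery
#'
#' A DNA tag occupies vertices up to two bonds away from its backbone, which
#' runs from the tagged residue outward. The blocker count is the minimum,
#' over candidate routes, of the number of chain residues intersecting the
#' swept tag volume. Routes are straight rays along the eight bond directions
#' from the tagged residue to outside the structure's bounding box; if every
#' straight ray is blocked, single-bend routes (first leg 1–3 steps, then
#' straight to the exit) are also searched. The tagged residue and its two
#' bonded chain neighbours are never counted (they are covalently constrained
#' into the tag's vicinity). A count of 0 means the tag fits without steric
#' hindrance.
#'
#' @param s A valid \code{lattice_structure}.
#' @param idx Index of a tagged residue.
#' @return Integer blocker count (minimum over routes).
#' @export
clearance_blockers <- function(s, idx) {
  if (is.na(s$tags[idx])) stop("residue ", idx, " is not tagged")
  coords <- s$coords
  v <- coords[idx, ]
  excl <- unique(pmax(1L, pmin(s$n_res, c(idx - 1L, idx, idx + 1L))))
  others <- coords[-excl, , drop = FALSE]
  lo <- c(min(coords[, 1L]), min(coords[, 2L]), min(coords[, 3L])) - 2L
  hi <- c(max(coords[, 1L]), max(coords[, 2L]), max(coords[, 3L])) + 2L
  ray <- function(from, d) {
    # vertices from+d, from+2d, ..., first vertex outside [lo, hi] included
    lim <- ifelse(d > 0L, hi - from, from - lo)
    kmax <- max(1L, min(lim) + 1L)
    matrix(from, kmax, 3L, byrow = TRUE) +
      seq_len(kmax) %o% as.integer(d)
  }
  # all straight rays batched: one blocked-matrix evaluation
  rays <- lapply(seq_len(8L), function(k) ray(v, .bond_vectors[k, ]))
  pts <- do.call(rbind, rays)
  ray_id <- rep.int(seq_len(8L), vapply(rays, nrow, integer(1)))
  a1 <- abs(outer(others[, 1L], pts[, 1L], "-"))
  a2 <- abs(outer(others[, 2L], pts[, 2L], "-"))
  a3 <- abs(outer(others[, 3L], pts[, 3L], "-"))
  blocked <- (a1 == 1L & a2 == 1L & a3 == 1L) | (a1 + a2 + a3 <= 2L)
  best <- Inf
  for (k in seq_len(8L)) {
    bk <- blocked[, ray_id == k, drop = FALSE]
    b <- sum(rowSums(bk) > 0L)
    if (b < best) best <- b
    if (best == 0L) return(0L)
  }
  # single-bend routes, batched over deduplicated route vertices
  routes <- list()
  all_pts <- list()
  for (k1 in seq_len(8L)) {
    d1 <- .bond_vectors[k1, ]
    for (steps in 1:3) {
      leg1 <- matrix(v, steps, 3L, byrow = TRUE) + .bend_legs[[k1]][[steps]]
      elbow <- v + steps * d1
      for (k2 in seq_len(8L)) {
        if (k2 == k1) next
        d2 <- .bond_vectors[k2, ]
        if (all(d2 == -d1)) next
        route <- rbind(leg1, ray(elbow, d2))
        routes[[length(routes) + 1L]] <- route
        all_pts[[length(all_pts) + 1L]] <- route
      }
    }
  }
  pts <- do.call(rbind, all_pts)
  keys <- .vertex_key(pts)
  ukeys <- unique(keys)
  upts <- pts[match(ukeys, keys), , drop = FALSE]
  a1 <- abs(outer(others[, 1L], upts[, 1L], "-"))
  a2 <- abs(outer(others[, 2L], upts[, 2L], "-"))
  a3 <- abs(outer(others[, 3L], upts[, 3L], "-"))
  blocked_u <- ((a1 == 1L & a2 == 1L & a3 == 1L) |
                  (a1 + a2 + a3 <= 2L)) * 1
  # membership matrix: unique vertex x route; per-route blocker counts via
  # one matrix product
  membership <- matrix(0, length(ukeys), length(routes))
  membership[cbind(match(keys, ukeys),
                   rep.int(seq_along(routes),
                           vapply(routes, nrow, integer(1))))] <- 1
  counts <- colSums((blocked_u %*% membership) > 0)
  as.integer(min(best, counts))
}

#' Check the repulsion constraint between a pair of nearby tags
#'
#' Tags repel electrostatically: when two tagged residues lie within 20 Å of
#' each other, their tag orientations must differ by at least 70 degrees in
#' both the inter-tag angle and the dihedral about the inter-residue axis.
#' Beyond 20 Å the constraint is inactive.
#'
#' @param orient_a,orient_b Orientation vectors (lattice directions) of the
#'   two tags.
#' @param distance Distance in Å between the two tagged residues.
#' @param axis Optional inter-residue axis vector (needed for the dihedral;
#'   if omitted only the angle is checked).
#' @param min_angle Minimum angle and dihedral in degrees (default 70).
#' @param max_distance Distance threshold in Å (default 20).
#' @return Logical.
#' @export
tag_pair_constraint_ok <- function(orient_a, orient_b, distance, axis = NULL,
                                   min_angle = 70, max_distance = 20) {
  if (sum(orient_a^2) == 0 || sum(orient_b^2) == 0) {
    stop("zero-length tag orientation")
  }
  if (distance > max_distance) return(TRUE)
  ang <- .vec_angle(orient_a, orient_b)
  if (ang < min_angle) return(FALSE)
  if (is.null(axis)) return(TRUE)
  dih <- .dihedral_about(orient_a, orient_b, axis)
  is.na(dih) || dih >= min_angle
}

.vec_angle <- function(a, b) {
  ct <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

# Dihedral between two vectors about an axis: angle between their components
# perpendicular to the axis. NA when a projection degenerates (tag parallel
# to the axis), in which case the constraint is treated as satisfied.
.dihedral_about <- function(a, b, axis) {
  r <- axis / sqrt(sum(axis^2))
  pa <- a - sum(a * r) * r
  pb <- b - sum(b * r) * r
  if (sum(pa^2) < 1e-12 || sum(pb^2) < 1e-12) return(NA_real_)
  .vec_angle(pa, pb)
}
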