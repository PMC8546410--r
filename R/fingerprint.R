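#' FRET model constants
#'
#' @param r0 Förster radius in Å (default 54, Cy3–Cy5).
#' @param resolution Fingerprint bin width in FRET efficiency units
#'   (default 0.01).
#' @param dye_offset Dye standoff from the tagged residue along the tag
#'   orientation, in Å: the effective arm of the DNA docking/imager duplex
#'   carrying the dye. The default (22 Å, roughly a 6 bp duplex segment plus
#'   linker) is the one calibrated parameter of the fingerprint model; see
#'   the methods vignette.
#' @return An object of class \code{fret_constants}.
#' @export
fret_constants <- function(r0 = 54, resolution = 0.01, dye_offset = 22) {
  stopifnot(r0 > 0, resolution > 0, resolution <= 1, dye_offset >= 0)
  structure(list(r0 = r0, resolution = resolution, dye_offset = dye_offset),
            class = "fret_constants")
}

#' FRET efficiency from a donor-acceptor distance
#'
#' \eqn{E = 1 / (1 + (R/R_0)^6)}; \eqn{E = 0.5} exactly at \eqn{R = R_0},
#' strictly decreasing in \eqn{R}.
#'
#' @param r Distance(s) in Å, non-negative.
#' @param constants A \code{\link{fret_constants}} (only \code{r0} is used).
#' @return Efficiency in (0, 1].
#' @export
fret_efficiency <- function(r, constants = fret_constants()) {
  if (any(r < 0)) stop("distance must be non-negative")
  1 / (1 + (r / constants$r0)^6)
}

#' Sample conformational snapshots after folding
#'
#' Continues the cold-chain MCMC of a finished, hindrance-free folding run
#' for another \code{n_steps} steps (default 1,000), recording the structure
#' every \code{interval} steps (default 10), i.e. 100 slightly different
#' conformations that emulate molecular motion during a measurement.
#'
#' @param result A \code{folding_result} with \code{hindrance_free = TRUE}.
#' @param n_steps,interval Continuation length and snapshot cadence.
#' @param seed Optional integer seed.
#' @return List of \code{lattice_structure} snapshots.
#' @export
sample_snapshots <- function(result, n_steps = 1000L, interval = 10L,
                             seed = NULL) {
  if (!isTRUE(result$hindrance_free)) {
    stop("fingerprint undefined: folding did not reach a hindrance-free structure")
  }
  if (!is.null(seed)) set.seed(seed)
  .continue_chain(result$structure, result$params, result$config$t_cold,
                  as.integer(n_steps), as.integer(interval))
}

# Accessible tag directions at residue idx: bond directions whose first two
# arm vertices have an unoccupied swept volume (no chain residue within the
# tag volume, the tagged residue and its bonded neighbours excepted).
.accessible_directions <- function(s, idx) {
  v <- s$coords[idx, ]
  excl <- unique(pmax(1L, pmin(s$n_res, c(idx - 1L, idx, idx + 1L))))
  others <- s$coords[-excl, , drop = FALSE]
  if (nrow(others) == 0L) return(seq_len(8L))
  pts <- rbind(sweep(.bond_vectors, 2L, v, "+"),
               sweep(2L * .bond_vectors, 2L, v, "+"))
  a1 <- abs(outer(others[, 1L], pts[, 1L], "-"))
  a2 <- abs(outer(others[, 2L], pts[, 2L], "-"))
  a3 <- abs(outer(others[, 3L], pts[, 3L], "-"))
  blocked <- colSums((a1 == 1L & a2 == 1L & a3 == 1L) |
                       (a1 + a2 + a3 <= 2L)) > 0L
  which(!(blocked[1:8] | blocked[9:16]))
}

#' Place dyes on a snapshot
#'
#' For every tagged residue an orientation is drawn uniformly from the
#' accessible lattice directions (those whose swept tag volume is
#' unoccupied); orientations of tag pairs closer than 20 Å are redrawn
#' (bounded rejection sampling) until the mutual-repulsion constraint
#' (\code{\link{tag_pair_constraint_ok}}) holds for all such pairs. The dye
#' sits at the tagged residue's physical position plus \code{dye_offset}
#' along the orientation.
#'
#' @param snapshot A tagged \code{lattice_structure}.
#' @param constants A \code{\link{fret_constants}}.
#' @param max_attempts Rejection-sampling bound (default 50).
#' @return A list with \code{residue} (indices), \code{channel}, \code{dye}
#'   (k x 3 matrix of dye positions in Å), or \code{NULL} when no admissible
#'   placement exists (snapshot skipped).
#' @export
place_dyes <- function(snapshot, constants = fret_constants(),
                       max_attempts = 50L) {
  tagged <- which(!is.na(snapshot$tags))
  if (!length(tagged)) stop("snapshot has no tagged residues")
  dirs <- lapply(tagged, function(i) .accessible_directions(snapshot, i))
  if (any(lengths(dirs) == 0L)) return(NULL)
  pos <- snapshot$coords[tagged, , drop = FALSE] * .lattice_scale
  k <- length(tagged)
  # residue pairs subject to the repulsion constraint
  close_pairs <- NULL
  if (k > 1L) {
    pr <- utils::combn(k, 2L)
    d <- sqrt(colSums((t(pos[pr[1L, ], , drop = FALSE]) -
                         t(pos[pr[2L, ], , drop = FALSE]))^2))
    close_pairs <- pr[, d <= 20, drop = FALSE]
  }
  draw <- function() {
    sel <- vapply(dirs, function(dd) dd[sample.int(length(dd), 1L)],
                  integer(1))
    .bond_vectors[sel, , drop = FALSE] / sqrt(3)
  }
  orient <- draw()
  if (!is.null(close_pairs) && ncol(close_pairs)) {
    ok <- function(o) {
      for (c_i in seq_len(ncol(close_pairs))) {
        a <- close_pairs[1L, c_i]; b <- close_pairs[2L, c_i]
        dist_ab <- sqrt(sum((pos[a, ] - pos[b, ])^2))
        if (!tag_pair_constraint_ok(o[a, ], o[b, ], dist_ab,
                                    axis = pos[b, ] - pos[a, ])) {
          return(FALSE)
        }
      }
      TRUE
    }
    attempt <- 1L
    while (!ok(orient)) {
      attempt <- attempt + 1L
      if (attempt > max_attempts) return(NULL)
      orient <- draw()
    }
  }
  list(residue = tagged,
       channel = snapshot$tags[tagged],
       dye = pos + orient * constants$dye_offset)
}

#' Build a simulated FRET fingerprint from snapshots
#'
#' Per tag channel: the donor–acceptor distance (dye on the channel residue
#' to the dye on the N-terminal reference residue) is measured on every
#' snapshot, averaged over consecutive non-overlapping blocks of
#' \code{block} snapshots (emulating molecular motion within one camera
#' frame), converted to a FRET efficiency per block, binned at
#' \code{resolution} and normalized over the number of frames. Snapshots with
#' no admissible dye placement are dropped (with renormalization over the
#' remaining frames).
#'
#' @param snapshots List of tagged \code{lattice_structure} snapshots (all
#'   the same molecule).
#' @param constants A \code{\link{fret_constants}}.
#' @param block Snapshots averaged per frame (default 10).
#' @param seed Optional integer seed (dye placement randomness).
#' @return An object of class \code{fingerprint}: \code{channels} (named
#'   list; per channel \code{values} (per-frame E), \code{counts} (normalized
#'   histogram), \code{breaks}), \code{resolution}, \code{n_frames},
#'   \code{n_skipped}.
#' @export
build_fingerprint <- function(snapshots, constants = fret_constants(),
                              block = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(snapshots) < block) stop("need at least one full block of snapshots")
  tags0 <- snapshots[[1L]]$tags
  ref <- which(tags0 == "ref")[1L]
  if (is.na(ref)) stop("snapshots carry no reference tag")
  placements <- lapply(snapshots, place_dyes, constants = constants)
  skipped <- vapply(placements, is.null, logical(1))
  placements <- placements[!skipped]
  if (length(placements) < block) {
    stop("too few usable snapshots after dye-placement rejection")
  }
  chan_res <- setdiff(unique(stats::na.omit(tags0)), "ref")
  residues <- which(!is.na(tags0) & tags0 != "ref")
  # distances: snapshots x tagged residues
  dmat <- t(vapply(placements, function(p) {
    refrow <- match(ref, p$residue)
    dye_ref <- p$dye[refrow, ]
    rows <- match(residues, p$residue)
    sqrt(rowSums((p$dye[rows, , drop = FALSE] -
                    matrix(dye_ref, length(rows), 3L, byrow = TRUE))^2))
  }, numeric(length(residues))))
  if (length(residues) == 1L) dmat <- matrix(dmat, ncol = 1L)
  n_blocks <- nrow(dmat) %/% block
  dmat <- dmat[seq_len(n_blocks * block), , drop = FALSE]
  grp <- rep(seq_len(n_blocks), each = block)
  channels <- list()
  breaks <- seq(0, 1, by = constants$resolution)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  for (ch in chan_res) {
    cols <- which(tags0[residues] == ch)
    vals <- numeric(0)
    for (cc in cols) {
      mean_d <- vapply(split(dmat[, cc], grp), mean, numeric(1))
      vals <- c(vals, fret_efficiency(mean_d, constants))
    }
    counts <- graphics::hist(vals, breaks = breaks, plot = FALSE,
                             include.lowest = TRUE, right = TRUE)$counts
    channels[[ch]] <- list(values = unname(vals),
                           counts = counts / max(1L, length(vals)),
                           breaks = breaks)
  }
  structure(list(channels = channels,
                 resolution = constants$resolution,
                 n_frames = n_blocks,
                 n_skipped = sum(skipped)),
            class = "fingerprint")
}

#' Simulate one molecule's fingerprint end to end
#'
#' Convenience composition: label, fold, snapshot, fingerprint.
#'
#' @param s A \code{lattice_structure} (untagged).
#' @param scheme A \code{\link{labeling_scheme}}.
#' @param mode Labeling mode (\code{"optimal"} / \code{"suboptimal"}).
#' @param params,config,constants Model parameter objects.
#' @param seed Integer seed driving labeling, folding and snapshots.
#' @return A \code{fingerprint}, or \code{NULL} when folding never reached a
#'   hindrance-free structure or the molecule drew no non-reference tags.
#' @export
simulate_fingerprint <- function(s, scheme, mode = "optimal",
                                 params = energy_params(),
                                 config = folding_config(),
                                 constants = fret_constants(),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- label_structure(s, scheme, mode)
  if (sum(!is.na(s$tags)) < 2L) return(NULL)   # reference only: no FRET pair
  res <- fold(s, params, config)
  if (!res$hindrance_free) return(NULL)
  snaps <- sample_snapshots(res)
  tryCatch(build_fingerprint(snaps, constants),
           error = function(e) NULL)   # molecule unusable (dye rejection)
}

#' Simulate replicate fingerprints until a target count is measured
#'
#' Repeatedly simulates independent molecules
#' (\code{\link{simulate_fingerprint}}) with consecutive seeds until
#' \code{n} usable fingerprints are collected, mirroring an experiment that
#' keeps measuring molecules until the required number is recorded;
#' molecules whose folding never clears the tags or whose dye placement is
#' rejected are skipped.
#'
#' @inheritParams simulate_fingerprint
#' @param n Number of replicate fingerprints to collect.
#' @param seed Base seed; molecule k uses \code{seed + k}.
#' @param max_attempts Attempt cap (default \code{4 * n}).
#' @return List of \code{n} fingerprints (fewer, with a warning, if the cap
#'   is hit).
#' @export
simulate_replicates <- function(s, scheme, mode = "optimal",
                                params = energy_params(),
                                config = folding_config(),
                                constants = fret_constants(),
                                n = 10L, seed = 1L, max_attempts = 4L * n) {
  out <- list()
  k <- 0L
  while (length(out) < n && k < max_attempts) {
    k <- k + 1L
    fp <- simulate_fingerprint(s, scheme, mode, params, config, constants,
                               seed = seed + k)
    if (!is.null(fp)) out[[length(out) + 1L]] <- fp
  }
  if (length(out) < n) {
    warning("collected only ", length(out), " of ", n,
            " usable fingerprints")
  }
  out
}

#' @export
print.fingerprint <- function(x, ...) {
  cat("fingerprint:", length(x$channels), "channel(s),", x$n_frames,
      "frames, resolution", x$resolution, "\n")
  for (ch in names(x$channels)) {
    v <- x$channels[[ch]]$values
    cat(sprintf("  %s: %d value(s), mean E = %.3f\n", ch, length(v),
                mean(v)))
  }
  invisible(x)
}

#' Write / read fingerprints as TSV (channel, bin_left_edge, weight)
#'
#' The TSV holds one row per channel bin. Reading reconstructs the binned
#' histogram (the per-frame values are not stored in this format).
#'
#' @param fp A \code{fingerprint}.
#' @param path File path.
#' @export
write_fingerprint_tsv <- function(fp, path) {
  rows <- do.call(rbind, lapply(names(fp$channels), function(ch) {
    b <- fp$channels[[ch]]
    data.frame(channel = ch, bin_left_edge = b$breaks[-length(b$breaks)],
               weight = b$counts)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_fingerprint_tsv
#' @export
read_fingerprint_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("channel", "bin_left_edge", "weight") %in% names(tab)))
  channels <- lapply(split(tab, tab$channel), function(t0) {
    t0 <- t0[order(t0$bin_left_edge), ]
    res <- diff(t0$bin_left_edge[1:2])
    list(values = numeric(0), counts = t0$weight,
         breaks = c(t0$bin_left_edge, t0$bin_left_edge[nrow(t0)] + res))
  })
  res <- diff(sort(unique(tab$bin_left_edge))[1:2])
  structure(list(channels = channels, resolution = res,
                 n_frames = NA_integer_, n_skipped = NA_integer_),
            class = "fingerprint")
}

#' Write a fingerprint as JSON
#'
#' @param fp A \code{fingerprint}.
#' @param path Output path.
#' @export
write_fingerprint_json <- function(fp, path) {
  jsonlite::write_json(list(resolution = fp$resolution,
                            n_frames = fp$n_frames,
                            channels = lapply(fp$channels, function(b) {
                              list(bin_left_edge =
                                     b$breaks[-length(b$breaks)],
                                   weight = b$counts,
                                   values = b$values)
                            })),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
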