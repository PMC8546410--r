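#' Construct a donor/acceptor intensity trace
#'
#' @param donor,acceptor Equal-length numeric vectors of per-frame donor and
#'   acceptor intensities (arbitrary units).
#' @param exposure Exposure time per frame in seconds (default 0.1).
#' @return An object of class \code{intensity_trace}.
#' @export
intensity_trace <- function(donor, acceptor, exposure = 0.1) {
  stopifnot(length(donor) == length(acceptor), all(is.finite(donor)),
            all(is.finite(acceptor)), exposure > 0)
  structure(list(donor = as.numeric(donor), acceptor = as.numeric(acceptor),
                 exposure = exposure, n_frames = length(donor)),
            class = "intensity_trace")
}

#' Read intensity traces from delimited text
#'
#' Accepts either one trace per file (columns \code{donor}, \code{acceptor},
#' optional \code{frame}) or a long-format table with a \code{molecule}
#' column, split into one trace per molecule.
#'
#' @param path Path to a delimited text file (sep auto-detected by
#'   \code{read.table}'s default whitespace or given explicitly).
#' @param sep Field separator (default tab).
#' @param exposure Exposure time in seconds.
#' @return A named list of \code{intensity_trace} objects.
#' @export
read_traces <- function(path, sep = "\t", exposure = 0.1) {
  tab <- utils::read.table(path, header = TRUE, sep = sep)
  names(tab) <- tolower(names(tab))
  stopifnot(all(c("donor", "acceptor") %in% names(tab)))
  if ("molecule" %in% names(tab)) {
    split_tab <- split(tab, tab$molecule)
    lapply(split_tab, function(t0) {
      intensity_trace(t0$donor, t0$acceptor, exposure)
    })
  } else {
    list(trace1 = intensity_trace(tab$donor, tab$acceptor, exposure))
  }
}

#' Detect imager-strand binding events in an intensity trace
#'
#' Two-state K-means clustering of the summed donor + acceptor intensity of
#' the individual molecule separates bound (high-intensity) from unbound
#' frames; maximal runs of bound frames lasting more than \code{min_frames}
#' consecutive frames (strictly; default > 3, i.e. at least 4) become events.
#' The clustering is initialized deterministically at the minimum and maximum
#' summed intensity. A trace whose two cluster centers are indistinguishable
#' — constant, or separated by less than \code{min_separation} pooled
#' within-cluster standard deviations (K-means splits even pure noise into
#' two levels about 2.7 within-cluster SDs apart) — yields zero events with
#' a warning.
#'
#' @param trace An \code{intensity_trace}.
#' @param min_frames Events must exceed this many frames (default 3).
#' @param min_separation Minimum center separation in pooled within-cluster
#'   standard deviations (default 3).
#' @return A data frame with columns \code{start}, \code{end} (inclusive
#'   frame indices), one row per event.
#' @export
detect_events <- function(trace, min_frames = 3L, min_separation = 3) {
  total <- trace$donor + trace$acceptor
  if (length(total) < 10L) stop("trace too short (< 10 frames)")
  rng <- range(total)
  if (diff(rng) < .Machine$double.eps * max(1, abs(rng[2L]))) {
    warning("constant intensity trace: no events detectable")
    return(data.frame(start = integer(0), end = integer(0)))
  }
  km <- stats::kmeans(total, centers = matrix(rng, 2L, 1L))
  within_sd <- sqrt(km$tot.withinss / length(total))
  if (abs(diff(as.vector(km$centers))) < min_separation * within_sd) {
    warning("bound and unbound intensity levels are indistinguishable")
    return(data.frame(start = integer(0), end = integer(0)))
  }
  bound_cluster <- which.max(km$centers)
  bound <- km$cluster == bound_cluster
  r <- rle(bound)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths > min_frames
  data.frame(start = starts[keep], end = ends[keep])
}

#' Per-event FRET efficiency
#'
#' The per-frame efficiency is the proximity ratio
#' \eqn{E = I_A / (I_A + I_D)} (optionally corrected for donor leakage and
#' detection-efficiency ratio gamma); the event value is its mean over the
#' event's frames. Frames with non-positive total intensity are dropped from
#' the mean.
#'
#' @param trace An \code{intensity_trace}.
#' @param start,end Inclusive frame span of the event.
#' @param leakage Fraction of donor signal leaking into the acceptor channel
#'   (default 0: raw proximity ratio).
#' @param gamma Detection-efficiency correction factor (default 1).
#' @return A list of class \code{fret_event}: \code{start}, \code{end},
#'   \code{values} (per-frame E, clipped to [0, 1]), \code{mean_e}.
#' @export
event_fret <- function(trace, start, end, leakage = 0, gamma = 1) {
  stopifnot(start >= 1L, end <= trace$n_frames, start <= end)
  id <- trace$donor[start:end]
  ia <- trace$acceptor[start:end] - leakage * id
  tot <- ia + gamma * id
  ok <- tot > 0
  e <- pmin(1, pmax(0, ia[ok] / tot[ok]))
  structure(list(start = start, end = end, values = e,
                 mean_e = mean(e)),
            class = "fret_event")
}

#' Event table for one molecule
#'
#' Composition of \code{\link{detect_events}} and \code{\link{event_fret}}.
#'
#' @inheritParams event_fret
#' @param ... Passed to \code{detect_events}.
#' @return Data frame with \code{start}, \code{end}, \code{n_frames},
#'   \code{mean_e}.
#' @export
trace_events <- function(trace, leakage = 0, gamma = 1, ...) {
  ev <- detect_events(trace, ...)
  if (nrow(ev) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      n_frames = integer(0), mean_e = numeric(0)))
  }
  me <- vapply(seq_len(nrow(ev)), function(i) {
    event_fret(trace, ev$start[i], ev$end[i], leakage, gamma)$mean_e
  }, numeric(1))
  data.frame(start = ev$start, end = ev$end,
             n_frames = ev$end - ev$start + 1L, mean_e = me)
}

#' Fit a Gaussian-mixture fingerprint to event FRET values
#'
#' Populations in the histogram of per-event mean FRET efficiencies are
#' resolved by Gaussian mixture modelling; the number of components (1 to
#' \code{max_components}) is selected automatically by BIC. Component means,
#' widths (standard deviations) and weights constitute the experimental
#' fingerprint. A collapsed component (width below \code{width_floor}) causes
#' a refit with equal variances, flagged in the result.
#'
#' @param event_means Numeric vector of per-event mean FRET efficiencies
#'   (at least 10).
#' @param max_components Maximum number of mixture components (default 3).
#' @param width_floor Minimum admissible component standard deviation
#'   (default 1e-3).
#' @return An object of class \code{experimental_fingerprint}: \code{means},
#'   \code{widths}, \code{weights} (summing to 1), \code{n_components},
#'   \code{dominant} (mean of the heaviest component), \code{degenerate}.
#' @export
fit_fingerprint <- function(event_means, max_components = 3L,
                            width_floor = 1e-3) {
  if (length(event_means) < 10L) stop("need at least 10 events")
  mclustBIC <- mclust::mclustBIC   # Mclust resolves it in the caller frame
  fit <- mclust::Mclust(event_means, G = seq_len(max_components),
                        modelNames = c("E", "V"), verbose = FALSE)
  sd_of <- function(f) {
    v <- f$parameters$variance$sigmasq
    sqrt(rep_len(v, f$G))
  }
  degenerate <- any(sd_of(fit) < width_floor)
  if (degenerate) {
    fit <- mclust::Mclust(event_means, G = seq_len(max_components),
                          modelNames = "E", verbose = FALSE)
  }
  w <- as.numeric(fit$parameters$pro)
  m <- as.numeric(fit$parameters$mean)
  o <- order(m)
  structure(list(means = m[o], widths = sd_of(fit)[o], weights = w[o],
                 n_components = fit$G,
                 dominant = m[which.max(w)],
                 degenerate = degenerate),
            class = "experimental_fingerprint")
}

#' @export
print.experimental_fingerprint <- function(x, ...) {
  cat("experimental_fingerprint:", x$n_components, "component(s)\n")
  for (i in seq_along(x$means)) {
    cat(sprintf("  E = %.3f +/- %.3f (weight %.2f)\n", x$means[i],
                x$widths[i], x$weights[i]))
  }
  invisible(x)
}
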