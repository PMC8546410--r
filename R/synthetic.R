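#' Synthetic model peptide
#'
#' Builds a 40-residue-style model peptide: lysine at the N terminus (the
#' reference-tag attachment site), a single cysteine at a chosen position,
#' and an inert low-interaction glycine/serine filler elsewhere (synthetic
#' stand-in; a real backbone sequence can be supplied via \code{filler}).
#' The starting structure is a stretched configuration.
#'
#' @param length Peptide length (default 40).
#' @param cys_position 1-based cysteine position.
#' @param filler Either a repeat unit used to fill remaining positions
#'   (default \code{c("G", "S")}) or a full-length backbone sequence whose
#'   positions 1 and \code{cys_position} are overwritten with K and C.
#' @return A list: \code{sequence} (character vector), \code{structure}
#'   (stretched \code{lattice_structure}).
#' @export
make_peptide <- function(length = 40L, cys_position = 10L,
                         filler = c("G", "S")) {
  if (cys_position < 1L || cys_position > length) {
    stop("cys_position out of range")
  }
  if (length(filler) == length) {
    seq1 <- toupper(filler)
  } else {
    seq1 <- rep_len(toupper(filler), length)
  }
  seq1[1L] <- "K"
  seq1[cys_position] <- "C"
  list(sequence = seq1, structure = stretched_peptide(seq1))
}

#' Specification for a synthetic two-state intensity trace
#'
#' Emulates the transient-binding signal of exchangeable donor/acceptor
#' imager strands: alternating exponentially distributed bound and unbound
#' dwells discretized to camera frames. Bound frames emit
#' \code{I_A = signal * E + noise}, \code{I_D = signal * (1 - E) + noise};
#' unbound frames emit background + noise.
#'
#' @param true_e True FRET efficiency of the bound state.
#' @param dwell_bound,dwell_unbound Mean dwell times in seconds (defaults 2
#'   and 2; the imager strands are designed for roughly 2 s dwells).
#' @param frame_time Exposure time in seconds (default 0.1).
#' @param signal,background Intensity levels (arbitrary units).
#' @param noise_sd Gaussian noise standard deviation.
#' @param n_frames Trace length in frames.
#' @return An object of class \code{trace_sim_spec}.
#' @export
trace_sim_spec <- function(true_e = 0.6, dwell_bound = 2, dwell_unbound = 2,
                           frame_time = 0.1, signal = 1000, background = 50,
                           noise_sd = 30, n_frames = 2000L) {
  stopifnot(true_e >= 0, true_e <= 1, dwell_bound > 0, dwell_unbound > 0,
            frame_time > 0, n_frames >= 10L)
  structure(list(true_e = true_e, dwell_bound = dwell_bound,
                 dwell_unbound = dwell_unbound, frame_time = frame_time,
                 signal = signal, background = background,
                 noise_sd = noise_sd, n_frames = as.integer(n_frames)),
            class = "trace_sim_spec")
}

#' Simulate a two-state donor/acceptor intensity trace
#'
#' @param spec A \code{\link{trace_sim_spec}}.
#' @param seed Optional integer seed.
#' @return A list: \code{trace} (an \code{intensity_trace}), \code{events}
#'   (ground-truth data frame with \code{start}, \code{end} of every bound
#'   run, regardless of length), \code{spec}.
#' @export
simulate_trace <- function(spec = trace_sim_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_frames
  bound <- logical(n)
  t_now <- 0
  state <- FALSE                       # start unbound
  end_time <- n * spec$frame_time
  while (t_now < end_time) {
    dwell <- stats::rexp(1L, rate = 1 / if (state) spec$dwell_bound else
      spec$dwell_unbound)
    f0 <- floor(t_now / spec$frame_time) + 1
    f1 <- min(n, ceiling((t_now + dwell) / spec$frame_time))
    if (state && f0 <= n) bound[f0:f1] <- TRUE
    t_now <- t_now + dwell
    state <- !state
  }
  ia <- ifelse(bound, spec$signal * spec$true_e, spec$background)
  id <- ifelse(bound, spec$signal * (1 - spec$true_e), spec$background)
  if (spec$noise_sd > 0) {
    ia <- ia + stats::rnorm(n, 0, spec$noise_sd)
    id <- id + stats::rnorm(n, 0, spec$noise_sd)
  }
  r <- rle(bound)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  events <- data.frame(start = starts[r$values], end = ends[r$values])
  list(trace = intensity_trace(id, ia, spec$frame_time),
       events = events, spec = spec)
}

#' Synthetic class-structured fingerprint dataset
#'
#' Generates a dataset for classifier tests without any folding: each class
#' is a set of FRET peak locations; each replicate jitters the peak positions
#' with Gaussian noise, spreads a fixed number of frame values around them,
#' and bins the values into a \code{fingerprint}.
#'
#' @param n_classes Number of protein identities.
#' @param replicates Replicates per class (default 10).
#' @param separation Spacing between adjacent class peak sets in E units.
#' @param noise Replicate-to-replicate peak jitter (standard deviation,
#'   E units).
#' @param n_peaks Peaks per class per channel (default 2).
#' @param channels Channel names (default \code{"C"}).
#' @param values_per_peak Frame values drawn per peak (default 10).
#' @param resolution Fingerprint bin width (default 0.01).
#' @param seed Optional integer seed.
#' @return A \code{\link{fingerprint_dataset}}.
#' @export
make_fingerprint_classes <- function(n_classes = 3L, replicates = 10L,
                                     separation = 0.1, noise = 0.01,
                                     n_peaks = 2L, channels = "C",
                                     values_per_peak = 10L,
                                     resolution = 0.01, seed = NULL) {
  stopifnot(n_classes >= 2L, replicates >= 2L, noise >= 0, separation >= 0)
  if (!is.null(seed)) set.seed(seed)
  breaks <- seq(0, 1, by = resolution)
  base <- seq(0.15, 0.85, length.out = n_peaks)
  proteins <- list()
  for (cl in seq_len(n_classes)) {
    peaks <- (base + (cl - 1L) * separation) %% 0.9 + 0.05
    reps <- list()
    for (r in seq_len(replicates)) {
      chans <- list()
      for (ch in channels) {
        centers <- peaks + stats::rnorm(n_peaks, 0, noise)
        vals <- pmin(1, pmax(1e-6, rep(centers, each = values_per_peak) +
                               stats::rnorm(n_peaks * values_per_peak, 0,
                                            noise / 2)))
        counts <- graphics::hist(vals, breaks = breaks, plot = FALSE,
                                 include.lowest = TRUE,
                                 right = TRUE)$counts
        chans[[ch]] <- list(values = vals,
                            counts = counts / length(vals),
                            breaks = breaks)
      }
      reps[[r]] <- structure(list(channels = chans, resolution = resolution,
                                  n_frames = n_peaks * values_per_peak,
                                  n_skipped = 0L),
                             class = "fingerprint")
    }
    proteins[[paste0("protein_", cl)]] <- reps
  }
  fingerprint_dataset(proteins)
}

#' Random canonical protein sequence
#'
#' Draws residues with replacement, optionally forcing a composition
#' enriched in the taggable types C/K/R, for desk-scale classifier studies.
#'
#' @param length Sequence length.
#' @param n_c,n_k,n_r Counts of cysteine / lysine / arginine placed at
#'   random positions (besides the leading K attachment site).
#' @param seed Optional integer seed.
#' @return Character vector of one-letter codes, starting with K.
#' @export
random_sequence <- function(length = 30L, n_c = 2L, n_k = 2L, n_r = 2L,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pool <- setdiff(.aa_codes, c("C", "K", "R"))
  seq1 <- sample(pool, length, replace = TRUE)
  seq1[1L] <- "K"
  slots <- sample(2:length, n_c + n_k + n_r)
  seq1[slots[seq_len(n_c)]] <- "C"
  if (n_k) seq1[slots[n_c + seq_len(n_k)]] <- "K"
  if (n_r) seq1[slots[n_c + n_k + seq_len(n_r)]] <- "R"
  seq1
}
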