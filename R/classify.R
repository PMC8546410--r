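#' Bundle replicate fingerprints into a dataset
#'
#' @param fingerprints Named list: one element per protein identity, each a
#'   list of replicate \code{fingerprint} objects (all sharing channel set
#'   and resolution).
#' @return An object of class \code{fingerprint_dataset} with fields
#'   \code{proteins}, \code{channels}, \code{resolution},
#'   \code{n_replicates}.
#' @export
fingerprint_dataset <- function(fingerprints) {
  stopifnot(is.list(fingerprints), length(names(fingerprints)) > 0L)
  reps <- lengths(fingerprints)
  if (any(reps < 2L)) stop("every protein needs at least 2 replicates")
  fp1 <- fingerprints[[1L]][[1L]]
  channels <- sort(unique(unlist(lapply(fingerprints, function(rr) {
    unlist(lapply(rr, function(f) names(f$channels)))
  }))))
  structure(list(proteins = fingerprints,
                 channels = channels,
                 resolution = fp1$resolution,
                 n_replicates = unname(reps)),
            class = "fingerprint_dataset")
}

#' Fixed-length feature vector from a fingerprint
#'
#' Concatenates, in a fixed channel order, each channel's histogram re-binned
#' at the requested resolution (bins merged by summation, conserving total
#' weight); channels absent from the fingerprint (no tagged residue of that
#' type) give an all-zero block. Length = \code{length(channels) *
#' ceiling(1/resolution)}.
#'
#' @param fp A \code{fingerprint}.
#' @param channels Character vector fixing the channel order.
#' @param resolution Target bin width; must be an integer multiple of the
#'   fingerprint's native resolution.
#' @return Numeric vector.
#' @export
to_features <- function(fp, channels, resolution = fp$resolution) {
  k <- resolution / fp$resolution
  if (abs(k - round(k)) > 1e-9 || k < 1) {
    stop("target resolution must be an integer multiple of the native one")
  }
  k <- as.integer(round(k))
  n_out <- ceiling(1 / resolution)
  out <- lapply(channels, function(ch) {
    b <- fp$channels[[ch]]
    if (is.null(b)) return(numeric(n_out))
    cnt <- b$counts
    grp <- ceiling(seq_along(cnt) / k)
    merged <- as.numeric(tapply(cnt, grp, sum))
    length(merged) <- n_out          # pad (never needed when 1/res integral)
    merged[is.na(merged)] <- 0
    merged
  })
  unlist(out, use.names = FALSE)
}

.feature_matrix <- function(ds, channels, resolution) {
  rows <- list()
  labels <- character(0)
  rep_id <- integer(0)
  for (p in names(ds$proteins)) {
    for (r in seq_along(ds$proteins[[p]])) {
      rows[[length(rows) + 1L]] <- to_features(ds$proteins[[p]][[r]],
                                               channels, resolution)
      labels <- c(labels, p)
      rep_id <- c(rep_id, r)
    }
  }
  list(x = do.call(rbind, rows), y = factor(labels), rep_id = rep_id)
}

.fit_svm <- function(x, y, ...) {
  keep <- apply(x, 2L, function(col) stats::var(col) > 0)
  if (!any(keep)) keep[1L] <- TRUE
  model <- e1071::svm(x[, keep, drop = FALSE], y, kernel = "radial",
                      scale = FALSE, ...)
  list(model = model, keep = keep)
}

.predict_svm <- function(fit, x) {
  stats::predict(fit$model, x[, fit$keep, drop = FALSE])
}

#' Tune the fingerprint resolution on training data
#'
#' Evaluates candidate bin widths (steps of 0.01 E by default) by the
#' training accuracy of an SVM fitted at each, returning the best; ties are
#' broken toward the finer resolution. Uses training data only.
#'
#' @param ds A \code{fingerprint_dataset}.
#' @param train_idx Row indices (into the dataset's replicate-major ordering)
#'   forming the training split.
#' @param candidates Candidate resolutions (default \code{seq(0.01, 0.1,
#'   0.01)}, restricted to multiples of the native resolution).
#' @return The selected resolution.
#' @export
tune_resolution <- function(ds, train_idx = NULL,
                            candidates = seq(0.01, 0.10, by = 0.01)) {
  candidates <- candidates[
    abs(candidates / ds$resolution - round(candidates / ds$resolution)) < 1e-9]
  candidates <- sort(candidates)
  if (length(candidates) == 1L) return(candidates)
  best_res <- candidates[1L]
  best_acc <- -1
  for (res in candidates) {
    fm <- .feature_matrix(ds, ds$channels, res)
    idx <- if (is.null(train_idx)) seq_along(fm$y) else train_idx
    fit <- .fit_svm(fm$x[idx, , drop = FALSE], droplevels(fm$y[idx]))
    acc <- mean(.predict_svm(fit, fm$x[idx, , drop = FALSE]) ==
                  droplevels(fm$y[idx]))
    if (acc > best_acc + 1e-12) {     # strict improvement: ties stay finer
      best_acc <- acc
      best_res <- res
    }
  }
  best_res
}

#' Cross-validated SVM identification of proteins from fingerprints
#'
#' Stratified k-fold cross-validation of a support-vector machine
#' (radial-basis kernel) on binned fingerprint features. When the replicate
#' count equals the fold count, each fold holds exactly one replicate of
#' every protein (so per-protein correct counts are counts over replicates).
#' Reported accuracy is the arithmetic mean of the per-fold test accuracies.
#'
#' @param ds A \code{fingerprint_dataset}.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed (fold assignment).
#' @param tune Tune the resolution per fold on the training split
#'   (default FALSE: the dataset's native resolution is used).
#' @param channels Channel subset to use (default: all channels in the
#'   dataset).
#' @param ... Passed to \code{e1071::svm}.
#' @return An object of class \code{cv_report}: \code{accuracy},
#'   \code{fold_accuracies}, \code{per_protein_correct} (named counts),
#'   \code{n_replicates}, \code{resolution} (per fold), \code{folds}.
#' @export
cross_validate <- function(ds, folds = 10L, seed = NULL, tune = FALSE,
                           channels = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(channels)) channels <- ds$channels
  reps <- ds$n_replicates
  if (any(reps < folds)) stop("every protein needs at least `folds` replicates")
  fm <- .feature_matrix(ds, channels, ds$resolution)
  # stratified assignment: permute each protein's replicates over folds
  fold_of <- integer(length(fm$y))
  for (p in levels(fm$y)) {
    idx <- which(fm$y == p)
    k <- length(idx)
    fold_of[idx] <- sample(rep_len(seq_len(folds), k))
  }
  fold_acc <- numeric(folds)
  res_used <- numeric(folds)
  correct <- stats::setNames(integer(nlevels(fm$y)), levels(fm$y))
  for (f in seq_len(folds)) {
    test <- which(fold_of == f)
    train <- which(fold_of != f)
    res <- ds$resolution
    if (isTRUE(tune)) {
      ds_sub <- ds
      res <- tune_resolution(ds_sub, train_idx = train)
    }
    xf <- if (res != ds$resolution) {
      .feature_matrix(ds, channels, res)$x
    } else fm$x
    fit <- .fit_svm(xf[train, , drop = FALSE], droplevels(fm$y[train]), ...)
    pred <- .predict_svm(fit, xf[test, , drop = FALSE])
    hits <- as.character(pred) == as.character(fm$y[test])
    fold_acc[f] <- mean(hits)
    res_used[f] <- res
    for (i in which(hits)) {
      p <- as.character(fm$y[test[i]])
      correct[p] <- correct[p] + 1L
    }
  }
  structure(list(accuracy = mean(fold_acc),
                 fold_accuracies = fold_acc,
                 per_protein_correct = correct,
                 n_replicates = max(reps),
                 resolution = res_used,
                 folds = folds),
            class = "cv_report")
}

#' Well-identifiable proteins
#'
#' Proteins correctly classified in strictly more than half of their
#' replicate fingerprints across cross-validation (e.g. more than 5 of 10).
#'
#' @param report A \code{cv_report}.
#' @param replicates Replicate count (default taken from the report).
#' @return Character vector of protein names.
#' @export
well_identifiable <- function(report, replicates = report$n_replicates) {
  names(report$per_protein_correct)[
    report$per_protein_correct > replicates / 2]
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %d-fold CV accuracy = %.3f\n", x$folds,
              x$accuracy))
  wi <- well_identifiable(x)
  cat(sprintf("  well-identifiable: %d of %d proteins\n", length(wi),
              length(x$per_protein_correct)))
  invisible(x)
}
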