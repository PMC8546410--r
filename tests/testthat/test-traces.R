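test_that("noise-only traces yield no binding events", {
  set.seed(1)
  tr <- intensity_trace(rnorm(2000, 50, 5), rnorm(2000, 50, 5))
  expect_warning(ev0 <- detect_events(tr), "indistinguishable")
  expect_equal(nrow(ev0), 0L)
  const <- intensity_trace(rep(10, 50), rep(10, 50))
  expect_warning(ev <- detect_events(const), "constant")
  expect_equal(nrow(ev), 0L)
  expect_error(detect_events(intensity_trace(1:5, 1:5)), "short")
})

test_that("plateaus above three frames are detected, shorter ones rejected", {
  don <- rep(50, 200)
  acc <- rep(50, 200)
  starts <- c(11, 51, 91, 131, 171)
  for (s0 in starts) {
    don[s0:(s0 + 4L)] <- 400   # 5-frame plateaus
    acc[s0:(s0 + 4L)] <- 600
  }
  ev <- detect_events(intensity_trace(don, acc))
  expect_equal(nrow(ev), 5L)
  expect_equal(ev$start, starts)
  expect_equal(ev$end, starts + 4L)

  don3 <- rep(50, 100); acc3 <- rep(50, 100)
  don3[21:23] <- 400; acc3[21:23] <- 600       # exactly 3 frames
  expect_equal(nrow(detect_events(intensity_trace(don3, acc3))), 0L)
  don4 <- don3; acc4 <- acc3
  don4[61:64] <- 400; acc4[61:64] <- 600       # exactly 4 frames
  ev4 <- detect_events(intensity_trace(don4, acc4))
  expect_equal(nrow(ev4), 1L)
  expect_equal(c(ev4$start, ev4$end), c(61L, 64L))
})

test_that("event detection is invariant to common affine rescaling", {
  sim <- simulate_trace(trace_sim_spec(n_frames = 3000), seed = 2)
  ev1 <- detect_events(sim$trace)
  scaled <- intensity_trace(sim$trace$donor * 7.3, sim$trace$acceptor * 7.3)
  expect_equal(detect_events(scaled), ev1)
})

test_that("per-event FRET is the mean proximity ratio", {
  tr <- intensity_trace(rep(100, 20), rep(100, 20))
  expect_equal(event_fret(tr, 1, 20)$mean_e, 0.5)
  tr2 <- intensity_trace(rep(100, 20), rep(300, 20))
  expect_equal(event_fret(tr2, 1, 20)$mean_e, 0.75)
  # frames with non-positive total intensity are dropped
  don <- rep(100, 10); acc <- rep(100, 10)
  don[4] <- -200; acc[4] <- 100
  expect_equal(event_fret(intensity_trace(don, acc), 1, 10)$mean_e, 0.5)
  # noisy event recovers the true efficiency within 3 standard errors
  set.seed(3)
  n <- 400
  e_true <- 0.6
  ia <- 1000 * e_true + rnorm(n, 0, 30)
  id <- 1000 * (1 - e_true) + rnorm(n, 0, 30)
  ev <- event_fret(intensity_trace(id, ia), 1, n)
  se <- sd(ev$values) / sqrt(length(ev$values))
  expect_lt(abs(ev$mean_e - e_true), 3 * se)
})

test_that("Gaussian-mixture fingerprints recover synthetic populations", {
  set.seed(4)
  one <- pmin(1, pmax(0, rnorm(400, 0.5, 0.03)))
  f1 <- fit_fingerprint(one)
  expect_equal(f1$n_components, 1L)
  expect_equal(f1$means, 0.5, tolerance = 0.02)
  expect_equal(sum(f1$weights), 1)

  two <- c(rnorm(500, 0.3, 0.05), rnorm(500, 0.8, 0.05))
  f2 <- fit_fingerprint(pmin(1, pmax(0, two)))
  expect_equal(f2$n_components, 2L)
  expect_lt(max(abs(sort(f2$means) - c(0.3, 0.8))), 0.02)

  # donor-leakage population at low E next to the signal population
  leak <- c(rnorm(150, 0.1, 0.04), rnorm(500, 0.88, 0.05))
  f3 <- fit_fingerprint(pmin(1, pmax(0, leak)))
  expect_gte(f3$n_components, 2L)
  expect_equal(f3$dominant, 0.88, tolerance = 0.02)
  expect_error(fit_fingerprint(rnorm(5, 0.5, 0.1)), "at least 10")
})

test_that("traces round-trip through delimited text", {
  sim <- simulate_trace(trace_sim_spec(n_frames = 500), seed = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(molecule = rep(c("m1", "m2"), each = 250),
                    frame = rep(1:250, 2),
                    donor = sim$trace$donor,
                    acceptor = sim$trace$acceptor)
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  traces <- read_traces(f)
  expect_length(traces, 2L)
  expect_equal(traces[["m1"]]$donor, sim$trace$donor[1:250])
  expect_equal(traces[["m2"]]$n_frames, 250L)
})
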