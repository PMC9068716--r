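make_rec <- function(p1, p2, fs = 250, events = NULL) {
  structure(list(signals_p1 = p1, signals_p2 = p2, fs = fs,
                 channel_labels = rownames(p1),
                 events = events, dyad_id = "t", group = "strangers"),
            class = "dyad_recording")
}

test_that("rereferencing subtracts the earlobe mean and drops references", {
  set.seed(1)
  labs <- c("Fp1", "Fp2", "Cz", "A1", "A2")
  p1 <- matrix(rnorm(5 * 100), 5, 100, dimnames = list(labs, NULL))
  p2 <- matrix(rnorm(5 * 100), 5, 100, dimnames = list(labs, NULL))
  rec <- make_rec(p1, p2)

  # zero references leave the data untouched
  z <- rec
  z$signals_p1[c("A1", "A2"), ] <- 0
  z$signals_p2[c("A1", "A2"), ] <- 0
  out <- rereference(z)
  expect_equal(out$signals_p1, z$signals_p1[1:3, ])
  expect_identical(out$channel_labels, labs[1:3])

  # a constant +5 uV on both references shifts every channel by -5 uV
  o <- z
  o$signals_p1[c("A1", "A2"), ] <- 5
  out2 <- rereference(o)
  expect_equal(out2$signals_p1, z$signals_p1[1:3, ] - 5)

  # random data: equals the direct arithmetic
  out3 <- rereference(rec)
  ref <- colMeans(p1[c("A1", "A2"), ])
  expect_equal(out3$signals_p1, sweep(p1[1:3, ], 2, ref))

  expect_error(rereference(make_rec(p1[1:3, ], p2[1:3, ])), "A1")
  expect_identical(
    rereference(make_rec(p1[1:3, ], p2[1:3, ]), allow_missing = TRUE),
    make_rec(p1[1:3, ], p2[1:3, ]))
})

test_that("band-pass keeps in-band and rejects out-of-band tones", {
  fs <- 250
  t <- seq(0, 8, by = 1 / fs)
  x <- matrix(sin(2 * pi * 10 * t), 1)
  amp <- function(y) sqrt(2 * mean(y[500:1500]^2))
  in_band <- hyperbrain:::filter_matrix(x, fs, 8, 12)
  expect_gt(amp(in_band), 0.95)
  out_band <- hyperbrain:::filter_matrix(x, fs, 30, 45)
  expect_lt(amp(out_band), 0.1)
  expect_equal(hyperbrain:::filter_matrix(matrix(0, 1, 1000), fs, 8, 12),
               matrix(0, 1, 1000))
  expect_error(hyperbrain:::filter_matrix(x, fs, 30, 130), "Nyquist")
})

test_that("filtering is zero-phase: symmetric pulse keeps its center", {
  fs <- 250
  n <- 2000
  x <- matrix(0, 1, n)
  x[1, 950:1050] <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = 101)))
  y <- hyperbrain:::filter_matrix(x, fs, 4, 45)
  com <- function(v) sum(seq_along(v) * v^2) / sum(v^2)
  expect_lt(abs(com(y[1, ]) - com(x[1, ])), 1)
})

test_that("blink detection thresholds, pads and merges intervals", {
  fs <- 250
  n <- 5 * fs
  labs <- c("Fp1", "Fp2", "Cz")
  mk <- function(pulse_at = NULL, peak = 100, len = 0.06) {
    p <- matrix(0, 3, n, dimnames = list(labs, NULL))
    for (t0 in pulse_at) {
      idx <- round(t0 * fs):round((t0 + len) * fs)
      p[1:2, idx] <- peak
    }
    make_rec(p, matrix(0, 3, n, dimnames = list(labs, NULL)), fs)
  }
  m <- detect_blinks(mk(1.0))
  on <- which(m)
  expect_equal(min(on), round(0.96 * fs))
  expect_equal(max(on), round(1.10 * fs))

  expect_false(any(detect_blinks(mk(1.0, peak = 69))))

  # two pulses 50 ms apart merge through the +/-40 ms padding
  m2 <- detect_blinks(mk(c(1.0, 1.11)))
  expect_equal(sum(diff(which(m2)) > 1), 0)  # one contiguous interval

  bad <- mk(1.0)
  rownames(bad$signals_p1) <- c("X1", "X2", "Cz")
  expect_error(detect_blinks(bad), "Fp1")
})

test_that("epoching applies the analysis window and exclusion rules", {
  fs <- 250
  n <- 40 * fs
  labs <- c("Fp1", "Fp2", "Cz")
  sig <- matrix(rnorm(3 * n, 0, 1), 3, n, dimnames = list(labs, NULL))
  mk_events <- function(durations, cond = "eye_contact") {
    onset <- as.integer(seq(fs, by = 3 * fs, length.out = length(durations)))
    data.frame(onset = onset,
               offset = onset + as.integer(round(durations * fs)),
               condition = cond)
  }
  # a 1.8 s common reproduction period is too short for the 0.5-2 s window
  ev <- rbind(mk_events(c(1.8, 2.5, 2.5, 1.9, 2.6, 2.4)),
              mk_events(rep(2.5, 5), "control"))
  rec <- make_rec(sig, sig, fs, events = ev)
  es <- epoch_analytic(rec, "alpha", min_trials = 3L)
  expect_equal(unname(es$n_valid["eye_contact"]), 4L)  # 1.8, 1.9 dropped
  expect_equal(unname(es$n_valid["control"]), 5L)
  expect_true(es$valid_dyad)
  expect_equal(dim(es$epochs$eye_contact$p1),
               c(4L, 3L, as.integer(1.5 * fs)))

  # 4 valid eye-contact trials: dyad invalid under the <5-trial rule
  es5 <- epoch_analytic(rec, "alpha", min_trials = 5L)
  expect_false(es5$valid_dyad)
})

test_that("analytic phase of a pure tone advances at the tone frequency", {
  fs <- 500
  t <- seq(0, 6, by = 1 / fs)
  z <- hyperbrain:::analytic_signal(cos(2 * pi * 40 * t))
  ph <- Arg(z)[500:2500]
  step <- atan2(sin(diff(ph)), cos(diff(ph)))  # wrapped phase increments
  rate <- mean(step) * fs
  expect_lt(abs(rate - 2 * pi * 40) / (2 * pi * 40), 0.01)
})

test_that("masked samples never contribute to connectivity estimates", {
  set.seed(4)
  ph1 <- random_phases(4, 3, 200)
  ph2 <- random_phases(4, 3, 200)
  mask <- matrix(FALSE, 4, 200)
  mask[2, 50:90] <- TRUE
  mask[4, 1:30] <- TRUE
  e <- epochs_from_phases(ph1, ph2, mask = mask)
  ref <- ciplv_matrix(e, min_samples = 10L)
  # poison the masked samples; estimates must not move
  poisoned <- e
  poisoned$p1[2, , 50:90] <- 1e6 * exp(1i * 9)
  poisoned$p2[4, , 1:30] <- -1e6
  expect_identical(ciplv_matrix(poisoned, min_samples = 10L), ref)
})
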