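test_that("configuration invariants are enforced", {
  expect_error(sim_config(fs = 80), "fs must exceed")
  expect_error(sim_config(bands = list()), "band set")
  expect_error(sim_config(leadership_bias = 0.3), "leadership_bias")
  expect_error(sim_config(leadership_bias = 1.2), "leadership_bias")
  expect_error(sim_config(inter_coupling = list(
    eye_contact = c(gamma = 1.4), control = numeric(0))), "\\[0, 1\\]")
  expect_error(sim_config(shared_source_gain = -0.1), "shared_source_gain")
  expect_error(sim_config(n_trials = 0), "n_trials")
})

test_that("identical seed and config give bit-identical recordings", {
  cfg <- fast_config(n_trials = 4L, seed = 77L)
  r1 <- generate_dyad(cfg, "d")
  r2 <- generate_dyad(cfg, "d")
  expect_identical(r1$signals_p1, r2$signals_p1)
  expect_identical(r1$signals_p2, r2$signals_p2)
  expect_identical(r1$events, r2$events)
})

test_that("recordings carry the montage and in-range events", {
  cfg <- fast_config(n_trials = 6L)
  rec <- generate_dyad(cfg, "d", group = "friends")
  expect_identical(rec$channel_labels[1:18], eeg_montage())
  expect_identical(rec$channel_labels[19:20], c("A1", "A2"))
  expect_equal(nrow(rec$signals_p1), 20)
  expect_true(all(rec$events$onset >= 1))
  expect_true(all(rec$events$offset <= ncol(rec$signals_p1)))
  expect_true(all(rec$events$offset > rec$events$onset))
  expect_identical(rec$group, "friends")
  # background amplitude stays under the blink threshold except at blinks
  no_ref <- rec$signals_p1[setdiff(rownames(rec$signals_p1),
                                   c("Fp1", "Fp2", "A1", "A2")), ]
  expect_lt(stats::quantile(abs(no_ref), 0.999), 70)
})

test_that("behavioral trial generator matches its marginal contracts", {
  cfg <- fast_config(leadership_bias = 1.0)
  beh <- generate_behavior(cfg, n_trials = 20L, tasks = "eye_contact")
  expect_equal(sum(beh$first_breaker == "P1"), 20L)
  expect_true(all(beh$tone_p1 %in% c(1.5, 2.5)))

  cfg <- fast_config(leadership_bias = 0.5, seed = 5L)
  beh <- generate_behavior(cfg, n_trials = 10000L, tasks = "eye_contact")
  frac <- mean(beh$first_breaker == "P1")
  expect_gt(frac, 0.48)
  expect_lt(frac, 0.52)

  cfg <- fast_config(pair_correlation = 0.9, seed = 6L)
  beh <- generate_behavior(cfg, n_trials = 50L, tasks = "eye_contact")
  same <- beh$tone_p1 == beh$tone_p2
  expect_gt(cor(beh$repro_p1[same], beh$repro_p2[same],
                method = "spearman"), 0.6)
})

test_that("eye-contact coupling concentrates inter-brain phase differences", {
  # direct phase-difference histogram oracle: resultant length of the
  # phase-difference distribution on coupled channel pairs
  cfg <- fast_config(n_trials = 36L, seed = 3L,
                     inter_coupling = gamma_only_coupling(0.8))
  rec <- rereference(generate_dyad(cfg))
  es <- epoch_analytic(rec, "gamma", min_trials = 2L)
  resultant <- function(e, ch) {
    d <- Arg(e$p1[, ch, ]) - Arg(e$p2[, ch, ])
    Mod(mean(exp(1i * d)))
  }
  ch <- match("Pz", rec$channel_labels)
  expect_gt(resultant(es$epochs$eye_contact, ch),
            resultant(es$epochs$control, ch) + 0.2)
})

test_that("downstream ciPLV is monotone in the coupling strength", {
  vals <- sapply(c(0, 0.4, 0.8), function(k) {
    out <- numeric(3)
    for (s in 1:3) {
      cfg <- fast_config(n_trials = 28L, seed = 100L + s,
                         inter_coupling = gamma_only_coupling(k))
      rec <- rereference(generate_dyad(cfg))
      es <- epoch_analytic(rec, "gamma", min_trials = 2L)
      m <- ciplv_matrix(es$epochs$eye_contact)
      out[s] <- mean(m[coupled_inter_cells(cfg)])
    }
    mean(out)
  })
  expect_true(all(diff(vals) > 0))
})

test_that("cohort generation splits groups, boosts friends, reproduces", {
  cfg <- fast_config(n_trials = 3L,
                     inter_coupling = gamma_only_coupling(0.6),
                     friend_effect = 0.3)
  cfg$seed <- 42L
  co <- generate_cohort(10, 0.5, cfg)
  groups <- vapply(co$recordings, `[[`, character(1), "group")
  expect_equal(sum(groups == "friends"), 5L)
  kappas <- vapply(co$recordings,
                   function(r) r$config$inter_coupling$eye_contact[["gamma"]],
                   numeric(1))
  expect_equal(kappas[groups == "friends"], rep(0.9, 5))
  expect_equal(kappas[groups == "strangers"], rep(0.6, 5))
  co2 <- generate_cohort(10, 0.5, cfg)
  expect_identical(co$recordings[[3]]$signals_p1,
                   co2$recordings[[3]]$signals_p1)
  expect_error(generate_cohort(1, 0.5, cfg), "n_dyads")
  expect_error(generate_cohort(4, 1.5, cfg), "friends_fraction")
})

test_that("zero-lag shared source inflates PLV but not ciPLV", {
  # estimator-level volume-conduction contract on an explicit mixture:
  # each channel is half private oscillation, half common zero-lag source
  set.seed(201)
  mix_epochs <- function(g) {
    nt <- 20; len <- 1000
    p1 <- p2 <- array(complex(real = 0), c(nt, 1, len))
    for (t in seq_len(nt)) {
      th1 <- cumsum(rnorm(len, 0.5, 0.25))
      th2 <- cumsum(rnorm(len, 0.5, 0.25))
      ths <- cumsum(rnorm(len, 0.5, 0.25))
      p1[t, 1, ] <- (1 - g) * exp(1i * th1) + g * exp(1i * ths)
      p2[t, 1, ] <- (1 - g) * exp(1i * th2) + g * exp(1i * ths)
    }
    structure(list(p1 = p1, p2 = p2, mask = matrix(FALSE, nt, len),
                   condition = "eye_contact", n_valid = nt,
                   band = c(8, 12), window = c(0.5, 2), fs = 250,
                   channel_labels = "ch1"),
              class = "analytic_epochs")
  }
  vals <- sapply(c(0, 0.5), function(g) {
    e <- mix_epochs(g)
    c(ciplv = ciplv_matrix(e, min_samples = 10L)[1, 2],
      plv = plv_matrix(e, min_samples = 10L)[1, 2])
  })
  expect_lt(abs(vals["ciplv", 2] - vals["ciplv", 1]), 0.05)
  expect_gt(vals["plv", 2] - vals["plv", 1], 0.2)
})
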