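rand_mats <- function(n, dim, mu = 0, sd = 1) {
  lapply(seq_len(n), function(i) matrix(rnorm(dim * dim, mu, sd), dim, dim))
}

test_that("edge t statistics match the paired-t formula", {
  set.seed(20)
  a <- rand_mats(10, 6)
  b <- rand_mats(10, 6)
  tm <- edge_tstats(a, b)
  for (cell in list(c(1, 2), c(3, 5), c(6, 6))) {
    x <- sapply(a, function(m) m[cell[1], cell[2]])
    y <- sapply(b, function(m) m[cell[1], cell[2]])
    expect_equal(tm[cell[1], cell[2]], oracle_paired_t(x, y),
                 tolerance = 1e-10)
  }
  expect_true(all(edge_tstats(a, a) == 0))
  shifted <- lapply(a, function(m) m + 1)
  expect_true(all(edge_tstats(shifted, a) > 0))
  expect_error(edge_tstats(a[1:2], b[1:2]), "at least 3")
})

test_that("clusters are same-sign connected components above threshold", {
  tm <- matrix(0, 6, 6)
  tm[1, 2] <- 3; tm[2, 3] <- 3; tm[5, 6] <- 3
  cl <- form_clusters(tm, edge_threshold = 2)
  expect_length(cl, 2)
  sizes <- sort(vapply(cl, `[[`, integer(1), "n_edges"))
  expect_equal(sizes, c(1L, 2L))
  expect_equal(sort(vapply(cl, `[[`, numeric(1), "score")), c(3, 6))

  # opposite signs never merge even when sharing a node
  tm2 <- matrix(0, 6, 6)
  tm2[1, 2] <- 3; tm2[2, 3] <- -3
  cl2 <- form_clusters(tm2, edge_threshold = 2)
  expect_length(cl2, 2)
  expect_setequal(vapply(cl2, `[[`, numeric(1), "sign"), c(1, -1))

  expect_length(form_clusters(matrix(1.9, 6, 6)), 0)
  expect_length(form_clusters(tm, edge_threshold = 2,
                              allow_single = FALSE), 1)
})

test_that("cluster membership is invariant to channel relabeling", {
  set.seed(21)
  tm <- matrix(0, 10, 10)
  tm[upper.tri(tm)] <- rnorm(45, 0, 2)
  cl <- form_clusters(tm)
  perm <- sample(10)
  tmp <- matrix(0, 10, 10)
  tmp[perm, perm] <- tm + t(tm)
  clp <- form_clusters(tmp)
  key <- function(cls) sort(vapply(cls, function(c)
    paste(c$n_edges, round(abs(c$score), 8)), character(1)))
  expect_equal(key(cl), key(clp))
})

test_that("permutation test: null behavior and argument contracts", {
  set.seed(22)
  a <- rand_mats(10, 8)
  res <- cluster_permutation(a, a, upper.tri(diag(8)), n_perm = 100)
  expect_length(res$clusters, 0)
  expect_true(all(res$null_distribution == 0))

  b <- rand_mats(10, 8)
  expect_error(cluster_permutation(a, b, upper.tri(diag(8)), n_perm = 0),
               "positive")
  expect_warning(cluster_permutation(a, b, upper.tri(diag(8)), n_perm = 50),
                 "coarse")
  expect_error(cluster_permutation(a[1:2], b[1:2], upper.tri(diag(8)),
                                   n_perm = 100), "at least 3")
})

test_that("significance calls agree with p-values and the critical value", {
  set.seed(23)
  a <- rand_mats(12, 8)
  shift <- matrix(0, 8, 8)
  shift[1:4, 5:8] <- 1.2
  b <- lapply(a, function(m) m + shift + matrix(rnorm(64, 0, 0.3), 8))
  mask <- matrix(TRUE, 8, 8); diag(mask) <- FALSE; mask[lower.tri(mask)] <- FALSE
  res <- cluster_permutation(b, a, mask, n_perm = 400)
  expect_gt(length(res$clusters), 0)
  for (cl in res$clusters) {
    expect_identical(cl$significant, cl$p_value <= res$alpha)
    expect_true(all(abs(cl$t_values) > res$edge_threshold))
  }
  sig <- vapply(res$clusters, `[[`, logical(1), "significant")
  sc <- abs(vapply(res$clusters, `[[`, numeric(1), "score"))
  if (any(sig)) expect_true(all(sc[sig] >= res$t_critical))
})

test_that("an injected connected effect is recovered with its edges", {
  set.seed(24)
  n_units <- 14
  inj <- cbind(1:5, c(2:5, 6))  # a connected 5-edge path
  found <- 0
  for (s in 1:3) {
    a <- rand_mats(n_units, 8)
    b <- lapply(a, function(m) {
      m2 <- m + matrix(rnorm(64, 0, 0.5), 8)
      for (k in seq_len(nrow(inj))) m2[inj[k, 1], inj[k, 2]] <-
          m2[inj[k, 1], inj[k, 2]] + 1.0
      m2
    })
    mask <- upper.tri(diag(8))
    res <- cluster_permutation(b, a, mask, n_perm = 300)
    sig <- Filter(function(cl) cl$significant && cl$sign > 0, res$clusters)
    if (length(sig)) {
      edges <- do.call(rbind, lapply(sig, `[[`, "edges"))
      hit <- sum(apply(inj, 1, function(e)
        any(edges[, 1] == e[1] & edges[, 2] == e[2])))
      if (hit >= 4) found <- found + 1
    }
  }
  expect_gte(found, 2)
})

test_that("monotonicity: detection never degrades with effect size", {
  set.seed(25)
  rates <- sapply(c(0, 0.8, 1.6), function(delta) {
    hits <- 0
    for (s in 1:8) {
      a <- rand_mats(10, 6)
      b <- lapply(a, function(m) {
        m2 <- m + matrix(rnorm(36, 0, 0.6), 6)
        m2[1, 2] <- m2[1, 2] + delta
        m2[2, 3] <- m2[2, 3] + delta
        m2
      })
      res <- suppressWarnings(
        cluster_permutation(b, a, upper.tri(diag(6)), n_perm = 99))
      if (res$any_significant) hits <- hits + 1
    }
    hits
  })
  expect_true(rates[3] >= rates[1])
  expect_true(rates[3] >= 6)  # large effect nearly always found
})

test_that("shuffled-pairs control separates pair-specific coupling", {
  # pair-specific coupling: partner phases share a dyad-specific rhythm
  set.seed(26)
  mk_dyad <- function(coupled, common = NULL) {
    nt <- 6; len <- 250
    mk_cond <- function(k) {
      ph1 <- random_phases(nt, 2, len)
      ph2 <- random_phases(nt, 2, len)
      if (!is.null(common)) {       # stimulus shared by every dyad
        for (t in seq_len(nt)) {
          ph1[t, 1, ] <- common[t, ] + rnorm(len, 0, 0.3)
          ph2[t, 1, ] <- common[t, ] + pi / 3 + rnorm(len, 0, 0.3)
        }
      } else if (k > 0) {           # dyad-private locking
        for (t in seq_len(nt)) {
          base <- cumsum(rnorm(len, 0.5, 0.15))
          ph1[t, 1, ] <- base + rnorm(len, 0, 0.2)
          ph2[t, 1, ] <- base + pi / 3 + rnorm(len, 0, 0.2)
        }
      }
      epochs_from_phases(ph1, ph2)
    }
    eye <- mk_cond(coupled)
    ctl <- mk_cond(0)
    ctl$condition <- "control"
    structure(list(epochs = list(eye_contact = eye, control = ctl),
                   channel_labels = c("ch1", "ch2")),
              class = "analytic_epochs_set")
  }

  private <- lapply(1:5, function(d) mk_dyad(coupled = 1))
  res <- shuffled_pairs_control(private, n_shuffles = 40)
  expect_lte(res$p_value, 0.05)

  common <- matrix(cumsum(rnorm(6 * 250, 0.5, 0.15)), 6, 250, byrow = TRUE)
  shared <- lapply(1:5, function(d) mk_dyad(coupled = 0, common = common))
  res2 <- shuffled_pairs_control(shared, n_shuffles = 40)
  expect_gt(res2$p_value, 0.05)

  expect_error(shuffled_pairs_control(private[1:2], 10), "at least 3")
  expect_error(shuffled_pairs_control(private, 0), "positive")
})
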