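sym_rand <- function(n, p = 0.3) random_graph(n, p)

test_that("edge z-scoring follows the block rule exactly", {
  n_ch <- 4
  set.seed(30)
  ctl <- matrix(runif(64, 0.1, 0.4), 8)
  ctl <- (ctl + t(ctl)) / 2; diag(ctl) <- 0
  eye <- ctl
  eye[inter_mask(n_ch)] <- 0.30
  # worked value: C = 0.30 against the control block's mu and sigma
  z <- zscore_edges(eye, ctl, n_ch)
  cells <- which(inter_mask(n_ch))
  mu <- mean(ctl[cells]); sg <- sd(ctl[cells])
  expect_equal(z$Z[cells], rep((0.30 - mu) / sg, 16), tolerance = 1e-12)

  # eye identical to control: block-mean z is zero
  set.seed(31)
  c2 <- matrix(0, 8, 8)
  c2[upper.tri(c2)] <- runif(28, 0.1, 0.6)
  c2 <- c2 + t(c2)
  z2 <- zscore_edges(c2, c2, n_ch)
  expect_equal(mean(z2$Z[cells]), 0, tolerance = 1e-12)

  # brute-force normalization oracle on random matrices, all three blocks
  set.seed(32)
  e3 <- matrix(runif(64), 8); e3 <- (e3 + t(e3)) / 2; diag(e3) <- 0
  c3 <- matrix(runif(64), 8); c3 <- (c3 + t(c3)) / 2; diag(c3) <- 0
  z3 <- zscore_edges(e3, c3, n_ch)
  blocks <- list(inter_mask(n_ch), intra_mask(n_ch, 1), intra_mask(n_ch, 2))
  for (b in blocks) {
    cells <- which(b)
    expect_equal(z3$Z[cells],
                 (e3[cells] - mean(c3[cells])) / sd(c3[cells]),
                 tolerance = 1e-12)
  }
  # zero-variance control block is an error naming the block
  expect_error(zscore_edges(eye, matrix(0.2, 8, 8), n_ch), "block")
})

test_that("thresholding yields consistent binary and weighted views", {
  n_ch <- 4
  z0 <- structure(list(Z = matrix(0, 8, 8), mu = c(inter = 0),
                       sigma = c(inter = 1), sign = NULL,
                       directed = FALSE, n_ch = n_ch),
                  class = "edge_zscores")
  g0 <- threshold_graph(z0)
  expect_equal(sum(g0$adj), 0)

  Z <- matrix(0, 8, 8)
  Z[1, 5] <- Z[5, 1] <- 1.5
  Z[2, 6] <- Z[6, 2] <- 1.5
  Z[3, 7] <- Z[7, 3] <- 1.5
  z1 <- z0; z1$Z <- Z
  g1 <- threshold_graph(z1)
  expect_equal(sum(g1$adj) / 2, 3)
  expect_equal(network_summary(g1)$density[["inter"]], 3 / 16)
  expect_true(all(g1$weights[g1$adj > 0] == 1.5))
  # binary view is the indicator of the weighted view
  expect_identical(unname(g1$adj > 0), unname(g1$weights > 0))

  # signed (directed) mode keeps the input signs on retained edges
  sgn <- matrix(0, 8, 8); sgn[1, 5] <- 1; sgn[5, 1] <- -1
  sgn[2, 6] <- -1; sgn[6, 2] <- 1
  zd <- z0; zd$Z <- Z; zd$directed <- TRUE; zd$sign <- sgn
  gd <- threshold_graph(zd)
  expect_true(all(gd$sign %in% c(-1, 0, 1)))
  expect_equal(gd$sign[1, 5], 1)
  expect_equal(gd$sign[5, 1], -1)
  expect_equal(gd$adj_directed[1, 5], 1L)
  expect_equal(gd$adj_directed[5, 1], 0L)
})

test_that("efficiency measures reproduce hand-enumerated values", {
  k4 <- matrix(1, 4, 4) - diag(4)
  expect_equal(global_efficiency(k4)$E, 1)
  expect_equal(local_efficiency(k4)$E_loc, 1)

  p3 <- matrix(0, 3, 3); p3[1, 2] <- p3[2, 1] <- p3[2, 3] <- p3[3, 2] <- 1
  expect_equal(global_efficiency(p3)$E, 5 / 6)
  expect_equal(local_efficiency(p3)$E_loc, 0)

  k3 <- matrix(1, 3, 3) - diag(3)
  expect_equal(local_efficiency(k3)$E_loc, 1)

  empty <- matrix(0, 5, 5)
  expect_equal(global_efficiency(empty)$E, 0)
})

test_that("modularity matches hand evaluation and the brute-force sum", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- w[3, 4] <- w[4, 3] <- 1
  expect_equal(modularity_p1p2(w, membership = c("A", "A", "B", "B")), 0.5)

  # all edges between communities: negative modularity
  wx <- matrix(0, 4, 4)
  wx[1, 3] <- wx[3, 1] <- wx[2, 4] <- wx[4, 2] <- 1
  expect_lt(modularity_p1p2(wx, membership = c("A", "A", "B", "B")), 0)

  set.seed(33)
  wd <- matrix(runif(64), 8); diag(wd) <- 0   # weighted digraph
  mem <- rep(c("P1", "P2"), each = 4)
  expect_equal(modularity_p1p2(wd, membership = mem),
               oracle_modularity(wd, mem), tolerance = 1e-12)
  expect_warning(modularity_p1p2(matrix(0, 4, 4), membership = mem[1:4]),
                 "zero")
})

test_that("degree assortativity matches its defining sums", {
  # all edges join equal-degree nodes: perfect assortativity
  # (a triangle of degree-2 nodes plus a separate degree-1 pair)
  a1 <- matrix(0, 5, 5)
  a1[1, 2] <- a1[2, 3] <- a1[1, 3] <- a1[4, 5] <- 1
  a1 <- a1 + t(a1)
  expect_equal(assortativity_degree(a1), 1)

  star <- matrix(0, 6, 6); star[1, 2:6] <- 1; star <- star + t(star)
  expect_lt(assortativity_degree(star), 0)

  set.seed(34)
  for (i in 1:5) {
    a <- sym_rand(10, 0.35)
    if (sum(a) < 4) next
    expect_equal(assortativity_degree(a), oracle_assortativity(a),
                 tolerance = 1e-10)
  }
  expect_warning(assortativity_degree(matrix(0, 4, 4)), "fewer than 2")
})

test_that("rich-club coefficient, null and membership behave correctly", {
  k5 <- matrix(1, 5, 5) - diag(5)
  rc <- rich_club(k5, n_rand = 10)
  expect_true(all(rc$phi == 1))
  # swaps cannot alter a complete graph, so rho is exactly 1 (no club call)
  expect_true(all(rc$rho == 1))

  star <- matrix(0, 6, 6); star[1, 2:6] <- 1; star <- star + t(star)
  # only one node has degree > 1: no evaluable k beyond 0
  rc_star <- rich_club(star, n_rand = 5)
  expect_true(all(rc_star$k == 0))

  expect_error(rich_club(matrix(0, 3, 3)), "4 nodes")

  # double-edge swaps preserve every degree
  set.seed(35)
  a <- sym_rand(12, 0.3)
  edges <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  e2 <- hyperbrain:::double_edge_swap_cpp(edges, 12, 10 * nrow(edges))
  a2 <- matrix(0L, 12, 12); a2[e2] <- 1L; a2 <- a2 + t(a2)
  expect_equal(rowSums(a2), rowSums(a))
  expect_true(all(a2 %in% c(0L, 1L)))
  expect_true(all(diag(a2) == 0))

  # phi matches the brute-force count on the original graph
  deg <- rowSums(a)
  rc2 <- rich_club(a, n_rand = 5)
  for (i in seq_along(rc2$k))
    expect_equal(rc2$phi[i], oracle_rich_club_phi(a, rc2$k[i]),
                 tolerance = 1e-12)

  # membership frequencies: single dyad gives 0/1; unanimous gives 1
  rc_one <- list(list(present = TRUE, k_onset = 2,
                      degrees = c(3, 1, 1, 3, 1, 1)))
  mem <- rich_club_membership(rc_one, channel_labels = c("x", "y", "z"))
  expect_true(all(mem$frequency %in% c(0, 0.5, 1)))
  mem43 <- rich_club_membership(rep(rc_one, 43),
                                channel_labels = c("x", "y", "z"))
  expect_equal(mem43$frequency[mem43$channel == "x"], 1)
  expect_equal(nrow(rich_club_membership(list(list(present = FALSE)))), 0)
})

test_that("efficiency is monotone under edge addition", {
  set.seed(36)
  a <- matrix(0L, 9, 9)
  cells <- which(upper.tri(a))
  order_add <- sample(cells)
  prev_e <- 0; prev_l <- 0
  for (step in seq(5, 36, by = 5)) {
    a2 <- matrix(0L, 9, 9)
    a2[order_add[seq_len(step)]] <- 1L
    a2 <- a2 + t(a2)
    e <- global_efficiency(a2)$E
    l <- local_efficiency(a2)$E_loc
    expect_gte(e, prev_e)
    prev_e <- e
  }
})

test_that("network summaries aggregate strength, density, degree and ROI", {
  n_ch <- 18
  Z <- matrix(0, 36, 36)
  pick <- cbind(c(1, 2, 3), c(19, 20, 21))
  Z[pick] <- c(1.2, 1.5, 1.8)
  Z <- pmax(Z, t(Z))
  z <- structure(list(Z = Z, mu = 0, sigma = 1, sign = NULL,
                      directed = FALSE, n_ch = n_ch),
                 class = "edge_zscores")
  g <- threshold_graph(z)
  s <- network_summary(g)
  expect_equal(s$strength[["inter"]], 1.5)
  expect_equal(s$density[["inter"]], 3 / 324)
  expect_equal(sum(s$degree), 6)

  # full inter block: density 1 over 324 possible edges
  Zf <- matrix(0, 36, 36)
  Zf[inter_mask(n_ch)] <- 2
  Zf <- pmax(Zf, t(Zf))
  zf <- z; zf$Z <- Zf
  expect_equal(network_summary(threshold_graph(zf))$density[["inter"]], 1)

  # ROI means equal hand-computed channel-group averages
  deg <- s$degree
  roi <- s$roi
  rp_rows <- which(eeg_montage() %in% c("P8", "P4"))
  hand <- mean(deg[rp_rows])
  expect_equal(roi$degree[roi$participant == "P1" & roi$roi == "RP"], hand)
})

test_that("directed flow counts outgoing and incoming inter-brain edges", {
  n_ch <- 3
  Z <- matrix(0, 6, 6)
  sgn <- matrix(0, 6, 6)
  # 4 leader->follower edges, 1 follower->leader
  lf <- rbind(c(1, 4), c(1, 5), c(2, 4), c(3, 6))
  fl <- rbind(c(5, 2))
  for (r in seq_len(nrow(lf))) {
    Z[lf[r, 1], lf[r, 2]] <- Z[lf[r, 2], lf[r, 1]] <- 2
    sgn[lf[r, 1], lf[r, 2]] <- 1; sgn[lf[r, 2], lf[r, 1]] <- -1
  }
  Z[5, 2] <- Z[2, 5] <- 2; sgn[5, 2] <- 1; sgn[2, 5] <- -1
  z <- structure(list(Z = Z, mu = 0, sigma = 1, sign = sgn,
                      directed = TRUE, n_ch = n_ch),
                 class = "edge_zscores")
  fl_tab <- directed_flow(threshold_graph(z), leader = "P1")
  lead <- fl_tab[fl_tab$role == "leader", ]
  expect_equal(lead$n_out, 4)
  expect_equal(lead$n_in, 1)
  expect_equal(lead$proportion_out, 4)

  # symmetric flows give proportion 1 for both
  sgn2 <- matrix(0, 6, 6)
  Z2 <- matrix(0, 6, 6)
  Z2[1, 4] <- Z2[4, 1] <- 2; sgn2[1, 4] <- 1; sgn2[4, 1] <- -1
  Z2[5, 2] <- Z2[2, 5] <- 2; sgn2[5, 2] <- 1; sgn2[2, 5] <- -1
  z2 <- z; z2$Z <- Z2; z2$sign <- sgn2
  fl2 <- directed_flow(threshold_graph(z2), leader = "P1")
  expect_equal(fl2$proportion_out, c(1, 1))

  # no inter-brain edges at all: participant flagged
  z3 <- z; z3$Z <- matrix(0, 6, 6); z3$sign <- matrix(0, 6, 6)
  fl3 <- directed_flow(threshold_graph(z3), leader = "P1")
  expect_false(any(fl3$has_inter))
})
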