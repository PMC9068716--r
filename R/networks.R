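#' Z-score eye-contact edges against the control condition
#'
#' For each edge, `Z = (C_eye - mu) / sigma` where `mu` and `sigma` are the
#' mean and SD of the control-condition values across all edges of the same
#' block: one block for the inter-brain edges (pair level) and one per
#' participant for the intra-brain edges (single-subject level). For
#' directed (antisymmetric) measures the statistics are computed on edge
#' magnitudes and the eye-contact sign is kept alongside.
#'
#' @param eye,control 2N x 2N connectivity matrices for one dyad and band.
#' @param n_ch Channels per brain.
#' @param directed `TRUE` for antisymmetric (PSI) matrices.
#' @return Object of class `"edge_zscores"`: `Z` matrix, per-block `mu` and
#'   `sigma`, `sign` (directed only: sign of the eye-contact value),
#'   `directed`, `n_ch`.
#' @export
zscore_edges <- function(eye, control, n_ch, directed = FALSE) {
  stopifnot(all(dim(eye) == 2 * n_ch), all(dim(control) == 2 * n_ch))
  blocks <- list(inter = inter_mask(n_ch),
                 intra1 = intra_mask(n_ch, 1L),
                 intra2 = intra_mask(n_ch, 2L))
  val_eye <- if (directed) abs(eye) else eye
  val_ctl <- if (directed) abs(control) else control
  Z <- matrix(NA_real_, 2 * n_ch, 2 * n_ch, dimnames = dimnames(eye))
  mu <- sigma <- numeric(0)
  for (bn in names(blocks)) {
    cells <- which(blocks[[bn]])
    m <- mean(val_ctl[cells])
    s <- sd(val_ctl[cells])
    if (!is.finite(s) || s == 0)
      stop("zero control-condition SD in block '", bn, "'")
    Z[cells] <- (val_eye[cells] - m) / s
    mu[bn] <- m
    sigma[bn] <- s
  }
  # mirror to the lower triangles so the matrix covers both orientations
  Z[lower.tri(Z)] <- t(Z)[lower.tri(Z)]
  Z[is.na(Z)] <- t(Z)[is.na(Z)]
  diag(Z) <- NA_real_
  structure(list(Z = Z, mu = mu, sigma = sigma,
                 sign = if (directed) sign(eye) else NULL,
                 directed = directed, n_ch = n_ch),
            class = "edge_zscores")
}

#' Threshold z-scored edges into a hyperbrain graph
#'
#' Retains edges whose z-score exceeds `z_threshold` (1 SD of the control
#' by default), yielding a binary adjacency and a weighted view holding the
#' retained z values. For directed measures the sign (+1 edge emitted by
#' the row node, -1 received) is kept and a directed adjacency is derived.
#'
#' @param z An `"edge_zscores"` object.
#' @param z_threshold Retention threshold on Z.
#' @param channel_labels Channel labels (length N); default [eeg_montage()].
#' @return Object of class `"hyperbrain_graph"`: `adj` (binary, symmetric
#'   undirected skeleton), `weights` (retained z), `sign` (-1/0/+1,
#'   directed only), `adj_directed` (directed only), `nodes` data frame
#'   (node, channel, participant, roi), `directed`, `threshold`.
#' @export
threshold_graph <- function(z, z_threshold = 1, channel_labels = NULL) {
  stopifnot(inherits(z, "edge_zscores"))
  n_ch <- z$n_ch
  labels <- channel_labels %||% eeg_montage()[seq_len(n_ch)]
  Z <- z$Z
  keep <- !is.na(Z) & Z > z_threshold
  adj <- (keep | t(keep)) * 1L
  diag(adj) <- 0L
  weights <- ifelse(adj > 0, pmax(Z, t(Z), na.rm = TRUE), 0)
  diag(weights) <- 0
  nodes <- data.frame(
    node = seq_len(2 * n_ch),
    channel = rep(labels, 2),
    participant = rep(c("P1", "P2"), each = n_ch),
    roi = rep(unname(roi_map()[labels]), 2),
    stringsAsFactors = FALSE)
  sign_mat <- NULL
  adj_dir <- NULL
  if (z$directed) {
    sign_mat <- z$sign * (adj > 0)
    adj_dir <- (sign_mat > 0) * 1L
  }
  nm <- c(paste0("P1_", labels), paste0("P2_", labels))
  dimnames(adj) <- dimnames(weights) <- list(nm, nm)
  structure(list(adj = adj, weights = weights, sign = sign_mat,
                 adj_directed = adj_dir, nodes = nodes,
                 directed = z$directed, threshold = z_threshold,
                 n_ch = n_ch),
            class = "hyperbrain_graph")
}

as_adjacency <- function(graph) {
  if (inherits(graph, "hyperbrain_graph")) graph$adj else (graph > 0) * 1L
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over all node pairs of the binary
#' graph (`1/d = 0` for disconnected pairs). The per-node value is the
#' harmonic closeness centrality: the mean of `1/d_ij` over all `j != i`,
#' i.e. how much access node `i` has to the entire network.
#'
#' @param graph A `"hyperbrain_graph"` or binary adjacency matrix.
#' @return List with `E` (scalar) and `nodal` (per-node efficiency).
#' @export
global_efficiency <- function(graph) {
  adj <- as_adjacency(graph)
  n <- nrow(adj)
  if (n < 2) return(list(E = NA_real_, nodal = rep(NA_real_, n)))
  d <- bfs_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  nodal <- rowSums(inv) / (n - 1)
  list(E = mean(nodal), nodal = nodal)
}

#' Local efficiency
#'
#' For each node, the global efficiency of the subgraph induced by its
#' neighbors after removing the node itself; subgraphs with fewer than two
#' nodes contribute 0. The network value is the mean across nodes.
#'
#' @inheritParams global_efficiency
#' @return List with `E_loc` (scalar) and `nodal` (per-node values).
#' @export
local_efficiency <- function(graph) {
  adj <- as_adjacency(graph)
  n <- nrow(adj)
  nodal <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) next
    nodal[i] <- global_efficiency(adj[nb, nb, drop = FALSE])$E
  }
  list(E_loc = mean(nodal), nodal = nodal)
}

#' Modularity of the two-brain partition
#'
#' Weighted (optionally directed) modularity of the fixed partition into
#' participant-1 and participant-2 nodes:
#' `Q = (1/W) * sum_ij (w_ij - s_out_i * s_in_j / W) * delta(C_i, C_j)`.
#' Undirected graphs are evaluated with every edge counted in both
#' directions.
#'
#' @param graph A `"hyperbrain_graph"`, or a weight matrix with
#'   `membership` supplied.
#' @param membership Optional community vector (defaults to the P1/P2
#'   partition of a hyperbrain graph).
#' @return Modularity `Q`, or `NA` (flagged by warning) if the total
#'   weight is zero.
#' @export
modularity_p1p2 <- function(graph, membership = NULL) {
  if (inherits(graph, "hyperbrain_graph")) {
    w <- if (graph$directed) graph$weights * (graph$sign > 0) else
      graph$weights
    membership <- membership %||% graph$nodes$participant
  } else {
    w <- graph
    if (is.null(membership)) stop("membership required for plain matrices")
  }
  W <- sum(w)
  if (W == 0) {
    warning("total edge weight is zero; modularity undefined")
    return(NA_real_)
  }
  s_out <- rowSums(w)
  s_in <- colSums(w)
  same <- outer(membership, membership, "==")
  sum((w - (s_out %o% s_in) / W) * same) / W
}

#' Degree assortativity
#'
#' Assortativity coefficient with node degree as the node type:
#' `r = (sum_i e_ii - sum_i a_i b_i) / (1 - sum_i a_i b_i)`, where `e_xy`
#' is the fraction of edge ends joining degree `x` to degree `y` (each
#' undirected edge counted in both orientations).
#'
#' @inheritParams global_efficiency
#' @return `r` in `[-1, 1]`, or `NA` (flagged) when undefined (fewer than
#'   2 edges or no variance in edge-end degrees).
#' @export
assortativity_degree <- function(graph) {
  adj <- as_adjacency(graph)
  deg <- rowSums(adj)
  ends <- which(adj > 0, arr.ind = TRUE)  # both orientations
  if (nrow(ends) < 4) {
    warning("fewer than 2 edges; assortativity undefined")
    return(NA_real_)
  }
  dx <- deg[ends[, 1]]
  dy <- deg[ends[, 2]]
  types <- sort(unique(c(dx, dy)))
  e <- table(factor(dx, types), factor(dy, types)) / nrow(ends)
  a <- rowSums(e)
  b <- colSums(e)
  den <- 1 - sum(a * b)
  if (den == 0) {
    warning("no variance in edge-end degrees; assortativity undefined")
    return(NA_real_)
  }
  (sum(diag(e)) - sum(a * b)) / den
}

#' Rich-club coefficient and degree-preserving null
#'
#' For each degree `k` with at least two nodes of higher degree, the
#' rich-club coefficient `phi(k) = 2 E_k / (N_k (N_k - 1))` is the density
#' of the subgraph over nodes of degree > k. The normalization
#' `phi_ran(k)` is the mean coefficient over `n_rand` degree-preserving
#' randomizations (double-edge swaps), giving `rho(k) = phi / phi_ran`.
#' A rich club is declared when `rho(k) > 1` for every `k` of a contiguous
#' run covering the top tertile of evaluable degrees; the club onset is
#' the smallest `k` from which `rho > 1` holds through the largest
#' evaluable `k`.
#'
#' @inheritParams global_efficiency
#' @param n_rand Number of randomized graphs.
#' @param swaps_per_edge Attempted swaps per edge and randomization.
#' @return List: `k`, `phi`, `phi_ran`, `rho`, `present`, `k_onset`
#'   (`NA` when no club), `degrees`.
#' @export
rich_club <- function(graph, n_rand = 100, swaps_per_edge = 10) {
  adj <- as_adjacency(graph)
  n <- nrow(adj)
  if (n < 4) stop("rich-club analysis needs at least 4 nodes")
  deg <- rowSums(adj)
  ks <- 0:(max(deg) - 1)
  ks <- ks[vapply(ks, function(k) sum(deg > k) >= 2, logical(1))]
  if (!length(ks)) {
    warning("no degree level with at least 2 richer nodes")
    return(list(k = integer(0), phi = numeric(0), phi_ran = numeric(0),
                rho = numeric(0), present = FALSE, k_onset = NA_integer_,
                degrees = deg))
  }
  phi_of <- function(a, dg) {
    vapply(ks, function(k) {
      rich <- dg > k
      nk <- sum(rich)
      sum(a[rich, rich]) / (nk * (nk - 1))
    }, numeric(1))
  }
  phi <- phi_of(adj, deg)
  edges <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  m <- nrow(edges)
  phi_ran <- matrix(0, n_rand, length(ks))
  for (r in seq_len(n_rand)) {
    e2 <- double_edge_swap_cpp(edges, n, swaps_per_edge * m)
    a2 <- matrix(0L, n, n)
    a2[e2] <- 1L
    a2 <- a2 + t(a2)
    phi_ran[r, ] <- phi_of(a2, rowSums(a2))  # degrees preserved by swaps
  }
  phi_ran <- colMeans(phi_ran)
  rho <- ifelse(phi_ran > 0, phi / phi_ran, NA_real_)
  ok <- !is.na(rho)
  k_eval <- ks[ok]
  rho_eval <- rho[ok]
  present <- FALSE
  k_onset <- NA_integer_
  if (length(k_eval)) {
    top <- tail(k_eval, max(1L, ceiling(length(k_eval) / 3)))
    present <- all(rho_eval[k_eval %in% top] > 1)
    if (present) {
      above <- rho_eval > 1
      run <- rev(cumprod(rev(above)))  # suffix of uninterrupted rho > 1
      k_onset <- k_eval[which(run == 1)[1]]
    }
  }
  list(k = ks, phi = phi, phi_ran = phi_ran, rho = rho, present = present,
       k_onset = k_onset, degrees = deg)
}

#' Rich-club membership frequency across dyads
#'
#' For the dyads whose graphs exhibit a rich club, counts how often each
#' channel's node degree exceeds the dyad's club onset, aggregated over
#' both participants.
#'
#' @param rc_list List of [rich_club()] results, one per dyad.
#' @param channel_labels Channel labels (length N).
#' @return Data frame `channel`, `frequency` sorted by frequency; empty
#'   when no dyad has a rich club.
#' @export
rich_club_membership <- function(rc_list, channel_labels = NULL) {
  rc_list <- Filter(function(r) isTRUE(r$present), rc_list)
  if (!length(rc_list))
    return(data.frame(channel = character(0), frequency = numeric(0)))
  n2 <- length(rc_list[[1]]$degrees)
  labels <- channel_labels %||% eeg_montage()[seq_len(n2 / 2)]
  counts <- numeric(n2)
  for (r in rc_list)
    counts <- counts + (r$degrees > r$k_onset)
  freq <- counts / length(rc_list)
  per_channel <- (freq[seq_len(n2 / 2)] + freq[n2 / 2 + seq_len(n2 / 2)]) / 2
  out <- data.frame(channel = labels, frequency = per_channel,
                    stringsAsFactors = FALSE)
  out[order(-out$frequency), , drop = FALSE]
}

#' Strength, density, degree and ROI aggregates
#'
#' Block-wise summaries of a thresholded hyperbrain graph: strength (mean
#' retained z per block), density (retained / possible edges per block;
#' `N^2` for the inter block, `N (N - 1) / 2` per intra block), per-node
#' degree, and per-participant ROI means of degree and nodal global/local
#' efficiency.
#'
#' @param graph A `"hyperbrain_graph"`.
#' @return List: `strength`, `density` (named by block), `degree`
#'   (per node), `roi` data frame.
#' @export
network_summary <- function(graph) {
  stopifnot(inherits(graph, "hyperbrain_graph"))
  n_ch <- graph$n_ch
  blocks <- list(inter = inter_mask(n_ch),
                 intra1 = intra_mask(n_ch, 1L),
                 intra2 = intra_mask(n_ch, 2L))
  possible <- c(inter = n_ch^2, intra1 = n_ch * (n_ch - 1) / 2,
                intra2 = n_ch * (n_ch - 1) / 2)
  strength <- density <- numeric(0)
  for (bn in names(blocks)) {
    cells <- which(blocks[[bn]])
    w <- graph$weights[cells]
    retained <- sum(graph$adj[cells] > 0)
    strength[bn] <- if (retained > 0) mean(w[w > 0]) else NA_real_
    density[bn] <- retained / possible[[bn]]
  }
  degree <- rowSums(graph$adj)
  ge <- global_efficiency(graph)
  le <- local_efficiency(graph)
  nodes <- graph$nodes
  roi <- aggregate(cbind(degree = degree, global_efficiency = ge$nodal,
                         local_efficiency = le$nodal),
                   by = list(participant = nodes$participant,
                             roi = nodes$roi),
                   FUN = mean)
  list(strength = strength, density = density, degree = degree, roi = roi)
}

#' Directed flow between leader and follower
#'
#' On a signed/directed PSI hyperbrain graph, counts each participant's
#' outgoing versus incoming inter-brain edges (ratio reported as the
#' outgoing proportion) and the mean |z| strength of outgoing and incoming
#' inter-brain edges.
#'
#' @param graph A directed `"hyperbrain_graph"`.
#' @param leader `"P1"` or `"P2"`.
#' @return Data frame per participant: `participant`, `role`, `n_out`,
#'   `n_in`, `proportion_out` (`NA` with counts preserved when no incoming
#'   edges), `strength_out`, `strength_in`, `has_inter` (dyads without any
#'   inter-brain edge are flagged).
#' @export
directed_flow <- function(graph, leader = "P1") {
  stopifnot(inherits(graph, "hyperbrain_graph"), isTRUE(graph$directed))
  n_ch <- graph$n_ch
  p1 <- seq_len(n_ch)
  p2 <- n_ch + seq_len(n_ch)
  dir_adj <- graph$adj_directed
  w <- graph$weights
  res <- lapply(c("P1", "P2"), function(p) {
    own <- if (p == "P1") p1 else p2
    oth <- if (p == "P1") p2 else p1
    out_e <- dir_adj[own, oth, drop = FALSE]
    in_e <- dir_adj[oth, own, drop = FALSE]
    n_out <- sum(out_e)
    n_in <- sum(in_e)
    data.frame(
      participant = p,
      role = if (p == leader) "leader" else "follower",
      n_out = n_out, n_in = n_in,
      proportion_out = if (n_in > 0) n_out / n_in else NA_real_,
      strength_out = if (n_out > 0)
        mean(abs(w[own, oth][out_e > 0])) else NA_real_,
      strength_in = if (n_in > 0)
        mean(abs(w[oth, own][in_e > 0])) else NA_real_,
      has_inter = (n_out + n_in) > 0,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
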