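#' Edge masks for hyperbrain matrices
#'
#' Logical masks selecting the unique edges of a 2N x 2N hyperbrain matrix:
#' the inter-brain block (participant 1 rows by participant 2 columns) or
#' one participant's intra-brain upper triangle. For antisymmetric
#' (directed) matrices the same masks apply; each retained cell `(i, j)`
#' represents the ordered edge i -> j.
#'
#' @param n_ch Channels per brain.
#' @param participant 1 or 2 (for `intra_mask`).
#' @return Logical 2N x 2N matrix.
#' @export
inter_mask <- function(n_ch) {
  m <- matrix(FALSE, 2 * n_ch, 2 * n_ch)
  m[seq_len(n_ch), n_ch + seq_len(n_ch)] <- TRUE
  m
}

#' @rdname inter_mask
#' @export
intra_mask <- function(n_ch, participant = 1L) {
  m <- matrix(FALSE, 2 * n_ch, 2 * n_ch)
  idx <- (participant - 1L) * n_ch + seq_len(n_ch)
  blk <- upper.tri(matrix(TRUE, n_ch, n_ch))
  m[idx, idx] <- blk
  m
}

#' Paired edge-wise t statistics
#'
#' Paired t values (`A - B`) for every matrix cell across matched sampling
#' units (dyads for inter-brain edges, participants for intra-brain edges).
#'
#' @param mats_a,mats_b Lists of equally sized matrices, matched by unit.
#' @return Matrix of t values (0 where the difference is identically 0;
#'   signed `Inf` for a nonzero constant difference).
#' @export
edge_tstats <- function(mats_a, mats_b) {
  n <- length(mats_a)
  if (n != length(mats_b)) stop("condition lists differ in length")
  if (n < 3) stop("need at least 3 matched pairs, got ", n)
  d <- vapply(seq_len(n), function(k) as.vector(mats_a[[k]] - mats_b[[k]]),
              numeric(length(mats_a[[1]])))
  m <- rowMeans(d)
  v <- apply(d, 1L, var)
  t <- m / sqrt(v / n)
  t[v == 0 & m == 0] <- 0
  t[v == 0 & m != 0] <- sign(m[v == 0 & m != 0]) * Inf
  out <- matrix(t, nrow(mats_a[[1]]), ncol(mats_a[[1]]))
  dimnames(out) <- dimnames(mats_a[[1]])
  out
}

# connected components (weak connectivity) of suprathreshold same-sign
# edges; cells: integer matrix of (i, j) indices; tvals matching values
cluster_components <- function(tvals, cells, edge_threshold, allow_single) {
  sel <- which(is.finite(tvals) & abs(tvals) > edge_threshold |
                 is.infinite(tvals))
  if (!length(sel)) return(list())
  out <- list()
  for (sgn in c(1, -1)) {
    ss <- sel[sign(tvals[sel]) == sgn]
    if (!length(ss)) next
    comps <- edge_components(cells[ss, , drop = FALSE])
    for (comp in comps) {
      e <- ss[comp]
      if (!allow_single && length(e) < 2L) next
      out[[length(out) + 1L]] <- list(
        edges = cells[e, , drop = FALSE],
        t_values = tvals[e],
        score = sum(tvals[e]),
        sign = sgn,
        n_edges = length(e),
        single_edge = length(e) == 1L)
    }
  }
  out
}

#' Form clusters from a t matrix
#'
#' Suprathreshold edges (|t| above `edge_threshold`) of the same sign are
#' grouped into connected components of the graph they induce; opposite
#' signs never merge. For directed (antisymmetric) matrices each cell of
#' the mask is an ordered edge, so sign separation doubles as direction
#' separation.
#'
#' @param t_mat Square t matrix.
#' @param edge_threshold Absolute t threshold for edge inclusion.
#' @param mask Logical matrix selecting the edge set under test (e.g.
#'   [inter_mask()], [intra_mask()]). Default: upper triangle.
#' @param allow_single Admit single-edge components as clusters (flagged).
#' @return List of clusters: `edges` (index pairs), `t_values`, `score`
#'   (summed t), `sign`, `n_edges`, `single_edge`.
#' @export
form_clusters <- function(t_mat, edge_threshold = 2, mask = NULL,
                          allow_single = TRUE) {
  if (is.null(mask)) mask <- upper.tri(t_mat)
  cells_lin <- which(mask)
  cells <- arrayInd(cells_lin, dim(t_mat))
  cluster_components(t_mat[cells_lin], cells, edge_threshold, allow_single)
}

#' Nonparametric cluster permutation test
#'
#' Paired two-condition test on an edge set with family-wise error control
#' through the maximum cluster statistic. Edge-wise paired t values are
#' thresholded at `edge_threshold`, suprathreshold same-sign edges are
#' clustered into connected components, and each cluster's summed t is
#' compared against the permutation null built by randomly flipping the
#' condition labels of each sampling unit and retaining the maximum
#' absolute cluster score of every permutation. The critical value aligns
#' with a two-tailed test at level `alpha`.
#'
#' @inheritParams edge_tstats
#' @param mask Logical matrix selecting the edge set under test.
#' @param n_perm Number of permutations.
#' @param alpha Significance level (two-tailed via the max-|score| null).
#' @param edge_threshold Absolute t threshold for cluster membership.
#' @param allow_single Admit single-edge clusters.
#' @return Object of class `"cluster_result"`: `clusters` (each with
#'   `score`, `p_value`, `significant`, edge list), `t_critical`,
#'   `null_distribution`, `max_score`, `any_significant`, and the test
#'   parameters.
#' @export
cluster_permutation <- function(mats_a, mats_b, mask, n_perm = 5000,
                                alpha = 0.05, edge_threshold = 2,
                                allow_single = TRUE) {
  if (n_perm <= 0) stop("n_perm must be positive")
  if (n_perm < 100) warning("n_perm < 100: permutation null is coarse")
  n <- length(mats_a)
  if (n != length(mats_b)) stop("condition lists differ in length")
  if (n < 3) stop("need at least 3 matched pairs, got ", n)

  cells_lin <- which(mask)
  cells <- arrayInd(cells_lin, dim(mats_a[[1]]))
  d <- vapply(seq_len(n),
              function(k) (mats_a[[k]] - mats_b[[k]])[cells_lin],
              numeric(length(cells_lin)))
  d <- t(d)  # n x E
  ss <- colSums(d^2)

  t_of <- function(s) {
    m <- as.vector(s %*% d) / n
    v <- pmax((ss - n * m^2) / (n - 1), 0)
    t <- ifelse(v > 0, m / sqrt(v / n),
                ifelse(m == 0, 0, sign(m) * Inf))
    t
  }

  t_obs <- t_of(rep(1, n))
  clusters <- cluster_components(t_obs, cells, edge_threshold, allow_single)

  null <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    s <- sample(c(-1, 1), n, replace = TRUE)
    cl <- cluster_components(t_of(s), cells, edge_threshold, allow_single)
    null[p] <- if (length(cl))
      max(abs(vapply(cl, `[[`, numeric(1), "score"))) else 0
  }

  t_critical <- sort(null, decreasing = TRUE)[ceiling(alpha * (n_perm + 1))]
  for (k in seq_along(clusters)) {
    sc <- abs(clusters[[k]]$score)
    clusters[[k]]$p_value <- (1 + sum(null >= sc)) / (n_perm + 1)
    clusters[[k]]$significant <- clusters[[k]]$p_value <= alpha
  }
  structure(list(clusters = clusters, t_critical = t_critical,
                 null_distribution = null,
                 max_score = if (length(clusters))
                   max(abs(vapply(clusters, `[[`, numeric(1), "score")))
                 else 0,
                 any_significant = any(vapply(clusters, `[[`, logical(1),
                                              "significant")),
                 alpha = alpha, n_perm = n_perm,
                 edge_threshold = edge_threshold, n_units = n),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result>", length(x$clusters), "cluster(s), t-critical",
      round(x$t_critical, 2), "(alpha", x$alpha, ",", x$n_perm,
      "permutations)\n")
  for (cl in x$clusters)
    cat(sprintf("  %+d x %d edges  score %.2f  p %.4f%s\n", cl$sign,
                cl$n_edges, cl$score, cl$p_value,
                if (cl$significant) " *" else ""))
  invisible(x)
}

#' Shuffled-pairs common-input control
#'
#' Rebuilds the inter-brain analysis after repeatedly re-pairing
#' participant 1 of each dyad with participant 2 of a different dyad
#' (a random derangement per shuffle). Pair-specific coupling vanishes
#' under the shuffle while coupling driven by a stimulus common to all
#' dyads survives, so an observed cluster statistic that is extreme
#' against this null cannot be explained by shared input.
#'
#' @param epoch_sets List (one per dyad) of `"analytic_epochs_set"` objects
#'   holding both conditions for one band.
#' @param n_shuffles Number of shuffled datasets.
#' @param edge_threshold Absolute t threshold for clustering.
#' @param conditions The two condition labels (first minus second).
#' @return List: `observed` (max absolute cluster score of the true
#'   pairing), `null` (per-shuffle statistics), `p_value`.
#' @export
shuffled_pairs_control <- function(epoch_sets, n_shuffles = 1000,
                                   edge_threshold = 2,
                                   conditions = c("eye_contact", "control")) {
  if (n_shuffles <= 0) stop("n_shuffles must be positive")
  nd <- length(epoch_sets)
  if (nd < 3) stop("need at least 3 dyads, got ", nd)
  n_ch <- length(epoch_sets[[1]]$channel_labels)
  mask <- inter_mask(n_ch)

  stat_for <- function(pairing) {
    a <- b <- vector("list", nd)
    for (d in seq_len(nd)) {
      e1 <- epoch_sets[[d]]$epochs
      e2 <- epoch_sets[[pairing[d]]]$epochs
      a[[d]] <- ciplv_matrix(e1[[conditions[1]]], e2[[conditions[1]]])
      b[[d]] <- ciplv_matrix(e1[[conditions[2]]], e2[[conditions[2]]])
    }
    tm <- edge_tstats(a, b)
    cl <- form_clusters(tm, edge_threshold, mask)
    if (length(cl)) max(abs(vapply(cl, `[[`, numeric(1), "score"))) else 0
  }

  observed <- stat_for(seq_len(nd))
  null <- numeric(n_shuffles)
  for (s in seq_len(n_shuffles))
    null[s] <- stat_for(random_derangement(nd))
  list(observed = observed, null = null,
       p_value = (1 + sum(null >= observed)) / (n_shuffles + 1))
}
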