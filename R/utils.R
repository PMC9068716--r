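#' @useDynLib hyperbrain, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate cor fft median pt qt quantile rbinom rnorm
#'   rpois runif sd setNames var complete.cases
#' @importFrom utils write.csv read.csv head tail
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Derive per-unit seeds from a master seed
#'
#' Draws `n` distinct 31-bit integers with the master seed so that cohort
#' members are independently yet reproducibly seeded.
#' @param master_seed Integer master seed.
#' @param n Number of seeds.
#' @return Integer vector of length `n`, all below 2^31.
#' @keywords internal
derive_seeds <- function(master_seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Connected components of an edge list over integer node ids (union-find).
# edges: m x 2 integer matrix. Returns list of edge-index vectors, one per
# component (weak connectivity: edge direction ignored).
edge_components <- function(edges) {
  m <- nrow(edges)
  if (m == 0L) return(list())
  nodes <- sort(unique(as.vector(edges)))
  idx <- match(edges, nodes)
  dim(idx) <- dim(edges)
  parent <- seq_along(nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_len(m)) {
    ra <- find(idx[e, 1]); rb <- find(idx[e, 2])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(idx[, 1], find, integer(1))
  unname(split(seq_len(m), roots))
}

# All-pairs shortest-path lengths of a binary undirected graph by BFS.
# adj: symmetric 0/1 matrix. Returns matrix of hop counts (Inf if
# unreachable), zero diagonal.
bfs_distances <- function(adj) {
  n <- nrow(adj)
  nb <- apply(adj > 0, 1, which, simplify = FALSE)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(nb[frontier], use.names = FALSE))
      nxt <- nxt[is.infinite(dist[nxt])]
      dist[nxt] <- d
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  D
}

stopifnot_scalar01 <- function(x, name) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1))
    stop("`", name, "` must lie in [0, 1]", call. = FALSE)
  invisible(x)
}

# Uniform random derangement (permutation with no fixed point) of 1..n.
random_derangement <- function(n) {
  if (n < 2) stop("cannot derange fewer than 2 elements")
  repeat {
    p <- sample.int(n)
    if (all(p != seq_len(n))) return(p)
  }
}
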