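# --- minimal European Data Format (EDF) reader/writer -----------------------
# 16-bit integer encoding, one-second data records. Samples are quantized to
# the per-channel physical range, so round-trips are exact only up to EDF's
# 16-bit resolution.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  sprintf(paste0("%-", width, "s"), x)
}

#' Write a multichannel signal matrix as EDF
#'
#' @param signals Channel-by-time numeric matrix (uV) with rownames.
#' @param fs Sampling rate in Hz (integer).
#' @param path Output file path (written atomically).
#' @param patient,recording Free-text header fields.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(signals, fs, path, patient = "X", recording = "X") {
  stopifnot(is.matrix(signals), fs == as.integer(fs))
  ns <- nrow(signals)
  n <- ncol(signals)
  n_rec <- ceiling(n / fs)
  pad <- n_rec * fs - n
  if (pad > 0) signals <- cbind(signals, matrix(0, ns, pad))
  pmin_ <- apply(signals, 1L, min)
  pmax_ <- apply(signals, 1L, max)
  flat <- pmax_ - pmin_ == 0
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768L
  dmax <- 32767L

  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "wb")
  on.exit(try(close(con), silent = TRUE), add = TRUE)
  hdr <- paste0(
    pad_field("0", 8), pad_field(patient, 80), pad_field(recording, 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 + 256 * ns, 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field("1", 8), pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    c(16, function(i) rownames(signals)[i] %||% paste0("ch", i)),
    c(80, function(i) ""), c(8, function(i) "uV"),
    c(8, function(i) format(pmin_[i], digits = 7)),
    c(8, function(i) format(pmax_[i], digits = 7)),
    c(8, function(i) dmin), c(8, function(i) dmax),
    c(80, function(i) ""), c(8, function(i) fs), c(32, function(i) ""))
  for (f in fields) {
    w <- as.numeric(f[[1]])
    fun <- f[[2]]
    for (i in seq_len(ns)) writeChar(pad_field(fun(i), w), con, eos = NULL)
  }
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns)) {
      dig <- round((signals[i, idx] - pmin_[i]) * scale[i]) + dmin
      writeBin(as.integer(pmin(dmax, pmax(dmin, dig))), con, size = 2L,
               endian = "little")
    }
  }
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return List: `signals` (channel-by-time, uV), `fs`, `labels`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("malformed EDF header in ", path)
  rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1 || is.na(n_rec))
    stop("malformed EDF header in ", path)
  per <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- per(16)
  per(80); per(8)
  pmin_ <- as.numeric(per(8))
  pmax_ <- as.numeric(per(8))
  dmin <- as.numeric(per(8))
  dmax <- as.numeric(per(8))
  per(80)
  spr <- as.integer(per(8))
  per(32)
  if (length(unique(spr)) != 1L)
    stop("mixed sampling rates not supported: ", path)
  fs <- spr[1] / rec_dur
  out <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[1], size = 2L, signed = TRUE,
                     endian = "little")
      out[i, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <-
        (dig - dmin[i]) / (dmax[i] - dmin[i]) * (pmax_[i] - pmin_[i]) +
        pmin_[i]
    }
  }
  rownames(out) <- labels
  list(signals = out, fs = fs, labels = labels)
}

#' Write a dyad recording as EDF + JSON sidecar + CSV events
#'
#' Produces `<dyad_id>_p1.edf`, `<dyad_id>_p2.edf`, `<dyad_id>.json`
#' (events, group, seed, channel bookkeeping) and `<dyad_id>_events.csv`.
#'
#' @param recording A `dyad_recording`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the sidecar path.
#' @export
write_dyad <- function(recording, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- recording$dyad_id
  write_edf(recording$signals_p1, recording$fs,
            file.path(dir, paste0(id, "_p1.edf")), patient = "P1")
  write_edf(recording$signals_p2, recording$fs,
            file.path(dir, paste0(id, "_p2.edf")), patient = "P2")
  sidecar <- list(dyad_id = id, group = recording$group,
                  seed = recording$seed, fs = recording$fs,
                  n_samples = ncol(recording$signals_p1),
                  channel_labels = recording$channel_labels,
                  events = recording$events)
  path <- file.path(dir, paste0(id, ".json"))
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(sidecar, tmp, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  file.rename(tmp, path)
  csv <- file.path(dir, paste0(id, "_events.csv"))
  tmp <- paste0(csv, ".tmp")
  write.csv(recording$events, tmp, row.names = FALSE)
  file.rename(tmp, csv)
  invisible(path)
}

#' Read a dyad recording written by [write_dyad()]
#'
#' @param dir Directory holding the EDF pair and sidecar.
#' @param dyad_id Dyad identifier.
#' @return A `dyad_recording`.
#' @export
read_dyad <- function(dir, dyad_id) {
  sidecar_path <- file.path(dir, paste0(dyad_id, ".json"))
  if (!file.exists(sidecar_path))
    stop("missing sidecar file: ", sidecar_path)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  p1 <- read_edf(file.path(dir, paste0(dyad_id, "_p1.edf")))
  p2 <- read_edf(file.path(dir, paste0(dyad_id, "_p2.edf")))
  for (p in list(p1, p2)) {
    if (nrow(p$signals) != length(sc$channel_labels))
      stop("sidecar/recording inconsistency: sidecar lists ",
           length(sc$channel_labels), " channels, EDF has ",
           nrow(p$signals))
  }
  if (is.null(sc$events) || !length(sc$events))
    stop("missing events in sidecar: ", sidecar_path)
  events <- as.data.frame(sc$events, stringsAsFactors = FALSE)
  structure(list(
    signals_p1 = p1$signals[, seq_len(sc$n_samples), drop = FALSE],
    signals_p2 = p2$signals[, seq_len(sc$n_samples), drop = FALSE],
    fs = sc$fs, channel_labels = sc$channel_labels, events = events,
    dyad_id = sc$dyad_id, group = sc$group, seed = sc$seed),
    class = "dyad_recording")
}

#' Export a hyperbrain graph as GraphML
#'
#' Node attributes: channel, participant, ROI; edge attributes: retained z
#' weight and (for directed graphs) sign.
#'
#' @param graph A `"hyperbrain_graph"`.
#' @param path Output path (written atomically).
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "hyperbrain_graph"))
  g <- igraph::graph_from_adjacency_matrix(graph$weights, weighted = TRUE,
                                           mode = "undirected", diag = FALSE)
  igraph::V(g)$channel <- graph$nodes$channel
  igraph::V(g)$participant <- graph$nodes$participant
  igraph::V(g)$roi <- graph$nodes$roi
  if (graph$directed) {
    el <- igraph::as_edgelist(g, names = FALSE)
    igraph::E(g)$sign <- graph$sign[el]
  }
  tmp <- paste0(path, ".tmp")
  igraph::write_graph(g, tmp, format = "graphml")
  file.rename(tmp, path)
  invisible(path)
}

#' Write a cluster permutation report as JSON
#'
#' @param result A `"cluster_result"`.
#' @param path Output path.
#' @param channel_names Optional node names to label edges.
#' @return Invisibly, `path`.
#' @export
write_cluster_report <- function(result, path, channel_names = NULL) {
  stopifnot(inherits(result, "cluster_result"))
  report <- list(
    t_critical = result$t_critical, alpha = result$alpha,
    n_perm = result$n_perm, edge_threshold = result$edge_threshold,
    null_summary = list(mean = mean(result$null_distribution),
                        q95 = unname(quantile(result$null_distribution,
                                              0.95))),
    clusters = lapply(result$clusters, function(cl) {
      edges <- cl$edges
      if (!is.null(channel_names))
        edges <- matrix(channel_names[edges], ncol = 2)
      list(score = cl$score, p_value = cl$p_value,
           significant = cl$significant, sign = cl$sign,
           n_edges = cl$n_edges, single_edge = cl$single_edge,
           edges = apply(edges, 1L, paste, collapse = "--"))
    }))
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(report, tmp, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, path)
  invisible(path)
}
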