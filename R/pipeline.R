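#' Pipeline run configuration
#'
#' Bundles every knob of the end-to-end run: cohort composition, bands and
#' measures to test, permutation and thresholding parameters, and the
#' simulation configuration. Fully serializable; re-running from the same
#' configuration and seed reproduces all outputs.
#'
#' @param n_dyads Number of dyads to simulate.
#' @param friends_fraction Fraction of friend dyads.
#' @param bands Band names to analyze.
#' @param measures Connectivity measures: `"ciplv"`, `"psi"` or both.
#' @param n_perm Cluster permutations per band.
#' @param n_shuffles Shuffles for the behavioral correlation null.
#' @param alpha Cluster significance level.
#' @param edge_threshold Absolute edge-t threshold for clustering.
#' @param z_threshold Hyperbrain graph retention threshold (SD of control).
#' @param window Analysis window (s) after epoch onset.
#' @param min_trials Minimum valid trials per condition.
#' @param rich_club_rand Randomizations for the rich-club null.
#' @param sim A [sim_config()]; its seed is overridden by `seed`.
#' @param seed Master seed for the whole run.
#' @param leadership_bias Optional per-dyad leadership bias vector.
#' @param out_dir Optional output directory for stage artifacts.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(n_dyads = 20L, friends_fraction = 0.5,
                       bands = names(frequency_bands()),
                       measures = c("ciplv", "psi"),
                       n_perm = 500L, n_shuffles = 1000L, alpha = 0.05,
                       edge_threshold = 2, z_threshold = 1,
                       window = c(0.5, 2.0), min_trials = 5L,
                       rich_club_rand = 100L, sim = sim_config(),
                       seed = 1L, leadership_bias = NULL, out_dir = NULL) {
  sim$seed <- as.integer(seed)
  cfg <- list(n_dyads = as.integer(n_dyads),
              friends_fraction = friends_fraction, bands = bands,
              measures = measures, n_perm = as.integer(n_perm),
              n_shuffles = as.integer(n_shuffles), alpha = alpha,
              edge_threshold = edge_threshold, z_threshold = z_threshold,
              window = window, min_trials = as.integer(min_trials),
              rich_club_rand = as.integer(rich_club_rand), sim = sim,
              seed = as.integer(seed), leadership_bias = leadership_bias,
              out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Two-group comparison helper
#'
#' Welch (independent) or paired t test with Cohen's d (pooled-SD
#' convention for independent groups; mean difference over the SD of the
#' differences for paired samples).
#'
#' @param values_a,values_b Numeric vectors (matched when `paired`).
#' @param paired Paired comparison?
#' @return List: `t`, `df`, `p_value`, `cohen_d`, `mean_a`, `mean_b`.
#' @export
group_compare <- function(values_a, values_b, paired = FALSE) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (paired) {
    keep <- seq_len(min(length(values_a), length(values_b)))
    d <- values_a[keep] - values_b[keep]
    n <- length(d)
    if (n < 3) stop("need at least 3 pairs")
    if (sd(d) == 0 && mean(d) == 0)
      return(list(t = 0, df = n - 1, p_value = 1, cohen_d = 0,
                  mean_a = mean(values_a), mean_b = mean(values_b)))
    tt <- stats::t.test(values_a[keep], values_b[keep], paired = TRUE)
    dd <- mean(d) / sd(d)
  } else {
    if (length(values_a) < 3 || length(values_b) < 3)
      stop("need at least 3 observations per group")
    va <- var(values_a)
    vb <- var(values_b)
    if (va == 0 && vb == 0) {
      if (mean(values_a) == mean(values_b))
        return(list(t = 0, df = NA_real_, p_value = 1, cohen_d = 0,
                    mean_a = mean(values_a), mean_b = mean(values_b)))
      warning("zero variance in both groups; comparison undefined")
      return(list(t = NA_real_, df = NA_real_, p_value = NA_real_,
                  cohen_d = NA_real_, mean_a = mean(values_a),
                  mean_b = mean(values_b)))
    }
    tt <- stats::t.test(values_a, values_b)
    na <- length(values_a)
    nb <- length(values_b)
    sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
    dd <- (mean(values_a) - mean(values_b)) / sp
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, cohen_d = dd, mean_a = mean(values_a),
       mean_b = mean(values_b))
}

# extract one participant's intra-brain block
intra_block <- function(mat, n_ch, participant) {
  idx <- (participant - 1L) * n_ch + seq_len(n_ch)
  mat[idx, idx, drop = FALSE]
}

# reorder a hyperbrain matrix so the leader occupies the P1 block
leader_first <- function(mat, n_ch, leader) {
  if (leader == "P1" || is.na(leader)) return(mat)
  idx <- c(n_ch + seq_len(n_ch), seq_len(n_ch))
  mat[idx, idx, drop = FALSE]
}

#' Run the full hyperbrain pipeline
#'
#' Simulate -> preprocess -> connectivity -> cluster inference -> band
#' selection -> hyperbrain networks -> behavior, in the two-step design:
#' cluster permutation first identifies the band(s) showing a condition
#' effect per measure, then z-scored thresholded graphs and their metrics
#' are computed on the selected band(s) only. Directed (PSI) cluster
#' inference and flow metrics use the strong-leadership dyads with each
#' matrix reordered leader-first.
#'
#' @param config A [run_config()].
#' @return List of class `"hyperbrain_results"`: `cluster_tests` (per
#'   measure and band), `selected_bands`, `metrics`, `networks`,
#'   `friend_contrasts`, `rich_club`, `leadership`, `directed`,
#'   `excluded_dyads`, `manifest`, `manifest_hash`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  n_ch <- config$sim$n_channels
  cohort <- generate_cohort(config$n_dyads, config$friends_fraction,
                            config$sim,
                            leadership_bias = config$leadership_bias)

  # ---- preprocessing and connectivity stacks -------------------------------
  conn <- list(ciplv = list(), psi = list())
  groups <- character(0)
  excluded <- character(0)
  kept_ids <- character(0)
  for (rec0 in cohort$recordings) {
    rec <- rereference(rec0, allow_missing = TRUE)
    mask <- detect_blinks(rec)
    dyad_ok <- TRUE
    mats <- list(ciplv = list(), psi = list())
    raw_set <- if ("psi" %in% config$measures)
      epoch_raw(rec, window = config$window, mask = mask,
                min_trials = config$min_trials) else NULL
    esets <- epoch_analytic_bands(rec, config$bands, window = config$window,
                                  mask = mask,
                                  min_trials = config$min_trials)
    for (band in config$bands) {
      eset <- esets[[band]]
      if (!eset$valid_dyad) {
        dyad_ok <- FALSE
        break
      }
      if ("ciplv" %in% config$measures)
        mats$ciplv[[band]] <- lapply(eset$epochs, ciplv_matrix)
      if ("psi" %in% config$measures) {
        psi_band <- tryCatch(
          lapply(raw_set$epochs, psi_matrix, band = band),
          error = function(e) NULL)  # too few clean segments
        if (is.null(psi_band)) {
          dyad_ok <- FALSE
          break
        }
        mats$psi[[band]] <- psi_band
      }
    }
    if (!dyad_ok) {
      excluded <- c(excluded, rec0$dyad_id)
      next
    }
    kept_ids <- c(kept_ids, rec0$dyad_id)
    groups <- c(groups, rec0$group)
    for (m in config$measures)
      conn[[m]][[rec0$dyad_id]] <- mats[[m]]
  }
  if (length(kept_ids) < 3)
    stop("stage connectivity: fewer than 3 valid dyads")
  behavior <- cohort$behavior[cohort$behavior$dyad_id %in% kept_ids, ,
                              drop = FALSE]

  # ---- behavior ------------------------------------------------------------
  lead <- leadership_split(behavior)
  correlations <- lapply(kept_ids, function(d)
    pair_correlation(behavior[behavior$dyad_id == d &
                                behavior$task == "eye_contact", ,
                              drop = FALSE],
                     n_shuffles = config$n_shuffles))
  names(correlations) <- kept_ids

  strong_ids <- lead$dyad_id[lead$group == "strong"]
  leaders <- setNames(lead$leader, lead$dyad_id)

  # ---- step 1: cluster permutation per measure and band --------------------
  cluster_tests <- list()
  selected <- list()
  for (m in config$measures) {
    cluster_tests[[m]] <- list()
    selected[[m]] <- character(0)
    use_ids <- if (m == "psi") intersect(kept_ids, strong_ids) else kept_ids
    if (m == "psi" && length(use_ids) < 3) {
      cluster_tests[[m]] <- NULL
      next
    }
    for (band in config$bands) {
      eye <- lapply(use_ids, function(d) {
        mt <- conn[[m]][[d]][[band]]$eye_contact
        if (m == "psi") leader_first(mt, n_ch, leaders[[d]]) else mt
      })
      ctl <- lapply(use_ids, function(d) {
        mt <- conn[[m]][[d]][[band]]$control
        if (m == "psi") leader_first(mt, n_ch, leaders[[d]]) else mt
      })
      inter <- cluster_permutation(eye, ctl, inter_mask(n_ch),
                                   n_perm = config$n_perm,
                                   alpha = config$alpha,
                                   edge_threshold = config$edge_threshold)
      # intra edges are paired at the participant level
      intra_a <- c(lapply(eye, intra_block, n_ch, 1L),
                   lapply(eye, intra_block, n_ch, 2L))
      intra_b <- c(lapply(ctl, intra_block, n_ch, 1L),
                   lapply(ctl, intra_block, n_ch, 2L))
      intra <- cluster_permutation(intra_a, intra_b,
                                   upper.tri(diag(n_ch)),
                                   n_perm = config$n_perm,
                                   alpha = config$alpha,
                                   edge_threshold = config$edge_threshold)
      cluster_tests[[m]][[band]] <- list(inter = inter, intra = intra)
      if (inter$any_significant)
        selected[[m]] <- c(selected[[m]], band)
    }
  }

  # ---- step 2: hyperbrain networks on the selected band(s) -----------------
  metrics <- list()
  networks <- list()
  friend_contrasts <- list()
  rc_results <- list()
  directed <- list()
  if ("ciplv" %in% config$measures) {
    for (band in selected$ciplv) {
      rows <- list()
      graphs <- list()
      rcs <- list()
      for (d in kept_ids) {
        z <- zscore_edges(conn$ciplv[[d]][[band]]$eye_contact,
                          conn$ciplv[[d]][[band]]$control, n_ch)
        g <- threshold_graph(z, config$z_threshold)
        s <- network_summary(g)
        rc <- rich_club(g, n_rand = config$rich_club_rand)
        graphs[[d]] <- g
        rcs[[d]] <- rc
        rows[[d]] <- data.frame(
          dyad_id = d, band = band,
          group = groups[match(d, kept_ids)],
          strength_inter = s$strength[["inter"]],
          strength_intra = mean(s$strength[c("intra1", "intra2")],
                                na.rm = TRUE),
          density_inter = s$density[["inter"]],
          density_intra = mean(s$density[c("intra1", "intra2")]),
          global_efficiency = global_efficiency(g)$E,
          local_efficiency = local_efficiency(g)$E_loc,
          modularity = modularity_p1p2(g),
          assortativity = suppressWarnings(assortativity_degree(g)),
          rich_club_present = rc$present,
          stringsAsFactors = FALSE)
      }
      tab <- do.call(rbind, rows)
      metrics[[band]] <- tab
      networks[[band]] <- graphs
      rc_results[[band]] <- list(
        per_dyad = rcs,
        fraction_present = mean(tab$rich_club_present),
        membership = rich_club_membership(rcs))
      fr <- tab$group == "friends"
      friend_contrasts[[band]] <- if (sum(fr) >= 3 && sum(!fr) >= 3) list(
        strength_inter = group_compare(tab$strength_inter[fr],
                                       tab$strength_inter[!fr]),
        density_inter = group_compare(tab$density_inter[fr],
                                      tab$density_inter[!fr]),
        strength_intra = group_compare(tab$strength_intra[fr],
                                       tab$strength_intra[!fr])) else NULL
    }
  }
  if ("psi" %in% config$measures && length(strong_ids) >= 3) {
    for (band in selected$psi) {
      flows <- list()
      for (d in intersect(kept_ids, strong_ids)) {
        eye <- leader_first(conn$psi[[d]][[band]]$eye_contact, n_ch,
                            leaders[[d]])
        ctl <- leader_first(conn$psi[[d]][[band]]$control, n_ch,
                            leaders[[d]])
        z <- zscore_edges(eye, ctl, n_ch, directed = TRUE)
        g <- threshold_graph(z, config$z_threshold)
        fl <- directed_flow(g, leader = "P1")
        fl$dyad_id <- d
        flows[[d]] <- fl
      }
      flow_tab <- do.call(rbind, flows)
      lead_rows <- flow_tab[flow_tab$role == "leader", , drop = FALSE]
      foll_rows <- flow_tab[flow_tab$role == "follower", , drop = FALSE]
      directed[[band]] <- list(
        flows = flow_tab,
        outgoing_count = group_compare(lead_rows$n_out, foll_rows$n_out,
                                       paired = TRUE),
        outgoing_strength =
          if (sum(is.finite(lead_rows$strength_out)) >= 3 &&
              sum(is.finite(foll_rows$strength_out)) >= 3)
            group_compare(lead_rows$strength_out, foll_rows$strength_out)
          else NULL)
    }
  }

  # ---- manifest ------------------------------------------------------------
  manifest <- list(
    config = unclass_recursive(config),
    n_dyads_analyzed = length(kept_ids),
    excluded_dyads = excluded,
    selected_bands = selected,
    cluster_summary = lapply(cluster_tests, function(mm)
      lapply(mm, function(bb) list(
        inter_max_score = bb$inter$max_score,
        inter_t_critical = bb$inter$t_critical,
        inter_significant = bb$inter$any_significant,
        intra_max_score = bb$intra$max_score,
        intra_significant = bb$intra$any_significant))),
    leadership_median = attr(lead, "median"))
  hash <- manifest_hash(manifest)

  results <- list(cluster_tests = cluster_tests, selected_bands = selected,
                  metrics = metrics, networks = networks,
                  friend_contrasts = friend_contrasts,
                  rich_club = rc_results, leadership = lead,
                  correlations = correlations, directed = directed,
                  excluded_dyads = excluded, dyad_ids = kept_ids,
                  groups = groups, behavior = behavior,
                  manifest = manifest, manifest_hash = hash)
  class(results) <- "hyperbrain_results"

  if (!is.null(config$out_dir)) write_results(results, config$out_dir)
  results
}

unclass_recursive <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_recursive)
  } else x
}

manifest_hash <- function(manifest) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  unname(tools::md5sum(tmp))
}

#' Persist pipeline results
#'
#' Writes the manifest, leadership and metric tables, cluster reports and
#' (for each selected band) per-dyad GraphML graphs.
#'
#' @param results A `"hyperbrain_results"` object.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tmp <- file.path(dir, "manifest.json.tmp")
  jsonlite::write_json(results$manifest, tmp, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  file.rename(tmp, file.path(dir, "manifest.json"))
  tmp <- file.path(dir, "leadership.csv.tmp")
  write.csv(results$leadership, tmp, row.names = FALSE)
  file.rename(tmp, file.path(dir, "leadership.csv"))
  for (band in names(results$metrics)) {
    tmp <- file.path(dir, paste0("metrics_", band, ".csv.tmp"))
    write.csv(results$metrics[[band]], tmp, row.names = FALSE)
    file.rename(tmp, file.path(dir, paste0("metrics_", band, ".csv")))
    for (d in names(results$networks[[band]]))
      write_graphml(results$networks[[band]][[d]],
                    file.path(dir, paste0("graph_", band, "_", d,
                                          ".graphml")))
  }
  for (m in names(results$cluster_tests))
    for (band in names(results$cluster_tests[[m]]))
      write_cluster_report(results$cluster_tests[[m]][[band]]$inter,
                           file.path(dir, paste0("cluster_", m, "_", band,
                                                 ".json")))
  invisible(dir)
}

#' @export
print.hyperbrain_results <- function(x, ...) {
  cat("<hyperbrain_results>", length(x$dyad_ids), "dyads analyzed,",
      length(x$excluded_dyads), "excluded\n")
  for (m in names(x$selected_bands))
    cat("  ", m, "selected band(s):",
        if (length(x$selected_bands[[m]]))
          paste(x$selected_bands[[m]], collapse = ", ") else "none", "\n")
  cat("  manifest", x$manifest_hash, "\n")
  invisible(x)
}
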