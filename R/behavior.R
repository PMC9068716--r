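#' Reproduction-duration summary
#'
#' Mean reproduced duration per participant, task, tone duration and pair
#' duration (same vs. different tones for the two partners), after
#' excluding reproductions shorter than 0.5 s or longer than 4 s.
#'
#' @param trials Trial table (see [generate_behavior()]).
#' @param min_s,max_s Retention bounds on reproduced durations (seconds).
#' @return Data frame with one row per participant x task x tone x
#'   pair-duration cell: `mean_duration` (`NA` for empty cells) and
#'   `n_trials`.
#' @export
reproduction_summary <- function(trials, min_s = 0.5, max_s = 4) {
  long <- rbind(
    data.frame(participant = "P1", task = trials$task,
               tone = trials$tone_p1,
               pair_duration = ifelse(trials$tone_p1 == trials$tone_p2,
                                      "same", "different"),
               duration = trials$repro_p1, stringsAsFactors = FALSE),
    data.frame(participant = "P2", task = trials$task,
               tone = trials$tone_p2,
               pair_duration = ifelse(trials$tone_p1 == trials$tone_p2,
                                      "same", "different"),
               duration = trials$repro_p2, stringsAsFactors = FALSE))
  long <- long[long$duration >= min_s & long$duration <= max_s, ,
               drop = FALSE]
  cells <- expand.grid(participant = c("P1", "P2"),
                       task = unique(trials$task),
                       tone = sort(unique(c(trials$tone_p1,
                                            trials$tone_p2))),
                       pair_duration = c("same", "different"),
                       stringsAsFactors = FALSE)
  cells$mean_duration <- NA_real_
  cells$n_trials <- 0L
  for (r in seq_len(nrow(cells))) {
    sel <- long$participant == cells$participant[r] &
      long$task == cells$task[r] & long$tone == cells$tone[r] &
      long$pair_duration == cells$pair_duration[r]
    cells$n_trials[r] <- sum(sel)
    if (any(sel)) cells$mean_duration[r] <- mean(long$duration[sel])
  }
  cells
}

#' Partner correlation of reproduced durations with a shuffled null
#'
#' Spearman correlation of the two partners' reproduced durations on
#' same-duration trials, compared against a null built by shuffling each
#' participant's trial order independently (never across participants).
#' Pairs with fewer than `min_trials` usable trials are excluded.
#'
#' @param trials Trial table for one dyad (one task).
#' @param n_shuffles Number of shuffled iterations.
#' @param min_trials Minimum usable same-duration trials.
#' @return List: `r_observed`, `null_mean`, `null_sd`, `z` (standardized
#'   observed position), `n_trials`, `excluded` (with `reason`).
#' @export
pair_correlation <- function(trials, n_shuffles = 5000, min_trials = 5L) {
  use <- trials$tone_p1 == trials$tone_p2
  x <- trials$repro_p1[use]
  y <- trials$repro_p2[use]
  n <- length(x)
  if (n < min_trials)
    return(list(r_observed = NA_real_, null_mean = NA_real_,
                null_sd = NA_real_, z = NA_real_, n_trials = n,
                excluded = TRUE, reason = "fewer than 5 usable trials"))
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r_observed = NA_real_, null_mean = NA_real_,
                null_sd = NA_real_, z = NA_real_, n_trials = n,
                excluded = TRUE, reason = "constant durations"))
  r_obs <- cor(x, y, method = "spearman")
  rx <- rank(x)
  ry <- rank(y)
  null <- vapply(seq_len(n_shuffles), function(i) {
    cor(rx[sample.int(n)], ry[sample.int(n)])
  }, numeric(1))
  list(r_observed = r_obs, null_mean = mean(null), null_sd = sd(null),
       z = (r_obs - mean(null)) / sd(null), n_trials = n,
       excluded = FALSE, reason = NA_character_)
}

#' Leadership profile of a dyad
#'
#' The participant who breaks eye contact first on a trial is that trial's
#' leader. The raw fraction of same-duration eye-contact trials led by P1
#' is reflected to `[0.5, 1]` (values below 0.5 are subtracted from 1) to
#' give the leadership strength; the leading participant is the one with
#' the majority. A strength of exactly 0.5 means no leadership
#' relationship and the dyad is excluded from leadership analyses.
#'
#' @param trials Trial table for one dyad.
#' @param same_duration_only Restrict to trials where both partners heard
#'   the same tone duration.
#' @return List of class `"leadership_profile"`: `raw_fraction`,
#'   `strength`, `leader` (`NA` when none), `n_trials`.
#' @export
leadership <- function(trials, same_duration_only = TRUE) {
  t_ec <- trials[trials$task == "eye_contact" &
                   !is.na(trials$first_breaker), , drop = FALSE]
  if (same_duration_only)
    t_ec <- t_ec[t_ec$tone_p1 == t_ec$tone_p2, , drop = FALSE]
  n <- nrow(t_ec)
  if (n == 0) stop("no usable trials for leadership")
  raw <- mean(t_ec$first_breaker == "P1")
  strength <- max(raw, 1 - raw)
  leader <- if (strength == 0.5) NA_character_ else
    if (raw > 0.5) "P1" else "P2"
  structure(list(raw_fraction = raw, strength = strength, leader = leader,
                 n_trials = n),
            class = "leadership_profile")
}

#' Strong/weak leadership split of a cohort
#'
#' Computes per-dyad leadership profiles and splits the cohort at the
#' median strength: dyads at or above the median are "strong", below are
#' "weak", and dyads with strength exactly 0.5 are "none" and excluded.
#'
#' @param behavior Row-bound trial tables with a `dyad_id` column.
#' @param median_split_value Optional fixed split value; defaults to the
#'   cohort median strength.
#' @return Data frame per dyad: `dyad_id`, `raw_fraction`, `strength`,
#'   `leader`, `group` (strong/weak/none), plus the split value as
#'   attribute `"median"`.
#' @export
leadership_split <- function(behavior, median_split_value = NULL) {
  ids <- unique(behavior$dyad_id)
  profs <- lapply(ids, function(d)
    leadership(behavior[behavior$dyad_id == d, , drop = FALSE]))
  out <- data.frame(
    dyad_id = ids,
    raw_fraction = vapply(profs, `[[`, numeric(1), "raw_fraction"),
    strength = vapply(profs, `[[`, numeric(1), "strength"),
    leader = vapply(profs, `[[`, character(1), "leader"),
    stringsAsFactors = FALSE)
  med <- median_split_value %||% median(out$strength)
  out$group <- ifelse(out$strength == 0.5, "none",
                      ifelse(out$strength >= med, "strong", "weak"))
  attr(out, "median") <- med
  out
}
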