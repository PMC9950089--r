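#' Per-activity sensitivity and specificity
#'
#' Scores classification results against labelled seconds, per activity
#' group: sensitivity (detected fraction) for walking groups, specificity
#' (rejected fraction) for non-walking groups.  When a subject performed
#' several trials of one activity, the trial scores are averaged within
#' subject first; the per-subject scores are then averaged across subjects
#' and reported with a normal-approximation 95% confidence interval
#' (mean +/- 1.96 SE).  Labels should be motion-adjusted beforehand (see
#' [adjust_walking_labels()]); seconds labelled `"adjusted_out"` are
#' ignored.
#'
#' @param trials list of trials; each a list with elements `result` (a
#'   `walk_result` from [classify()]), `labels` ([activity_labels()] on the
#'   recording's time axis), `subject` (id), and optionally `location`.
#' @param grouping raw-name -> group map; see [default_grouping()].
#' @param walking_groups groups scored as sensitivity; default `"walking"`.
#' @return data.frame with columns `group`, `location`, `kind`
#'   (`"sensitivity"`/`"specificity"`), `mean`, `ci_lo`, `ci_hi`,
#'   `n_subjects`.
#' @export
evaluate_walking <- function(trials, grouping = default_grouping(),
                             walking_groups = "walking") {
  rows <- list()
  for (tr in trials) {
    res <- tr$result
    sec <- res$seconds
    lab <- rep(NA_character_, nrow(sec))
    mid <- sec$time_start + 0.5
    for (i in seq_len(nrow(tr$labels))) {
      hit <- mid >= tr$labels$start[i] & mid < tr$labels$end[i]
      lab[hit] <- tr$labels$activity[i]
    }
    grp <- apply_grouping(lab, grouping)
    loc <- if (!is.null(tr$location)) tr$location else res$location
    for (g in setdiff(unique(grp[!is.na(grp)]), "adjusted_out")) {
      idx <- which(!is.na(grp) & grp == g)
      if (!length(idx)) next
      detected <- mean(sec$walking[idx])
      is_walk <- g %in% walking_groups
      rows[[length(rows) + 1L]] <- data.frame(
        subject = as.character(tr$subject), group = g, location = loc,
        kind = if (is_walk) "sensitivity" else "specificity",
        score = if (is_walk) detected else 1 - detected,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(group = character(0), location = character(0),
                      kind = character(0), mean = numeric(0),
                      ci_lo = numeric(0), ci_hi = numeric(0),
                      n_subjects = integer(0)))
  df <- do.call(rbind, rows)
  # trial average within subject, then mean across subjects with normal CI
  out <- list()
  for (key in unique(paste(df$group, df$location, sep = "\r"))) {
    sub <- df[paste(df$group, df$location, sep = "\r") == key, , drop = FALSE]
    per_subj <- tapply(sub$score, sub$subject, mean)
    m <- mean(per_subj)
    se <- if (length(per_subj) > 1) sd(per_subj) / sqrt(length(per_subj)) else 0
    out[[length(out) + 1L]] <- data.frame(
      group = sub$group[1L], location = sub$location[1L],
      kind = sub$kind[1L], mean = m,
      ci_lo = m - qnorm(0.975) * se, ci_hi = m + qnorm(0.975) * se,
      n_subjects = length(per_subj), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
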