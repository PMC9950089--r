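#' Activity label intervals
#'
#' Labels are half-open intervals `[start, end)` in seconds, on the same
#' time axis as the recording they annotate.  A one-second analysis window
#' carries a label when its midpoint falls inside the interval.
#'
#' @param start,end numeric vectors, interval bounds in seconds.
#' @param activity character vector of raw activity names.
#' @return object of class `activity_labels`: a data.frame with columns
#'   `start`, `end`, `activity`.
#' @export
activity_labels <- function(start, end, activity) {
  if (any(end <= start)) stop("every interval must satisfy start < end")
  df <- data.frame(start = as.numeric(start), end = as.numeric(end),
                   activity = as.character(activity),
                   stringsAsFactors = FALSE)
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("activity_labels", "data.frame")
  df
}

#' Read an activity label CSV
#'
#' Expects columns `start`, `end`, `activity` (seconds on the recording's
#' time axis).
#'
#' @param path CSV file path.
#' @return an [activity_labels()] object.
#' @export
read_labels <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("start", "end", "activity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  activity_labels(df$start, df$end, df$activity)
}

#' Default label-grouping map
#'
#' Maps raw activity names to canonical groups: variants of flat walking to
#' `"walking"`, jogging to `"running"`, jumping variants to `"jumping"`.
#' Names absent from the map are their own group.
#'
#' @return named character vector (raw name -> group).
#' @export
default_grouping <- function() {
  c("normal walking" = "walking", "slow walking" = "walking",
    "fast walking" = "walking", "self-paced walking" = "walking",
    walking = "walking",
    jogging = "running", running = "running",
    "rope jumping" = "jumping", "jumping in place" = "jumping",
    "forward jumping" = "jumping", jumping = "jumping")
}

# Apply a grouping map; unmapped names pass through unchanged.
apply_grouping <- function(activity, grouping = default_grouping()) {
  out <- unname(grouping[activity])
  out[is.na(out)] <- activity[is.na(out)]
  out
}

# Label of each whole second of each session, by the window-midpoint rule.
# Returns a data.frame(session, second, time_mid, activity); activity is NA
# for unlabeled seconds.
seconds_table <- function(u, labels = NULL) {
  fs <- u$fs
  out <- lapply(seq_along(u$sessions), function(si) {
    s <- u$sessions[[si]]
    n_sec <- nrow(s$xyz) %/% fs
    if (n_sec == 0L) return(NULL)
    data.frame(session = si, second = seq_len(n_sec),
               time_mid = s$start + (seq_len(n_sec) - 1L) + 0.5)
  })
  df <- do.call(rbind, out)
  if (is.null(df))
    return(data.frame(session = integer(0), second = integer(0),
                      time_mid = numeric(0), activity = character(0)))
  df$activity <- NA_character_
  if (!is.null(labels) && nrow(labels)) {
    for (i in seq_len(nrow(labels))) {
      hit <- df$time_mid >= labels$start[i] & df$time_mid < labels$end[i]
      df$activity[hit] <- labels$activity[i]
    }
  }
  df
}

#' Restrict walking labels to seconds with recorded motion
#'
#' Within intervals whose (grouped) activity is a walking group, seconds
#' whose per-axis moving standard deviation (one-second non-overlapping
#' windows) exceeds `sd_threshold` on fewer than `min_axes` of the three
#' axes are relabeled to the reserved group `"adjusted_out"`.  This trims
#' flatlined stand-still padding that is sometimes labeled as part of a
#' walking trial.  Non-walking labels are untouched, and no label is ever
#' converted *to* walking.
#'
#' @param u a `uniform_recording` in g.
#' @param labels an [activity_labels()] object.
#' @param grouping raw-name -> group map; see [default_grouping()].
#' @param walking_groups groups treated as walking; default `"walking"`.
#' @param sd_threshold per-axis SD threshold in g; default 0.1.
#' @param min_axes minimum number of axes that must exceed the threshold;
#'   default 2.
#' @return an [activity_labels()] object with walking intervals carved at
#'   one-second resolution.
#' @export
adjust_walking_labels <- function(u, labels, grouping = default_grouping(),
                                  walking_groups = "walking",
                                  sd_threshold = 0.1, min_axes = 2L) {
  stopifnot(inherits(u, "uniform_recording"))
  grp <- apply_grouping(labels$activity, grouping)
  is_walk_iv <- grp %in% walking_groups
  keep <- labels[!is_walk_iv, , drop = FALSE]
  walk_iv <- labels[is_walk_iv, , drop = FALSE]
  if (nrow(walk_iv) == 0L) return(labels)

  sec <- seconds_table(u, walk_iv)
  moving <- rep(NA, nrow(sec))
  for (si in unique(sec$session)) {
    sds <- second_axis_sd(u$sessions[[si]]$xyz, u$fs)
    rows <- sec$session == si
    moving[rows] <- rowSums(sds[sec$second[rows], , drop = FALSE] >
                              sd_threshold) >= min_axes
  }
  lab_sec <- sec[!is.na(sec$activity), , drop = FALSE]
  mov_sec <- moving[!is.na(sec$activity)]
  pieces <- list(keep)
  for (si in unique(lab_sec$session)) {
    rows <- which(lab_sec$session == si)
    if (!length(rows)) next
    t0 <- lab_sec$time_mid[rows] - 0.5
    # merge consecutive seconds with identical (activity, moving) status
    act <- ifelse(mov_sec[rows], lab_sec$activity[rows], "adjusted_out")
    brk <- c(TRUE, act[-1L] != act[-length(act)] |
               diff(t0) > 1 + 1e-9)
    grp_id <- cumsum(brk)
    for (gi in unique(grp_id)) {
      ii <- rows[grp_id == gi]
      pieces[[length(pieces) + 1L]] <-
        data.frame(start = t0[grp_id == gi][1L],
                   end = t0[grp_id == gi][sum(grp_id == gi)] + 1,
                   activity = act[grp_id == gi][1L],
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, pieces)
  activity_labels(out$start, out$end, out$activity)
}
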