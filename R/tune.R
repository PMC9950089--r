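#' Sequential ROC tuning of all classifier thresholds
#'
#' Reproduces the tuning procedure on a labelled dataset: each tuning
#' parameter is selected by a Youden-optimal ROC cutoff on the one-vs-all
#' task (walking seconds vs. all non-walking seconds), sequentially and
#' carrying earlier choices forward:
#' \enumerate{
#'   \item `A` on the per-second peak-to-peak amplitude;
#'   \item the band `[f_min, f_max]` on whether the scalogram's dominant
#'     frequency falls inside a candidate band (amplitude-valid seconds
#'     only);
#'   \item `(alpha, beta)` jointly, over a logarithmic grid, on the two
#'     harmonic-ratio conditions;
#'   \item `T` on the length of the run of consecutive passing seconds a
#'     second belongs to.
#' }
#' For the two multi-parameter stages the ROC is the cloud of candidate
#' operating points; its AUC is the trapezoidal area under the
#' best-sensitivity-so-far envelope.  Ties in the Youden index resolve to
#' the smallest candidate in grid order.
#'
#' @param sessions list of labelled sessions: `sim_session` objects (see
#'   [make_benchmark()]) or lists with elements `recording`
#'   (`uniform_recording`), `labels` ([activity_labels()]) and optionally
#'   `subject`.
#' @param device preset family tag recorded on the result.
#' @param grids candidate grids; see [default_tuning_grids()].
#' @param grouping,walking_groups label grouping; see [default_grouping()].
#' @param freq_grid,gamma,P2,pad_seconds wavelet settings as in
#'   [classify()].
#' @return a [walk_params()] whose `"aucs"` attribute holds the per-stage
#'   AUCs (`A`, `f_w`, `alpha_beta`, `T`).
#' @export
tune_pipeline <- function(sessions,
                          device = c("smartphone", "smartwatch"),
                          grids = default_tuning_grids(),
                          grouping = default_grouping(),
                          walking_groups = "walking",
                          freq_grid = default_freq_grid(),
                          gamma = 3, P2 = 60, pad_seconds = 5) {
  device <- match.arg(device)
  feats <- tuning_features(sessions, grouping, walking_groups,
                           freq_grid, gamma, P2, pad_seconds)
  truth <- feats$truth
  scored <- !is.na(truth)
  if (!any(truth[scored]) || all(truth[scored]))
    stop("degenerate input at stage A: both classes required")

  ## stage 1: amplitude threshold on per-second peak-to-peak
  roc_A <- roc_tune(feats$p2p[scored], truth[scored], grids$A, "ge")
  A_hat <- roc_A$optimal
  valid <- feats$p2p >= A_hat

  ## stage 2: walking band on dominant-frequency membership
  cand_fw <- expand.grid(f_min = grids$f_min, f_max = grids$f_max)
  n_pos <- sum(truth[scored]); n_neg <- sum(!truth[scored])
  sens <- spec <- numeric(nrow(cand_fw))
  for (i in seq_len(nrow(cand_fw))) {
    pred <- valid & !is.na(feats$dominant) &
      feats$dominant >= cand_fw$f_min[i] - 1e-9 &
      feats$dominant <= cand_fw$f_max[i] + 1e-9
    sens[i] <- sum(pred[scored] & truth[scored]) / n_pos
    spec[i] <- sum(!pred[scored] & !truth[scored]) / n_neg
  }
  if (all(sens + spec - 1 <= -1 + 1e-12))
    stop("degenerate input at stage f_w")
  i_fw <- which.max(sens + spec)
  f_min_hat <- cand_fw$f_min[i_fw]; f_max_hat <- cand_fw$f_max[i_fw]
  auc_fw <- roc_auc(1 - spec, sens)

  ## stage 3: (alpha, beta) jointly on the harmonic-ratio conditions
  bm <- band_masks(freq_grid, f_min_hat, f_max_hat)
  m_in <- col_band_max(feats$coef, bm$inb)
  m_lo <- col_band_max(feats$coef, bm$low)
  m_hi <- col_band_max(feats$coef, bm$high)
  st <- stage_alpha_beta(m_in, m_lo, m_hi, truth, valid,
                         grids$alpha, grids$beta)
  alpha_hat <- st$alpha; beta_hat <- st$beta; auc_ab <- st$auc

  ## stage 4: minimum duration on run lengths of passing seconds
  w <- valid & !is.na(m_in) & alpha_hat * m_in > m_lo & beta_hat * m_in > m_hi
  run_len <- numeric(length(w))
  for (sid in unique(feats$session_uid)) {
    idx <- which(feats$session_uid == sid)
    r <- rle(w[idx])
    run_len[idx] <- rep(ifelse(r$values, r$lengths, 0), r$lengths)
  }
  roc_T <- roc_tune(run_len[scored], truth[scored], grids$T, "ge")

  params <- walk_params(A = A_hat, f_min = f_min_hat, f_max = f_max_hat,
                        alpha = alpha_hat, beta = beta_hat,
                        T_min = roc_T$optimal, preset = device)
  attr(params, "aucs") <- list(A = roc_A$auc, f_w = auc_fw,
                               alpha_beta = auc_ab, T = roc_T$auc)
  params
}

#' Default candidate grids for [tune_pipeline()]
#'
#' `A` from 0.05 to 1 g in 0.05 g steps; `f_min` 1.0--1.6 Hz and `f_max`
#' 2.0--3.0 Hz in 0.1 Hz steps; `alpha` and `beta` on a 25-point
#' logarithmic grid from 0.1 to 100; `T` from 1 to 10 s.  The grids span
#' all published presets.
#'
#' @return named list of numeric grids.
#' @export
default_tuning_grids <- function() {
  list(A = seq(0.05, 1, by = 0.05),
       f_min = seq(1.0, 1.6, by = 0.1),
       f_max = seq(2.0, 3.0, by = 0.1),
       alpha = 10^seq(-1, 2, length.out = 25),
       beta = 10^seq(-1, 2, length.out = 25),
       T = 1:10)
}

#' Joint Youden selection of the harmonic ratios
#'
#' Grid search over `(alpha, beta)` candidates for the two strict
#' harmonic-ratio conditions of the walking test, given per-second band
#' maxima and truth labels.  A second predicts walking when it is
#' amplitude-valid and `alpha * m_in > m_lo` and `beta * m_in > m_hi`.
#' The Youden-maximal candidate is returned (ties to the smallest `alpha`,
#' then smallest `beta`) together with the trapezoidal AUC of the
#' candidate operating points.
#'
#' @param m_in,m_lo,m_hi per-second maxima of the scalogram inside, below
#'   and above the walking band.
#' @param truth logical walking labels (`NA` seconds are not scored).
#' @param valid logical amplitude-screen mask.
#' @param alpha_grid,beta_grid candidate grids.
#' @return list with `alpha`, `beta`, `auc`, and the candidate `curve`.
#' @export
stage_alpha_beta <- function(m_in, m_lo, m_hi, truth, valid,
                             alpha_grid, beta_grid) {
  scored <- !is.na(truth)
  n_pos <- sum(truth[scored]); n_neg <- sum(!truth[scored])
  if (n_pos == 0L || n_neg == 0L)
    stop("degenerate input at stage alpha-beta")
  cand <- expand.grid(alpha = alpha_grid, beta = beta_grid)
  sens <- spec <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    pred <- valid & !is.na(m_in) &
      cand$alpha[i] * m_in > m_lo & cand$beta[i] * m_in > m_hi
    sens[i] <- sum(pred[scored] & truth[scored]) / n_pos
    spec[i] <- sum(!pred[scored] & !truth[scored]) / n_neg
  }
  ord <- order(cand$alpha, cand$beta)
  i_best <- ord[which.max((sens + spec)[ord])]
  list(alpha = cand$alpha[i_best], beta = cand$beta[i_best],
       auc = roc_auc(1 - spec, sens),
       curve = cbind(cand, sensitivity = sens, specificity = spec))
}

# Max over a frequency subset for every column of the stacked coefficient
# matrix; NA columns (seconds with no scalogram) propagate NA.
col_band_max <- function(coef, mask) {
  if (!any(mask)) return(rep(0, ncol(coef)))
  apply(coef[mask, , drop = FALSE], 2L, max)
}

# Per-second features pooled over all sessions.  The scalogram here is
# computed over each full contiguous session (not only amplitude-valid
# segments) so that every tuning stage sees every labelled second.
tuning_features <- function(sessions, grouping, walking_groups,
                            freq_grid, gamma, P2, pad_seconds) {
  p2p <- numeric(0); truth <- logical(0); uid <- character(0)
  coef <- NULL; dominant <- numeric(0)
  bank_cache <- new.env(parent = emptyenv())
  for (k in seq_along(sessions)) {
    ses <- sessions[[k]]
    rec <- ses$recording
    labels <- adjust_walking_labels(rec, ses$labels, grouping,
                                    walking_groups)
    sec <- seconds_table(rec, labels)
    m <- vector_magnitude(rec)
    for (si in seq_along(m$sessions)) {
      s <- m$sessions[[si]]
      if (s$n_sec == 0L) next
      rows <- sec$session == si
      grp <- apply_grouping(sec$activity[rows], grouping)
      tr <- rep(NA, s$n_sec)
      tr[!is.na(grp) & grp %in% walking_groups] <- TRUE
      tr[!is.na(grp) & !(grp %in% c(walking_groups, "adjusted_out"))] <- FALSE
      n_samp <- s$n_sec * m$fs
      key <- as.character(n_samp)
      if (is.null(bank_cache[[key]]))
        bank_cache[[key]] <- build_morse_bank(
          gamma = gamma, P2 = P2, freq_grid = freq_grid,
          segment_length = n_samp, sample_rate = m$fs,
          pad_seconds = pad_seconds)
      sg <- cwt_segment(s$v[seq_len(n_samp)], bank_cache[[key]])
      p2p <- c(p2p, second_p2p(s$v, m$fs))
      truth <- c(truth, tr)
      uid <- c(uid, rep(sprintf("%d.%d", k, si), s$n_sec))
      dominant <- c(dominant, freq_grid[apply(sg$coef, 2L, which.max)])
      coef <- if (is.null(coef)) sg$coef else cbind(coef, sg$coef)
    }
  }
  list(p2p = p2p, truth = truth, session_uid = uid, coef = coef,
       dominant = dominant)
}
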