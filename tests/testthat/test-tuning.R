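test_that("roc_tune computes the curve, AUC and Youden optimum", {
  # perfectly separated scores
  scores <- c(rnorm(50, 10, 0.1), rnorm(50, 0, 0.1))
  truth <- rep(c(TRUE, FALSE), each = 50)
  roc <- roc_tune(scores, truth, grid = seq(-2, 12, by = 0.5))
  expect_equal(roc$auc, 1.0)
  expect_gt(roc$optimal, max(scores[!truth]))
  expect_lte(roc$optimal, min(scores[truth]))

  # hand contingency: TP=9 FN=1 TN=8 FP=2 at threshold 5
  sc <- c(rep(6, 9), 4, rep(3, 8), 7, 7)
  tr <- c(rep(TRUE, 10), rep(FALSE, 10))
  roc2 <- roc_tune(sc, tr, grid = c(5))
  expect_equal(roc2$curve$sensitivity, 0.9)
  expect_equal(roc2$curve$specificity, 0.8)
  expect_equal(roc2$curve$youden, 0.7)

  expect_error(roc_tune(1:5, rep(TRUE, 5), 1:3), "degenerate")
})

test_that("AUC is about one half under the permutation null", {
  set.seed(7)
  scores <- rnorm(2000)
  truth <- sample(rep(c(TRUE, FALSE), 1000))
  roc <- roc_tune(scores, truth, grid = quantile(scores, seq(0, 1, 0.01)))
  expect_equal(roc$auc, 0.5, tolerance = 0.06)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(13)
  scores <- rnorm(300, mean = rep(c(1, 0), 150))
  truth <- rep(c(TRUE, FALSE), 150)
  grid <- sort(scores)
  a1 <- roc_tune(scores, truth, grid)$auc
  a2 <- roc_tune(exp(scores), truth, exp(grid))$auc
  a3 <- roc_tune(scores^3, truth, grid^3)$auc
  expect_equal(a1, a2, tolerance = 1e-12)
  expect_equal(a1, a3, tolerance = 1e-12)
})

make_eval_trial <- function(pred, label, subject, duration = length(pred)) {
  sec <- data.frame(session = 1L, second = seq_along(pred),
                    time_start = seq_along(pred) - 1,
                    p2p = 1, valid = TRUE, w = as.integer(pred),
                    walking = pred, cadence = ifelse(pred, 1.8, NA))
  res <- structure(list(seconds = sec, bouts = data.frame(),
                        summary = list(), params = preset_params(),
                        id = "t", location = "waist"),
                   class = "walk_result")
  list(result = res,
       labels = activity_labels(0, duration, label),
       subject = subject, location = "waist")
}

test_that("evaluation averages trials within subject before subjects", {
  # perfect classifier: sensitivity and specificity 1 with collapsed CIs
  perfect <- list(make_eval_trial(rep(TRUE, 20), "walking", "s1"),
                  make_eval_trial(rep(FALSE, 20), "rest", "s1"))
  ev <- evaluate_walking(perfect)
  expect_equal(ev$mean, c(1, 1))
  expect_equal(ev$ci_lo, ev$ci_hi)

  # 18 of 20 walking seconds detected -> sensitivity 0.9
  part <- list(make_eval_trial(c(rep(TRUE, 18), FALSE, FALSE),
                               "walking", "s1"))
  expect_equal(evaluate_walking(part)$mean, 0.9)

  # trials of 0.8 and 1.0 average to 0.9 within the subject
  two <- list(make_eval_trial(c(rep(TRUE, 16), rep(FALSE, 4)), "walking", "s1"),
              make_eval_trial(rep(TRUE, 20), "walking", "s1"))
  expect_equal(evaluate_walking(two)$mean, 0.9)

  # complement symmetry: flipping predictions swaps the error rates
  flip <- list(make_eval_trial(c(rep(FALSE, 18), TRUE, TRUE), "walking", "s1"))
  expect_equal(evaluate_walking(flip)$mean, 1 - 0.9, tolerance = 1e-12)
})

test_that("sequential tuning recovers the generator thresholds", {
  bench <- make_benchmark(n_subjects = 8, seed = 11, duration = 40)
  p <- tune_pipeline(bench, "smartphone")
  expect_gte(p$A, 0.2); expect_lte(p$A, 0.4)
  expect_lte(p$f_min, 1.5); expect_gte(p$f_max, 2.2)
  aucs <- attr(p, "aucs")
  expect_true(all(unlist(aucs) >= 0.5))
  expect_named(aucs, c("A", "f_w", "alpha_beta", "T"))
})

test_that("the joint alpha-beta stage equals brute-force grid search", {
  # 200-second toy set: fabricate per-second band maxima and labels, then
  # compare the vectorized stage against an explicit double loop
  set.seed(29)
  n <- 200
  truth <- rep(c(TRUE, FALSE), each = n / 2)
  m_in <- ifelse(truth, runif(n, 0.5, 1), runif(n, 0.05, 0.6))
  m_lo <- ifelse(truth, runif(n, 0, 0.4), runif(n, 0.2, 1.5))
  m_hi <- ifelse(truth, runif(n, 0, 0.3), runif(n, 0.3, 2))
  grids <- default_tuning_grids()
  # brute-force oracle: explicit double loop, ties to smallest (alpha, beta)
  best <- c(NA, NA); best_y <- -Inf
  for (a in grids$alpha) for (b in grids$beta) {
    pred <- a * m_in > m_lo & b * m_in > m_hi
    y <- mean(pred[truth]) + mean(!pred[!truth]) - 1
    if (y > best_y + 1e-12) { best_y <- y; best <- c(a, b) }
  }
  st <- stage_alpha_beta(m_in, m_lo, m_hi, truth, valid = rep(TRUE, n),
                         grids$alpha, grids$beta)
  expect_equal(c(st$alpha, st$beta), best, tolerance = 1e-12)
  y_st <- with(st, curve$sensitivity + curve$specificity - 1)
  expect_equal(max(y_st), best_y, tolerance = 1e-12)
})

test_that("a tuned classifier generalizes to held-out simulated subjects", {
  p <- tune_pipeline(make_benchmark(n_subjects = 8, seed = 11,
                                    duration = 40), "smartphone")
  hold <- make_benchmark(n_subjects = 4, seed = 97, duration = 40)
  trials <- lapply(hold, function(s)
    list(result = classify(s$recording, p),
         labels = adjust_walking_labels(s$recording, s$labels),
         subject = s$subject, location = s$recording$location))
  ev <- evaluate_walking(trials)
  sens <- ev$mean[ev$group == "walking"]
  expect_true(all(sens >= 0.9))
  expect_true(all(ev$mean[ev$group == "rest"] >= 0.99))
})
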