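feature_frames <- function(n_subj = 8, segs = 2, seed = 1) {
  set.seed(seed)
  keys <- expand.grid(segment = seq_len(segs),
                      subject = sprintf("S%02d", seq_len(n_subj)))[, 2:1]
  label <- as.integer(as.integer(sub("S", "", keys$subject)) > n_subj / 2)
  n <- nrow(keys)
  acoustic <- data.frame(keys, label = label,
                         pivd = stats::rnorm(n, 1 + label), afvc = stats::rnorm(n),
                         pitch_mean = stats::rnorm(n, 150), pitch_sd = stats::rnorm(n, 20),
                         int_mean = stats::runif(n), int_min = stats::runif(n),
                         int_max = stats::runif(n), int_sd = stats::runif(n))
  head <- data.frame(keys, label = label,
                     rhr = stats::rnorm(n, 1 + label), uhd = stats::rnorm(n, 5))
  rrf <- data.frame(keys, label = label,
                    rrf1 = stats::rnorm(n), rrf2 = stats::rnorm(n),
                    rrf3 = stats::rnorm(n), rrf4 = stats::rnorm(n))
  list(acoustic = acoustic, head = head, rrf = rrf)
}

test_that("assemble_features joins on keys and selects 2/6/8 columns", {
  fr <- feature_frames()
  sp <- assemble_features(fr$acoustic, fr$head, fr$rrf, "speech")
  vd <- assemble_features(fr$acoustic, fr$head, fr$rrf, "video")
  fu <- assemble_features(fr$acoustic, fr$head, fr$rrf, "fused")
  feat_cols <- function(d) setdiff(names(d), c("subject", "segment", "label"))
  expect_equal(feat_cols(sp), c("pivd", "afvc"))
  expect_length(feat_cols(vd), 6)
  expect_length(feat_cols(fu), 8)
  expect_equal(nrow(fu), nrow(fr$acoustic))

  # disjoint keys abort with the offending keys named
  bad <- fr$head
  bad$subject <- paste0("X", bad$subject)
  expect_error(assemble_features(fr$acoustic, bad), "missing")
})

test_that("compute_metrics reproduces hand-computed confusion values", {
  perfect <- compute_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(unname(perfect), c(100, 100, 100, 100))
  m <- compute_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0), c(0.9, 0.4, 0.5, 0.1))
  expect_equal(unname(m[c("accuracy", "sensitivity", "specificity")]),
               c(75, 50, 100))
  expect_error(compute_metrics(c(1, 1), c(1, 0), c(0.5, 0.4)), "single-class")
})

test_that("metric identity: accuracy recombines from sensitivity and specificity", {
  set.seed(21)
  for (i in 1:20) {
    n <- 40
    y <- sample(0:1, n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(y)) < 2) next
    p <- sample(0:1, n, replace = TRUE)
    s <- stats::runif(n)
    m <- compute_metrics(y, p, s)
    P <- sum(y == 1); N <- sum(y == 0)
    expect_equal(m[["accuracy"]],
                 (m[["sensitivity"]] * P + m[["specificity"]] * N) / (P + N))
  }
})

test_that("rank AUC agrees with pROC and is ~50% under label-independent scores", {
  skip_if_not_installed("pROC")
  set.seed(33)
  for (i in 1:10) {
    y <- sample(0:1, 50, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- stats::rnorm(50)
    expect_equal(rank_auc(y, s),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-10)
  }
  set.seed(2000)
  y <- sample(0:1, 2000, replace = TRUE)
  s <- stats::rnorm(2000)
  expect_lt(abs(100 * rank_auc(y, s) - 50), 3)
})

test_that("a label-equal feature scores perfectly under both classifiers", {
  fr <- feature_frames(n_subj = 10, segs = 2, seed = 5)
  tab <- assemble_features(fr$acoustic, fr$head, fr$rrf, c("pivd", "afvc"))
  tab$pivd <- as.numeric(tab$label)          # leak by construction
  rep <- cross_validate(tab, c("svm", "rf"), cv_config(folds = 5, repeats = 1,
                                                       seed = 2))
  expect_true(all(rep$summary$accuracy == 100))
})

test_that("cross_validate averages folds x repeats and respects subject grouping", {
  fr <- feature_frames(n_subj = 10, segs = 2, seed = 6)
  tab <- assemble_features(fr$acoustic, fr$head, NULL, c("pivd", "rhr"))
  cfg <- cv_config(folds = 5, repeats = 3, seed = 4)
  rep <- cross_validate(tab, "svm", cfg)
  expect_equal(nrow(rep$folds), 5 * 3)
  expect_equal(nrow(rep$per_repeat), 3)
  expect_equal(rep$summary$accuracy, mean(rep$per_repeat$accuracy))
  # class with fewer subjects than folds errors
  expect_error(cross_validate(tab, "svm", cv_config(folds = 11, repeats = 1)),
               "fewer")
})

test_that("duplicating every row leaves fold-mean accuracy roughly unchanged", {
  fr <- feature_frames(n_subj = 12, segs = 2, seed = 7)
  tab <- assemble_features(fr$acoustic, fr$head, NULL, c("pivd", "rhr"))
  cfg <- cv_config(folds = 4, repeats = 3, seed = 8)
  base <- cross_validate(tab, "svm", cfg)$summary$accuracy
  dup <- tab[rep(seq_len(nrow(tab)), each = 2), ]
  dup$segment <- paste0(dup$segment, c("a", "b"))
  doubled <- cross_validate(dup, "svm", cfg)$summary$accuracy
  expect_lt(abs(base - doubled), 2)
})

test_that("a pure-noise canary feature does not lift AUC materially", {
  fr <- feature_frames(n_subj = 10, segs = 2, seed = 9)
  tab <- assemble_features(fr$acoustic, fr$head, NULL, c("pivd", "rhr"))
  cfg <- cv_config(folds = 5, repeats = 5, seed = 10)
  base <- cross_validate(tab, "svm", cfg)$summary$auc
  set.seed(99)
  tab$canary <- stats::rnorm(nrow(tab))
  with_canary <- cross_validate(tab, "svm", cfg)$summary$auc
  expect_lt(with_canary - base, 3)
})
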