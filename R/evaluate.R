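SPEECH_FEATURES <- c("pivd", "afvc")
HEAD_FEATURES <- c("rhr", "uhd")
RRF_FEATURES <- paste0("rrf", 1:4)
VIDEO_FEATURES <- c(HEAD_FEATURES, RRF_FEATURES)

#' Resolve a feature selection to column names
#'
#' \code{"speech"} = PIVD + AFVC (2 columns), \code{"video"} = RHR + UHD +
#' RRF1-4 (6), \code{"fused"} = both (8); any character vector of feature
#' names is passed through.
#'
#' @param selection One of \code{"speech"}, \code{"video"}, \code{"fused"},
#'   or a character vector of feature names.
#' @return Character vector of feature column names.
#' @export
feature_selection <- function(selection) {
  if (length(selection) == 1L && selection %in% c("speech", "video", "fused"))
    switch(selection,
           speech = SPEECH_FEATURES,
           video = VIDEO_FEATURES,
           fused = c(SPEECH_FEATURES, VIDEO_FEATURES))
  else as.character(selection)
}

#' Assemble the per-segment feature table
#'
#' Inner join of the acoustic, head-movement and (optionally) RRF feature
#' frames on the (subject, segment) key, keeping the group label, then
#' restricted to the selected features.
#'
#' @param acoustic Data frame with columns \code{subject}, \code{segment},
#'   \code{label} and acoustic features.
#' @param head Data frame keyed the same way with head features.
#' @param rrf Optional data frame with RRF features.
#' @param selection Feature selection (see \code{\link{feature_selection}});
#'   default \code{"fused"}.
#' @return Data frame with key columns, \code{label}, and the selected
#'   feature columns.
#' @export
assemble_features <- function(acoustic, head, rrf = NULL, selection = "fused") {
  key <- function(d) paste(d$subject, d$segment, sep = "\r")
  frames <- Filter(Negate(is.null), list(acoustic = acoustic, head = head, rrf = rrf))
  keys <- lapply(frames, key)
  common <- Reduce(intersect, keys)
  missing <- unique(unlist(lapply(keys, function(k) setdiff(k, common))))
  if (length(missing))
    stop("assemble_features: keys missing from some source: ",
         paste(gsub("\r", "/", missing), collapse = ", "))
  if (length(common) == 0L) stop("assemble_features: no common keys")
  merged <- frames[[1L]][match(common, keys[[1L]]), , drop = FALSE]
  for (i in seq_along(frames)[-1L]) {
    extra <- frames[[i]][match(common, keys[[i]]), , drop = FALSE]
    add <- setdiff(names(extra), names(merged))
    merged <- cbind(merged, extra[, add, drop = FALSE])
  }
  cols <- feature_selection(selection)
  absent <- setdiff(cols, names(merged))
  if (length(absent))
    stop("assemble_features: selected features not present: ",
         paste(absent, collapse = ", "))
  out <- merged[, c("subject", "segment", "label", cols), drop = FALSE]
  if (anyNA(out$label)) stop("assemble_features: missing labels")
  if (any(!is.finite(as.matrix(out[cols]))))
    stop("assemble_features: non-finite feature values")
  rownames(out) <- NULL
  out
}

#' Rank-based AUC of continuous scores
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic with
#' mid-ranks, which equals the trapezoidal ROC area with tied thresholds
#' averaged.
#'
#' @param labels Binary truth (1 = positive/patient).
#' @param scores Continuous scores, larger = more positive.
#' @return AUC in [0, 1].
#' @export
rank_auc <- function(labels, scores) {
  y <- as.integer(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("rank_auc: need both classes")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binary classification metrics
#'
#' Accuracy, specificity (true-negative rate over controls), sensitivity
#' (true-positive rate over patients) and rank AUC, all in percent.
#' Positive class is the patient label 1.
#'
#' @param labels Binary truth vector (0 = control, 1 = patient).
#' @param predictions Binary predictions.
#' @param scores Continuous scores for AUC (larger = more patient-like).
#' @return Named numeric vector \code{c(accuracy, specificity, sensitivity,
#'   auc)} in percent.
#' @export
compute_metrics <- function(labels, predictions, scores) {
  y <- as.integer(labels); p <- as.integer(predictions)
  if (length(y) != length(p) || length(y) != length(scores))
    stop("compute_metrics: length mismatch")
  if (!all(y %in% 0:1) || !all(p %in% 0:1))
    stop("compute_metrics: labels/predictions must be 0/1")
  if (length(unique(y)) < 2L)
    stop("compute_metrics: single-class truth; AUC undefined")
  tp <- sum(y == 1L & p == 1L); fn <- sum(y == 1L & p == 0L)
  tn <- sum(y == 0L & p == 0L); fp <- sum(y == 0L & p == 1L)
  c(accuracy = 100 * (tp + tn) / length(y),
    specificity = 100 * tn / (tn + fp),
    sensitivity = 100 * tp / (tp + fn),
    auc = 100 * rank_auc(y, scores))
}

#' Cross-validation configuration
#'
#' 10-fold stratified cross-validation repeated 5 times, with the mean over
#' all repeats-by-folds evaluations as the final result. By default folds
#' split by subject so that no subject contributes segments to both a
#' training and a test fold; \code{by_subject = FALSE} is the optimistic
#' by-segment variant.
#'
#' @param folds Number of folds (default 10, >= 2).
#' @param repeats Number of repetitions (default 5, >= 1).
#' @param stratified Stratify folds by class (default TRUE).
#' @param by_subject Group folds by subject (default TRUE).
#' @param seed Integer seed (default 1).
#' @return A \code{cv_config} list.
#' @export
cv_config <- function(folds = 10, repeats = 5, stratified = TRUE,
                      by_subject = TRUE, seed = 1) {
  if (folds < 2L) stop("cv_config: folds must be >= 2")
  if (repeats < 1L) stop("cv_config: repeats must be >= 1")
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 stratified = isTRUE(stratified),
                 by_subject = isTRUE(by_subject), seed = as.integer(seed)),
            class = "cv_config")
}

# Stratified fold assignment for units (subjects or rows): returns integer
# fold id per unit.
assign_folds <- function(unit_labels, folds, stratified) {
  n <- length(unit_labels)
  fold <- integer(n)
  if (stratified) {
    for (cl in unique(unit_labels)) {
      idx <- which(unit_labels == cl)
      if (length(idx) < folds)
        stop(sprintf("cross_validate: class '%s' has %d units, fewer than %d folds",
                     cl, length(idx), folds))
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  } else {
    if (n < folds) stop("cross_validate: fewer units than folds")
    fold <- sample(rep_len(seq_len(folds), n))
  }
  fold
}

fit_and_score <- function(classifier, xtr, ytr, xte, seed) {
  set.seed(seed)
  if (classifier == "svm") {
    fit <- e1071::svm(xtr, factor(ytr, levels = c(0, 1)), kernel = "radial",
                      cost = 1, scale = FALSE)
    pr <- stats::predict(fit, xte, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    dec <- dv[, 1L]
    # orient decision values so that larger means class 1
    if (startsWith(colnames(dv)[1L], "0/")) dec <- -dec
    list(pred = as.integer(as.character(pr)), score = dec)
  } else if (classifier == "rf") {
    fit <- randomForest::randomForest(xtr, factor(ytr, levels = c(0, 1)),
                                      ntree = 500)
    list(pred = as.integer(as.character(stats::predict(fit, xte))),
         score = stats::predict(fit, xte, type = "prob")[, "1"])
  } else stop("unknown classifier: ", classifier)
}

#' Repeated stratified cross-validated evaluation
#'
#' Evaluates one or more classifiers on a feature table under the repeated
#' stratified k-fold protocol. Within every fold, feature standardization
#' uses training-fold statistics only, and when RRF inputs are supplied the
#' two classification heads are retrained on the training fold alone before
#' RRF features are extracted for both splits — no test-fold information
#' enters any training computation.
#'
#' @param table Feature table from \code{\link{assemble_features}} (columns
#'   \code{subject}, \code{segment}, \code{label}, features).
#' @param classifiers Character vector from \code{c("svm", "rf")}.
#' @param cfg A \code{cv_config}.
#' @param rrf_inputs Optional list for per-fold RRF training:
#'   \code{map_features} and \code{spec_features} (backbone feature matrices
#'   aligned with the table rows), \code{backbone}, \code{train_cfg}. When
#'   given, columns rrf1-4 of the table are recomputed per fold.
#' @return An \code{eval_report} list: \code{summary} data frame of metric
#'   means per classifier, \code{per_repeat} data frame, \code{folds} data
#'   frame of per-fold metrics.
#' @export
cross_validate <- function(table, classifiers = c("svm", "rf"),
                           cfg = cv_config(), rrf_inputs = NULL) {
  classifiers <- match.arg(classifiers, c("svm", "rf"), several.ok = TRUE)
  feat_cols <- setdiff(names(table), c("subject", "segment", "label"))
  y <- as.integer(table$label)
  if (!all(y %in% 0:1)) stop("cross_validate: labels must be 0/1")
  use_rrf <- !is.null(rrf_inputs) && any(RRF_FEATURES %in% feat_cols)
  rows <- list()
  for (rep_i in seq_len(cfg$repeats)) {
    set.seed(cfg$seed + 1000L * rep_i)
    if (cfg$by_subject) {
      subj <- unique(table$subject)
      subj_lab <- y[match(subj, table$subject)]
      sf <- assign_folds(subj_lab, cfg$folds, cfg$stratified)
      fold <- sf[match(table$subject, subj)]
    } else {
      fold <- assign_folds(y, cfg$folds, cfg$stratified)
    }
    for (k in seq_len(cfg$folds)) {
      te <- which(fold == k); tr <- which(fold != k)
      if (length(unique(y[te])) < 2L || length(unique(y[tr])) < 2L)
        stop("cross_validate: fold without both classes; increase data or reduce folds")
      x <- as.matrix(table[, feat_cols, drop = FALSE])
      if (use_rrf) {
        tc <- rrf_inputs$train_cfg
        tc$seed <- tc$seed + 17L * rep_i + k
        map_head <- train_head(NULL, y[tr], rrf_inputs$backbone, tc,
                               features = rrf_inputs$map_features[tr, , drop = FALSE])
        spec_head <- train_head(NULL, y[tr], rrf_inputs$backbone, tc,
                                features = rrf_inputs$spec_features[tr, , drop = FALSE])
        ml <- head_logits(map_head, rrf_inputs$backbone,
                          features = rrf_inputs$map_features)
        sl <- head_logits(spec_head, rrf_inputs$backbone,
                          features = rrf_inputs$spec_features)
        x[, "rrf1"] <- ml[, 1L]; x[, "rrf2"] <- ml[, 2L]
        x[, "rrf3"] <- sl[, 1L]; x[, "rrf4"] <- sl[, 2L]
      }
      mu <- colMeans(x[tr, , drop = FALSE])
      sdv <- apply(x[tr, , drop = FALSE], 2, stats::sd)
      sdv[sdv < 1e-12] <- 1
      xs <- sweep(sweep(x, 2, mu), 2, sdv, `/`)
      for (cl in classifiers) {
        res <- fit_and_score(cl, xs[tr, , drop = FALSE], y[tr],
                             xs[te, , drop = FALSE],
                             seed = cfg$seed + 7919L * rep_i + 131L * k)
        m <- compute_metrics(y[te], res$pred, res$score)
        rows[[length(rows) + 1L]] <- data.frame(classifier = cl, rep = rep_i,
                                                fold = k, t(m))
      }
    }
  }
  folds_df <- do.call(rbind, rows)
  per_repeat <- stats::aggregate(folds_df[c("accuracy", "specificity",
                                            "sensitivity", "auc")],
                                 by = folds_df[c("classifier", "rep")], mean)
  summary <- stats::aggregate(per_repeat[c("accuracy", "specificity",
                                           "sensitivity", "auc")],
                              by = per_repeat["classifier"], mean)
  structure(list(summary = summary, per_repeat = per_repeat, folds = folds_df,
                 config = cfg),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %d-fold x %d repeats>\n",
              x$config$folds, x$config$repeats))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
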