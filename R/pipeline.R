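#' Acoustic feature row for one segment
#'
#' PIVD, AFVC and the comparator pitch/intensity statistics of one audio
#' segment, using the shared column naming of the feature table.
#'
#' @param signal An \code{audio_signal}.
#' @param params Optional \code{frame_params} (default 25 ms / 10 ms at the
#'   signal's rate).
#' @param convention Intensity convention passed to
#'   \code{\link{intensity_means}}.
#' @return Named numeric vector: \code{pivd, afvc, pitch_mean, pitch_sd,
#'   int_mean, int_min, int_max, int_sd}.
#' @export
extract_audio_features <- function(signal, params = NULL,
                                   convention = "power") {
  if (is.null(params)) params <- frame_params_ms(audio_rate(signal))
  track <- intensity_means(frame_signal(signal, params), convention)
  m <- mfcc(signal, params)
  dm <- delta2_mfcc(m)
  pit <- baseline_pitch_stats(signal)
  ints <- baseline_intensity_stats(track)
  c(pivd = pivd(track), afvc = afvc(m, dm),
    pitch_mean = unname(pit["mean"]), pitch_sd = unname(pit["sd"]),
    int_mean = unname(ints["mean"]), int_min = unname(ints["min"]),
    int_max = unname(ints["max"]), int_sd = unname(ints["sd"]))
}

#' Head-movement feature row for one segment
#'
#' RHR and UHD from the landmark trajectory.
#'
#' @param lm A \code{landmark_sequence}.
#' @param meta A \code{reading_meta}.
#' @param eps Dead-band for \code{\link{binarize_rr}}.
#' @param min_run Minimum run length for \code{\link{count_rotations}}.
#' @return Named numeric vector \code{c(rhr, uhd)}.
#' @export
extract_head_features <- function(lm, meta, eps = 0.2, min_run = 3) {
  tr <- head_trajectory(lm)
  n_r <- count_rotations(binarize_rr(tr$hm_r, eps), min_run)
  c(rhr = rhr(n_r, meta), uhd = uhd(tr$hm_u, meta))
}

#' Streamed feature extraction over a synthetic cohort
#'
#' Generates each segment from the manifest, extracts the acoustic and
#' head-movement features and the two fluency images, encodes the images
#' with the frozen backbone, and discards the raw media. The backbone
#' feature matrices feed per-fold RRF head training in
#' \code{\link{cross_validate}}.
#'
#' @param spec A \code{cohort_spec}.
#' @param backbone An \code{rrf_backbone} (default \code{backbone_spec()}).
#' @param verbose Print per-segment progress (default FALSE).
#' @return List: \code{acoustic} and \code{head} feature data frames,
#'   \code{map_features} and \code{spec_features} backbone matrices (rows
#'   aligned with \code{manifest}), \code{manifest}, \code{backbone}.
#' @export
cohort_features <- function(spec, backbone = backbone_spec(), verbose = FALSE) {
  man <- cohort_manifest(spec)
  n <- nrow(man)
  ac <- vector("list", n); hd <- vector("list", n)
  mapf <- vector("list", n); spcf <- vector("list", n)
  man$total_sweeps <- NA_integer_
  for (i in seq_len(n)) {
    seg <- synth_segment(man[i, ], spec)
    man$total_sweeps[i] <- seg$truth$total_sweeps
    ac[[i]] <- extract_audio_features(seg$audio)
    hd[[i]] <- extract_head_features(seg$landmarks, seg$meta)
    ms <- mar_sequence(seg$landmarks)
    mapf[[i]] <- backbone_features(backbone, time_domain_map(ms))
    spcf[[i]] <- backbone_features(backbone, spectrogram_3d(ms))
    if (verbose && i %% 20L == 0L)
      message(sprintf("cohort_features: %d/%d segments", i, n))
  }
  keys <- man[, c("subject", "segment", "label")]
  list(acoustic = cbind(keys, as.data.frame(do.call(rbind, ac))),
       head = cbind(keys, as.data.frame(do.call(rbind, hd))),
       map_features = do.call(rbind, mapf),
       spec_features = do.call(rbind, spcf),
       manifest = man, backbone = backbone)
}

#' Global (leak-prone) RRF feature table
#'
#' Trains the two RRF heads once on the whole cohort and extracts the
#' 4-element RRF vector for every segment. This mirrors training outside the
#' cross-validation folds and is optimistic: test segments influence head
#' training. Prefer passing \code{rrf_inputs} to \code{\link{cross_validate}}
#' for per-fold training.
#'
#' @param feats Output of \code{\link{cohort_features}}.
#' @param train_cfg A \code{train_config}.
#' @return Data frame with key columns and rrf1-4.
#' @export
global_rrf_features <- function(feats, train_cfg = train_config()) {
  y <- feats$manifest$label
  mh <- train_head(NULL, y, feats$backbone, train_cfg,
                   features = feats$map_features)
  sh <- train_head(NULL, y, feats$backbone, train_cfg,
                   features = feats$spec_features)
  ml <- head_logits(mh, feats$backbone, features = feats$map_features)
  sl <- head_logits(sh, feats$backbone, features = feats$spec_features)
  out <- data.frame(subject = feats$manifest$subject,
                    segment = feats$manifest$segment,
                    label = y,
                    rrf1 = ml[, 1L], rrf2 = ml[, 2L],
                    rrf3 = sl[, 1L], rrf4 = sl[, 2L])
  out
}

#' Pipeline configuration
#'
#' One structure carrying every tunable of the pipeline; serializable to
#' YAML with a lossless round trip.
#'
#' @param cohort A \code{cohort_spec}.
#' @param frame_ms,hop_ms Acoustic framing in ms.
#' @param n_mels Number of mel filters.
#' @param dead_band Rr binarization dead-band (px/frame-step).
#' @param min_run Minimum run length for rotation counting (frames).
#' @param map_side Fluency image side (px).
#' @param seg_s,hop_s Spectrogram segment length / interval (s).
#' @param backbone_seed Seed of the frozen backbone.
#' @param train A \code{train_config}.
#' @param cv A \code{cv_config}.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(cohort = cohort_spec(), frame_ms = 25, hop_ms = 10,
                            n_mels = 12, dead_band = 0.2, min_run = 3,
                            map_side = 224, seg_s = 3, hop_s = 1,
                            backbone_seed = 2022, train = train_config(),
                            cv = cv_config()) {
  structure(list(cohort = cohort, frame_ms = frame_ms, hop_ms = hop_ms,
                 n_mels = n_mels, dead_band = dead_band, min_run = min_run,
                 map_side = map_side, seg_s = seg_s, hop_s = hop_s,
                 backbone_seed = backbone_seed, train = train, cv = cv),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A \code{pipeline_config}.
#' @param path File path.
#' @return \code{read_config} returns a \code{pipeline_config};
#'   \code{write_config} returns \code{path} invisibly.
#' @export
write_config <- function(config, path) {
  plain <- rapply(unclass(config),
                  function(x) if (is.list(x)) x else x, how = "replace")
  strip <- function(x) {
    if (is.list(x)) { x <- lapply(x, strip); attributes(x) <- list(names = names(x)) }
    x
  }
  yaml::write_yaml(strip(plain), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  co <- raw$cohort
  cfg <- pipeline_config(
    cohort = cohort_spec(co$n_per_group, co$segments_per_subject,
                         co$duration_s, co$fps, co$audio_rate, co$n_lines,
                         control = do.call(group_block, co$control),
                         patient = do.call(group_block, co$patient),
                         seed = co$seed),
    frame_ms = raw$frame_ms, hop_ms = raw$hop_ms, n_mels = raw$n_mels,
    dead_band = raw$dead_band, min_run = raw$min_run,
    map_side = raw$map_side, seg_s = raw$seg_s, hop_s = raw$hop_s,
    backbone_seed = raw$backbone_seed,
    train = do.call(train_config, raw$train),
    cv = do.call(cv_config, raw$cv))
  cfg
}

#' Run the full synthetic-cohort pipeline
#'
#' Generates the cohort, extracts all features, and evaluates the speech,
#' video and fused feature selections with both classifiers under the
#' repeated stratified cross-validation protocol (RRF heads retrained per
#' fold). Deterministic for a given configuration.
#'
#' @param config A \code{pipeline_config}.
#' @param out_dir Optional directory; when given, the feature table, the
#'   evaluation report (CSV and JSON) and the config snapshot are written
#'   there.
#' @param selections Feature selections to evaluate (default speech, video,
#'   fused).
#' @param verbose Print stage progress (default TRUE).
#' @return List: \code{results} data frame (selection x classifier x
#'   metrics), \code{reports} per-selection \code{eval_report}s,
#'   \code{features} the extracted \code{cohort_features}.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         selections = c("speech", "video", "fused"),
                         verbose = TRUE) {
  if (config$cv$folds < 2L) stop("run_pipeline: cv folds must be >= 2")
  backbone <- backbone_spec(seed = config$backbone_seed,
                            input_side = config$map_side)
  t0 <- Sys.time()
  if (verbose) message("run_pipeline: generating cohort and extracting features")
  feats <- cohort_features(config$cohort, backbone, verbose = verbose)
  if (verbose)
    message(sprintf("run_pipeline: %d segments extracted in %.1f s",
                    nrow(feats$manifest),
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  rrf_stub <- data.frame(subject = feats$manifest$subject,
                         segment = feats$manifest$segment,
                         label = feats$manifest$label,
                         rrf1 = 0, rrf2 = 0, rrf3 = 0, rrf4 = 0)
  rrf_inputs <- list(map_features = feats$map_features,
                     spec_features = feats$spec_features,
                     backbone = backbone, train_cfg = config$train)
  reports <- list(); rows <- list()
  for (sel in selections) {
    tab <- assemble_features(feats$acoustic, feats$head,
                             rrf = if (any(RRF_FEATURES %in% feature_selection(sel)))
                               rrf_stub else NULL,
                             selection = sel)
    rep <- cross_validate(tab, c("svm", "rf"), config$cv,
                          rrf_inputs = if (any(RRF_FEATURES %in% names(tab)))
                            rrf_inputs else NULL)
    reports[[sel]] <- rep
    s <- rep$summary; s$selection <- sel
    rows[[sel]] <- s
    if (verbose)
      message(sprintf("run_pipeline: %s done (mean acc %s)", sel,
                      paste(sprintf("%s %.1f%%", s$classifier, s$accuracy),
                            collapse = ", ")))
  }
  results <- do.call(rbind, rows)
  results <- results[, c("selection", "classifier", "accuracy", "specificity",
                         "sensitivity", "auc")]
  rownames(results) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    full <- assemble_features(feats$acoustic, feats$head,
                              global_rrf_features(feats, config$train),
                              "fused")
    utils::write.csv(full, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(results, file.path(out_dir, "report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(results, file.path(out_dir, "report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    write_config(config, file.path(out_dir, "config.yaml"))
  }
  list(results = results, reports = reports, features = feats)
}
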