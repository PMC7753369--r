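#' End-to-end run configuration
#'
#' Bundles everything one pipeline invocation needs: the data source (the
#' synthetic generator), the preprocessing preset, channel count, fusion
#' scheme, feature set, classifier and seeds.
#'
#' @param synth A [synth_config()]; the data source of the run.
#' @param preset Preprocessing preset name, see [preprocess_preset()].
#' @param k_channels Channels selected per modality (default 6).
#' @param scheme Fusion scheme: `"system"` or `"feature"`.
#' @param features Feature set for the fused signal: `"dwt"`, `"stats"` or
#'   `"dwt+stats"`.
#' @param classifier Classifier spec, see [cross_validate()].
#' @param folds CV folds (default 10).
#' @param msvd_levels MSVD depth for fusion (default 1).
#' @param sync_fs Common synchronization grid in Hz (default 10).
#' @param dwt_level Target DWT depth for features (default 4, capped to the
#'   admissible maximum for short fused trials).
#' @param nirs_lag_s Hemodynamic lag in seconds applied to the fNIRS epoch
#'   windows (default 3): the HbO response to a task peaks several seconds
#'   after onset, so each fNIRS trial window is `[onset + lag,
#'   onset + lag + task)`, which captures the response instead of its onset
#'   ramp.
#' @param seed Master seed for cross-validation fold shuffles.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(synth = synth_config(),
                       preset = "synthetic",
                       k_channels = 6,
                       scheme = c("system", "feature"),
                       features = c("dwt", "stats", "dwt+stats"),
                       classifier = list(model = "knn", k = 5),
                       folds = 10,
                       msvd_levels = 1,
                       sync_fs = 10,
                       dwt_level = 4,
                       nirs_lag_s = 3,
                       seed = 1) {
  scheme <- match.arg(scheme)
  features <- match.arg(features)
  stopifnot(k_channels >= 1, nirs_lag_s >= 0)
  structure(list(synth = synth, preset = preset, k_channels = k_channels,
                 scheme = scheme, features = features, classifier = classifier,
                 folds = folds, msvd_levels = msvd_levels, sync_fs = sync_fs,
                 dwt_level = dwt_level, nirs_lag_s = nirs_lag_s, seed = seed),
            class = "run_config")
}

#' Restrict an epochs object to a channel subset
#'
#' @param ep An [epochs()] object.
#' @param channels Channel names or indices.
#' @return An [epochs()] with only those channels, in the given order.
#' @export
subset_epochs <- function(ep, channels) {
  stopifnot(inherits(ep, "epochs"))
  idx <- if (is.character(channels)) match(channels, ep$channel_names)
         else as.integer(channels)
  if (anyNA(idx)) stop("unknown channel(s)")
  epochs(ep$data[, idx, , drop = FALSE], ep$labels, ep$fs,
         channel_names = ep$channel_names[idx])
}

#' Prepare synchronized, channel-selected data for a pipeline run
#'
#' Generates the synthetic session, applies the preset filters, standardizes
#' baselines, builds the common synchronization grid (the HbO signal and the
#' 1-s moving-average EEG band-power envelope, both resampled to `sync_fs`),
#' ranks channels by cross-modal correlation once per recording, and epochs
#' every stream.
#'
#' @param cfg A [run_config()].
#' @param artifact_hook Optional function `recording -> recording` applied to
#'   the filtered EEG before synchronization — the plug-in point for ocular
#'   artifact removal (e.g. a blind source separation step); no
#'   implementation is shipped.
#' @return A list with the filtered native-rate EEG epochs
#'   (`eeg_native_epochs`), the synchronized EEG-envelope and HbO epochs
#'   (`eeg_sync_epochs`, `hbo_sync_epochs`), the [rank_channels()] result
#'   (`ranking`) and the trial labels.
#' @export
prepare_run <- function(cfg, artifact_hook = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  sim <- gen_hybrid(cfg$synth)
  preset <- preprocess_preset(cfg$preset)

  eeg <- sim$eeg; eeg_ann <- sim$eeg_annotation
  if (!is.null(preset$eeg_downsample_hz)) {
    eeg <- downsample(eeg, preset$eeg_downsample_hz)
    eeg_ann <- annotation_resample(eeg_ann, preset$eeg_downsample_hz)
  }
  eeg <- baseline_standardize(butterworth_filter(eeg, preset$eeg))
  if (!is.null(artifact_hook)) eeg <- artifact_hook(eeg)

  hbo <- sim$hbo; nirs_ann <- sim$nirs_annotation
  if (!is.null(preset$nirs_downsample_hz)) {
    hbo <- downsample(hbo, preset$nirs_downsample_hz)
    nirs_ann <- annotation_resample(nirs_ann, preset$nirs_downsample_hz)
  }
  hbo <- baseline_standardize(butterworth_filter(hbo, preset$nirs))

  # common grid: EEG band-power envelope and HbO, both at sync_fs
  eeg_sq <- eeg; eeg_sq$data <- eeg$data^2
  eeg_sync <- moving_average_downsize(eeg_sq, 1, cfg$sync_fs)
  hbo_sync <- moving_average_downsize(hbo, 1, cfg$sync_fs)
  n_common <- min(n_samples(eeg_sync), n_samples(hbo_sync))
  eeg_sync$data <- eeg_sync$data[, seq_len(n_common), drop = FALSE]
  hbo_sync$data <- hbo_sync$data[, seq_len(n_common), drop = FALSE]
  eeg_sync <- baseline_standardize(eeg_sync)
  hbo_sync <- baseline_standardize(hbo_sync)

  ranking <- rank_channels(eeg_sync, hbo_sync, cfg$k_channels,
                           envelope = FALSE)  # the stream already is an envelope
  ann_sync <- annotation_resample(eeg_ann, cfg$sync_fs)
  # fNIRS windows shifted by the hemodynamic lag
  ann_nirs_lag <- ann_sync
  ann_nirs_lag$onsets <- ann_sync$onsets +
    as.integer(round(cfg$nirs_lag_s * cfg$sync_fs))

  list(
    eeg_native_epochs = epoch(eeg, eeg_ann),
    eeg_sync_epochs = epoch(eeg_sync, ann_sync),
    hbo_sync_epochs = epoch(hbo_sync, ann_nirs_lag),
    ranking = ranking,
    labels = eeg_ann$labels
  )
}

#' Unimodal EEG benchmark: one report per DWT approximation level
#'
#' For each decomposition level 1..4, per-trial features are the normalized
#' approximation coefficients of that level for every selected EEG channel
#' (native rate), classified per the configuration.
#'
#' @param cfg A [run_config()].
#' @param data Optional pre-built [prepare_run()] bundle (reused across
#'   benchmark arms so every arm sees the same data and selection).
#' @return Named list of [cross_validate()] reports, `A1`..`A4`.
#' @export
run_unimodal_eeg <- function(cfg, data = prepare_run(cfg)) {
  ep <- subset_epochs(data$eeg_native_epochs, data$ranking$selected_eeg)
  out <- list()
  for (lev in 1:4) {
    ft <- eeg_dwt_features(ep, level = lev)
    out[[paste0("A", lev)]] <-
      cross_validate(ft, cfg$classifier, cfg$folds, seed = cfg$seed + lev)
  }
  out
}

#' Unimodal fNIRS benchmark: one report per statistical feature pair
#'
#' Evaluates all 15 unordered pairs of the six statistical features computed
#' on the spatially averaged selected HbO channels (synchronized grid).
#'
#' @inheritParams run_unimodal_eeg
#' @return Named list of 15 [cross_validate()] reports (`"M+P"`, ...).
#' @export
run_unimodal_fnirs <- function(cfg, data = prepare_run(cfg)) {
  ep <- subset_epochs(data$hbo_sync_epochs, data$ranking$selected_nirs)
  pairs <- utils::combn(c("M", "P", "SK", "KR", "SD", "VAR"), 2)
  out <- list()
  for (j in seq_len(ncol(pairs))) {
    ft <- fnirs_stat_features(ep, features = pairs[, j])
    out[[paste(pairs[, j], collapse = "+")]] <-
      cross_validate(ft, cfg$classifier, cfg$folds, seed = cfg$seed + j)
  }
  out
}

# Feature extraction from fused (or unimodal) epochs per the feature-set key.
.fused_features <- function(ep, features, dwt_level) {
  dwt_ft <- function() eeg_dwt_features(ep, level = dwt_level, cap = TRUE)
  stat_ft <- function() fnirs_stat_features(ep)
  switch(features,
    "dwt" = dwt_ft(),
    "stats" = stat_ft(),
    "dwt+stats" = {
      a <- dwt_ft(); b <- stat_ft()
      if (nrow(a$X) != nrow(b$X))
        stop("trial mismatch between feature blocks (degenerate trials?)")
      feature_table(cbind(a$X, b$X), a$y,
                    feature_names = c(a$feature_names, b$feature_names))
    },
    stop("unknown feature set: ", features))
}

#' Run one hybrid fusion pipeline end to end
#'
#' Channel selection, synchronization, the chosen MSVD fusion scheme, feature
#' extraction and stratified cross-validation. For the feature scheme the two
#' per-trial 6-vectors (EEG per-channel DWT scalars, fNIRS statistics) are
#' fused; for the system scheme the synchronized 6-channel signal matrices
#' are fused and features are extracted from the fused signal.
#'
#' @inheritParams run_unimodal_eeg
#' @return A [cross_validate()] report with a `provenance` attribute
#'   (selected channels per modality, scheme, MSVD depth, feature set).
#' @export
run_hybrid <- function(cfg, data = prepare_run(cfg)) {
  sel_e <- data$ranking$selected_eeg
  sel_n <- data$ranking$selected_nirs
  if (cfg$scheme == "feature") {
    eeg_vec <- eeg_dwt_scalar_features(
      subset_epochs(data$eeg_native_epochs, sel_e), level = cfg$dwt_level)
    nirs_tab <- fnirs_stat_features(subset_epochs(data$hbo_sync_epochs, sel_n))
    if (nrow(nirs_tab$X) != nrow(eeg_vec))
      stop("stage feature_based_fusion: trial counts diverged")
    # rescale each feature column to [0, 1] before fusing so the two
    # modalities' vectors live on comparable scales; when k_channels != 6 the
    # narrower block is zero-padded to the wider one
    ea <- apply(eeg_vec, 2, minmax_normalize)
    nb <- apply(nirs_tab$X, 2, minmax_normalize)
    w <- max(ncol(ea), ncol(nb))
    pad <- function(M) cbind(M, matrix(0, nrow(M), w - ncol(M)))
    fused <- feature_based_fusion(pad(ea), pad(nb), L = cfg$msvd_levels)
    ft <- feature_table(fused, data$labels)
  } else {
    fused_ep <- system_based_fusion(
      subset_epochs(data$eeg_sync_epochs, sel_e),
      subset_epochs(data$hbo_sync_epochs, sel_n),
      L = cfg$msvd_levels)
    ft <- .fused_features(fused_ep, cfg$features, cfg$dwt_level)
  }
  rep <- cross_validate(ft, cfg$classifier, cfg$folds, seed = cfg$seed)
  attr(rep, "provenance") <- list(
    scheme = cfg$scheme, features = cfg$features, msvd_levels = cfg$msvd_levels,
    selected_eeg = sel_e, selected_nirs = sel_n,
    sync_fs = cfg$sync_fs
  )
  rep
}

#' Benchmark grid: pipelines x classifiers
#'
#' Runs unimodal EEG (level-4 approximation features), unimodal fNIRS (six
#' statistical features), feature-based fusion and system-based fusion, each
#' with the KNN and tree classifiers on the same generated data and channel
#' selection, and tabulates mean accuracy/specificity/AUC.
#'
#' @param cfg A [run_config()].
#' @return A data frame with 8 rows and columns `pipeline`, `classifier`,
#'   `accuracy`, `specificity`, `auc`.
#' @export
benchmark <- function(cfg) {
  data <- prepare_run(cfg)
  classifiers <- list(knn = list(model = "knn", k = cfg$classifier$k %||% 5),
                      tree = list(model = "tree"))
  sel_e <- data$ranking$selected_eeg
  sel_n <- data$ranking$selected_nirs
  rows <- list()
  for (cl_name in names(classifiers)) {
    cfg_cl <- cfg; cfg_cl$classifier <- classifiers[[cl_name]]
    ft_eeg <- eeg_dwt_features(subset_epochs(data$eeg_native_epochs, sel_e),
                               level = cfg$dwt_level, cap = TRUE)
    ft_nirs <- fnirs_stat_features(subset_epochs(data$hbo_sync_epochs, sel_n))
    arms <- list(
      eeg = cross_validate(ft_eeg, cfg_cl$classifier, cfg$folds, cfg$seed),
      fnirs = cross_validate(ft_nirs, cfg_cl$classifier, cfg$folds, cfg$seed),
      feature_fusion = run_hybrid(`class<-`(utils::modifyList(
        unclass(cfg_cl), list(scheme = "feature")), "run_config"), data),
      system_fusion = run_hybrid(`class<-`(utils::modifyList(
        unclass(cfg_cl), list(scheme = "system")), "run_config"), data)
    )
    for (arm in names(arms)) {
      r <- arms[[arm]]
      rows[[length(rows) + 1]] <- data.frame(
        pipeline = arm, classifier = cl_name,
        accuracy = r$accuracy, specificity = r$specificity, auc = r$auc)
    }
  }
  do.call(rbind, rows)
}
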