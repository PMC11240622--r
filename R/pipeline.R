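# End-to-end orchestration: simulate -> preprocess -> features -> select ->
# balance -> train -> evaluate, with one seed driving every stage through
# fixed derived sub-seeds, and a JSON-serializable run report.

#' Pipeline run configuration
#'
#' Nested stage configurations plus a global seed. Every stage seed is
#' derived deterministically from the global seed, so a run is reproducible
#' end to end from this one object.
#'
#' @param synth List of [synth_config] arguments for the simulated record
#'   (defaults: 360 Hz, 70 bpm, 20 percent anomalous beats, 400 beats' worth
#'   of duration).
#' @param detector List of [detector_config] arguments.
#' @param features List of [feature_config] arguments.
#' @param select List: `enabled` (default TRUE), `foxes`, `iterations`,
#'   `lambda`, `binarize_threshold`, `reinit_fraction`.
#' @param balance List: `enabled` (default TRUE), `weights_on` — `"resampled"`
#'   (inverse counts after oversampling, the literal order; weights then
#'   uniform) or `"raw"` (inverse raw counts).
#' @param model List of [model_config] arguments (all but `input_length`,
#'   `n_classes`, `seed`).
#' @param split Train/validation/test fractions, summing to 1.
#' @param seed Global integer seed.
#' @param out_dir Optional directory for stage artifacts (CSV/JSON).
#' @return A list of class `run_config`.
#' @export
run_config <- function(synth = list(), detector = list(), features = list(),
                       select = list(), balance = list(), model = list(),
                       split = c(train = 0.8, val = 0.1, test = 0.1),
                       seed = 7L, out_dir = NULL) {
  if (abs(sum(split) - 1) > 1e-9) stop("split fractions must sum to 1")
  synth <- utils::modifyList(list(fs = 360, heart_rate = 70,
                                  duration = ceiling(400 * 60 / 70) + 2,
                                  anomaly_fraction = 0.2,
                                  noise_spec = list(muscle = list(sd = 0.02))),
                             synth)
  select <- utils::modifyList(list(enabled = TRUE, foxes = 20, iterations = 40,
                                   lambda = 0.01, binarize_threshold = 0.5,
                                   reinit_fraction = 0.1), select)
  balance <- utils::modifyList(list(enabled = TRUE, weights_on = "resampled"),
                               balance)
  structure(list(synth = synth, detector = detector, features = features,
                 select = select, balance = balance, model = model,
                 split = split, seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

# stratified train/val/test assignment by beat label
split_indices <- function(labels, split, seed) {
  grp <- character(length(labels))
  with_seed(seed, for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    n <- length(idx)
    n_tr <- round(split[1] * n)
    n_va <- round(split[2] * n)
    grp[idx[seq_len(n_tr)]] <- "train"
    grp[idx[n_tr + seq_len(min(n_va, n - n_tr))]] <- "val"
    grp[idx[grp[idx] == ""]] <- "test"
  })
  grp
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order: simulate a synthetic record (or use
#' `record`), detect R-peaks and segment 600 ms beats, extract the
#' multi-transform feature matrix (z-scoring fitted on the training fold
#' only), red-fox feature selection on the training fold, random
#' oversampling of the training fold, i-AlexNet training with inverse-count
#' class weights, and test-fold evaluation. Fixed seed, fixed report.
#'
#' @param cfg A [run_config].
#' @param record Optional [ecg_record] to use instead of simulating one (it
#'   must carry ground-truth labels).
#' @return A list of class `run_report`: per-stage `timings` (seconds),
#'   `detection` summary, `selection` summary, `balance` report, `metrics`,
#'   `loss_curves`, `config` echo, `software` version string.
#' @export
run_pipeline <- function(cfg = run_config(), record = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  timings <- c()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }
  # -- simulate
  if (is.null(record)) {
    sc <- do.call(synth_config,
                  utils::modifyList(cfg$synth, list(seed = derive_seed(cfg$seed, 1L))))
    record <- tick("simulate", generate_clean_ecg(sc))
  }
  # -- preprocess
  det_cfg <- do.call(detector_config, cfg$detector)
  det <- tick("detect", detect_r_peaks(record, det_cfg))
  beats <- tick("segment", segment_beats(record, det$r_peaks))
  labs <- vapply(beats$beats, `[[`, character(1), "label")
  keep <- labs != "unknown"
  beats$beats <- beats$beats[keep]
  labs <- labs[keep]
  if (length(unique(labs)) < 2L)
    stop("pipeline stage 'segment' failed: fewer than two beat classes found")
  # -- split before any statistic is fitted (leakage guard)
  grp <- split_indices(labs, cfg$split, derive_seed(cfg$seed, 2L))
  fcfg <- do.call(feature_config, cfg$features)
  tr <- grp == "train"; va <- grp == "val"; te <- grp == "test"
  fm_tr <- tick("features", extract_feature_matrix(
    structure(list(beats = beats$beats[tr], fs = beats$fs,
                   length = beats$length, n_dropped = 0L),
              class = "beat_segments"), fcfg))
  apply_fm <- function(sel) extract_feature_matrix(
    structure(list(beats = beats$beats[sel], fs = beats$fs,
                   length = beats$length, n_dropped = 0L),
              class = "beat_segments"), fcfg, scaling = fm_tr$scaling)
  fm_va <- if (any(va)) apply_fm(va) else NULL
  fm_te <- apply_fm(te)
  # -- selection (training fold only)
  if (isTRUE(cfg$select$enabled)) {
    sel <- tick("select", rfo_select(
      fm_tr, foxes = cfg$select$foxes, iterations = cfg$select$iterations,
      lambda = cfg$select$lambda,
      binarize_threshold = cfg$select$binarize_threshold,
      reinit_fraction = cfg$select$reinit_fraction,
      seed = derive_seed(cfg$seed, 3L)))
    mask <- sel$mask
    # the conv stack needs a minimum input length; top up a too-sparse mask
    # from the largest soft coordinates
    min_feat <- .min_input_length(model_config(input_length = 64)$conv_blocks)
    if (sum(mask) < min_feat)
      mask[order(sel$position, decreasing = TRUE)[seq_len(min_feat)]] <- TRUE
    sel_summary <- list(n_selected = sum(mask),
                        selected_names = fm_tr$names[mask],
                        best_fitness = sel$best_fitness,
                        fitness_history = sel$fitness_history)
  } else {
    mask <- rep(TRUE, ncol(fm_tr$values))
    sel_summary <- list(skipped = TRUE, n_selected = sum(mask))
  }
  Xtr <- fm_tr$values[, mask, drop = FALSE]; ytr <- fm_tr$labels
  Xva <- if (!is.null(fm_va)) fm_va$values[, mask, drop = FALSE]
  Xte <- fm_te$values[, mask, drop = FALSE]
  # -- balance (training fold only)
  if (isTRUE(cfg$balance$enabled)) {
    os <- tick("balance", random_oversample(Xtr, ytr,
                                            seed = derive_seed(cfg$seed, 4L)))
    Xtr <- os$X; ytr <- os$y
    bal_report <- os$report
    wts <- if (identical(cfg$balance$weights_on, "raw"))
      class_weights(fm_tr$labels) else bal_report$class_weights
  } else {
    bal_report <- NULL
    wts <- class_weights(ytr)
  }
  # -- train + evaluate
  mcfg <- do.call(model_config,
                  utils::modifyList(cfg$model,
                                    list(input_length = ncol(Xtr),
                                         n_classes = length(unique(ytr)),
                                         seed = derive_seed(cfg$seed, 5L))))
  model <- build_ialexnet(mcfg)
  model <- tick("train", train_ialexnet(model, Xtr, ytr, Xva,
                                        if (!is.null(fm_va)) fm_va$labels,
                                        weights = wts))
  metrics <- tick("evaluate", evaluate_model(model, Xte, fm_te$labels))
  report <- structure(list(
    timings = as.list(timings),
    detection = list(n_detected = length(det$r_peaks),
                     n_annotated = length(record$r_peaks),
                     n_beats_used = length(labs),
                     n_dropped = beats$n_dropped),
    selection = sel_summary,
    balance = if (!is.null(bal_report))
      bal_report[c("counts_before", "counts_after", "class_weights")]
      else list(skipped = TRUE),
    metrics = list(accuracy = metrics$accuracy, precision = metrics$precision,
                   recall = metrics$recall, f1 = metrics$f1,
                   confusion = metrics$confusion),
    loss_curves = model$history,
    config = unclass_deep(cfg),
    software = paste0("cardiosift ",
                      as.character(utils::packageVersion("cardiosift")))),
    class = "run_report")
  report$model <- model
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_run_report(report, file.path(cfg$out_dir, "run_report.json"))
  }
  report
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

#' Serialize a run report to JSON
#'
#' Writes every serializable component of the report (the fitted model object
#' itself is omitted). The layout follows the schema shipped in
#' `inst/schema/run_report.json`.
#'
#' @param report A `run_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  r <- unclass_deep(report)
  r$model <- NULL
  r$metrics$confusion <- as.matrix(report$metrics$confusion)
  jsonlite::write_json(r, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       matrix = "rowmajor", force = TRUE)
  invisible(path)
}

#' Structurally validate a run report
#'
#' Checks the presence and types of the required report fields (the same
#' constraints declared in `inst/schema/run_report.json`).
#'
#' @param report A `run_report` or a list parsed from its JSON serialization.
#' @return `TRUE`, or stops with the offending field.
#' @export
validate_run_report <- function(report) {
  need <- c("timings", "detection", "selection", "balance", "metrics",
            "loss_curves", "config", "software")
  for (f in need) if (is.null(report[[f]])) stop("run report lacks field: ", f)
  for (f in c("accuracy", "precision", "recall", "f1")) {
    v <- report$metrics[[f]]
    if (!is.numeric(v) || v < 0 || v > 100)
      stop("run report metric out of range: ", f)
  }
  TRUE
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat("  detected beats:", x$detection$n_detected,
      "(used:", x$detection$n_beats_used, ")\n")
  if (is.null(x$selection$skipped))
    cat("  selected features:", x$selection$n_selected, "\n")
  else cat("  selection: skipped\n")
  cat(sprintf("  test metrics: accuracy %.1f%%, precision %.1f%%, recall %.1f%%, F1 %.1f%%\n",
              x$metrics$accuracy, x$metrics$precision, x$metrics$recall,
              x$metrics$f1))
  invisible(x)
}
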