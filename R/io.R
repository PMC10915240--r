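#' Write / read an RF trace as CSV
#'
#' Interchange format: a UTF-8 CSV with mandatory header and columns
#' `time_s, rf_mhz, subject_id, state, minute_mark` ('.' decimal
#' separator). Values are written with 15 significant digits so a
#' write–read round trip preserves the trace to well below 1e-9 MHz.
#'
#' @param trace An [rf_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "rf_trace"))
  df <- as.data.frame(trace)
  df$time_s <- formatC(df$time_s, digits = 15, format = "g")
  df$rf_mhz <- formatC(df$rf_mhz, digits = 15, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trace_csv
#' @param tolerance_s Permitted timestamp jitter in seconds (default 1e-6);
#'   larger gaps raise a non-uniform-sampling error naming the row.
#' @return For `read_trace_csv`: an [rf_trace()].
#' @export
read_trace_csv <- function(path, tolerance_s = 1e-6) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  required <- c("time_s", "rf_mhz", "subject_id", "state", "minute_mark")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("read_trace_csv: missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) < 1) stop("read_trace_csv: empty trace")
  if (nrow(df) >= 3) {
    dt <- diff(df$time_s)
    bad <- which(abs(dt - stats::median(dt)) > tolerance_s)
    if (length(bad))
      stop("read_trace_csv: non-uniform sampling at data row ", bad[1] + 1,
           " (gap ", signif(dt[bad[1]], 6), " s)")
  }
  fs <- if (nrow(df) >= 2) 1 / stats::median(diff(df$time_s)) else 20
  rf_trace(df$rf_mhz, fs = fs, t0 = df$time_s[1],
           subject_id = as.character(df$subject_id[1]),
           state = as.character(df$state[1]),
           minute_mark = suppressWarnings(as.numeric(df$minute_mark[1])))
}

#' Read a pipeline configuration file
#'
#' JSON (`.json`) or YAML (`.yml`/`.yaml`) files whose keys mirror
#' [default_config()]; missing fields fall back to the defaults.
#'
#' @param path Config file path.
#' @return A nested configuration list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  user <- switch(ext,
                 json = jsonlite::read_json(path, simplifyVector = TRUE),
                 yml = ,
                 yaml = yaml::read_yaml(path),
                 stop("read_config: unsupported extension '", ext, "'"))
  modifyList(default_config(), user)
}

#' Default pipeline configuration
#'
#' Every field defaults to the reference analysis settings: 20 Hz sampling,
#' 300/60 windows (16 per minute), 100 x 100 bicubic resize, 0.5%
#' importance threshold with GLCM always kept, 4:1 stratified split,
#' 5-fold grid search over the full reference grids.
#'
#' @return A nested list with sections `simulate`, `preprocess`, `imaging`,
#'   `selection` and `classify`.
#' @export
default_config <- function() {
  list(
    simulate = list(n_subjects = 13, post_minute = 30, minutes_per_state = 1,
                    fs = 20,
                    circuit = list(L = 1e-6, C = 1e-9, Ccap = 1e-10, Rind = 1),
                    params = list(drive_rate = 1, pulse_volume = 1,
                                  dicrotic_ratio = 0.3, dicrotic_delay = 0.65,
                                  depth = 2, lateral_offset = 0,
                                  amplitude_decay_per_min = 0.02,
                                  noise_sd = 1e-5, drift_sd = 2e-6)),
    preprocess = list(wavelet = "db4", level = 4, mode = "hard"),
    imaging = list(window = 300, step = 60, canvas_height = 300,
                   y_mode = "global", headroom = 0.05,
                   out_w = 100, out_h = 100),
    selection = list(threshold = 0.005, always_keep = "glcm",
                     num_trees = 500),
    classify = list(models = c("knn", "svm", "random_forest"),
                    test_fraction = 0.2, folds = 5, grid = "full")
  )
}

.validate_config <- function(config) {
  im <- config$imaging
  if (im$step > im$window)
    stop("config: imaging step (", im$step, ") exceeds window length (",
         im$window, ")")
  if (config$simulate$n_subjects < 1)
    stop("config: n_subjects must be >= 1")
  if (!config$imaging$y_mode %in% c("global", "per_window"))
    stop("config: imaging y_mode must be 'global' or 'per_window'")
  invisible(config)
}

#' Run the full two-state analysis pipeline
#'
#' Executes simulate -> denoise -> imagify -> featurize -> select ->
#' train -> evaluate in one reproducible run. Every stage derives its own
#' seed from the single run seed, writes its artifact under `out_dir`
#' (trace CSVs, PNG images with a manifest, a feature table, the selection
#' result and one report per model, plus a run manifest with the full
#' configuration) and logs one line per stage.
#'
#' @param config Configuration list as from [default_config()] /
#'   [read_config()].
#' @param out_dir Output directory (created if absent).
#' @param seed Single run seed; all stage randomness derives from it.
#' @param write_images Write the PNG image set (default TRUE; the feature
#'   table is computed from the in-memory images either way).
#' @param verbose Log stage progress to stderr.
#' @return Invisibly, a list with the traces, image manifest, feature
#'   matrix, selection result, fitted models and reports, and artifact
#'   paths.
#' @export
run_pipeline <- function(config = default_config(), out_dir, seed = 1,
                         write_images = TRUE, verbose = TRUE) {
  .validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(stage, ...) {
    if (verbose)
      message(sprintf("[ecs-cbf] %s: %s", stage, sprintf(...)))
  }

  # -- simulate ------------------------------------------------------------
  sim <- config$simulate
  circuit <- do.call(equivalent_circuit, sim$circuit)
  params <- do.call(pulsation_params, sim$params)
  sim_seed <- derive_seed(seed, 1L)
  traces <- generate_cohort(sim$n_subjects, minutes = sim$post_minute,
                            circuit = circuit, params_base = params,
                            seed = sim_seed,
                            minutes_per_state = sim$minutes_per_state,
                            fs = sim$fs)
  tr_dir <- file.path(out_dir, "traces")
  dir.create(tr_dir, showWarnings = FALSE)
  for (tr in traces) {
    nm <- sprintf("%s_%s%s.csv", tr$subject_id, tr$state,
                  if (is.na(tr$minute_mark)) "" else paste0("_", tr$minute_mark))
    write_trace_csv(tr, file.path(tr_dir, nm))
  }
  log_line("simulate", "%d traces (seed %d)", length(traces), sim_seed)

  # -- denoise -------------------------------------------------------------
  pp <- config$preprocess
  denoised <- lapply(traces, wavelet_denoise, wavelet = pp$wavelet,
                     level = pp$level, mode = pp$mode)
  log_line("denoise", "%s level %d, %s threshold", pp$wavelet, pp$level,
           pp$mode)

  # -- imagify -------------------------------------------------------------
  im <- config$imaging
  spec <- window_spec(im$window, im$step)
  subjects <- vapply(denoised, function(tr) tr$subject_id, character(1))
  images <- list()
  manifest <- list()
  img_dir <- file.path(out_dir, "images")
  if (write_images) dir.create(img_dir, showWarnings = FALSE)
  for (sid in unique(subjects)) {
    strs <- denoised[subjects == sid]
    rng <- range(unlist(lapply(strs, function(tr) tr$values)))
    span <- diff(rng)
    y_range <- c(rng[1] - im$headroom * span, rng[2] + im$headroom * span)
    for (tr in strs) {
      imgs <- trace_to_images(tr, spec = spec, y_mode = im$y_mode,
                              y_range = if (im$y_mode == "global") y_range,
                              canvas_height = im$canvas_height,
                              out_w = im$out_w, out_h = im$out_h)
      for (w in seq_along(imgs)) {
        fname <- sprintf("%s_%s_%s_%03d.png", tr$subject_id, tr$state,
                         ifelse(is.na(tr$minute_mark), "0", tr$minute_mark),
                         w)
        if (write_images)
          png::writePNG(imgs[[w]] / 255, file.path(img_dir, fname))
        images[[length(images) + 1L]] <- imgs[[w]]
        manifest[[length(manifest) + 1L]] <-
          data.frame(path = file.path("images", fname),
                     label = tr$state, subject_id = tr$subject_id,
                     state = tr$state, window = w)
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  log_line("imagify", "%d images (%dx%d, %s y-scaling)", length(images),
           im$out_h, im$out_w, im$y_mode)

  # -- featurize -----------------------------------------------------------
  feats <- t(vapply(images, extract_all, numeric(14379)))
  ft <- data.table::as.data.table(feats)
  ft$label <- manifest$label
  ft$subject_id <- manifest$subject_id
  data.table::fwrite(ft, file.path(out_dir, "features.csv"))
  log_line("featurize", "%d x %d feature matrix", nrow(feats), ncol(feats))

  # -- select --------------------------------------------------------------
  sel_cfg <- config$selection
  sel <- importance_selection(feats, manifest$label,
                              threshold = sel_cfg$threshold,
                              always_keep = sel_cfg$always_keep,
                              num_trees = sel_cfg$num_trees,
                              seed = derive_seed(seed, 5L))
  jsonlite::write_json(list(kept_names = sel$kept_names,
                            threshold = sel$threshold,
                            always_keep = sel$always_keep),
                       file.path(out_dir, "selection.json"),
                       auto_unbox = TRUE)
  log_line("select", "%d features kept (threshold %g)",
           length(sel$kept_names), sel_cfg$threshold)

  # -- train / evaluate ----------------------------------------------------
  cl <- config$classify
  xs <- feats[, sel$kept_names, drop = FALSE]
  split <- split_and_standardize(xs, manifest$label,
                                 test_fraction = cl$test_fraction,
                                 seed = derive_seed(seed, 6L))
  models <- list()
  reports <- list()
  for (mt in cl$models) {
    m <- grid_search_train(mt, split$x_train, split$y_train,
                           folds = cl$folds,
                           reduced = identical(cl$grid, "reduced"),
                           seed = derive_seed(seed, 7L))
    rep <- evaluate(m, split$x_test, split$y_test,
                    x_train = split$x_train, y_train = split$y_train,
                    seed = derive_seed(seed, 8L))
    models[[mt]] <- m
    reports[[mt]] <- rep
    jsonlite::write_json(
      list(model = mt, accuracy = rep$accuracy, recall = rep$recall,
           precision = rep$precision, f1 = rep$f1, auc = rep$auc,
           confusion = as.vector(rep$confusion),
           roc_points = rep$roc_points, pr_points = rep$pr_points,
           learning_curve = rep$learning_curve,
           best_params = rep$best_params),
      file.path(out_dir, sprintf("report_%s.json", mt)),
      auto_unbox = TRUE, digits = NA)
    log_line("train", "%s: accuracy %.3f, AUC %.3f", mt, rep$accuracy,
             rep$auc)
  }

  jsonlite::write_json(
    list(config = config, seed = seed,
         package_version = as.character(utils::packageVersion("ecscbf")),
         n_traces = length(traces), n_images = nrow(manifest)),
    file.path(out_dir, "run.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(traces = traces, denoised = denoised, manifest = manifest,
                 features = feats, selection = sel, split = split,
                 models = models, reports = reports, out_dir = out_dir))
}
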