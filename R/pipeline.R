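# End-to-end pipeline driver: simulate (or ingest) -> preprocess ->
# features -> prep -> train -> evaluate -> explain, with a validated
# configuration and a JSON run manifest that records seeds and per-stage
# outputs so any run is reproducible from its manifest.

pipeline_schema <- list(
  seed = "integer",
  out_dir = "character",
  simulate = list(
    fs = "numeric", n_channels = "integer", duration_s = "numeric",
    n_per_class = "integer", noise_sd = "numeric",
    weight_jitter = "numeric", classes = "list", write_edf = "logical"
  ),
  input_dir = "character",
  labels_csv = "character",
  preprocess = list(
    enabled = "logical", band_lo = "numeric", band_hi = "numeric",
    filter_order = "integer", asr_window_s = "numeric",
    asr_cutoff = "numeric", ica_components = "any",
    frontal_channels = "character"
  ),
  features = list(
    scheme = "character", epoch_s = "numeric", epoch_overlap = "numeric",
    seg_len_s = "numeric", seg_overlap = "numeric", window = "character"
  ),
  prep = list(
    task = "integer", train = "numeric", val = "numeric", test = "numeric",
    mode = "character", smote = "logical", k_neighbors = "integer",
    normalize = "character"
  ),
  train = list(
    learning_rate = "numeric", batch_size = "integer",
    max_epochs = "integer", patience = "integer",
    spatial_dropout = "numeric", dense_dropout = "numeric"
  ),
  explain = list(
    enabled = "logical", n_background = "integer", n_instances = "integer",
    plots = "logical"
  )
)

validate_section <- function(cfg, schema, path = "") {
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown)) {
    stop("config error: unknown key(s) ", path,
         paste(unknown, collapse = ", "))
  }
  for (nm in names(cfg)) {
    want <- schema[[nm]]
    if (is.list(want)) {
      if (!is.list(cfg[[nm]])) {
        stop("config error: '", path, nm, "' must be a section")
      }
      if (nm != "classes") validate_section(cfg[[nm]], want,
                                            paste0(path, nm, "."))
    }
  }
  invisible(TRUE)
}

#' Build and validate a pipeline configuration
#'
#' Accepts a YAML file path or a nested list, checks every key against the
#' configuration schema (unknown keys are rejected before any stage runs),
#' and fills defaults.
#'
#' @param config YAML path or named list.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config error: configuration must be a list")
  validate_section(cfg, pipeline_schema)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$out_dir <- cfg$out_dir %||% "eegdem_run"
  sim <- cfg$simulate
  if (!is.null(sim)) {
    sim$fs <- sim$fs %||% 500
    sim$n_channels <- sim$n_channels %||% 19L
    sim$duration_s <- sim$duration_s %||% 60
    sim$n_per_class <- sim$n_per_class %||% 10L
    sim$noise_sd <- sim$noise_sd %||% 1
    sim$weight_jitter <- sim$weight_jitter %||% 0.15
    sim$write_edf <- sim$write_edf %||% FALSE
    cfg$simulate <- sim
  }
  pp <- cfg$preprocess %||% list()
  pp$enabled <- pp$enabled %||% FALSE
  cfg$preprocess <- pp
  ft <- cfg$features %||% list()
  ft$scheme <- ft$scheme %||% "modified"
  if (!ft$scheme %in% c("modified", "standard")) {
    stop("config error: features.scheme must be 'modified' or 'standard'")
  }
  ft$epoch_s <- ft$epoch_s %||% 6
  ft$epoch_overlap <- ft$epoch_overlap %||% 0.5
  ft$seg_len_s <- ft$seg_len_s %||% 2
  ft$seg_overlap <- ft$seg_overlap %||% 0.5
  ft$window <- ft$window %||% "hann"
  cfg$features <- ft
  pr <- cfg$prep %||% list()
  pr$task <- as.integer(pr$task %||% 1L)
  if (!pr$task %in% 1:4) {
    stop("config error: prep.task must be 1, 2, 3 or 4")
  }
  pr$train <- pr$train %||% 0.8
  pr$val <- pr$val %||% 0.1
  pr$test <- pr$test %||% 0.1
  pr$mode <- pr$mode %||% "epoch"
  pr$smote <- pr$smote %||% FALSE
  pr$k_neighbors <- as.integer(pr$k_neighbors %||% 5L)
  pr$normalize <- pr$normalize %||% "train"
  if (!pr$normalize %in% c("train", "all")) {
    stop("config error: prep.normalize must be 'train' or 'all'")
  }
  cfg$prep <- pr
  tr <- cfg$train %||% list()
  tr$learning_rate <- tr$learning_rate %||% 1e-4
  tr$batch_size <- as.integer(tr$batch_size %||% 32L)
  tr$max_epochs <- as.integer(tr$max_epochs %||% 100L)
  tr$patience <- as.integer(tr$patience %||% 10L)
  tr$spatial_dropout <- tr$spatial_dropout %||% 0.2
  tr$dense_dropout <- tr$dense_dropout %||% 0.2
  cfg$train <- tr
  ex <- cfg$explain %||% list()
  ex$enabled <- ex$enabled %||% TRUE
  ex$n_background <- as.integer(ex$n_background %||% 20L)
  ex$n_instances <- as.integer(ex$n_instances %||% 50L)
  ex$plots <- ex$plots %||% TRUE
  cfg$explain <- ex
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

default_sim_profiles <- function(sim, scheme) {
  if (!is.null(sim$classes)) {
    lapply(names(sim$classes), function(lb) {
      class_profile(
        lb, unlist(sim$classes[[lb]]),
        noise_sd = sim$noise_sd, weight_jitter = sim$weight_jitter,
        scheme = scheme
      )
    })
  } else {
    unname(default_profiles(
      noise_sd = sim$noise_sd, weight_jitter = sim$weight_jitter
    ))
  }
}

#' Run the full pipeline
#'
#' Executes the configured stages in order — simulate or ingest,
#' preprocess, feature extraction, dataset preparation, training,
#' evaluation, explanation — writing all artifacts (feature CSV,
#' evaluation report JSON, confusion and ROC CSVs, attribution tables and
#' plots) plus a run manifest into `out_dir`. Any stage error aborts with
#' the stage name; the partial manifest is still written.
#'
#' @param config YAML path, list, or [pipeline_config()].
#' @return The run manifest (invisibly), a list recording the seed,
#'   configuration and per-stage outputs.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("eegdem")),
    seed = cfg$seed, config = unclass(cfg), stages = list(),
    started = format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  )
  finish <- function() {
    jsonlite::write_json(
      manifest, file.path(cfg$out_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE
    )
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
      finish()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- c(
      list(status = "ok",
           seconds = round(proc.time()[["elapsed"]] - t0, 2)),
      res$info
    )
    res$value
  }
  scheme <- band_scheme(cfg$features$scheme)

  dataset <- stage("ingest", {
    if (!is.null(cfg$input_dir)) {
      lab <- utils::read.csv(cfg$labels_csv, stringsAsFactors = FALSE)
      recs <- lapply(seq_len(nrow(lab)), function(i) {
        r <- read_eeg(file.path(cfg$input_dir, lab$filename[i]))
        r$label <- lab$label[i]
        r
      })
      list(value = recs, info = list(n_recordings = length(recs)))
    } else {
      profiles <- default_sim_profiles(cfg$simulate, scheme)
      ds <- generate_eeg_dataset(
        profiles, cfg$simulate$n_per_class, cfg$simulate$duration_s,
        fs = cfg$simulate$fs, n_channels = cfg$simulate$n_channels,
        seed = cfg$seed
      )
      if (isTRUE(cfg$simulate$write_edf)) {
        sim_dir <- file.path(cfg$out_dir, "simulated")
        dir.create(sim_dir, showWarnings = FALSE)
        fn <- sprintf("%s.edf", vapply(ds$recordings, `[[`, "",
                                       "subject_id"))
        for (i in seq_along(ds$recordings)) {
          write_edf(ds$recordings[[i]], file.path(sim_dir, fn[i]))
        }
        utils::write.csv(
          data.frame(filename = fn, label = ds$labels),
          file.path(sim_dir, "labels.csv"), row.names = FALSE
        )
      }
      list(value = ds$recordings,
           info = list(n_recordings = length(ds$recordings)))
    }
  })

  if (isTRUE(cfg$preprocess$enabled)) {
    dataset <- stage("preprocess", {
      pc <- preprocess_config(
        band_lo = cfg$preprocess$band_lo %||% 0.5,
        band_hi = cfg$preprocess$band_hi %||% 45,
        filter_order = cfg$preprocess$filter_order %||% 4,
        asr_window_s = cfg$preprocess$asr_window_s %||% 0.5,
        asr_cutoff = cfg$preprocess$asr_cutoff %||% 17,
        ica_components = cfg$preprocess$ica_components %||% "none",
        frontal_channels = cfg$preprocess$frontal_channels %||%
          c("Fp1", "Fp2")
      )
      flagged <- 0L
      out <- lapply(dataset, function(r) {
        res <- preprocess_eeg(r, pc, seed = cfg$seed)
        flagged <<- flagged + sum(res$asr_mask)
        res$eeg
      })
      list(value = out, info = list(windows_flagged = flagged))
    })
  }

  fm <- stage("features", {
    f <- extract_features(
      dataset, scheme,
      epoch_s = cfg$features$epoch_s,
      epoch_overlap = cfg$features$epoch_overlap,
      seg_len_s = cfg$features$seg_len_s,
      seg_overlap = cfg$features$seg_overlap,
      window = cfg$features$window
    )
    write_feature_matrix(f, file.path(cfg$out_dir, "features.csv"))
    list(value = f, info = list(n_epochs = nrow(f$values),
                                csv = "features.csv"))
  })

  prep <- stage("prep", {
    task <- cfg$prep$task
    fmx <- subset_task(fm, task)
    fmx$labels <- map_task_labels(fmx$labels, task)
    sp <- split_features(
      fmx, cfg$prep$train, cfg$prep$val, cfg$prep$test,
      seed = cfg$seed, mode = cfg$prep$mode
    )
    if (isTRUE(cfg$prep$smote)) {
      sp$train <- smote_balance(sp$train, cfg$prep$k_neighbors,
                                seed = cfg$seed)
    }
    mm <- if (cfg$prep$normalize == "train") fit_minmax(sp$train) else
      fit_minmax(fmx)
    list(
      value = list(
        train = apply_minmax(sp$train, mm), val = apply_minmax(sp$val, mm),
        test = apply_minmax(sp$test, mm), params = mm, task = task
      ),
      info = list(
        task = task, n_train = nrow(sp$train$values),
        n_val = nrow(sp$val$values), n_test = nrow(sp$test$values),
        smote = isTRUE(cfg$prep$smote)
      )
    )
  })

  fit <- stage("train", {
    spec <- model_spec(
      input_len = length(fm$band_names),
      n_classes = length(task_classes(prep$task)),
      spatial_dropout = cfg$train$spatial_dropout,
      dense_dropout = cfg$train$dense_dropout
    )
    ctrl <- train_control(
      learning_rate = cfg$train$learning_rate,
      batch_size = cfg$train$batch_size,
      max_epochs = cfg$train$max_epochs,
      patience = cfg$train$patience,
      seed = cfg$seed
    )
    m <- tcn_lstm(
      prep$train$values, prep$train$labels, spec = spec, control = ctrl,
      validation = list(x = prep$val$values, y = prep$val$labels)
    )
    utils::write.csv(m$history, file.path(cfg$out_dir, "history.csv"),
                     row.names = FALSE)
    list(value = m, info = list(epochs_run = nrow(m$history)))
  })

  report <- stage("evaluate", {
    probs <- predict(fit, prep$test$values, type = "prob")
    pred <- fit$class_order[max.col(probs)]
    cm <- confusion(prep$test$labels, pred, fit$class_order)
    mr <- metrics_from_confusion(cm)
    roc <- roc_auc(prep$test$labels, probs, fit$class_order)
    utils::write.csv(as.data.frame(unclass(cm)),
                     file.path(cfg$out_dir, "confusion.csv"))
    for (k in names(roc$curves)) {
      if (!is.null(roc$curves[[k]])) {
        utils::write.csv(
          roc$curves[[k]],
          file.path(cfg$out_dir, sprintf("roc_%s.csv", k)),
          row.names = FALSE
        )
      }
    }
    rep_list <- list(
      accuracy = mr$accuracy, per_class = mr$per_class,
      auc = as.list(roc$auc)
    )
    jsonlite::write_json(rep_list, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(value = rep_list,
         info = list(accuracy = mr$accuracy, report = "report.json"))
  })

  if (isTRUE(cfg$explain$enabled)) {
    stage("explain", {
      bg <- shap_background(prep$train$values, cfg$explain$n_background,
                            seed = cfg$seed)
      n_inst <- min(cfg$explain$n_instances, nrow(prep$test$values))
      set.seed(cfg$seed)
      take <- sort(sample.int(nrow(prep$test$values), n_inst))
      attr_ <- shap_values(fit, prep$test$values[take, , drop = FALSE], bg)
      top <- character(0)
      for (cl in fit$class_order) {
        gi <- global_importance(attr_, cl)
        utils::write.csv(
          gi, file.path(cfg$out_dir, sprintf("shap_importance_%s.csv", cl)),
          row.names = FALSE
        )
        utils::write.csv(
          summary_data(attr_, cl),
          file.path(cfg$out_dir, sprintf("shap_summary_%s.csv", cl)),
          row.names = FALSE
        )
        if (isTRUE(cfg$explain$plots)) {
          plot_importance(attr_, cl, file.path(
            cfg$out_dir, sprintf("shap_importance_%s.png", cl)
          ))
          plot_beeswarm(attr_, cl, file.path(
            cfg$out_dir, sprintf("shap_beeswarm_%s.png", cl)
          ))
          plot_heatmap(attr_, cl, file.path(
            cfg$out_dir, sprintf("shap_heatmap_%s.png", cl)
          ))
        }
        top <- c(top, gi$feature[1])
      }
      list(value = NULL,
           info = list(top_feature = stats::setNames(
             as.list(top), fit$class_order
           )))
    })
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  finish()
  invisible(manifest)
}
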