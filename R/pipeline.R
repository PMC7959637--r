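# End-to-end pipeline: simulate/read -> transform -> extract -> fuse ->
# select -> evaluate, with persisted intermediates and a run manifest.

#' Pipeline configuration
#'
#' Collects every stage's parameters with the pipeline defaults. All
#' randomness flows from `seed`, expanded deterministically per stage.
#'
#' @param simulate Generate a synthetic cohort (`TRUE`) or read WFDB records
#'   from `input_dir` labelled via `manifest` (`FALSE`).
#' @param n_per_class Records per rhythm class when simulating.
#' @param n_samples,sampling_rate,noise_sd,baseline_wander_amp Simulation
#'   settings, see [simulation_config()].
#' @param input_dir,manifest For `simulate = FALSE`: directory of WFDB
#'   records and a CSV with columns `record_id,rhythm_class`.
#' @param lead Lead index used by the transform.
#' @param segment_length,side,binarize_method,threshold,reshape_order
#'   Transform settings, see [transform_record()].
#' @param backends List of [backend_spec()]s, fused in order. The default is
#'   three stub blocks with the published CNN widths (4096, 4096, 2048),
#'   each under its own projection seed.
#' @param selection_fraction,selection_order,n_bins Selection settings;
#'   `selection_fraction = NULL` skips selection.
#' @param protocol,k,train_fraction,roster Evaluation settings, see
#'   [run_experiment()].
#' @param seed Root seed.
#' @param out_dir Optional directory for persisted intermediates.
#'
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = TRUE,
                            n_per_class = 30L,
                            n_samples = 8192L,
                            sampling_rate = 360,
                            noise_sd = 0.05,
                            baseline_wander_amp = 0.1,
                            input_dir = NULL,
                            manifest = NULL,
                            lead = 1L,
                            segment_length = 1024L,
                            side = 32L,
                            binarize_method = "minmax",
                            threshold = 0.5,
                            reshape_order = "column",
                            backends = NULL,
                            selection_fraction = 0.5,
                            selection_order = "ascending",
                            n_bins = 256L,
                            protocol = "cv10",
                            k = 10L,
                            train_fraction = 0.5,
                            roster = list("cubic_svm"),
                            seed = 1L,
                            out_dir = NULL) {
  if (is.null(backends)) {
    backends <- list(
      backend_spec("stub", output_dim = 4096L, stub_seed = derive_seed(seed, 101L)),
      backend_spec("stub", output_dim = 4096L, stub_seed = derive_seed(seed, 102L)),
      backend_spec("stub", output_dim = 2048L, stub_seed = derive_seed(seed, 103L))
    )
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' @noRd
load_labeled_records <- function(config) {
  if (isTRUE(config$simulate)) {
    generate_cohort(
      config$n_per_class,
      base_config = simulation_config(
        "NSR", n_samples = config$n_samples,
        sampling_rate = config$sampling_rate,
        noise_sd = config$noise_sd,
        baseline_wander_amp = config$baseline_wander_amp),
      seed = derive_seed(config$seed, 1L))
  } else {
    if (is.null(config$input_dir) || is.null(config$manifest)) {
      stopf("simulate = FALSE requires input_dir and manifest")
    }
    man <- utils::read.csv(config$manifest, stringsAsFactors = FALSE)
    records <- lapply(man$record_id, function(rid) {
      rec <- read_wfdb(file.path(config$input_dir, paste0(rid, ".hea")))
      attr(rec, "rhythm_class") <-
        toupper(man$rhythm_class[man$record_id == rid][1])
      rec
    })
    list(records = records, labels = as_rhythm_class(man$rhythm_class))
  }
}

#' Run the full pipeline
#'
#' Executes simulate/read, transform, extract, fuse, select and evaluate in
#' sequence. Failures abort with the failing stage named. When
#' `config$out_dir` is set, the image dataset, fused features, selection
#' JSON, metric table CSV and a run-log JSON are written there.
#'
#' @param config A [pipeline_config()].
#' @return List with `reports`, `table` (the classifier-by-metric
#'   data.frame), `selection`, `fused_width`, `n_images`, `labels`, and
#'   `image_sets`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  cohort <- stage("input", load_labeled_records(config))

  image_sets <- stage("transform", lapply(cohort$records, function(rec) {
    transform_record(rec, lead = config$lead,
                     segment_length = config$segment_length,
                     side = config$side, method = config$binarize_method,
                     threshold = config$threshold,
                     order = config$reshape_order)
  }))
  images <- do.call(c, lapply(image_sets, `[[`, "images"))
  labels <- do.call(c, lapply(image_sets, function(s) as.character(s$labels)))
  labels <- as_rhythm_class(labels)
  image_ids <- unlist(lapply(image_sets, function(s) {
    sprintf("%s_seg%04d", s$source_record, s$segment_indices)
  }))

  fused <- stage("extract+fuse", {
    blocks <- lapply(config$backends, function(bk) {
      extract_features(images, bk, image_ids = image_ids)
    })
    fuse_features(blocks)
  })

  selection <- NULL
  if (!is.null(config$selection_fraction)) {
    selection <- stage("select", select_by_entropy(
      fused, fraction = config$selection_fraction,
      order = config$selection_order, n_bins = config$n_bins))
  }

  reports <- stage("evaluate", run_experiment(
    fused, labels, roster = config$roster, selection = selection,
    protocol = config$protocol, k = config$k,
    train_fraction = config$train_fraction,
    seed = derive_seed(config$seed, 2L)))
  tab <- metrics_table(reports)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_image_dataset(image_sets, file.path(config$out_dir, "images"))
    saveRDS(fused, file.path(config$out_dir, "fused_features.rds"))
    if (!is.null(selection)) {
      write_selection_json(selection, file.path(config$out_dir, "selection.json"))
    }
    utils::write.csv(tab, file.path(config$out_dir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed, protocol = config$protocol,
           n_images = length(images), fused_width = ncol(fused),
           n_selected = if (is.null(selection)) ncol(fused) else
             length(selection$selected_indices),
           r_version = as.character(getRversion())),
      file.path(config$out_dir, "run_log.json"), auto_unbox = TRUE)
  }

  list(reports = reports, table = tab, selection = selection,
       fused_width = ncol(fused), n_images = length(images),
       labels = labels, image_sets = image_sets)
}
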