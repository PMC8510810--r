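#' @title End-to-end pipeline
#' @name pipeline
#' @description
#' The two-phase flow: synthesize (or load) tiles -> train the wavelet
#' U-shaped segmentation network -> generate bounding-box strong labels from
#' its probability maps and the weak labels -> train the region-based
#' detector on those boxes -> detect on held-out tiles -> score with the
#' 8 um center-distance protocol.
NULL

#' Pipeline configuration
#'
#' One global `seed` fans out to per-stage seeds by fixed offsets (+1 synth,
#' +1000 segmentation net, +2000 segmentation training, +3000 detector), so
#' every stage is independently reproducible.
#'
#' @param seed global integer seed.
#' @param workdir directory for all stage outputs.
#' @param n_tiles,split,synth dataset size, train fraction and
#'   [synth_config()] overrides (list).
#' @param segnet [segnet_config()] overrides (list).
#' @param train [train_config()] overrides (list).
#' @param labelgen list with `threshold` and `min_area`.
#' @param detector [detector_config()] overrides (list).
#' @param eval list with `microns_per_pixel` and `match_radius_um`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, workdir = tempfile("mitorun"),
                            n_tiles = 20L, split = 0.8, synth = list(),
                            segnet = list(), train = list(),
                            labelgen = list(), detector = list(),
                            eval = list()) {
  seed <- as.integer(seed)
  synth <- utils::modifyList(list(seed = seed + 1L), synth)
  segnet <- utils::modifyList(list(seed = seed + 1000L), segnet)
  train <- utils::modifyList(list(seed = seed + 2000L), train)
  labelgen <- utils::modifyList(list(threshold = 0.5, min_area = 5L),
                                labelgen)
  detector <- utils::modifyList(list(seed = seed + 3000L), detector)
  eval <- utils::modifyList(list(microns_per_pixel = 0.25,
                                 match_radius_um = 8), eval)
  # each block must satisfy its module's invariants before any stage runs
  do.call(synth_config, synth)
  do.call(segnet_config, segnet)
  do.call(train_config, train)
  do.call(detector_config, detector)
  do.call(resolution_spec, eval)
  if (!(labelgen$threshold > 0 && labelgen$threshold < 1)) {
    stop("labelgen threshold must be in (0, 1)")
  }
  structure(list(seed = seed, workdir = workdir, n_tiles = as.integer(n_tiles),
                 split = split, synth = synth, segnet = segnet, train = train,
                 labelgen = labelgen, detector = detector, eval = eval),
            class = "pipeline_config")
}

#' Desk-scale pipeline configuration
#'
#' The reference CPU-scale study configuration: 20 tiles of 64 x 64 px
#' (16 train / 4 validation) with 2-4 mitoses each, a 2-level 8/16-channel
#' segmentation network trained 30 epochs (batch 4, lr 2e-3 -> 2e-4), and a
#' detector trained 40 minibatch steps (lr 1e-3 -> 1e-4) on sliding-window
#' proposals, evaluated at 0.25 microns per pixel. Runs end to end in a few
#' minutes on one CPU core.
#'
#' @param seed global seed.
#' @param workdir output directory.
#' @return a [pipeline_config()].
#' @export
desk_scale_config <- function(seed = 1L, workdir = tempfile("mitorun")) {
  pipeline_config(
    seed = seed, workdir = workdir, n_tiles = 20L, split = 0.8,
    segnet = list(levels = 2L, channels = c(8L, 16L)),
    train = list(epochs = 30L, batch_size = 4L,
                 lr_start = 2e-3, lr_end = 2e-4),
    detector = list(steps = 40L, lr_start = 1e-3, lr_end = 1e-4),
    eval = list(microns_per_pixel = 0.25))
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()]'s arguments as nested blocks.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  y <- y[names(y) %in% names(formals(pipeline_config))]
  do.call(pipeline_config, y)
}

.log_stage <- function(stage, seed, t0) {
  message(sprintf("[%s] seed=%s %.1fs", stage, seed,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full two-phase pipeline
#'
#' Chains synth -> train-seg -> gen-labels -> train-det -> detect ->
#' evaluate. All artefacts (dataset, loss logs, generated labels,
#' detections, metrics JSON) are written under `cfg$workdir`.
#'
#' @param cfg a [pipeline_config()].
#' @param verbose log stage timings and seeds (default TRUE).
#' @return list with `metrics` (val-set `mito_metrics`), `train_metrics`,
#'   `segnet`, `detector`, `dice` (training-tile Dice of the segmentation),
#'   `dataset_dir` and `workdir`.
#' @export
run_all <- function(cfg = pipeline_config(), verbose = TRUE) {
  say <- if (verbose) .log_stage else function(...) invisible(NULL)
  dir.create(cfg$workdir, recursive = TRUE, showWarnings = FALSE)

  t0 <- as.numeric(Sys.time())
  ds_dir <- file.path(cfg$workdir, "dataset")
  generate_dataset(cfg$n_tiles, do.call(synth_config, cfg$synth),
                   cfg$split, ds_dir)
  tr <- load_dataset(ds_dir, "train")
  va <- load_dataset(ds_dir, "val")
  say("synth", cfg$synth$seed, t0)

  t0 <- as.numeric(Sys.time())
  seg <- train_segmentation(tr$tiles, tr$masks,
                            do.call(train_config, cfg$train),
                            do.call(segnet_config, cfg$segnet))
  utils::write.csv(seg$history, file.path(cfg$workdir, "segnet_loss.csv"),
                   row.names = FALSE)
  say("train-seg", cfg$segnet$seed, t0)

  t0 <- as.numeric(Sys.time())
  gen_boxes <- vector("list", length(tr$tiles))
  dice <- numeric(length(tr$tiles))
  dir.create(file.path(cfg$workdir, "genlabels"), showWarnings = FALSE)
  for (i in seq_along(tr$tiles)) {
    pm <- predict_probmap(seg, tr$tiles[[i]])
    sl <- generate_strong_labels(pm, tr$weak_labels[[i]],
                                 cfg$labelgen$threshold,
                                 cfg$labelgen$min_area)
    gen_boxes[[i]] <- sl$boxes
    dice[i] <- dice_coefficient(binarize_probmap(pm, cfg$labelgen$threshold),
                                tr$masks[[i]])
    write_boxes(file.path(cfg$workdir, "genlabels",
                          paste0(tr$stems[i], ".csv")), sl$boxes)
  }
  say("gen-labels", cfg$segnet$seed, t0)

  t0 <- as.numeric(Sys.time())
  det <- train_detector(tr$tiles, gen_boxes,
                        do.call(detector_config, cfg$detector))
  say("train-det", cfg$detector$seed, t0)

  t0 <- as.numeric(Sys.time())
  res <- do.call(resolution_spec, cfg$eval)
  dir.create(file.path(cfg$workdir, "detections"), showWarnings = FALSE)
  detect_split <- function(split_data, stems) {
    dets <- vector("list", length(split_data$tiles))
    for (i in seq_along(split_data$tiles)) {
      dets[[i]] <- detect(det, split_data$tiles[[i]])
      write_detections(file.path(cfg$workdir, "detections",
                                 paste0(stems[i], ".csv")), dets[[i]])
    }
    dets
  }
  val_dets <- detect_split(va, va$stems)
  train_dets <- detect_split(tr, paste0(tr$stems, "_train"))
  say("detect", cfg$detector$seed, t0)

  # undefined precision is carried in the precision_defined flag; a batch
  # run must not stop on a tile set with no detections
  metrics <- suppressWarnings(evaluate_detections(val_dets, va$weak_labels, res))
  train_metrics <- suppressWarnings(
    evaluate_detections(train_dets, tr$weak_labels, res))
  write_metrics(file.path(cfg$workdir, "metrics.json"), metrics)
  list(metrics = metrics, train_metrics = train_metrics, segnet = seg,
       detector = det, dice = dice, dataset_dir = ds_dir,
       workdir = cfg$workdir)
}
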