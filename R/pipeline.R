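#' Scaled-down configurations for desk-scale experiments
#'
#' The full-scale defaults ([model_config()], [train_config()],
#' [preprocess_config()]) mirror a GPU-scale training regime. For CPU-scale
#' phantom experiments the package uses a reduced setting: depth 2, base 8
#' channels, 48^3 patches at a 3 x 3 x 4.5 mm working spacing (one patch
#' then covers the whole phantom liver), one patch per case per epoch,
#' batch size 1, and SGD with learning rate 0.3, momentum 0.95 (Nesterov),
#' decayed by 0.1 at epoch 16 — a step-size schedule suited to a
#' few-hundred-step run; the full-scale 1e-3 schedule assumes tens of
#' thousands of steps. All training patches are centred on liver voxels.
#'
#' @param epochs training epochs.
#' @param seed integer seed.
#' @return list with `model`, `train`, `pre` configs.
#' @export
scaled_configs <- function(epochs = 20L, seed = 1L) {
  list(model = model_config(base_channels = 8L, depth = 2L),
       train = train_config(lr_initial = 0.3, lr_decay_factor = 0.1,
                            lr_decay_every_epochs = 16L,
                            epochs = as.integer(epochs),
                            batch_size = 1L, patches_per_case = 1L,
                            momentum = 0.95, foreground_fraction = 1,
                            seed = as.integer(seed)),
       pre = preprocess_config(target_spacing_mm = c(3, 3, 4.5),
                               patch_shape = c(48L, 48L, 48L)))
}

phantom_paths <- function(dir, i) {
  list(image = file.path(dir, sprintf("case%03d_image.nii.gz", i)),
       mask = file.path(dir, sprintf("case%03d_mask.nii.gz", i)),
       labels = file.path(dir, sprintf("case%03d_labels.nii.gz", i)),
       landmarks = file.path(dir, sprintf("case%03d_landmarks.json", i)),
       lesions = file.path(dir, sprintf("case%03d_lesions.json", i)))
}

write_case <- function(case, dir, i) {
  p <- phantom_paths(dir, i)
  write_volume(case$image, p$image)
  write_volume(vol_grid(case$liver_mask$data, case$liver_mask$spacing,
                        case$liver_mask$origin), p$mask)
  write_volume(case$labels, p$labels)
  write_landmarks(case$landmarks, p$landmarks)
  write_lesions(case$lesions, p$lesions)
  data.frame(case = sprintf("case%03d", i), image = p$image, mask = p$mask,
             labels = p$labels, landmarks = p$landmarks,
             lesions = p$lesions)
}

#' Run a pipeline subcommand
#'
#' Programmatic entry point behind the `couinaud3d` command-line script.
#' Supported commands:
#' \describe{
#'   \item{phantom}{`n`, `seed`, `out`, optional `lesions`, `straddle`:
#'     generate phantom cases and a `manifest.csv`.}
#'   \item{label}{`mask`, `landmarks`, `out`: run the Couinaud labeler.}
#'   \item{train}{`data` (phantom dir), `out`, optional `epochs`, `seed`:
#'     train the reduced network; writes `model.rds` and
#'     `history.csv`.}
#'   \item{predict}{`image`, `model`, `out`: predict a label map.}
#'   \item{evaluate}{`pred`, `ref`, `out`: write the per-segment metric
#'     table as CSV.}
#'   \item{rubric}{`pred`, `ref`, `out`: write a quality report as JSON.}
#'   \item{localize}{`pred`, `lesions`, `out`: localization results as
#'     CSV.}
#' }
#'
#' @param command one of the subcommands above.
#' @param args named list of arguments.
#' @return 0 invisibly on success; errors propagate to the caller.
#' @export
run_pipeline <- function(command, args = list()) {
  need <- function(keys) {
    miss <- setdiff(keys, names(args))
    if (length(miss)) {
      stop("missing argument(s) for ", command, ": ",
           paste(miss, collapse = ", "))
    }
  }
  switch(command,
    phantom = {
      need(c("n", "seed", "out"))
      dir.create(args$out, showWarnings = FALSE, recursive = TRUE)
      n <- as.integer(args$n)
      rows <- lapply(seq_len(n), function(i) {
        cfg <- phantom_config(seed = as.integer(args$seed) + i - 1L,
                              lesion_count =
                                as.integer(args$lesions %||% 0L))
        case <- generate_case(cfg, straddle = isTRUE(args$straddle))
        write_case(case, args$out, i)
      })
      write.csv(do.call(rbind, rows),
                file.path(args$out, "manifest.csv"), row.names = FALSE)
    },
    label = {
      need(c("mask", "landmarks", "out"))
      mask <- read_volume(args$mask, as_labels = FALSE)
      lm <- read_landmarks(args$landmarks)
      write_volume(assign_couinaud_labels(mask, lm), args$out)
    },
    train = {
      need(c("data", "out"))
      man <- read.csv(file.path(args$data, "manifest.csv"))
      cases <- lapply(seq_len(nrow(man)), function(i) {
        list(image = read_volume(man$image[i], as_labels = FALSE),
             labels = read_volume(man$labels[i], as_labels = TRUE))
      })
      cfgs <- scaled_configs(epochs = as.integer(args$epochs %||% 20L),
                             seed = as.integer(args$seed %||% 1L))
      r <- train_segmenter(cases, cfgs$model, cfgs$train, cfgs$pre,
                           verbose = isTRUE(args$verbose))
      dir.create(args$out, showWarnings = FALSE, recursive = TRUE)
      saveRDS(list(format = SCHEMA, handle = r$handle, pre = cfgs$pre),
              file.path(args$out, "model.rds"))
      write.csv(r$history, file.path(args$out, "history.csv"),
                row.names = FALSE)
    },
    predict = {
      need(c("image", "model", "out"))
      mdl <- readRDS(args$model)
      if (!identical(mdl$format, SCHEMA)) stop("unrecognized model file")
      img <- read_volume(args$image, as_labels = FALSE)
      pred <- predict_segments(img, mdl$handle, mdl$pre)
      write_volume(pred$labels, args$out)
    },
    evaluate = {
      need(c("pred", "ref", "out"))
      pred <- read_volume(args$pred, as_labels = TRUE)
      ref <- read_volume(args$ref, as_labels = TRUE)
      write.csv(evaluate_segmentation(pred, ref,
                                      case = args$case %||% "case"),
                args$out, row.names = FALSE)
    },
    rubric = {
      need(c("pred", "ref", "out"))
      pred <- read_volume(args$pred, as_labels = TRUE)
      ref <- read_volume(args$ref, as_labels = TRUE)
      qr <- quality_report(pred, ref)
      jsonlite::write_json(list(schema = SCHEMA, overall = qr$overall,
                                fault = qr$fault, shifts = qr$shifts),
                           args$out, digits = NA, auto_unbox = TRUE,
                           dataframe = "rows")
    },
    localize = {
      need(c("pred", "lesions", "out"))
      pred <- read_volume(args$pred, as_labels = TRUE)
      lesions <- read_lesions(args$lesions, pred)
      res <- localization_accuracy(lesions, pred)
      rows <- do.call(rbind, lapply(res$lesions, function(l) {
        data.frame(id = l$id, diameter_mm = l$diameter_mm,
                   true_segments = paste(l$true_segments, collapse = "+"),
                   assigned_segments = paste(l$assigned_segments,
                                             collapse = "+"),
                   correct = identical(l$assigned_segments,
                                       l$true_segments))
      }))
      write.csv(rows, args$out, row.names = FALSE)
    },
    stop("unknown command: ", command,
         " (expected phantom, label, train, predict, evaluate, rubric, ",
         "localize)")
  )
  invisible(0L)
}
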