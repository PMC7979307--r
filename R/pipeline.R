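#' Full run configuration
#'
#' Bundles the stage configurations of the end-to-end pipeline. Every
#' stage's seed is derived deterministically from the single global seed, so
#' a rerun with the same configuration reproduces the manifest and training
#' history.
#'
#' @param architecture architecture name for [canonical_description()].
#' @param phantom a [phantom_config()]; its `edge` must match the
#'   architecture input.
#' @param train a [train_config()].
#' @param n_positive,n_negative phantom counts per class.
#' @param train_fraction,validation_fraction split fractions
#'   (see [make_splits()]).
#' @param seed global integer seed.
#' @param output_dir run directory to create.
#' @param volume_format `"nii.gz"` or `"nrrd"` for written volumes.
#' @return An object of class `run_config`.
#' @export
run_config <- function(architecture = "proposed3d",
                       phantom = phantom_config(),
                       train = train_config(),
                       n_positive = 200L, n_negative = 200L,
                       train_fraction = 0.7, validation_fraction = 0.1,
                       seed = 1L, output_dir = tempfile("nodulecam_run_"),
                       volume_format = c("nii.gz", "nrrd")) {
  stopifnot(inherits(phantom, "phantom_config"), inherits(train, "train_config"))
  volume_format <- match.arg(volume_format)
  structure(list(architecture = architecture, phantom = phantom, train = train,
                 n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative),
                 train_fraction = train_fraction,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed), output_dir = output_dir,
                 volume_format = volume_format),
            class = "run_config")
}

# Deterministic per-stage seed from the global seed (kept below 2^31).
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 92821) %% 2147483647)
}

#' Run the whole study pipeline
#'
#' Executes generate -> split -> train -> validate -> evaluate -> explain in
#' order, writing every artifact under the run's output directory: the
#' phantom volumes and masks, the manifest CSV, the serialized architecture
#' description, the trained checkpoint, the training history CSV, metrics
#' JSON for the validation and held-out test splits, an ROC point CSV,
#' Grad-CAM heatmaps (NIfTI) with mid-slice PNG overlays for a few
#' true-positive test volumes, and a JSON provenance log listing every
#' output file with its MD5 content hash. A stage failure aborts with the
#' stage name; artifacts of completed stages are retained.
#'
#' @param config a [run_config()].
#' @param n_explain number of true-positive test volumes to explain.
#' @param verbose print stage progress.
#' @return The output directory path, invisibly; the provenance log is
#'   `run_log.json` inside it.
#' @export
pipeline_run <- function(config, n_explain = 3L, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "volumes"), showWarnings = FALSE)
  dir.create(file.path(out, "heatmaps"), showWarnings = FALSE)
  say <- function(...) if (verbose) message(...)
  stage <- "generate"
  artifacts <- character(0)
  note <- function(p) artifacts <<- c(artifacts, p)
  tryCatch({
    say("stage: generate")
    ds <- generate_dataset(config$phantom, config$n_positive, config$n_negative,
                           derive_seed(config$seed, "generate"))
    n <- length(ds$samples)

    stage <- "split"
    say("stage: split")
    splits <- make_splits(ds$labels, config$train_fraction,
                          config$validation_fraction,
                          derive_seed(config$seed, "split"))
    ext <- config$volume_format
    paths <- file.path("volumes", sprintf("sample_%04d.%s", seq_len(n), ext))
    for (i in seq_len(n)) {
      write_volume(ds$samples[[i]]$volume, file.path(out, paths[i]))
      if (ds$labels[i] == 1) {
        mp <- sub(sprintf("\\.%s$", gsub(".", "\\.", ext, fixed = TRUE)),
                  paste0("_mask.", ext), paths[i])
        write_volume(ds$samples[[i]]$mask + 0, file.path(out, mp))
        note(mp)
      }
      note(paths[i])
    }
    manifest <- data.frame(path = paths, label = ds$labels,
                           split = splits$split, seed = ds$seeds)
    write_manifest(manifest, file.path(out, "manifest.csv"))
    note("manifest.csv")

    stage <- "build"
    say("stage: build")
    desc <- canonical_description(config$architecture)
    write_description(desc, file.path(out, "architecture.yaml"))
    note("architecture.yaml")
    model <- build_model(desc, derive_seed(config$seed, "init"))

    stage <- "train"
    say("stage: train")
    fit <- train(model, ds, splits, config$train, verbose = verbose)
    saveRDS(fit$model, file.path(out, "checkpoint.rds"))
    note("checkpoint.rds")
    utils::write.csv(as.data.frame(fit$history),
                     file.path(out, "history.csv"), row.names = FALSE)
    note("history.csv")

    stage <- "validate"
    say("stage: validate")
    vrep <- validate(fit$model, ds, splits)
    write_metrics_json(vrep, file.path(out, "metrics_validation.json"))
    note("metrics_validation.json")

    stage <- "evaluate"
    say("stage: evaluate")
    trep <- evaluate_test(fit$model, ds, splits)
    write_metrics_json(trep, file.path(out, "metrics_test.json"))
    note("metrics_test.json")
    roc <- roc_auc(attr(trep, "labels"), attr(trep, "probabilities"))$roc
    utils::write.csv(roc, file.path(out, "roc_test.csv"), row.names = FALSE)
    note("roc_test.csv")

    stage <- "explain"
    say("stage: explain")
    te <- which(splits$split == "test")
    probs <- attr(trep, "probabilities")
    tp <- te[ds$labels[te] == 1 & probs >= 0.5]
    # nothing confidently detected (e.g. a smoke run): explain positives anyway
    if (length(tp) == 0L) tp <- te[ds$labels[te] == 1]
    for (i in utils::head(tp, n_explain)) {
      hm <- grad_cam(fit$model, ds$samples[[i]]$volume, class_index = 1L)
      hp <- file.path("heatmaps", sprintf("heatmap_%04d.%s", i, ext))
      write_volume(hm$upsampled, file.path(out, hp))
      note(hp)
      for (ax in 1:3) {
        img <- overlay(ds$samples[[i]]$volume, hm, slice_axis = ax)
        pp <- file.path("heatmaps", sprintf("overlay_%04d_axis%d.png", i, ax))
        png::writePNG(img, file.path(out, pp))
        note(pp)
      }
    }

    stage <- "log"
    log <- list(
      seed = config$seed,
      architecture = config$architecture,
      phantom = unclass(config$phantom),
      train = unclass(config$train),
      counts = as.list(attr(splits, "counts")),
      best_epoch = attr(fit$history, "best_epoch"),
      r_version = as.character(getRversion()),
      package_version = as.character(utils::packageVersion("nodulecam")),
      artifacts = lapply(artifacts, function(p)
        list(path = p, md5 = unname(tools::md5sum(file.path(out, p))))))
    jsonlite::write_json(log, file.path(out, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(out)
}

write_metrics_json <- function(report, path) {
  x <- report[c("accuracy", "precision", "recall", "specificity", "fpr", "f1")]
  x$auc <- report$auc
  x$counts <- report$counts[c("tp", "fp", "fn", "tn")]
  x$threshold <- report$threshold
  x$undefined <- report$undefined
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
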