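#' Configuration for the synthetic nodule-phantom generator
#'
#' The generator emulates, at desk scale, the balanced nodule / non-nodule
#' volume dichotomy of CT candidate screening: cubic single-channel volumes
#' containing one bright quasi-spherical (axis-aligned ellipsoidal) nodule
#' for positives, vessel-like bright cylinders as distractors in both
#' classes, and additive Gaussian noise. Intensities are abstract floats (no
#' Hounsfield calibration); structures combine by voxelwise maximum, as for
#' tissue of one attenuation class.
#'
#' @param edge volume edge length in voxels. 27 matches the proposed 3D
#'   network's input; use 32 for the AlexNet-style baselines.
#' @param nodule_radius_range per-axis ellipsoid semi-axis range in voxels.
#' @param nodule_contrast peak nodule intensity above background (intensity
#'   falls to half the peak at the nodule boundary).
#' @param vessel_count_range number of cylinder distractors per volume.
#' @param vessel_radius_range cylinder radius range in voxels.
#' @param vessel_contrast peak vessel intensity above background; kept below
#'   `nodule_contrast` so the classes stay separable when noise-free.
#' @param noise_sd additive Gaussian noise standard deviation (>= 0).
#' @param background base intensity level.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(edge = 27L,
                           nodule_radius_range = c(3, 6),
                           nodule_contrast = 1,
                           vessel_count_range = c(1L, 3L),
                           vessel_radius_range = c(0.8, 1.5),
                           vessel_contrast = 0.6,
                           noise_sd = 0.05,
                           background = 0.1) {
  if (max(nodule_radius_range) >= edge / 2)
    stop("infeasible nodule radius range: max radius must be < edge/2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(edge = as.integer(edge),
                 nodule_radius_range = nodule_radius_range,
                 nodule_contrast = nodule_contrast,
                 vessel_count_range = as.integer(vessel_count_range),
                 vessel_radius_range = vessel_radius_range,
                 vessel_contrast = vessel_contrast,
                 noise_sd = noise_sd,
                 background = background),
            class = "phantom_config")
}

#' Noise-free easy configuration
#'
#' Convenience preset: the default geometry with `noise_sd = 0`, under which
#' an intensity-threshold baseline separates the classes perfectly and
#' trained-model tests are well-posed.
#' @param ... overrides passed to [phantom_config()].
#' @return A `phantom_config`.
#' @export
phantom_config_easy <- function(...) phantom_config(noise_sd = 0, ...)

.grid_cache <- new.env(parent = emptyenv())

voxel_grid <- function(edge) {
  key <- as.character(edge)
  g <- .grid_cache[[key]]
  if (is.null(g)) {
    ax <- seq_len(edge)
    g <- list(x = array(rep(ax, times = edge * edge), c(edge, edge, edge)),
              y = array(rep(ax, each = edge, times = edge), c(edge, edge, edge)),
              z = array(rep(ax, each = edge * edge), c(edge, edge, edge)))
    .grid_cache[[key]] <- g
  }
  g
}

# Intensity footprint of one axis-aligned ellipsoid with quadratic falloff:
# contrast * (1 - rho^2 / 2) inside the boundary rho <= 1, zero outside.
ellipsoid_profile <- function(edge, center, radii, contrast) {
  g <- voxel_grid(edge)
  rho2 <- ((g$x - center[1]) / radii[1])^2 +
          ((g$y - center[2]) / radii[2])^2 +
          ((g$z - center[3]) / radii[3])^2
  contrast * (1 - rho2 / 2) * (rho2 <= 1)
}

# Cylinder of given radius around an arbitrary line through `point` with unit
# direction `dir`, quadratic falloff like the ellipsoid.
cylinder_profile <- function(edge, point, dir, radius, contrast) {
  g <- voxel_grid(edge)
  vx <- g$x - point[1]; vy <- g$y - point[2]; vz <- g$z - point[3]
  # squared distance to line = |v|^2 - (v . dir)^2
  proj <- vx * dir[1] + vy * dir[2] + vz * dir[3]
  d2 <- pmax(vx^2 + vy^2 + vz^2 - proj^2, 0)
  rho2 <- d2 / radius^2
  contrast * (1 - rho2 / 2) * (rho2 <= 1)
}

#' Generate one labeled phantom volume
#'
#' A positive sample carries one bright quasi-spherical nodule at a uniformly
#' random interior position (plus vessel distractors); a negative sample
#' carries distractors only. The returned ground-truth mask is exactly the
#' nodule's ellipsoid footprint, and every mask voxel's noise-free intensity
#' exceeds the background. Identical `(config, label, seed)` produce a
#' bit-identical volume.
#'
#' @param config a [phantom_config()].
#' @param label 0 (non-nodule) or 1 (nodule).
#' @param seed integer seed.
#' @return An object of class `phantom_sample` with fields `volume` (edge^3
#'   array), `label`, `mask` (logical array, empty iff label 0) and
#'   `provenance`.
#' @export
#' @examples
#' s <- generate_sample(phantom_config_easy(), label = 1, seed = 7)
#' sum(s$mask) > 0
generate_sample <- function(config, label, seed) {
  stopifnot(inherits(config, "phantom_config"), label %in% c(0, 1))
  e <- config$edge
  run_seeded(seed, {
    vol <- array(0, c(e, e, e))
    mask <- array(FALSE, c(e, e, e))
    if (label == 1) {
      radii <- runif(3, config$nodule_radius_range[1], config$nodule_radius_range[2])
      lo <- ceiling(radii) + 1
      hi <- e - ceiling(radii)
      center <- runif(3, lo, hi)
      nod <- ellipsoid_profile(e, center, radii, config$nodule_contrast)
      vol <- pmax(vol, nod)
      mask <- nod > 0
    }
    nv <- if (config$vessel_count_range[1] == config$vessel_count_range[2])
      config$vessel_count_range[1]
    else sample(config$vessel_count_range[1]:config$vessel_count_range[2], 1L)
    if (nv > 0) for (v in seq_len(nv)) {
      point <- runif(3, 1, e)
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      radius <- runif(1, config$vessel_radius_range[1], config$vessel_radius_range[2])
      vol <- pmax(vol, cylinder_profile(e, point, dir, radius, config$vessel_contrast))
    }
    vol <- vol + config$background
    if (config$noise_sd > 0) vol <- vol + rnorm(length(vol), 0, config$noise_sd)
    structure(list(volume = vol, label = as.integer(label), mask = mask,
                   provenance = list(config = config, seed = as.integer(seed),
                                     label = as.integer(label))),
              class = "phantom_sample")
  })
}

#' Generate a balanced (or arbitrary-count) phantom dataset
#'
#' Draws per-sample seeds deterministically from `seed`, generates the
#' requested number of positive and negative samples, and randomizes their
#' order. The same `(config, counts, seed)` reproduce the dataset bit-exactly.
#'
#' @param config a [phantom_config()].
#' @param n_positive,n_negative sample counts per class (>= 1).
#' @param seed integer seed.
#' @return An object of class `phantom_dataset`: list with `samples` (list of
#'   [generate_sample()] results), `labels`, `seeds` and `config`.
#' @export
generate_dataset <- function(config, n_positive, n_negative, seed) {
  stopifnot(n_positive >= 1, n_negative >= 1)
  n <- n_positive + n_negative
  run_seeded(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    labels <- c(rep(1L, n_positive), rep(0L, n_negative))
    ord <- sample.int(n)
    labels <- labels[ord]
    samples <- lapply(seq_len(n), function(i)
      generate_sample(config, labels[i], seeds[i]))
    structure(list(samples = samples, labels = labels, seeds = seeds,
                   config = config, seed = as.integer(seed)),
              class = "phantom_dataset")
  })
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset> %d samples (%d nodule / %d non-nodule), edge %d\n",
              length(x$samples), sum(x$labels == 1), sum(x$labels == 0),
              x$config$edge))
  invisible(x)
}

#' Stratified train / validation / test assignment
#'
#' Follows the holdout study design: the test set is carved out first
#' (`1 - train_fraction` of all volumes), then the stated fraction of the
#' training volumes is set aside for validation and removed from the
#' effective training set. Assignment is stratified by label so each split's
#' class balance is within one sample of the global ratio. On a balanced
#' 2,000-volume set with `train_fraction = 0.7` and
#' `validation_fraction = 0.1` this yields 1,400 train (140 of which become
#' validation, leaving 1,260 effective) and 600 test volumes.
#'
#' @param labels 0/1 vector, one entry per sample.
#' @param train_fraction fraction of all samples assigned to training
#'   (validation included) — the remainder is the test set.
#' @param validation_fraction fraction of the training samples held out for
#'   validation.
#' @param seed integer seed.
#' @return An object of class `split_manifest`: a `data.frame` with columns
#'   `sample` and `split` (`"train"`, `"validation"`, `"test"`), with a
#'   `counts` attribute.
#' @export
#' @examples
#' sp <- make_splits(rep(0:1, 1000), 0.7, 0.1, seed = 1)
#' attr(sp, "counts")
make_splits <- function(labels, train_fraction = 0.7, validation_fraction = 0.1,
                        seed = 1L) {
  n <- length(labels)
  stopifnot(n >= 2, all(labels %in% c(0, 1)),
            train_fraction > 0, train_fraction <= 1,
            validation_fraction >= 0, validation_fraction < 1)
  n_train_total <- round(train_fraction * n)
  n_val <- round(validation_fraction * n_train_total)
  if (n_train_total - n_val < 1 || (train_fraction < 1 && n - n_train_total < 1))
    stop("split smaller than one sample")
  split <- rep(NA_character_, n)
  run_seeded(seed, {
    # stratify: allocate per class by largest remainder so totals are exact
    alloc <- function(n_needed, sizes) {
      raw <- n_needed * sizes / sum(sizes)
      base <- floor(raw)
      rem <- n_needed - sum(base)
      if (rem > 0) {
        extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1L
      }
      base
    }
    classes <- sort(unique(labels))
    sizes <- vapply(classes, function(k) sum(labels == k), numeric(1))
    tr_c <- alloc(n_train_total, sizes)
    pool_train <- integer(0)
    for (j in seq_along(classes)) {
      idx <- which(labels == classes[j])
      tr <- sample(idx, tr_c[j])
      split[setdiff(idx, tr)] <- "test"
      pool_train <- c(pool_train, tr)
    }
    trlab <- labels[pool_train]
    va_c <- alloc(n_val, vapply(classes, function(k) sum(trlab == k), numeric(1)))
    for (j in seq_along(classes)) {
      idx <- pool_train[trlab == classes[j]]
      va <- if (va_c[j] > 0) sample(idx, va_c[j]) else integer(0)
      split[va] <- "validation"
      split[setdiff(idx, va)] <- "train"
    }
  })
  out <- data.frame(sample = seq_len(n), split = split)
  class(out) <- c("split_manifest", "data.frame")
  attr(out, "counts") <- table(factor(split, c("train", "validation", "test")))
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Intensity-threshold baseline score
#'
#' The maximum voxel intensity of each volume — the score of the trivial
#' "is anything brighter than a vessel present?" classifier. Under a
#' noise-free configuration with nodule contrast above vessel contrast this
#' separates the classes perfectly; it serves as the separability oracle for
#' trained-model tests.
#'
#' @param volumes list of volumes / `phantom_sample`s, or a batch array.
#' @return Numeric score vector (higher = more nodule-like).
#' @export
threshold_baseline <- function(volumes) {
  if (inherits(volumes, "phantom_dataset")) volumes <- volumes$samples
  if (is.list(volumes))
    vapply(volumes, function(v) {
      if (inherits(v, "phantom_sample")) v <- v$volume
      max(v)
    }, numeric(1))
  else apply(volumes, length(dim(volumes)), max)
}
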