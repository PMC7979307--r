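#' Global average pooling of feature maps
#'
#' Reduces each feature map to the arithmetic mean of its spatial entries
#' (the average-pooled global output `J^p` of map `p` over its `z` spatial
#' positions).
#'
#' @param activations array whose last dimension indexes feature maps and
#'   whose leading dimensions are spatial, or a matrix
#'   (positions x maps), or a vector (one map).
#' @return Numeric vector of per-map means.
#' @export
#' @examples
#' global_average_pool(array(0:7, c(2, 2, 2, 1)))  # 3.5
global_average_pool <- function(activations) {
  if (length(activations) == 0) stop("empty feature map")
  if (is.null(dim(activations))) return(mean(activations))
  d <- dim(activations)
  apply(activations, length(d), mean)
}

#' Grad-CAM feature-map weights from class-score gradients
#'
#' One weight per feature map: the sum of the gradient of the target class
#' score with respect to every spatial entry of that map. (Averaging instead
#' of summing rescales every weight by the constant spatial size only, which
#' min-max normalization of the heatmap absorbs.)
#'
#' @param gradients array shaped like the activations (last dimension =
#'   feature maps), matrix (positions x maps), or vector (one map).
#' @param mode `"sum"` (the definition) or `"mean"` (the 1/z variant).
#' @return Numeric vector of per-map weights.
#' @export
#' @examples
#' class_weights(array(c(1, 2, 3, 4), c(2, 2, 1)))  # 10
class_weights <- function(gradients, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  f <- if (mode == "sum") sum else mean
  if (is.null(dim(gradients))) return(f(gradients))
  d <- dim(gradients)
  apply(gradients, length(d), f)
}

relu <- function(x) pmax(x, 0)

# Affine receptive-field mapping from a layer's output grid to input voxel
# coordinates: cell c (0-based) of the target layer is centred at
# input coordinate scale * c + offset, per axis. Composed over the conv and
# pool layers below the target; batchnorm/dropout are spatially inert.
receptive_field_map <- function(compiled, target_layer) {
  ax <- c(scale = 1, offset = 0)
  az <- c(scale = 1, offset = 0)
  for (li in seq(target_layer, 1L)) {
    kind <- compiled$desc[li, 1]
    if (!kind %in% c(1L, 3L)) next   # conv or pool only
    kx <- compiled$desc[li, 4]; kz <- compiled$desc[li, 5]
    s <- compiled$desc[li, 6]; sz <- compiled$desc[li, 7]
    plo <- compiled$desc[li, 8]; plo_z <- compiled$desc[li, 10]
    ax <- c(scale = s * ax[["scale"]],
            offset = s * ax[["offset"]] + (kx - 1) / 2 - plo)
    az <- c(scale = sz * az[["scale"]],
            offset = sz * az[["offset"]] + (kz - 1) / 2 - plo_z)
  }
  list(x = ax, z = az)
}

# Resample a target-grid map onto the input grid using the receptive-field
# mapping (linear interpolation between cell centres, clamped at the rim).
resample_to_input <- function(cam, in_dim, rf) {
  d <- dim(cam)
  coords <- lapply(1:3, function(a) {
    m <- if (a == 3) rf$z else rf$x
    src <- (seq_len(in_dim[a]) - 1 - m[["offset"]]) / m[["scale"]]
    src <- pmin(pmax(src, 0), d[a] - 1)
    lo <- pmin(floor(src), d[a] - 1)
    list(lo = lo + 1, hi = pmin(lo + 1, d[a] - 1) + 1, w = src - lo)
  })
  cx <- coords[[1]]; cy <- coords[[2]]; cz <- coords[[3]]
  gx <- function(iy, iz) {
    a <- cam[cx$lo, iy, iz, drop = FALSE]
    b <- cam[cx$hi, iy, iz, drop = FALSE]
    a * (1 - cx$w) + b * cx$w
  }
  gy <- function(iz) {
    a <- gx(cy$lo, iz); b <- gx(cy$hi, iz)
    sweep(a, 2, 1 - cy$w, "*") + sweep(b, 2, cy$w, "*")
  }
  a <- gy(cz$lo); b <- gy(cz$hi)
  sweep(a, 3, 1 - cz$w, "*") + sweep(b, 3, cz$w, "*")
}

# Trilinear (bilinear when an axis is degenerate) resampling of a 3D array
# onto a target grid, with half-voxel center alignment.
upsample_linear <- function(arr, out_dim) {
  d <- dim(arr)
  coords <- lapply(1:3, function(a) {
    if (out_dim[a] == d[a]) return(list(lo = seq_len(d[a]), hi = seq_len(d[a]), w = rep(0, d[a])))
    src <- (seq_len(out_dim[a]) - 0.5) * d[a] / out_dim[a] - 0.5
    src <- pmin(pmax(src, 0), d[a] - 1)
    lo <- floor(src)
    w <- src - lo
    list(lo = pmin(lo, d[a] - 1) + 1, hi = pmin(lo + 1, d[a] - 1) + 1, w = w)
  })
  cx <- coords[[1]]; cy <- coords[[2]]; cz <- coords[[3]]
  out <- array(0, out_dim)
  # blend along x for both y/z corner pairs, then along y, then z
  mix <- function(ix, iy, iz) arr[ix, iy, iz, drop = FALSE]
  gx <- function(iy, iz) {
    a <- arr[cx$lo, iy, iz, drop = FALSE]
    b <- arr[cx$hi, iy, iz, drop = FALSE]
    a * (1 - cx$w) + b * cx$w
  }
  gy <- function(iz) {
    a <- gx(cy$lo, iz)
    b <- gx(cy$hi, iz)
    sweep(a, 2, 1 - cy$w, "*") + sweep(b, 2, cy$w, "*")
  }
  a <- gy(cz$lo)
  b <- gy(cz$hi)
  out <- sweep(a, 3, 1 - cz$w, "*") + sweep(b, 3, cz$w, "*")
  out
}

#' Gradient-weighted class activation map for a volume
#'
#' Computes the Grad-CAM saliency of a target class at a convolutional
#' layer: the class score (pre-softmax, as the derivation differentiates the
#' score directly) is backpropagated to the layer's feature maps, each map
#' is weighted by the summed gradient ([class_weights()]), the weighted maps
#' are summed and rectified —
#' `L = ReLU(sum_k alpha_k^c A^k)` —
#' then resampled to the input resolution and min-max normalized.
#' Recomputation on identical inputs is bit-identical.
#'
#' @param model a `cnn_model` (trained or not).
#' @param volume a single input volume (matching the model input shape).
#' @param class_index target class, 0 (non-nodule) or 1 (nodule).
#' @param target_layer index of a convolution layer in the description, or
#'   `NULL` for the last convolution layer (the standard choice: the finest
#'   semantic grid).
#' @param weight_mode `"sum"` (definition) or `"mean"`; normalized heatmaps
#'   are identical under either.
#' @return An object of class `gradcam_heatmap`: `values` (raw, target-layer
#'   grid), `upsampled` (input grid, min-max normalized to `[0, 1]` with max
#'   exactly 1 whenever any raw value is positive), `weights`, `activations`,
#'   `gradients`, `scores`, `target_layer` and `normalization`.
#' @export
grad_cam <- function(model, volume, class_index = 1L, target_layer = NULL,
                     weight_mode = c("sum", "mean")) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(inherits(model, "cnn_model"))
  if (!class_index %in% c(0L, 1L)) stop("class index out of range")
  convs <- conv_layer_indices(model$description)
  if (is.null(target_layer)) target_layer <- max(convs)
  if (!target_layer %in% convs)
    stop("target layer ", target_layer, " is not a convolution layer")
  x <- as_batch_matrix(model, volume)
  tap <- cpp_gradcam(model$compiled$desc, model$compiled$drop,
                     model$theta, model$state, x[, 1], as.integer(class_index),
                     as.integer(target_layer))
  # engine returns (channels, x, y, z); reorder to spatial-first
  A <- aperm(tap$activations, c(2, 3, 4, 1))
  G <- aperm(tap$gradients, c(2, 3, 4, 1))
  w <- class_weights(G, mode = weight_mode)
  nmap <- dim(A)[4]
  cam <- array(0, dim(A)[1:3])
  for (k in seq_len(nmap)) cam <- cam + w[k] * A[, , , k]
  cam <- relu(cam)
  ndim <- model$compiled$ndim
  in_sp <- model$description$input_shape[seq_len(ndim)]
  if (ndim == 2L) in_sp <- c(in_sp, 1L)
  up <- resample_to_input(cam, in_sp, receptive_field_map(model$compiled, target_layer))
  mx <- max(up)
  upn <- if (mx > 0) up / mx else up
  structure(list(values = cam, upsampled = upn, weights = w,
                 activations = A, gradients = G, scores = tap$scores,
                 target_layer = target_layer, class_index = as.integer(class_index),
                 normalization = "minmax"),
            class = "gradcam_heatmap")
}

#' @export
print.gradcam_heatmap <- function(x, ...) {
  cat(sprintf("<gradcam_heatmap> class %d, layer %d, grid %s, max raw %.4g\n",
              x$class_index, x$target_layer,
              paste(dim(x$values), collapse = "x"), max(x$values)))
  invisible(x)
}

#' Closed-form CAM for a GAP + linear network
#'
#' For a network whose classifier head is global average pooling followed by
#' a single dense layer, the class activation map is available in closed
#' form: the dense weights of the target class serve directly as feature-map
#' weights, `CAM = ReLU(sum_k W[class, k] A^k)`. Grad-CAM is the strict
#' generalization of this map, and on such networks the two normalized maps
#' coincide — the property used as this module's correctness oracle.
#'
#' @param model a `cnn_model` whose layer sequence ends
#'   `conv -> avgpool_global -> flatten -> dense`.
#' @param volume a single input volume.
#' @param class_index target class (0 or 1).
#' @return List with `values` (raw CAM on the conv grid) and `normalized`.
#' @export
cam_reference <- function(model, volume, class_index = 1L) {
  desc <- model$description
  kinds <- vapply(desc$layers, function(l) l$kind, character(1))
  nl <- length(kinds)
  if (!(kinds[nl] == "dense" &&
        any(kinds[seq_len(nl - 1)] == "avgpool_global")))
    stop("cam_reference needs a GAP + single dense head")
  conv_i <- max(conv_layer_indices(desc))
  tap <- cpp_gradcam(model$compiled$desc, model$compiled$drop, model$theta,
                     model$state, as_batch_matrix(model, volume)[, 1],
                     as.integer(class_index), as.integer(conv_i))
  A <- aperm(tap$activations, c(2, 3, 4, 1))
  # dense weight matrix: out x in, row class_index + 1
  di <- nl
  to <- model$compiled$desc[di, 19] + 1L
  out_c <- model$compiled$desc[di, 3]; in_c <- model$compiled$desc[di, 2]
  W <- matrix(model$theta[to:(to + out_c * in_c - 1L)], out_c, in_c)
  w <- W[class_index + 1L, ]
  cam <- array(0, dim(A)[1:3])
  for (k in seq_along(w)) cam <- cam + w[k] * A[, , , k]
  cam <- relu(cam)
  mx <- max(cam)
  list(values = cam, normalized = if (mx > 0) cam / mx else cam)
}

#' Blend a heatmap slice over a grayscale volume slice
#'
#' Extracts one slice of the volume and of the (input-resolution) heatmap,
#' contrast-scales the volume slice to `[0, 1]`, color-maps the saliency,
#' and alpha-blends the two with a per-pixel opacity proportional to the
#' saliency: a zero heatmap returns the grayscale slice untouched, a
#' saturated heatmap at `alpha = 1` returns pure colormap.
#'
#' @param volume input volume.
#' @param heatmap a [grad_cam()] result (or an array at volume resolution).
#' @param slice_axis 1, 2 or 3.
#' @param slice_index slice position along that axis (default: middle).
#' @param alpha maximum overlay opacity in `[0, 1]`.
#' @param palette colormap name passed to [grDevices::hcl.colors()].
#' @return An `height x width x 3` RGB array in `[0, 1]`.
#' @export
overlay <- function(volume, heatmap, slice_axis = 3L, slice_index = NULL,
                    alpha = 0.5, palette = "Inferno") {
  h <- if (inherits(heatmap, "gradcam_heatmap")) heatmap$upsampled else heatmap
  if (length(dim(volume)) == 2L) volume <- array(volume, c(dim(volume), 1L))
  if (length(dim(h)) == 2L) h <- array(h, c(dim(h), 1L))
  if (!identical(dim(h), dim(volume)))
    stop("heatmap must be upsampled to the volume resolution")
  if (!slice_axis %in% 1:3) stop("slice_axis must be 1, 2 or 3")
  n <- dim(volume)[slice_axis]
  if (is.null(slice_index)) slice_index <- (n + 1L) %/% 2L
  if (slice_index < 1 || slice_index > n) stop("slice index out of bounds")
  take <- function(a) switch(slice_axis,
                             a[slice_index, , ], a[, slice_index, ], a[, , slice_index])
  g <- take(volume); s <- take(h)
  rng <- range(g)
  g <- if (diff(rng) > 0) (g - rng[1]) / diff(rng) else g * 0
  cmap <- grDevices::hcl.colors(256L, palette)
  rgbm <- grDevices::col2rgb(cmap) / 255
  ci <- pmin(pmax(floor(s * 255) + 1L, 1L), 256L)
  out <- array(0, c(dim(g), 3L))
  a <- alpha * s
  for (ch in 1:3)
    out[, , ch] <- (1 - a) * g + a * matrix(rgbm[ch, ci], nrow(g), ncol(g))
  out
}
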