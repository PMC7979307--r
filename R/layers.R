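#' Declarative layer specification
#'
#' A `layer_spec` describes one layer of a network declaratively: what it is,
#' its channel transition, kernel geometry, padding mode and activation. The
#' trainable parameter count of a spec is a pure function of
#' `(kind, in_channels, out_channels, kernel, bias)` and never depends on the
#' spatial extent of the input.
#'
#' @param kind one of `"conv2d"`, `"conv3d"`, `"batchnorm"`, `"maxpool2d"`,
#'   `"maxpool3d"`, `"flatten"`, `"avgpool_global"`, `"dense"`, `"dropout"`.
#' @param in_channels,out_channels channel counts (equal for channel-preserving
#'   kinds; for `dense` they are the input and output widths).
#' @param kernel cubic/square kernel edge length in voxels; required for
#'   conv/pool kinds and disallowed otherwise.
#' @param stride step of the kernel; defaults to 1 for convolutions and to the
#'   kernel edge for pooling layers.
#' @param padding `"same"` (spatial extent preserved at stride 1) or
#'   `"valid"` (no padding).
#' @param activation `"relu"` or `"none"`, applied at the layer output.
#' @param dropout_rate fraction of units dropped during training (dropout
#'   layers only).
#' @param bias whether conv/dense layers carry a bias vector.
#' @return An object of class `layer_spec`.
#' @seealso [count_parameters()], [network_description()]
#' @export
#' @examples
#' layer_spec("conv3d", in_channels = 1, out_channels = 16, kernel = 6)
layer_spec <- function(kind,
                       in_channels = NULL, out_channels = NULL,
                       kernel = NULL, stride = NULL,
                       padding = c("valid", "same"),
                       activation = c("none", "relu"),
                       dropout_rate = NULL, bias = TRUE) {
  kinds <- c("conv2d", "conv3d", "batchnorm", "maxpool2d", "maxpool3d",
             "flatten", "avgpool_global", "dense", "dropout")
  if (!is.character(kind) || length(kind) != 1L || !kind %in% kinds)
    stop("invalid layer spec: unknown kind ",
         deparse(substitute(kind)), " (", paste(kind, collapse = ","), ")")
  padding <- match.arg(padding)
  activation <- match.arg(activation)
  windowed <- kind %in% c("conv2d", "conv3d", "maxpool2d", "maxpool3d")
  if (windowed) {
    if (is.null(kernel) || kernel < 1 || kernel != round(kernel))
      stop("invalid layer spec: '", kind, "' needs an integer kernel >= 1")
    if (is.null(stride))
      stride <- if (kind %in% c("maxpool2d", "maxpool3d")) kernel else 1L
  } else {
    if (!is.null(kernel))
      stop("invalid layer spec: kernel is only meaningful for conv/pool kinds")
    stride <- 1L
  }
  if (kind == "dropout") {
    if (is.null(dropout_rate)) dropout_rate <- 0.5
    if (dropout_rate < 0 || dropout_rate > 1)
      stop("invalid layer spec: dropout_rate must lie in [0, 1]")
  } else if (!is.null(dropout_rate)) {
    stop("invalid layer spec: dropout_rate only applies to dropout layers")
  }
  if (kind %in% c("conv2d", "conv3d", "dense")) {
    if (is.null(in_channels) || is.null(out_channels))
      stop("invalid layer spec: '", kind, "' needs in_channels and out_channels")
    if (out_channels < 1) stop("invalid layer spec: out_channels must be >= 1")
  }
  if (kind == "batchnorm" && is.null(out_channels)) {
    if (is.null(in_channels))
      stop("invalid layer spec: batchnorm needs its channel count")
    out_channels <- in_channels
  }
  structure(
    list(kind = kind,
         in_channels = if (is.null(in_channels)) NA_integer_ else as.integer(in_channels),
         out_channels = if (is.null(out_channels)) NA_integer_ else as.integer(out_channels),
         kernel = if (is.null(kernel)) NA_integer_ else as.integer(kernel),
         stride = as.integer(stride),
         padding = padding,
         activation = activation,
         dropout_rate = if (is.null(dropout_rate)) NA_real_ else dropout_rate,
         bias = isTRUE(bias)),
    class = "layer_spec")
}

#' @export
print.layer_spec <- function(x, ...) {
  cat(sprintf("<layer_spec> %s", x$kind))
  if (!is.na(x$in_channels)) cat(sprintf(" %d->%d", x$in_channels, x$out_channels))
  if (!is.na(x$kernel)) cat(sprintf(" k=%d s=%d %s", x$kernel, x$stride, x$padding))
  if (x$activation != "none") cat(" +", x$activation)
  cat("\n")
  invisible(x)
}

#' Closed-form trainable parameter count of a layer
#'
#' Counts follow the usual conventions of framework model summaries:
#' an N-dimensional convolution holds `kernel^N * in_channels * out_channels`
#' weights plus `out_channels` biases; batch normalization holds 4 values per
#' channel (scale, shift, running mean, running variance); a dense layer holds
#' `in * out + out`; pooling, flatten and dropout layers hold none.
#'
#' @param spec a [layer_spec()].
#' @return Integer parameter count.
#' @export
#' @examples
#' count_parameters(layer_spec("conv3d", 1, 16, kernel = 6))   # 3472
#' count_parameters(layer_spec("batchnorm", 16))               # 64
#' count_parameters(layer_spec("dense", 64, 256))              # 16640
count_parameters <- function(spec) {
  if (!inherits(spec, "layer_spec")) stop("invalid spec: not a layer_spec")
  switch(spec$kind,
    conv2d = spec$kernel^2 * spec$in_channels * spec$out_channels +
      if (spec$bias) spec$out_channels else 0L,
    conv3d = spec$kernel^3 * spec$in_channels * spec$out_channels +
      if (spec$bias) spec$out_channels else 0L,
    batchnorm = 4L * spec$out_channels,
    dense = spec$in_channels * spec$out_channels + spec$out_channels,
    maxpool2d = 0L,
    maxpool3d = 0L,
    flatten = 0L,
    avgpool_global = 0L,
    dropout = 0L,
    stop("invalid spec: unknown kind '", spec$kind, "'")) |> as.integer()
}

#' Recover a kernel edge length from a printed parameter count
#'
#' Published layer tables often print parameter counts but not kernel sizes.
#' For a biased N-dimensional convolution the count determines the kernel
#' uniquely through `k^N * in * out + out = params`; this inverts that
#' relation by brute force over `k = 1..11`. A cell admitting no integer
#' solution is flagged inconsistent (a table typo) rather than guessed at.
#'
#' @param in_channels,out_channels the layer's channel transition.
#' @param printed_params the printed parameter count.
#' @param ndim 2 or 3, the convolution dimensionality.
#' @return A list with elements `kernel` (integer, or `NA` if no solution)
#'   and `consistent` (logical).
#' @export
#' @examples
#' derive_kernel_size(1, 16, 8208, 3)    # k = 8
#' derive_kernel_size(64, 32, 53328, 3)  # inconsistent cell
derive_kernel_size <- function(in_channels, out_channels, printed_params, ndim) {
  if (!ndim %in% c(2, 3)) stop("ndim must be 2 or 3")
  if (in_channels < 1 || out_channels < 1) stop("channel counts must be >= 1")
  ks <- 1:11
  hit <- ks[ks^ndim * in_channels * out_channels + out_channels == printed_params]
  if (length(hit) > 1L)
    stop("internal error: multiple kernel sizes reproduce the printed count")
  if (length(hit) == 0L)
    return(list(kernel = NA_integer_, consistent = FALSE))
  list(kernel = as.integer(hit), consistent = TRUE)
}
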