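# Compilation of a network_description into the integer layer table consumed
# by the C++ engine, plus model construction and prediction.

KIND_CODE <- c(conv2d = 1L, conv3d = 1L, batchnorm = 2L, maxpool2d = 3L,
               maxpool3d = 3L, flatten = 4L, dense = 5L, dropout = 6L,
               avgpool_global = 7L)

# Evaluate the spatial/channel flow of a description and lay out the
# parameter (theta) and batchnorm running-statistics (state) vectors.
compile_description <- function(description) {
  ndim <- length(description$input_shape) - 1L
  sp <- description$input_shape[seq_len(ndim)]
  if (ndim == 2L) sp <- c(sp, 1L)
  chans <- description$input_shape[ndim + 1L]
  nl <- length(description$layers)
  desc <- matrix(0L, nl, 22L)
  drop <- numeric(nl)
  to <- 0L; so <- 0L
  flat <- FALSE
  for (i in seq_len(nl)) {
    l <- description$layers[[i]]
    kind <- KIND_CODE[[l$kind]]
    in_c <- chans; out_c <- chans
    kx <- 0L; kz <- 0L; s <- 1L; sz <- 1L
    plo <- phi <- plo_z <- phi_z <- 0L
    osp <- sp
    tl <- 0L; sl <- 0L
    if (l$kind %in% c("conv2d", "conv3d")) {
      if (!is.na(l$in_channels) && l$in_channels != chans)
        stop(sprintf("layer %d (%s): expects %d input channels, receives %d",
                     i, l$kind, l$in_channels, chans))
      out_c <- l$out_channels
      kx <- l$kernel; s <- l$stride
      is3 <- l$kind == "conv3d"
      kz <- if (is3) kx else 1L
      sz <- if (is3) s else 1L
      if (l$padding == "same") {
        oxy <- as.integer(ceiling(sp[1:2] / s))
        oz <- if (is3) as.integer(ceiling(sp[3] / sz)) else sp[3]
        tot <- max((oxy[1] - 1L) * s + kx - sp[1], 0L)
        plo <- as.integer(tot %/% 2L); phi <- as.integer(tot - plo)
        if (is3) {
          totz <- max((oz - 1L) * sz + kz - sp[3], 0L)
          plo_z <- as.integer(totz %/% 2L); phi_z <- as.integer(totz - plo_z)
        }
        osp <- c(oxy, oz)
      } else {
        osp <- c((sp[1:2] - kx) %/% s + 1L,
                 if (is3) (sp[3] - kz) %/% sz + 1L else sp[3])
      }
      if (any(osp < 1L))
        stop(sprintf("layer %d (%s, kernel %d, valid): spatial extent driven below 1",
                     i, l$kind, kx))
      nk <- kx * kx * kz
      tl <- as.integer(nk * in_c * out_c + out_c)
      chans <- out_c
    } else if (l$kind %in% c("maxpool2d", "maxpool3d")) {
      kx <- l$kernel; s <- l$stride
      is3 <- l$kind == "maxpool3d"
      kz <- if (is3) kx else 1L
      sz <- if (is3) s else 1L
      osp <- c((sp[1:2] - kx) %/% s + 1L,
               if (is3) (sp[3] - kz) %/% sz + 1L else sp[3])
      if (any(osp < 1L))
        stop(sprintf("layer %d (%s, kernel %d): spatial extent driven below 1",
                     i, l$kind, kx))
    } else if (l$kind == "batchnorm") {
      if (!is.na(l$out_channels) && l$out_channels != chans)
        stop(sprintf("layer %d (batchnorm): %d channels expected, %d received",
                     i, l$out_channels, chans))
      out_c <- chans
      tl <- 2L * chans; sl <- 2L * chans
    } else if (l$kind == "avgpool_global") {
      osp <- c(1L, 1L, 1L)
    } else if (l$kind == "flatten") {
      chans <- as.integer(chans * prod(sp))
      in_c <- out_c <- chans   # logical width after flatten; no-op in the engine
      osp <- c(1L, 1L, 1L)
    } else if (l$kind == "dense") {
      width <- as.integer(chans * prod(sp))
      if (l$in_channels != width)
        stop(sprintf("layer %d (dense): consumes %d features, %d available",
                     i, l$in_channels, width))
      in_c <- width; out_c <- l$out_channels
      tl <- as.integer(in_c * out_c + out_c)
      chans <- out_c
      osp <- c(1L, 1L, 1L)
    } else if (l$kind == "dropout") {
      drop[i] <- l$dropout_rate
    }
    desc[i, ] <- c(kind, in_c, out_c, kx, kz, s, sz, plo, phi, plo_z, phi_z,
                   as.integer(l$activation == "relu"),
                   sp, osp, to, tl, so, sl)
    sp <- osp
    to <- to + tl; so <- so + sl
  }
  list(desc = desc, drop = drop, theta_len = to, state_len = so,
       ndim = ndim, n_classes = chans,
       out_spatial = sp,
       input_len = as.integer(prod(description$input_shape)))
}

run_seeded <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Construct a trainable network from a description
#'
#' Allocates and initializes the flat parameter vector for a
#' [network_description()] and records per-layer realized parameter counts.
#' Convolution and dense weights draw from a fan-scaled uniform distribution
#' (limit `sqrt(6 / (fan_in + fan_out))`, capped at magnitude 1) so that every
#' weight has maximum absolute value 1 and activations keep a stable scale at
#' depth; biases start at zero and batch normalization at identity (scale 1,
#' shift 0, running mean 0, running variance 1). The same `(description,
#' seed)` pair always yields bit-identical initial weights.
#'
#' @param description a [network_description()].
#' @param seed integer seed for weight initialization.
#' @return An object of class `cnn_model`: the description, the compiled
#'   layer table, parameter (`theta`) and running-statistics (`state`)
#'   vectors, and `realized_counts` per layer.
#' @export
#' @examples
#' m <- build_model(canonical_description("proposed3d"), seed = 1)
#' sum(m$realized_counts)
build_model <- function(description, seed = 1L) {
  comp <- compile_description(description)
  theta <- numeric(comp$theta_len)
  state <- numeric(comp$state_len)
  run_seeded(seed, {
    for (i in seq_along(description$layers)) {
      l <- description$layers[[i]]
      to <- comp$desc[i, 19] + 1L
      tl <- comp$desc[i, 20]
      if (tl == 0L) next
      if (l$kind %in% c("conv2d", "conv3d", "dense")) {
        out_c <- comp$desc[i, 3]
        nw <- tl - out_c
        fan_in <- nw / out_c
        fan_out <- if (l$kind == "dense") out_c else {
          nk <- comp$desc[i, 4]^2 * comp$desc[i, 5]
          nk * out_c
        }
        lim <- min(1, sqrt(6 / (fan_in + fan_out)))
        theta[to:(to + nw - 1L)] <- stats::runif(nw, -lim, lim)
        # biases stay zero
      } else if (l$kind == "batchnorm") {
        cc <- comp$desc[i, 3]
        theta[to:(to + cc - 1L)] <- 1              # gamma
        so <- comp$desc[i, 21] + 1L
        state[(so + cc):(so + 2L * cc - 1L)] <- 1  # running variance
      }
    }
  })
  structure(list(description = description, compiled = comp,
                 theta = theta, state = state, seed = as.integer(seed),
                 realized_counts = as.integer(comp$desc[, 20] + comp$desc[, 22]),
                 standardize = c(center = 0, scale = 1),
                 trained = FALSE),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> %s  %s parameters (%d trainable)  seed=%d  %s\n",
              x$description$name,
              format(sum(x$realized_counts), big.mark = ","),
              x$compiled$theta_len, x$seed,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# Coerce volumes (single array, list of arrays, or batch array with a
# trailing sample dimension) into the features x batch matrix the engine
# expects, applying the model's stored intensity standardization.
as_batch_matrix <- function(model, volumes) {
  ndim <- model$compiled$ndim
  sp <- model$description$input_shape[seq_len(ndim)]
  if (is.list(volumes)) {
    vols <- lapply(volumes, function(v) if (inherits(v, "phantom_sample")) v$volume else v)
    X <- vapply(vols, function(v) {
      if (!identical(dim(v), as.integer(sp)))
        stop("volume shape ", paste(dim(v), collapse = "x"),
             " does not match model input ", paste(sp, collapse = "x"))
      as.numeric(v)
    }, numeric(prod(sp)))
    if (is.null(dim(X))) X <- matrix(X, ncol = length(vols))
  } else if (is.array(volumes) && length(dim(volumes)) == ndim + 1L) {
    if (!identical(dim(volumes)[seq_len(ndim)], as.integer(sp)))
      stop("volume shape does not match model input ", paste(sp, collapse = "x"))
    X <- matrix(as.numeric(volumes), nrow = prod(sp))
  } else if (is.array(volumes) && length(dim(volumes)) == ndim) {
    if (!identical(dim(volumes), as.integer(sp)))
      stop("volume shape ", paste(dim(volumes), collapse = "x"),
           " does not match model input ", paste(sp, collapse = "x"))
    X <- matrix(as.numeric(volumes), ncol = 1L)
  } else stop("volumes must be an array, batch array, or list of arrays")
  (X - model$standardize["center"]) / model$standardize["scale"]
}

forward_scores <- function(model, volumes) {
  X <- as_batch_matrix(model, volumes)
  t(cpp_forward(model$compiled$desc, model$compiled$drop,
                model$theta, model$state, X))   # samples x classes
}

softmax_rows <- function(s) {
  m <- apply(s, 1, max)
  e <- exp(s - m)
  e / rowSums(e)
}

#' Predict class probabilities for volumes
#'
#' Runs the network in inference mode (running batch-norm statistics, no
#' dropout) and returns the softmax probability of the positive (nodule)
#' class for each sample, in input order.
#'
#' @param object a `cnn_model`.
#' @param volumes a volume array, a batch array with trailing sample
#'   dimension, or a list of volumes / `phantom_sample`s.
#' @param type `"prob"` (positive-class probability), `"score"` (pre-softmax
#'   score matrix) or `"class"` (0/1 at threshold 0.5).
#' @param ... unused.
#' @return Numeric vector of probabilities (or matrix of scores).
#' @export
predict.cnn_model <- function(object, volumes, type = c("prob", "score", "class"), ...) {
  type <- match.arg(type)
  s <- forward_scores(object, volumes)
  if (type == "score") return(s)
  p1 <- softmax_rows(s)[, 2L]
  if (type == "class") as.integer(p1 >= 0.5) else p1
}

# 1-based indices of convolution layers in a description.
conv_layer_indices <- function(description) {
  which(vapply(description$layers,
               function(l) l$kind %in% c("conv2d", "conv3d"), logical(1)))
}
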