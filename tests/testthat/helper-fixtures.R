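# Shared fixtures: all built in code at test time.

# A small 3D net exercising every layer kind; cheap to train.
tiny_description <- function(edge = 7L, dropout = 0) {
  layers <- list(
    layer_spec("conv3d", 1, 4, kernel = 3, padding = "same", activation = "relu"),
    layer_spec("batchnorm", 4),
    layer_spec("maxpool3d", kernel = 2),
    layer_spec("conv3d", 4, 6, kernel = 2, padding = "valid", activation = "relu"),
    layer_spec("batchnorm", 6),
    layer_spec("avgpool_global"),
    layer_spec("flatten"),
    layer_spec("dense", 6, 8, activation = "relu"))
  if (dropout > 0) layers <- c(layers, list(layer_spec("dropout", dropout_rate = dropout)))
  layers <- c(layers, list(layer_spec("dense", 8, 2)))
  network_description("tiny3d", c(edge, edge, edge, 1L), layers)
}

# GAP + linear head with no nonlinearity between the conv output and the
# class scores: the configuration where the class activation map is
# available in closed form.
gap_toy_description <- function(edge = 6L, maps = 5L, kernel = 2L,
                                conv_act = "none") {
  network_description("gap_toy", c(edge, edge, edge, 1L), list(
    layer_spec("conv3d", 1, maps, kernel = kernel, padding = "valid",
               activation = conv_act),
    layer_spec("avgpool_global"),
    layer_spec("flatten"),
    layer_spec("dense", maps, 2)))
}

# Tiny phantoms for fast end-to-end checks.
tiny_phantom_config <- function(...) {
  phantom_config(edge = 7L, nodule_radius_range = c(1.5, 2.5),
                 vessel_count_range = c(0L, 1L),
                 vessel_radius_range = c(0.6, 0.9), noise_sd = 0, ...)
}

random_confusion <- function(n = 1L, max_count = 50L) {
  data.frame(tp = sample(0:max_count, n, TRUE), fp = sample(0:max_count, n, TRUE),
             fn = sample(0:max_count, n, TRUE), tn = sample(0:max_count, n, TRUE))
}

# Round doubles through IEEE float32 (what volume files store).
single_round <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L), "numeric",
          n = length(x), size = 4L)
}

# Exhaustive pairwise Mann-Whitney AUC oracle.
auc_pairwise_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}
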