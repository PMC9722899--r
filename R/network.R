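#' Network architecture configuration
#'
#' The backbone is fully convolutional: `n_pre` 3x3 convolutions with ReLU
#' at full resolution, one 2x2 max-pool, `n_post` 3x3 convolutions with
#' ReLU at half resolution, and a linear 1x1 head with `3 + length(extras)`
#' output channels (two position offsets, one weight logit, plus any extra
#' property channels). There are no normalization layers, so the network is
#' a pure function of its input and exactly translation-equivariant at
#' stride 2 away from the boundary.
#'
#' @param channels Feature channels per convolutional layer.
#' @param n_pre,n_post Number of 3x3 conv layers before/after the pool.
#' @param in_channels Input image channels (1 for intensity images, 2 for
#'   complex fields stored as real/imaginary planes).
#' @param extras Character vector of extra output channels, a subset of
#'   `c("z", "lns")`: axial position and log signal scale.
#' @param normalize Input normalization applied to every crop/image:
#'   `"standard"` (default) centers on the image mean and divides by the
#'   image standard deviation, giving contrast of order one regardless of
#'   exposure; `"mean"` only divides by the mean; `"none"` leaves inputs
#'   untouched. Complex-field planes are already expressed relative to the
#'   background, and for scale- or propagation-symmetric training the
#'   per-image statistics must not be touched (the signal scale *is* the
#'   regression target), so networks with extra channels use `"none"`.
#' @return A `network_config` object. The pooling factor `k = 2` is fixed
#'   by the architecture.
#' @export
network_config <- function(channels = 32L, n_pre = 3L, n_post = 8L,
                           in_channels = 1L, extras = character(),
                           normalize = c("standard", "mean", "none")) {
  normalize <- match.arg(normalize)
  if (length(extras) && !all(extras %in% c("z", "lns")))
    abort("extras must be a subset of c('z', 'lns')")
  if (channels < 1 || n_pre < 1 || n_post < 0) abort("invalid layer counts")
  structure(list(channels = as.integer(channels), n_pre = as.integer(n_pre),
                 n_post = as.integer(n_post), in_channels = as.integer(in_channels),
                 extras = extras, k = 2L, kernel = 3L,
                 out_channels = 3L + length(extras), normalize = normalize),
            class = "network_config")
}

channel_names <- function(cfg) c("dx", "dy", "rho", cfg$extras)

init_layer <- function(fan_rows, n_out) {
  lim <- sqrt(6 / fan_rows)
  list(W = matrix(runif(fan_rows * n_out, -lim, lim), fan_rows, n_out),
       b = rep(0, n_out))
}

#' Build a randomly initialized network
#'
#' Weights use variance-scaled uniform initialization (bounded by
#' `sqrt(6 / fan_in)`); biases start at zero. Two builds with the same seed
#' produce identical weights.
#'
#' @param cfg A [network_config()].
#' @param seed Optional integer seed for reproducible initialization.
#' @return A `lodestar_network` object.
#' @export
build_network <- function(cfg = network_config(), seed = NULL) {
  with_seed(seed, {
    layers <- list()
    ka <- cfg$kernel^2
    layers[[1]] <- init_layer(ka * cfg$in_channels, cfg$channels)
    for (l in seq_len(cfg$n_pre - 1L))
      layers[[length(layers) + 1L]] <- init_layer(ka * cfg$channels, cfg$channels)
    for (l in seq_len(cfg$n_post))
      layers[[length(layers) + 1L]] <- init_layer(ka * cfg$channels, cfg$channels)
    layers[[length(layers) + 1L]] <- init_layer(cfg$channels, cfg$out_channels)
    structure(list(cfg = cfg, layers = layers), class = "lodestar_network")
  })
}

#' @export
print.lodestar_network <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf(paste0("<lodestar_network> %d+%d conv layers x %d channels, ",
                     "%d -> %d channels, %d parameters\n"),
              cfg$n_pre, cfg$n_post, cfg$channels, cfg$in_channels,
              cfg$out_channels, n_parameters(x)))
  if (length(cfg$extras)) cat("  extras:", paste(cfg$extras, collapse = ", "), "\n")
  invisible(x)
}

#' Number of trainable parameters
#' @param net A `lodestar_network`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(net) {
  sum(vapply(net$layers, function(l) length(l$W) + length(l$b), numeric(1)))
}

# Coerce any supported input to an H x W x Cin array, applying the
# configured normalization.
prepare_input <- function(net, image) {
  cfg <- net$cfg
  if (inherits(image, "complex_field")) image <- field_to_planes(image)
  if (is.matrix(image)) {
    x <- unclass(image)
    attributes(x) <- list(dim = dim(image))
    dim(x) <- c(dim(x), 1L)
  } else x <- image
  if (length(dim(x)) != 3L || dim(x)[3] != cfg$in_channels)
    abort(sprintf("expected input with %d channel(s)", cfg$in_channels))
  if (dim(x)[1] %% cfg$k != 0 || dim(x)[2] %% cfg$k != 0)
    abort("input dimensions must be divisible by the pooling factor; pad first")
  if (cfg$normalize == "standard") {
    s <- sd(x)
    if (s == 0) abort("cannot standardize a constant image")
    x <- (x - mean(x)) / s
  } else if (cfg$normalize == "mean") {
    m <- mean(x)
    if (m == 0) abort("cannot mean-normalize an all-zero image")
    x <- x / m
  }
  storage.mode(x) <- "double"
  x
}

new_feature_stack <- function(arr, cfg, input_dim) {
  dimnames(arr) <- list(NULL, NULL, channel_names(cfg))
  structure(arr, class = "feature_stack", input_dim = as.integer(input_dim),
            k = cfg$k)
}

#' Run the network forward
#'
#' @param net A `lodestar_network`.
#' @param image Matrix (intensity image), H x W x C array, or
#'   `complex_field`. Spatial dimensions must be divisible by 2.
#' @param with_cache Keep intermediate activations for a backward pass
#'   (training use only).
#' @return A `feature_stack`: an `(H/2) x (W/2) x out_channels` array with
#'   channels `dx`, `dy`, `rho` and any extras, plus the input dimensions
#'   as an attribute. If `with_cache`, the cache handle is attached.
#' @export
predict_feature_maps <- function(net, image, with_cache = FALSE) {
  x <- prepare_input(net, image)
  res <- cpp_net_forward(x, lapply(net$layers, `[[`, "W"),
                         lapply(net$layers, `[[`, "b"),
                         net$cfg$n_pre, net$cfg$n_post, with_cache)
  stack <- new_feature_stack(res$out, net$cfg, dim(x)[1:2])
  if (with_cache) attr(stack, "cache") <- res$cache
  stack
}

#' Decode per-pixel position maps from a feature stack
#'
#' Feature pixel `(i, j)` (0-based) predicts position
#' `x = dx[i, j] + i * k - N/2` along the first image axis and
#' `y = dy[i, j] + j * k - M/2` along the second, where `N x M` is the
#' *input* image size and `k = 2` the pooling stride. With
#' `convention = "top_left"` the half-size offsets are added back so
#' positions are in input-pixel coordinates from the top-left pixel center.
#'
#' @param stack A `feature_stack`.
#' @param convention `"top_left"` (default) or `"center"`.
#' @return List with matrices `x` and `y`.
#' @export
position_maps <- function(stack, convention = c("top_left", "center")) {
  convention <- match.arg(convention)
  nd <- attr(stack, "input_dim"); k <- attr(stack, "k")
  n1 <- dim(stack)[1]; n2 <- dim(stack)[2]
  off <- if (convention == "center") c(-nd[1] / 2, -nd[2] / 2) else c(0, 0)
  x <- stack[, , "dx"] + matrix((0:(n1 - 1)) * k, n1, n2) + off[1]
  y <- stack[, , "dy"] + matrix((0:(n2 - 1)) * k, n1, n2, byrow = TRUE) + off[2]
  list(x = x, y = y)
}

# All property maps (positions in top-left convention plus extras),
# as a named list of matrices; these are the channels chi pooled and
# scored downstream.
property_maps <- function(stack) {
  pm <- position_maps(stack, "top_left")
  maps <- list(x = pm$x, y = pm$y)
  for (e in setdiff(dimnames(stack)[[3]], c("dx", "dy", "rho")))
    maps[[e]] <- stack[, , e]
  maps
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Evaluation-mode weight map
#'
#' Elementwise sigmoid of the weight logits, normalized to sum to one.
#'
#' @param rho Weight-logit matrix (the `rho` channel) or a `feature_stack`.
#' @return Matrix of weights summing to 1.
#' @export
eval_weights <- function(rho) {
  if (inherits(rho, "feature_stack")) rho <- rho[, , "rho"]
  s <- sigmoid(rho)
  tot <- sum(s)
  if (!is.finite(tot) || tot <= 0) abort("degenerate weight map: total mass is 0")
  s / tot
}

#' Training-mode weight map with dropout and floor
#'
#' `w = (eps + D[S(rho)]) / (M * N * eps + sum(D[S(rho)]))` where `D` drops
#' each sigmoid weight with probability `dropout`. The dropout prevents
#' collapse onto a single pixel; the floor `eps` assigns a minimum weight
#' everywhere, pushing the network to use the full sigmoid range. The
#' result always sums to 1 with every entry strictly positive.
#'
#' @param rho Weight-logit matrix or `feature_stack`.
#' @param dropout Dropout rate (default 0.01).
#' @param eps Weight floor (default 1e-6).
#' @param seed Optional integer seed for the dropout draw.
#' @return Weight matrix with attribute `keep` (the dropout mask).
#' @export
train_weights <- function(rho, dropout = 0.01, eps = 1e-6, seed = NULL) {
  if (inherits(rho, "feature_stack")) rho <- rho[, , "rho"]
  s <- sigmoid(rho)
  keep <- with_seed(seed, matrix(runif(length(s)) >= dropout, nrow(s), ncol(s)))
  d <- s * keep
  tot <- length(s) * eps + sum(d)
  structure((eps + d) / tot, keep = keep, total = tot)
}

#' Globally pooled prediction
#'
#' Weighted average of every property map under the weight map: the
#' single-object prediction of the network.
#'
#' @param stack A `feature_stack`.
#' @param mode `"eval"` (deterministic sigmoid weights) or `"train"`
#'   (dropout weights of [train_weights()]).
#' @param seed Optional seed for training-mode dropout.
#' @param weights Optional externally computed weight matrix (overrides
#'   `mode`).
#' @return One-row tibble with `x`, `y` (px, top-left convention), any
#'   extra channels (`z`, `lns`), and `weight_mass` (the unnormalized
#'   sigmoid mass, a crude confidence).
#' @export
pooled_prediction <- function(stack, mode = c("eval", "train"), seed = NULL,
                              weights = NULL) {
  mode <- match.arg(mode)
  w <- weights %||% switch(mode,
    eval = eval_weights(stack),
    train = train_weights(stack, seed = seed))
  if (abs(sum(w)) < .Machine$double.xmin) abort("zero total weight")
  maps <- property_maps(stack)
  vals <- lapply(maps, function(m) sum(m * w))
  out <- tibble::as_tibble(vals)
  if ("lns" %in% names(out)) names(out)[names(out) == "lns"] <- "log_scale"
  out$weight_mass <- sum(sigmoid(stack[, , "rho"]))
  out
}

#' Save / load a trained network
#'
#' The architecture is written as a YAML sidecar next to the weights;
#' loading verifies that the stored architecture matches the weights file
#' and refuses silent casts.
#'
#' @param net A `lodestar_network`.
#' @param path Weights file path (`.rds`); the config is written to
#'   `<path>.yml`.
#' @export
save_network <- function(net, path) {
  cfg <- net$cfg
  yaml::write_yaml(list(channels = cfg$channels, n_pre = cfg$n_pre,
                        n_post = cfg$n_post, in_channels = cfg$in_channels,
                        extras = as.list(cfg$extras), k = cfg$k,
                        normalize = cfg$normalize),
                   paste0(path, ".yml"))
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_network
#' @return `load_network()` returns the `lodestar_network`.
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  cfg_file <- paste0(path, ".yml")
  if (file.exists(cfg_file)) {
    y <- yaml::read_yaml(cfg_file)
    same <- identical(as.integer(y$channels), net$cfg$channels) &&
      identical(as.integer(y$n_pre), net$cfg$n_pre) &&
      identical(as.integer(y$n_post), net$cfg$n_post) &&
      identical(as.integer(y$in_channels), net$cfg$in_channels) &&
      setequal(unlist(y$extras), net$cfg$extras) &&
      identical(y$normalize, net$cfg$normalize)
    if (!same) abort("stored config does not match weights file")
  }
  net
}
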