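#' Transformation sampling ranges
#'
#' The symmetry group used for self-distillation: in-plane translations and
#' rotations (with reflections) always; Fourier propagation and
#' signal-scale transformations when the corresponding extra channels are
#' trained. Each transformation is sampled independently per view.
#'
#' @param translation Maximum |translation| per axis in px (uniform box).
#' @param rotation Sample rotation angles uniformly on `[0, 2*pi)`.
#' @param reflection Sample independent axis reflections (Bernoulli 1/2).
#' @param dz_range Maximum |propagation distance| in micrometres (0
#'   disables the propagation symmetry).
#' @param lns_range Maximum |log signal scale| (0 disables the scale
#'   symmetry; default when enabled is `log(2)`).
#' @return A `transform_ranges` object.
#' @export
transform_ranges <- function(translation = 8, rotation = TRUE,
                             reflection = TRUE, dz_range = 0, lns_range = 0) {
  if (translation < 0 || dz_range < 0 || lns_range < 0)
    abort("ranges must be non-negative")
  structure(list(translation = translation, rotation = rotation,
                 reflection = reflection, dz_range = dz_range,
                 lns_range = lns_range), class = "transform_ranges")
}

#' Sample one group element
#'
#' @param ranges A [transform_ranges()].
#' @param seed Optional integer seed.
#' @return A `transform_spec`: translation `t`, rotation `angle`,
#'   reflection `flip` (per axis), propagation `dz`, log-scale `lns`.
#' @export
sample_transform <- function(ranges = transform_ranges(), seed = NULL) {
  with_seed(seed, {
    spec <- list(
      t = runif(2, -ranges$translation, ranges$translation),
      angle = if (isTRUE(ranges$rotation)) runif(1, 0, 2 * pi) else 0,
      flip = if (isTRUE(ranges$reflection)) runif(2) < 0.5 else c(FALSE, FALSE),
      dz = if (ranges$dz_range > 0) runif(1, -ranges$dz_range, ranges$dz_range) else 0,
      lns = if (ranges$lns_range > 0) runif(1, -ranges$lns_range, ranges$lns_range) else 0
    )
    structure(spec, class = "transform_spec")
  })
}

identity_transform <- function() {
  structure(list(t = c(0, 0), angle = 0, flip = c(FALSE, FALSE), dz = 0, lns = 0),
            class = "transform_spec")
}

# Rotation+reflection matrix acting on (row, col) points: reflection first,
# then counter-clockwise rotation.
transform_matrix <- function(spec) {
  f <- diag(ifelse(spec$flip, -1, 1))
  th <- spec$angle
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) %*% f
}

# Forward point action in input coordinates: tau(p) = R (p - c) + c + t.
transform_point <- function(p, spec, dim_in) {
  cen <- (dim_in - 1) / 2
  as.numeric(transform_matrix(spec) %*% (p - cen) + cen + spec$t)
}

reflect_index <- function(idx, n) {
  # mirror about the edge pixel centers 0 and n-1
  period <- 2 * (n - 1)
  idx <- abs(idx) %% period
  ifelse(idx > n - 1, period - idx, idx)
}

bilinear_sample <- function(mat, r, c) {
  n1 <- nrow(mat); n2 <- ncol(mat)
  r <- reflect_index(r, n1); c <- reflect_index(c, n2)
  r0 <- pmin(floor(r), n1 - 2); c0 <- pmin(floor(c), n2 - 2)
  fr <- r - r0; fc <- c - c0
  i00 <- r0 + 1 + c0 * n1
  v <- (1 - fr) * (1 - fc) * mat[i00] + fr * (1 - fc) * mat[i00 + 1] +
    (1 - fr) * fc * mat[i00 + n1] + fr * fc * mat[i00 + n1 + 1]
  v
}

#' Apply a sampled transformation to a training image
#'
#' Rotation/reflection about the image center followed by translation
#' (bilinear interpolation, reflected boundary fill), then a center crop to
#' `out_size`. For complex fields, propagation by `dz` and signal rescaling
#' by `exp(lns)` are additionally applied after the geometric warp.
#'
#' @param image Matrix, H x W x C array, or `complex_field` (square crop).
#' @param spec A `transform_spec`.
#' @param out_size Output crop side length (defaults to the input size).
#' @return The transformed image, same type as the input.
#' @export
transform_image <- function(image, spec, out_size = NULL) {
  dim_in <- dim(image)[1:2]
  out_size <- out_size %||% dim_in
  out_size <- rep_len(as.integer(out_size), 2L)
  if (any(out_size > dim_in)) abort("crop larger than the input image")
  if (any((dim_in - out_size) %% 2L != 0L))
    abort("input minus crop size must be even for a centered crop")
  off <- (dim_in - out_size) / 2
  # inverse map: input coordinate feeding each output pixel
  cen <- (dim_in - 1) / 2
  Rinv <- solve(transform_matrix(spec))
  qr <- rep(0:(out_size[1] - 1), times = out_size[2]) + off[1]
  qc <- rep(0:(out_size[2] - 1), each = out_size[1]) + off[2]
  pr <- Rinv[1, 1] * (qr - cen[1] - spec$t[1]) + Rinv[1, 2] * (qc - cen[2] - spec$t[2]) + cen[1]
  pc <- Rinv[2, 1] * (qr - cen[1] - spec$t[1]) + Rinv[2, 2] * (qc - cen[2] - spec$t[2]) + cen[2]

  warp_plane <- function(m) matrix(bilinear_sample(m, pr, pc), out_size[1], out_size[2])

  if (inherits(image, "complex_field")) {
    # geometric warp at full size, then propagate, then crop: propagating
    # after the center crop would wrap the defocused pattern around the
    # small crop's FFT boundary and corrupt the axial supervision
    if (spec$dz != 0 && any(out_size < dim_in)) {
      full_spec <- spec; full_spec$dz <- 0; full_spec$lns <- 0
      out <- transform_image(image, full_spec, out_size = dim_in)
      out <- propagate_field(out, spec$dz)
      if (spec$lns != 0) out <- rescale_scatter(out, exp(spec$lns))
      off1 <- (dim_in - out_size) / 2
      vals <- unclass(out)[(off1[1] + 1):(off1[1] + out_size[1]),
                           (off1[2] + 1):(off1[2] + out_size[2])]
      return(new_complex_field(vals, attr(image, "optics"),
                               background = attr(image, "background"),
                               sigma = attr(image, "sigma")))
    }
    vals <- unclass(image)
    out <- matrix(complex(real = bilinear_sample(Re(vals), pr, pc),
                          imaginary = bilinear_sample(Im(vals), pr, pc)),
                  out_size[1], out_size[2])
    out <- new_complex_field(out, attr(image, "optics"),
                             background = attr(image, "background"),
                             sigma = attr(image, "sigma"))
    if (spec$dz != 0) out <- propagate_field(out, spec$dz)
    if (spec$lns != 0) out <- rescale_scatter(out, exp(spec$lns))
    return(out)
  }
  if (is.matrix(image)) return(warp_plane(image))
  out <- array(0, c(out_size, dim(image)[3]))
  for (ch in seq_len(dim(image)[3])) out[, , ch] <- warp_plane(image[, , ch])
  out
}

#' Invert a transformation on a pooled prediction
#'
#' Position channels transform as points under the inverse
#' roto-translation/reflection about the crop center; the axial channel
#' subtracts the propagation distance and the log-scale channel subtracts
#' the sampled log scale.
#'
#' @param pred One-row tibble from [pooled_prediction()], with positions in
#'   the transformed view's top-left coordinates.
#' @param spec The `transform_spec` that produced the view.
#' @param dim_in Original image dimensions (the frame in which `spec` was
#'   applied); defaults to the view size for same-size transforms.
#' @param dim_out Dimensions of the transformed view/crop.
#' @return The prediction mapped back to the original image frame.
#' @export
invert_prediction <- function(pred, spec, dim_in = NULL, dim_out = NULL) {
  p <- c(pred$x[1], pred$y[1])
  dim_out <- dim_out %||% dim_in
  if (is.null(dim_in)) abort("dim_in required to invert positions")
  off <- (dim_in - dim_out) / 2
  cen <- (dim_in - 1) / 2
  Rinv <- solve(transform_matrix(spec))
  q <- as.numeric(Rinv %*% (p + off - cen - spec$t) + cen)
  out <- pred
  out$x[1] <- q[1]; out$y[1] <- q[2]
  if ("z" %in% names(out)) out$z[1] <- out$z[1] - spec$dz
  if ("log_scale" %in% names(out)) out$log_scale[1] <- out$log_scale[1] - spec$lns
  out
}

#' Batch consistency loss
#'
#' Sum over views and channels of the absolute deviation of each inversely
#' transformed pooled prediction from the batch-wise mean prediction.
#'
#' @param preds K x C numeric matrix (rows = views, columns = channels) of
#'   inverted pooled predictions.
#' @return Scalar loss.
#' @export
consistency_loss <- function(preds) {
  preds <- as.matrix(preds)
  if (nrow(preds) < 2) abort("need at least 2 views")
  mu <- colMeans(preds)
  sum(abs(sweep(preds, 2, mu)))
}

#' Internal consistency loss
#'
#' Weighted L1 spread of each property map around its own pooled mean,
#' summed over channels; this is the term that clusters predictions around
#' the object and suppresses weights elsewhere.
#'
#' @param stack A `feature_stack`.
#' @param pooled One-row tibble of pooled channel values (train-mode).
#' @param weights Training-mode weight matrix from [train_weights()].
#' @return Scalar loss.
#' @export
internal_loss <- function(stack, pooled, weights) {
  maps <- property_maps(stack)
  names(maps)[names(maps) == "lns"] <- "log_scale"
  tot <- 0
  for (nm in names(maps)) tot <- tot + sum(abs(maps[[nm]] - pooled[[nm]][1]) * weights)
  tot
}

#' Training configuration
#'
#' Defaults follow the published protocol: Adam with learning rate 0.001,
#' mini-batches of 8 transformed views, 5000 mini-batches (15000 for the
#' propagation-symmetry task in the original study). The two losses are
#' combined with equal weight.
#'
#' @param steps Number of mini-batches.
#' @param views Views per mini-batch (K).
#' @param lr Adam learning rate.
#' @param ranges A [transform_ranges()].
#' @param crop Working crop side length; `NULL` chooses the largest even
#'   crop that keeps sampled translations inside the original image.
#' @param dropout,eps Training weight-map parameters (see
#'   [train_weights()]).
#' @param restart_threshold Optional stall guard: if the mean loss over
#'   the 50 mini-batches before `restart_probe` still exceeds this value,
#'   the run is judged stuck in a degenerate basin (healthy runs are an
#'   order of magnitude lower by then) and restarts from a fresh
#'   deterministic initialization, at most `max_restarts` times. `NULL`
#'   (the default) disables the guard.
#' @param restart_probe Mini-batch at which the stall guard is evaluated.
#' @param max_restarts Maximum number of re-initializations.
#' @return A `train_config` object.
#' @export
train_config <- function(steps = 5000L, views = 8L, lr = 0.001,
                         ranges = transform_ranges(), crop = NULL,
                         dropout = 0.01, eps = 1e-6,
                         restart_threshold = NULL, restart_probe = 600L,
                         max_restarts = 2L) {
  if (views < 2) abort("need at least 2 views per mini-batch")
  if (lr <= 0) abort("learning rate must be positive")
  structure(list(steps = as.integer(steps), views = as.integer(views),
                 lr = lr, ranges = ranges, crop = crop,
                 dropout = dropout, eps = eps,
                 restart_threshold = restart_threshold,
                 restart_probe = as.integer(restart_probe),
                 max_restarts = as.integer(max_restarts)),
            class = "train_config")
}

default_crop <- function(dim_in, translation) {
  s <- min(dim_in) - 2 * ceiling(translation)
  s <- max(16L, s - (s %% 2L))
  as.integer(s)
}

#' Train a network by geometric self-distillation on a single image
#'
#' Each mini-batch draws one training image (if several are provided),
#' samples `views` independent transformations, runs the network on every
#' transformed view, inversely transforms the pooled predictions, and takes
#' one Adam step on the sum of the batch [consistency_loss()] and the
#' per-view [internal_loss()].
#'
#' @param image A single-object crop: matrix, array, `complex_field`, or a
#'   list of such crops (one is drawn per mini-batch).
#' @param net A `lodestar_network` (its `extras` determine which
#'   symmetries can be exercised; enable the matching ranges).
#' @param cfg A [train_config()].
#' @param seed Optional integer seed covering every stochastic choice
#'   (transform sampling, dropout, image choice).
#' @return A `lodestar_fit`: the trained network plus a per-step loss
#'   history tibble.
#' @export
train_lodestar <- function(image, net, cfg = train_config(), seed = NULL) {
  images <- if (is.list(image) && !inherits(image, "complex_field")) image else list(image)
  dim_in <- dim(images[[1]])[1:2]
  crop <- cfg$crop %||% default_crop(dim_in, cfg$ranges$translation)
  crop <- rep_len(as.integer(crop), 2L)
  if (any((dim_in - crop) %% 2L != 0L)) abort("image minus crop size must be even")
  if (any(crop < 16L)) abort("crop too small for the requested translation margin")
  extras <- net$cfg$extras
  if (cfg$ranges$dz_range > 0 && !("z" %in% extras))
    abort("dz_range > 0 requires a network with a 'z' channel")
  if (cfg$ranges$lns_range > 0 && !("lns" %in% extras))
    abort("lns_range > 0 requires a network with a 'lns' channel")

  n_layers <- length(net$layers)
  net0 <- net
  m1 <- lapply(net$layers, function(l) list(W = 0 * l$W, b = 0 * l$b))
  m2 <- m1
  beta1 <- 0.9; beta2 <- 0.999; aeps <- 1e-8
  history <- vector("list", cfg$steps)
  stalled <- FALSE
  attempt <- 0L

  run <- function() {
    for (step in seq_len(cfg$steps)) {
      img <- images[[if (length(images) > 1) sample.int(length(images), 1) else 1]]
      views <- vector("list", cfg$views)
      for (k in seq_len(cfg$views)) {
        sp <- sample_transform(cfg$ranges)
        view <- transform_image(img, sp, out_size = crop)
        stack <- predict_feature_maps(net, view, with_cache = TRUE)
        w <- train_weights(stack, dropout = cfg$dropout, eps = cfg$eps)
        pooled <- pooled_prediction(stack, weights = w)
        inv <- invert_prediction(pooled, sp, dim_in = dim_in, dim_out = crop)
        views[[k]] <- list(spec = sp, stack = stack, w = w, pooled = pooled,
                           inv = inv)
      }
      prop_names <- c("x", "y", setdiff(channel_names(net$cfg), c("dx", "dy", "rho")))
      pretty <- function(nm) ifelse(nm == "lns", "log_scale", nm)
      inv_mat <- do.call(rbind, lapply(views, function(v)
        unlist(v$inv[1, pretty(prop_names)])))
      mu <- colMeans(inv_mat)
      la <- sum(abs(sweep(inv_mat, 2, mu)))
      sgn <- sign(sweep(inv_mat, 2, mu))
      d_inv <- sweep(sgn, 2, colMeans(sgn))   # dL_a / d inverted prediction

      lb_tot <- 0
      grads <- NULL
      for (k in seq_len(cfg$views)) {
        v <- views[[k]]
        maps <- property_maps(v$stack)
        chi_bar <- unlist(v$pooled[1, pretty(names(maps))])
        w <- v$w
        # dL_a wrt pooled prediction (before inversion): positions via R^-T
        Rinv <- solve(transform_matrix(v$spec))
        g_inv <- d_inv[k, ]
        g_bar <- g_inv
        g_bar[1:2] <- as.numeric(t(Rinv) %*% g_inv[1:2])
        # internal loss and its gradients
        dmaps <- list(); dw <- 0
        for (ci in seq_along(maps)) {
          dev <- maps[[ci]] - chi_bar[ci]
          lb_tot <- lb_tot + sum(abs(dev) * w)
          s <- sign(dev)
          g_bar[ci] <- g_bar[ci] - sum(s * w)
          dmaps[[ci]] <- s * w
          dw <- dw + abs(dev)
        }
        # pooled mean backward: chi_bar = sum(maps * w)
        for (ci in seq_along(maps)) {
          dmaps[[ci]] <- dmaps[[ci]] + g_bar[ci] * w
          dw <- dw + g_bar[ci] * maps[[ci]]
        }
        # weight-map backward through Eq.-36-style normalization
        u <- sigmoid(v$stack[, , "rho"])
        keep <- attr(w, "keep"); Tt <- attr(w, "total")
        du <- keep * (dw - sum(dw * w)) / Tt
        drho <- du * u * (1 - u)
        dout <- array(0, dim(v$stack))
        dout[, , 1] <- dmaps[[1]]
        dout[, , 2] <- dmaps[[2]]
        dout[, , 3] <- drho
        if (length(maps) > 2)
          for (ci in 3:length(maps)) dout[, , ci + 1] <- dmaps[[ci]]
        gk <- cpp_net_backward(attr(v$stack, "cache"), dout,
                               lapply(net$layers, `[[`, "W"))
        if (is.null(grads)) grads <- gk
        else for (l in seq_len(n_layers)) {
          grads$dW[[l]] <- grads$dW[[l]] + gk$dW[[l]]
          grads$db[[l]] <- grads$db[[l]] + gk$db[[l]]
        }
      }
      loss <- la + lb_tot
      if (!is.finite(loss)) {
        abort(sprintf("non-finite loss at step %d (L_a = %.3g, L_b = %.3g)",
                      step, la, lb_tot))
      }
      # Adam update
      t_adam <- step
      for (l in seq_len(n_layers)) {
        gW <- grads$dW[[l]]; gb <- grads$db[[l]]
        m1[[l]]$W <<- beta1 * m1[[l]]$W + (1 - beta1) * gW
        m1[[l]]$b <<- beta1 * m1[[l]]$b + (1 - beta1) * gb
        m2[[l]]$W <<- beta2 * m2[[l]]$W + (1 - beta2) * gW^2
        m2[[l]]$b <<- beta2 * m2[[l]]$b + (1 - beta2) * gb^2
        mhW <- m1[[l]]$W / (1 - beta1^t_adam); mhb <- m1[[l]]$b / (1 - beta1^t_adam)
        vhW <- m2[[l]]$W / (1 - beta2^t_adam); vhb <- m2[[l]]$b / (1 - beta2^t_adam)
        net$layers[[l]]$W <<- net$layers[[l]]$W - cfg$lr * mhW / (sqrt(vhW) + aeps)
        net$layers[[l]]$b <<- net$layers[[l]]$b - cfg$lr * mhb / (sqrt(vhb) + aeps)
      }
      history[[step]] <<- c(step = step, loss = loss, loss_a = la, loss_b = lb_tot)
      if (!is.null(cfg$restart_threshold) && step == cfg$restart_probe &&
          attempt < cfg$max_restarts) {
        recent <- vapply(history[max(1, step - 49):step], function(h) h[["loss"]],
                         numeric(1))
        if (mean(recent) > cfg$restart_threshold) {
          stalled <<- TRUE
          return(invisible(NULL))
        }
      }
      if (step %% 500L == 0L) gc(verbose = FALSE)
    }
  }
  repeat {
    stalled <- FALSE
    with_seed(if (is.null(seed)) NULL else seed + 7919L * attempt, run())
    if (!stalled) break
    attempt <- attempt + 1L
    warn(sprintf("training stalled at probe step %d; restarting (attempt %d)",
                 cfg$restart_probe, attempt))
    net <- build_network(net0$cfg, seed = 7919L * attempt +
                           (if (is.null(seed)) 1L else seed))
    m1 <- lapply(net$layers, function(l) list(W = 0 * l$W, b = 0 * l$b))
    m2 <- m1
    history <- vector("list", cfg$steps)
  }

  hist_tb <- if (cfg$steps > 0) tibble::as_tibble(do.call(rbind, history)) else
    tibble::tibble(step = integer(), loss = numeric(), loss_a = numeric(),
                   loss_b = numeric())
  structure(list(network = net, history = hist_tb, cfg = cfg, crop = crop,
                 restarts = attempt),
            class = "lodestar_fit")
}

#' @export
tidy.lodestar_fit <- function(x, ...) x$history

#' @export
glance.lodestar_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    steps = nrow(h),
    final_loss = if (nrow(h)) mean(tail(h$loss, 50)) else NA_real_,
    final_loss_a = if (nrow(h)) mean(tail(h$loss_a, 50)) else NA_real_,
    final_loss_b = if (nrow(h)) mean(tail(h$loss_b, 50)) else NA_real_,
    n_parameters = n_parameters(x$network)
  )
}

#' @export
print.lodestar_fit <- function(x, ...) {
  cat(sprintf("<lodestar_fit> %d steps, %d parameters, final loss %.4f\n",
              nrow(x$history), n_parameters(x$network),
              glance(x)$final_loss))
  invisible(x)
}
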