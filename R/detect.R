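#' Detection parameters
#'
#' The detection score is the geometric combination `w^alpha * b^beta` of
#' the weight map `w` and the clustering map `b` (inverse local variance of
#' the property maps). `alpha = 0.1` suits homogeneous particles, where the
#' clustering signal is highly discriminative; `alpha` up to 1 suits
#' morphologically variable objects, where clustering degrades.
#'
#' @param alpha Weight-map exponent in `[0, 1]`.
#' @param beta Clustering-map exponent; defaults to `1 - alpha`.
#' @param quantile Score quantile used as the detection threshold.
#' @param prominence Minimum maxima prominence `h`; `NULL` uses
#'   `1e-3 * max(score)`.
#' @param window Refinement window half-width in feature-map px.
#' @param eps_b Lower clamp on the local variance before inversion, which
#'   bounds `b` on locally constant maps.
#' @return A `detect_params` object.
#' @export
detect_params <- function(alpha = 0.1, beta = 1 - alpha, quantile = 0.99,
                          prominence = NULL, window = 5L, eps_b = 1e-6) {
  if (alpha < 0 || alpha > 1) abort("alpha must lie in [0, 1]")
  if (quantile <= 0 || quantile >= 1) abort("quantile must lie in (0, 1)")
  structure(list(alpha = alpha, beta = beta, quantile = quantile,
                 prominence = prominence, window = as.integer(window),
                 eps_b = eps_b), class = "detect_params")
}

# 3x3 box mean with replicated edges.
box3_mean <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  up <- m[c(1, 1:(n1 - 1)), , drop = FALSE]
  dn <- m[c(2:n1, n1), , drop = FALSE]
  v <- up + m + dn
  (v[, c(1, 1:(n2 - 1)), drop = FALSE] + v + v[, c(2:n2, n2), drop = FALSE]) / 9
}

#' Clustering map: inverse local variance of the property maps
#'
#' `b^-1[i, j]` is the total 3x3 local variance, summed over property
#' channels, of the per-pixel position (and extra property) predictions;
#' where the network's predictions agree locally — i.e. cluster on one
#' object — the variance is small and `b` is large. The variance is clamped
#' below at `eps_b` before inversion.
#'
#' @param stack A `feature_stack`.
#' @param eps_b Variance clamp.
#' @return Matrix `b`, same size as the feature maps.
#' @export
clustering_map <- function(stack, eps_b = 1e-6) {
  maps <- property_maps(stack)
  b_inv <- 0
  for (m in maps) b_inv <- b_inv + pmax(box3_mean(m^2) - box3_mean(m)^2, 0)
  1 / pmax(b_inv, eps_b)
}

#' Combine weight and clustering maps into a detection score
#'
#' @param w Weight map (non-negative, from [eval_weights()]).
#' @param b Clustering map (non-negative, from [clustering_map()]).
#' @param params A [detect_params()] supplying the exponents.
#' @return Elementwise `w^alpha * b^beta`.
#' @export
score_map <- function(w, b, params = detect_params()) {
  if (any(w < 0) || any(b < 0)) abort("score inputs must be non-negative")
  w^params$alpha * b^params$beta
}

#' Find candidate detections as prominent local maxima
#'
#' Regional maxima of the h-maxima transform (grayscale reconstruction of
#' `score - h` under `score`) whose score strictly exceeds the configured
#' quantile of all scores.
#'
#' @param score Score matrix.
#' @param params A [detect_params()].
#' @return Tibble of candidate feature-map pixels (`i`, `j`, 0-based) and
#'   their scores.
#' @export
local_maxima <- function(score, params = detect_params()) {
  h <- params$prominence %||% (1e-3 * max(score))
  recon <- cpp_reconstruct_dilation(score - h, score)
  labs <- cpp_regional_maxima(recon)
  thr <- quantile(score, params$quantile, names = FALSE)
  out <- list()
  for (lab in setdiff(unique(as.vector(labs)), 0L)) {
    idx <- which(labs == lab)
    best <- idx[which.max(score[idx])]
    i <- (best - 1L) %% nrow(score)
    j <- (best - 1L) %/% nrow(score)
    if (score[best] > thr)
      out[[length(out) + 1L]] <- c(i = i, j = j, score = score[best])
  }
  if (!length(out))
    return(tibble::tibble(i = integer(), j = integer(), score = numeric()))
  tb <- tibble::as_tibble(do.call(rbind, out))
  tb$i <- as.integer(tb$i); tb$j <- as.integer(tb$j)
  tb
}

#' Refine candidates to sub-pixel detections
#'
#' Around each candidate, the property maps are averaged under the weight
#' map restricted to a local window (weights renormalized within the
#' window) — the multi-object analogue of the global pooled prediction.
#'
#' @param candidates Tibble from [local_maxima()].
#' @param stack The `feature_stack` the candidates came from.
#' @param params A [detect_params()].
#' @return Tibble of detections: `x`, `y` (input px, top-left convention),
#'   any extra channels, and `score`.
#' @export
refine <- function(candidates, stack, params = detect_params()) {
  maps <- property_maps(stack)
  names(maps)[names(maps) == "lns"] <- "log_scale"
  w <- eval_weights(stack)
  hw <- params$window
  n1 <- dim(stack)[1]; n2 <- dim(stack)[2]
  rows <- list()
  for (r in seq_len(nrow(candidates))) {
    i <- candidates$i[r]; j <- candidates$j[r]
    ri <- max(0, i - hw):min(n1 - 1, i + hw)
    rj <- max(0, j - hw):min(n2 - 1, j + hw)
    wloc <- w[ri + 1, rj + 1, drop = FALSE]
    tot <- sum(wloc)
    if (tot <= 0) {
      warn(sprintf("dropping candidate at (%d, %d): zero window weight", i, j))
      next
    }
    wloc <- wloc / tot
    vals <- lapply(maps, function(m) sum(m[ri + 1, rj + 1] * wloc))
    rows[[length(rows) + 1L]] <- tibble::as_tibble(
      c(vals, list(score = candidates$score[r])))
  }
  if (!length(rows)) {
    cols <- c(names(maps), "score")
    return(tibble::as_tibble(setNames(rep(list(numeric()), length(cols)), cols)))
  }
  dplyr::bind_rows(rows)
}

#' Detect all objects in an image
#'
#' Full multi-object pipeline: forward pass, clustering map, score map,
#' prominent local maxima above the score quantile, and local weighted
#' refinement. Deterministic given the network weights and the image.
#'
#' @param net A trained `lodestar_network`.
#' @param image Matrix, array, or `complex_field`. Odd spatial dimensions
#'   are trimmed by one pixel.
#' @param params A [detect_params()].
#' @return Tibble of detections (`x`, `y`, extras, `score`).
#' @export
detect_objects <- function(net, image, params = detect_params()) {
  d <- dim(image)[1:2]
  if (any(d < 16L)) abort("image smaller than the minimum detectable size")
  if (any(d %% 2L != 0L)) {
    keep1 <- seq_len(d[1] - d[1] %% 2L); keep2 <- seq_len(d[2] - d[2] %% 2L)
    image <- if (length(dim(image)) == 3L) image[keep1, keep2, , drop = FALSE]
             else image[keep1, keep2, drop = FALSE]
  }
  stack <- predict_feature_maps(net, image)
  b <- clustering_map(stack, eps_b = params$eps_b)
  w <- eval_weights(stack)
  score <- score_map(w, b, params)
  cand <- local_maxima(score, params)
  out <- refine(cand, stack, params)
  class(out) <- c("lodestar_detections", class(out))
  out
}

#' Link detections across frames into traces
#'
#' For each consecutive frame pair, a minimum-total-distance one-to-one
#' assignment (linear sum assignment) links current detections to open
#' traces; pairs farther apart than `max_dist` are forbidden. Unmatched
#' detections open new traces; traces that skip a frame are closed; traces
#' shorter than `min_length` frames are discarded.
#'
#' @param detections Tibble with columns `frame`, `x`, `y` (px) and any
#'   extra columns to carry along.
#' @param max_dist Maximum link distance in micrometres (default 1).
#' @param min_length Minimum trace length in frames (default 1).
#' @param pixel_size Micrometres per px used to convert positions.
#' @return The detections tibble filtered to linked traces, with a
#'   `trace` id column, ordered by trace and frame.
#' @export
link_traces <- function(detections, max_dist = 1, min_length = 1L,
                        pixel_size = 1) {
  if (!all(c("frame", "x", "y") %in% names(detections)))
    abort("detections need columns frame, x, y")
  det <- dplyr::arrange(detections, .data$frame)
  det$trace <- NA_integer_
  next_id <- 0L
  frames <- sort(unique(det$frame))
  open <- tibble::tibble(trace = integer(), x = numeric(), y = numeric(),
                         frame = numeric())
  for (f in frames) {
    cur <- which(det$frame == f)
    act <- open[open$frame == f - 1, , drop = FALSE]
    assigned <- rep(NA_integer_, length(cur))
    if (nrow(act) > 0 && length(cur) > 0) {
      cost <- outer(seq_len(nrow(act)), seq_along(cur),
                    Vectorize(function(a, b) {
                      dx <- (act$x[a] - det$x[cur[b]]) * pixel_size
                      dy <- (act$y[a] - det$y[cur[b]]) * pixel_size
                      d <- sqrt(dx^2 + dy^2)
                      if (d > max_dist) Inf else d
                    }))
      if (nrow(cost) <= ncol(cost)) {
        sol <- cpp_lsap(cost)
        for (a in seq_along(sol))
          if (!is.na(sol[a])) assigned[sol[a]] <- act$trace[a]
      } else {
        sol <- cpp_lsap(t(cost))
        for (b in seq_along(sol))
          if (!is.na(sol[b])) assigned[b] <- act$trace[sol[b]]
      }
    }
    for (ib in seq_along(cur)) {
      if (is.na(assigned[ib])) {
        next_id <- next_id + 1L
        assigned[ib] <- next_id
      }
      det$trace[cur[ib]] <- assigned[ib]
    }
    open <- tibble::tibble(trace = assigned, x = det$x[cur], y = det$y[cur],
                           frame = f)
  }
  keep <- names(which(table(det$trace) >= min_length))
  det <- det[det$trace %in% as.integer(keep), , drop = FALSE]
  dplyr::arrange(det, .data$trace, .data$frame)
}
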