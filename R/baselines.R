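#' Centroid localization baseline
#'
#' Median background subtraction, negative residuals clamped to zero, then
#' the intensity-weighted centroid.
#'
#' @param image Single-object image matrix.
#' @return Length-2 numeric `(x, y)` in px (top-left, 0-based).
#' @export
centroid_localize <- function(image) {
  v <- pmax(image - median(image), 0)
  tot <- sum(v)
  if (tot <= 0) abort("no signal mass above the median background")
  i <- matrix(0:(nrow(image) - 1), nrow(image), ncol(image))
  j <- matrix(0:(ncol(image) - 1), nrow(image), ncol(image), byrow = TRUE)
  c(x = sum(i * v) / tot, y = sum(j * v) / tot)
}

#' Radial-symmetry-center localization baseline
#'
#' Finds the point minimizing the gradient-magnitude-weighted squared
#' distance to the lines through each interior pixel along its intensity
#' gradient: for a radially symmetric spot every gradient line passes
#' through the center. Gradients are central differences smoothed with a
#' 3x3 box, weights are squared gradient magnitudes, and the normal
#' equations are solved in closed form.
#'
#' @param image Single-object image matrix with a radially symmetric core.
#' @return Length-2 numeric `(x, y)` in px (top-left, 0-based).
#' @export
radial_center_localize <- function(image) {
  n1 <- nrow(image); n2 <- ncol(image)
  gx <- (image[c(2:n1, n1), ] - image[c(1, 1:(n1 - 1)), ]) / 2
  gy <- (image[, c(2:n2, n2)] - image[, c(1, 1:(n2 - 1))]) / 2
  gx <- box3_mean(gx); gy <- box3_mean(gy)
  gx <- gx[2:(n1 - 1), 2:(n2 - 1)]
  gy <- gy[2:(n1 - 1), 2:(n2 - 1)]
  w <- gx^2 + gy^2
  g2 <- w
  g2[g2 == 0] <- .Machine$double.eps
  ux <- gx / sqrt(g2); uy <- gy / sqrt(g2)
  ri <- matrix(1:(n1 - 2), n1 - 2, n2 - 2)
  rj <- matrix(1:(n2 - 2), n1 - 2, n2 - 2, byrow = TRUE)
  # A p = b with A = sum w (I - u u^T), b = sum w (I - u u^T) r
  a11 <- sum(w * (1 - ux * ux)); a12 <- sum(w * (-ux * uy))
  a22 <- sum(w * (1 - uy * uy))
  b1 <- sum(w * ((1 - ux * ux) * ri - ux * uy * rj))
  b2 <- sum(w * (-ux * uy * ri + (1 - uy * uy) * rj))
  det <- a11 * a22 - a12^2
  if (abs(det) < 1e-12) abort("degenerate gradient field")
  c(x = (a22 * b1 - a12 * b2) / det, y = (a11 * b2 - a12 * b1) / det)
}

#' Root-mean-square localization error
#'
#' `"euclidean"` averages the squared two-dimensional position error;
#' `"per_axis"` divides the squared error by two first, putting the result
#' on the same scale as the localization bound `sqrt((var_x + var_y)/2)`
#' of [rmse_bound()] (use this convention when comparing against the
#' Cramer-Rao bound).
#'
#' @param pred,truth Tibbles/data frames with `x`, `y` columns, or 2-column
#'   matrices. With `pairs = NULL` rows are paired in order.
#' @param pairs Optional 2-column matrix/tibble of (pred row, truth row)
#'   matched indices.
#' @param convention `"euclidean"` (default) or `"per_axis"`.
#' @return RMSE of the position error in px.
#' @export
rmse_localization <- function(pred, truth, pairs = NULL,
                              convention = c("euclidean", "per_axis")) {
  convention <- match.arg(convention)
  px <- if (is.matrix(pred)) pred[, 1] else pred$x
  py <- if (is.matrix(pred)) pred[, 2] else pred$y
  tx <- if (is.matrix(truth)) truth[, 1] else truth$x
  ty <- if (is.matrix(truth)) truth[, 2] else truth$y
  if (!is.null(pairs)) {
    pairs <- as.matrix(pairs)
    px <- px[pairs[, 1]]; py <- py[pairs[, 1]]
    tx <- tx[pairs[, 2]]; ty <- ty[pairs[, 2]]
  }
  if (!length(px)) abort("need at least one matched pair")
  se <- (px - tx)^2 + (py - ty)^2
  if (convention == "per_axis") se <- se / 2
  sqrt(mean(se))
}

#' Match predicted detections to ground truth
#'
#' Distance mode performs a one-to-one minimum-cost assignment with a
#' radius cutoff. Mask mode applies the segmentation-overlap rule: a
#' prediction falling on a labelled mask claims it (first one is a true
#' positive, additional ones are false positives); predictions on
#' background are false positives; unclaimed masks are false negatives.
#'
#' @param pred Tibble with `x`, `y` (px).
#' @param truth Tibble with `x`, `y` for distance mode; ignored in mask
#'   mode.
#' @param mode `"distance"` or `"mask"`.
#' @param threshold Matching radius in px (distance mode).
#' @param masks Integer-labelled matrix (mask mode), 0 = background.
#' @return A `match_result`: list with `tp`, `fp`, `fn` and a `pairs`
#'   tibble of matched (pred, truth/label) indices.
#' @export
match_detections <- function(pred, truth = NULL, mode = c("distance", "mask"),
                             threshold = 2, masks = NULL) {
  mode <- match.arg(mode)
  if (mode == "distance") {
    np <- nrow(pred); nt <- nrow(truth)
    if (np == 0 || nt == 0) {
      res <- list(tp = 0L, fp = np, fn = nt,
                  pairs = tibble::tibble(pred = integer(), truth = integer()))
      return(structure(res, class = "match_result"))
    }
    cost <- outer(seq_len(np), seq_len(nt), function(a, b)
      sqrt((pred$x[a] - truth$x[b])^2 + (pred$y[a] - truth$y[b])^2))
    cost[cost > threshold] <- Inf
    if (np <= nt) {
      sol <- cpp_lsap(cost)
      pairs <- tibble::tibble(pred = which(!is.na(sol)),
                              truth = sol[!is.na(sol)])
    } else {
      sol <- cpp_lsap(t(cost))
      pairs <- tibble::tibble(pred = sol[!is.na(sol)],
                              truth = which(!is.na(sol)))
    }
    tp <- nrow(pairs)
    res <- list(tp = tp, fp = np - tp, fn = nt - tp, pairs = pairs)
  } else {
    if (is.null(masks)) abort("mask mode requires a label matrix")
    lab <- integer(nrow(pred))
    for (r in seq_len(nrow(pred))) {
      i <- round(pred$x[r]) + 1L; j <- round(pred$y[r]) + 1L
      lab[r] <- if (i >= 1 && j >= 1 && i <= nrow(masks) && j <= ncol(masks))
        masks[i, j] else 0L
    }
    labels <- setdiff(unique(as.vector(masks)), 0L)
    hit <- lab[lab != 0L]
    tp <- length(unique(hit))
    fp <- sum(lab == 0L) + (length(hit) - tp)
    fn <- length(setdiff(labels, hit))
    first_hit <- !duplicated(lab) & lab != 0L
    res <- list(tp = tp, fp = fp, fn = fn,
                pairs = tibble::tibble(pred = which(first_hit),
                                       truth = lab[first_hit]))
  }
  structure(res, class = "match_result")
}

#' F1 score of a match result
#'
#' `2 TP / (2 TP + FP + FN)`.
#'
#' @param match A `match_result` from [match_detections()].
#' @return F1 score in `[0, 1]`.
#' @export
f1_score <- function(match) {
  denom <- 2 * match$tp + match$fp + match$fn
  if (denom == 0) abort("empty match: no predictions and no truth")
  2 * match$tp / denom
}

#' Covariance-based diffusion coefficient estimator
#'
#' Per-axis estimator from frame-to-frame displacements:
#' `D = mean(d^2)/(2 dt) + mean(d_n d_{n+1})/dt`. The covariance term
#' cancels the bias from static localization noise. Positions are taken in
#' px and converted with `pixel_size` (the optional `z` column is assumed
#' to be in micrometres already).
#'
#' @param trace Tibble with `x`, `y` and optionally `z`, ordered by frame.
#' @param dt Frame interval in seconds.
#' @param pixel_size Micrometres per px.
#' @return One-row tibble with per-axis estimates (`D_x`, `D_y`,
#'   optionally `D_z`) and the in-plane mean `D_xy`, in um^2/s.
#' @export
diffusion_coefficient <- function(trace, dt, pixel_size = 1) {
  if (nrow(trace) < 10) abort("trace too short (need >= 10 frames)")
  est <- function(pos) {
    d <- diff(pos)
    mean(d^2) / (2 * dt) + mean(head(d, -1) * tail(d, -1)) / dt
  }
  dx <- est(trace$x * pixel_size)
  dy <- est(trace$y * pixel_size)
  out <- tibble::tibble(D_x = dx, D_y = dy, D_xy = (dx + dy) / 2)
  if ("z" %in% names(trace)) out$D_z <- est(trace$z)
  out
}

#' Simulate Brownian traces
#'
#' @param n_traces Number of independent traces.
#' @param n_steps Steps per trace.
#' @param D Diffusion coefficient in um^2/s.
#' @param dt Frame interval in seconds.
#' @param seed Optional integer seed.
#' @param drift Optional per-axis drift velocity in um/s (length 3).
#' @return Tibble with `id`, `frame`, and `x`, `y`, `z` positions in
#'   micrometres.
#' @export
simulate_brownian_traces <- function(n_traces, n_steps, D = 0.97, dt = 1 / 30,
                                     seed = NULL, drift = c(0, 0, 0)) {
  with_seed(seed, {
    sd_step <- sqrt(2 * D * dt)
    purrr::map_dfr(seq_len(n_traces), function(id) {
      steps <- matrix(rnorm(3 * n_steps, sd = sd_step), n_steps, 3)
      steps <- sweep(steps, 2, drift * dt, `+`)
      pos <- apply(steps, 2, cumsum)
      tibble::tibble(id = id, frame = seq_len(n_steps),
                     x = pos[, 1], y = pos[, 2], z = pos[, 3])
    })
  })
}
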