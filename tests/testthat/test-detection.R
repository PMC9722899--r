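make_stack <- function(arr, input_dim = 2L * dim(arr)[1:2]) {
  lodestar:::new_feature_stack(arr, network_config(channels = 4L), input_dim)
}

test_that("clustering map equals the hand-computed local variance", {
  arr <- array(0, c(8, 8, 3))
  st <- make_stack(arr)
  # constant maps: zero variance everywhere, clamped at 1 / eps_b
  b <- clustering_map(st, eps_b = 1e-6)
  # position maps vary linearly, so interior variance is that of the ramp:
  # var of {0, 2, 4} per axis under a 3x3 mean = 8/3 per channel
  ramp_var <- mean((c(0, 2, 4) - 2)^2)
  expect_equal(b[4, 4], 1 / (2 * ramp_var), tolerance = 1e-10)

  # hand-computed 3x3 patch in the dx channel
  arr2 <- array(0, c(8, 8, 3))
  patch <- matrix((0:8) / 9, 3, 3)
  arr2[3:5, 3:5, 1] <- patch
  st2 <- make_stack(arr2)
  b2 <- clustering_map(st2, eps_b = 1e-6)
  # x map around (4, 4): the offset patch plus the i*k row ramp
  v <- patch + matrix(c(6, 8, 10), 3, 3)    # rows i = 3, 4, 5 (0-based), k = 2
  manual <- (mean(v^2) - mean(v)^2) + ramp_var
  expect_equal(1 / b2[4, 4], manual, tolerance = 1e-10)

  # adding a constant to a channel leaves b unchanged (variance shift)
  arr3 <- arr2; arr3[, , 2] <- arr3[, , 2] + 11
  expect_equal(clustering_map(make_stack(arr3)), b2, tolerance = 1e-10)
})

test_that("score map combines weight and clustering geometrically", {
  set.seed(5)
  w <- matrix(runif(64), 8, 8); b <- matrix(runif(64) * 10, 8, 8)
  expect_equal(score_map(w, b, detect_params(alpha = 1)), w)
  expect_equal(score_map(w, b, detect_params(alpha = 0)), b)
  expect_equal(score_map(w, b, detect_params(alpha = 0.5)), sqrt(w * b),
               tolerance = 1e-12)
  expect_error(score_map(-w, b, detect_params()), "non-negative")
})

test_that("morphological reconstruction matches the brute-force oracle", {
  set.seed(8)
  for (rep in 1:5) {
    mask <- matrix(runif(100), 10, 10)
    marker <- mask - runif(1, 0.05, 0.3)
    fast <- lodestar:::cpp_reconstruct_dilation(marker, mask)
    slow <- brute_reconstruct(marker, mask)
    expect_equal(fast, slow, tolerance = 1e-12)
  }
})

test_that("local maxima finds prominent bumps and ignores flat maps", {
  g1 <- outer(dnorm(1:32, 10, 2), dnorm(1:32, 12, 2))
  cand <- local_maxima(g1, detect_params(quantile = 0.9))
  expect_equal(nrow(cand), 1L)
  expect_equal(c(cand$i, cand$j), c(9, 11))  # 0-based peak position

  g2 <- g1 + outer(dnorm(1:32, 25, 2), dnorm(1:32, 24, 2))
  cand2 <- local_maxima(g2, detect_params(quantile = 0.9))
  expect_equal(nrow(cand2), 2L)

  expect_equal(nrow(local_maxima(matrix(1, 16, 16), detect_params())), 0L)
})

test_that("raising the quantile threshold never increases detections", {
  set.seed(13)
  smooth <- lodestar:::box3_mean(lodestar:::box3_mean(matrix(runif(900), 30, 30)))
  prev <- Inf
  for (q in c(0.5, 0.8, 0.9, 0.99)) {
    n <- nrow(local_maxima(smooth, detect_params(quantile = q)))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("refinement returns encoded positions for synthetic stacks", {
  arr <- array(0, c(16, 16, 3))
  arr[, , 3] <- -30
  arr[9, 7, 3] <- 30                       # all weight on one pixel
  st <- make_stack(arr)
  cand <- tibble::tibble(i = 8L, j = 6L, score = 1)
  det <- refine(cand, st, detect_params(window = 2L))
  pm <- lodestar:::property_maps(st)
  expect_equal(det$x, pm$x[9, 7])
  expect_equal(det$y, pm$y[9, 7])
})

test_that("linear sum assignment matches brute force on small instances", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(2:5, 1); m <- n + sample(0:2, 1)
    cost <- matrix(runif(n * m), n, m)
    sol <- lodestar:::cpp_lsap(cost)
    oracle <- brute_lsap(cost)
    expect_equal(sum(cost[cbind(1:n, sol)]), oracle$cost, tolerance = 1e-12)
  }
})

test_that("trace linking preserves identities and filters short traces", {
  # one drifting particle: a single trace spanning all frames
  det <- tibble::tibble(frame = 1:50, x = 10 + 0.2 * (1:50), y = 20,
                        score = 1)
  tr <- link_traces(det, max_dist = 1, pixel_size = 1)
  expect_equal(length(unique(tr$trace)), 1L)
  expect_equal(nrow(tr), 50L)

  # two particles whose swap would need a jump beyond max_dist
  det2 <- dplyr::bind_rows(
    tibble::tibble(frame = 1:20, x = 10 + 0.1 * (1:20), y = 10, score = 1),
    tibble::tibble(frame = 1:20, x = 30 - 0.1 * (1:20), y = 10, score = 1))
  tr2 <- link_traces(det2, max_dist = 1)
  expect_equal(length(unique(tr2$trace)), 2L)
  by_trace <- split(tr2$x, tr2$trace)
  # each trace stays on its own side
  expect_true(all(vapply(by_trace, function(v) all(v < 20) || all(v > 20),
                         logical(1))))

  # a 39-frame trace does not survive a 40-frame minimum
  det3 <- tibble::tibble(frame = 1:39, x = 5, y = 5, score = 1)
  expect_equal(nrow(link_traces(det3, max_dist = 1, min_length = 40L)), 0L)
  expect_equal(nrow(link_traces(det3, max_dist = 1, min_length = 39L)), 39L)
})

test_that("distance conversion applies before the gating threshold", {
  det <- tibble::tibble(frame = c(1, 2), x = c(0, 8), y = c(0, 0), score = 1)
  # 8 px at 0.1 um/px = 0.8 um < 1 um: linked
  tr <- link_traces(det, max_dist = 1, pixel_size = 0.1)
  expect_equal(length(unique(tr$trace)), 1L)
  # at 0.2 um/px = 1.6 um: two separate traces
  tr2 <- link_traces(det, max_dist = 1, pixel_size = 0.2)
  expect_equal(length(unique(tr2$trace)), 2L)
})
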