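# Shared fixtures: everything is generated in code at test time.

tiny_grid <- function(n = 64L) grid_spec(n, n)

# A quick noiseless render of each shape at a given position.
quick_render <- function(shape, position = c(31.5, 31.5), orientation = 0,
                         grid = tiny_grid(), ...) {
  render_shape(shape_spec(shape, ...), position, orientation, grid)
}

# Brute-force weighted average used as the oracle for pooled predictions.
brute_pooled <- function(stack, w) {
  maps <- lodestar:::property_maps(stack)
  vapply(maps, function(m) sum(m * w) / sum(w), numeric(1))
}

# Brute-force O(n!) assignment oracle for tiny cost matrices.
brute_lsap <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(m))) {
    sel <- p[seq_len(n)]
    cc <- sum(cost[cbind(seq_len(n), sel)])
    if (cc < best_cost) { best_cost <- cc; best <- sel }
  }
  list(assignment = best, cost = best_cost)
}

# Brute-force grayscale reconstruction oracle (iterated 3x3 dilation).
brute_reconstruct <- function(marker, mask) {
  J <- pmin(marker, mask)
  repeat {
    padded <- rbind(-Inf, cbind(-Inf, J, -Inf), -Inf)
    n1 <- nrow(J); n2 <- ncol(J)
    dil <- J
    for (di in -1:1) for (dj in -1:1)
      dil <- pmax(dil, padded[(2 + di):(n1 + 1 + di), (2 + dj):(n2 + 1 + dj)])
    Jn <- pmin(dil, mask)
    if (identical(Jn, J)) return(J)
    J <- Jn
  }
}
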