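# Small programmatic fixtures shared across test files.

# filled disc image (bright on dark), 0-based center coordinates
disc_frame <- function(shape, cx, cy, radius, fg = 0.8, bg = 0.1) {
  x <- matrix(rep(seq_len(shape[2]) - 1, each = shape[1]), shape[1], shape[2])
  y <- matrix(rep(seq_len(shape[1]) - 1, times = shape[2]), shape[1], shape[2])
  img <- matrix(bg, shape[1], shape[2])
  img[(x - cx)^2 + (y - cy)^2 <= radius^2] <- fg
  img
}

# horizontal bright bar of given length/thickness, top-left at (x0, y0)
bar_frame <- function(shape, x0, y0, len, thick, fg = 0.9, bg = 0.05) {
  img <- matrix(bg, shape[1], shape[2])
  img[(y0 + 1):(y0 + thick), (x0 + 1):(x0 + len)] <- fg
  img
}

# independent brute-force ZNCC over all integer offsets (oracle for
# match_subset); returns c(u, v, corr) of the argmax
brute_force_match <- function(ref, def, node, subset_size, search_radius) {
  half <- (subset_size - 1) / 2
  xs <- (node[1] - half):(node[1] + half) + 1
  ys <- (node[2] - half):(node[2] + half) + 1
  tmpl <- as.vector(ref[ys, xs])
  best <- c(NA, NA, -Inf)
  for (du in -search_radius:search_radius) {
    for (dv in -search_radius:search_radius) {
      w <- as.vector(def[ys + dv, xs + du])
      if (stats::sd(w) < 1e-12) next
      cc <- stats::cor(tmpl, w)
      if (is.finite(cc) && cc > best[3]) best <- c(du, dv, cc)
    }
  }
  best
}

# exact rigid-rotation displacement field evaluated at grid nodes
rotation_field <- function(grid, angle) {
  cx <- mean(range(grid$node_x)); cy <- mean(range(grid$node_y))
  x <- grid$nodes$x; y <- grid$nodes$y
  u <- cos(angle) * (x - cx) - sin(angle) * (y - cy) + cx - x
  v <- sin(angle) * (x - cx) + cos(angle) * (y - cy) + cy - y
  structure(list(field = data.frame(node_x = x, node_y = y, u = u, v = v,
                                    peak_corr = 1, valid = TRUE),
                 grid = grid),
            class = "displacement_field")
}

default_kv <- function(tau = 7.74, sigma0 = 770, E1 = 2.2e4, E2 = 1.55e4) {
  kv_params(sigma0 = sigma0, E1 = E1, E2 = E2, eta = E2 * tau)
}
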