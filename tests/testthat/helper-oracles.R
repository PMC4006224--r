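# Independent reference implementations used to cross-check the package:
# written from the definitions, by a different route than the production
# code, and kept deliberately slow and literal.

# Kendall's W from the definition: ranks built by explicit counting
# (average ranks for ties), rank-sums and dispersion by explicit loops.
oracle_kendalls_w <- function(mat) {
  m <- nrow(mat); k <- ncol(mat)
  ranks <- matrix(0, m, k)
  for (i in seq_len(m)) {
    for (j in seq_len(k)) {
      smaller <- sum(mat[i, ] < mat[i, j])
      equal <- sum(mat[i, ] == mat[i, j])
      ranks[i, j] <- smaller + (equal + 1) / 2
    }
  }
  S <- 0
  for (j in seq_len(k)) {
    Rj <- sum(ranks[, j])
    S <- S + (Rj - m * (k + 1) / 2)^2
  }
  12 * S / (m^2 * (k^3 - k))
}

# Monte-Carlo RMS deviation: root mean squared displacement of points
# sampled uniformly in the radius-R ball centred at `center`.
oracle_rms_mc <- function(a, b, R = 80, center = c(0, 0, 0),
                          n = 1e5, seed = 0) {
  set.seed(seed)
  # uniform in ball: direction * radius with r ~ R * U^(1/3)
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- u * (R * runif(n)^(1 / 3)) +
    matrix(center, n, 3, byrow = TRUE)
  d <- b %*% solve(a)
  moved <- pts %*% t(d[1:3, 1:3]) + matrix(d[1:3, 4], n, 3, byrow = TRUE)
  sqrt(mean(rowSums((moved - pts)^2)))
}

# Dense-threshold TFCE: per-threshold connected components labelled with
# igraph, which shares no code with the union-find kernel.
oracle_tfce <- function(stat_map, mask, H, E, dh, connectivity = 26) {
  skip_if_not_installed("igraph")
  idx <- which(mask)
  sv <- pmax(stat_map[idx], 0)
  adj <- motiondiff:::build_adjacency(mask, connectivity)
  edges <- cbind(rep(seq_along(idx), diff(adj$ptr)), adj$idx + 1L)
  edges <- edges[edges[, 1] < edges[, 2], , drop = FALSE]
  out <- numeric(length(idx))
  hmax <- max(sv)
  if (hmax <= 0) return(array(0, dim(mask)))
  nst <- ceiling(hmax / dh - 1e-12)
  for (s in seq_len(nst)) {
    h <- (s - 0.5) * dh
    act <- sv >= h
    keep <- edges[act[edges[, 1]] & act[edges[, 2]], , drop = FALSE]
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    if (nrow(keep) > 0) g <- igraph::add_edges(g, t(keep))
    comp <- igraph::components(g)
    sizes <- comp$csize[comp$membership]   # isolated actives -> size 1
    out[act] <- out[act] + sizes[act]^E * h^H * dh
  }
  vol <- array(0, dim(mask))
  vol[idx] <- out
  vol
}

# small straight-slab FA map spanning the whole grid, for skeleton tests
make_slab_fa <- function(shape = c(20, 20, 12), half = 2, fa = 0.8) {
  iy <- slice.index(array(0, shape), 2) - 1
  center <- floor(shape[2] / 2)
  fa * (abs(iy - center) <= half)
}

expect_allclose <- function(x, y, tol = 1e-9) {
  expect_lt(max(abs(x - y)), tol)
}
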