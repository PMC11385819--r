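# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths and igraph.

# queue-based flood fill labelling of positive cells
flood_fill_label <- function(mat, connectivity = 8) {
  nr <- nrow(mat); nc <- ncol(mat)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, ]
  }
  cur <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (mat[r, c] > 0 && lab[r, c] == 0L) {
      cur <- cur + 1L
      queue <- list(c(r, c))
      lab[r, c] <- cur
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (i in seq_len(nrow(nb))) {
          rr <- p[1] + nb[i, 1]; cc <- p[2] + nb[i, 2]
          if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
              mat[rr, cc] > 0 && lab[rr, cc] == 0L) {
            lab[rr, cc] <- cur
            queue[[length(queue) + 1]] <- c(rr, cc)
          }
        }
      }
    }
  }
  lab
}

# adjacency matrix of a spatial_network over its visited nodes
net_adjacency <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0L, n, n)
  if (nrow(net$links) > 0) {
    iu <- match(net$links[, 1], net$nodes)
    iv <- match(net$links[, 2], net$nodes)
    A[cbind(iu, iv)] <- 1L
    A[cbind(iv, iu)] <- 1L
  }
  A
}

# global transitivity by exhaustive triple enumeration:
# 3 * triangles / connected triples (a triple is a path of length 2)
brute_clustering <- function(A) {
  n <- nrow(A)
  triangles <- 0; triples <- 0
  for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    e <- A[i, j] + A[j, k] + A[i, k]
    if (e == 2) triples <- triples + 1
    if (e == 3) { triples <- triples + 3; triangles <- triangles + 1 }
  }
  if (triples == 0) return(0)
  3 * triangles / triples
}

# characteristic path length by Floyd-Warshall over reachable pairs
brute_path_length <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  up <- D[upper.tri(D)]
  fin <- is.finite(up)
  list(L = if (any(fin)) mean(up[fin]) else NA_real_,
       n_unreachable = sum(!fin))
}

# empirical semivariogram over replicate fields at axis-aligned integer lags
empirical_variogram <- function(fields, lags) {
  vapply(lags, function(h) {
    acc <- 0; npairs <- 0
    for (f in fields) {
      nc <- ncol(f); nr <- nrow(f)
      dh <- f[, seq_len(nc - h)] - f[, (h + 1):nc]
      dv <- f[seq_len(nr - h), ] - f[(h + 1):nr, ]
      acc <- acc + sum(dh^2) + sum(dv^2)
      npairs <- npairs + length(dh) + length(dv)
    }
    acc / (2 * npairs)
  }, numeric(1))
}

# random spatial_network on n nodes with m links (universe = n patches)
random_test_network <- function(n, m, seed) {
  set.seed(seed)
  all_pairs <- t(utils::combn(n, 2))
  sel <- sample(nrow(all_pairs), m)
  spatial_network(seq_len(n), all_pairs[sel, , drop = FALSE], n)
}

# sorted-array quantile oracle (type-7 interpolation)
quantile7 <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# resource grid wrapper around a plain value matrix (for scripted landscapes)
grid_from_matrix <- function(vals) {
  structure(list(values = vals / sum(vals), raw = vals, spec = NULL,
                 frag_level = "custom", empty = all(vals <= 0), seed = NA),
            class = "resource_grid")
}
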