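#' Minimum boundary-to-boundary distances between patches
#'
#' Inter-patch distance is the minimum Euclidean distance between boundary
#' cell centers of the two patches (a centroid-based alternative is
#' available). Used for realized link lengths, distance-threshold networks
#' and the planar graph.
#'
#' @param pm A `patch_map`.
#' @param method "boundary" (default) or "centroid".
#' @return A symmetric P x P distance matrix (0 on the diagonal).
#' @export
patch_distances <- function(pm, method = c("boundary", "centroid")) {
  method <- match.arg(method)
  P <- pm$n_patches
  d <- matrix(0, P, P)
  if (P < 2) return(d)
  if (method == "centroid") {
    xy <- as.matrix(pm$patches[, c("centroid_x", "centroid_y")])
    return(as.matrix(stats::dist(xy)))
  }
  for (i in seq_len(P - 1)) {
    bi <- pm$boundary[[i]]
    for (j in (i + 1):P) {
      bj <- pm$boundary[[j]]
      dx <- outer(bi[, 1], bj[, 1], "-")
      dy <- outer(bi[, 2], bj[, 2], "-")
      d[i, j] <- d[j, i] <- sqrt(min(dx^2 + dy^2))
    }
  }
  d
}

#' Minimum planar graph of a patch map
#'
#' Grid-Voronoi approximation under uniform resistance: every cell is
#' assigned to its nearest patch (Euclidean distance from cell center to the
#' patch's boundary cells; ties broken toward the lower patch id), and two
#' patches are linked when their regions share a rook-adjacent cell edge.
#' Region adjacency makes the graph planar in the patch-region embedding, so
#' links never cross.
#'
#' @param pm A `patch_map` (with < 2 patches the link set is empty).
#' @return A `spatial_network` whose nodes are all patches.
#' @export
build_mpg <- function(pm) {
  P <- pm$n_patches
  if (P < 2)
    return(spatial_network(seq_len(P), NULL, pm,
                           provenance = list(model = "MPG")))
  nr <- pm$nrows; nc <- pm$ncols
  cx <- rep(seq_len(nc) - 0.5, each = nr)
  cy <- rep(seq_len(nr) - 0.5, times = nc)
  best_d <- rep(Inf, nr * nc)
  region <- integer(nr * nc)
  for (i in seq_len(P)) {
    b <- pm$boundary[[i]]
    di <- rep(Inf, nr * nc)
    for (kk in seq_len(nrow(b))) {
      dd <- (cx - b[kk, 1])^2 + (cy - b[kk, 2])^2
      di <- pmin(di, dd)
    }
    upd <- di < best_d
    best_d[upd] <- di[upd]
    region[upd] <- i
  }
  region[as.vector(pm$labels) > 0] <- as.vector(pm$labels)[as.vector(pm$labels) > 0]
  reg <- matrix(region, nr, nc)
  pairs <- rbind(cbind(as.vector(reg[-nr, ]), as.vector(reg[-1, ])),
                 cbind(as.vector(reg[, -nc]), as.vector(reg[, -1])))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  spatial_network(seq_len(P), pairs, pm, provenance = list(model = "MPG"))
}

#' Realized link lengths and distance thresholds
#'
#' Length of each realized link (minimum boundary-to-boundary distance of its
#' two patches) plus the median (`L_med`) and the 95\% empirical quantile
#' (`L_95`) of the length distribution, the thresholds of the DIST50 and
#' DIST95 models.
#'
#' @param net A realized `spatial_network` with >= 1 link.
#' @param pm The patch universe.
#' @param dist Optional precomputed [patch_distances()] matrix.
#' @return List with `lengths`, `L_med`, `L_95`.
#' @export
realized_link_lengths <- function(net, pm, dist = NULL) {
  if (nrow(net$links) == 0)
    stop("network has no links; thresholds undefined")
  if (is.null(dist)) dist <- patch_distances(pm)
  len <- dist[net$links]
  list(lengths = len,
       L_med = stats::median(len),
       L_95 = unname(stats::quantile(len, 0.95, type = 7)))
}

#' Distance-threshold connectivity network
#'
#' Links every unordered patch pair whose boundary-to-boundary distance does
#' not exceed the threshold. The comparison is inclusive by default: on a
#' cell grid the link-length distribution has large atoms (e.g. many patch
#' pairs exactly 2 cells apart), and a strict cutoff at the median of such a
#' distribution would drop the entire median atom and routinely produce an
#' empty DIST50 graph; set `strict = TRUE` for the strict variant.
#'
#' @param pm A `patch_map`.
#' @param threshold Distance threshold (>= 0).
#' @param dist Optional precomputed distance matrix.
#' @param strict Use `<` instead of `<=` (default FALSE).
#' @return A `spatial_network` over all patches.
#' @export
build_distance_network <- function(pm, threshold, dist = NULL,
                                   strict = FALSE) {
  stopifnot(threshold >= 0)
  P <- pm$n_patches
  if (is.null(dist)) dist <- patch_distances(pm)
  pairs <- if (strict) which(upper.tri(dist) & dist < threshold, arr.ind = TRUE)
           else which(upper.tri(dist) & dist <= threshold, arr.ind = TRUE)
  spatial_network(seq_len(P), pairs, pm,
                  provenance = list(model = "DIST", threshold = threshold))
}

#' Random connectivity network
#'
#' Uniform sample without replacement of `n_links` unordered pairs among all
#' patches of the landscape (not only visited ones).
#'
#' @param pm A `patch_map`.
#' @param n_links Number of links (<= P(P-1)/2).
#' @param seed Integer seed.
#' @return A `spatial_network` over all patches.
#' @export
build_random_network <- function(pm, n_links, seed = NULL) {
  P <- pm$n_patches
  n_max <- P * (P - 1) / 2
  if (n_links > n_max)
    stop("n_links exceeds the number of available patch pairs")
  if (!is.null(seed)) set.seed(seed)
  sel <- sample.int(n_max, n_links)
  # map linear indices to (i, j) pairs of the upper triangle, column-major
  ut <- which(upper.tri(matrix(0, P, P)), arr.ind = TRUE)
  spatial_network(seq_len(P), ut[sel, , drop = FALSE], pm,
                  provenance = list(model = "Rand"))
}

.link_keys <- function(net) {
  if (nrow(net$links) == 0) return(character(0))
  paste(net$links[, 1], net$links[, 2], sep = "-")
}

#' Cohen's kappa between predicted and realized links
#'
#' Chance-corrected agreement between two 0/1 labelings of the same
#' patch-pair universe: `a` pairs linked in both, `b` predicted only, `c`
#' realized only, `d` in neither; `po = (a + d)/N`,
#' `pe = [(a+b)(a+c) + (c+d)(b+d)] / N^2`, `kappa = (po - pe)/(1 - pe)`.
#' When `pe = 1` kappa is defined as 1 if `po = 1` and 0 otherwise (flagged).
#'
#' @param predicted,realized `spatial_network`s over the same patch universe.
#' @param universe Optional two-column matrix of patch pairs restricting the
#'   comparison; default: all unordered pairs of the universe's patches.
#' @return List of class `kappa_result`: `a`, `b`, `c`, `d`, `n_pairs`, `po`,
#'   `pe`, `kappa`, `degenerate`.
#' @export
cohens_kappa <- function(predicted, realized, universe = NULL) {
  if (is.null(universe)) {
    P <- predicted$n_universe
    stopifnot(P == realized$n_universe)
    N <- P * (P - 1) / 2
    pk <- .link_keys(predicted)
    rk <- .link_keys(realized)
  } else {
    u <- cbind(pmin(universe[, 1], universe[, 2]),
               pmax(universe[, 1], universe[, 2]))
    keys <- unique(paste(u[, 1], u[, 2], sep = "-"))
    N <- length(keys)
    pk <- intersect(.link_keys(predicted), keys)
    rk <- intersect(.link_keys(realized), keys)
  }
  if (N == 0) stop("empty patch-pair universe")
  a <- length(intersect(pk, rk))
  b <- length(setdiff(pk, rk))
  cc <- length(setdiff(rk, pk))
  d <- N - a - b - cc
  po <- (a + d) / N
  pe <- ((a + b) * (a + cc) + (cc + d) * (b + d)) / N^2
  degenerate <- abs(1 - pe) < 1e-12
  kappa <- if (degenerate) { if (abs(po - 1) < 1e-12) 1 else 0 }
           else (po - pe) / (1 - pe)
  structure(list(a = a, b = b, c = cc, d = d, n_pairs = N, po = po, pe = pe,
                 kappa = kappa, degenerate = degenerate),
            class = "kappa_result")
}
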