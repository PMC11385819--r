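#' Map relocations to patch labels
#'
#' Assigns each relocation of a trajectory to the patch label of the cell
#' containing it (0 for matrix cells). Cells are half-open intervals: a
#' position with coordinate `x` lies in column `floor(x) + 1`.
#'
#' @param traj A `trajectory`.
#' @param pm A `patch_map`.
#' @return Integer vector of patch ids (0 = matrix), one per relocation.
#' @export
locate <- function(traj, pm) {
  stopifnot(inherits(traj, "trajectory"), inherits(pm, "patch_map"))
  cc <- floor(traj$x) + 1
  rr <- floor(traj$y) + 1
  bad <- which(cc < 1 | cc > pm$ncols | rr < 1 | rr > pm$nrows)
  if (length(bad) > 0)
    stop(sprintf("relocation %d of trajectory %s is outside the landscape",
                 bad[1], traj$id))
  pm$labels[cbind(rr, cc)]
}

#' Collapse a patch-id sequence into patch visits
#'
#' Drops matrix relocations, collapses consecutive runs within one patch
#' into a single visit, and merges immediate re-entries (patch A, matrix
#' only, patch A again) into the previous visit so no self-link can arise.
#'
#' @param ids Integer vector of patch ids (0 = matrix), e.g. from [locate()].
#' @return Integer vector of successive distinct visited patches (class
#'   `visit_sequence`).
#' @export
visit_sequence <- function(ids) {
  ids <- ids[ids != 0]
  if (length(ids) == 0) return(structure(integer(0), class = "visit_sequence"))
  keep <- c(TRUE, ids[-1] != ids[-length(ids)])
  structure(as.integer(ids[keep]), class = "visit_sequence")
}

#' Construct a spatial network
#'
#' @param nodes Integer vector of visited patch ids.
#' @param links Two-column matrix of patch-id pairs (unordered); normalized
#'   so each row has the smaller id first, duplicates and self-loops removed.
#' @param pm The patch universe (`patch_map`), or an integer giving the
#'   number of patches in the universe.
#' @param provenance Optional list (trajectory ids, resampling factor, ...).
#' @return An object of class `spatial_network` with sorted `nodes`, a
#'   normalized `links` matrix, and `n_universe`.
#' @export
spatial_network <- function(nodes, links, pm, provenance = list()) {
  n_universe <- if (inherits(pm, "patch_map")) pm$n_patches else as.integer(pm)
  nodes <- sort(unique(as.integer(nodes)))
  if (is.null(links) || length(links) == 0) {
    links <- matrix(integer(0), ncol = 2)
  } else {
    links <- matrix(as.integer(links), ncol = 2)
    links <- cbind(pmin(links[, 1], links[, 2]), pmax(links[, 1], links[, 2]))
    links <- links[links[, 1] != links[, 2], , drop = FALSE]
    links <- unique(links)
    links <- links[order(links[, 1], links[, 2]), , drop = FALSE]
  }
  if (nrow(links) > 0) {
    stopifnot(all(links %in% nodes))
  }
  stopifnot(all(nodes >= 1), all(nodes <= n_universe))
  colnames(links) <- c("u", "v")
  structure(list(nodes = nodes, links = links, n_universe = n_universe,
                 provenance = provenance),
            class = "spatial_network")
}

#' @exportS3Method base::print
print.spatial_network <- function(x, ...) {
  cat(sprintf("<spatial_network> %d nodes, %d links (universe of %d patches)\n",
              length(x$nodes), nrow(x$links), x$n_universe))
  invisible(x)
}

#' Build a patch network from visit sequences
#'
#' Nodes are all visited patches; links are the unique unordered pairs of
#' successive visits (unweighted, undirected). Multiple individuals'
#' sequences are pooled into one network.
#'
#' @param vs A `visit_sequence` or list of them.
#' @param pm The patch universe (`patch_map` or patch count).
#' @param provenance Optional provenance list.
#' @return A `spatial_network`.
#' @export
build_network <- function(vs, pm, provenance = list()) {
  if (!is.list(vs)) vs <- list(vs)
  nodes <- integer(0)
  links <- matrix(integer(0), ncol = 2)
  for (s in vs) {
    s <- as.integer(s)
    nodes <- c(nodes, s)
    if (length(s) >= 2)
      links <- rbind(links, cbind(s[-length(s)], s[-1]))
  }
  spatial_network(nodes, links, pm, provenance)
}

#' Network straight from a trajectory
#'
#' Convenience wrapper: [locate()] then [visit_sequence()] then
#' [build_network()], pooling multiple trajectories when given a list.
#'
#' @param traj A `trajectory` or list of trajectories.
#' @param pm A `patch_map`.
#' @param k Resampling factor recorded in provenance (default 1, no
#'   resampling performed here).
#' @return A `spatial_network`.
#' @export
trajectory_network <- function(traj, pm, k = 1L) {
  if (inherits(traj, "trajectory")) traj <- list(traj)
  vs <- lapply(traj, function(tr) visit_sequence(locate(tr, pm)))
  build_network(vs, pm,
                provenance = list(ids = vapply(traj, `[[`, "", "id"), k = k))
}

#' Resample a trajectory at a coarser schedule
#'
#' Keeps relocations at indices `start, start + k, start + 2k, ...`
#' (0-based `start`), emulating a coarser relocation frequency. With a
#' `daily_shift`, the sampling phase advances by `shift` indices at each
#' day boundary (`day_length` relocations per day), covering all phases over
#' successive days as in rotating GPS duty cycles.
#'
#' @param traj A `trajectory`.
#' @param k Keep one relocation in `k` (`k = 1` is the identity).
#' @param start 0-based phase offset, `0 <= start < k`.
#' @param daily_shift Optional list(`day_length`, `shift`).
#' @return The thinned `trajectory` (step indices renumbered 0, 1, 2, ...;
#'   original indices kept in `$orig_steps`).
#' @export
resample_trajectory <- function(traj, k, start = 0L, daily_shift = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  n <- length(traj$steps)
  k <- as.integer(k)
  if (k < 1 || k > n) stop("resampling factor k must be in [1, length]")
  if (start < 0 || start >= k) stop("start must satisfy 0 <= start < k")
  i0 <- seq_len(n) - 1L                  # 0-based indices
  if (is.null(daily_shift)) {
    keep <- (i0 - start) %% k == 0 & i0 >= start
  } else {
    day <- i0 %/% as.integer(daily_shift$day_length)
    phase <- (start + day * as.integer(daily_shift$shift)) %% k
    keep <- (i0 %% k) == phase
  }
  idx <- which(keep)
  out <- new_trajectory(id = traj$id, steps = seq_along(idx) - 1L,
                        x = traj$x[idx], y = traj$y[idx],
                        process = traj$process,
                        landscape_id = traj$landscape_id, seed = traj$seed)
  out$orig_steps <- traj$steps[idx]
  out$k <- k
  out
}

#' Convert a spatial network to an igraph graph
#'
#' Vertices are the visited patches (isolated visited patches included),
#' names carry the patch ids.
#'
#' @param net A `spatial_network`.
#' @return An igraph object.
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = length(net$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(net$nodes))
  if (nrow(net$links) > 0) {
    idx <- match(t(net$links), net$nodes)
    g <- igraph::add_edges(g, idx)
  }
  g
}
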