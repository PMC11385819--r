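#' Regular mosaic of square patches
#'
#' Deterministic patch map: `n_patches` square patches of side `patch_size`
#' laid out row by row (from the bottom-left) with `spacing` matrix cells
#' between patch edges. Centroids, areas and pairwise distances are known in
#' closed form, which makes the mosaic the analytic test surface for the
#' network pipeline.
#'
#' @param n_patches Number of patches.
#' @param spacing Matrix cells between adjacent patch edges (>= 1).
#' @param patch_size Patch side length in cells.
#' @param dims `c(nrows, ncols)` of the landscape.
#' @return A `patch_map` with patch ids 1..n in layout order.
#' @export
make_patch_mosaic <- function(n_patches, spacing = 3, patch_size = 3,
                              dims = c(50, 50)) {
  stopifnot(n_patches >= 1, spacing >= 1, patch_size >= 1)
  nr <- dims[1]; nc <- dims[2]
  pitch <- patch_size + spacing
  per_row <- max(1, (nc - spacing - patch_size) %/% pitch + 1)
  n_rows_needed <- ceiling(n_patches / per_row)
  if (spacing + (n_rows_needed - 1) * pitch + patch_size > nr ||
      spacing + patch_size > nc)
    stop("mosaic does not fit: reduce n_patches, spacing or patch_size")
  labels <- matrix(0L, nr, nc)
  for (i in seq_len(n_patches)) {
    gr <- (i - 1) %/% per_row
    gc <- (i - 1) %% per_row
    r0 <- spacing + gr * pitch
    c0 <- spacing + gc * pitch
    if (r0 + patch_size > nr || c0 + patch_size > nc)
      stop("mosaic does not fit: patch ", i, " exceeds the landscape")
    labels[(r0 + 1):(r0 + patch_size), (c0 + 1):(c0 + patch_size)] <- i
  }
  .patch_map_from_labels(labels)
}

# independent collapse/link enumeration used for fixture ground truth:
# deliberately restated here (not via visit_sequence/build_network) so the
# pipeline is checked against plain index arithmetic
.enumerate_links <- function(ids) {
  ids <- ids[ids != 0]
  if (length(ids) == 0)
    return(list(nodes = integer(0), links = matrix(integer(0), ncol = 2)))
  r <- rle(ids)$values
  nodes <- sort(unique(r))
  if (length(r) < 2) return(list(nodes = nodes,
                                 links = matrix(integer(0), ncol = 2)))
  u <- pmin(r[-length(r)], r[-1]); v <- pmax(r[-length(r)], r[-1])
  keep <- u != v
  links <- unique(cbind(u[keep], v[keep]))
  links <- links[order(links[, 1], links[, 2]), , drop = FALSE]
  list(nodes = nodes, links = links)
}

#' Scripted trajectory over a patch mosaic
#'
#' Builds a piecewise-linear trajectory visiting patches in a prescribed
#' order: `dwell` relocations at each patch centroid, then `transit`
#' relocations on the straight segment to the next centroid. The emitted
#' trajectory's visit sequence is verified against the itinerary (an error
#' means the straight segments clip a patch not in the itinerary). Ground
#' truth (reference network, per-k expected detected and spurious links) is
#' computed by exhaustive index arithmetic on the located patch-id sequence,
#' independently of the network-building code under test.
#'
#' @param pm A `patch_map` (typically from [make_patch_mosaic()]).
#' @param itinerary Integer vector of patch ids to visit in order.
#' @param dwell Relocations spent inside each patch (recycled).
#' @param transit Relocations on each inter-patch segment (recycled).
#' @return List of class `scripted_trajectory`: `traj`, `itinerary`, `pm`,
#'   `patch_ids` (located sequence), `reference` (`spatial_network`), and
#'   `expect(k, start)` returning the expected nodes/detected/spurious sets
#'   for that resampling.
#' @export
make_scripted_trajectory <- function(pm, itinerary, dwell = 10, transit = 5) {
  stopifnot(all(itinerary %in% pm$patches$id))
  dwell <- rep_len(dwell, length(itinerary))
  transit <- rep_len(transit, max(1, length(itinerary) - 1))
  cx <- pm$patches$centroid_x[itinerary]
  cy <- pm$patches$centroid_y[itinerary]
  # transit fixes must fall in the matrix, not in the patches they connect,
  # so the dwell/transit index arithmetic is exact: sample the straight
  # segment finely and keep `transit` evenly spaced matrix points
  matrix_transit <- function(from, to, x0, y0, x1, y1, n) {
    tt <- seq(0, 1, length.out = 2001)
    px <- x0 + tt * (x1 - x0); py <- y0 + tt * (y1 - y0)
    lab <- pm$labels[cbind(floor(py) + 1, floor(px) + 1)]
    a_end <- max(which(lab == from))
    b_start <- min(which(lab == to & seq_along(lab) > a_end))
    between <- lab[(a_end + 1):(b_start - 1)]
    if (length(between) < 1 || any(between != 0))
      stop("itinerary leg ", from, " -> ", to,
           " crosses a patch not scheduled at that point")
    gap <- (a_end + 1):(b_start - 1)
    pick <- gap[unique(round(seq(1, length(gap), length.out = n)))]
    pick <- rep_len(pick, n)
    cbind(px[pick], py[pick])
  }
  xs <- ys <- numeric(0)
  for (i in seq_along(itinerary)) {
    xs <- c(xs, rep(cx[i], dwell[i]))
    ys <- c(ys, rep(cy[i], dwell[i]))
    if (i < length(itinerary)) {
      tp <- matrix_transit(itinerary[i], itinerary[i + 1],
                           cx[i], cy[i], cx[i + 1], cy[i + 1], transit[i])
      xs <- c(xs, tp[, 1])
      ys <- c(ys, tp[, 2])
    }
  }
  traj <- new_trajectory(id = "scripted", steps = seq_along(xs) - 1L,
                         x = xs, y = ys, process = "scripted")
  ids <- locate(traj, pm)
  vs <- visit_sequence(ids)
  collapsed <- rle(as.integer(itinerary))$values
  if (!identical(as.integer(vs), collapsed))
    stop("scripted path does not realize the itinerary; ",
         "straight segments cross a patch not scheduled at that point")
  ref <- .enumerate_links(ids)
  reference <- spatial_network(ref$nodes, ref$links, pm,
                               provenance = list(ids = "scripted", k = 1L))
  expect_fun <- function(k, start = 0L) {
    kept <- ids[seq_along(ids) %% k == (start + 1L) %% k]
    e <- .enumerate_links(kept)
    ref_keys <- paste(ref$links[, 1], ref$links[, 2], sep = "-")
    e_keys <- if (nrow(e$links)) paste(e$links[, 1], e$links[, 2], sep = "-")
              else character(0)
    list(nodes = e$nodes,
         detected = intersect(e_keys, ref_keys),
         spurious = setdiff(e_keys, ref_keys))
  }
  structure(list(traj = traj, itinerary = itinerary, pm = pm,
                 patch_ids = ids, reference = reference,
                 expect = expect_fun),
            class = "scripted_trajectory")
}

#' Write a self-contained fixture directory
#'
#' Emits a patch mosaic (ASCII raster), a scripted relocation CSV and the
#' reference network edge list in the exact formats the empirical readers
#' consume, so the empirical code path can be exercised end-to-end without
#' external data. All contents are synthetic.
#'
#' @param dir Output directory (created if missing).
#' @param n_patches,spacing,patch_size,dims Mosaic layout, see
#'   [make_patch_mosaic()].
#' @param itinerary Patch itinerary (default a tour hitting every patch with
#'   a revisit, which creates resampling-sensitive structure).
#' @param dwell,transit See [make_scripted_trajectory()].
#' @return The `scripted_trajectory`, invisibly; files `patches.asc`,
#'   `relocations.csv`, `reference.tsv` under `dir`.
#' @export
write_fixture_dir <- function(dir, n_patches = 6, spacing = 4,
                              patch_size = 3, dims = c(20, 50),
                              itinerary = NULL, dwell = 8, transit = 5) {
  pm <- make_patch_mosaic(n_patches, spacing, patch_size, dims)
  if (is.null(itinerary))
    itinerary <- c(seq_len(n_patches), rev(seq_len(n_patches))[-1])
  st <- make_scripted_trajectory(pm, itinerary, dwell, transit)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ascii_grid(pm$labels, file.path(dir, "patches.asc"),
                   metadata = list(synthetic = TRUE, n_patches = n_patches))
  write_relocations_csv(st$traj, file.path(dir, "relocations.csv"))
  write_network_tsv(st$reference, file.path(dir, "reference.tsv"))
  invisible(st)
}
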