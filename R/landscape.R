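#' Variogram specification for landscape simulation
#'
#' Parameters of the exponential-variogram Gaussian random field used to
#' generate resource landscapes. The covariance between two cells at
#' separation \eqn{h} is \eqn{sill \cdot e^{-h/range}}, with an additional
#' `nugget` variance at \eqn{h = 0}; the field mean is `trend_t`. Note that
#' `range_r` is the exponential-model range parameter (the *effective* range,
#' where autocorrelation drops below ~5\%, is about `3 * range_r`).
#'
#' @param range_r Range parameter of the exponential model, in cell units.
#' @param trend_t Mean field value (the "trend").
#' @param nugget Nugget variance (default 0).
#' @param sill Partial sill variance (default 1).
#' @param nrows,ncols Grid dimensions in cells (default 50 x 50).
#' @param seed Integer seed used when the landscape is generated.
#' @return An object of class `variogram_spec`.
#' @examples
#' variogram_spec(range_r = 5, trend_t = 0.3, seed = 1)
#' @export
variogram_spec <- function(range_r, trend_t, nugget = 0, sill = 1,
                           nrows = 50, ncols = 50, seed = NULL) {
  stopifnot(nugget >= 0, sill > 0, range_r > 0, nrows >= 2, ncols >= 2)
  structure(list(nugget = nugget, sill = sill, range_r = range_r,
                 trend_t = trend_t, nrows = as.integer(nrows),
                 ncols = as.integer(ncols), seed = seed),
            class = "variogram_spec")
}

#' Canonical fragmentation-level parameter sets
#'
#' The three study parameterizations: low fragmentation (r = 5, t = 0.3),
#' medium (r = 2, t = -0.5) and high (r = 2, t = -1.5), all with nugget 0 and
#' sill 1 on a 50 x 50 grid.
#'
#' @param level One of "low", "medium", "high".
#' @param seed Optional integer seed.
#' @return A `variogram_spec`.
#' @export
frag_level_spec <- function(level = c("low", "medium", "high"), seed = NULL) {
  level <- match.arg(level)
  p <- switch(level,
              low    = c(r = 5, t = 0.3),
              medium = c(r = 2, t = -0.5),
              high   = c(r = 2, t = -1.5))
  sp <- variogram_spec(range_r = p[["r"]], trend_t = p[["t"]], seed = seed)
  sp$level <- level
  sp
}

# session cache for Cholesky factors of the grid covariance, keyed by
# (nrows, ncols, nugget, sill, range_r)
.chol_cache <- new.env(parent = emptyenv())

.grid_chol <- function(spec) {
  key <- paste(spec$nrows, spec$ncols, spec$nugget, spec$sill, spec$range_r,
               sep = "|")
  got <- .chol_cache[[key]]
  if (!is.null(got)) return(got)
  xy <- cbind(rep(seq_len(spec$ncols) - 0.5, each = spec$nrows),
              rep(seq_len(spec$nrows) - 0.5, times = spec$ncols))
  d <- as.matrix(stats::dist(xy))
  C <- spec$sill * exp(-d / spec$range_r)
  diag(C) <- spec$sill + spec$nugget + 1e-10
  R <- tryCatch(chol(C), error = function(e)
    stop("covariance matrix is not positive definite for this spec", call. = FALSE))
  .chol_cache[[key]] <- R
  R
}

#' Generate a fragmented resource landscape
#'
#' Draws a stationary Gaussian random field with mean `trend_t` and
#' exponential covariance `sill * exp(-h / range_r)` (plus nugget) on the
#' grid, truncates negative values to zero, and normalizes the field to sum
#' to one. Cells with positive values carry resources of gradual quality;
#' zero cells are non-resource matrix.
#'
#' @param spec A [variogram_spec()].
#' @param seed Integer seed; overrides `spec$seed` when given.
#' @return An object of class `resource_grid` with elements `values`
#'   (normalized non-negative matrix, rows indexed from the grid's bottom),
#'   `raw` (the untruncated field), `spec`, `frag_level` and `empty` (TRUE
#'   when every cell truncated to zero; such grids cannot be normalized).
#' @examples
#' g <- generate_landscape(frag_level_spec("high"), seed = 42)
#' sum(g$values)  # 1
#' @export
generate_landscape <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "variogram_spec"))
  if (!is.null(seed)) set.seed(seed)
  R <- .grid_chol(spec)
  z <- stats::rnorm(spec$nrows * spec$ncols)
  field <- spec$trend_t + as.vector(crossprod(R, z))
  raw <- matrix(field, nrow = spec$nrows, ncol = spec$ncols)
  vals <- pmax(raw, 0)
  tot <- sum(vals)
  empty <- tot <= 0
  if (!empty) vals <- vals / tot
  structure(list(values = vals, raw = raw, spec = spec,
                 frag_level = spec$level %||% "custom",
                 empty = empty, seed = seed),
            class = "resource_grid")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @exportS3Method base::print
print.resource_grid <- function(x, ...) {
  cat(sprintf("<resource_grid> %dx%d cells, %d positive, level=%s%s\n",
              nrow(x$values), ncol(x$values), sum(x$values > 0),
              x$frag_level, if (x$empty) " [EMPTY]" else ""))
  invisible(x)
}

#' Generate a landscape, redrawing empty fields
#'
#' Wraps [generate_landscape()] and, when truncation leaves an all-zero
#' field, retries with an incremented seed (bounded number of attempts).
#'
#' @inheritParams generate_landscape
#' @param max_tries Maximum number of draws (default 25).
#' @return A non-empty `resource_grid`.
#' @export
generate_landscape_nonempty <- function(spec, seed = spec$seed,
                                        max_tries = 25L) {
  s <- seed %||% 1L
  for (i in seq_len(max_tries)) {
    g <- generate_landscape(spec, seed = s)
    if (!g$empty) return(g)
    s <- s + 1L
  }
  stop("no non-empty landscape after ", max_tries, " draws", call. = FALSE)
}

#' Delineate resource patches
#'
#' Truncates positive cells to presence and labels connected components as
#' patches. Patch geometry (area, perimeter in cell-edge units, centroid,
#' boundary cells) is computed per patch. Coordinates place cell centers at
#' `(col - 0.5, row - 0.5)` with the origin at the grid's lower-left corner.
#'
#' @param grid A `resource_grid`, or a plain matrix of cell values.
#' @param connectivity 8 (default, queen) or 4 (rook) neighbourhood for
#'   component labelling. Perimeters always count rook edges.
#' @return An object of class `patch_map`: `labels` matrix (0 = matrix cells,
#'   1..P = patch ids), `patches` data frame (id, area, perimeter,
#'   centroid_x, centroid_y), `boundary` list of per-patch boundary-cell
#'   coordinate matrices, `n_patches`, `nrows`, `ncols`.
#' @export
delineate_patches <- function(grid, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  vals <- if (inherits(grid, "resource_grid")) grid$values else grid
  nr <- nrow(vals); nc <- ncol(vals)
  pos <- vals > 0
  labels <- matrix(0L, nr, nc)
  n_pos <- sum(pos)
  if (n_pos > 0) {
    idx <- which(pos)                    # column-major cell ids
    cellno <- matrix(0L, nr, nc)
    cellno[idx] <- seq_along(idx)
    # gather adjacency among positive cells via shifted comparisons
    edges <- list()
    add_edges <- function(dr, dc) {
      r <- row(vals); c <- col(vals)
      ok <- pos & r + dr >= 1 & r + dr <= nr & c + dc >= 1 & c + dc <= nc
      from <- which(ok)
      to <- from + dr + dc * nr
      keep <- pos[to]
      cbind(cellno[from[keep]], cellno[to[keep]])
    }
    shifts <- list(c(1L, 0L), c(0L, 1L))
    if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(-1L, 1L)))
    for (s in shifts) edges[[length(edges) + 1L]] <- add_edges(s[1], s[2])
    em <- do.call(rbind, edges)
    g <- igraph::make_empty_graph(n = n_pos, directed = FALSE)
    if (nrow(em) > 0) g <- igraph::add_edges(g, t(em))
    comp <- igraph::components(g)$membership
    labels[idx] <- comp
  }
  .patch_map_from_labels(labels)
}

# build a patch_map (geometry included) from an integer label matrix
.patch_map_from_labels <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  ids <- sort(unique(labels[labels > 0]))
  # relabel to 1..P in case input labels are sparse
  if (length(ids) > 0 && !identical(ids, seq_along(ids))) {
    lut <- integer(max(ids)); lut[ids] <- seq_along(ids)
    labels[labels > 0] <- lut[labels[labels > 0]]
    ids <- seq_along(ids)
  }
  P <- length(ids)
  patches <- data.frame(id = integer(0), area = integer(0),
                        perimeter = integer(0), centroid_x = numeric(0),
                        centroid_y = numeric(0))
  boundary <- list()
  if (P > 0) {
    padded <- matrix(0L, nr + 2, nc + 2)
    padded[2:(nr + 1), 2:(nc + 1)] <- labels
    core <- padded[2:(nr + 1), 2:(nc + 1)]
    # per-cell count of rook sides facing a different label (matrix/boundary
    # counts, same-patch neighbour does not)
    diffn <- (padded[1:nr, 2:(nc + 1)] != core) +
             (padded[3:(nr + 2), 2:(nc + 1)] != core) +
             (padded[2:(nr + 1), 1:nc] != core) +
             (padded[2:(nr + 1), 3:(nc + 2)] != core)
    rr <- row(labels); cc <- col(labels)
    area <- tabulate(labels[labels > 0], nbins = P)
    perim <- vapply(ids, function(i) sum(diffn[labels == i]), numeric(1))
    cx <- vapply(ids, function(i) mean(cc[labels == i]) - 0.5, numeric(1))
    cy <- vapply(ids, function(i) mean(rr[labels == i]) - 0.5, numeric(1))
    boundary <- lapply(ids, function(i) {
      sel <- labels == i & diffn > 0
      cbind(x = cc[sel] - 0.5, y = rr[sel] - 0.5)
    })
    patches <- data.frame(id = ids, area = area, perimeter = as.integer(perim),
                          centroid_x = cx, centroid_y = cy)
  }
  structure(list(labels = labels, patches = patches, boundary = boundary,
                 n_patches = P, nrows = nr, ncols = nc),
            class = "patch_map")
}

#' @exportS3Method base::print
print.patch_map <- function(x, ...) {
  cat(sprintf("<patch_map> %dx%d cells, %d patches, %d patch cells\n",
              x$nrows, x$ncols, x$n_patches, sum(x$labels > 0)))
  invisible(x)
}

#' Landscape fragmentation indices
#'
#' Computes four class-level fragmentation indices on a patch map:
#' the aggregation index (AI, percent), the patch cohesion index (percent),
#' the division index (probability) and the proportion of cells occupied by
#' resource patches (percent).
#'
#' AI is the ratio of realized to maximum-possible shared rook edges among
#' patch cells, with the maximum from the largest-integer-square rule: for
#' class area \eqn{A}, \eqn{n = \lfloor\sqrt A\rfloor}, \eqn{m = A - n^2};
#' \eqn{e_{max} = 2n(n-1)} when \eqn{m = 0}, \eqn{2n(n-1) + 2m - 1} when
#' \eqn{0 < m \le n}, else \eqn{2n(n-1) + 2m - 2}. Cohesion is
#' \eqn{100\,[1 - \sum p_j / \sum p_j\sqrt{a_j}]\,[1 - 1/\sqrt Z]^{-1}} over
#' patches \eqn{j} with perimeter \eqn{p_j} and area \eqn{a_j}, \eqn{Z} the
#' total cell count. Division is \eqn{1 - \sum_j (a_j/Z)^2}.
#'
#' @param pm A `patch_map`.
#' @return A list with `ai`, `cohesion`, `division`, `proportion`. With zero
#'   patches AI and cohesion are `NA`, division 1, proportion 0; with total
#'   area 1 AI is 0.
#' @export
fragmentation_indices <- function(pm) {
  stopifnot(inherits(pm, "patch_map"))
  Z <- pm$nrows * pm$ncols
  if (pm$n_patches == 0)
    return(list(ai = NA_real_, cohesion = NA_real_, division = 1,
                proportion = 0))
  a <- pm$patches$area
  p <- pm$patches$perimeter
  A <- sum(a)
  pres <- pm$labels > 0
  # realized shared rook edges among patch cells
  e <- sum(pres[-1, ] & pres[-nrow(pres), ]) + sum(pres[, -1] & pres[, -ncol(pres)])
  n <- floor(sqrt(A)); m <- A - n^2
  e_max <- if (m == 0) 2 * n * (n - 1)
           else if (m <= n) 2 * n * (n - 1) + 2 * m - 1
           else 2 * n * (n - 1) + 2 * m - 2
  ai <- if (e_max <= 0) 0 else 100 * e / e_max
  cohesion <- 100 * (1 - sum(p) / sum(p * sqrt(a))) / (1 - 1 / sqrt(Z))
  division <- 1 - sum((a / Z)^2)
  proportion <- 100 * A / Z
  list(ai = ai, cohesion = cohesion, division = division,
       proportion = proportion)
}
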