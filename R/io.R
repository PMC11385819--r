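#' Write a grid as ESRI ASCII raster
#'
#' Internal row order places row 1 at the grid's bottom; the ASCII format
#' stores the top row first, so rows are flipped on write and read.
#'
#' @param mat Numeric or integer matrix (rows bottom-up).
#' @param path Output file.
#' @param metadata Optional named list written to `<path>.meta` as
#'   plain-text `key=value` lines (e.g. seed, range, trend, level).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(mat, path, metadata = NULL) {
  nr <- nrow(mat); nc <- ncol(mat)
  hdr <- c(paste("ncols", nc), paste("nrows", nr),
           "xllcorner 0", "yllcorner 0", "cellsize 1", "NODATA_value -9999")
  body <- apply(mat[nr:1, , drop = FALSE], 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  if (!is.null(metadata)) {
    writeLines(paste0(names(metadata), "=",
                      vapply(metadata, function(v) paste(format(v), collapse = ","),
                             character(1))),
               paste0(path, ".meta"))
  }
  invisible(path)
}

#' Read a labeled patch raster (ESRI ASCII)
#'
#' Reads an integer-labeled grid (0 = matrix, positive = patch label) and
#' rebuilds the patch map, including per-patch geometry. Labels need not be
#' contiguous; they are relabeled to 1..P.
#'
#' @param path ASCII grid file.
#' @param min_area Optional minimum patch area (cells); smaller patches are
#'   reclassified as matrix.
#' @return A `patch_map`.
#' @export
read_patch_raster <- function(path, min_area = NULL) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("raster body has ", length(vals), " values, expected ", nr * nc)
  if (any(vals != round(vals)))
    stop("patch raster must contain integer labels")
  labels <- matrix(as.integer(vals), nrow = nr, ncol = nc, byrow = TRUE)
  labels <- labels[nr:1, , drop = FALSE]          # back to bottom-up rows
  labels[labels < 0] <- 0L                        # NODATA -> matrix
  pm <- .patch_map_from_labels(labels)
  if (!is.null(min_area) && pm$n_patches > 0) {
    drop <- pm$patches$id[pm$patches$area < min_area]
    if (length(drop) > 0) {
      lab <- pm$labels
      lab[lab %in% drop] <- 0L
      pm <- .patch_map_from_labels(lab)
    }
  }
  pm
}

#' Write the patch attribute table as CSV
#'
#' @param pm A `patch_map`.
#' @param path Output CSV (columns id, area, perimeter, centroid_x, centroid_y).
#' @return `path`, invisibly.
#' @export
write_patch_table <- function(pm, path) {
  utils::write.csv(pm$patches, path, row.names = FALSE)
  invisible(path)
}

#' Write trajectories as relocation CSV
#'
#' One row per relocation, columns `id, step, x, y`.
#'
#' @param trajs A `trajectory` or list of them.
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_relocations_csv <- function(trajs, path) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  rows <- do.call(rbind, lapply(trajs, function(tr)
    data.frame(id = tr$id, step = tr$steps, x = tr$x, y = tr$y)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read relocation CSV into trajectories
#'
#' Expects columns `id`, a time column (`step`, `timestamp` or `t`), `x`, `y`.
#' Rows are sorted by time within individual; duplicated times are an error.
#' Gaps in an integer step sequence are reported via a message (and optionally
#' filled by carrying the previous location forward).
#'
#' @param path CSV file (header required, "." decimal).
#' @param carry_forward Fill integer step gaps with the preceding location
#'   (default FALSE: gaps are only reported).
#' @return A list of `trajectory` objects, one per individual.
#' @export
read_relocations_csv <- function(path, carry_forward = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tcol <- intersect(c("step", "timestamp", "t", "time"), names(df))[1]
  if (is.na(tcol) || !all(c("id", "x", "y") %in% names(df)))
    stop("relocation CSV needs columns id, step/timestamp, x, y")
  out <- lapply(split(df, df$id), function(d) {
    d <- d[order(d[[tcol]]), ]
    dup <- duplicated(d[[tcol]])
    if (any(dup))
      stop(sprintf("duplicated timestamp %s for individual %s",
                   d[[tcol]][dup][1], d$id[1]))
    steps <- d[[tcol]]
    if (is.numeric(steps) && all(steps == round(steps))) {
      gaps <- which(diff(steps) > 1)
      if (length(gaps) > 0) {
        message(sprintf("individual %s: %d gap(s) in step sequence",
                        d$id[1], length(gaps)))
        if (carry_forward) {
          full <- seq(min(steps), max(steps))
          idx <- findInterval(full, steps)
          d <- d[idx, ]
          d[[tcol]] <- full
          steps <- full
        }
      }
    }
    new_trajectory(id = as.character(d$id[1]), steps = steps,
                   x = d$x, y = d$y, process = "empirical")
  })
  unname(out)
}

#' Write a spatial network as edge-list TSV
#'
#' Writes `<path>` with columns `patch_u`, `patch_v` (one row per link) and
#' `<path>.nodes` with the visited patch ids.
#'
#' @param net A `spatial_network`.
#' @param path Output TSV file.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(net, path) {
  el <- as.data.frame(net$links)
  names(el) <- c("patch_u", "patch_v")
  utils::write.table(el, path, sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(as.character(net$nodes), paste0(path, ".nodes"))
  invisible(path)
}
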