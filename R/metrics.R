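#' Node degrees and degree frequency table
#'
#' @param net A `spatial_network` (at least one node).
#' @return List with `degree` (named integer vector, one entry per visited
#'   patch) and `freq` (data frame `degree`, `count` over observed degrees
#'   >= 1).
#' @export
degree_distribution <- function(net) {
  stopifnot(length(net$nodes) >= 1)
  deg <- stats::setNames(integer(length(net$nodes)), net$nodes)
  if (nrow(net$links) > 0) {
    tab <- table(factor(c(net$links[, 1], net$links[, 2]), levels = net$nodes))
    deg[] <- as.integer(tab)
  }
  pos <- deg[deg >= 1]
  freq <- if (length(pos) > 0) {
    t <- table(pos)
    data.frame(degree = as.integer(names(t)), count = as.integer(t))
  } else data.frame(degree = integer(0), count = integer(0))
  list(degree = deg, freq = freq)
}

#' Fit a power law to a degree frequency table
#'
#' Ordinary least squares of log(frequency) on log(degree), the classical
#' log-log diagnostic for scale-free structure. The scale parameter estimate
#' is the negated slope; a network is called scale-free when it exceeds 1.
#' Degrees with zero frequency never enter (the table only lists observed
#' degrees).
#'
#' @param freq Data frame with columns `degree` and `count` (counts > 0), as
#'   from [degree_distribution()]`$freq`.
#' @return List of class `power_law_fit`: `alpha_hat`, `r2`, `n_degrees`,
#'   `scale_free`. With fewer than two distinct degrees the fit is undefined
#'   (`alpha_hat = NA`, `defined = FALSE`).
#' @export
fit_power_law <- function(freq) {
  freq <- freq[freq$count > 0, , drop = FALSE]
  if (nrow(freq) < 2) {
    return(structure(list(alpha_hat = NA_real_, r2 = NA_real_,
                          n_degrees = nrow(freq), scale_free = NA,
                          defined = FALSE), class = "power_law_fit"))
  }
  fit <- stats::lm(log(count) ~ log(degree), data = freq)
  alpha <- -unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  structure(list(alpha_hat = alpha, r2 = r2, n_degrees = nrow(freq),
                 scale_free = alpha > 1, defined = TRUE),
            class = "power_law_fit")
}

#' Global clustering coefficient
#'
#' Transitivity: three times the number of triangles over the number of
#' connected triples. Zero when the network has no connected triple.
#'
#' @param net A `spatial_network` with >= 3 nodes.
#' @return C in `[0, 1]`.
#' @export
clustering_coefficient <- function(net) {
  stopifnot(length(net$nodes) >= 3)
  C <- igraph::transitivity(as_igraph(net), type = "global")
  if (is.nan(C)) 0 else C
}

#' Characteristic path length
#'
#' Mean shortest-path length over all reachable unordered node pairs. On
#' disconnected graphs unreachable pairs are excluded from the average and
#' counted separately.
#'
#' @param net A `spatial_network` with >= 2 nodes.
#' @return List with `L` (NA when no pair is reachable) and
#'   `n_unreachable_pairs`.
#' @export
characteristic_path_length <- function(net) {
  stopifnot(length(net$nodes) >= 2)
  d <- igraph::distances(as_igraph(net))
  up <- d[upper.tri(d)]
  fin <- is.finite(up)
  list(L = if (any(fin)) mean(up[fin]) else NA_real_,
       n_unreachable_pairs = sum(!fin))
}

#' Small-world test against a random-graph ensemble
#'
#' Draws `ensemble_size` Erdős–Rényi G(n, m) graphs with the same number of
#' nodes and links as the network, computes their clustering coefficient
#' `C_R` and characteristic path length `L_R`, and forms
#' `sigma = (C / C_R) / (L / L_R)` per replicate. The network is declared
#' small-world when `min(sigma) > 1`. Degenerate replicates: `C_R = 0` with
#' `C > 0` gives `sigma = Inf`; a network with `C = 0` is declared not
#' small-world without ensemble comparison.
#'
#' @param net A `spatial_network` with >= 3 nodes and >= 1 link.
#' @param ensemble_size Number of random graphs (default 100).
#' @param seed Integer seed for the ensemble.
#' @return List of class `small_world_result`: `C`, `L`, `ensemble` (data
#'   frame C_R, L_R, sigma), `min_sigma`, `small_world`.
#' @export
small_world_test <- function(net, ensemble_size = 100L, seed = NULL) {
  n <- length(net$nodes); m <- nrow(net$links)
  stopifnot(n >= 3, m >= 1)
  if (m > n * (n - 1) / 2) stop("more links than the simple-graph maximum")
  if (!is.null(seed)) set.seed(seed)
  C <- clustering_coefficient(net)
  L <- characteristic_path_length(net)$L
  CR <- LR <- numeric(ensemble_size)
  for (i in seq_len(ensemble_size)) {
    g <- igraph::sample_gnm(n, m)
    cr <- igraph::transitivity(g, type = "global")
    CR[i] <- if (is.nan(cr)) 0 else cr
    d <- igraph::distances(g)
    up <- d[upper.tri(d)]
    fin <- is.finite(up)
    LR[i] <- if (any(fin)) mean(up[fin]) else NA_real_
  }
  if (C <= 0 || is.na(L)) {
    sigma <- rep(0, ensemble_size)
    sw <- FALSE
  } else {
    sigma <- ifelse(CR <= 0, Inf, (C / CR) / (L / LR))
    sw <- min(sigma) > 1
  }
  structure(list(C = C, L = L,
                 ensemble = data.frame(C_R = CR, L_R = LR, sigma = sigma),
                 min_sigma = if (length(sigma)) min(sigma) else NA_real_,
                 small_world = sw),
            class = "small_world_result")
}

#' One-row topology summary of a network
#'
#' Computes the metrics table row used throughout the study: node and link
#' counts, power-law fit, clustering, path length, small-world diagnosis.
#'
#' @param net A `spatial_network`.
#' @param ensemble_size Random-graph ensemble size for the small-world test.
#' @param seed Seed for the ensemble.
#' @param meta Optional named list merged into the row (process, k, ...).
#' @return A one-row data frame.
#' @export
network_metrics <- function(net, ensemble_size = 100L, seed = NULL,
                            meta = list()) {
  n <- length(net$nodes); m <- nrow(net$links)
  dd <- if (n >= 1) degree_distribution(net) else NULL
  pl <- if (!is.null(dd)) fit_power_law(dd$freq) else NULL
  C <- if (n >= 3) clustering_coefficient(net) else NA_real_
  L <- if (n >= 2) characteristic_path_length(net)$L else NA_real_
  sw <- if (n >= 3 && m >= 1)
    small_world_test(net, ensemble_size = ensemble_size, seed = seed)
  else NULL
  row <- data.frame(n_nodes = n, n_links = m,
                    alpha_hat = if (is.null(pl)) NA_real_ else pl$alpha_hat,
                    r2 = if (is.null(pl)) NA_real_ else pl$r2,
                    scale_free = if (is.null(pl) || !isTRUE(pl$defined)) NA
                                 else pl$scale_free,
                    C = C, L = L,
                    min_sigma = if (is.null(sw)) NA_real_ else sw$min_sigma,
                    small_world = if (is.null(sw)) NA else sw$small_world)
  for (nm in names(meta)) row[[nm]] <- meta[[nm]]
  row
}
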