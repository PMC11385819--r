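#' Information loss of a resampled network against a reference
#'
#' Quantifies what a coarser relocation schedule misses relative to the
#' full-resolution reference: the proportion of the reference's visited
#' patches that are still detected, the proportion of realized links still
#' detected, and the proportion of the resampled network's links that are
#' spurious (absent from the reference, typically shortcut links bridging a
#' skipped stepping-stone visit).
#'
#' @param reference Reference `spatial_network` (>= 1 node).
#' @param resampled Resampled `spatial_network` over the same patch universe.
#' @param k Resampling factor recorded in the result.
#' @return List of class `information_loss`: `prop_patches_detected`,
#'   `prop_links_detected`, `prop_spurious`, `k`.
#' @export
information_loss <- function(reference, resampled, k = NA) {
  if (length(reference$nodes) == 0) stop("empty reference network")
  stopifnot(reference$n_universe == resampled$n_universe)
  rk <- .link_keys(reference)
  sk <- .link_keys(resampled)
  pp <- length(intersect(resampled$nodes, reference$nodes)) /
        length(reference$nodes)
  pl <- if (length(rk) == 0) NA_real_
        else length(intersect(sk, rk)) / length(rk)
  ps <- if (length(sk) == 0) 0 else length(setdiff(sk, rk)) / length(sk)
  structure(list(prop_patches_detected = pp, prop_links_detected = pl,
                 prop_spurious = ps, k = k),
            class = "information_loss")
}

#' Spurious and detected link sets
#'
#' Set-level companion to [information_loss()]: which links survive the
#' resampling and which are artifacts.
#'
#' @inheritParams information_loss
#' @return List with `detected` and `spurious` two-column link matrices.
#' @export
link_sets <- function(reference, resampled) {
  rk <- .link_keys(reference); sk <- .link_keys(resampled)
  parse <- function(keys) {
    if (length(keys) == 0) return(matrix(integer(0), ncol = 2))
    do.call(rbind, lapply(strsplit(keys, "-"), as.integer))
  }
  list(detected = parse(intersect(sk, rk)),
       spurious = parse(setdiff(sk, rk)))
}

#' Mixed-effects model of node degree
#'
#' Simulation mode fits `log(degree) ~ fragmentation * log(n_relocations)`
#' with a random intercept per landscape; empirical mode (single landscape)
#' fits the linear model `log(degree) ~ log(n_relocations)`. Degrees must be
#' >= 1 (isolated nodes carry no degree information on the log scale).
#'
#' @param records Data frame with columns `degree`, `n_relocations`, and for
#'   the mixed model `frag_level` and `landscape_id`.
#' @param log_relocations Enter the relocation count on the log scale
#'   (default TRUE).
#' @return List of class `degree_model_result`: `coefficients` (estimate and
#'   Wald 95\% CI per term), `ranef_variance` (NA for the fixed-effects
#'   fallback), `pseudo_r2` (squared correlation of fitted vs observed),
#'   `model`.
#' @export
degree_model <- function(records, log_relocations = TRUE) {
  stopifnot(all(records$degree >= 1))
  records$y <- log(records$degree)
  records$nrel <- if (log_relocations) log(records$n_relocations)
                  else records$n_relocations
  mixed <- all(c("frag_level", "landscape_id") %in% names(records)) &&
           length(unique(records$landscape_id)) > 1
  if (mixed) {
    records$frag_level <- factor(records$frag_level)
    fit <- lme4::lmer(y ~ frag_level * nrel + (1 | landscape_id),
                      data = records, REML = TRUE)
    est <- lme4::fixef(fit)
    ci <- stats::confint(fit, parm = "beta_", method = "Wald")
    vc <- as.data.frame(lme4::VarCorr(fit))
    rv <- vc$vcov[vc$grp == "landscape_id"]
    fitted_y <- stats::fitted(fit)
  } else {
    if (all(c("frag_level", "landscape_id") %in% names(records)))
      warning("single landscape: falling back to a fixed-effects fit")
    fit <- stats::lm(y ~ nrel, data = records)
    est <- stats::coef(fit)
    ci <- stats::confint(fit)
    rv <- NA_real_
    fitted_y <- stats::fitted(fit)
  }
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      ci_lo = ci[, 1], ci_hi = ci[, 2], row.names = NULL)
  structure(list(coefficients = coefs, ranef_variance = rv,
                 pseudo_r2 = stats::cor(fitted_y, records$y)^2,
                 model = fit),
            class = "degree_model_result")
}

#' Aggregate per-network metric tables
#'
#' Grouped means of the numeric metrics plus the proportion of small-world
#' networks per group, with replicate counts; empty groups are omitted (a
#' message is emitted when grouping variables had unused level combinations).
#'
#' @param metrics Data frame of per-network rows (e.g. from
#'   [network_metrics()]), including the grouping columns.
#' @param by Character vector of grouping column names (default
#'   `c("process", "frag_level", "k")`, intersected with what is present).
#' @return Data frame sorted by the grouping columns, with `n` (replicates),
#'   mean columns for every numeric metric, and `prop_small_world`.
#' @export
summarize_experiment <- function(metrics, by = c("process", "frag_level", "k")) {
  by <- intersect(by, names(metrics))
  stopifnot(length(by) > 0)
  key <- interaction(metrics[by], drop = TRUE, lex.order = TRUE)
  groups <- split(metrics, key)
  num_cols <- setdiff(names(metrics)[vapply(metrics, is.numeric, logical(1))],
                      by)
  rows <- lapply(groups, function(g) {
    out <- g[1, by, drop = FALSE]
    out$n <- nrow(g)
    for (cn in num_cols)
      out[[paste0("mean_", cn)]] <- mean(g[[cn]], na.rm = TRUE)
    if ("small_world" %in% names(g))
      out$prop_small_world <- mean(g$small_world, na.rm = TRUE)
    out
  })
  res <- do.call(rbind, rows)
  res <- res[do.call(order, res[by]), , drop = FALSE]
  rownames(res) <- NULL
  res
}
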