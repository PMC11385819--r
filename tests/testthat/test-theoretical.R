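test_that("patch distances use minimum boundary-to-boundary separation", {
  pm <- make_patch_mosaic(2, spacing = 5, patch_size = 3, dims = c(12, 20))
  d <- patch_distances(pm)
  expect_equal(d[1, 2], 6)                 # boundary centers spacing+1 apart
  dc <- patch_distances(pm, method = "centroid")
  expect_equal(dc[1, 2], 8)                # pitch = patch_size + spacing
})

test_that("the planar graph links only adjacent patch regions", {
  two <- make_patch_mosaic(2, spacing = 4, patch_size = 3, dims = c(12, 20))
  mpg2 <- build_mpg(two)
  expect_equal(nrow(mpg2$links), 1L)

  # three collinear, well-separated patches: end patches not adjacent
  three <- make_patch_mosaic(3, spacing = 8, patch_size = 3, dims = c(14, 44))
  mpg3 <- build_mpg(three)
  expect_equal(unname(mpg3$links), rbind(c(1L, 2L), c(2L, 3L)))

  # single patch: no links
  one <- make_patch_mosaic(1, dims = c(10, 10))
  expect_equal(nrow(build_mpg(one)$links), 0L)
})

test_that("planar-graph link counts respect the 3P - 6 bound on random landscapes", {
  for (s in 1:8) {
    g <- generate_landscape_nonempty(frag_level_spec("high"), seed = 8000 + s)
    pm <- delineate_patches(g)
    if (pm$n_patches < 3) next
    mpg <- build_mpg(pm)
    expect_lte(nrow(mpg$links), 3 * pm$n_patches - 6)
    # every patch is a node (the graph predicts over the whole landscape)
    expect_equal(mpg$nodes, seq_len(pm$n_patches))
  }
})

test_that("realized link lengths and thresholds match sorted-array oracles", {
  pm <- make_patch_mosaic(2, spacing = 2, patch_size = 3, dims = c(12, 20))
  net <- spatial_network(1:2, rbind(c(1L, 2L)), pm)
  rl <- realized_link_lengths(net, pm)
  expect_equal(rl$L_med, 3)
  expect_equal(rl$L_95, 3)

  expect_equal(stats::median(1:5), 3)      # the documented median convention
  set.seed(4)
  lengths <- runif(100, 1, 40)
  expect_equal(unname(stats::quantile(lengths, 0.95, type = 7)),
               quantile7(lengths, 0.95))

  empty <- spatial_network(1:2, NULL, pm)
  expect_error(realized_link_lengths(empty, pm), "no links")
})

test_that("distance-threshold networks behave at the extremes and nest", {
  pm <- make_patch_mosaic(4, spacing = 3, patch_size = 2, dims = c(20, 24))
  d <- patch_distances(pm)
  expect_equal(nrow(build_distance_network(pm, 0, dist = d)$links), 0L)
  full <- build_distance_network(pm, 1e6, dist = d)
  expect_equal(nrow(full$links), choose(4, 2))
  # nesting: DIST50 links are a subset of DIST95 links
  l50 <- build_distance_network(pm, 4, dist = d)
  l95 <- build_distance_network(pm, 9, dist = d)
  k50 <- paste(l50$links[, 1], l50$links[, 2])
  k95 <- paste(l95$links[, 1], l95$links[, 2])
  expect_true(all(k50 %in% k95))
})

test_that("a hand-built triple of patches links exactly below the threshold", {
  labels <- matrix(0L, 12, 16)
  labels[2, 2] <- 1L
  labels[2, 5] <- 2L                       # distance 3 from patch 1
  labels[2, 11] <- 3L                      # distance 6 from patch 2, 9 from 1
  pm <- patchnet:::.patch_map_from_labels(labels)
  d <- patch_distances(pm)
  expect_equal(d[1, 2], 3)
  expect_equal(d[2, 3], 6)
  expect_equal(d[1, 3], 9)
  net <- build_distance_network(pm, 6, dist = d)
  expect_equal(nrow(net$links), 2L)
  # strict variant excludes the pair exactly at the threshold
  expect_equal(nrow(build_distance_network(pm, 6, dist = d,
                                           strict = TRUE)$links), 1L)
})

test_that("random networks are uniform over patch pairs and respect bounds", {
  pm <- make_patch_mosaic(5, spacing = 3, patch_size = 2, dims = c(20, 30))
  n_max <- choose(5, 2)
  expect_equal(nrow(build_random_network(pm, n_max, seed = 1)$links), n_max)
  expect_equal(nrow(build_random_network(pm, 0, seed = 1)$links), 0L)
  expect_error(build_random_network(pm, n_max + 1), "exceeds")

  counts <- integer(n_max)
  names(counts) <- apply(t(combn(5, 2)), 1, paste, collapse = "-")
  for (s in 1:600) {
    net <- build_random_network(pm, 3, seed = s)
    keys <- paste(net$links[, 1], net$links[, 2], sep = "-")
    counts[keys] <- counts[keys] + 1L
  }
  expected <- 600 * 3 / n_max
  expect_true(all(abs(counts - expected) / expected < 0.25))
})

test_that("Cohen's kappa matches hand-computed contingencies", {
  pm5 <- 5L
  realized <- spatial_network(1:5, rbind(c(1, 2), c(1, 3), c(1, 4),
                                         c(1, 5), c(2, 3)), pm5)
  predicted <- spatial_network(1:5, rbind(c(1, 2), c(1, 3), c(1, 4),
                                          c(2, 4)), pm5)
  kr <- cohens_kappa(predicted, realized)
  expect_equal(c(kr$a, kr$b, kr$c, kr$d), c(3, 1, 2, 4))
  expect_equal(kr$po, 0.7)
  expect_equal(kr$pe, 0.5)
  expect_equal(kr$kappa, 0.4)

  expect_equal(cohens_kappa(realized, realized)$kappa, 1)

  # complement prediction scores below chance
  comp_pairs <- t(combn(5, 2))
  rk <- paste(realized$links[, 1], realized$links[, 2])
  keep <- !(paste(comp_pairs[, 1], comp_pairs[, 2]) %in% rk)
  complement <- spatial_network(1:5, comp_pairs[keep, , drop = FALSE], pm5)
  expect_lt(cohens_kappa(complement, realized)$kappa, 0)
})

test_that("kappa handles restricted universes and degenerate agreement", {
  realized <- spatial_network(1:4, rbind(c(1, 2)), 4)
  predicted <- spatial_network(1:4, rbind(c(1, 2), c(3, 4)), 4)
  uni <- rbind(c(1, 2), c(1, 3), c(3, 4))
  kr <- cohens_kappa(predicted, realized, universe = uni)
  expect_equal(kr$n_pairs, 3)
  expect_equal(c(kr$a, kr$b, kr$c, kr$d), c(1, 1, 0, 1))

  # both predict everything: pe = 1, po = 1 -> kappa 1, flagged
  allp <- spatial_network(1:3, rbind(c(1, 2), c(1, 3), c(2, 3)), 3)
  kd <- cohens_kappa(allp, allp)
  expect_true(kd$degenerate)
  expect_equal(kd$kappa, 1)
})

test_that("random-graph kappa is centred on zero over many draws", {
  g <- generate_landscape_nonempty(frag_level_spec("medium"), seed = 901)
  pm <- delineate_patches(g)
  tr <- simulate_movement(g, "F", n_steps = 5000, seed = 902)
  net <- trajectory_network(tr, pm)
  kap <- vapply(1:100, function(s)
    cohens_kappa(build_random_network(pm, nrow(net$links), seed = s),
                 net)$kappa, numeric(1))
  expect_lt(abs(mean(kap)), 0.02)
})
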