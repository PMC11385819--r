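make_test_grid <- function(seed = 3, level = "medium") {
  generate_landscape_nonempty(frag_level_spec(level), seed = seed)
}

test_that("identical grid, params and seed give identical trajectories", {
  g <- make_test_grid()
  for (pr in c("F", "F+Pe", "F+Ps")) {
    t1 <- simulate_movement(g, pr, n_steps = 500, seed = 99)
    t2 <- simulate_movement(g, pr, n_steps = 500, seed = 99)
    expect_identical(t1$x, t2$x)
    expect_identical(t1$y, t2$y)
  }
  l1 <- simulate_movement(g, "F+T", n_steps = 300, burn_in = 200, seed = 99)
  l2 <- simulate_movement(g, "F+T", n_steps = 300, burn_in = 200, seed = 99)
  expect_identical(lapply(l1, `[[`, "x"), lapply(l2, `[[`, "x"))
})

test_that("reflecting boundaries keep every relocation inside the landscape", {
  g <- make_test_grid(5)
  for (pr in c("F", "F+Pe", "F+T")) {
    tr <- simulate_movement(g, pr, n_steps = 3000, burn_in = 0, seed = 17)
    if (inherits(tr, "trajectory")) tr <- list(tr)
    for (t1 in tr) {
      expect_true(all(t1$x >= 0 & t1$x < ncol(g$values)))
      expect_true(all(t1$y >= 0 & t1$y < nrow(g$values)))
    }
  }
})

test_that("n_steps = 0 yields just the initial position and F+T burn-in is discarded", {
  g <- make_test_grid()
  t0 <- simulate_movement(g, "F", n_steps = 0, seed = 1)
  expect_equal(length(t0), 1L)
  tf <- simulate_movement(g, "F+T", n_steps = 1000, burn_in = 1000, seed = 1)
  expect_equal(length(tf), 2L)            # default pair of foragers
  expect_equal(length(tf[[1]]), 1000L)
  expect_equal(tf[[1]]$steps, 0:999)
  expect_error(simulate_movement(g, "F+T",
                                 params = movement_params(n_foragers = 1)),
               "n_foragers")
})

test_that("resource dynamics follow the stated recurrences", {
  base <- c(0.5, 0.2, 0.1)
  # zero rates: identity
  expect_equal(resource_dynamics_step(base, base, 1, 0, 0), base)
  # occupied cell loses consumption * value
  v1 <- resource_dynamics_step(base, base, 2, consumption = 0.3, regen = 0)
  expect_equal(v1[2], 0.2 * 0.7)
  expect_equal(v1[c(1, 3)], base[c(1, 3)])
  # recovery from full depletion: baseline * (1 - (1 - rho)^k)
  rho <- 0.05
  v <- c(0, 0, 0)
  for (k in 1:20) v <- resource_dynamics_step(v, base, integer(0),
                                              consumption = 0, regen = rho)
  expect_equal(v, base * (1 - (1 - rho)^20), tolerance = 1e-12)
  # values never exceed baseline nor drop below zero
  v2 <- resource_dynamics_step(base * 2, base, integer(0), 0, 0.5)
  expect_true(all(v2 <= base))
})

test_that("memory bias anchors the forager to a known resource hotspot", {
  vals <- matrix(0, 30, 30)
  vals[15, 15] <- 1                        # single resource cell
  g <- grid_from_matrix(vals)
  p_bias <- movement_params(mem_w = 3, consumption = 0, kappa = 2)
  p_none <- movement_params(mem_w = 0, consumption = 0, kappa = 2)
  near <- function(tr) mean(sqrt((tr$x - 14.5)^2 + (tr$y - 14.5)^2) <= 3)
  f_bias <- mean(vapply(1:3, function(s)
    near(simulate_movement(g, "F", p_bias, n_steps = 2000, seed = s)),
    numeric(1)))
  f_none <- mean(vapply(1:3, function(s)
    near(simulate_movement(g, "F", p_none, n_steps = 2000, seed = s)),
    numeric(1)))
  expect_gt(f_bias, f_none)
})

test_that("encounter bookkeeping respects probability and expiry", {
  g <- make_test_grid()
  p0 <- movement_params(p_encounter = 0)
  st <- list(x = 10, y = 10, step = 0L, avoid = NULL)
  set.seed(1)
  for (i in 1:50) {
    st$step <- i
    st <- encounter_and_avoid(st, g, p0, "elusive")
  }
  expect_equal(nrow(st$avoid), 0L)

  p1 <- movement_params(p_encounter = 1, avoid_duration = 10L)
  st <- list(x = 10, y = 10, step = 0L, avoid = NULL)
  set.seed(2)
  st <- encounter_and_avoid(st, g, p1, "elusive")
  expect_true(st$encounter)
  e <- st$step
  expect_equal(st$avoid$expiry, e + 10L)
  # entry still present when processing step e+9, gone at e+10
  p_none <- movement_params(p_encounter = 0, avoid_duration = 10L)
  st9 <- st; st9$step <- e + 9L
  st9 <- encounter_and_avoid(st9, g, p_none, "elusive")
  expect_equal(nrow(st9$avoid), 1L)
  st10 <- st; st10$step <- e + 10L
  st10 <- encounter_and_avoid(st10, g, p_none, "elusive")
  expect_equal(nrow(st10$avoid), 0L)
})

test_that("stalking encounters sit on valued resource cells, elusive ones near the forager", {
  g <- make_test_grid()
  set.seed(3)
  p <- movement_params(p_encounter = 1)
  st <- list(x = 25, y = 25, step = 0L, avoid = NULL)
  st_e <- encounter_and_avoid(st, g, p, "elusive")
  d <- sqrt((st_e$avoid$x - 25)^2 + (st_e$avoid$y - 25)^2)
  expect_lte(d, p$perception_radius)
  st_s <- encounter_and_avoid(st, g, p, "stalking")
  cc <- floor(st_s$avoid$x) + 1; rr <- floor(st_s$avoid$y) + 1
  expect_gt(g$values[rr, cc], 0)
})

test_that("predator pressure spreads movement relative to undisturbed foraging", {
  g <- make_test_grid(9)
  p_pred <- movement_params(p_encounter = 0.02, avoid_w = 4)
  cells <- function(tr) length(unique(paste(floor(tr$x), floor(tr$y))))
  n_pred <- mean(vapply(1:3, function(s)
    cells(simulate_movement(g, "F+Pe", p_pred, n_steps = 3000, seed = s)),
    numeric(1)))
  n_f <- mean(vapply(1:3, function(s)
    cells(simulate_movement(g, "F", p_pred, n_steps = 3000, seed = s)),
    numeric(1)))
  expect_gt(n_pred, n_f)
})

test_that("scent avoidance separates territories and shrinks reachable patch sets", {
  g <- make_test_grid(21)
  pm <- delineate_patches(g)
  p_terr <- movement_params()
  p_ctrl <- movement_params(scent_w = 0)
  occ_set <- function(tr) {
    cell <- paste(floor(tr$x), floor(tr$y))
    tab <- sort(table(cell), decreasing = TRUE)
    names(tab)[cumsum(tab) <= 0.95 * length(cell)]
  }
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  ov_terr <- ov_ctrl <- numeric(0)
  np_terr <- np_f <- numeric(0)
  for (s in 1:3) {
    tt <- simulate_movement(g, "F+T", p_terr, n_steps = 3000,
                            burn_in = 3000, seed = 30 + s)
    tc <- simulate_movement(g, "F+T", p_ctrl, n_steps = 3000,
                            burn_in = 3000, seed = 30 + s)
    ov_terr <- c(ov_terr, jac(occ_set(tt[[1]]), occ_set(tt[[2]])))
    ov_ctrl <- c(ov_ctrl, jac(occ_set(tc[[1]]), occ_set(tc[[2]])))
    np_terr <- c(np_terr,
                 length(trajectory_network(tt[[1]], pm)$nodes))
    tf <- simulate_movement(g, "F", p_terr, n_steps = 3000, seed = 30 + s)
    np_f <- c(np_f, length(trajectory_network(tf, pm)$nodes))
  }
  expect_lt(mean(ov_terr), mean(ov_ctrl))
  expect_lt(mean(np_terr), mean(np_f))
})
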