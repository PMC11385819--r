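#' Movement process parameters
#'
#' Parameter set for the continuous correlated biased random walk. Defaults
#' define the package's concrete instantiation of the forager model: a
#' von Mises turning kernel around the desired heading, exponential decay of
#' a per-cell resource memory refreshed within the perception radius,
#' distance-discounted attraction toward remembered resources, and (per
#' process) repulsion from remembered predator encounters or conspecific
#' scent marks. One relocation is recorded per timestep; speed is in cell
#' units per step.
#'
#' @param speed Step length (cells/step).
#' @param kappa Turning-angle concentration of the von Mises kernel.
#' @param mem_decay Memory decay rate per step (exponential).
#' @param mem_dist Distance-discount scale (cells) of the memory attraction.
#' @param mem_w Weight of the memory-attraction bias vector.
#' @param persist_w Weight of directional persistence.
#' @param perception_radius Radius (cells) within which resource values are
#'   perceived and memory refreshed.
#' @param consumption Fraction of the occupied cell's value consumed per step.
#' @param regen Regeneration rate per step toward the cell baseline.
#' @param p_encounter Predator encounter probability per step (F+Pe, F+Ps).
#' @param avoid_duration Steps an encounter location stays avoided.
#' @param avoid_w,avoid_dist Weight and distance scale of encounter repulsion.
#' @param flee_dist Immediate flee displacement (cells) on encounter.
#' @param mark_interval Steps between scent-mark depositions (F+T).
#' @param mark_lifetime Steps a scent mark persists.
#' @param scent_w,scent_dist Weight and distance scale of repulsion from
#'   foreign scent marks.
#' @param n_foragers Number of simultaneous foragers for the territorial
#'   process (>= 2).
#' @return A list of class `movement_params`.
#' @export
movement_params <- function(speed = 1, kappa = 4, mem_decay = 0.002,
                            mem_dist = 8, mem_w = 1, persist_w = 1,
                            perception_radius = 3, consumption = 0.9,
                            regen = 2e-4, p_encounter = 0.005,
                            avoid_duration = 300L, avoid_w = 2,
                            avoid_dist = 5, flee_dist = 3,
                            mark_interval = 5L, mark_lifetime = 2000L,
                            scent_w = 2, scent_dist = 5, n_foragers = 2L) {
  p <- list(speed = speed, kappa = kappa, mem_decay = mem_decay,
            mem_dist = mem_dist, mem_w = mem_w, persist_w = persist_w,
            perception_radius = perception_radius, consumption = consumption,
            regen = regen, p_encounter = p_encounter,
            avoid_duration = as.integer(avoid_duration), avoid_w = avoid_w,
            avoid_dist = avoid_dist, flee_dist = flee_dist,
            mark_interval = as.integer(mark_interval),
            mark_lifetime = as.integer(mark_lifetime), scent_w = scent_w,
            scent_dist = scent_dist, n_foragers = as.integer(n_foragers))
  stopifnot(all(vapply(p, function(v) v >= 0, logical(1))))
  class(p) <- "movement_params"
  p
}

#' Construct a trajectory object
#'
#' @param id Individual identifier.
#' @param steps Integer step indices (strictly increasing).
#' @param x,y Continuous cell coordinates.
#' @param process Process tag ("F", "F+Pe", "F+Ps", "F+T", or "empirical").
#' @param landscape_id,seed Optional provenance.
#' @return An object of class `trajectory`.
#' @export
new_trajectory <- function(id, steps, x, y, process = "F",
                           landscape_id = NA, seed = NA) {
  stopifnot(length(steps) == length(x), length(x) == length(y))
  if (length(steps) > 1 && any(diff(steps) <= 0))
    stop("step indices must be strictly increasing")
  structure(list(id = id, steps = steps, x = x, y = y, process = process,
                 landscape_id = landscape_id, seed = seed),
            class = "trajectory")
}

#' @exportS3Method base::print
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> id=%s process=%s, %d relocations\n",
              x$id, x$process, length(x$steps)))
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$steps)

.process_code <- function(process) {
  match(process, c("F", "F+Pe", "F+Ps", "F+T")) - 1L
}

#' Simulate forager trajectories
#'
#' Runs the continuous correlated biased random walk on a resource grid for
#' one of four processes: `"F"` (foraging only), `"F+Pe"` (foraging +
#' avoidance of an elusive predator), `"F+Ps"` (foraging + avoidance of a
#' stalking predator), `"F+T"` (foraging + territoriality; `n_foragers`
#' foragers moving simultaneously and avoiding each other's scent marks).
#' Resources deplete on occupancy and regenerate toward baseline. Recorded
#' output is `n_steps` relocations taken after discarding `burn_in` steps
#' (the territorial process defaults to a 10,000-step burn-in so territories
#' establish first).
#'
#' @param grid A non-empty `resource_grid`.
#' @param process One of "F", "F+Pe", "F+Ps", "F+T".
#' @param params A [movement_params()] set.
#' @param n_steps Number of recorded relocations (default 10000). `n_steps =
#'   0` yields a trajectory holding only the initial position.
#' @param burn_in Steps discarded before recording (default 10000 for F+T,
#'   else 0).
#' @param seed Integer seed (reproducible trajectories).
#' @return For single-forager processes, a `trajectory`; for `"F+T"`, a list
#'   of `n_foragers` trajectories.
#' @export
simulate_movement <- function(grid, process = c("F", "F+Pe", "F+Ps", "F+T"),
                              params = movement_params(), n_steps = 10000L,
                              burn_in = NULL, seed = NULL) {
  process <- match.arg(process)
  stopifnot(inherits(grid, "resource_grid"))
  if (grid$empty || sum(grid$values) <= 0)
    stop("cannot simulate movement on an empty landscape")
  if (is.null(burn_in)) burn_in <- if (process == "F+T") 10000L else 0L
  nf <- if (process == "F+T") params$n_foragers else 1L
  if (process == "F+T" && nf < 2)
    stop("the territorial process needs n_foragers >= 2")
  if (!is.null(seed)) set.seed(seed)

  vals <- grid$values
  nr <- nrow(vals); nc <- ncol(vals)
  res_idx <- which(vals > 0)             # column-major cell ids
  res_r <- (res_idx - 1) %% nr + 1
  res_c <- (res_idx - 1) %/% nr + 1
  cell_of <- rep(-1L, nr * nc)
  cell_of[res_idx] <- seq_along(res_idx) - 1L   # 0-based for C++

  init <- sample(length(res_idx), nf, replace = nf > length(res_idx))
  init_x <- res_c[init] - 0.5
  init_y <- res_r[init] - 0.5
  init_theta <- stats::runif(nf, -pi, pi)

  n_rec <- max(as.integer(n_steps), 1L)  # n_steps = 0 -> initial position only
  sim <- simulate_cbrw_cpp(res_c - 0.5, res_r - 0.5, vals[res_idx],
                           cell_of, nr, nc, .process_code(process), params,
                           n_rec, as.integer(burn_in),
                           init_x, init_y, init_theta)
  trajs <- lapply(seq_along(sim), function(f) {
    m <- sim[[f]]
    new_trajectory(id = paste0("sim", f), steps = as.integer(m[, 1]),
                   x = m[, 2], y = m[, 3], process = process,
                   landscape_id = grid$seed, seed = seed)
  })
  if (nf == 1) trajs[[1]] else trajs
}

#' One resource depletion/regeneration step
#'
#' Pure-function form of the per-step resource dynamics used inside the
#' simulator: each occupied cell loses `consumption * value`; all cells then
#' relax toward baseline at rate `regen`, clipped to `[0, baseline]`.
#'
#' @param values Current cell values (vector).
#' @param baseline Baseline (carrying) values, same length.
#' @param occupied Indices (1-based) of occupied cells; may be empty.
#' @param consumption,regen Rates per step.
#' @return Updated values vector.
#' @export
resource_dynamics_step <- function(values, baseline, occupied = integer(0),
                                   consumption, regen) {
  stopifnot(length(values) == length(baseline))
  resource_step_cpp(values, baseline, as.integer(occupied) - 1L,
                    consumption, regen)
}

#' Predator encounter and avoidance-memory update
#'
#' Single-step encounter bookkeeping for the predator-avoidance processes.
#' With probability `params$p_encounter` an encounter location is placed —
#' uniformly within the perception disc for an elusive predator
#' (`variant = "elusive"`), or at a resource cell near the forager drawn
#' proportionally to current resource value for a stalking predator
#' (`variant = "stalking"`) — and enters the avoidance memory with expiry
#' `step + avoid_duration`. Expired entries are dropped.
#'
#' @param state List with `x`, `y` (forager position), `step` (current step)
#'   and `avoid` (data frame x, y, expiry; may be NULL).
#' @param grid A `resource_grid` (for stalking placement).
#' @param params A [movement_params()].
#' @param variant "elusive" or "stalking".
#' @return The state with updated `avoid` memory and logical `encounter`.
#' @export
encounter_and_avoid <- function(state, grid, params = movement_params(),
                                variant = c("elusive", "stalking")) {
  variant <- match.arg(variant)
  avoid <- state$avoid
  if (is.null(avoid))
    avoid <- data.frame(x = numeric(0), y = numeric(0), expiry = integer(0))
  avoid <- avoid[avoid$expiry > state$step, , drop = FALSE]
  state$encounter <- FALSE
  if (stats::runif(1) < params$p_encounter) {
    vals <- grid$values
    nr <- nrow(vals)
    res_idx <- which(vals > 0)
    loc <- place_encounter_cpp(if (variant == "elusive") 0L else 1L,
                               state$x, state$y,
                               (res_idx - 1) %/% nr + 0.5,
                               (res_idx - 1) %% nr + 0.5,
                               vals[res_idx], params$perception_radius,
                               2 * params$perception_radius)
    avoid <- rbind(avoid, data.frame(x = loc[1], y = loc[2],
                                     expiry = state$step + params$avoid_duration))
    state$encounter <- TRUE
  }
  state$avoid <- avoid
  state
}
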