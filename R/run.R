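STATE_LEVELS <- c("MOVING", "STOPPED", "YIELDING", "TURNING")

type_to_int <- function(type) {
  m <- match(type, PARTICLE_TYPES)
  if (anyNA(m)) abort("particle types must be 'O', 'U' or 'L'")
  m - 1L
}

state_to_int <- function(state) {
  if (is.numeric(state)) return(as.integer(state))
  m <- match(state, STATE_LEVELS)
  if (anyNA(m)) {
    abort(paste0(
      "motion states must be one of: ", paste(STATE_LEVELS, collapse = ", ")
    ))
  }
  m - 1L
}

int_to_state <- function(state) STATE_LEVELS[state + 1L]

# Completes a user-supplied data frame of on-trail particles into the full
# engine layout. Only `type` and `x` are required.
build_init <- function(init, config) {
  if (is.null(init) || nrow(as.data.frame(init)) == 0) {
    init <- tibble::tibble(type = character(), x = numeric())
  }
  init <- tibble::as_tibble(init)
  if (!all(c("type", "x") %in% names(init))) {
    abort("init particles need at least columns `type` and `x`")
  }
  n <- nrow(init)
  defaults <- tibble::tibble(
    id = if (n > 0) seq_len(n) - 1L else integer(),
    w = rep(config$trail_width / 2, n),
    state = rep("MOVING", n),
    yield_until = rep(-1, n),
    yield_trigger = rep(-1L, n),
    t_entry = rep(0, n)
  )
  for (col in names(defaults)) {
    if (!col %in% names(init)) init[[col]] <- defaults[[col]]
  }
  if (any(init$x < 0 | init$x > config$trail_length)) {
    abort("init positions must lie within [0, trail_length]")
  }
  data.frame(
    id = as.integer(init$id),
    type = type_to_int(init$type),
    x = as.double(init$x),
    w = as.double(init$w),
    state = state_to_int(init$state),
    yield_until = as.double(init$yield_until),
    yield_trigger = as.integer(init$yield_trigger),
    t_entry = as.double(init$t_entry)
  )
}

engine_cfg <- function(config) {
  list(
    trail_length = config$trail_length,
    trail_width = config$trail_width,
    dt = config$dt,
    mu_step = mu_per_step(config),
    p_laden = config$p_laden,
    s_OU = config$s_OU,
    s_L = config$s_L,
    interaction_radius = config$interaction_radius,
    coop_dist = config$coop_dist,
    coop_time_per_passer = config$coop_time_per_passer,
    entry_w_mean = config$entry_w_mean,
    entry_w_sd = config$entry_w_sd,
    entry_w_clamp_lo = config$entry_w_clamp[1],
    entry_w_clamp_hi = config$entry_w_clamp[2],
    avoidance_rule = config$avoidance_rule
  )
}

#' Run a trail simulation
#'
#' Executes the discrete-time self-propelled particle model defined by a
#' [sim_config()]: `run_narrow()` the 1-D stop/give-way model with the
#' cooperative rule, `run_wide()` the 2-D turn/give-way model (or its
#' stop-rule control variant); `run_trail()` dispatches on the config's
#' geometry. The update is synchronous: all interaction decisions are taken
#' on the start-of-step snapshot, then every particle moves by
#' `delta * s * h * dt` (narrow) or by the turn-decomposed 2-D displacement
#' (wide). Midpoint crossings -- sign changes of `x - trail_length/2`
#' between consecutive steps -- are logged with particle type, direction
#' and (wide) lateral position. Runs are bit-reproducible for a fixed seed.
#'
#' @param config A [sim_config()] with the matching geometry.
#' @param init Optional data frame of particles already on the trail, with
#'   columns `type` and `x` (plus optional `id`, `w`, `state`,
#'   `yield_until`, `yield_trigger`, `t_entry`). Used for staged scenarios;
#'   normal runs start from an empty trail.
#' @param n_steps Number of steps; default `duration / dt`.
#' @param record_trajectory If `TRUE`, keep every particle's position each
#'   step (memory-heavy; meant for short diagnostic runs).
#' @param seed Seed for this run; defaults to `config$seed`. Use `NA` to
#'   leave the RNG state untouched.
#' @return A `trail_run` object: list with `crossings` (tibble `time_s`,
#'   `particle_id`, `type`, `direction`, and `w_cm` on the wide trail),
#'   `particles` (final on-trail state), `counters` (per-type spawned /
#'   exited / queued / on-trail tallies), `queue` (remaining entry-queue
#'   lengths), `config`, and optionally `trajectory`.
#' @examples
#' cfg <- sim_config("narrow", duration = 60, seed = 42)
#' run <- run_narrow(cfg)
#' glance(run)
#' @export
run_trail <- function(config, init = NULL, n_steps = NULL,
                      record_trajectory = FALSE, seed = config$seed) {
  config <- validate_sim_config(config)
  if (config$geometry == "narrow") {
    run_narrow(config, init, n_steps, record_trajectory, seed)
  } else {
    run_wide(config, init, n_steps, record_trajectory, seed)
  }
}

#' @rdname run_trail
#' @export
run_narrow <- function(config, init = NULL, n_steps = NULL,
                       record_trajectory = FALSE, seed = config$seed) {
  config <- validate_sim_config(config)
  if (config$geometry != "narrow") {
    abort("run_narrow() requires a narrow-geometry config")
  }
  if (is.null(n_steps)) n_steps <- as.integer(round(config$duration / config$dt))
  if (!is.na(seed)) set.seed(seed)
  raw <- narrow_engine_cpp(
    engine_cfg(config), build_init(init, config),
    as.integer(n_steps), isTRUE(record_trajectory)
  )
  as_trail_run(raw, config, n_steps, record_trajectory)
}

#' @rdname run_trail
#' @export
run_wide <- function(config, init = NULL, n_steps = NULL,
                     record_trajectory = FALSE, seed = config$seed) {
  config <- validate_sim_config(config)
  if (config$geometry != "wide") {
    abort("run_wide() requires a wide-geometry config")
  }
  if (is.null(n_steps)) n_steps <- as.integer(round(config$duration / config$dt))
  if (!is.na(seed)) set.seed(seed)
  raw <- wide_engine_cpp(
    engine_cfg(config), build_init(init, config),
    as.integer(n_steps), isTRUE(record_trajectory)
  )
  as_trail_run(raw, config, n_steps, record_trajectory)
}

as_trail_run <- function(raw, config, n_steps, record_trajectory) {
  counters <- tibble::tibble(
    type = PARTICLE_TYPES,
    spawned = as.numeric(raw$spawned),
    exited = as.numeric(raw$exited),
    queued = as.numeric(raw$queued),
    on_trail = as.numeric(raw$on_trail)
  )
  particles <- tibble::as_tibble(raw$particles)
  if ("state" %in% names(particles)) {
    particles$state <- int_to_state(particles$state)
  }
  out <- list(
    crossings = tibble::as_tibble(raw$crossings),
    particles = particles,
    counters = counters,
    queue = c(nest = raw$queue_nest, source = raw$queue_source),
    config = config,
    n_steps = n_steps
  )
  if (record_trajectory) {
    traj <- tibble::as_tibble(raw$trajectory)
    traj$state <- int_to_state(traj$state)
    out$trajectory <- traj
  }
  structure(out, class = "trail_run")
}

#' @export
print.trail_run <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<trail_run> %s trail, %d steps (%.0f s)\n", x$config$geometry,
    x$n_steps, x$n_steps * x$config$dt
  ))
  cat(sprintf(
    "  crossings %d (flow %.1f/h); spawned %d, exited %d, on trail %d, queued %d\n",
    g$n_crossings, g$flow_per_hour, g$spawned, g$exited, g$on_trail, g$queued
  ))
  invisible(x)
}

#' Tidy methods for trail runs
#'
#' `tidy()` returns the midpoint crossing log as a tibble; `glance()` a
#' one-row summary with the crossing count, the flow scaled to crossings
#' per hour, the conservation tallies and whether they balance
#' (`spawned == exited + on_trail + queued`).
#'
#' @param x A `trail_run`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.trail_run <- function(x, ...) {
  x$crossings
}

#' @rdname tidy.trail_run
#' @export
glance.trail_run <- function(x, ...) {
  ct <- x$counters
  tibble::tibble(
    geometry = x$config$geometry,
    n_crossings = nrow(x$crossings),
    flow_per_hour = nrow(x$crossings) * 3600 /
      (x$n_steps * x$config$dt),
    spawned = sum(ct$spawned),
    exited = sum(ct$exited),
    on_trail = sum(ct$on_trail),
    queued = sum(ct$queued),
    conservation_ok = all(ct$spawned == ct$exited + ct$on_trail + ct$queued)
  )
}
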