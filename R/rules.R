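#' Base priority action at an encounter
#'
#' The pairwise give-way table for the three particle types: outbound (`O`),
#' inbound unladen (`U`) and inbound laden (`L`). Priority follows
#' `L > O > U`: a laden particle never gives way to `O` or `U`, and an
#' outbound particle never gives way to `U`. On the narrow trail giving way
#' means stopping; on the wide trail every stop becomes a turn. The result
#' is the *base* action before state-dependent exceptions (the cooperative
#' rule and yielding transparency) that the engines layer on top.
#'
#' @param actor,other Particle types, `"O"`, `"U"` or `"L"` (vectorized).
#' @param geometry `"narrow"` or `"wide"`.
#' @return Character vector over `"WALK"`, `"STOP"` (narrow) and `"TURN"`
#'   (wide).
#' @examples
#' priority_action("O", "L", "narrow") # STOP
#' priority_action("L", "U", "narrow") # WALK
#' priority_action("U", "U", "wide")   # TURN
#' @export
priority_action <- function(actor, other, geometry = c("narrow", "wide")) {
  geometry <- match.arg(geometry)
  bad <- !(actor %in% PARTICLE_TYPES) | !(other %in% PARTICLE_TYPES)
  if (any(bad)) {
    abort("particle types must be 'O', 'U' or 'L'")
  }
  gives <- matrix(
    c(
      1, 0, 1, # actor O vs O, U, L
      1, 1, 1, # actor U
      0, 0, 1  # actor L
    ),
    nrow = 3, byrow = TRUE,
    dimnames = list(PARTICLE_TYPES, PARTICLE_TYPES)
  )
  give_way <- gives[cbind(actor, other)] == 1
  yield_action <- if (geometry == "narrow") "STOP" else "TURN"
  ifelse(give_way, yield_action, "WALK")
}

#' Draw from the cooperative-passage distribution
#'
#' When an outbound particle gives way to a laden one, `n` unladen particles
#' trailing the laden may be allowed passage: the outbound particle waits
#' `tau = coop_time_per_passer * n` seconds before reclaiming priority.
#' `n` is drawn from `config$coop_dist` over `0..15`.
#'
#' @param config A [sim_config()].
#' @param draws Number of draws.
#' @return A tibble with integer column `n` and column `tau` (seconds).
#' @examples
#' cfg <- sim_config("narrow")
#' set.seed(1)
#' coop_draw(cfg, draws = 3)
#' @export
coop_draw <- function(config, draws = 1) {
  config <- validate_sim_config(config)
  n <- sample(0:15, size = draws, replace = TRUE, prob = config$coop_dist)
  tibble::tibble(n = as.integer(n), tau = config$coop_time_per_passer * n)
}

#' Sample lateral entry positions on the wide trail
#'
#' Entry positions are normal with mean `entry_w_mean` and s.d.
#' `entry_w_sd`; draws above `trail_width` are replaced by the upper clamp
#' value and draws below 0 by the lower clamp value, so every entrant
#' starts strictly inside the walls.
#'
#' @param config A wide-geometry [sim_config()].
#' @param draws Number of draws.
#' @return Numeric vector of lateral positions in cm.
#' @export
entry_w_sample <- function(config, draws = 1) {
  config <- validate_sim_config(config)
  if (config$geometry != "wide") {
    abort("entry_w_sample applies to the wide geometry only")
  }
  w <- rnorm(draws, mean = config$entry_w_mean, sd = config$entry_w_sd)
  w[w > config$trail_width] <- config$entry_w_clamp[2]
  w[w < 0] <- config$entry_w_clamp[1]
  w
}

#' Poisson arrivals at a trail endpoint
#'
#' Draws the number of new particles appearing at one endpoint in one time
#' step, `k ~ Poisson(mu_per_step(config))`, and assigns their types: every
#' nest arrival is outbound (`O`); each leaf-source arrival is laden (`L`)
#' with probability `p_laden`, otherwise inbound unladen (`U`). On the wide
#' trail each arrival also receives a lateral entry position from
#' [entry_w_sample()] and joins the endpoint's FIFO entry queue, stepping
#' onto the trail only once the entry is clear of same-direction particles
#' it would have to give way to; on the narrow trail arrivals step onto the
#' trail at their endpoint immediately.
#'
#' @param endpoint `"nest"` or `"source"`.
#' @param config A [sim_config()].
#' @return A tibble with one row per arrival: `endpoint`, `ptype`, heading
#'   `h`, speed `s` (cm/s) and lateral entry `w` (cm; `NA` on the narrow
#'   trail).
#' @examples
#' set.seed(1)
#' spawn_arrivals("source", sim_config("narrow"))
#' @export
spawn_arrivals <- function(endpoint = c("nest", "source"), config) {
  endpoint <- match.arg(endpoint)
  config <- validate_sim_config(config)
  k <- rpois(1, mu_per_step(config))
  ptype <- if (endpoint == "nest") {
    rep("O", k)
  } else {
    ifelse(stats::runif(k) < config$p_laden, "L", "U")
  }
  w <- if (config$geometry == "wide" && k > 0) {
    entry_w_sample(config, draws = k)
  } else {
    rep(NA_real_, k)
  }
  tibble::tibble(
    endpoint = rep(endpoint, k),
    ptype = ptype,
    h = ifelse(ptype == "O", 1L, -1L),
    s = ifelse(ptype == "L", config$s_L, config$s_OU),
    w = w
  )
}
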