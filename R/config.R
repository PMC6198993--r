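#' Simulation configuration
#'
#' Builds the full parameterization of one trail simulation. Defaults follow
#' the calibrated leaf-cutting ant setup: a 300 cm trail observed for one
#' hour at a 0.1 s time step, outbound/unladen speed 2.3 cm/s, laden speed
#' 1.9 cm/s, laden probability 0.24 at the leaf source, and an interaction
#' radius of `1 + 2 * dt * s_OU` cm (1.46 cm at the defaults). Arrivals at
#' each endpoint are Poisson; the rate `mu` is expressed in the units under
#' which each model was calibrated (per second on the narrow trail, per
#' time step on the wide trail, see [mu_per_step()]), and the defaults
#' (`mu = 1` narrow, `mu = 0.8` wide) are the calibrated values.
#'
#' @param geometry `"narrow"` (1-D, stop/give-way rules plus the cooperative
#'   rule) or `"wide"` (2-D, turn/give-way rules).
#' @param mu Poisson arrival rate per endpoint: ants/s (narrow) or
#'   ants/step (wide). Defaults to the calibrated values 1 (narrow) and 0.8
#'   (wide).
#' @param duration Simulated time in seconds.
#' @param dt Time step in seconds.
#' @param trail_length Trail length in cm; nest at `x = 0`, leaf source at
#'   `x = trail_length`.
#' @param trail_width Trail width in cm (wide geometry only).
#' @param p_laden Probability that a particle leaving the leaf source carries
#'   a leaf fragment.
#' @param s_OU Speed of outbound and inbound-unladen particles, cm/s.
#' @param s_L Speed of laden particles, cm/s.
#' @param interaction_radius Interaction distance in cm; `NULL` computes the
#'   default `1 + 2 * dt * s_OU`.
#' @param coop_dist Probability vector over `n = 0..15`, the number of
#'   unladen particles allowed passage while an outbound particle yields to a
#'   laden one (narrow geometry). `NULL` uses [default_coop_dist()], a
#'   geometric placeholder with mean about 1 -- it is *not* the empirically
#'   measured distribution, which should be supplied here when available.
#' @param coop_time_per_passer Yield time per benefiting unladen particle in
#'   seconds; the yield lasts `tau = coop_time_per_passer * n`.
#' @param entry_w_mean,entry_w_sd Mean and s.d. (cm) of the normal lateral
#'   entry position on the wide trail.
#' @param entry_w_clamp Replacement values used when a sampled entry position
#'   falls outside the trail: below 0 or above `trail_width`.
#' @param central_zone Half-open interval `[lo, hi)` in cm defining the
#'   central zone of the wide trail; the remainder splits into two marginal
#'   zones.
#' @param avoidance_rule Wide-trail collision resolution: `"turn"` (the
#'   model) or `"stop"` (control variant with turning replaced by stopping).
#' @param seed Integer seed; every source of randomness in a run derives
#'   from it.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config("narrow")
#' cfg$interaction_radius
#' @export
sim_config <- function(geometry = c("narrow", "wide"),
                       mu = NULL,
                       duration = 3600,
                       dt = 0.1,
                       trail_length = 300,
                       trail_width = 5,
                       p_laden = 0.24,
                       s_OU = 2.3,
                       s_L = 1.9,
                       interaction_radius = NULL,
                       coop_dist = NULL,
                       coop_time_per_passer = 0.8,
                       entry_w_mean = 2.5,
                       entry_w_sd = 0.8,
                       entry_w_clamp = c(0.01, 4.99),
                       central_zone = c(1.25, 3.75),
                       avoidance_rule = c("turn", "stop"),
                       seed = 1L) {
  geometry <- match.arg(geometry)
  avoidance_rule <- match.arg(avoidance_rule)
  if (is.null(mu)) mu <- if (geometry == "narrow") 1 else 0.8
  if (is.null(interaction_radius)) interaction_radius <- 1 + 2 * dt * s_OU
  if (is.null(coop_dist)) coop_dist <- default_coop_dist()
  cfg <- structure(
    list(
      geometry = geometry,
      mu = mu,
      duration = duration,
      dt = dt,
      trail_length = trail_length,
      trail_width = trail_width,
      p_laden = p_laden,
      s_OU = s_OU,
      s_L = s_L,
      interaction_radius = interaction_radius,
      coop_dist = coop_dist,
      coop_time_per_passer = coop_time_per_passer,
      entry_w_mean = entry_w_mean,
      entry_w_sd = entry_w_sd,
      entry_w_clamp = entry_w_clamp,
      central_zone = central_zone,
      avoidance_rule = avoidance_rule,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants of a [sim_config()]: positive lengths,
#' times and speeds, a 16-entry cooperative-passage distribution summing to
#' 1, `p_laden` in `[0, 1]`, and a central zone inside `[0, trail_width)`.
#'
#' @param config A `sim_config` (or a plain list with the same fields).
#' @return The validated config, invisibly classed as `sim_config`.
#' @export
validate_sim_config <- function(config) {
  stopifnot(is.list(config))
  missing <- setdiff(sim_config_fields(), names(config))
  if (length(missing) > 0) {
    abort(paste0("config is missing fields: ", paste(missing, collapse = ", ")))
  }
  with(config, {
    if (!geometry %in% c("narrow", "wide")) {
      abort("geometry must be 'narrow' or 'wide'")
    }
    if (!avoidance_rule %in% c("turn", "stop")) {
      abort("avoidance_rule must be 'turn' or 'stop'")
    }
    if (mu < 0) abort("mu must be >= 0")
    if (!(p_laden >= 0 && p_laden <= 1)) abort("p_laden must be in [0, 1]")
    pos <- c(
      duration = duration, dt = dt, trail_length = trail_length,
      trail_width = trail_width, s_OU = s_OU, s_L = s_L,
      interaction_radius = interaction_radius
    )
    if (any(pos <= 0)) {
      abort(paste0(
        "fields must be > 0: ",
        paste(names(pos)[pos <= 0], collapse = ", ")
      ))
    }
    if (coop_time_per_passer < 0) abort("coop_time_per_passer must be >= 0")
    if (length(coop_dist) != 16 || any(coop_dist < 0) ||
        abs(sum(coop_dist) - 1) > 1e-6) {
      abort("coop_dist must be 16 non-negative probabilities summing to 1")
    }
    if (entry_w_sd < 0) abort("entry_w_sd must be >= 0")
    if (length(entry_w_clamp) != 2 ||
        any(entry_w_clamp <= 0) || any(entry_w_clamp >= trail_width)) {
      abort("entry_w_clamp must be two values strictly inside (0, trail_width)")
    }
    if (length(central_zone) != 2 || central_zone[1] >= central_zone[2] ||
        central_zone[1] < 0 || central_zone[2] > trail_width) {
      abort("central_zone must be an increasing interval within [0, trail_width]")
    }
  })
  structure(config, class = "sim_config")
}

#' Per-step arrival mean implied by a configuration
#'
#' The arrival rate `mu` is specified in the units under which the two
#' models were calibrated: ants per endpoint per *second* on the narrow
#' trail (per-step Poisson mean `mu * dt`) and ants per endpoint per *time
#' step* on the wide trail (per-step mean `mu`). This helper returns the
#' per-step mean the engines use.
#'
#' @param config A [sim_config()].
#' @return A single number, the Poisson mean per endpoint per time step.
#' @export
mu_per_step <- function(config) {
  if (config$geometry == "narrow") config$mu * config$dt else config$mu
}

sim_config_fields <- function() {
  c(
    "geometry", "mu", "duration", "dt", "trail_length", "trail_width",
    "p_laden", "s_OU", "s_L", "interaction_radius", "coop_dist",
    "coop_time_per_passer", "entry_w_mean", "entry_w_sd", "entry_w_clamp",
    "central_zone", "avoidance_rule", "seed"
  )
}

#' Placeholder cooperative-passage distribution
#'
#' A geometric distribution over `n = 0..15` (ratio 1/2, renormalized) with
#' mean close to 1, used as the default for `coop_dist`. It stands in for
#' the empirically measured probabilities of `n` unladen ants benefiting
#' from a laden ant's passage, which are not shipped with the package;
#' narrow-trail flow and group statistics are sensitive to this choice.
#'
#' @return Numeric vector of 16 probabilities summing to 1.
#' @examples
#' sum(default_coop_dist())
#' sum(0:15 * default_coop_dist()) # mean ~ 1
#' @export
default_coop_dist <- function() {
  p <- 0.5^(1 + 0:15)
  p / sum(p)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$geometry, " trail\n", sep = "")
  cat(sprintf(
    "  length %g cm%s, dt %g s, duration %g s, mu %g/step/endpoint\n",
    x$trail_length,
    if (x$geometry == "wide") sprintf(" x %g cm", x$trail_width) else "",
    x$dt, x$duration, x$mu
  ))
  cat(sprintf(
    "  speeds: O/U %g cm/s, L %g cm/s; p_laden %g; radius %g cm\n",
    x$s_OU, x$s_L, x$p_laden, x$interaction_radius
  ))
  if (x$geometry == "wide") {
    cat(sprintf(
      "  avoidance rule '%s'; entry w ~ N(%g, %g^2) clamped to (%g, %g)\n",
      x$avoidance_rule, x$entry_w_mean, x$entry_w_sd,
      x$entry_w_clamp[1], x$entry_w_clamp[2]
    ))
  }
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' Read or write a simulation configuration file
#'
#' Configurations serialize to YAML (`.yml`/`.yaml`) or JSON (`.json`) with
#' exactly the `sim_config` field names. Unknown keys in a file are an
#' error; omitted keys fall back to the [sim_config()] defaults for the
#' file's geometry.
#'
#' @param path File path; the extension selects the format.
#' @param config A `sim_config`.
#' @return `read_sim_config()` returns a validated `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yml = ,
    yaml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    abort(paste0("unsupported config format: .", ext))
  )
  raw <- lapply(raw, function(x) if (is.list(x)) unlist(x) else x)
  unknown <- setdiff(names(raw), sim_config_fields())
  if (length(unknown) > 0) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  config <- validate_sim_config(config)
  ext <- tolower(tools::file_ext(path))
  fields <- unclass(config)
  switch(ext,
    yml = ,
    yaml = yaml::write_yaml(fields, path, precision = 12),
    json = jsonlite::write_json(fields, path,
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    ),
    abort(paste0("unsupported config format: .", ext))
  )
  invisible(path)
}
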