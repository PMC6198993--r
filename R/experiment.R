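#' Specify a replicate experiment
#'
#' The three in-silico experiment presets batch seeded replicate runs:
#' `narrow_default` (narrow trail, `mu = 1`), `wide_turn` (wide trail,
#' turning rule, `mu = 0.8`) and `wide_stop` (wide trail, stop-rule control,
#' `mu = 0.8`). Replicate `r` runs with seed `base_seed + r - 1`, so an
#' experiment is fully determined by its spec.
#'
#' @param name Preset name.
#' @param n_replicates Number of replicate runs (the reference protocol used
#'   1000; smaller counts give the same means with wider sampling error).
#' @param base_seed Seed of the first replicate.
#' @param output_dir Optional directory for per-replicate crossing-log CSVs
#'   and a summary JSON.
#' @param config Optional [sim_config()] overriding the preset's config
#'   (its geometry must match the preset; `mu` stays pinned to the preset
#'   value).
#' @return A list of class `experiment_spec`.
#' @examples
#' experiment_spec("wide_turn", n_replicates = 3, base_seed = 7)
#' @export
experiment_spec <- function(name = c("narrow_default", "wide_turn", "wide_stop"),
                            n_replicates = 1000,
                            base_seed = 1,
                            output_dir = NULL,
                            config = NULL) {
  name <- match.arg(name)
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  preset <- switch(name,
    narrow_default = sim_config("narrow", mu = 1),
    wide_turn = sim_config("wide", mu = 0.8, avoidance_rule = "turn"),
    wide_stop = sim_config("wide", mu = 0.8, avoidance_rule = "stop")
  )
  if (!is.null(config)) {
    config <- validate_sim_config(config)
    if (config$geometry != preset$geometry) {
      abort(sprintf("preset '%s' requires geometry '%s'", name, preset$geometry))
    }
    config$mu <- preset$mu
    if (preset$geometry == "wide") config$avoidance_rule <- preset$avoidance_rule
    preset <- validate_sim_config(config)
  }
  structure(
    list(
      name = name,
      config = preset,
      n_replicates = as.integer(n_replicates),
      base_seed = as.integer(base_seed),
      output_dir = output_dir
    ),
    class = "experiment_spec"
  )
}

#' Run a replicate experiment
#'
#' Runs `n_replicates` seeded simulations of the spec's configuration,
#' summarizes each with [summarize_replicate()], aggregates across
#' replicates with [aggregate_replicates()], and (when `output_dir` is set)
#' writes one crossing-log CSV per replicate plus a summary JSON. The whole
#' pipeline is deterministic given the spec.
#'
#' @param spec An [experiment_spec()], or a preset name forwarded to it.
#' @param ... When `spec` is a name, further arguments to
#'   [experiment_spec()].
#' @param keep_crossings Keep each replicate's crossing log in the returned
#'   object (off by default to bound memory over many replicates).
#' @param quiet Suppress progress/warning messages.
#' @return A list of class `ant_experiment` with the `spec`, per-replicate
#'   `summaries`, and the `aggregate`.
#' @examples
#' ex <- run_experiment("narrow_default",
#'   n_replicates = 2, base_seed = 1,
#'   config = sim_config("narrow", duration = 60), quiet = TRUE
#' )
#' glance(ex)
#' @export
run_experiment <- function(spec, ..., keep_crossings = FALSE, quiet = FALSE) {
  if (is.character(spec)) spec <- experiment_spec(spec, ...)
  stopifnot(inherits(spec, "experiment_spec"))
  cfg <- spec$config

  if (!quiet && cfg$geometry == "narrow" &&
      isTRUE(all.equal(cfg$coop_dist, default_coop_dist()))) {
    warn(paste(
      "narrow-trail run uses the placeholder cooperative-passage",
      "distribution (geometric, mean ~1), not empirically measured",
      "probabilities; flow and group statistics are sensitive to it"
    ))
  }

  out_dir <- spec$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  summaries <- vector("list", spec$n_replicates)
  crossings <- if (keep_crossings) vector("list", spec$n_replicates) else NULL
  for (r in seq_len(spec$n_replicates)) {
    cfg_r <- cfg
    cfg_r$seed <- spec$base_seed + r - 1L
    run <- run_trail(cfg_r)
    summaries[[r]] <- summarize_replicate(run)
    if (keep_crossings) crossings[[r]] <- run$crossings
    if (!is.null(out_dir)) {
      write_crossing_log(
        run$crossings,
        file.path(out_dir, sprintf("crossings_rep%03d.csv", r))
      )
    }
    if (!quiet && spec$n_replicates >= 10 && r %% 10 == 0) {
      message(sprintf(
        "[%s] replicate %d/%d: %d crossings",
        spec$name, r, spec$n_replicates, summaries[[r]]$n_crossings
      ))
    }
  }
  aggregate <- aggregate_replicates(summaries)

  result <- structure(
    list(
      spec = spec,
      summaries = summaries,
      crossings = crossings,
      aggregate = aggregate
    ),
    class = "ant_experiment"
  )
  if (!is.null(out_dir)) {
    write_summary_json(result, file.path(out_dir, "summary.json"))
  }
  result
}

#' @export
print.ant_experiment <- function(x, ...) {
  cat(sprintf(
    "<ant_experiment> %s: %d replicates, base seed %d\n",
    x$spec$name, x$spec$n_replicates, x$spec$base_seed
  ))
  print(x$aggregate$scalars)
  invisible(x)
}

#' Tidy methods for replicate experiments
#'
#' `tidy()` returns one row per replicate (seed, flow, group-size
#' statistics and, on the wide trail, per-type central-zone proportions);
#' `glance()` a one-row across-replicate summary.
#'
#' @param x An `ant_experiment`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ant_experiment <- function(x, ...) {
  base <- purrr::imap_dfr(x$summaries, function(s, r) {
    row <- tibble::tibble(
      replicate = r,
      seed = x$spec$base_seed + r - 1L,
      flow_total = s$flow_total,
      n_crossings = s$n_crossings,
      mean_group_size = s$group_stats$mean_group_size,
      max_group_size = as.numeric(s$group_stats$max_group_size)
    )
    if (!is.null(s$zone_props)) {
      wide <- s$zone_props |>
        dplyr::select("type", "prop_central") |>
        tidyr::pivot_wider(
          names_from = "type", values_from = "prop_central",
          names_prefix = "prop_central_"
        )
      row <- dplyr::bind_cols(row, wide)
    }
    row
  })
  base
}

#' @rdname tidy.ant_experiment
#' @export
glance.ant_experiment <- function(x, ...) {
  sc <- x$aggregate$scalars
  flow <- sc[sc$statistic == "flow_total", ]
  gs <- sc[sc$statistic == "mean_group_size", ]
  tibble::tibble(
    name = x$spec$name,
    n_replicates = x$spec$n_replicates,
    flow_mean = flow$mean,
    flow_sd = flow$sd,
    flow_min = flow$min,
    flow_max = flow$max,
    mean_group_size = gs$mean,
    max_group_size = max(purrr::map_dbl(
      x$summaries, ~ as.numeric(.x$group_stats$max_group_size)
    ))
  )
}
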