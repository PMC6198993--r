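#' Read and write crossing-log CSV files
#'
#' The interchange format for midpoint crossing logs: columns `time_s`
#' (seconds, 1 decimal), `particle_id`, `type` (`O`|`U`|`L`), `direction`
#' (`+1` outbound, `-1` inbound) and, for wide-trail logs, `w_cm` (lateral
#' position, 2 decimals). A header row is mandatory. Empirical logs in the
#' same shape can be fed to the statistics functions directly.
#'
#' @param log A crossing-log tibble.
#' @param path File path.
#' @return `read_crossing_log()` returns a tibble sorted by time;
#'   `write_crossing_log()` returns `path` invisibly.
#' @export
write_crossing_log <- function(log, path) {
  log <- tibble::as_tibble(log)
  need <- c("time_s", "particle_id", "type", "direction")
  if (!all(need %in% names(log))) {
    abort(paste0(
      "crossing log needs columns: ", paste(need, collapse = ", ")
    ))
  }
  out <- log
  out$time_s <- round(out$time_s, 1)
  if ("w_cm" %in% names(out)) out$w_cm <- round(out$w_cm, 2)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_crossing_log
#' @export
read_crossing_log <- function(path) {
  log <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time_s", "particle_id", "type", "direction")
  missing <- setdiff(need, names(log))
  if (length(missing) > 0) {
    abort(paste0(
      "crossing log is missing columns: ", paste(missing, collapse = ", ")
    ))
  }
  bad <- setdiff(unique(log$type), PARTICLE_TYPES)
  if (length(bad) > 0) {
    abort(paste0("unknown particle types in log: ", paste(bad, collapse = ", ")))
  }
  dplyr::arrange(log, .data$time_s)
}

summary_to_list <- function(s) {
  gs <- s$group_stats
  list(
    flow_total = s$flow_total,
    n_crossings = s$n_crossings,
    mean_group_size = gs$mean_group_size,
    max_group_size = gs$max_group_size,
    n_groups = gs$n_groups,
    size_distribution = gs$size_distribution,
    prop_laden_by_size = gs$prop_laden_by_size,
    prop_laden_by_position = gs$prop_laden_by_position,
    prop_led_by_laden = gs$prop_led_by_laden,
    zone_props = s$zone_props
  )
}

#' Write an experiment summary as JSON
#'
#' Serializes an [run_experiment()] result: one object per replicate plus
#' an `"aggregate"` object holding the across-replicate mean/s.d./min/max
#' tables.
#'
#' @param experiment An `ant_experiment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(experiment, path) {
  stopifnot(inherits(experiment, "ant_experiment"))
  agg <- experiment$aggregate
  payload <- list(
    experiment = experiment$spec$name,
    n_replicates = experiment$spec$n_replicates,
    base_seed = experiment$spec$base_seed,
    replicates = purrr::map(experiment$summaries, summary_to_list),
    aggregate = list(
      scalars = agg$scalars,
      size_distribution = agg$size_distribution,
      prop_laden_by_size = agg$prop_laden_by_size,
      prop_laden_by_position = agg$prop_laden_by_position,
      prop_led_by_laden = agg$prop_led_by_laden,
      zone_props = agg$zone_props
    )
  )
  jsonlite::write_json(
    payload, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(path)
}

#' Write the aggregated distribution tables as CSV
#'
#' One CSV per distributional statistic (group-size distribution, laden
#' proportion by group size, by within-group position, and laden-led
#' proportion by size), each mirroring the statistic's natural x-axis
#' (`N` or `P`) with mean/s.d./min/max columns across replicates.
#'
#' @param experiment An `ant_experiment` (or a `replicate_aggregate`).
#' @param dir Output directory, created if needed.
#' @return The written file paths, invisibly.
#' @export
write_aggregate_tables <- function(experiment, dir) {
  agg <- if (inherits(experiment, "ant_experiment")) {
    experiment$aggregate
  } else {
    experiment
  }
  stopifnot(inherits(agg, "replicate_aggregate"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- list(
    size_distribution = agg$size_distribution,
    prop_laden_by_size = agg$prop_laden_by_size,
    prop_laden_by_position = agg$prop_laden_by_position,
    prop_led_by_laden = agg$prop_led_by_laden
  )
  if (!is.null(agg$zone_props)) tables$zone_props <- agg$zone_props
  paths <- purrr::imap_chr(tables, function(tbl, nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tbl, p)
    p
  })
  invisible(paths)
}
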