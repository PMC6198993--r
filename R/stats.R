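#' Encode a crossing log as a signed sequence
#'
#' Each midpoint crossing maps to a signed code: `+1` outbound (`O`), `-1`
#' inbound unladen (`U`), `-2` inbound laden (`L`), in time order. The sign
#' carries the direction, so maximal same-sign runs of this sequence are
#' the alternating traffic groups.
#'
#' @param log A crossing-log tibble with columns `time_s` and `type` (as
#'   produced by [run_trail()] or [read_crossing_log()]).
#' @return Integer vector of codes in `{+1, -1, -2}`.
#' @examples
#' log <- tibble::tibble(
#'   time_s = 1:9,
#'   type = c("U", "U", "O", "O", "O", "L", "U", "U", "U")
#' )
#' encode_sequence(log)
#' @export
encode_sequence <- function(log) {
  log <- tibble::as_tibble(log)
  if (!all(c("time_s", "type") %in% names(log))) {
    abort("crossing log needs columns `time_s` and `type`")
  }
  if (is.unsorted(log$time_s)) {
    abort("crossing log must be sorted by time")
  }
  codes <- c(O = 1L, U = -1L, L = -2L)[log$type]
  if (anyNA(codes)) abort("crossing types must be 'O', 'U' or 'L'")
  unname(codes)
}

code_to_type <- function(code) {
  c(`1` = "O", `-1` = "U", `-2` = "L")[as.character(code)]
}

#' Decompose a crossing sequence into alternating groups
#'
#' Splits a signed crossing sequence into maximal runs of equal sign
#' (inbound codes `-1` and `-2` share a sign), the "groups" of the
#' de-synchronized traffic. Concatenating the groups in order reconstructs
#' the sequence exactly, and consecutive groups alternate direction by
#' construction.
#'
#' @param x Either an integer sequence over `{+1, -1, -2}` (see
#'   [encode_sequence()]) or a crossing-log tibble, which is encoded first.
#' @return A tibble with one row per group: `group` (1-based index),
#'   `direction` (`"outbound"`/`"inbound"`), `size`, `leader` (type of the
#'   first member), `n_laden`, and `members`, a list-column of member types
#'   in crossing order.
#' @examples
#' decompose_groups(c(-1, -1, 1, 1, 1, -2, -1, -1, -1))
#' @export
decompose_groups <- function(x) {
  if (is.data.frame(x)) x <- encode_sequence(x)
  x <- as.integer(x)
  if (!all(x %in% c(1L, -1L, -2L))) {
    abort("sequence codes must be +1, -1 or -2")
  }
  if (length(x) == 0) {
    return(tibble::tibble(
      group = integer(), direction = character(), size = integer(),
      leader = character(), n_laden = integer(), members = list()
    ))
  }
  sgn <- sign(x)
  runs <- rle(sgn)
  grp <- rep(seq_along(runs$lengths), runs$lengths)
  members <- unname(split(unname(code_to_type(x)), grp))
  tibble::tibble(
    group = seq_along(runs$lengths),
    direction = ifelse(runs$values > 0, "outbound", "inbound"),
    size = runs$lengths,
    leader = unname(purrr::map_chr(members, 1)),
    n_laden = unname(purrr::map_int(members, ~ sum(.x == "L"))),
    members = members
  )
}

#' Group statistics of the crossing sequence
#'
#' Computes the four distributional statistics used to characterize
#' de-synchronized trail traffic, plus the mean and maximum group size:
#' (i) the group size distribution over all groups; and over *inbound*
#' groups only (laden ants exist only inbound): (ii) the proportion of
#' laden members in groups of size `N`, (iii) the proportion of laden
#' members at position `P` within a group, and (iv) the proportion of
#' groups of size `N` led by a laden ant (first member `L`).
#'
#' @param groups A group tibble from [decompose_groups()].
#' @return A list of class `group_stats` with tibbles
#'   `size_distribution` (`N`, `n_groups`, `proportion`),
#'   `prop_laden_by_size` (`N`, `proportion`),
#'   `prop_laden_by_position` (`P`, `proportion`),
#'   `prop_led_by_laden` (`N`, `proportion`), and scalars
#'   `mean_group_size`, `max_group_size`, `n_groups`, `n_crossings`
#'   (mean/max are `NA` when there are no groups).
#' @examples
#' g <- decompose_groups(c(-1, -1, 1, 1, 1, -2, -1, -1, -1))
#' group_statistics(g)$prop_led_by_laden
#' @export
group_statistics <- function(groups) {
  groups <- tibble::as_tibble(groups)
  empty_np <- function(col) {
    stats::setNames(
      tibble::tibble(n = integer(), proportion = numeric()), c(col, "proportion")
    )
  }
  if (nrow(groups) == 0) {
    return(structure(
      list(
        size_distribution = tibble::tibble(
          N = integer(), n_groups = integer(), proportion = numeric()
        ),
        prop_laden_by_size = empty_np("N"),
        prop_laden_by_position = empty_np("P"),
        prop_led_by_laden = empty_np("N"),
        mean_group_size = NA_real_,
        max_group_size = NA_real_,
        n_groups = 0L,
        n_crossings = 0L
      ),
      class = "group_stats"
    ))
  }

  size_distribution <- groups |>
    dplyr::count(N = .data$size, name = "n_groups") |>
    dplyr::mutate(proportion = .data$n_groups / sum(.data$n_groups))

  inbound <- dplyr::filter(groups, .data$direction == "inbound")

  prop_laden_by_size <- inbound |>
    dplyr::group_by(N = .data$size) |>
    dplyr::summarise(
      proportion = sum(.data$n_laden) / sum(.data$size), .groups = "drop"
    )

  prop_laden_by_position <- inbound |>
    dplyr::mutate(member = .data$members) |>
    tidyr::unnest_longer("member") |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(P = dplyr::row_number()) |>
    dplyr::group_by(.data$P) |>
    dplyr::summarise(
      proportion = mean(.data$member == "L"), .groups = "drop"
    )

  prop_led_by_laden <- inbound |>
    dplyr::group_by(N = .data$size) |>
    dplyr::summarise(
      proportion = mean(.data$leader == "L"), .groups = "drop"
    )

  structure(
    list(
      size_distribution = size_distribution,
      prop_laden_by_size = prop_laden_by_size,
      prop_laden_by_position = prop_laden_by_position,
      prop_led_by_laden = prop_led_by_laden,
      mean_group_size = mean(groups$size),
      max_group_size = max(groups$size),
      n_groups = nrow(groups),
      n_crossings = sum(groups$size)
    ),
    class = "group_stats"
  )
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf(
    "<group_stats> %d groups over %d crossings; mean size %.2f, max %s\n",
    x$n_groups, x$n_crossings,
    x$mean_group_size, format(x$max_group_size)
  ))
  invisible(x)
}

#' Per-type central-zone proportions on the wide trail
#'
#' Lane segregation is measured at the trail midpoint: for each particle
#' type, the proportion of its crossings whose lateral position falls in
#' the central zone (`central_zone[1] <= w < central_zone[2]`, i.e. the
#' half-open interval `[1.25, 3.75)` cm at the defaults) rather than in the
#' two marginal zones. Types with no crossings are absent from the result.
#'
#' @param log A wide-trail crossing log with column `w_cm`.
#' @param config A [sim_config()] supplying the zone boundaries.
#' @return A tibble with columns `type`, `n`, `n_central`, `prop_central`.
#' @export
zone_proportions <- function(log, config = sim_config("wide")) {
  log <- tibble::as_tibble(log)
  if (!"w_cm" %in% names(log) || (nrow(log) > 0 && all(is.na(log$w_cm)))) {
    abort("zone_proportions needs a wide-trail log with lateral positions `w_cm`")
  }
  lo <- config$central_zone[1]
  hi <- config$central_zone[2]
  log |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_central = sum(.data$w_cm >= lo & .data$w_cm < hi),
      .groups = "drop"
    ) |>
    dplyr::mutate(prop_central = .data$n_central / .data$n)
}

#' Summarize one replicate run
#'
#' Produces the per-run summary used for replicate aggregation: total flow
#' scaled to crossings/hour, the group statistics of
#' [group_statistics()], and (wide geometry) the central-zone proportions.
#'
#' @param run A `trail_run`, or a crossing-log tibble (then `config` must
#'   be given).
#' @param config A [sim_config()]; taken from the run if omitted.
#' @return A list of class `replicate_summary`.
#' @export
summarize_replicate <- function(run, config = NULL) {
  if (inherits(run, "trail_run")) {
    log <- run$crossings
    if (is.null(config)) config <- run$config
    hours <- run$n_steps * config$dt / 3600
  } else {
    log <- tibble::as_tibble(run)
    if (is.null(config)) {
      abort("summarize_replicate needs a config when given a bare crossing log")
    }
    hours <- config$duration / 3600
  }
  stats <- group_statistics(decompose_groups(log))
  zone <- if (config$geometry == "wide" && "w_cm" %in% names(log) &&
                nrow(log) > 0) {
    zone_proportions(log, config)
  } else {
    NULL
  }
  structure(
    list(
      flow_total = nrow(log) / hours,
      n_crossings = nrow(log),
      group_stats = stats,
      zone_props = zone,
      geometry = config$geometry
    ),
    class = "replicate_summary"
  )
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf(
    "<replicate_summary> %s trail: flow %.1f/h, mean group size %.2f, max %s\n",
    x$geometry, x$flow_total, x$group_stats$mean_group_size,
    format(x$group_stats$max_group_size)
  ))
  invisible(x)
}

agg_stats <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0) {
    return(tibble::tibble(
      mean = NA_real_, sd = NA_real_, min = NA_real_, max = NA_real_,
      n_replicates = 0L
    ))
  }
  tibble::tibble(
    mean = mean(v),
    sd = if (length(v) > 1) sd(v) else 0,
    min = min(v),
    max = max(v),
    n_replicates = length(v)
  )
}

#' Aggregate replicate summaries
#'
#' Elementwise mean, s.d., min and max of every statistic across seeded
#' replicate runs, mirroring how simulation envelopes are compared with
#' experimental curves. Bins (group sizes `N`, positions `P`, zone types)
#' absent from a replicate are excluded from that bin's aggregation rather
#' than zero-filled.
#'
#' @param summaries A list of [summarize_replicate()] results.
#' @return A list of class `replicate_aggregate` with a `scalars` tibble
#'   (`statistic`, `mean`, `sd`, `min`, `max`) and per-bin tibbles
#'   `size_distribution`, `prop_laden_by_size`, `prop_laden_by_position`,
#'   `prop_led_by_laden`, and `zone_props` (wide only).
#' @export
aggregate_replicates <- function(summaries) {
  if (length(summaries) == 0) {
    abort("aggregate_replicates needs at least one replicate summary")
  }
  if (inherits(summaries, "replicate_summary")) summaries <- list(summaries)

  scalar_tbl <- purrr::map_dfr(summaries, function(s) {
    tibble::tibble(
      flow_total = s$flow_total,
      mean_group_size = s$group_stats$mean_group_size,
      max_group_size = as.numeric(s$group_stats$max_group_size)
    )
  })
  scalars <- scalar_tbl |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "statistic") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$statistic) |>
    dplyr::reframe(agg_stats(.data$value))

  agg_binned <- function(field, key) {
    purrr::map_dfr(summaries, ~ .x$group_stats[[field]]) |>
      dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
      dplyr::reframe(agg_stats(.data$proportion)) |>
      dplyr::arrange(dplyr::across(dplyr::all_of(key)))
  }

  size_distribution <- purrr::map_dfr(
    summaries, ~ .x$group_stats$size_distribution
  ) |>
    dplyr::group_by(.data$N) |>
    dplyr::reframe(agg_stats(.data$proportion)) |>
    dplyr::arrange(.data$N)

  zone <- purrr::compact(purrr::map(summaries, "zone_props"))
  zone_props <- if (length(zone) > 0) {
    purrr::map_dfr(zone, ~.x) |>
      dplyr::group_by(.data$type) |>
      dplyr::reframe(agg_stats(.data$prop_central))
  } else {
    NULL
  }

  structure(
    list(
      scalars = scalars,
      size_distribution = size_distribution,
      prop_laden_by_size = agg_binned("prop_laden_by_size", "N"),
      prop_laden_by_position = agg_binned("prop_laden_by_position", "P"),
      prop_led_by_laden = agg_binned("prop_led_by_laden", "N"),
      zone_props = zone_props,
      n_replicates = length(summaries)
    ),
    class = "replicate_aggregate"
  )
}

#' @export
print.replicate_aggregate <- function(x, ...) {
  cat(sprintf("<replicate_aggregate> %d replicates\n", x$n_replicates))
  print(x$scalars)
  invisible(x)
}
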