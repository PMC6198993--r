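test_that("crossing logs encode to signed sequences", {
  expect_equal(encode_sequence(log9), seq9)
  expect_equal(encode_sequence(log9[0, ]), integer())
  all_o <- tibble::tibble(time_s = 1:5, type = rep("O", 5))
  expect_equal(encode_sequence(all_o), rep(1L, 5))
  shuffled <- log9[c(2, 1, 3:9), ]
  expect_error(encode_sequence(shuffled), "sorted")
  bad <- tibble::tibble(time_s = 1, type = "Q")
  expect_error(encode_sequence(bad), "types")
})

test_that("group decomposition splits maximal same-sign runs", {
  g <- decompose_groups(seq9)
  expect_equal(g$size, c(2, 3, 4))
  expect_equal(g$direction, c("inbound", "outbound", "inbound"))
  expect_equal(g$leader[3], "L")
  expect_equal(g$members[[3]], c("L", "U", "U", "U"))

  expect_equal(nrow(decompose_groups(integer())), 0)
  alt <- decompose_groups(c(1, -1, 1, -1))
  expect_equal(alt$size, rep(1, 4))
  expect_error(decompose_groups(c(1, 2)), "codes")
  # a crossing log can be decomposed directly
  expect_equal(decompose_groups(log9)$size, c(2, 3, 4))
})

test_that("group decomposition round-trips and alternates direction", {
  set.seed(99)
  for (rep in 1:20) {
    codes <- sample(c(1L, -1L, -2L), sample(1:200, 1), replace = TRUE)
    g <- decompose_groups(codes)
    # concatenating members reconstructs the sequence
    flat <- unlist(g$members)
    expect_equal(flat, c(`1` = "O", `-1` = "U", `-2` = "L")[as.character(codes)],
      ignore_attr = TRUE
    )
    expect_equal(sum(g$size), length(codes))
    # consecutive groups alternate direction (the de-synchronization pattern)
    if (nrow(g) > 1) {
      expect_true(all(g$direction[-1] != g$direction[-nrow(g)]))
    }
    # outbound groups contain only outbound particles
    out_members <- unlist(g$members[g$direction == "outbound"])
    expect_true(all(out_members == "O"))
  }
})

test_that("the four group statistics match hand enumeration on the worked example", {
  st <- group_statistics(decompose_groups(seq9))
  # (i) over all groups
  expect_equal(st$size_distribution$N, c(2, 3, 4))
  expect_equal(st$size_distribution$proportion, rep(1 / 3, 3))
  # (iv): the size-4 inbound group is laden-led, the size-2 group is not
  led <- st$prop_led_by_laden
  expect_equal(led$proportion[led$N == 4], 1)
  expect_equal(led$proportion[led$N == 2], 0)
  # (iii): leaders of the two inbound groups are U and L
  pos <- st$prop_laden_by_position
  expect_equal(pos$proportion[pos$P == 1], 0.5)
  expect_equal(pos$proportion[pos$P == 4], 0)
  # (ii): laden share among members of inbound size-4 groups
  by_size <- st$prop_laden_by_size
  expect_equal(by_size$proportion[by_size$N == 4], 0.25)
  expect_equal(st$mean_group_size, 3)
  expect_equal(st$max_group_size, 4)
})

test_that("statistics degrade gracefully without laden particles or groups", {
  no_l <- group_statistics(decompose_groups(c(-1, -1, 1, -1)))
  expect_true(all(no_l$prop_laden_by_size$proportion == 0))
  expect_true(all(no_l$prop_laden_by_position$proportion == 0))
  expect_true(all(no_l$prop_led_by_laden$proportion == 0))

  empty <- group_statistics(decompose_groups(integer()))
  expect_true(is.na(empty$mean_group_size))
  expect_equal(empty$n_groups, 0L)

  # statistic (ii) at N = 1 is the laden fraction of singleton inbound crossings
  st <- group_statistics(decompose_groups(c(-2, 1, -1, 1, -2, 1)))
  ii <- st$prop_laden_by_size
  expect_equal(ii$proportion[ii$N == 1], 2 / 3)
})

test_that("zone proportions use the half-open central interval", {
  cfg <- sim_config("wide")
  log <- tibble::tibble(
    time_s = 1:6, particle_id = 1:6,
    type = c("L", "L", "U", "U", "O", "O"),
    direction = c(-1, -1, -1, -1, 1, 1),
    w_cm = c(2.5, 2.6, 0.5, 2.5, 1.25, 1.24)
  )
  zp <- zone_proportions(log, cfg)
  expect_equal(zp$prop_central[zp$type == "L"], 1)
  expect_equal(zp$prop_central[zp$type == "U"], 0.5)
  # 1.25 is central, 1.24 marginal
  expect_equal(zp$prop_central[zp$type == "O"], 0.5)
  # a type with no crossings is absent, not zero-filled
  expect_false("X" %in% zp$type)
  expect_error(zone_proportions(log9, cfg), "w_cm")
})

test_that("replicate aggregation computes mean, sd, min, max with bin exclusion", {
  mk <- function(flow, codes, zone = NULL) {
    log <- tibble::tibble(
      time_s = seq_along(codes), particle_id = seq_along(codes),
      type = c(`1` = "O", `-1` = "U", `-2` = "L")[as.character(codes)],
      direction = sign(codes)
    )
    s <- summarize_replicate(log, sim_config("narrow"))
    s$flow_total <- flow
    s
  }
  s1 <- mk(5300, c(1, 1, -1))
  agg1 <- aggregate_replicates(list(s1))
  flow_row <- agg1$scalars[agg1$scalars$statistic == "flow_total", ]
  expect_equal(flow_row$mean, 5300)
  expect_equal(flow_row$sd, 0)
  expect_equal(flow_row$min, flow_row$max)

  s2 <- mk(5400, c(1, -1, -1, -1))
  agg <- aggregate_replicates(list(s1, s2))
  flow_row <- agg$scalars[agg$scalars$statistic == "flow_total", ]
  expect_equal(flow_row$mean, 5350)
  expect_equal(flow_row$min, 5300)
  expect_equal(flow_row$max, 5400)
  expect_equal(flow_row$sd, sd(c(5300, 5400)))

  # size 3 occurs in only one replicate: its bin aggregates one value
  sd3 <- agg$size_distribution[agg$size_distribution$N == 3, ]
  expect_equal(sd3$n_replicates, 1)
  expect_error(aggregate_replicates(list()), "at least one")
})
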