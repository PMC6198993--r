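test_that("a lone particle follows the closed-form free-flow trajectory", {
  cfg <- narrow_quiet()
  run <- run_narrow(cfg,
    init = tibble::tibble(type = "O", x = 0),
    n_steps = 200, record_trajectory = TRUE
  )
  tr <- traj_of(run, 0)
  expect_equal(tr$x, (1:200) * 0.23, tolerance = 1e-10)
  expect_true(all(tr$moved == 1))

  # transit times: 300 / 2.3 ~ 130.4 s (O), 300 / 1.9 ~ 157.9 s (L)
  for (case in list(list(type = "O", t = 300 / 2.3),
                    list(type = "L", t = 300 / 1.9))) {
    x0 <- if (case$type == "O") 0 else 300
    run <- run_narrow(cfg,
      init = tibble::tibble(type = case$type, x = x0),
      n_steps = 1700, record_trajectory = TRUE
    )
    expect_equal(sum(run$counters$exited), 1)
    transit <- max(traj_of(run, 0)$time_s)
    expect_lt(abs(transit - case$t), 0.2)
  }
})

test_that("a follower stops until the particle ahead moves out of range", {
  # two outbound particles, follower 1.0 cm behind (inside the 1.46 radius)
  run <- run_narrow(narrow_quiet(),
    init = tibble::tibble(type = c("O", "O"), x = c(10, 9)),
    n_steps = 10, record_trajectory = TRUE
  )
  follower <- traj_of(run, 1)
  # gap grows by 0.23/step; walking resumes once the gap exceeds the radius
  expect_equal(follower$moved[1:3], c(0, 0, 0))
  expect_true(all(follower$moved[4:10] == 1))
  # per-step displacement is exactly 0 or s dt
  steps <- diff(c(9, follower$x))
  expect_true(all(abs(steps) < 1e-9 | abs(steps - 0.23) < 1e-9))
})

test_that("an unladen particle waits behind a moving laden particle", {
  run <- run_narrow(narrow_quiet(),
    init = tibble::tibble(type = c("L", "U"), x = c(199, 200)),
    n_steps = 6, record_trajectory = TRUE
  )
  u <- traj_of(run, 1)
  # gap 1.0 + 0.19 (k - 1) exceeds the 1.46 radius from step 4 on
  expect_equal(u$moved[1:3], c(0, 0, 0))
  expect_true(all(u$moved[4:6] == 1))
})

test_that("an unladen particle passes a yielding outbound particle", {
  init <- tibble::tibble(
    type = c("O", "U"), x = c(99, 100),
    state = c("YIELDING", "MOVING"), yield_until = c(1e9, -1)
  )
  run <- run_narrow(narrow_quiet(), init,
    n_steps = 20, record_trajectory = TRUE
  )
  u <- traj_of(run, 1)
  expect_true(all(u$moved == 1))
  expect_lt(min(u$x), 99) # walked through the yielding particle's position
  # the yielding particle stays put the whole time
  expect_equal(unique(traj_of(run, 0)$x), 99)
})

test_that("an outbound particle encountering an oncoming laden particle starts yielding", {
  run <- run_narrow(narrow_quiet(),
    init = tibble::tibble(type = c("O", "L"), x = c(150, 151.2)),
    n_steps = 1, record_trajectory = TRUE, seed = 5
  )
  o <- traj_of(run, 0)
  expect_equal(o$state, "YIELDING")
  expect_equal(o$moved, 0)
  expect_equal(o$x, 150)
  # the laden particle keeps walking
  expect_equal(traj_of(run, 1)$moved, 1)
})

test_that("with a point-mass passage distribution about n unladen pass the yielder", {
  n_coop <- 5
  cfg <- narrow_quiet(coop_dist = coop_point(n_coop))
  init <- tibble::tibble(
    type = c("O", "L", rep("U", 10)),
    x = c(150, 151.2, 151.2 + 1.6 * (1:10))
  )
  run <- run_narrow(cfg, init, n_steps = 120, record_trajectory = TRUE, seed = 3)
  o <- traj_of(run, 0)
  expect_equal(o$state[1], "YIELDING")
  resume <- o$time_s[which(o$moved == 1)[1]]
  # the yield lasts tau = 0.8 n seconds from the encounter
  expect_equal(resume, 0.8 * n_coop + 0.1, tolerance = 0.11)
  # unladen particles that crossed x = 150 before the yielder resumed
  passed <- run$trajectory |>
    dplyr::filter(.data$type == "U", .data$time_s <= resume, .data$x < 150) |>
    dplyr::distinct(.data$particle_id) |>
    nrow()
  expect_gte(passed, n_coop - 1)
  expect_lte(passed, n_coop + 1)
})

test_that("unladen particles never overtake each other", {
  # U gives way to every particle type, so its crossing order must equal its
  # entry order. (Higher-priority types can occasionally slip past a
  # same-type particle when a nearer walk-through particle governs the
  # encounter, so the strict form of this property is U-specific.)
  run <- run_narrow(sim_config("narrow", duration = 300, seed = 11))
  ids <- run$crossings$particle_id[run$crossings$type == "U"]
  expect_true(!is.unsorted(ids, strictly = TRUE))

  # staged same-type pair: the follower can never pass the leader
  run2 <- run_narrow(narrow_quiet(),
    init = tibble::tibble(type = c("O", "O"), x = c(50, 49.5)),
    n_steps = 400, record_trajectory = TRUE
  )
  both <- tidyr::pivot_wider(
    run2$trajectory[, c("time_s", "particle_id", "x")],
    names_from = "particle_id", values_from = "x", names_prefix = "p"
  )
  both <- both[stats::complete.cases(both), ]
  expect_true(all(both$p0 > both$p1))
})

test_that("full runs conserve particles and log crossings coherently", {
  run <- run_narrow(sim_config("narrow", duration = 300, seed = 2))
  ct <- run$counters
  expect_equal(ct$spawned, ct$exited + ct$on_trail + ct$queued)
  cr <- run$crossings
  expect_true(!is.unsorted(cr$time_s))
  expect_equal(anyDuplicated(cr$particle_id), 0)
  expect_true(all(cr$direction[cr$type == "O"] == 1))
  expect_true(all(cr$direction[cr$type != "O"] == -1))
  # on-trail particles sit within the trail
  expect_true(all(run$particles$x >= 0 & run$particles$x <= 300))
})

test_that("runs are bit-reproducible for a fixed seed", {
  cfg <- sim_config("narrow", duration = 120, seed = 21)
  r1 <- run_narrow(cfg)
  r2 <- run_narrow(cfg)
  expect_identical(r1$crossings, r2$crossings)
  expect_identical(r1$counters, r2$counters)
  r3 <- run_narrow(cfg, seed = 22)
  expect_false(identical(r1$crossings, r3$crossings))
})

test_that("zero arrival rate yields an empty crossing log", {
  run <- run_narrow(narrow_quiet(duration = 60))
  expect_equal(nrow(run$crossings), 0)
  expect_equal(sum(run$counters$spawned), 0)
  expect_error(run_narrow(sim_config("wide")), "narrow")
})
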