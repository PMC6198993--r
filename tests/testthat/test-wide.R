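test_that("a lone particle keeps its lateral position for the whole transit", {
  run <- run_wide(wide_quiet(),
    init = tibble::tibble(type = "O", x = 0, w = 3.7),
    n_steps = 1400, record_trajectory = TRUE
  )
  tr <- traj_of(run, 0)
  expect_equal(unique(tr$w), 3.7)
  expect_true(all(tr$moved == 1))
  expect_lt(abs(max(tr$time_s) - 300 / 2.3), 0.2)
  expect_equal(run$crossings$w_cm, 3.7)
})

test_that("turning freezes longitudinal progress and moves laterally by s dt", {
  # inbound unladen vs oncoming outbound ahead: the unladen turns, the
  # outbound keeps walking
  init <- tibble::tibble(
    type = c("U", "O"), x = c(150, 148.9), w = c(2.0, 2.3)
  )
  run <- run_wide(wide_quiet(), init, n_steps = 1, record_trajectory = TRUE)
  u <- traj_of(run, 0)
  o <- traj_of(run, 1)
  expect_equal(u$x, 150) # cos(+-pi/2) = 0
  expect_equal(u$state, "TURNING")
  # inbound avoider steps away from the governor's side (governor above)
  expect_equal(u$w, 2.0 - 0.23)
  expect_equal(o$x, 148.9 + 0.23)
  expect_equal(o$w, 2.3)
})

test_that("outbound avoiders turn toward the encountered particle's side", {
  # heading decomposition: theta_I = +pi/2 iff w_i < w_j, so an outbound
  # particle below a laden one moves up
  init <- tibble::tibble(
    type = c("O", "L"), x = c(150, 151.1), w = c(2.0, 2.3)
  )
  run <- run_wide(wide_quiet(), init, n_steps = 1, record_trajectory = TRUE)
  o <- traj_of(run, 0)
  expect_equal(o$x, 150)
  expect_equal(o$w, 2.0 + 0.23)
  # the laden particle has priority and walks
  expect_equal(traj_of(run, 1)$x, 151.1 - 0.19)
})

test_that("walls clamp partial turns and convert fully blocked turns into walks", {
  # partial clamp: an instructed turn that would overshoot stops at the wall
  init <- tibble::tibble(
    type = c("U", "O"), x = c(150, 148.9), w = c(4.95, 4.2)
  )
  run <- run_wide(wide_quiet(), init, n_steps = 1, record_trajectory = TRUE)
  u <- traj_of(run, 0)
  expect_equal(u$x, 150)
  expect_equal(u$w, 5) # 4.95 + 0.23 clamped, not 5.18

  # fully blocked: already on the wall, instructed outward -> walks on
  init2 <- tibble::tibble(
    type = c("U", "O"), x = c(150, 148.9), w = c(5, 4.2)
  )
  run2 <- run_wide(wide_quiet(), init2, n_steps = 1, record_trajectory = TRUE)
  u2 <- traj_of(run2, 0)
  expect_equal(u2$w, 5)
  expect_equal(u2$x, 150 - 0.23)
})

test_that("the stop-rule control variant halts instead of turning", {
  init <- tibble::tibble(
    type = c("U", "O"), x = c(150, 148.9), w = c(2.0, 2.3)
  )
  run <- run_wide(wide_quiet(avoidance_rule = "stop"), init,
    n_steps = 1, record_trajectory = TRUE
  )
  u <- traj_of(run, 0)
  expect_equal(u$x, 150)
  expect_equal(u$w, 2.0)
  expect_equal(u$state, "STOPPED")
})

test_that("per-step displacement magnitude is s dt, less only at a wall, or 0 when stopped", {
  run <- run_wide(sim_config("wide", duration = 60, seed = 3),
    record_trajectory = TRUE
  )
  sp <- run$trajectory |>
    dplyr::group_by(.data$particle_id) |>
    dplyr::arrange(.data$time_s, .by_group = TRUE) |>
    dplyr::mutate(
      step = sqrt((c(NA, diff(.data$x)))^2 + (c(NA, diff(.data$w)))^2),
      s_dt = ifelse(.data$type == "L", 0.19, 0.23),
      at_wall = .data$w %in% c(0, 5)
    ) |>
    dplyr::filter(!is.na(.data$step))
  ok <- abs(sp$step) < 1e-9 | abs(sp$step - sp$s_dt) < 1e-9 |
    (sp$at_wall & sp$step < sp$s_dt + 1e-9)
  expect_true(all(ok))
  # lateral positions stay inside the walls
  expect_true(all(sp$w >= 0 & sp$w <= 5))
})

test_that("wide runs conserve particles across trail, queues and exits", {
  run <- run_wide(sim_config("wide", duration = 120, seed = 8))
  ct <- run$counters
  expect_equal(ct$spawned, ct$exited + ct$on_trail + ct$queued)
  expect_true(all(run$crossings$w_cm >= 0 & run$crossings$w_cm <= 5))
  expect_true(!is.unsorted(run$crossings$time_s))
  expect_equal(anyDuplicated(run$crossings$particle_id), 0)
})

test_that("wide runs are reproducible and respect the geometry guard", {
  cfg <- sim_config("wide", duration = 60, seed = 13)
  expect_identical(run_wide(cfg)$crossings, run_wide(cfg)$crossings)
  expect_error(run_wide(sim_config("narrow")), "wide")
  expect_equal(nrow(run_wide(wide_quiet(duration = 30))$crossings), 0)
})
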