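# Shared fixtures: tiny configs and staged particle layouts.

# the worked nine-crossing example: two inbound, three outbound, then a
# laden-led inbound group of four
seq9 <- c(-1, -1, 1, 1, 1, -2, -1, -1, -1)

log9 <- tibble::tibble(
  time_s = seq(0.5, by = 0.5, length.out = 9),
  particle_id = 0:8,
  type = c("U", "U", "O", "O", "O", "L", "U", "U", "U"),
  direction = c(-1, -1, 1, 1, 1, -1, -1, -1, -1)
)

# point mass at n for the cooperative-passage distribution
coop_point <- function(n) {
  p <- rep(0, 16)
  p[n + 1] <- 1
  p
}

# short, empty-trail configs used where only staged particles matter
narrow_quiet <- function(...) sim_config("narrow", mu = 0, ...)
wide_quiet <- function(...) sim_config("wide", mu = 0, ...)

# trajectory rows of one particle, ordered by time
traj_of <- function(run, id) {
  dplyr::arrange(
    dplyr::filter(run$trajectory, .data$particle_id == id),
    .data$time_s
  )
}
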