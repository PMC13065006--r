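# shared fixtures, built lazily and memoised for the session

default_player <- function(sex = "male", height = 1.82, mass = 77.2) {
  list(id = "P01", sex = sex, height = height, body_mass = mass,
       segment_lengths = default_segment_lengths(height))
}

# one default generator trial with cameras, reused by several tests
.fixture_env <- new.env(parent = emptyenv())

fixture_trial <- function() {
  if (is.null(.fixture_env$trial))
    .fixture_env$trial <- simulate_trial(default_player(), 1L, 6.0, seed = 42L,
                                         with_cameras = TRUE)
  .fixture_env$trial
}

# tiny hand-built motion trial: CoM moving, segments frozen relative to the
# CoM, proxies identical to the CoM
rigid_trial <- function(n = 1200, rate = 200) {
  t <- (seq_len(n) - 1L) / rate
  com <- cbind(sin(2 * pi * 0.5 * t), 2 * t, 1 + 0.1 * sin(2 * pi * 0.7 * t))
  tab <- segment_parameters("male")
  segs <- lapply(seq_len(nrow(tab)), function(i)
    list(com = com + matrix(c(0.1 * i, -0.05 * i, 0.2 - 0.03 * i),
                            n, 3L, byrow = TRUE),
         omega = matrix(0, n, 3L)))
  names(segs) <- tab$name
  structure(list(time = t, rate = rate, com = com, pelvis = com,
                 segments = segs, pseudo_com = com, boxes = NULL,
                 cameras = NULL, player_id = "T01", sex = "male", cycle = 1L,
                 body_mass = 77.2,
                 height = 1.82,
                 segment_lengths = default_segment_lengths(1.82),
                 sprint_threshold = 8.5, seed = 0L),
            class = "motion_trial")
}

expect_all_close <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a - b)), tol)
}
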