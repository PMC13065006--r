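#' Protocol configuration
#'
#' Parameters of the on-court fatiguing protocol that the synthetic
#' generator emulates: 30-s captures at 200 Hz containing one serve, eight
#' alternating groundstrokes at a metronome cadence (one ball every 2.0 s
#' for male, 2.5 s for female players), and a maximal sprint crossing 8.5 m
#' forward of the baseline. Rest structure is carried for completeness but
#' does not affect the simulated kinematics.
#'
#' @param n_players cohort size.
#' @param rate sampling rate (Hz).
#' @param trial_duration capture length (s).
#' @param serve_interval_male,serve_interval_female ball cadence (s).
#' @param n_groundstrokes strokes per set.
#' @param sprint_threshold sprint end distance (m).
#' @param cycle_range admissible protocol cycle counts (min, max).
#' @param rest_between_sets,rest_reduction_after,rest_between_cycles rest
#'   structure (s; reduction applied after the named cycles).
#' @return list of class `protocol_config`.
#' @export
protocol_config <- function(n_players = 15L, rate = 200, trial_duration = 30,
                            serve_interval_male = 2.0,
                            serve_interval_female = 2.5,
                            n_groundstrokes = 8L, sprint_threshold = 8.5,
                            cycle_range = c(4L, 12L),
                            rest_between_sets = 20, rest_reduction_after = c(5L, 10L),
                            rest_between_cycles = 60) {
  stopifnot(rate > 0, trial_duration > 0, serve_interval_male > 0,
            serve_interval_female > 0, n_groundstrokes >= 1,
            sprint_threshold > 0, cycle_range[1] >= 1, cycle_range[2] <= 50,
            cycle_range[1] <= cycle_range[2])
  structure(as.list(environment()), class = "protocol_config")
}

#' Fatigue model
#'
#' Linear decline of peak sprint velocity with cumulative total mechanical
#' work: for cycle c, the modelled peak velocity is
#' `baseline - slope * W_cum(c-1) + noise`, with per-player slopes drawn
#' log-normally around `slope_mean`. Players stop (volitional exhaustion)
#' once the modelled velocity falls below `exhaustion_fraction` of
#' baseline, echoing the roughly 20% velocity reduction observed at the end
#' of such protocols.
#'
#' @param baseline_mean,baseline_sd cohort baseline peak sprint velocity
#'   (m/s); defaults 6.0 and 0.5.
#' @param slope_mean mean velocity loss per unit cumulative work
#'   (m/s per J/kg).
#' @param slope_cv log-scale coefficient of variation of per-player slopes.
#' @param noise_sd trial-to-trial velocity noise (m/s).
#' @param exhaustion_fraction stop threshold as a fraction of baseline.
#' @return list of class `fatigue_model`.
#' @export
fatigue_model <- function(baseline_mean = 6.0, baseline_sd = 0.5,
                          slope_mean = 6.5e-4, slope_cv = 0.35,
                          noise_sd = 0.15, exhaustion_fraction = 0.8) {
  stopifnot(baseline_mean > 0, baseline_sd >= 0, slope_mean > 0,
            noise_sd >= 0, exhaustion_fraction > 0, exhaustion_fraction < 1)
  structure(as.list(environment()), class = "fatigue_model")
}

# anthropometric segment lengths as fractions of stature
segment_length_fractions <- c(
  head_trunk = 0.45, pelvis = 0.12,
  thigh_l = 0.245, thigh_r = 0.245, shank_l = 0.246, shank_r = 0.246,
  foot_l = 0.152, foot_r = 0.152,
  upper_arm_l = 0.188, upper_arm_r = 0.188,
  forearm_l = 0.145, forearm_r = 0.145, hand_l = 0.108, hand_r = 0.108)

#' Default segment lengths for a subject
#'
#' @param height stature (m).
#' @return named numeric vector of segment lengths (m) for the 14-segment
#'   configuration.
#' @export
default_segment_lengths <- function(height) {
  stopifnot(height > 0)
  segment_length_fractions * height
}

#' Eight-camera rig around a half court
#'
#' Ideal pinhole cameras positioned around the half court in use, all
#' aimed at a point above mid half-court, emulating a surround
#' motion-capture arrangement.
#'
#' @param n_cameras number of cameras.
#' @param radius horizontal distance from the half-court centre (m).
#' @return list of `camera_model`s.
#' @export
make_camera_rig <- function(n_cameras = 8L, radius = 14) {
  target <- c(0, 4.5, 1.1)
  ang <- seq(0, 2 * pi, length.out = n_cameras + 1L)[-(n_cameras + 1L)]
  lapply(seq_len(n_cameras), function(i) {
    centre <- c(target[1] + radius * cos(ang[i]),
                target[2] + radius * sin(ang[i]),
                3 + 1.5 * (i %% 2))
    camera_looking_at(centre, target, id = sprintf("cam%02d", i))
  })
}

#' Draw a random stroke style
#'
#' Limb-chain oscillation phases (with fixed proximal-to-distal lags and
#' roughly antiphase bilateral coordination) and a small frequency jitter
#' — the per-player movement signature used by the trial generator.
#'
#' @return list with `phases` (named, one per segment) and `freq_jit`.
#' @export
draw_stroke_style <- function() {
  ph_leg <- stats::runif(1, 0, 2 * pi)
  ph_arm <- stats::runif(1, 0, 2 * pi)
  ph_trunk <- stats::runif(2, 0, 2 * pi)
  phases <- c(head_trunk = ph_trunk[1L], pelvis = ph_trunk[2L],
              thigh_l = ph_leg, shank_l = ph_leg + 0.9, foot_l = ph_leg + 1.8,
              thigh_r = NA, shank_r = NA, foot_r = NA,
              upper_arm_l = ph_arm, forearm_l = ph_arm + 0.8,
              hand_l = ph_arm + 1.6,
              upper_arm_r = NA, forearm_r = NA, hand_r = NA)
  right <- c("thigh_r", "shank_r", "foot_r", "upper_arm_r", "forearm_r", "hand_r")
  left <- sub("_r$", "_l", right)
  phases[right] <- phases[left] + pi + stats::runif(length(right), -0.25, 0.25)
  list(phases = phases, freq_jit = stats::runif(1, 0.95, 1.05))
}

# smooth 0->1 ramp (cosine), clamped outside [t0, t1]
smooth_ramp <- function(t, t0, t1) {
  u <- pmin(pmax((t - t0) / (t1 - t0), 0), 1)
  0.5 * (1 - cos(pi * u))
}

gauss_bump <- function(t, centre, width) exp(-0.5 * ((t - centre) / width)^2)

# segment oscillation templates: baseline offset from the CoM (standing),
# positional amplitude (m) and angular-velocity amplitude (rad/s) per
# segment, and the oscillation frequency band per limb group
segment_offsets <- rbind(
  head_trunk  = c( 0.00, 0.00,  0.25),
  pelvis      = c( 0.00, 0.00, -0.10),
  thigh_l     = c(-0.10, 0.00, -0.35), thigh_r     = c(0.10, 0.00, -0.35),
  shank_l     = c(-0.10, 0.02, -0.70), shank_r     = c(0.10, 0.02, -0.70),
  foot_l      = c(-0.10, 0.08, -0.90), foot_r      = c(0.10, 0.08, -0.90),
  upper_arm_l = c(-0.22, 0.00,  0.15), upper_arm_r = c(0.22, 0.00,  0.15),
  forearm_l   = c(-0.27, 0.06, -0.05), forearm_r   = c(0.27, 0.06, -0.05),
  hand_l      = c(-0.30, 0.12, -0.20), hand_r      = c(0.30, 0.12, -0.20))

segment_pos_amp <- c(
  head_trunk = 0.035, pelvis = 0.02,
  thigh_l = 0.07, thigh_r = 0.07, shank_l = 0.14, shank_r = 0.14,
  foot_l = 0.22, foot_r = 0.22,
  upper_arm_l = 0.11, upper_arm_r = 0.11,
  forearm_l = 0.20, forearm_r = 0.20, hand_l = 0.28, hand_r = 0.28)

segment_omega_amp <- c(
  head_trunk = 0.5, pelvis = 1.0,
  thigh_l = 3, thigh_r = 3, shank_l = 5, shank_r = 5, foot_l = 8, foot_r = 8,
  upper_arm_l = 4, upper_arm_r = 4, forearm_l = 6, forearm_r = 6,
  hand_l = 8, hand_r = 8)

segment_freq <- c(
  head_trunk = 1.0, pelvis = 1.6,
  thigh_l = 2.2, thigh_r = 2.2, shank_l = 2.2, shank_r = 2.2,
  foot_l = 2.2, foot_r = 2.2,
  upper_arm_l = 1.8, upper_arm_r = 1.8, forearm_l = 1.8, forearm_r = 1.8,
  hand_l = 1.8, hand_r = 1.8)

#' Simulate one protocol trial
#'
#' Builds a deterministic kinematic skeleton for one 30-s capture — serve
#' (with a two-dip countermovement before the most prominent vertical
#' peak), eight alternating lateral groundstrokes at the configured
#' cadence, a change of direction, and a forward sprint crossing the
#' 8.5-m threshold with a prescribed peak velocity — then superimposes
#' limb-segment oscillation (amplitudes scaled by `internal_scale` so that
#' internal work comes out near one third of total), a pelvis proxy with a
#' slow offset plus a high-frequency component, and optionally an
#' eight-camera bounding-box observation stream. Ground-truth events and
#' section works are computed from the noise-free skeleton through the same
#' filtering and energetics path used in processing.
#'
#' @param player list with `id`, `sex`, `body_mass`, `height`,
#'   `segment_lengths`, and optionally `style` (see [draw_stroke_style()];
#'   drawn from the trial seed when absent).
#' @param cycle_index protocol cycle number (0 = baseline sprint test).
#' @param v_peak prescribed peak forward sprint velocity (m/s).
#' @param seed integer seed for this trial's random components.
#' @param config `protocol_config`.
#' @param with_cameras generate camera models and bounding-box streams
#'   (and the triangulated pseudo-CoM).
#' @param pos_noise_sd marker-level positional noise SD (m).
#' @param internal_scale multiplier on segment oscillation amplitudes.
#' @param pelvis_hf_amp,pelvis_hf_freq amplitude (m) and frequency (Hz) of
#'   the pelvis proxy's extra high-frequency motion.
#' @param px_noise_sd bounding-box centre observation noise (px).
#' @param compute_truth_works also compute ground-truth section works from
#'   the noise-free skeleton (slower; needed by the cohort simulator).
#' @return list with `trial` (class `motion_trial`) and `truth` (class
#'   `ground_truth`: `start`, `transition`, `end`, `peak_velocity`,
#'   optionally `works`).
#' @export
simulate_trial <- function(player, cycle_index, v_peak, seed,
                           config = protocol_config(), with_cameras = TRUE,
                           pos_noise_sd = 0.003, internal_scale = 2.7,
                           pelvis_hf_amp = 0.018, pelvis_hf_freq = 3.5,
                           px_noise_sd = 1, compute_truth_works = TRUE) {
  set.seed(seed)
  rate <- config$rate
  n <- round(config$trial_duration * rate)
  t <- (seq_len(n) - 1L) / rate
  s_int <- if (identical(player$sex, "female")) config$serve_interval_female
           else config$serve_interval_male

  ## --- CoM skeleton ------------------------------------------------------
  z0 <- 0.5 * player$height
  # serve: two countermovement dips then the prominent peak
  z <- z0 - 0.06 * gauss_bump(t, 1.2, 0.12) - 0.10 * gauss_bump(t, 1.8, 0.13) +
    0.35 * gauss_bump(t, 2.3, 0.12)

  # groundstrokes: lateral shuttling between the forehand and backhand
  # target zones, one stroke per serve_interval; the closing down-ramp of
  # the envelope carries the player back along the baseline (the run into
  # the change of direction)
  t_gs0 <- 3.0
  gs_dur <- config$n_groundstrokes * s_int
  t_gs1 <- t_gs0 + gs_dur
  t_turn <- t_gs1 + 1.2
  env_gs <- smooth_ramp(t, t_gs0 - 0.5, t_gs0 + 1) *
    (1 - smooth_ramp(t, t_gs1 - 0.3, t_turn))
  x <- 2.5 * env_gs * sin(pi * (t - t_gs0) / s_int + pi / 2)
  # forward/back micro-adjustments towards the target zones, plus small
  # vertical loading at each stroke
  y_gs <- 0.3 * env_gs * sin(pi * (t - t_gs0) / s_int)
  z <- z + 0.04 * env_gs * sin(2 * pi * (t - t_gs0) / s_int)

  # sprint: logistic forward run with peak velocity v_peak at its midpoint
  y_final <- 10.5
  tau <- y_final / (4 * v_peak)
  t_mid <- t_turn + 1.7
  y_sprint <- y_final / (1 + exp(-(t - t_mid) / tau))
  y_sprint <- y_sprint - y_final / (1 + exp(-(t[1] - t_mid) / tau))
  y <- y_gs + y_sprint
  # slight crouch while sprinting
  z <- z - 0.05 * smooth_ramp(t, t_turn, t_turn + 1)

  com_skel <- cbind(x = x, y = y, z = z)

  ## --- segment skeletons -------------------------------------------------
  v_skel <- differentiate(ts_series(com_skel, rate))$values
  speed_skel <- sqrt(rowSums(v_skel^2))
  env_act <- 0.25 + 0.75 * speed_skel / max(speed_skel)

  seg_names <- rownames(segment_offsets)
  # stroke style: intra-limb coordination with one base phase per limb
  # chain and fixed proximal-to-distal lags; bilateral chains roughly
  # antiphase, the jitter leaving a net asymmetric component as real
  # strokes do. A player's style is a stable characteristic: the cohort
  # simulator draws it once per player and passes it in; standalone trials
  # draw it from the trial seed.
  style <- player$style
  if (is.null(style)) style <- draw_stroke_style()
  phases <- style$phases
  freq_jit <- style$freq_jit
  # racket-arm dominance: the right arm swings harder
  amp_side <- stats::setNames(rep(1, length(seg_names)), seg_names)
  amp_side[c("upper_arm_r", "forearm_r", "hand_r")] <- 1.5

  height_scale <- player$height / 1.78
  seg_delta <- lapply(seg_names, function(s) {
    a <- internal_scale * segment_pos_amp[[s]] * amp_side[[s]] * height_scale
    f <- segment_freq[[s]] * freq_jit
    ph <- phases[[s]]
    cbind(a * env_act * sin(2 * pi * f * t + ph),
          0.6 * a * env_act * sin(2 * pi * f * t + ph + pi / 3),
          0.4 * a * env_act * sin(2 * pi * f * t + ph + 2 * pi / 3))
  })
  names(seg_delta) <- seg_names

  scaled <- scale_segment_parameters(player$body_mass, player$segment_lengths,
                                     segment_parameters(player$sex))
  masses <- stats::setNames(scaled$mass, scaled$name)
  # static posture balance: head_trunk offset chosen so the mass-weighted
  # mean of the standing offsets is zero (CoM central in the body)
  other <- setdiff(seg_names, "head_trunk")
  offset_balance <- -colSums(segment_offsets[other, , drop = FALSE] *
                               masses[other]) / masses[["head_trunk"]]

  segments_skel <- lapply(seg_names, function(s) {
    off <- if (s == "head_trunk") offset_balance else segment_offsets[s, ]
    sweep(com_skel + seg_delta[[s]], 2L, off, FUN = "+")
  })
  names(segments_skel) <- seg_names

  omega <- lapply(seg_names, function(s) {
    w <- segment_omega_amp[[s]] * internal_scale
    f <- segment_freq[[s]] * freq_jit
    ph <- phases[[s]]
    cbind(w * env_act * sin(2 * pi * f * t + ph + pi / 5),
          0.7 * w * env_act * sin(2 * pi * f * t + ph + pi / 2),
          0.5 * w * env_act * sin(2 * pi * f * t + ph + 4 * pi / 5))
  })
  names(omega) <- seg_names

  ## --- pelvis proxy skeleton ---------------------------------------------
  pelvis_skel <- segments_skel[["pelvis"]] +
    cbind(0.04 * sin(2 * pi * 0.3 * t),
          0.03 * sin(2 * pi * 0.3 * t + 1),
          0.02 * sin(2 * pi * 0.3 * t + 2)) +
    pelvis_hf_amp * env_act *
      cbind(sin(2 * pi * pelvis_hf_freq * t),
            sin(2 * pi * pelvis_hf_freq * t + 2),
            0.5 * sin(2 * pi * pelvis_hf_freq * t + 4))

  ## --- ground truth from the noise-free skeleton --------------------------
  bounds <- segment_trial(
    butterworth_lowpass(ts_series(com_skel, rate), 6)$values,
    rate, config$sprint_threshold)
  vy_skel <- differentiate(ts_series(com_skel[, 2L], rate))$values
  truth <- list(start = bounds$start, transition = bounds$transition,
                end = bounds$end,
                peak_velocity = max(vy_skel[bounds$transition:bounds$end]),
                v_target = v_peak)

  ## --- observation noise ---------------------------------------------------
  add_noise <- function(p) p + matrix(stats::rnorm(length(p), 0, pos_noise_sd),
                                      nrow(p), 3L)
  trial <- structure(list(
    time = t, rate = rate,
    com = add_noise(com_skel),
    pelvis = add_noise(pelvis_skel),
    segments = stats::setNames(lapply(seg_names, function(s)
      list(com = add_noise(segments_skel[[s]]), omega = omega[[s]])), seg_names),
    pseudo_com = NULL, boxes = NULL, cameras = NULL,
    player_id = player$id, sex = player$sex, cycle = cycle_index,
    body_mass = player$body_mass, height = player$height,
    segment_lengths = player$segment_lengths,
    sprint_threshold = config$sprint_threshold, seed = seed),
    class = "motion_trial")

  ## --- camera observations -------------------------------------------------
  if (with_cameras) {
    cameras <- make_camera_rig()
    keypoints <- c(segments_skel, list(
      head_top = segments_skel[["head_trunk"]] +
        matrix(c(0, 0, 0.45), n, 3L, byrow = TRUE)))
    boxes <- do.call(rbind, lapply(seq_along(cameras), function(ci) {
      cam <- cameras[[ci]]
      px <- lapply(keypoints, function(p) project_point(cam, p))
      u <- vapply(px, function(m) m[, 1L], numeric(n))
      v <- vapply(px, function(m) m[, 2L], numeric(n))
      cx <- (apply(u, 1L, min) + apply(u, 1L, max)) / 2 +
        stats::rnorm(n, 0, px_noise_sd)
      cy <- (apply(v, 1L, min) + apply(v, 1L, max)) / 2 +
        stats::rnorm(n, 0, px_noise_sd)
      data.frame(camera_id = ci, frame = seq_len(n), cx = cx, cy = cy)
    }))
    trial$cameras <- cameras
    trial$boxes <- boxes
  }

  ## --- ground-truth section works ------------------------------------------
  if (compute_truth_works) {
    skel_trial <- trial
    skel_trial$com <- com_skel
    skel_trial$pelvis <- pelvis_skel
    for (s in seg_names) skel_trial$segments[[s]]$com <- segments_skel[[s]]
    if (with_cameras) {
      skel_trial$pseudo_com <- pseudo_com_trajectory(trial$boxes, trial$cameras,
                                                     rate, cutoff = 6)
      trial$pseudo_com <- skel_trial$pseudo_com
    }
    truth$works <- trial_work(skel_trial, bounds, scaled)
  } else if (with_cameras) {
    trial$pseudo_com <- pseudo_com_trajectory(trial$boxes, trial$cameras,
                                              rate, cutoff = 6)
  }
  class(truth) <- "ground_truth"
  list(trial = trial, truth = truth)
}

#' Simulate a cohort under the fatiguing protocol
#'
#' Draws per-player anthropometrics, baseline velocities and fatigue
#' slopes, then simulates a baseline sprint trial plus protocol cycles
#' until the exhaustion rule fires or the cycle maximum is reached. The
#' peak sprint velocity of cycle c follows the linear fatigue model driven
#' by the ground-truth cumulative total positive work of cycles 1..c —
#' including the current cycle, whose work is done before its closing
#' sprint. Because a cycle's work itself depends (weakly, through the
#' sprint) on the prescribed velocity, each cycle is generated twice: a
#' first pass without cameras evaluates the cycle's work, the velocity is
#' refined once against it, and the final trial is generated at the
#' refined value (the remaining fixed-point residual is negligible: the
#' sensitivity of cycle work to velocity times the slope is of order
#' 1e-3). With `noise_sd = 0` the velocity is therefore an exact linear
#' function of cumulative work. All randomness flows from `seed` through
#' per-player and per-trial substreams.
#'
#' @param config `protocol_config`.
#' @param fatigue `fatigue_model`.
#' @param seed integer cohort seed.
#' @param with_cameras forward to [simulate_trial()].
#' @param female_fraction fraction of female players (default 1/3, i.e. 5
#'   of 15).
#' @param ... forwarded to [simulate_trial()] (noise and amplitude
#'   settings).
#' @return list of class `cohort` with one entry per player: `player`
#'   (parameters), `baseline` (trial + truth), `cycles` (list of trial +
#'   truth per protocol cycle).
#' @export
simulate_cohort <- function(config = protocol_config(),
                            fatigue = fatigue_model(), seed = 1L,
                            with_cameras = TRUE, female_fraction = 1 / 3,
                            ...) {
  stopifnot(config$n_players >= 1)
  set.seed(seed)
  player_seeds <- sample.int(.Machine$integer.max %/% 2L, config$n_players)
  cohort <- vector("list", config$n_players)
  for (p in seq_len(config$n_players)) {
    set.seed(player_seeds[p])
    sex <- if (stats::runif(1) < female_fraction) "female" else "male"
    height <- stats::rnorm(1, if (sex == "male") 1.82 else 1.71,
                           if (sex == "male") 0.06 else 0.05)
    body_mass <- stats::rnorm(1, if (sex == "male") 77.2 else 67.2,
                              if (sex == "male") 4.7 else 10.6)
    body_mass <- max(body_mass, 40)
    player <- list(id = sprintf("P%02d", p), sex = sex, height = height,
                   body_mass = body_mass,
                   segment_lengths = default_segment_lengths(height),
                   baseline_velocity = stats::rnorm(1, fatigue$baseline_mean,
                                                    fatigue$baseline_sd),
                   slope = fatigue$slope_mean *
                     exp(stats::rnorm(1, 0, fatigue$slope_cv)),
                   style = draw_stroke_style())
    trial_seeds <- sample.int(.Machine$integer.max %/% 2L,
                              config$cycle_range[2] + 1L)
    baseline <- simulate_trial(player, 0L, player$baseline_velocity,
                               trial_seeds[1L], config,
                               with_cameras = with_cameras, ...)
    cycles <- list()
    cum_work <- 0
    w_est <- cycle_work(baseline$truth$works$groundstrokes,
                        baseline$truth$works$sprint)$w_tot_pos
    repeat {
      c_idx <- length(cycles) + 1L
      if (c_idx > config$cycle_range[2]) break
      set.seed(trial_seeds[c_idx + 1L])
      v_noise <- stats::rnorm(1, 0, fatigue$noise_sd)
      v_of <- function(w_cycle) {
        v <- player$baseline_velocity -
          player$slope * (cum_work + w_cycle) + v_noise
        max(v, 0.5 * player$baseline_velocity)
      }
      pass1 <- simulate_trial(player, c_idx, v_of(w_est),
                              trial_seeds[c_idx + 1L], config,
                              with_cameras = FALSE, ...)
      w1 <- cycle_work(pass1$truth$works$groundstrokes,
                       pass1$truth$works$sprint)$w_tot_pos
      v_target <- v_of(w1)
      cycles[[c_idx]] <- simulate_trial(player, c_idx, v_target,
                                        trial_seeds[c_idx + 1L], config,
                                        with_cameras = with_cameras, ...)
      w_est <- cycle_work(cycles[[c_idx]]$truth$works$groundstrokes,
                          cycles[[c_idx]]$truth$works$sprint)$w_tot_pos
      cum_work <- cum_work + w_est
      exhausted <- v_target <= fatigue$exhaustion_fraction * player$baseline_velocity
      if (exhausted && c_idx >= config$cycle_range[1]) break
    }
    cohort[[p]] <- list(player = player, baseline = baseline, cycles = cycles)
  }
  structure(cohort, class = "cohort", seed = seed)
}
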