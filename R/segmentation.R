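#' Detect the serve start in the vertical CoM trajectory
#'
#' The serve start is the second local minimum counting backwards from the
#' most prominent peak of the vertical CoM position (the top of the serve):
#' the countermovement dip preceding the upward drive. If only one minimum
#' precedes the peak an error is raised with a diagnostic.
#'
#' @param vertical_com scalar `ts_series` of vertical CoM position (m).
#' @return 1-based sample index of the serve start.
#' @export
detect_serve_start <- function(vertical_com) {
  peak <- most_prominent_peak(vertical_com)
  ex <- find_local_extrema(vertical_com)
  prior <- ex$minima[ex$minima < peak]
  if (length(prior) < 2L)
    stop("found ", length(prior), " local minim",
         if (length(prior) == 1L) "um" else "a",
         " before the most prominent vertical peak (index ", peak,
         "); need at least 2 to locate the serve start")
  sort(prior, decreasing = TRUE)[2L]
}

#' Detect the sprint end by forward-position threshold
#'
#' First sample at which the forward CoM coordinate (relative to the
#' baseline) reaches the threshold distance towards the net.
#'
#' @param forward_position scalar `ts_series` (m, baseline = 0).
#' @param threshold crossing distance in m (default 8.5).
#' @return 1-based sample index of the first crossing.
#' @export
detect_sprint_end <- function(forward_position, threshold = 8.5) {
  y <- forward_position$values
  hit <- which(y >= threshold)
  if (!length(hit))
    stop("incomplete sprint: forward position never reached ", threshold,
         " m (max ", format(max(y), digits = 4), " m)")
  hit[1L]
}

#' Detect the groundstroke-to-sprint transition
#'
#' The transition is the change of direction as the player leaves the last
#' groundstroke and starts the sprint: the local minimum of resultant CoM
#' speed immediately preceding the sustained rise to the sprint's peak
#' speed. Only minima that separate substantial speed maxima qualify
#' (depth at least `min_depth_frac` of the window's speed range), which
#' keeps shallow dips on the accelerating flank from masquerading as the
#' change of direction; among qualifying minima the slowest point is
#' taken, the earliest on ties.
#'
#' @param resultant_velocity scalar `ts_series` of CoM speed (m/s).
#' @param search_from index from which to search (after the last
#'   groundstroke's lateral excursion).
#' @param search_to optional upper index bound (e.g. the sprint end);
#'   defaults to the series end.
#' @param min_depth_frac qualifying prominence as a fraction of the speed
#'   range in the window.
#' @return 1-based sample index of the transition.
#' @export
detect_transition <- function(resultant_velocity, search_from = 1L,
                              search_to = NULL, min_depth_frac = 0.2) {
  v <- resultant_velocity$values
  n <- length(v)
  if (is.null(search_to)) search_to <- n
  if (search_from < 1L || search_to > n || search_from >= search_to)
    stop("invalid search window [", search_from, ", ", search_to, "]")
  win <- v[search_from:search_to]
  peak_rel <- length(win) + 1L - which.max(rev(win))  # last max under ties
  ex <- find_local_extrema(win)
  minima_rel <- ex$minima[ex$minima < peak_rel]
  if (!length(minima_rel))
    stop("no local speed minimum found before the sprint peak in the search window")
  amp <- max(win) - min(win)
  depth <- vapply(minima_rel, function(m) {
    min(max(win[seq_len(m)]), max(win[m:peak_rel])) - win[m]
  }, numeric(1))
  qual <- minima_rel[depth >= min_depth_frac * amp]
  if (!length(qual))
    stop("no local speed minimum found before the sprint peak in the search window")
  qual[which.min(win[qual])] + search_from - 1L
}

#' Peak forward CoM velocity over the sprint
#'
#' Maximum of the forward (towards-the-net) velocity component between the
#' transition and the sprint end; the trial's measure of acute
#' neuromuscular fatigue when compared to baseline.
#'
#' @param com_velocity_forward scalar `ts_series` (m/s).
#' @param boundaries a `trial_boundaries` object.
#' @return peak forward velocity (m/s).
#' @export
peak_forward_velocity <- function(com_velocity_forward, boundaries) {
  v <- com_velocity_forward$values
  max(v[boundaries$transition:boundaries$end])
}

#' Trial boundaries constructor
#'
#' @param start serve-start sample index.
#' @param transition groundstrokes-to-sprint change-of-direction index.
#' @param end sprint-end index (CoM 8.5 m forward of the baseline).
#' @param n_total trial length in samples (for validation).
#' @return object of class `trial_boundaries`.
#' @export
trial_boundaries <- function(start, transition, end, n_total) {
  if (!(start < transition && transition < end))
    stop("boundaries must be ordered: start < transition < end (got ",
         start, ", ", transition, ", ", end, ")")
  if (start < 1L || end > n_total)
    stop("boundaries outside trial length ", n_total)
  structure(list(start = as.integer(start), transition = as.integer(transition),
                 end = as.integer(end)),
            class = "trial_boundaries")
}

#' Segment a motion trial into groundstroke and sprint sections
#'
#' Applies the three event detectors to a (filtered) CoM trajectory:
#' serve start from the vertical position, sprint end from the forward
#' position, and the transition from the resultant speed, searched between
#' the serve start and the sprint end after the last lateral excursion.
#'
#' @param com n-by-3 filtered CoM position matrix (court frame: x along the
#'   baseline, y forward towards the net, z up; origin on the baseline).
#' @param rate sampling rate (Hz).
#' @param sprint_threshold forward distance defining the sprint end (m).
#' @return `trial_boundaries`.
#' @export
segment_trial <- function(com, rate, sprint_threshold = 8.5) {
  z <- ts_series(com[, 3L], rate)
  y <- ts_series(com[, 2L], rate)
  start <- detect_serve_start(z)
  end <- detect_sprint_end(y, sprint_threshold)
  v <- differentiate(ts_series(com, rate))$values
  # the change of direction is a slow (~1 Hz) feature; an extra zero-lag
  # smoothing pass on the speed trace keeps residual observation noise
  # from shifting the argmin across the flat valley floor
  speed <- butterworth_lowpass(ts_series(sqrt(rowSums(v^2)), rate),
                               cutoff = 3)
  # skip past the groundstroke shuttling: search from the last large lateral
  # excursion (|x| within 25% of its maximum over [start, end]) onwards
  x <- com[start:end, 1L]
  lat <- which(abs(x) >= 0.75 * max(abs(x)))
  search_from <- start + (if (length(lat)) lat[length(lat)] else 1L) - 1L
  if (search_from >= end) search_from <- start
  transition <- detect_transition(speed, search_from, end)
  trial_boundaries(start, transition, end, nrow(com))
}

#' Work summaries for one trial
#'
#' Computes external (CoM), internal (limb) and proxy work for the
#' groundstroke section `[start, transition]` and the sprint section
#' `[transition, end]` of a segmented trial. Proxy work fields are `NA`
#' when the corresponding proxy trajectory is absent.
#'
#' @param trial a `motion_trial` (see [simulate_trial()] / [read_trial()]).
#' @param boundaries `trial_boundaries` for the trial.
#' @param scaled `scaled_segments` table for the subject.
#' @param cutoff low-pass cut-off applied to positions before energy
#'   computation (Hz).
#' @param g gravitational acceleration (m/s^2).
#' @return list with `groundstrokes` and `sprint` `work_summary` rows.
#' @export
trial_work <- function(trial, boundaries, scaled, cutoff = 6, g = 9.81) {
  rate <- trial$rate
  body_mass <- sum(scaled$mass)
  filt <- function(p) butterworth_lowpass(ts_series(p, rate), cutoff)$values

  com_f <- filt(trial$com)
  e_com <- com_energy(com_f, rate, body_mass, g)

  # limb kinetic energies relative to the CoM
  com_v <- differentiate(ts_series(com_f, rate))$values
  kin <- lapply(trial$segments, function(s) {
    v_seg <- differentiate(ts_series(filt(s$com), rate))$values
    list(v_rel = v_seg - com_v, omega = s$omega)
  })
  e_limbs <- limb_energies(kin, scaled, rate)

  section_summary <- function(a, b, section) {
    w_ext <- positive_negative_work(e_com, a, b)
    w_int <- Reduce(`+`, lapply(e_limbs, positive_negative_work, start = a, end = b))
    proxy_w <- function(p) {
      if (is.null(p)) return(c(NA_real_, NA_real_))
      positive_negative_work(com_energy(filt(p), rate, body_mass, g), a, b)
    }
    work_summary(w_ext, w_int,
                 w_pelvis = proxy_w(trial$pelvis),
                 w_bb = proxy_w(trial$pseudo_com),
                 section = section)
  }
  list(
    groundstrokes = section_summary(boundaries$start, boundaries$transition,
                                    "groundstrokes"),
    sprint = section_summary(boundaries$transition, boundaries$end, "sprint")
  )
}

#' Build a per-player cycle series
#'
#' For an ordered set of processed cycles, assembles the per-cycle records
#' behind the fatigue analysis: peak sprint velocity, its percentage of the
#' player's overall maximum (baseline included), and cumulative positive
#' work per variant.
#'
#' @param peak_velocities per-cycle peak forward sprint velocities (m/s),
#'   in protocol order.
#' @param cycle_summaries list of `work_summary` rows with section
#'   `"cycle"`, same order.
#' @param baseline_peak baseline sprint peak velocity (m/s).
#' @param player_id identifier copied into the output.
#' @return data.frame of class `player_series`: one row per cycle with
#'   `peak_velocity`, `peak_velocity_pct` and `cum_*` columns for the
#'   positive-work variants (total, external, internal, pelvis, bb).
#' @export
build_player_series <- function(peak_velocities, cycle_summaries,
                                baseline_peak, player_id = NA_character_) {
  n <- length(peak_velocities)
  if (n == 0L) stop("empty trial list: no cycles to assemble")
  if (length(cycle_summaries) != n)
    stop("peak_velocities and cycle_summaries differ in length")
  works <- do.call(rbind, lapply(cycle_summaries, function(s) {
    if (s$section != "cycle") stop("cycle summaries must have section 'cycle'")
    as.data.frame(s)[work_fields]
  }))
  vmax <- max(c(baseline_peak, peak_velocities))
  out <- data.frame(
    player_id = player_id,
    cycle = seq_len(n),
    peak_velocity = peak_velocities,
    peak_velocity_pct = 100 * peak_velocities / vmax,
    cum_tot = cumsum(works$w_tot_pos),
    cum_ext = cumsum(works$w_ext_pos),
    cum_int = cumsum(works$w_int_pos),
    cum_pelvis = cumsum(works$w_pelvis_pos),
    cum_bb = cumsum(works$w_bb_pos),
    cum_tot_neg = cumsum(works$w_tot_neg),
    cum_ext_neg = cumsum(works$w_ext_neg),
    stringsAsFactors = FALSE
  )
  class(out) <- c("player_series", "data.frame")
  out
}
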