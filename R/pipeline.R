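#' Process one motion trial into work summaries
#'
#' Runs the single-trial pipeline: reconstruct the bounding-box pseudo-CoM
#' if camera observations are present, low-pass filter, segment into
#' groundstroke and sprint sections, and compute external, internal and
#' proxy work for each section plus the protocol-cycle aggregate
#' (3 x groundstrokes + sprint). Also extracts the peak forward sprint
#' velocity.
#'
#' @param trial `motion_trial`.
#' @param cutoff low-pass cut-off (Hz).
#' @param table `segment_parameters` table; defaults to the shipped table
#'   for the trial's sex.
#' @param g gravitational acceleration (m/s^2).
#' @return list with `boundaries`, `works` (`groundstrokes`, `sprint`),
#'   `cycle` (`work_summary`), `peak_velocity` (m/s).
#' @export
process_trial <- function(trial, cutoff = 6, table = NULL, g = 9.81) {
  if (is.null(table))
    table <- segment_parameters(if (identical(trial$sex, "female")) "female" else "male")
  scaled <- scale_segment_parameters(trial$body_mass, trial$segment_lengths, table)
  if (is.null(trial$pseudo_com) && !is.null(trial$boxes))
    trial$pseudo_com <- pseudo_com_trajectory(trial$boxes, trial$cameras,
                                              trial$rate, cutoff)
  com_f <- butterworth_lowpass(ts_series(trial$com, trial$rate), cutoff)$values
  thr <- if (is.null(trial$sprint_threshold)) 8.5 else trial$sprint_threshold
  boundaries <- segment_trial(com_f, trial$rate, thr)
  works <- trial_work(trial, boundaries, scaled, cutoff = cutoff, g = g)
  vy <- differentiate(ts_series(com_f[, 2L], trial$rate))
  list(boundaries = boundaries, works = works,
       cycle = cycle_work(works$groundstrokes, works$sprint),
       peak_velocity = peak_forward_velocity(vy, boundaries))
}

#' Analyse a simulated or loaded cohort
#'
#' Processes every trial of every player, assembles per-player cycle
#' series, and computes the fatigue-vs-work statistics: per-player Pearson
#' correlations and their random-effects pooled value (with 95% CI and
#' magnitude label) for each work variant, plus repeated-measures
#' Bland-Altman agreement between CoM external work and each proxy at the
#' cycle level. Trials that fail segmentation are excluded with a named
#' reason; the run fails if more than `max_excluded_fraction` of trials
#' are excluded.
#'
#' @param cohort `cohort` from [simulate_cohort()] (or the same structure
#'   built from loaded trials).
#' @param variants work variants to correlate (cumulative positive work).
#' @param include_negative also report negative-work correlations
#'   (near-duplicates of the positive ones; off by default).
#' @param max_excluded_fraction failure threshold for excluded trials.
#' @return list of class `cohort_analysis` with `player_series`,
#'   `correlations` (per variant: per-player table + `pooled_correlation`),
#'   `agreement` (`pelvis`, `bb`), `cycle_table`, `excluded`.
#' @export
analyze_cohort <- function(cohort, variants = c("tot", "ext", "pelvis", "bb"),
                           include_negative = FALSE,
                           max_excluded_fraction = 0.2) {
  if (include_negative) variants <- c(variants, "tot_neg", "ext_neg")
  excluded <- data.frame(player_id = character(), cycle = integer(),
                         reason = character(), stringsAsFactors = FALSE)
  n_trials <- 0L
  series_list <- list()
  cycle_rows <- list()
  for (entry in cohort) {
    pid <- entry$player$id
    base <- tryCatch(process_trial(entry$baseline$trial), error = function(e) e)
    n_trials <- n_trials + 1L
    if (inherits(base, "error")) {
      excluded <- rbind(excluded, data.frame(player_id = pid, cycle = 0L,
                                             reason = conditionMessage(base)))
      next
    }
    peaks <- numeric(0)
    summaries <- list()
    for (cy in entry$cycles) {
      n_trials <- n_trials + 1L
      res <- tryCatch(process_trial(cy$trial), error = function(e) e)
      if (inherits(res, "error")) {
        excluded <- rbind(excluded, data.frame(
          player_id = pid, cycle = cy$trial$cycle,
          reason = conditionMessage(res)))
        next
      }
      peaks <- c(peaks, res$peak_velocity)
      summaries <- c(summaries, list(res$cycle))
      row <- as.data.frame(res$cycle)
      row$player_id <- pid
      row$cycle <- cy$trial$cycle
      row$peak_velocity <- res$peak_velocity
      cycle_rows <- c(cycle_rows, list(row))
    }
    if (length(peaks) == 0L) next
    series_list[[pid]] <- build_player_series(peaks, summaries,
                                              base$peak_velocity, pid)
  }
  n_excl <- nrow(excluded)
  if (n_excl > max_excluded_fraction * n_trials)
    stop("more than ", round(100 * max_excluded_fraction),
         "% of trials failed segmentation (", n_excl, " of ", n_trials, ")")

  correlations <- lapply(stats::setNames(variants, variants), function(v) {
    per <- lapply(series_list, function(s) {
      if (nrow(s) < 4L) return(NULL)  # Fisher-z weight needs n > 3
      pc <- tryCatch(player_correlation(s, v), error = function(e) NULL)
      if (is.null(pc)) NULL
      else data.frame(player_id = s$player_id[1L], r = pc$r, n = pc$n)
    })
    per <- do.call(rbind, per[!vapply(per, is.null, logical(1))])
    pooled <- pooled_correlation(per$r, per$n)
    list(per_player = per, pooled = pooled,
         label = magnitude_label(pooled$r_pooled))
  })

  cycle_table <- do.call(rbind, cycle_rows)
  agreement <- list()
  for (proxy in c("pelvis", "bb")) {
    col <- paste0("w_", proxy, "_pos")
    ok <- !is.na(cycle_table[[col]])
    agreement[[proxy]] <- if (sum(ok) >= 2L)
      rm_bland_altman(cycle_table$w_ext_pos[ok], cycle_table[[col]][ok],
                      cycle_table$player_id[ok])
    else NULL
  }
  structure(list(player_series = series_list, correlations = correlations,
                 agreement = agreement, cycle_table = cycle_table,
                 excluded = excluded),
            class = "cohort_analysis")
}

#' Run the full simulate-process-analyse pipeline
#'
#' Simulates a cohort, analyses it, and writes the output set: per-player
#' cycle CSVs, a cycle-level work table, a JSON statistics report and a
#' run manifest. Re-running with the same seed and configuration
#' reproduces all outputs byte-identically.
#'
#' @param out_dir output directory (created if absent).
#' @param config `protocol_config`.
#' @param fatigue `fatigue_model`.
#' @param seed integer cohort seed.
#' @param with_cameras simulate camera/bounding-box observations (enables
#'   the bb variant).
#' @param ... forwarded to [simulate_cohort()].
#' @return (invisibly) list with `analysis`, `manifest`, `paths`.
#' @export
run_pipeline <- function(out_dir, config = protocol_config(),
                         fatigue = fatigue_model(), seed = 1L,
                         with_cameras = TRUE, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(config, fatigue, seed, with_cameras = with_cameras, ...)
  variants <- if (with_cameras) c("tot", "ext", "pelvis", "bb")
              else c("tot", "ext", "pelvis")
  analysis <- analyze_cohort(cohort, variants = variants)

  paths <- list(
    player_series = file.path(out_dir, "player_series.csv"),
    cycle_table = file.path(out_dir, "cycle_work.csv"),
    report = file.path(out_dir, "report.json"),
    manifest = file.path(out_dir, "manifest.json"))

  ps <- do.call(rbind, analysis$player_series)
  write_csv_plain(ps, paths$player_series)
  write_csv_plain(analysis$cycle_table, paths$cycle_table)

  report <- list(
    pooled_correlations = lapply(analysis$correlations, function(cc)
      list(r = cc$pooled$r_pooled, ci_low = cc$pooled$ci_low,
           ci_high = cc$pooled$ci_high, tau2 = cc$pooled$tau2,
           k = cc$pooled$k, label = cc$label)),
    per_player_r = lapply(analysis$correlations, function(cc) cc$per_player),
    agreement = lapply(analysis$agreement, function(a)
      if (is.null(a)) NULL else unclass(a)),
    n_excluded = nrow(analysis$excluded))
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("tenniswork")),
    seed = seed,
    config = unclass(config),
    fatigue = unclass(fatigue),
    with_cameras = with_cameras,
    n_players = length(cohort),
    n_cycles = vapply(cohort, function(p) length(p$cycles), integer(1)),
    rows = list(player_series = nrow(ps),
                cycle_table = nrow(analysis$cycle_table)),
    # names only: the manifest stays byte-identical wherever the run lands
    outputs = lapply(paths[c("player_series", "cycle_table", "report")],
                     basename))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(analysis = analysis, manifest = manifest, paths = paths))
}

# deterministic CSV writer (fixed significant digits, no row names)
write_csv_plain <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 12, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write a motion trial to a trajectory CSV
#'
#' Plain-text tabular format: comment header lines (`# key: value`)
#' carrying the sampling rate and subject metadata, then one row per
#' sample with `time`, CoM, pelvis and per-segment position and
#' angular-velocity columns (metres, seconds, rad/s). Camera and
#' bounding-box observations are not part of this file.
#'
#' @param trial `motion_trial`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  seg_cols <- lapply(names(trial$segments), function(s) {
    out <- cbind(trial$segments[[s]]$com, trial$segments[[s]]$omega)
    colnames(out) <- c(paste0("seg_", s, "_", c("x", "y", "z")),
                       paste0("omg_", s, "_", c("x", "y", "z")))
    out
  })
  tab <- cbind(time = trial$time,
               com_x = trial$com[, 1L], com_y = trial$com[, 2L],
               com_z = trial$com[, 3L],
               pelvis_x = trial$pelvis[, 1L], pelvis_y = trial$pelvis[, 2L],
               pelvis_z = trial$pelvis[, 3L],
               do.call(cbind, seg_cols))
  sl <- paste(names(trial$segment_lengths),
              formatC(trial$segment_lengths, digits = 12, format = "g"),
              sep = "=", collapse = ";")
  hdr <- c("# tenniswork motion trial (units: m, s, rad/s)",
           paste0("# rate: ", formatC(trial$rate, digits = 12, format = "g")),
           paste0("# player_id: ", trial$player_id),
           paste0("# sex: ", trial$sex),
           paste0("# cycle: ", trial$cycle),
           paste0("# body_mass: ", formatC(trial$body_mass, digits = 12, format = "g")),
           paste0("# height: ", formatC(trial$height, digits = 12, format = "g")),
           paste0("# sprint_threshold: ",
                  formatC(trial$sprint_threshold, digits = 12, format = "g")),
           paste0("# segment_lengths: ", sl))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(tab), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a motion trial from a trajectory CSV
#'
#' Inverse of [write_trial()]. Unexpected extra columns are preserved (as
#' `trial$extra`) with a warning; a non-monotone time column or missing
#' required columns raise a format error.
#'
#' @param path file written by [write_trial()] (or compatible).
#' @return `motion_trial`.
#' @export
read_trial <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([a-z_]+):\\s*(.*)$", h))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- m[3L]
  }
  tab <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]),
                         stringsAsFactors = FALSE)
  if (!"time" %in% names(tab)) stop("trajectory file lacks a 'time' column")
  if (is.unsorted(tab$time, strictly = TRUE))
    stop("non-monotone time column in ", path)
  need <- c(paste0("com_", c("x", "y", "z")), paste0("pelvis_", c("x", "y", "z")))
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("trajectory file lacks column(s): ", paste(miss, collapse = ", "))
  seg_pos_cols <- grep("^seg_.*_[xyz]$", names(tab), value = TRUE)
  seg_names <- unique(sub("^seg_(.*)_[xyz]$", "\\1", seg_pos_cols))
  segments <- lapply(seg_names, function(s) {
    list(com = as.matrix(tab[paste0("seg_", s, "_", c("x", "y", "z"))]),
         omega = as.matrix(tab[paste0("omg_", s, "_", c("x", "y", "z"))]))
  })
  names(segments) <- seg_names
  known <- c("time", need, seg_pos_cols,
             grep("^omg_", names(tab), value = TRUE))
  extra <- setdiff(names(tab), known)
  if (length(extra))
    warning("unexpected extra column(s) preserved: ", paste(extra, collapse = ", "))
  sl <- NULL
  if (!is.null(meta$segment_lengths)) {
    kv <- strsplit(strsplit(meta$segment_lengths, ";")[[1L]], "=")
    sl <- stats::setNames(vapply(kv, function(p) as.numeric(p[2L]), numeric(1)),
                          vapply(kv, `[`, character(1), 1L))
  }
  rate <- if (!is.null(meta$rate)) as.numeric(meta$rate)
          else 1 / stats::median(diff(tab$time))
  structure(list(
    time = tab$time, rate = rate,
    com = as.matrix(tab[paste0("com_", c("x", "y", "z"))]),
    pelvis = as.matrix(tab[paste0("pelvis_", c("x", "y", "z"))]),
    segments = segments, pseudo_com = NULL, boxes = NULL, cameras = NULL,
    player_id = meta$player_id, sex = meta$sex,
    cycle = if (is.null(meta$cycle)) NA_integer_ else as.integer(meta$cycle),
    body_mass = as.numeric(meta$body_mass),
    height = if (is.null(meta$height)) NA_real_ else as.numeric(meta$height),
    segment_lengths = sl,
    sprint_threshold = if (is.null(meta$sprint_threshold)) 8.5
                       else as.numeric(meta$sprint_threshold),
    extra = if (length(extra)) tab[extra] else NULL),
    class = "motion_trial")
}

#' Write camera models to JSON
#'
#' @param cameras list of `camera_model`s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cameras <- function(cameras, path) {
  jsonlite::write_json(lapply(cameras, function(cm)
    list(id = cm$id, focal = cm$focal, principal_point = cm$principal_point,
         rotation = cm$rotation, centre = cm$centre,
         image_size = cm$image_size)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read camera models from JSON
#'
#' @param path file written by [write_cameras()].
#' @return list of `camera_model`s.
#' @export
read_cameras <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(cm)
    camera_model(unlist(cm$focal), unlist(cm$principal_point),
                 matrix(unlist(cm$rotation), 3L, 3L, byrow = TRUE),
                 unlist(cm$centre), unlist(cm$image_size), cm$id))
}
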