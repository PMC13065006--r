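#' Load a body-segment parameter table
#'
#' Reads one of the shipped segment inertial-parameter tables (de Leva-style
#' fractions for a 14-segment body: merged head+trunk, pelvis, and bilateral
#' thigh, shank, foot, upper arm, forearm and hand), or a user-supplied CSV
#' with the same columns. Each segment is tagged to one of the three limb
#' groups used for internal work: `legs`, `arms` or `trunk`.
#'
#' @param sex `"male"` or `"female"` selects a shipped table; ignored when
#'   `path` is given.
#' @param path optional path to a CSV with columns `name`, `mass_fraction`,
#'   `com_fraction`, `gyration_x/y/z`, `limb_group`.
#' @return data.frame of class `segment_parameters`.
#' @export
segment_parameters <- function(sex = c("male", "female"), path = NULL) {
  if (is.null(path)) {
    sex <- match.arg(sex)
    path <- system.file("extdata",
                        sprintf("segment_parameters_%s.csv", sex),
                        package = "tenniswork")
  }
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("name", "mass_fraction", "com_fraction",
                "gyration_x", "gyration_y", "gyration_z", "limb_group")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("segment parameter table lacks columns: ", paste(missing_cols, collapse = ", "))
  validate_segment_parameters(tab)
  class(tab) <- c("segment_parameters", "data.frame")
  tab
}

validate_segment_parameters <- function(tab) {
  if (anyDuplicated(tab$name)) stop("duplicate segment names in parameter table")
  fr <- c(tab$mass_fraction, tab$com_fraction,
          tab$gyration_x, tab$gyration_y, tab$gyration_z)
  if (any(fr <= 0 | fr >= 1)) stop("all fractions must lie in (0, 1)")
  if (abs(sum(tab$mass_fraction) - 1) > 1e-6)
    stop("segment mass fractions must sum to 1 (got ",
         format(sum(tab$mass_fraction), digits = 10), ")")
  bad <- setdiff(unique(tab$limb_group), c("legs", "arms", "trunk"))
  if (length(bad))
    stop("unknown limb_group(s): ", paste(bad, collapse = ", "))
  invisible(tab)
}

#' Scale segment parameters to a subject
#'
#' Converts dimensionless de Leva-style fractions into subject-specific
#' segment masses, CoM offsets and principal moments of inertia:
#' `mass = body_mass * mass_fraction` and
#' `I_k = mass * (gyration_k * length)^2`.
#'
#' @param body_mass subject body mass in kg (> 0).
#' @param segment_lengths named numeric vector of segment lengths in m, one
#'   entry per table row.
#' @param table a `segment_parameters` table (default: shipped male table).
#' @return data.frame of class `scaled_segments` with columns `name`,
#'   `mass` (kg), `length` (m), `com_offset` (m), `inertia_x/y/z` (kg m^2),
#'   `limb_group`.
#' @export
scale_segment_parameters <- function(body_mass, segment_lengths,
                                     table = segment_parameters()) {
  if (!is.numeric(body_mass) || length(body_mass) != 1L || body_mass <= 0)
    stop("body_mass must be a single positive number (kg)")
  missing_len <- setdiff(table$name, names(segment_lengths))
  if (length(missing_len))
    stop("missing segment length(s) for: ", paste(missing_len, collapse = ", "))
  len <- as.numeric(segment_lengths[table$name])
  if (any(len <= 0)) {
    bad <- table$name[len <= 0]
    stop("non-positive segment length(s) for: ", paste(bad, collapse = ", "))
  }
  mass <- body_mass * table$mass_fraction
  out <- data.frame(
    name = table$name,
    mass = mass,
    length = len,
    com_offset = table$com_fraction * len,
    inertia_x = mass * (table$gyration_x * len)^2,
    inertia_y = mass * (table$gyration_y * len)^2,
    inertia_z = mass * (table$gyration_z * len)^2,
    limb_group = table$limb_group,
    stringsAsFactors = FALSE
  )
  stopifnot(abs(sum(out$mass) - body_mass) < 1e-9)
  class(out) <- c("scaled_segments", "data.frame")
  out
}

#' Whole-body centre of mass from segment kinematics
#'
#' Mass-weighted mean of the per-segment CoM trajectories:
#' `CoM(t) = sum_i m_i p_i(t) / sum_i m_i`.
#'
#' @param segment_com_positions named list of n-by-3 matrices (m), one per
#'   segment, all on the same time base.
#' @param scaled a `scaled_segments` table covering every listed segment.
#' @return n-by-3 matrix of CoM positions (m).
#' @export
compute_whole_body_com <- function(segment_com_positions, scaled) {
  segs <- names(segment_com_positions)
  if (is.null(segs)) stop("segment_com_positions must be a named list")
  unknown <- setdiff(segs, scaled$name)
  if (length(unknown))
    stop("segments without scaled parameters: ", paste(unknown, collapse = ", "))
  n <- nrow(segment_com_positions[[1L]])
  acc <- matrix(0, n, 3L)
  total_mass <- 0
  for (s in segs) {
    p <- segment_com_positions[[s]]
    if (!is.matrix(p) || ncol(p) != 3L || nrow(p) != n)
      stop("segment series for '", s, "' does not match the shared time base")
    m <- scaled$mass[match(s, scaled$name)]
    acc <- acc + m * p
    total_mass <- total_mass + m
  }
  acc / total_mass
}
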