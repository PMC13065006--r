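#' Energy series constructor
#'
#' Mass-normalised mechanical energy over time (J/kg): kinetic, potential
#' and their sum. For limb energies (segment motion relative to the CoM)
#' the potential component is identically zero.
#'
#' @param ke kinetic energy per sample (J/kg, non-negative).
#' @param pe potential energy per sample (J/kg).
#' @param rate sampling rate (Hz).
#' @param subject_mass body mass (kg); multiply by it for absolute Joules.
#' @return object of class `energy_series` with fields `ke`, `pe`, `total`.
#' @export
energy_series <- function(ke, pe, rate, subject_mass = NA_real_) {
  if (length(ke) != length(pe)) stop("ke and pe must be the same length")
  if (any(ke < -1e-12)) stop("kinetic energy must be non-negative")
  structure(list(ke = ke, pe = pe, total = ke + pe,
                 rate = rate, subject_mass = subject_mass),
            class = "energy_series")
}

#' Centre-of-mass (or proxy point) mechanical energy
#'
#' Kinetic energy `0.5 |v|^2` (velocity by central differences of the
#' filtered position) plus potential energy `g h`, per unit body mass, with
#' height taken relative to the first sample. Used identically for the true
#' CoM and for the pelvis / bounding-box proxy points.
#'
#' @param position n-by-3 position matrix (m), already low-pass filtered.
#' @param rate sampling rate (Hz).
#' @param subject_mass body mass (kg), carried for unit conversion.
#' @param g gravitational acceleration (m/s^2), default 9.81.
#' @return `energy_series` (J/kg).
#' @export
com_energy <- function(position, rate, subject_mass = NA_real_, g = 9.81) {
  if (!is.matrix(position) || ncol(position) != 3L)
    stop("position must be an n-by-3 matrix")
  if (nrow(position) < 3L) stop("need at least 3 samples")
  if (g <= 0) stop("g must be positive")
  v <- differentiate(ts_series(position, rate))$values
  ke <- 0.5 * rowSums(v^2)
  pe <- g * (position[, 3L] - position[1L, 3L])
  energy_series(ke, pe, rate, subject_mass)
}

#' Limb kinetic energies relative to the whole-body CoM
#'
#' Per segment: translational kinetic energy of the segment CoM relative to
#' the whole-body CoM plus rotational energy about the segment's principal
#' axes, `0.5 m |v_rel|^2 + 0.5 w' I w`, normalised by body mass. Segment
#' energies are summed within the three limb groups (bilateral legs,
#' bilateral arms, trunk).
#'
#' @param segment_kinematics named list, one entry per segment, each a list
#'   with `v_rel` (n-by-3 velocity relative to the CoM, m/s) and `omega`
#'   (n-by-3 angular velocity about the principal axes, rad/s).
#' @param scaled a `scaled_segments` table; every segment must carry a limb
#'   group.
#' @param rate sampling rate (Hz).
#' @return named list of `energy_series` (J/kg), one per limb group present.
#' @export
limb_energies <- function(segment_kinematics, scaled, rate) {
  segs <- names(segment_kinematics)
  idx <- match(segs, scaled$name)
  if (anyNA(idx))
    stop("segments without scaled parameters: ",
         paste(segs[is.na(idx)], collapse = ", "))
  body_mass <- sum(scaled$mass)
  n <- nrow(segment_kinematics[[1L]]$v_rel)
  groups <- unique(scaled$limb_group[idx])
  ke_group <- stats::setNames(rep(list(numeric(n)), length(groups)), groups)
  for (j in seq_along(segs)) {
    k <- segment_kinematics[[j]]
    if (nrow(k$v_rel) != n || nrow(k$omega) != n)
      stop("segment series for '", segs[j], "' does not match the shared time base")
    i <- idx[j]
    grp <- scaled$limb_group[i]
    if (is.na(grp) || !nzchar(grp)) stop("segment '", segs[j], "' has no limb_group")
    trans <- 0.5 * scaled$mass[i] * rowSums(k$v_rel^2)
    inertia <- c(scaled$inertia_x[i], scaled$inertia_y[i], scaled$inertia_z[i])
    rot <- 0.5 * (k$omega^2 %*% inertia)[, 1L]
    ke_group[[grp]] <- ke_group[[grp]] + (trans + rot) / body_mass
  }
  lapply(ke_group, function(ke)
    energy_series(ke, rep(0, n), rate, body_mass))
}

#' Positive and negative work from an energy series
#'
#' Sums the increments and decrements of the total energy series over a
#' sample range: `w_pos = sum max(dE, 0)`, `w_neg = sum min(dE, 0)`. The
#' telescoping identity `w_pos + w_neg = E[end] - E[start]` holds exactly.
#'
#' @param energy `energy_series` (or numeric vector of total energy, J/kg).
#' @param start,end 1-based sample indices, `start < end`.
#' @return named numeric vector `c(w_pos =, w_neg =)` (J/kg).
#' @export
positive_negative_work <- function(energy, start = 1L,
                                   end = if (is.numeric(energy)) length(energy)
                                         else length(energy$total)) {
  e <- if (inherits(energy, "energy_series")) energy$total else as.numeric(energy)
  n <- length(e)
  if (start < 1L || end > n || start >= end)
    stop("invalid index range [", start, ", ", end, "] for series of length ", n)
  de <- diff(e[start:end])
  c(w_pos = sum(de[de > 0]), w_neg = sum(de[de < 0]))
}

#' Work summary constructor
#'
#' Positive/negative external, internal, total and proxy work for one trial
#' section (all J/kg). `w_tot_* = w_ext_* + w_int_*` is enforced on
#' construction. Proxy fields may be `NA` when a proxy trajectory is absent.
#'
#' @param w_ext,w_int,w_pelvis,w_bb length-2 numeric vectors
#'   `c(w_pos, w_neg)`.
#' @param section one of `"groundstrokes"`, `"sprint"`, `"cycle"`.
#' @return one-row data.frame of class `work_summary`.
#' @export
work_summary <- function(w_ext, w_int, w_pelvis = c(NA_real_, NA_real_),
                         w_bb = c(NA_real_, NA_real_),
                         section = c("groundstrokes", "sprint", "cycle")) {
  section <- match.arg(section)
  out <- data.frame(
    section = section,
    w_ext_pos = w_ext[[1L]], w_ext_neg = w_ext[[2L]],
    w_int_pos = w_int[[1L]], w_int_neg = w_int[[2L]],
    w_tot_pos = w_ext[[1L]] + w_int[[1L]],
    w_tot_neg = w_ext[[2L]] + w_int[[2L]],
    w_pelvis_pos = w_pelvis[[1L]], w_pelvis_neg = w_pelvis[[2L]],
    w_bb_pos = w_bb[[1L]], w_bb_neg = w_bb[[2L]],
    stringsAsFactors = FALSE
  )
  pos <- unlist(out[grep("_pos$", names(out))])
  neg <- unlist(out[grep("_neg$", names(out))])
  if (any(pos < -1e-12, na.rm = TRUE) || any(neg > 1e-12, na.rm = TRUE))
    stop("positive work must be >= 0 and negative work <= 0")
  class(out) <- c("work_summary", "data.frame")
  out
}

work_fields <- c("w_ext_pos", "w_ext_neg", "w_int_pos", "w_int_neg",
                 "w_tot_pos", "w_tot_neg", "w_pelvis_pos", "w_pelvis_neg",
                 "w_bb_pos", "w_bb_neg")

#' Combine section work into a protocol-cycle total
#'
#' Only the third of a cycle's three identical sets is captured, so cycle
#' work is taken as three times the groundstroke-section work plus the
#' sprint work, field by field.
#'
#' @param groundstroke `work_summary` with section `"groundstrokes"`.
#' @param sprint `work_summary` with section `"sprint"`.
#' @return `work_summary` with section `"cycle"`.
#' @export
cycle_work <- function(groundstroke, sprint) {
  if (groundstroke$section != "groundstrokes" || sprint$section != "sprint")
    stop("expected sections 'groundstrokes' and 'sprint', got '",
         groundstroke$section, "' and '", sprint$section, "'")
  out <- groundstroke
  out[work_fields] <- 3 * groundstroke[work_fields] + sprint[work_fields]
  out$section <- "cycle"
  out
}
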