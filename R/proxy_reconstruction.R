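#' Pinhole camera model
#'
#' Ideal (distortion-free) pinhole camera. Extrinsics map world coordinates
#' (m) into the camera frame: `x_cam = R %*% (x_world - centre)`.
#'
#' @param focal length-2 focal lengths in px (fx, fy).
#' @param principal_point length-2 principal point in px (cx, cy).
#' @param rotation 3x3 world-to-camera rotation (orthonormal, det +1).
#' @param centre camera centre in world coordinates (m).
#' @param image_size length-2 image size in px (width, height).
#' @param id camera identifier.
#' @return object of class `camera_model`.
#' @export
camera_model <- function(focal, principal_point, rotation, centre,
                         image_size = c(2560, 2048), id = NA_character_) {
  rotation <- as.matrix(rotation)
  if (any(focal <= 0)) stop("focal lengths must be positive")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(focal = as.numeric(focal),
                 principal_point = as.numeric(principal_point),
                 rotation = rotation, centre = as.numeric(centre),
                 image_size = as.numeric(image_size), id = id),
            class = "camera_model")
}

#' Camera looking at a target point
#'
#' Convenience constructor: builds the world-to-camera rotation so the
#' optical axis points from `centre` to `target`, with the image x axis
#' horizontal.
#'
#' @inheritParams camera_model
#' @param target world point on the optical axis (m).
#' @return `camera_model`.
#' @export
camera_looking_at <- function(centre, target, focal = c(2000, 2000),
                              principal_point = c(1280, 1024),
                              image_size = c(2560, 2048), id = NA_character_) {
  zc <- target - centre
  zc <- zc / sqrt(sum(zc^2))
  up <- c(0, 0, 1)
  xc <- c(zc[2] * up[3] - zc[3] * up[2],
          zc[3] * up[1] - zc[1] * up[3],
          zc[1] * up[2] - zc[2] * up[1])  # zc x up: horizontal image x
  nx <- sqrt(sum(xc^2))
  if (nx < 1e-12) stop("camera optical axis is vertical; choose another target")
  xc <- xc / nx
  yc <- c(zc[2] * xc[3] - zc[3] * xc[2],
          zc[3] * xc[1] - zc[1] * xc[3],
          zc[1] * xc[2] - zc[2] * xc[1])
  camera_model(focal, principal_point, rbind(xc, yc, zc), centre, image_size, id)
}

#' Project a world point into a camera
#'
#' @param camera `camera_model`.
#' @param point length-3 world point (m) or n-by-3 matrix of points.
#' @return length-2 pixel coordinates, or n-by-2 matrix.
#' @export
project_point <- function(camera, point) {
  single <- !is.matrix(point)
  p <- if (single) matrix(point, 1L) else point
  pc <- t(camera$rotation %*% (t(p) - camera$centre))
  if (any(pc[, 3L] <= 1e-9))
    stop("point behind (or on) the camera plane")
  px <- cbind(camera$focal[1L] * pc[, 1L] / pc[, 3L] + camera$principal_point[1L],
              camera$focal[2L] * pc[, 2L] / pc[, 3L] + camera$principal_point[2L])
  if (single) px[1L, ] else px
}

back_project_ray <- function(camera, px) {
  d_cam <- c((px[1L] - camera$principal_point[1L]) / camera$focal[1L],
             (px[2L] - camera$principal_point[2L]) / camera$focal[2L],
             1)
  d <- as.numeric(t(camera$rotation) %*% d_cam)
  d / sqrt(sum(d^2))
}

#' Least-squares intersection of back-projected camera rays
#'
#' Finds the 3D point minimising the sum of squared perpendicular distances
#' to the rays through the observed pixels (closed-form 3x3 normal
#' equations). Cameras whose final ray-to-point distance exceeds
#' `outlier_threshold` are dropped and the solve repeated once; residual
#' distances are reported for the cameras used in the final solve.
#'
#' @param cameras list of `camera_model`s.
#' @param observations n-by-2 matrix of pixel observations, one row per
#'   camera (rows of `NA` mark missing views).
#' @param outlier_threshold perpendicular-distance threshold in m
#'   (default 0.15).
#' @return list with `point` (length-3, m), `residuals` (m, named by
#'   camera position in `cameras`) and `used` (integer indices of cameras
#'   in the final solve).
#' @export
triangulate_rays <- function(cameras, observations, outlier_threshold = 0.15) {
  if (!is.matrix(observations)) observations <- matrix(observations, ncol = 2L, byrow = TRUE)
  avail <- which(!is.na(observations[, 1L]) & !is.na(observations[, 2L]))
  if (length(avail) < 2L)
    stop("degenerate geometry: need at least 2 camera observations")
  rays <- lapply(avail, function(i)
    list(o = cameras[[i]]$centre, d = back_project_ray(cameras[[i]], observations[i, ])))

  solve_rays <- function(idx) {
    A <- matrix(0, 3L, 3L); b <- numeric(3L)
    for (i in idx) {
      d <- rays[[i]]$d; o <- rays[[i]]$o
      P <- diag(3) - tcrossprod(d)  # projector orthogonal to the ray
      A <- A + P
      b <- b + P %*% o
    }
    if (rcond(A) < 1e-12)
      stop("degenerate geometry: rays are (nearly) parallel")
    as.numeric(solve(A, b))
  }
  dist_to_ray <- function(p, r) {
    w <- p - r$o
    perp <- w - sum(w * r$d) * r$d
    sqrt(sum(perp^2))
  }

  idx <- seq_along(rays)
  p <- solve_rays(idx)
  res <- vapply(rays, dist_to_ray, numeric(1), p = p)
  keep <- which(res <= outlier_threshold)
  if (length(keep) >= 2L && length(keep) < length(idx)) {
    idx <- keep
    p <- solve_rays(idx)
    res[idx] <- vapply(rays[idx], dist_to_ray, numeric(1), p = p)
  }
  list(point = p,
       residuals = stats::setNames(res[idx], avail[idx]),
       used = avail[idx])
}

#' Pseudo-CoM trajectory from bounding-box centres
#'
#' Triangulates the per-frame bounding-box centres from all available
#' camera views into a 3D point stream, then low-pass filters it; the
#' result stands in for the centre of mass in the bounding-box proxy
#' method.
#'
#' @param boxes data.frame with columns `camera_id` (index into `cameras`),
#'   `frame`, `cx`, `cy` (box centre, px).
#' @param cameras list of `camera_model`s.
#' @param rate frame rate (Hz).
#' @param cutoff low-pass cut-off (Hz); pass the residual-analysis choice
#'   or the 6 Hz default.
#' @param outlier_threshold passed to [triangulate_rays()].
#' @return n-by-3 matrix of filtered pseudo-CoM positions (m).
#' @export
pseudo_com_trajectory <- function(boxes, cameras, rate, cutoff = 6,
                                  outlier_threshold = 0.15) {
  frames <- sort(unique(boxes$frame))
  if (!identical(as.integer(frames), seq_len(length(frames))))
    stop("frames must be a gap-free 1..n sequence; gaps cannot be interpolated")
  n_cam <- length(cameras)
  obs_cx <- matrix(NA_real_, length(frames), n_cam)
  obs_cy <- matrix(NA_real_, length(frames), n_cam)
  obs_cx[cbind(boxes$frame, boxes$camera_id)] <- boxes$cx
  obs_cy[cbind(boxes$frame, boxes$camera_id)] <- boxes$cy
  n_views <- rowSums(!is.na(obs_cx))
  if (any(n_views < 2L))
    stop("frame(s) with fewer than 2 box observations: ",
         paste(utils::head(frames[n_views < 2L], 5L), collapse = ", "))
  raw <- t(vapply(seq_along(frames), function(f)
    triangulate_rays(cameras, cbind(obs_cx[f, ], obs_cy[f, ]),
                     outlier_threshold)$point,
    numeric(3L)))
  butterworth_lowpass(ts_series(raw, rate), cutoff)$values
}

#' Pelvis-point CoM proxy
#'
#' Returns the trial's pelvis-origin trajectory filtered identically to the
#' CoM, for use as the fixed-point proxy.
#'
#' @param trial `motion_trial` carrying a `pelvis` trajectory.
#' @param cutoff low-pass cut-off (Hz).
#' @return n-by-3 matrix (m).
#' @export
pelvis_proxy <- function(trial, cutoff = 6) {
  if (is.null(trial$pelvis))
    stop("trial carries no pelvis trajectory")
  butterworth_lowpass(ts_series(trial$pelvis, trial$rate), cutoff)$values
}
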