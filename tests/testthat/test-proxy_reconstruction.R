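test_that("pinhole projection: principal point, focal linearity, behind-camera error", {
  cam <- camera_model(c(1000, 1000), c(640, 512), diag(3), c(0, 0, 0),
                      id = "c1")
  # a point on the optical axis (camera z) lands on the principal point
  expect_equal(project_point(cam, c(0, 0, 5)), c(640, 512))

  cam2 <- camera_model(c(2000, 2000), c(640, 512), diag(3), c(0, 0, 0))
  off1 <- project_point(cam, c(0.3, -0.2, 5)) - c(640, 512)
  off2 <- project_point(cam2, c(0.3, -0.2, 5)) - c(640, 512)
  expect_equal(off2, 2 * off1, tolerance = 1e-12)

  expect_error(project_point(cam, c(0, 0, -1)), "behind")
  expect_error(camera_model(c(1000, 1000), c(640, 512),
                            matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 2), 3, 3),
                            c(0, 0, 0)),
               "orthonormal")
})

test_that("ray intersection recovers points exactly from noiseless views", {
  rig <- make_camera_rig()
  p <- c(1, 2, 1.2)

  # two roughly orthogonal views
  obs2 <- matrix(NA_real_, length(rig), 2)
  obs2[1, ] <- project_point(rig[[1]], p)
  obs2[3, ] <- project_point(rig[[3]], p)
  got2 <- triangulate_rays(rig, obs2)
  expect_all_close(got2$point, p, 1e-9)
  expect_true(all(got2$residuals <= 1e-9))

  # full 8-camera round trips on random points
  set.seed(61)
  for (i in 1:10) {
    q <- c(runif(1, -3, 3), runif(1, 0, 8), runif(1, 0.3, 2))
    obs <- t(vapply(rig, project_point, numeric(2), point = q))
    got <- triangulate_rays(rig, obs)
    expect_all_close(got$point, q, 1e-6)
  }

  expect_error(triangulate_rays(rig, matrix(NA_real_, 8, 2)),
               "at least 2 camera observations")
})

test_that("a corrupted view is dropped by the outlier pass", {
  rig <- make_camera_rig()
  p <- c(0.5, 3, 1.1)
  obs <- t(vapply(rig, project_point, numeric(2), point = p))
  obs[4, ] <- obs[4, ] + c(50, 0)  # 50 px corruption
  got <- triangulate_rays(rig, obs, outlier_threshold = 0.1)
  expect_false(4L %in% got$used)
  expect_length(got$used, 7L)
  expect_all_close(got$point, p, 1e-6)
})

test_that("noisy triangulation agrees with a nonlinear reprojection minimiser", {
  rig <- make_camera_rig()
  set.seed(62)
  p <- c(-1, 4, 1.4)
  obs <- t(vapply(rig, project_point, numeric(2), point = p)) +
    matrix(rnorm(16), 8, 2)  # 1 px isotropic noise
  lin <- triangulate_rays(rig, obs, outlier_threshold = 1)$point
  # independent oracle: minimise summed squared reprojection error
  reproj <- function(q) {
    tryCatch(
      sum(vapply(seq_along(rig), function(i)
        sum((project_point(rig[[i]], q) - obs[i, ])^2), numeric(1))),
      error = function(e) 1e12)  # point wandered behind a camera
  }
  nl <- stats::optim(p + rnorm(3, 0, 0.05), reproj, method = "BFGS",
                     control = list(reltol = 1e-14, maxit = 500))$par
  expect_lt(sqrt(sum((lin - nl)^2)), 0.005)
})

test_that("triangulation is equivariant under a rigid transform of the scene", {
  rig <- make_camera_rig()[1:4]
  p <- c(1.5, 2, 0.9)
  obs <- t(vapply(rig, project_point, numeric(2), point = p))
  base <- triangulate_rays(rig, obs)$point

  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  shift <- c(2, -1, 0.5)
  rig_t <- lapply(rig, function(cm)
    camera_model(cm$focal, cm$principal_point, cm$rotation %*% t(Rz),
                 as.numeric(Rz %*% cm$centre) + shift, cm$image_size, cm$id))
  obs_t <- t(vapply(rig_t, project_point, numeric(2),
                    point = as.numeric(Rz %*% p) + shift))
  expect_all_close(obs_t, obs, 1e-6)  # same pixels: rigidly moved scene
  got_t <- triangulate_rays(rig_t, obs_t)$point
  expect_all_close(got_t, as.numeric(Rz %*% base) + shift, 1e-6)
})

test_that("pseudo-CoM reconstruction recovers a known trajectory", {
  rig <- make_camera_rig()
  rate <- 200
  t <- (0:599) / rate
  traj <- cbind(0.5 * sin(2 * pi * 0.5 * t), 2 + 2 * t, 1 + 0.1 * cos(2 * pi * 0.4 * t))
  boxes <- do.call(rbind, lapply(seq_along(rig), function(ci) {
    px <- project_point(rig[[ci]], traj)
    data.frame(camera_id = ci, frame = seq_along(t), cx = px[, 1], cy = px[, 2])
  }))
  rec <- pseudo_com_trajectory(boxes, rig, rate, cutoff = 6)
  rmse <- sqrt(mean(rowSums((rec - traj)^2)))
  expect_lt(rmse, 0.005)

  # static subject: constant trajectory
  traj0 <- matrix(rep(c(0, 3, 1), each = 200), 200, 3)
  boxes0 <- do.call(rbind, lapply(seq_along(rig), function(ci) {
    px <- project_point(rig[[ci]], traj0)
    data.frame(camera_id = ci, frame = 1:200, cx = px[, 1], cy = px[, 2])
  }))
  rec0 <- pseudo_com_trajectory(boxes0, rig, rate, cutoff = 6)
  expect_all_close(rec0, traj0, 1e-6)

  # frames with fewer than 2 views are a gap error
  boxes_gap <- boxes[!(boxes$frame == 10 & boxes$camera_id > 1), ]
  expect_error(pseudo_com_trajectory(boxes_gap, rig, rate), "fewer than 2")
})

test_that("pelvis proxy work: translation invariance and high-frequency inflation", {
  rate <- 200
  t <- (0:5999) / rate
  # gentle base motion so the proxy's high-frequency term dominates the
  # energy increments and the 2Ak closed form applies
  com <- cbind(0.02 * sin(2 * pi * 0.2 * t), 2 * t,
               1 + 0.002 * sin(2 * pi * 0.3 * t))
  mk_trial <- function(pelvis) {
    tr <- rigid_trial(n = 6000, rate = rate)
    tr$com <- com
    tr$pelvis <- pelvis
    tr
  }
  w_of <- function(p) {
    tr <- mk_trial(p)
    pf <- pelvis_proxy(tr, cutoff = 6)
    positive_negative_work(com_energy(pf, rate))[["w_pos"]]
  }
  w_com <- w_of(com)
  expect_equal(w_of(com + matrix(rep(c(0.1, -0.2, 0.05), each = 6000), 6000, 3)),
               w_com, tolerance = 1e-9)

  # a high-frequency oscillation inflates positive work by about 2Ak on the
  # energy series; predict the energy-amplitude from the velocity cross-term
  f_hf <- 2; a_hf <- 0.01
  pel <- com + a_hf * cbind(0, sin(2 * pi * f_hf * t), 0)
  w_hf <- w_of(pel)
  expect_gt(w_hf, w_com)  # strict inflation

  # closed form: vy ~ 2 m/s steady, extra KE amplitude ~ vy * (2 pi f a)
  A <- 2 * (2 * pi * f_hf * a_hf)
  k <- f_hf * max(t)
  expect_lt(abs((w_hf - w_com) - 2 * A * k) / (2 * A * k), 0.05)

  tr_np <- mk_trial(com); tr_np$pelvis <- NULL
  expect_error(pelvis_proxy(tr_np), "no pelvis trajectory")
})
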