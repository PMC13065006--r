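test_that("positive/negative work bookkeeping matches hand enumeration and telescopes", {
  w <- positive_negative_work(c(0, 2, 1, 3))
  expect_equal(w[["w_pos"]], 4)
  expect_equal(w[["w_neg"]], -1)

  rise <- positive_negative_work(seq(2, 9, length.out = 50))
  expect_equal(rise[["w_pos"]], 7)
  expect_equal(rise[["w_neg"]], 0)

  set.seed(41)
  e <- cumsum(rnorm(1000))
  got <- positive_negative_work(e, 100, 900)
  de <- diff(e[100:900])
  expect_identical(got[["w_pos"]], sum(de[de > 0]))
  expect_identical(got[["w_neg"]], sum(de[de < 0]))
  expect_equal(got[["w_pos"]] + got[["w_neg"]], e[900] - e[100],
               tolerance = 1e-12)

  expect_error(positive_negative_work(e, 900, 100), "invalid index range")
  expect_error(positive_negative_work(e, 0, 10), "invalid index range")
})

test_that("CoM energy reproduces closed forms: uniform motion, lifting, ballistic flight", {
  rate <- 200
  n <- 600
  t <- (seq_len(n) - 1L) / rate

  # constant velocity at constant height
  pos <- cbind(2 * t, 0, 1)
  e <- com_energy(pos, rate)
  expect_all_close(e$ke, 2, 1e-9)
  expect_all_close(e$pe, 0, 1e-12)
  expect_all_close(e$total, e$ke + e$pe, 1e-12)

  # quasi-static raise by 1 m: potential gain g*h
  z <- 1 + seq(0, 1, length.out = n)
  still <- com_energy(cbind(0, 0, z), rate, g = 9.81)
  expect_equal(still$pe[n] - still$pe[1], 9.81, tolerance = 1e-9)

  # projectile: total mechanical energy conserved over the flight window
  v0 <- c(3, 4, 6)
  flight <- cbind(v0[1] * t, v0[2] * t, 1.0 + v0[3] * t - 0.5 * 9.81 * t^2)
  ef <- com_energy(flight, rate, g = 9.81)
  w <- positive_negative_work(ef, 3L, n - 2L)  # interior flight phase
  expect_lt(abs(w[["w_pos"]]), 1e-3)
  expect_lt(abs(w[["w_neg"]]), 1e-3)

  expect_error(com_energy(flight[1:2, ], rate), "3 samples")
})

test_that("work is invariant to horizontal origin and height datum shifts", {
  rate <- 200
  t <- (0:999) / rate
  pos <- cbind(sin(2 * pi * 0.8 * t), 2 * t, 1 + 0.2 * sin(2 * pi * 1.1 * t))
  w0 <- positive_negative_work(com_energy(pos, rate))
  shifted <- sweep(pos, 2L, c(100, -50, 13.7), "+")
  w1 <- positive_negative_work(com_energy(shifted, rate))
  expect_equal(w0, w1, tolerance = 1e-9)
})

test_that("limb energies sum translational and rotational terms per limb group", {
  tab <- segment_parameters("male")
  sc <- scale_segment_parameters(77.2, default_segment_lengths(1.82), tab)
  n <- 100

  # all segments frozen relative to the CoM
  kin0 <- setNames(lapply(sc$name, function(s)
    list(v_rel = matrix(0, n, 3), omega = matrix(0, n, 3))), sc$name)
  e0 <- limb_energies(kin0, sc, 200)
  expect_setequal(names(e0), c("legs", "arms", "trunk"))
  for (g in names(e0)) expect_all_close(e0[[g]]$total, 0, 1e-15)

  # one segment carrying the whole body mass at unit relative speed
  tab1 <- data.frame(name = "blob", mass_fraction = 0.999999,
                     com_fraction = 0.5, gyration_x = 0.3, gyration_y = 0.3,
                     gyration_z = 0.3, limb_group = "trunk")
  # complete to closure with a negligible second segment
  tab1 <- rbind(tab1, data.frame(name = "dust", mass_fraction = 1e-6,
                                 com_fraction = 0.5, gyration_x = 0.3,
                                 gyration_y = 0.3, gyration_z = 0.3,
                                 limb_group = "arms"))
  class(tab1) <- c("segment_parameters", "data.frame")
  sc1 <- scale_segment_parameters(60, c(blob = 1, dust = 0.1), tab1)
  kin1 <- list(blob = list(v_rel = cbind(1, 0, 0)[rep(1, n), ],
                           omega = matrix(0, n, 3)),
               dust = list(v_rel = matrix(0, n, 3), omega = matrix(0, n, 3)))
  e1 <- limb_energies(kin1, sc1, 200)
  expect_all_close(e1$trunk$ke, 0.5 * 0.999999, 1e-9)

  # random kinematics against a per-sample re-summation oracle
  set.seed(43)
  kin <- setNames(lapply(sc$name, function(s)
    list(v_rel = matrix(rnorm(n * 3), n, 3),
         omega = matrix(rnorm(n * 3, sd = 3), n, 3))), sc$name)
  got <- limb_energies(kin, sc, 200)
  M <- sum(sc$mass)
  oracle <- list(legs = numeric(n), arms = numeric(n), trunk = numeric(n))
  for (i in seq_len(nrow(sc))) {
    k <- kin[[sc$name[i]]]
    inertia <- c(sc$inertia_x[i], sc$inertia_y[i], sc$inertia_z[i])
    ke <- 0.5 * sc$mass[i] * rowSums(k$v_rel^2) +
      0.5 * colSums(t(k$omega^2) * inertia)
    oracle[[sc$limb_group[i]]] <- oracle[[sc$limb_group[i]]] + ke / M
  }
  for (g in c("legs", "arms", "trunk"))
    expect_all_close(got[[g]]$ke, oracle[[g]], 1e-12)

  # segment without a limb group is refused
  sc_bad <- sc; sc_bad$limb_group[3] <- NA
  expect_error(limb_energies(kin, sc_bad, 200), "limb_group")
})

test_that("cycle work is three groundstroke sets plus the sprint, field by field", {
  gs <- work_summary(w_ext = c(10, -8), w_int = c(4, -3),
                     w_pelvis = c(12, -9), w_bb = c(30, -20),
                     section = "groundstrokes")
  sp <- work_summary(w_ext = c(5, -2), w_int = c(2, -1),
                     w_pelvis = c(6, -3), w_bb = c(12, -5),
                     section = "sprint")
  cy <- cycle_work(gs, sp)
  expect_identical(cy$section, "cycle")
  expect_equal(cy$w_ext_pos, 35)
  expect_equal(cy$w_tot_pos, cy$w_ext_pos + cy$w_int_pos)

  # field-wise oracle on random summaries
  set.seed(44)
  for (rep in 1:5) {
    vals <- abs(rnorm(8, 10))
    g <- work_summary(c(vals[1], -vals[2]), c(vals[3], -vals[4]),
                      section = "groundstrokes")
    s <- work_summary(c(vals[5], -vals[6]), c(vals[7], -vals[8]),
                      section = "sprint")
    cc <- cycle_work(g, s)
    for (f in c("w_ext_pos", "w_ext_neg", "w_int_pos", "w_int_neg",
                "w_tot_pos", "w_tot_neg"))
      expect_equal(cc[[f]], 3 * g[[f]] + s[[f]], tolerance = 1e-12)
  }

  zero <- work_summary(c(0, 0), c(0, 0), section = "groundstrokes")
  zs <- work_summary(c(0, 0), c(0, 0), section = "sprint")
  expect_true(all(unlist(cycle_work(zero, zs)[c("w_ext_pos", "w_tot_neg")]) == 0))

  expect_error(cycle_work(sp, gs), "expected sections")
  expect_error(work_summary(c(-1, 0), c(0, 0)), "positive work")
})

test_that("trial work: identical proxies equal external work; frozen segments give zero internal", {
  tr <- rigid_trial()
  sc <- scale_segment_parameters(tr$body_mass, tr$segment_lengths,
                                 segment_parameters("male"))
  b <- trial_boundaries(10, 600, 1190, 1200)
  works <- trial_work(tr, b, sc)
  for (sec in works) {
    expect_equal(sec$w_pelvis_pos, sec$w_ext_pos, tolerance = 1e-12)
    expect_equal(sec$w_bb_pos, sec$w_ext_pos, tolerance = 1e-12)
    expect_equal(sec$w_pelvis_neg, sec$w_ext_neg, tolerance = 1e-12)
    # frozen segments: no internal work
    expect_lt(abs(sec$w_int_pos), 1e-9)
    expect_equal(sec$w_tot_pos, sec$w_ext_pos + sec$w_int_pos,
                 tolerance = 1e-12)
  }

  # absent proxies are flagged NA, not zero
  tr2 <- tr; tr2$pelvis <- NULL; tr2$pseudo_com <- NULL
  w2 <- trial_work(tr2, b, sc)
  expect_true(is.na(w2$sprint$w_pelvis_pos))
  expect_true(is.na(w2$sprint$w_bb_pos))
})

test_that("a sinusoidal energy component adds 2Ak of positive work", {
  rate <- 200
  t <- (0:5999) / rate
  base <- 5 + 0.1 * t              # slow drift
  A <- 2; k <- 24; f <- k / t[6000]
  e <- base + A * sin(2 * pi * f * t)
  w <- positive_negative_work(e)
  drift <- 0.1 * t[6000]
  expect_lt(abs((w[["w_pos"]] - drift) - 2 * A * k) / (2 * A * k), 0.02)
})
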