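# Kinematics, potential-well regression, kurtosis, visits, summaries.

test_that("kinematics differencing matches hand arithmetic", {
  fx <- data.frame(t = c(0, 3, 6), x = c(0, 3, 9), y = c(0, 0, 0))
  k <- kinematics(fx, center = c(0, 0))
  expect_equal(nrow(k), 1)
  expect_equal(k$vx, 2)           # velocity of the trailing transition
  expect_equal(k$ax, 1 / 3)       # (2 - 1) / 3
  expect_equal(k$x_rel, 3)        # sample sits at the shared fix
  expect_equal(k$ay, 0)

  # uniform motion: zero acceleration everywhere
  fx <- data.frame(t = (0:9) * 3, x = (0:9) * 12, y = (0:9) * -6)
  k <- kinematics(fx, center = c(5, 5))
  expect_equal(k$ax, rep(0, 8))
  expect_equal(k$ay, rep(0, 8))
  expect_equal(k$vx, rep(4, 8))

  # moving the centre shifts relative positions only
  k2 <- kinematics(fx, center = c(12, 5))
  expect_equal(k2$x_rel, k$x_rel - 7)
  expect_equal(k2$y_rel, k$y_rel)
  expect_equal(k2$vx, k$vx)
  expect_equal(k2$ax, k$ax)

  expect_equal(nrow(kinematics(fx[1:2, ], c(0, 0))), 0)
})

test_that("the mean-interval acceleration variant is available", {
  fx <- data.frame(t = c(0, 1, 4), x = c(0, 2, 14), y = c(0, 0, 0))
  # velocities 2 then 4; trailing dt 3, mean dt 2
  expect_equal(kinematics(fx, c(0, 0))$ax, 2 / 3)
  expect_equal(kinematics(fx, c(0, 0), accel_dt = "mean")$ax, 1)
})

test_that("potential-well regression reproduces exact lines", {
  s <- data.frame(x_rel = c(-10, 0, 10), ax = c(1, 0, -1))
  f <- fit_well(s, "x")
  expect_equal(f$slope, -0.1)
  expect_equal(f$intercept, 0)
  expect_equal(f$x_intercept, 0)

  s <- data.frame(x_rel = c(0, 10, 5), ax = c(0.5, -0.5, 0))
  f <- fit_well(s, "x")
  expect_equal(f$slope, -0.1)
  expect_equal(f$intercept, 0.5)
  expect_equal(f$x_intercept, 5)
  expect_equal(f$n, 3L)

  expect_error(fit_well(data.frame(x_rel = c(0, 10), ax = c(0.5, -0.5)),
                        "x"), "at least 3")
  expect_error(fit_well(data.frame(x_rel = rep(2, 5), ax = rnorm(5)), "x"),
               "degenerate")
})

test_that("well fits recover planted stiffness and centre", {
  set.seed(12)
  for (k in c(0.05, 0.1)) {
    path <- simulate_swarm_bout(c(10, -5), k, 0.5, 2, 2000, dt = 0.1)
    sub <- path[seq(1, nrow(path), 2), ]   # 0.2 s sampling
    kin <- kinematics(sub[, c("t", "x", "y")], c(0, 0))
    fx <- fit_well(kin, "x")
    fy <- fit_well(kin, "y")
    expect_lt(abs(fx$slope + k), 2 * fx$slope_se)
    expect_lt(abs(fx$x_intercept - 10), 2 * fx$x_intercept_se)
    expect_lt(abs(fy$x_intercept + 5), 2 * fy$x_intercept_se)
    expect_lt(fx$p_value, 1e-4)
  }
})

test_that("binned profiles summarise acceleration by position", {
  s <- data.frame(x_rel = c(-7, -6, 20, 21, 22), ax = c(1, 3, 0, 0, 3))
  bp <- binned_profile(s, "x")
  b1 <- bp[bp$bin_lo == -10, ]
  expect_equal(b1$mean_accel, 2)
  expect_equal(b1$se, 1)
  expect_equal(b1$n, 2L)
  expect_true(all(bp$empty[bp$bin_lo %in% c(0, 5, 40)]))
  expect_true(all(is.na(bp$mean_accel[bp$empty])))
  # bins tile [-50, 50] without overlap
  expect_equal(bp$bin_lo[-1], bp$bin_hi[-nrow(bp)])

  # exactly linear data: bin means fall on the regression line
  set.seed(9)
  lin <- data.frame(x_rel = runif(500, -49, 49))
  lin$ax <- 0.3 - 0.02 * lin$x_rel
  f <- fit_well(lin, "x")
  bp <- binned_profile(lin, "x")
  filled <- bp[!bp$empty, ]
  pred <- f$intercept + f$slope * vapply(seq_len(nrow(filled)), function(i) {
    with(lin, mean(x_rel[x_rel >= filled$bin_lo[i] & x_rel < filled$bin_hi[i]]))
  }, numeric(1))
  expect_equal(filled$mean_accel, pred, tolerance = 1e-10)
})

test_that("kurtosis matches analytic references and the moment oracle", {
  expect_equal(kurtosis(rep(c(-1, 1), 50)), 1)
  set.seed(10)
  expect_equal(kurtosis(runif(2e5)), 1.8, tolerance = 0.03)
  expect_equal(kurtosis(rnorm(2e5)), 3, tolerance = 0.05)
  v <- c(0.3, -1.2, 2.5, 0.1, -0.7, 1.9, 3.3, -2.2)
  expect_equal(kurtosis(v), kurtosis_oracle(v), tolerance = 1e-12)
  expect_error(kurtosis(rep(1, 10)), "zero variance")
  expect_error(kurtosis(c(1, 2, 3)), "at least 4")
})

test_that("normal-probability points diagnose Gaussian cores", {
  set.seed(13)
  g <- rnorm(5000)
  qq <- gaussian_core_points(g)
  core <- abs(qq$theoretical) < 2
  expect_lt(max(abs(qq$empirical[core] - qq$theoretical[core])), 0.15)
  # affine transforms leave the standardised plot unchanged
  qq2 <- gaussian_core_points(7 - 3.2 * g)
  expect_equal(qq2$empirical, -rev(qq$empirical), tolerance = 1e-9)
  # heavy-tailed mixture departs in the upper tail
  h <- c(rnorm(4750), rnorm(250, 0, 6))
  qqh <- gaussian_core_points(h)
  expect_gt(max(qqh$empirical), max(qqh$theoretical) * 1.3)
})

test_that("visits require convoluted CoM or a sufficient dwell", {
  areas <- list(list(area_id = "A", center = c(x = 0, y = 0)))
  empty_sections <- data.frame(segment_id = character(),
                               label = character(), com_x = numeric(),
                               com_y = numeric(), t_start = numeric(),
                               t_end = numeric())

  # pass-through: 9 s inside the disc, straight flight only
  seg <- make_seg(seq(-60, 60, by = 15), rep(0, 9), id = "pass")
  expect_equal(nrow(detect_visits(seg, empty_sections, areas)), 0)

  # convoluted section CoM 45 m out, dwell only 10 s
  seg2 <- make_seg(c(-60, -20, 45, 47, 100, 140), rep(0, 6), id = "com")
  secs2 <- data.frame(segment_id = "com", label = "convoluted",
                      com_x = 45, com_y = 0, t_start = 6, t_end = 9,
                      stringsAsFactors = FALSE)
  v <- detect_visits(seg2, secs2, areas)
  expect_equal(v$basis, "convoluted_com")
  expect_equal(v$area_id, "A")

  # signal lost for 60 s with both flanking fixes inside: dwell bridged
  seg3 <- flight_segment("gap", data.frame(t = c(0, 60, 63),
                                           x = c(10, 5, 300),
                                           y = c(0, 0, 0)))
  v3 <- detect_visits(seg3, empty_sections, areas)
  expect_equal(v3$basis, "dwell")
  expect_equal(v3$t_end - v3$t_start, 60)

  # dwell threshold monotonicity: longer requirement, never more visits
  set.seed(14)
  sim <- simulate_dataset(sim_config(seed = 14, n_drones = 3,
                                     flights_per_drone = 1))
  secs <- suppressWarnings(classify_all(sim$segments))
  sim_areas <- lapply(seq_len(nrow(sim$area_centers)), function(i) {
    list(area_id = LETTERS[i],
         center = c(x = sim$area_centers[i, 1],
                    y = sim$area_centers[i, 2]))
  })
  counts <- vapply(c(9, 21, 60, 200), function(dwell) {
    nrow(do.call(rbind, lapply(sim$segments, detect_visits, secs,
                               sim_areas, dwell_min_s = dwell)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("sections are assigned to the nearest location centre", {
  areas <- list(list(area_id = "A", center = c(x = 100, y = 0)))
  site <- site_config(data.frame(hive_id = "h1", x = 0, y = 0))
  seg <- circle_track(15, center = c(40, 0), id = "s1")
  secs <- classify_all(list(seg))
  secs$com_x <- 40   # 40 m from hive, 60 m from area: hive wins
  secs$com_y <- 0
  ls <- location_summary(list(seg), secs, areas, site)
  expect_equal(ls$sections$location_id, "h1")
  secs$com_x <- 60   # 60 m from hive, 40 m from area: area wins
  ls <- location_summary(list(seg), secs, areas, site)
  expect_equal(ls$sections$location_id, "A")
  secs$com_x <- 50   # equidistant: congregation preferred over hive
  ls <- location_summary(list(seg), secs, areas, site)
  expect_equal(ls$sections$location_id, "A")
})

test_that("hive hovering and swarm flight separate in kurtosis and speed", {
  set.seed(15)
  hive <- c(0, 0)
  lek <- c(400, 0)
  cfg <- sim_config(seed = 15)
  segs <- list()
  for (i in 1:6) {
    hov <- simulate_hover_bout(hive, 150, dt = 0.1, start = hive)
    sw <- simulate_swarm_bout(lek, 0.1, 0.5, 4, 150, dt = 0.1)
    sh <- radar_sample(hov, cfg, sprintf("hov%d", i))
    ss <- radar_sample(sw, cfg, sprintf("swm%d", i))
    segs <- c(segs, list(sh$segment, ss$segment))
  }
  secs <- suppressWarnings(classify_all(segs))
  site <- site_config(data.frame(hive_id = "h1", x = 0, y = 0))
  areas <- list(list(area_id = "A", center = c(x = 400, y = 0)))
  ls <- location_summary(segs, secs, areas, site)
  hv <- ls$locations[ls$locations$location_kind == "hive", ]
  cg <- ls$locations[ls$locations$location_kind == "congregation", ]
  expect_equal(nrow(hv), 1)
  expect_equal(nrow(cg), 1)
  expect_gt(hv$kurt_x, cg$kurt_x)
  expect_gt(hv$kurt_y, cg$kurt_y)
  expect_lt(hv$mean_speed_ms, cg$mean_speed_ms)
})
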