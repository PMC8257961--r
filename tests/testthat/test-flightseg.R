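# Straight/convoluted classification by windowed resultant vector length.

test_that("transition bearings follow the clockwise-from-north convention", {
  s <- north_track(5)
  tb <- transition_bearings(s)
  expect_equal(tb$bearing, rep(0, 4))
  expect_equal(tb$gap_s, rep(3, 4))
  expect_equal(tb$step_m, rep(15, 4))

  sq <- make_seg(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))
  deg <- (transition_bearings(sq)$bearing * 180 / pi) %% 360
  expect_equal(deg, c(90, 0, 270, 180))

  s2 <- make_seg(c(0, 3), c(0, 4))
  expect_equal(transition_bearings(s2)$bearing, atan2(3, 4))
  expect_equal(transition_bearings(s2)$bearing * 180 / pi, 36.87,
               tolerance = 1e-3)

  # zero displacement: undefined bearing, flagged NA
  s3 <- make_seg(c(0, 0, 5), c(0, 0, 0))
  expect_true(is.na(transition_bearings(s3)$bearing[1]))
})

test_that("windowed resultant vector length matches analytic cases", {
  p <- classifier_params()
  mk <- function(bearings) {
    data.frame(t_mid = seq_along(bearings), bearing = bearings,
               gap_s = 1, step_m = 1)
  }
  expect_equal(window_resultant(mk(rep(1.1, 7)), 4, p), 1)
  expect_equal(window_resultant(mk(c(0, pi / 2, pi, 3 * pi / 2)), 2.5, p),
               0, tolerance = 1e-12)
  expect_equal(window_resultant(mk(c(0, 0, pi / 2)), 2, p), sqrt(5) / 3)
  # fewer than 2 defined bearings: undefined
  expect_true(is.na(window_resultant(mk(c(0, NA, NA)), 2, p)))
  expect_true(is.na(window_resultant(mk(0), 10, p)))
})

test_that("straight flight yields a single straight section", {
  s <- north_track(20)
  sec <- classify_sections(s)
  expect_equal(nrow(sec), 1)
  expect_equal(sec$label, "straight")
  expect_equal(sec$start_idx, 1)
  expect_equal(sec$end_idx, 20)
  expect_equal(sec$mean_speed_ms, 5)
})

test_that("a tight loop is classified as one convoluted section", {
  # radius 15 m at 5 m/s: period ~18.8 s, under the 21 s window, so every
  # window spans a full revolution and R stays near 0
  s <- circle_track(20)
  sec <- classify_sections(s)
  expect_equal(sec$label, "convoluted")
  expect_equal(nrow(sec), 1)
  expect_equal(sec$n_fixes, 20)
  # centre of mass near the circle centre, inside the bounding box
  expect_lt(sqrt(sec$com_x^2 + sec$com_y^2), 8)
})

test_that("convoluted runs shorter than min_run are relabelled straight", {
  straight_in <- cbind(rep(0, 10), seq(0, 135, by = 15))
  straight_out <- cbind(rep(0, 10), seq(-20, -155, by = -15))
  wiggle <- function(k) {
    th <- seq_len(k) * 2.2
    cbind(6 * cos(th), -8 + 4 * sin(th))
  }
  build <- function(k) {
    xy <- rbind(straight_in[10:1, ], wiggle(k), straight_out)
    make_seg(xy[, 1], xy[, 2], id = paste0("w", k))
  }
  sec6 <- classify_sections(build(6))
  expect_false("convoluted" %in% sec6$label)
  expect_equal(nrow(sec6), 1)
  # a longer wiggle leaves a candidate run of at least 7 after the
  # straight windows claim the boundary fixes
  sec12 <- classify_sections(build(12))
  expect_true("convoluted" %in% sec12$label)
  conv <- sec12[sec12$label == "convoluted", ]
  expect_gte(min(conv$n_fixes), 7)
})

test_that("long displaced gaps sever convoluted sections", {
  loopA <- circle_track(10, center = c(0, 0))$fixes
  loopB <- circle_track(10, center = c(300, 0))$fixes
  gap_sever <- 15   # > 12 s and 300 m > 40 m: severs
  loopB_t <- loopB$t + max(loopA$t) + gap_sever
  seg <- flight_segment("sever", data.frame(
    t = c(loopA$t, loopB_t), x = c(loopA$x, loopB$x),
    y = c(loopA$y, loopB$y)))
  sec <- classify_sections(seg)
  conv <- sec[sec$label == "convoluted", ]
  expect_equal(nrow(conv), 2)

  # same spatial jump but a short gap: not severed, one section
  loopB_t2 <- loopB$t + max(loopA$t) + 10
  seg2 <- flight_segment("nosever", data.frame(
    t = c(loopA$t, loopB_t2), x = c(loopA$x, loopB$x),
    y = c(loopA$y, loopB$y)))
  sec2 <- classify_sections(seg2)
  expect_equal(nrow(sec2[sec2$label == "convoluted", ]), 1)

  # long gap but little movement: not severed either
  loopC <- circle_track(10, center = c(5, 0))$fixes
  seg3 <- flight_segment("near", data.frame(
    t = c(loopA$t, loopC$t + max(loopA$t) + gap_sever),
    x = c(loopA$x, loopC$x), y = c(loopA$y, loopC$y)))
  sec3 <- classify_sections(seg3)
  expect_equal(nrow(sec3[sec3$label == "convoluted", ]), 1)
})

test_that("sections partition the fixes of every segment", {
  set.seed(21)
  sim <- simulate_dataset(sim_config(seed = 21, n_drones = 4,
                                     flights_per_drone = 1))
  for (seg in sim$segments) {
    sec <- suppressWarnings(classify_sections(seg))
    n <- nrow(seg$fixes)
    covered <- unlist(Map(seq, sec$start_idx, sec$end_idx))
    expect_equal(sort(covered), seq_len(n))       # cover, no overlap
    expect_true(all(diff(sec$start_idx) > 0))     # ordered
    conv <- sec[sec$label == "convoluted", ]
    if (nrow(conv)) expect_gte(min(conv$n_fixes), 7)
    for (i in seq_len(nrow(sec))) {
      fx <- seg$fixes[sec$start_idx[i]:sec$end_idx[i], ]
      expect_gte(sec$com_x[i], min(fx$x))
      expect_lte(sec$com_x[i], max(fx$x))
      expect_gte(sec$com_y[i], min(fx$y))
      expect_lte(sec$com_y[i], max(fx$y))
    }
  }
})

test_that("labels are invariant to rotation and (gap rule aside) scale", {
  set.seed(31)
  sim <- simulate_dataset(sim_config(seed = 31, n_drones = 2,
                                     flights_per_drone = 1))
  seg <- sim$segments[[1]]
  base <- classify_sections(seg)

  th <- 0.83
  rot <- seg
  rot$fixes$x <- cos(th) * seg$fixes$x - sin(th) * seg$fixes$y + 50
  rot$fixes$y <- sin(th) * seg$fixes$x + cos(th) * seg$fixes$y - 20
  sec_rot <- classify_sections(rot)
  expect_equal(sec_rot$label, base$label)
  expect_equal(sec_rot$start_idx, base$start_idx)

  p_free <- classifier_params(max_gap_m = Inf)
  base_free <- classify_sections(seg, p_free)
  scl <- seg
  scl$fixes$x <- seg$fixes$x * 7
  scl$fixes$y <- seg$fixes$y * 7
  sec_scl <- classify_sections(scl, p_free)
  expect_equal(sec_scl$label, base_free$label)
  expect_equal(sec_scl$start_idx, base_free$start_idx)
})

test_that("lowering the R threshold never adds convoluted fixes", {
  set.seed(41)
  sim <- simulate_dataset(sim_config(seed = 41, n_drones = 3,
                                     flights_per_drone = 1))
  for (seg in sim$segments) {
    counts <- vapply(c(0.8, 0.7, 0.6), function(thr) {
      sec <- suppressWarnings(
        classify_sections(seg, classifier_params(r_threshold = thr)))
      sum(sec$n_fixes[sec$label == "convoluted"])
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("labels are stable across nearby window and threshold settings", {
  sim <- simulate_dataset(sim_config(seed = 51, n_drones = 8,
                                     flights_per_drone = 1))
  base <- lapply(sim$segments, function(s) {
    section_labels(suppressWarnings(classify_sections(s)), nrow(s$fixes))
  })
  sweep <- expand.grid(w = c(15, 21, 27), r = c(0.6, 0.7, 0.8))
  agr <- vapply(seq_len(nrow(sweep)), function(i) {
    p <- classifier_params(window_s = sweep$w[i], r_threshold = sweep$r[i])
    mean(unlist(Map(function(s, b) {
      suppressWarnings(section_labels(classify_sections(s, p),
                                      nrow(s$fixes))) == b
    }, sim$segments, base)))
  }, numeric(1))
  # the robustness sweep is reported, not tightly asserted: settings a
  # window or a tenth of R apart must broadly reproduce the labelling
  expect_true(all(is.finite(agr)))
  expect_true(all(agr > 0.5))
})

test_that("segments shorter than one window are labelled straight", {
  s <- make_seg(c(0, 5, 3, 8, 2), c(0, 4, 8, 3, 6))  # 12 s total
  expect_warning(sec <- classify_sections(s), "shorter than one window")
  expect_equal(sec$label, "straight")
})

test_that("sections_table aggregates per-flight convoluted statistics", {
  empty <- sections_table(data.frame())
  expect_equal(empty$aggregates$n_convoluted_sections, 0L)
  expect_equal(empty$aggregates$n_flights_with_convoluted, 0L)

  sec <- data.frame(
    segment_id = c("f1", "f1", "f1", "f2"),
    section_id = paste0("s", 1:4),
    label = c("convoluted", "straight", "convoluted", "straight"),
    duration_s = c(60, 120, 120, 90),
    stringsAsFactors = FALSE)
  st <- sections_table(sec)
  expect_equal(st$aggregates$n_convoluted_sections, 2L)
  expect_equal(st$aggregates$n_flights_with_convoluted, 1L)
  expect_equal(st$aggregates$n_flights_multi_convoluted, 1L)
  expect_equal(st$aggregates$mean_convoluted_duration_s, 90)
  expect_equal(st$aggregates$mean_fraction_time_convoluted, 180 / 300)
})
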