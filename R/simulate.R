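# Synthetic radar-track generator with known ground truth: commuting
# legs, potential-well swarming, hive hovering, and radar sampling
# artefacts (3 s rotation, dropouts, measurement noise, range limit).

#' Simulation configuration
#'
#' Defaults emulate the field conditions of a harmonic-radar drone study:
#' three hives in a meadow, four congregation areas within the ~800 m
#' trackable radius, straight commuting legs at 4.8 m/s, convoluted
#' swarming consistent with an elastic potential well (exponential dwell
#' times of mean 134 s), one fix per 3 s radar rotation with 2 m
#' measurement error and occasional missed sweeps.
#'
#' The default swarm well (`stiffness_k` 0.1 1/s^2, `damping_gamma` 0.5
#' 1/s, `noise_sigma` 4 m/s^1.5) has stationary position standard
#' deviation `sigma / sqrt(2 gamma k)` ~ 12.6 m — a swarm core of a few
#' tens of metres — and velocity standard deviation `sigma / sqrt(2
#' gamma)` = 4 m/s per axis, giving mean speeds near 5 m/s.
#'
#' @param seed integer RNG seed.
#' @param hives matrix-like of hive coordinates (m), one row per hive.
#' @param areas list of area definitions: each a list with `center`
#'   (length-2), `stiffness_k` (1/s^2), `damping_gamma` (1/s),
#'   `noise_sigma` (m/s^1.5).
#' @param n_drones number of drones.
#' @param flights_per_drone flights per drone.
#' @param commute_speed_ms commuting speed (default 4.8 m/s).
#' @param heading_noise_sd per-step heading perturbation of commuting
#'   flight (radians per 0.1 s step, default 0.1).
#' @param swarm_dwell_s mean swarm-bout duration (default 134 s;
#'   exponential, truncated at 21 s or more so bouts are detectable).
#' @param hover_prob probability that a flight opens with a hovering bout
#'   at the hive (default 0.3).
#' @param radar_interval_s radar rotation period (default 3 s).
#' @param detection_prob per-sweep detection probability (default 0.95).
#' @param measurement_sd_m per-axis Gaussian measurement error (default
#'   2 m).
#' @param max_range_m radar detection radius (default 800 m).
#' @param dt integration step for continuous paths (default 0.1 s, 30
#'   substeps per radar rotation).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       hives = rbind(c(0, 0), c(40, 25), c(-35, 50)),
                       areas = default_sim_areas(),
                       n_drones = 30,
                       flights_per_drone = 2,
                       commute_speed_ms = 4.8,
                       heading_noise_sd = 0.1,
                       swarm_dwell_s = 134,
                       hover_prob = 0.3,
                       radar_interval_s = 3,
                       detection_prob = 0.95,
                       measurement_sd_m = 2,
                       max_range_m = 800,
                       dt = 0.1) {
  hives <- as.matrix(hives)
  stopifnot(ncol(hives) == 2, n_drones >= 1, flights_per_drone >= 1,
            commute_speed_ms > 0, radar_interval_s > 0,
            detection_prob > 0, detection_prob <= 1,
            measurement_sd_m >= 0, dt > 0)
  for (a in areas) {
    stopifnot(a$stiffness_k > 0, a$damping_gamma > 0, a$noise_sigma > 0)
  }
  structure(list(seed = as.integer(seed), hives = hives, areas = areas,
                 n_drones = n_drones, flights_per_drone = flights_per_drone,
                 commute_speed_ms = commute_speed_ms,
                 heading_noise_sd = heading_noise_sd,
                 swarm_dwell_s = swarm_dwell_s, hover_prob = hover_prob,
                 radar_interval_s = radar_interval_s,
                 detection_prob = detection_prob,
                 measurement_sd_m = measurement_sd_m,
                 max_range_m = max_range_m, dt = dt),
            class = "sim_config")
}

#' Default simulated congregation areas
#'
#' Four areas a few hundred metres from the hives, all inside the radar
#' range, sharing the default swarm well parameters.
#'
#' @return List of area definitions (see [sim_config()]).
#' @export
default_sim_areas <- function() {
  centers <- list(c(300, -200), c(450, 120), c(-260, 320), c(140, 420))
  lapply(centers, function(ctr) {
    list(center = ctr, stiffness_k = 0.1, damping_gamma = 0.5,
         noise_sigma = 4)
  })
}

#' Simulate a swarm bout in an elastic potential well
#'
#' Per-axis second-order stochastic dynamics
#' `dv = (-k (x - c) - gamma v) dt + sigma dW`, integrated by
#' Euler-Maruyama: an Ornstein-Uhlenbeck process in velocity with a
#' linear restoring force toward the centre. At stationarity the position
#' variance is `sigma^2 / (2 gamma k)`, the velocity variance
#' `sigma^2 / (2 gamma)`, and the mean acceleration conditioned on
#' position is `-k (x - c)` — the potential-well signature the dynamics
#' analysis recovers.
#'
#' @param center length-2 numeric well centre (m).
#' @param k stiffness (1/s^2).
#' @param gamma damping (1/s).
#' @param sigma velocity noise intensity (m/s^1.5). `sigma = 0` with a
#'   start at the centre stays at the centre exactly.
#' @param duration_s bout duration (s).
#' @param dt integration step (s); must satisfy `dt * gamma < 1`.
#' @param start optional length-2 starting position (default: stationary
#'   draw around the centre).
#' @return Data frame: `t`, `x`, `y`, `label = "swarm"`.
#' @export
simulate_swarm_bout <- function(center, k, gamma, sigma, duration_s,
                                dt = 0.1, start = NULL) {
  if (dt * gamma >= 1) stop("unstable parameters: need dt * gamma < 1")
  n <- max(2L, ceiling(duration_s / dt) + 1L)
  pos <- matrix(0, n, 2)
  if (sigma > 0) {
    sd_x <- sigma / sqrt(2 * gamma * k)
    sd_v <- sigma / sqrt(2 * gamma)
  } else {
    sd_x <- sd_v <- 0
  }
  for (ax in 1:2) {
    x <- numeric(n)
    v <- numeric(n)
    x[1] <- if (is.null(start)) center[ax] + stats::rnorm(1, 0, sd_x) else start[ax]
    v[1] <- stats::rnorm(1, 0, sd_v)
    if (sigma == 0) v[1] <- 0
    noise <- stats::rnorm(n - 1, 0, sigma * sqrt(dt))
    for (i in seq_len(n - 1)) {
      v[i + 1] <- v[i] + (-k * (x[i] - center[ax]) - gamma * v[i]) * dt +
        noise[i]
      x[i + 1] <- x[i] + v[i] * dt
    }
    pos[, ax] <- x
  }
  data.frame(t = (seq_len(n) - 1) * dt, x = pos[, 1], y = pos[, 2],
             label = "swarm", stringsAsFactors = FALSE)
}

#' Simulate a hovering bout near a hive
#'
#' Looping flight around the hive generated as a mixture of two potential
#' wells — a tight, slow hover and wider, faster loops — switched every
#' `chunk_s` seconds. Pooling the two scales produces the heavy-tailed
#' (kurtosis above 3) position distribution and the lower mean speed that
#' distinguish hive-side convoluted flight from swarming at congregation
#' areas. The mixture is a generative stand-in chosen to create that
#' testable contrast, not a mechanistic model of hive behaviour.
#'
#' @param center hive position (m).
#' @param duration_s bout duration.
#' @param dt integration step.
#' @param chunk_s scale-switching period (default 20 s).
#' @param start optional starting position.
#' @return Data frame: `t`, `x`, `y`, `label = "hover"`.
#' @export
simulate_hover_bout <- function(center, duration_s, dt = 0.1,
                                chunk_s = 20, start = NULL) {
  # tight hover: position sd 3 m, velocity sd 1.5 m/s
  # wide loops: position sd 12 m, velocity sd 2.5 m/s
  scales <- list(
    list(k = 0.25, gamma = 1.0, sigma = sqrt(1.5^2 * 2 * 1.0)),
    list(k = 2.5^2 / 12^2, gamma = 0.5, sigma = sqrt(2.5^2 * 2 * 0.5))
  )
  t_off <- 0
  pos <- start
  out <- list()
  while (t_off < duration_s) {
    len <- min(chunk_s, duration_s - t_off)
    sc <- scales[[stats::rbinom(1, 1, 0.5) + 1L]]
    p <- simulate_swarm_bout(center, sc$k, sc$gamma, sc$sigma, len,
                             dt = dt, start = pos)
    pos <- c(p$x[nrow(p)], p$y[nrow(p)])
    p$t <- p$t + t_off
    out[[length(out) + 1]] <- if (t_off > 0) p[-1, ] else p
    t_off <- t_off + len
  }
  path <- do.call(rbind, out)
  path$label <- "hover"
  path
}

#' Simulate a commuting leg
#'
#' A correlated random walk steered toward the destination: at each step
#' the heading is the bearing to the target perturbed by Gaussian noise,
#' at constant speed. Terminates within 5 m of the destination.
#'
#' @param p_start,p_end distinct endpoints (m).
#' @param speed flight speed (m/s).
#' @param heading_noise_sd per-step heading noise (radians).
#' @param dt integration step (s).
#' @return Data frame: `t`, `x`, `y`, `label = "commute"`.
#' @export
simulate_commute <- function(p_start, p_end, speed = 4.8,
                             heading_noise_sd = 0.1, dt = 0.1) {
  d0 <- sqrt(sum((p_end - p_start)^2))
  if (d0 < 1e-9) stop("commute endpoints must be distinct")
  max_steps <- ceiling(10 * d0 / (speed * dt)) + 100L
  xs <- numeric(max_steps)
  ys <- numeric(max_steps)
  xs[1] <- p_start[1]
  ys[1] <- p_start[2]
  i <- 1L
  while (i < max_steps) {
    dx <- p_end[1] - xs[i]
    dy <- p_end[2] - ys[i]
    if (sqrt(dx^2 + dy^2) <= 5) break
    heading <- atan2(dx, dy) +
      if (heading_noise_sd > 0) stats::rnorm(1, 0, heading_noise_sd) else 0
    xs[i + 1] <- xs[i] + speed * dt * sin(heading)
    ys[i + 1] <- ys[i] + speed * dt * cos(heading)
    i <- i + 1L
  }
  data.frame(t = (seq_len(i) - 1) * dt, x = xs[seq_len(i)],
             y = ys[seq_len(i)], label = "commute",
             stringsAsFactors = FALSE)
}

#' Sample a continuous path the way the radar does
#'
#' Positions are read off the path every `radar_interval_s`, each sweep
#' detected with probability `detection_prob`, Gaussian measurement noise
#' added per axis, and fixes beyond `max_range_m` dropped.
#'
#' @param path data frame with `t`, `x`, `y` and optionally `label`,
#'   `area_id` columns (labels are inherited by the fixes).
#' @param config a [sim_config()].
#' @param segment_id label for the resulting segment.
#' @return `NULL` when fewer than 2 fixes survive; otherwise a list with
#'   `segment` (a [flight_segment()]) and `truth` (data frame `t`,
#'   `label`, `area_id`, one row per retained fix).
#' @export
radar_sample <- function(path, config, segment_id = "sim") {
  t_samp <- seq(0, max(path$t), by = config$radar_interval_s)
  idx <- findInterval(t_samp + 1e-9, path$t)
  detected <- stats::runif(length(t_samp)) <= config$detection_prob
  idx <- idx[detected]
  t_samp <- t_samp[detected]
  if (length(idx) < 2) return(NULL)
  x <- path$x[idx] + stats::rnorm(length(idx), 0, config$measurement_sd_m)
  y <- path$y[idx] + stats::rnorm(length(idx), 0, config$measurement_sd_m)
  inrange <- sqrt(x^2 + y^2) <= config$max_range_m
  if (sum(inrange) < 2) return(NULL)
  truth <- data.frame(
    t = t_samp[inrange],
    label = if ("label" %in% names(path)) path$label[idx][inrange] else NA,
    area_id = if ("area_id" %in% names(path)) path$area_id[idx][inrange] else NA,
    stringsAsFactors = FALSE)
  seg <- flight_segment(segment_id,
                        data.frame(t = t_samp[inrange], x = x[inrange],
                                   y = y[inrange]))
  list(segment = seg, truth = truth)
}

#' Simulate a full radar-track dataset with ground truth
#'
#' Per drone and flight: departure from the home hive (optionally opening
#' with a hovering bout at the hive), commuting legs to one to three
#' randomly chosen congregation areas with a potential-well swarm bout at
#' each (multi-lek itineraries), and a commuting leg home. Paths are
#' integrated at `config$dt` and sampled through the radar model.
#' Deterministic for a fixed `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A list with `segments` (list of [flight_segment()]), `truth`
#'   (per-fix data frame: `segment_id`, `t`, `label` in
#'   commute/swarm/hover, `area_id`), `site` (a [site_config()]) and
#'   `area_centers` (matrix of true centres).
#' @export
simulate_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  segments <- list()
  truth <- list()
  n_areas <- length(config$areas)
  for (d in seq_len(config$n_drones)) {
    hive_i <- sample.int(nrow(config$hives), 1)
    hive <- config$hives[hive_i, ]
    for (fl in seq_len(config$flights_per_drone)) {
      sid <- sprintf("d%02d_f%d", d, fl)
      legs <- list()
      pos <- hive
      if (stats::runif(1) < config$hover_prob) {
        dur <- max(30, stats::rexp(1, 1 / 60))
        legs[[1]] <- simulate_hover_bout(hive, dur, dt = config$dt,
                                         start = hive)
        legs[[1]]$area_id <- NA_character_
        p <- legs[[1]]
        pos <- c(p$x[nrow(p)], p$y[nrow(p)])
      }
      n_bouts <- sample.int(min(3, n_areas), 1)
      itinerary <- sample.int(n_areas, n_bouts)
      for (ai in itinerary) {
        area <- config$areas[[ai]]
        leg <- simulate_commute(pos, area$center, config$commute_speed_ms,
                                config$heading_noise_sd, config$dt)
        leg$area_id <- NA_character_
        legs[[length(legs) + 1]] <- leg
        pos <- c(leg$x[nrow(leg)], leg$y[nrow(leg)])
        dur <- max(21, stats::rexp(1, 1 / config$swarm_dwell_s))
        bout <- simulate_swarm_bout(area$center, area$stiffness_k,
                                    area$damping_gamma, area$noise_sigma,
                                    dur, dt = config$dt, start = pos)
        bout$area_id <- LETTERS[ai]
        legs[[length(legs) + 1]] <- bout
        pos <- c(bout$x[nrow(bout)], bout$y[nrow(bout)])
      }
      leg <- simulate_commute(pos, hive, config$commute_speed_ms,
                              config$heading_noise_sd, config$dt)
      leg$area_id <- NA_character_
      legs[[length(legs) + 1]] <- leg
      # concatenate legs on a common clock
      t_off <- 0
      for (k in seq_along(legs)) {
        legs[[k]]$t <- legs[[k]]$t + t_off
        t_off <- legs[[k]]$t[nrow(legs[[k]])] + config$dt
      }
      path <- do.call(rbind, legs)
      samp <- radar_sample(path, config, segment_id = sid)
      if (is.null(samp)) next
      samp$segment$drone_id <- sprintf("d%02d", d)
      samp$segment$hive_id <- as.character(hive_i)
      segments[[length(segments) + 1]] <- samp$segment
      samp$truth$segment_id <- sid
      truth[[length(truth) + 1]] <- samp$truth
    }
  }
  hives_df <- data.frame(hive_id = as.character(seq_len(nrow(config$hives))),
                         x = config$hives[, 1], y = config$hives[, 2])
  list(segments = segments,
       truth = do.call(rbind, truth),
       site = site_config(hives_df, max_range_m = config$max_range_m),
       area_centers = do.call(rbind, lapply(config$areas, `[[`, "center")))
}

#' Per-fix agreement between classifier labels and simulation truth
#'
#' Ground-truth commuting fixes should be labelled straight; swarm and
#' hover fixes convoluted.
#'
#' @param segments list of simulated [flight_segment()] objects.
#' @param truth truth table from [simulate_dataset()].
#' @param params a [classifier_params()].
#' @return Agreement fraction in `[0, 1]`.
#' @export
label_agreement <- function(segments, truth, params = classifier_params()) {
  n_match <- 0L
  n_tot <- 0L
  for (seg in segments) {
    sec <- suppressWarnings(classify_sections(seg, params))
    pred <- section_labels(sec, nrow(seg$fixes))
    tr <- truth[truth$segment_id == seg$segment_id, , drop = FALSE]
    expect <- ifelse(tr$label == "commute", "straight", "convoluted")
    n_match <- n_match + sum(pred == expect)
    n_tot <- n_tot + length(pred)
  }
  n_match / n_tot
}
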