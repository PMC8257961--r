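# Kinematics and swarm-cohesion statistics: velocity/acceleration fields,
# acceleration-vs-position regressions, binned profiles, kurtosis and
# Gaussian-core diagnostics, visit detection.

#' Per-fix kinematics of a flight section relative to a centre
#'
#' Velocities are finite differences of position over each transition;
#' accelerations are finite differences of consecutive velocities divided
#' by a time interval. Each kinematics sample sits at the fix shared by
#' two consecutive transitions, with its position expressed relative to
#' the given centre. By default the trailing interval (the duration of the
#' second transition) divides the velocity difference; `accel_dt = "mean"`
#' uses the mean of the two transition durations instead.
#'
#' @param fixes data frame of fixes (`t`, `x`, `y`) of one section.
#' @param center length-2 numeric `(x, y)`: congregation or hive centre.
#' @param accel_dt `"trailing"` (default) or `"mean"`.
#' @return Data frame of samples: `t`, `x_rel`, `y_rel`, `vx`, `vy`,
#'   `ax`, `ay`. Sections with fewer than 3 fixes yield zero rows.
#' @export
kinematics <- function(fixes, center, accel_dt = c("trailing", "mean")) {
  accel_dt <- match.arg(accel_dt)
  fixes <- as.data.frame(fixes)
  n <- nrow(fixes)
  empty <- data.frame(t = numeric(), x_rel = numeric(), y_rel = numeric(),
                      vx = numeric(), vy = numeric(),
                      ax = numeric(), ay = numeric())
  if (n < 3) return(empty)
  dt <- diff(fixes$t)
  vx <- diff(fixes$x) / dt
  vy <- diff(fixes$y) / dt
  # sample i sits at fix i + 1, shared by transitions i and i + 1
  a_dt <- switch(accel_dt,
                 trailing = dt[-1],
                 mean = (dt[-1] + dt[-(n - 1)]) / 2)
  out <- data.frame(
    t = fixes$t[2:(n - 1)],
    x_rel = fixes$x[2:(n - 1)] - center[1],
    y_rel = fixes$y[2:(n - 1)] - center[2],
    vx = vx[-1], vy = vy[-1],
    ax = diff(vx) / a_dt, ay = diff(vy) / a_dt
  )
  out[is.finite(out$ax) & is.finite(out$ay), , drop = FALSE]
}

#' Fit the potential-well (acceleration versus position) regression
#'
#' Ordinary least squares of one acceleration component on the matching
#' relative-position component, pooled over all samples at a location. A
#' negative slope means the further the bee strays from the centre, the
#' more strongly it accelerates back — the signature of an effective
#' elastic potential well binding individuals to a swarm. The x-intercept
#' (`-intercept / slope`) locates the point of zero mean acceleration,
#' which for a cohesive swarm sits at the swarm centre.
#'
#' @param samples data frame from [kinematics()] (possibly pooled over
#'   sections), needing columns `x_rel`/`ax` or `y_rel`/`ay`.
#' @param axis `"x"` or `"y"`.
#' @return A one-row data frame of class `well_fit`: `axis`, `slope`
#'   (1/s^2), `intercept` (m/s^2), `x_intercept` (m; `NA` when the slope
#'   is zero), `slope_se`, `intercept_se`, `p_value` (slope test), `n`.
#' @export
fit_well <- function(samples, axis = c("x", "y")) {
  axis <- match.arg(axis)
  pos <- samples[[paste0(axis, "_rel")]]
  acc <- samples[[paste0("a", axis)]]
  ok <- is.finite(pos) & is.finite(acc)
  pos <- pos[ok]
  acc <- acc[ok]
  if (length(pos) < 3) stop("potential-well fit needs at least 3 samples")
  if (stats::sd(pos) == 0) stop("degenerate fit: position is constant")
  fit <- stats::lm(acc ~ pos)
  co <- summary(fit)$coefficients
  slope <- co["pos", "Estimate"]
  intercept <- co["(Intercept)", "Estimate"]
  # delta-method standard error of the zero-acceleration point -b0/b1
  xint <- if (slope != 0) -intercept / slope else NA_real_
  xint_se <- NA_real_
  if (slope != 0) {
    V <- stats::vcov(fit)
    g <- c(-1 / slope, intercept / slope^2)
    xint_se <- sqrt(drop(t(g) %*% V %*% g))
  }
  structure(
    data.frame(axis = axis, slope = slope, intercept = intercept,
               x_intercept = xint,
               slope_se = co["pos", "Std. Error"],
               intercept_se = co["(Intercept)", "Std. Error"],
               x_intercept_se = xint_se,
               p_value = co["pos", "Pr(>|t|)"],
               n = length(pos), stringsAsFactors = FALSE),
    class = c("well_fit", "data.frame")
  )
}

#' Binned acceleration profile
#'
#' Mean acceleration by position bin, for visualising the linearity of
#' the acceleration field. Bins are left-closed 5 m intervals spanning
#' +/- 50 m of the centre by default; empty bins are flagged rather than
#' zero-filled.
#'
#' @inheritParams fit_well
#' @param bin_m bin width in metres (default 5).
#' @param span_m half-range covered by the bins (default 50 m).
#' @return Data frame: `bin_lo`, `bin_hi`, `bin_mid`, `mean_accel`, `se`
#'   (sd / sqrt(n); `NA` for n < 2), `n`, `empty`.
#' @export
binned_profile <- function(samples, axis = c("x", "y"), bin_m = 5,
                           span_m = 50) {
  axis <- match.arg(axis)
  pos <- samples[[paste0(axis, "_rel")]]
  acc <- samples[[paste0("a", axis)]]
  edges <- seq(-span_m, span_m, by = bin_m)
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  out <- data.frame(bin_lo = lo, bin_hi = hi, bin_mid = (lo + hi) / 2,
                    mean_accel = NA_real_, se = NA_real_, n = 0L,
                    empty = TRUE)
  for (i in seq_along(lo)) {
    inb <- pos >= lo[i] & pos < hi[i]
    ni <- sum(inb)
    if (ni == 0) next
    out$n[i] <- ni
    out$empty[i] <- FALSE
    out$mean_accel[i] <- mean(acc[inb])
    if (ni >= 2) out$se[i] <- stats::sd(acc[inb]) / sqrt(ni)
  }
  out
}

#' Pearson kurtosis
#'
#' The standardised fourth central moment `m4 / m2^2` (non-excess
#' convention): 3 for a Gaussian, 1.8 for a uniform distribution, larger
#' values for heavier tails.
#'
#' @param values numeric vector, `n >= 4`, non-zero variance.
#' @return Kurtosis (unitless).
#' @export
kurtosis <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4) stop("kurtosis needs at least 4 values")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) stop("kurtosis undefined for zero variance")
  mean((values - m)^4) / m2^2
}

#' Normal-probability plot points
#'
#' Pairs of theoretical standard-normal quantiles and standardised
#' empirical quantiles, for assessing whether a position or velocity
#' distribution has a Gaussian core (points on the identity line) with
#' departures in the tails.
#'
#' @param values numeric vector, `n >= 10`.
#' @return Data frame: `theoretical` (`qnorm((i - 0.5) / n)`), `empirical`
#'   (sorted values standardised by sample mean and sd).
#' @export
gaussian_core_points <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 10) stop("need at least 10 values")
  data.frame(
    theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
    empirical = (sort(values) - mean(values)) / stats::sd(values)
  )
}

#' Detect visits of a flight to congregation areas
#'
#' A flight visits an area when (a) it performs a convoluted section whose
#' centre of mass lies within `radius_m` of the area centre, or (b) it
#' remains within `radius_m` of the centre for at least `dwell_min_s`
#' seconds. Dwell intervals bridge signal-loss periods provided the fixes
#' on either side of the missing period are both inside the radius (the
#' bee may simply have flown too high to detect).
#'
#' @param seg a [flight_segment()].
#' @param sections section table for this segment.
#' @param areas list of congregations from [select_congregations()].
#' @param radius_m visit radius (default 50 m).
#' @param dwell_min_s minimum dwell duration (default 21 s, seven radar
#'   rotations).
#' @return Data frame of visits: `segment_id`, `area_id`, `basis`
#'   (`"convoluted_com"` or `"dwell"`), `t_start`, `t_end`. At most one
#'   row per (segment, area, basis, interval).
#' @export
detect_visits <- function(seg, sections, areas, radius_m = 50,
                          dwell_min_s = 21) {
  out <- list()
  f <- seg$fixes
  secs <- sections[sections$segment_id == seg$segment_id, , drop = FALSE]
  for (a in areas) {
    cx <- a$center[1]
    cy <- a$center[2]
    conv <- secs[secs$label == "convoluted", , drop = FALSE]
    if (nrow(conv)) {
      d <- sqrt((conv$com_x - cx)^2 + (conv$com_y - cy)^2)
      for (i in which(d <= radius_m)) {
        out[[length(out) + 1]] <- data.frame(
          segment_id = seg$segment_id, area_id = a$area_id,
          basis = "convoluted_com",
          t_start = conv$t_start[i], t_end = conv$t_end[i],
          stringsAsFactors = FALSE)
      }
    }
    # dwell: maximal runs of fixes inside the disc; a gap between two
    # inside fixes is bridged regardless of its length
    inside <- sqrt((f$x - cx)^2 + (f$y - cy)^2) <= radius_m
    r <- rle(inside)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      t0 <- f$t[starts[j]]
      t1 <- f$t[ends[j]]
      if (t1 - t0 >= dwell_min_s) {
        out[[length(out) + 1]] <- data.frame(
          segment_id = seg$segment_id, area_id = a$area_id,
          basis = "dwell", t_start = t0, t_end = t1,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(segment_id = character(), area_id = character(),
                      basis = character(), t_start = numeric(),
                      t_end = numeric()))
  }
  do.call(rbind, out)
}

#' Count distinct areas visited per flight
#'
#' @param segments list of [flight_segment()] objects.
#' @param sections combined section table.
#' @param areas list of congregations.
#' @inheritParams detect_visits
#' @return Data frame: `segment_id`, `n_areas_visited`, plus the combined
#'   visit table as attribute `"visits"`.
#' @export
count_areas_visited <- function(segments, sections, areas, radius_m = 50,
                                dwell_min_s = 21) {
  visits <- do.call(rbind, lapply(segments, detect_visits,
                                  sections = sections, areas = areas,
                                  radius_m = radius_m,
                                  dwell_min_s = dwell_min_s))
  counts <- data.frame(
    segment_id = vapply(segments, `[[`, "", "segment_id"),
    stringsAsFactors = FALSE)
  counts$n_areas_visited <- vapply(counts$segment_id, function(sid) {
    length(unique(visits$area_id[visits$segment_id == sid]))
  }, integer(1))
  attr(counts, "visits") <- visits
  counts
}

#' Assign convoluted sections to locations and summarise dynamics
#'
#' A convoluted section takes place at a congregation area or hive when
#' its centre of mass lies within `radius_m` of that centre (hives only
#' while active, if dates are known). A section within range of several
#' centres is assigned to the nearest; at exactly equal distance the
#' congregation wins over the hive. For every location the position and
#' velocity components of all assigned sections are pooled (relative to
#' the location centre) and their kurtosis computed — the per-section and
#' per-location tables feeding downstream comparisons of hive versus
#' congregation flight.
#'
#' @param segments list of [flight_segment()] objects.
#' @param sections combined section table.
#' @param areas list of congregations.
#' @param site a [site_config()].
#' @param radius_m assignment radius (default 50 m).
#' @param accel_dt passed to [kinematics()].
#' @return A list with `sections` (one row per assigned convoluted
#'   section: `section_id`, `segment_id`, `location_id`, `location_kind`,
#'   `duration_s`, `mean_speed_ms`) and `locations` (one row per location:
#'   `location_id`, `location_kind`, `n_sections`, `kurt_x`, `kurt_y`,
#'   `kurt_vx`, `kurt_vy`, `mean_duration_s`, `mean_speed_ms`).
#' @export
location_summary <- function(segments, sections, areas, site,
                             radius_m = 50, accel_dt = "trailing") {
  centers <- data.frame(location_id = character(), kind = character(),
                        x = numeric(), y = numeric(),
                        stringsAsFactors = FALSE)
  for (a in areas) {
    centers <- rbind(centers, data.frame(
      location_id = a$area_id, kind = "congregation",
      x = a$center[1], y = a$center[2], stringsAsFactors = FALSE))
  }
  if (!is.null(site)) {
    centers <- rbind(centers, data.frame(
      location_id = as.character(site$hives$hive_id), kind = "hive",
      x = site$hives$x, y = site$hives$y, stringsAsFactors = FALSE))
  }
  conv <- sections[sections$label == "convoluted", , drop = FALSE]
  seg_map <- stats::setNames(segments,
                             vapply(segments, `[[`, "", "segment_id"))
  rows <- list()
  for (i in seq_len(nrow(conv))) {
    seg <- seg_map[[conv$segment_id[i]]]
    cand <- centers
    if (!is.null(site) && !is.null(seg$start_time)) {
      active <- .hives_for_segment(seg, site, "active")$hive_id
      cand <- cand[cand$kind == "congregation" |
                     cand$location_id %in% as.character(active), ,
                   drop = FALSE]
    }
    if (nrow(cand) == 0) next
    d <- sqrt((cand$x - conv$com_x[i])^2 + (cand$y - conv$com_y[i])^2)
    inr <- which(d <= radius_m)
    if (length(inr) == 0) next
    # nearest centre wins; exact ties favour the congregation (candidate
    # table lists congregations first, which.min takes the first minimum)
    j <- inr[which.min(d[inr])]
    rows[[length(rows) + 1]] <- data.frame(
      section_id = conv$section_id[i], segment_id = conv$segment_id[i],
      location_id = cand$location_id[j], location_kind = cand$kind[j],
      duration_s = conv$duration_s[i],
      mean_speed_ms = conv$mean_speed_ms[i],
      start_idx = conv$start_idx[i], end_idx = conv$end_idx[i],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(list(sections = data.frame(), locations = data.frame()))
  }
  per_section <- do.call(rbind, rows)
  locs <- unique(per_section$location_id)
  loc_rows <- lapply(locs, function(loc) {
    ps <- per_section[per_section$location_id == loc, , drop = FALSE]
    ctr <- unlist(centers[centers$location_id == loc, c("x", "y")])
    pooled <- do.call(rbind, lapply(seq_len(nrow(ps)), function(k) {
      seg <- seg_map[[ps$segment_id[k]]]
      kinematics(seg$fixes[ps$start_idx[k]:ps$end_idx[k], , drop = FALSE],
                 ctr, accel_dt = accel_dt)
    }))
    data.frame(
      location_id = loc,
      location_kind = ps$location_kind[1],
      n_sections = nrow(ps),
      kurt_x = if (nrow(pooled) >= 4) kurtosis(pooled$x_rel) else NA_real_,
      kurt_y = if (nrow(pooled) >= 4) kurtosis(pooled$y_rel) else NA_real_,
      kurt_vx = if (nrow(pooled) >= 4) kurtosis(pooled$vx) else NA_real_,
      kurt_vy = if (nrow(pooled) >= 4) kurtosis(pooled$vy) else NA_real_,
      mean_duration_s = mean(ps$duration_s),
      mean_speed_ms = mean(ps$mean_speed_ms, na.rm = TRUE),
      stringsAsFactors = FALSE)
  })
  per_section$start_idx <- NULL
  per_section$end_idx <- NULL
  list(sections = per_section, locations = do.call(rbind, loc_rows))
}

#' Pool kinematics of sections assigned to one location
#'
#' Convenience used by the regression and profile stages: every convoluted
#' section whose centre of mass lies within `radius_m` of the given centre
#' contributes its kinematics samples relative to that centre.
#'
#' @param segments list of [flight_segment()] objects.
#' @param sections combined section table.
#' @param center length-2 numeric location centre.
#' @param radius_m assignment radius (default 50 m).
#' @param accel_dt passed to [kinematics()].
#' @return Pooled kinematics data frame.
#' @export
pool_kinematics <- function(segments, sections, center, radius_m = 50,
                            accel_dt = "trailing") {
  conv <- sections[sections$label == "convoluted", , drop = FALSE]
  d <- sqrt((conv$com_x - center[1])^2 + (conv$com_y - center[2])^2)
  conv <- conv[d <= radius_m, , drop = FALSE]
  seg_map <- stats::setNames(segments,
                             vapply(segments, `[[`, "", "segment_id"))
  pooled <- lapply(seq_len(nrow(conv)), function(i) {
    seg <- seg_map[[conv$segment_id[i]]]
    kinematics(seg$fixes[conv$start_idx[i]:conv$end_idx[i], , drop = FALSE],
               center, accel_dt = accel_dt)
  })
  out <- do.call(rbind, pooled)
  if (is.null(out)) {
    out <- data.frame(t = numeric(), x_rel = numeric(), y_rel = numeric(),
                      vx = numeric(), vy = numeric(), ax = numeric(),
                      ay = numeric())
  }
  out
}
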