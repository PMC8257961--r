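# Data model, coordinate conversion, segment filtering and file I/O for
# harmonic-radar insect tracks.

#' Site configuration
#'
#' Bundles the geometry of a radar tracking site: the radar origin, two
#' surveyed reference points used to calibrate the local-to-geographic
#' transform, and the hives with their active date ranges. All planar
#' coordinates are metres in a local east-north-up (ENU) frame anchored at
#' the radar origin.
#'
#' @param hives data frame with columns `hive_id`, `x`, `y` and optionally
#'   `active_start`, `active_end` (anything coercible with [as.POSIXct()];
#'   `NA` means open-ended). Hive ids must be unique.
#' @param radar_origin optional geographic coordinate `c(lon, lat)` of the
#'   radar (degrees, WGS84). Only needed for geographic export.
#' @param reference_points optional 2-row data frame with columns
#'   `x`, `y` (local metres) and `lon`, `lat` (degrees): two locations of
#'   known GPS position used to calibrate an affine (translation +
#'   rotation + scale) local-to-geographic transform.
#' @param max_range_m radar detection radius in metres (default 800).
#' @param params named list of extra pipeline parameters carried along with
#'   the site (merged over the classifier/cluster defaults by consumers).
#'
#' @return An object of class `site_config`.
#' @seealso [read_site_config()], [polar_to_local()]
#' @export
site_config <- function(hives,
                        radar_origin = NULL,
                        reference_points = NULL,
                        max_range_m = 800,
                        params = list()) {
  hives <- as.data.frame(hives)
  stopifnot(nrow(hives) >= 1, all(c("hive_id", "x", "y") %in% names(hives)))
  if (anyDuplicated(hives$hive_id)) {
    stop("hive_id values must be unique within a site")
  }
  if (!all(is.finite(hives$x)) || !all(is.finite(hives$y))) {
    stop("hive coordinates must be finite")
  }
  if (!"active_start" %in% names(hives)) hives$active_start <- NA
  if (!"active_end" %in% names(hives)) hives$active_end <- NA
  hives$active_start <- .as_time(hives$active_start)
  hives$active_end <- .as_time(hives$active_end)
  bad <- !is.na(hives$active_start) & !is.na(hives$active_end) &
    hives$active_start > hives$active_end
  if (any(bad)) {
    stop("hive active_start must not exceed active_end: ",
         paste(hives$hive_id[bad], collapse = ", "))
  }
  if (!is.null(reference_points)) {
    reference_points <- as.data.frame(reference_points)
    stopifnot(nrow(reference_points) == 2,
              all(c("x", "y", "lon", "lat") %in% names(reference_points)))
    d <- stats::dist(reference_points[, c("x", "y")])
    if (any(d < 1e-9) || any(rowSums(reference_points[, c("x", "y")]^2) < 1e-18)) {
      stop("reference points must be distinct from each other and the origin")
    }
  }
  structure(
    list(hives = hives, radar_origin = radar_origin,
         reference_points = reference_points,
         max_range_m = max_range_m, params = params),
    class = "site_config"
  )
}

.as_time <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  if (is.numeric(x)) return(as.POSIXct(x, origin = "1970-01-01", tz = "UTC"))
  as.POSIXct(as.character(x), tz = "UTC")
}

#' @export
print.site_config <- function(x, ...) {
  cat("<site_config>", nrow(x$hives), "hive(s); max range",
      x$max_range_m, "m\n")
  invisible(x)
}

#' Read a site configuration file
#'
#' Sites are described in a single YAML file with keys `radar_origin`
#' (`[lon, lat]`), `reference_points` (list of `{x, y, lon, lat}`), `hives`
#' (list of `{hive_id, x, y, active_start, active_end}`), `max_range_m`,
#' and an optional `params` mapping holding pipeline parameters.
#'
#' @param path path to the YAML site file.
#' @return A [site_config()] object.
#' @export
read_site_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$hives)) stop("site config must list at least one hive")
  hives <- do.call(rbind, lapply(cfg$hives, function(h) {
    data.frame(hive_id = as.character(h$hive_id), x = h$x, y = h$y,
               active_start = h$active_start %||% NA,
               active_end = h$active_end %||% NA,
               stringsAsFactors = FALSE)
  }))
  refs <- NULL
  if (!is.null(cfg$reference_points)) {
    refs <- do.call(rbind, lapply(cfg$reference_points, function(r) {
      data.frame(x = r$x, y = r$y, lon = r$lon, lat = r$lat)
    }))
  }
  site_config(hives = hives,
              radar_origin = unlist(cfg$radar_origin),
              reference_points = refs,
              max_range_m = cfg$max_range_m %||% 800,
              params = cfg$params %||% list())
}

#' Write a site configuration file
#'
#' @param site a [site_config()] object.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_site_config <- function(site, path) {
  hives <- lapply(seq_len(nrow(site$hives)), function(i) {
    h <- site$hives[i, ]
    out <- list(hive_id = h$hive_id, x = h$x, y = h$y)
    if (!is.na(h$active_start)) out$active_start <- format(h$active_start)
    if (!is.na(h$active_end)) out$active_end <- format(h$active_end)
    out
  })
  cfg <- list(hives = hives, max_range_m = site$max_range_m)
  if (!is.null(site$radar_origin)) cfg$radar_origin <- as.list(site$radar_origin)
  if (!is.null(site$reference_points)) {
    cfg$reference_points <- lapply(seq_len(nrow(site$reference_points)),
                                   function(i) as.list(site$reference_points[i, ]))
  }
  if (length(site$params)) cfg$params <- site$params
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert polar radar coordinates to the local planar frame
#'
#' The radar reports range and azimuth each antenna rotation. Azimuth
#' follows the navigation convention: degrees clockwise from true north,
#' so `x = range * sin(azimuth)` (east) and `y = range * cos(azimuth)`
#' (north) in the ENU frame anchored at the radar origin.
#'
#' @param range_m range in metres (>= 0).
#' @param azimuth_deg azimuth in degrees, clockwise from true north.
#' @return A data frame with columns `x` and `y` (metres).
#' @examples
#' polar_to_local(100, 0)   # 100 m due north
#' polar_to_local(100, 90)  # 100 m due east
#' @export
polar_to_local <- function(range_m, azimuth_deg) {
  if (any(range_m < 0, na.rm = TRUE)) stop("range must be non-negative")
  theta <- azimuth_deg * pi / 180
  data.frame(x = range_m * sin(theta), y = range_m * cos(theta))
}

#' Convert local planar coordinates back to polar
#'
#' Inverse of [polar_to_local()]; azimuth returned in `[0, 360)` degrees
#' clockwise from north.
#'
#' @param x,y local ENU coordinates in metres.
#' @return A data frame with columns `range_m` and `azimuth_deg`.
#' @export
local_to_polar <- function(x, y) {
  r <- sqrt(x^2 + y^2)
  az <- (atan2(x, y) * 180 / pi) %% 360
  data.frame(range_m = r, azimuth_deg = az)
}

#' Calibrate the local-to-geographic transform from two reference points
#'
#' Fits a similarity transform (translation, rotation, uniform scale) that
#' maps local ENU metres onto an equirectangular projection of the
#' geographic reference coordinates, and reports the fit residual. With
#' exactly two reference points the similarity transform is exactly
#' determined and the residual is zero up to floating point; it is surfaced
#' so that miskeyed references are caught.
#'
#' @param site a [site_config()] with `reference_points` and `radar_origin`.
#' @return A list with `lon0`, `lat0`, `m_per_deg_lon`, `m_per_deg_lat`,
#'   `rotation_rad`, `scale`, `residual_m`.
#' @keywords internal
#' @export
calibrate_geo_transform <- function(site) {
  refs <- site$reference_points
  if (is.null(refs) || is.null(site$radar_origin)) {
    stop("site must carry radar_origin and two reference_points")
  }
  lat0 <- site$radar_origin[2]
  lon0 <- site$radar_origin[1]
  m_per_deg_lat <- 111132.954
  m_per_deg_lon <- m_per_deg_lat * cos(lat0 * pi / 180)
  # reference points in metres of the equirectangular geographic frame
  gx <- (refs$lon - lon0) * m_per_deg_lon
  gy <- (refs$lat - lat0) * m_per_deg_lat
  lx <- refs$x
  ly <- refs$y
  # similarity transform local -> geo solved from the two point pairs
  dl <- c(lx[2] - lx[1], ly[2] - ly[1])
  dg <- c(gx[2] - gx[1], gy[2] - gy[1])
  nl <- sqrt(sum(dl^2))
  ng <- sqrt(sum(dg^2))
  if (nl < 1e-9) stop("degenerate reference points")
  scale <- ng / nl
  rot <- atan2(dg[2], dg[1]) - atan2(dl[2], dl[1])
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  t0 <- c(gx[1], gy[1]) - scale * as.vector(R %*% c(lx[1], ly[1]))
  pred <- scale * t(R %*% t(cbind(lx, ly))) + rep(t0, each = 2)
  residual <- sqrt(mean((pred[, 1] - gx)^2 + (pred[, 2] - gy)^2))
  list(lon0 = lon0, lat0 = lat0,
       m_per_deg_lon = m_per_deg_lon, m_per_deg_lat = m_per_deg_lat,
       rotation_rad = rot, scale = scale, translation_m = t0,
       residual_m = residual)
}

#' Transform local coordinates to geographic (WGS84)
#'
#' @param x,y local coordinates (m).
#' @param transform result of [calibrate_geo_transform()].
#' @return data frame with `lon`, `lat` in degrees.
#' @export
local_to_geographic <- function(x, y, transform) {
  R <- matrix(c(cos(transform$rotation_rad), sin(transform$rotation_rad),
                -sin(transform$rotation_rad), cos(transform$rotation_rad)),
              2, 2)
  g <- transform$scale * t(R %*% t(cbind(x, y)))
  gx <- g[, 1] + transform$translation_m[1]
  gy <- g[, 2] + transform$translation_m[2]
  data.frame(lon = transform$lon0 + gx / transform$m_per_deg_lon,
             lat = transform$lat0 + gy / transform$m_per_deg_lat)
}

#' Construct a flight segment
#'
#' A flight segment is an ordered series of positional fixes that can be
#' unambiguously attributed to one flight by one individual. It need not be
#' a complete record of the flight: the radar loses bees that fly too high
#' or low, land, or enter radar shadow.
#'
#' @param segment_id segment label.
#' @param fixes data frame with columns `t` (seconds, strictly increasing)
#'   and either `x`, `y` (local metres) or `range_m`, `azimuth_deg`
#'   (converted on construction). At least 2 fixes.
#' @param drone_id,hive_id optional identity labels.
#' @param year optional integer year.
#' @param flag one of `"complete_flight"`, `"outbound_only"`,
#'   `"return_only"`, `"unassigned"`.
#' @param start_time optional absolute datetime of the first fix (used for
#'   hive active-interval checks).
#' @param validate check invariants (default TRUE).
#' @return An object of class `flight_segment` whose `$fixes` carry both
#'   Cartesian and polar coordinates.
#' @export
flight_segment <- function(segment_id, fixes, drone_id = NA_character_,
                           hive_id = NA_character_, year = NA_integer_,
                           flag = "unassigned", start_time = NULL,
                           validate = TRUE) {
  fixes <- as.data.frame(fixes)
  has_xy <- all(c("x", "y") %in% names(fixes))
  has_polar <- all(c("range_m", "azimuth_deg") %in% names(fixes))
  if (!has_xy && !has_polar) {
    stop("fixes need either (x, y) or (range_m, azimuth_deg) columns")
  }
  if (!has_xy) {
    if (any(fixes$azimuth_deg < 0 | fixes$azimuth_deg >= 360, na.rm = TRUE)) {
      stop("azimuth must lie in [0, 360): segment ", segment_id)
    }
    xy <- polar_to_local(fixes$range_m, fixes$azimuth_deg)
    fixes$x <- xy$x
    fixes$y <- xy$y
  }
  if (!has_polar) {
    pol <- local_to_polar(fixes$x, fixes$y)
    fixes$range_m <- pol$range_m
    fixes$azimuth_deg <- pol$azimuth_deg
  }
  if (validate) {
    if (nrow(fixes) < 2) stop("segment ", segment_id, " has fewer than 2 fixes")
    if (!"t" %in% names(fixes)) stop("fixes need a time column t")
    if (any(diff(fixes$t) <= 0)) {
      stop("times must be strictly increasing within segment ", segment_id)
    }
  }
  structure(
    list(segment_id = as.character(segment_id), drone_id = drone_id,
         hive_id = hive_id, year = year, flag = flag,
         start_time = start_time,
         fixes = fixes[order(fixes$t), , drop = FALSE]),
    class = "flight_segment"
  )
}

#' @export
print.flight_segment <- function(x, ...) {
  cat(sprintf("<flight_segment %s> %d fixes over %.1f s\n",
              x$segment_id, nrow(x$fixes), diff(range(x$fixes$t))))
  invisible(x)
}

#' Read flight segments from a delimited track file
#'
#' Expects a CSV with columns `segment_id`, `t` and either `x`, `y` (local
#' metres) or `range_m`, `azimuth_deg`; optional identity columns
#' `drone_id`, `hive_id`, `year`, `flag`. Polar records are converted to
#' local Cartesian coordinates on ingestion.
#'
#' @param path path to the CSV file.
#' @param site optional [site_config()]; when given, fixes beyond
#'   `max_range_m` (+ 5 m tolerance) raise a validation error.
#' @return A list of [flight_segment()] objects, one per distinct
#'   `segment_id`, fixes sorted by time.
#' @export
read_tracks <- function(path, site = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("segment_id", "t") %in% names(df))) {
    stop("track file must have segment_id and t columns")
  }
  has_xy <- all(c("x", "y") %in% names(df))
  has_polar <- all(c("range_m", "azimuth_deg") %in% names(df))
  if (!has_xy && !has_polar) {
    stop("track file needs either x/y or range_m/azimuth_deg columns")
  }
  segs <- lapply(split(df, df$segment_id), function(d) {
    d <- d[order(d$t), , drop = FALSE]
    if (anyDuplicated(d$t)) {
      stop("duplicate timestamps within segment ", d$segment_id[1])
    }
    flight_segment(
      segment_id = d$segment_id[1],
      fixes = d[, setdiff(names(d), c("segment_id", "drone_id", "hive_id",
                                      "year", "flag")), drop = FALSE],
      drone_id = if ("drone_id" %in% names(d)) as.character(d$drone_id[1]) else NA_character_,
      hive_id = if ("hive_id" %in% names(d)) as.character(d$hive_id[1]) else NA_character_,
      year = if ("year" %in% names(d)) as.integer(d$year[1]) else NA_integer_,
      flag = if ("flag" %in% names(d)) as.character(d$flag[1]) else "unassigned"
    )
  })
  if (!is.null(site)) {
    tol <- 5
    for (s in segs) {
      r2 <- s$fixes$x^2 + s$fixes$y^2
      if (any(r2 > (site$max_range_m + tol)^2)) {
        stop("fixes beyond radar range in segment ", s$segment_id)
      }
    }
  }
  unname(segs[unique(as.character(df$segment_id))])
}

#' Write flight segments to a delimited track file
#'
#' Inverse of [read_tracks()]: one row per fix, with both Cartesian and
#' polar coordinates plus identity columns.
#'
#' @param segments list of [flight_segment()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(segments, path) {
  rows <- lapply(segments, function(s) {
    cbind(data.frame(segment_id = s$segment_id, drone_id = s$drone_id,
                     hive_id = s$hive_id, year = s$year, flag = s$flag,
                     stringsAsFactors = FALSE),
          s$fixes[, c("t", "x", "y", "range_m", "azimuth_deg")])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Export flight segments as GeoJSON LineStrings
#'
#' Each segment becomes one `LineString` feature in WGS84 lon-lat order,
#' using the site's calibrated local-to-geographic transform.
#'
#' @param segments list of [flight_segment()] objects.
#' @param site a [site_config()] carrying radar origin and reference points.
#' @param path output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_tracks_geojson <- function(segments, site, path) {
  tr <- calibrate_geo_transform(site)
  features <- lapply(segments, function(s) {
    ll <- local_to_geographic(s$fixes$x, s$fixes$y, tr)
    list(type = "Feature",
         properties = list(segment_id = s$segment_id, flag = s$flag),
         geometry = list(type = "LineString",
                         coordinates = unname(
                           lapply(seq_len(nrow(ll)),
                                  function(i) c(ll$lon[i], ll$lat[i])))))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

#' Summarise a flight segment
#'
#' Computes duration, the maximum displacement of any fix from the first
#' fix, the mean over consecutive-fix speeds, and whether the segment is
#' *substantial*: lasting at least 30 s with the bee moving at least 15 m
#' from its starting position. Shorter or more local segments are too brief
#' to reveal the character of a flight, though they still carry occupancy
#' evidence for heat maps.
#'
#' @param seg a [flight_segment()].
#' @param min_duration_s,min_displacement_m substantiality thresholds
#'   (defaults 30 s and 15 m, inclusive).
#' @return A one-row data frame: `segment_id`, `n_fixes`, `duration_s`,
#'   `max_displacement_m`, `mean_speed_ms`, `substantial`.
#' @export
summarize_segment <- function(seg, min_duration_s = 30,
                              min_displacement_m = 15) {
  f <- seg$fixes
  duration <- f$t[nrow(f)] - f$t[1]
  disp <- sqrt((f$x - f$x[1])^2 + (f$y - f$y[1])^2)
  dt <- diff(f$t)
  step <- sqrt(diff(f$x)^2 + diff(f$y)^2)
  data.frame(
    segment_id = seg$segment_id,
    n_fixes = nrow(f),
    duration_s = duration,
    max_displacement_m = max(disp),
    mean_speed_ms = mean(step / dt),
    substantial = duration >= min_duration_s && max(disp) >= min_displacement_m,
    stringsAsFactors = FALSE
  )
}

#' Partition segments into substantial and rejected
#'
#' Substantial segments (>= 30 s duration and >= 15 m maximum displacement
#' by default) feed the flight-section classifier and all downstream
#' analyses; rejected segments are retained because they still provide
#' occupancy evidence for heat maps.
#'
#' @param segments list of [flight_segment()] objects.
#' @inheritParams summarize_segment
#' @return A list with elements `kept` and `rejected` (both lists of
#'   segments) and `summary` (per-segment summary table).
#' @export
filter_substantial <- function(segments, min_duration_s = 30,
                               min_displacement_m = 15) {
  if (length(segments) == 0) {
    return(list(kept = list(), rejected = list(),
                summary = data.frame()))
  }
  summ <- do.call(rbind, lapply(segments, summarize_segment,
                                min_duration_s = min_duration_s,
                                min_displacement_m = min_displacement_m))
  list(kept = segments[summ$substantial],
       rejected = segments[!summ$substantial],
       summary = summ)
}
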