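# Landscape occupancy heat maps from a timesliced Brownian bridge model:
# per-transition bridge densities rasterised onto a 5 m grid, summed per
# segment, normalised so the hottest pixel of each segment is 1, then
# aggregated with percentile-based opacity.

#' Grid specification
#'
#' @param origin length-2 numeric: coordinates of the lower-left corner of
#'   pixel (1, 1), in metres.
#' @param pixel_m pixel side length (default 5 m).
#' @param nx,ny pixel counts east and north.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(origin, pixel_m = 5, nx, ny) {
  stopifnot(pixel_m > 0, nx >= 1, ny >= 1)
  structure(list(origin = as.numeric(origin), pixel_m = pixel_m,
                 nx = as.integer(nx), ny = as.integer(ny)),
            class = "grid_spec")
}

#' Grid covering a set of segments
#'
#' @param segments list of [flight_segment()] objects.
#' @param pixel_m pixel size (default 5 m).
#' @param pad_m margin beyond the fix bounding box (default 30 m, several
#'   bridge standard deviations, so the grid effectively covers the
#'   bridge support).
#' @return A [grid_spec()].
#' @export
grid_for_segments <- function(segments, pixel_m = 5, pad_m = 30) {
  xs <- unlist(lapply(segments, function(s) s$fixes$x))
  ys <- unlist(lapply(segments, function(s) s$fixes$y))
  x0 <- floor((min(xs) - pad_m) / pixel_m) * pixel_m
  y0 <- floor((min(ys) - pad_m) / pixel_m) * pixel_m
  grid_spec(origin = c(x0, y0), pixel_m = pixel_m,
            nx = ceiling((max(xs) + pad_m - x0) / pixel_m),
            ny = ceiling((max(ys) + pad_m - y0) / pixel_m))
}

#' Bridge parameters
#'
#' @param timeslices_per_s number of timeslices per second of transition
#'   (default 5).
#' @param sigma_mobility Brownian-bridge diffusion scale in m/sqrt(s). The
#'   default (2 * sqrt(4 / 3) ~ 2.31) makes the bridge standard deviation
#'   at the midpoint of a nominal 3 s inter-fix interval equal 2 m.
#' @param sigma_location positional error standard deviation in metres
#'   (default 2 m, the radar's accuracy).
#' @return An object of class `bridge_params`.
#' @export
bridge_params <- function(timeslices_per_s = 5,
                          sigma_mobility = 2 * sqrt(4 / 3),
                          sigma_location = 2) {
  stopifnot(timeslices_per_s > 0, sigma_mobility > 0, sigma_location > 0)
  structure(list(timeslices_per_s = timeslices_per_s,
                 sigma_mobility = sigma_mobility,
                 sigma_location = sigma_location),
            class = "bridge_params")
}

# per-axis pixel masses of a normal marginal: exact rectangle integration
# (pnorm differences) or density at the pixel centre times pixel width
.axis_mass <- function(mu, sd, origin, pixel_m, npix, method) {
  edges <- origin + pixel_m * (0:npix)
  if (method == "exact") {
    p <- stats::pnorm(edges, mean = mu, sd = sd)
    diff(p)
  } else {
    centers <- origin + pixel_m * (seq_len(npix) - 0.5)
    stats::dnorm(centers, mean = mu, sd = sd) * pixel_m
  }
}

#' Occupancy of one Brownian-bridge transition
#'
#' The interval between two fixes is split into
#' `ceiling((t_b - t_a) * timeslices_per_s)` timeslices. At the fraction
#' `alpha` through the interval the bee's position is modelled as a
#' bivariate Gaussian centred on the linear interpolation of the two fixes
#' with per-axis variance
#' `alpha * (1 - alpha) * (t_b - t_a) * sigma_mobility^2 +
#' sigma_location^2` (Brownian bridge pinned at both fixes, plus
#' positional error). Timeslices are placed at interval midpoints
#' (`alpha = (j - 0.5) / n`). Each timeslice density is integrated per
#' pixel (exactly, via normal CDF differences, by default) and the
#' timeslice rasters are summed, so the total mass of the result is the
#' number of timeslices when the grid covers the support.
#'
#' @param fix_a,fix_b single-row data frames (or lists) with `t`, `x`,
#'   `y`; `t_b > t_a` required.
#' @param spec a [grid_spec()].
#' @param params a [bridge_params()].
#' @param method `"exact"` rectangle integration (default) or `"center"`
#'   density-times-area approximation (faster, small aliasing error when
#'   the bridge sd is below the pixel size).
#' @return An `nx` by `ny` matrix of occupancy mass (rows index east).
#' @export
bridge_occupancy <- function(fix_a, fix_b, spec,
                             params = bridge_params(),
                             method = c("exact", "center")) {
  method <- match.arg(method)
  dt <- fix_b$t - fix_a$t
  if (dt <= 0) stop("fix_b must be later than fix_a")
  nts <- ceiling(dt * params$timeslices_per_s)
  vals <- matrix(0, spec$nx, spec$ny)
  for (j in seq_len(nts)) {
    alpha <- (j - 0.5) / nts
    mu_x <- (1 - alpha) * fix_a$x + alpha * fix_b$x
    mu_y <- (1 - alpha) * fix_a$y + alpha * fix_b$y
    s <- sqrt(alpha * (1 - alpha) * dt * params$sigma_mobility^2 +
                params$sigma_location^2)
    # restrict to pixels within 6 sd of the slice centre
    i0 <- max(1L, floor((mu_x - 6 * s - spec$origin[1]) / spec$pixel_m) + 1L)
    i1 <- min(spec$nx, ceiling((mu_x + 6 * s - spec$origin[1]) / spec$pixel_m))
    j0 <- max(1L, floor((mu_y - 6 * s - spec$origin[2]) / spec$pixel_m) + 1L)
    j1 <- min(spec$ny, ceiling((mu_y + 6 * s - spec$origin[2]) / spec$pixel_m))
    if (i0 > i1 || j0 > j1) next
    px <- .axis_mass(mu_x, s, spec$origin[1] + (i0 - 1L) * spec$pixel_m,
                     spec$pixel_m, i1 - i0 + 1L, method)
    py <- .axis_mass(mu_y, s, spec$origin[2] + (j0 - 1L) * spec$pixel_m,
                     spec$pixel_m, j1 - j0 + 1L, method)
    vals[i0:i1, j0:j1] <- vals[i0:i1, j0:j1] + outer(px, py)
  }
  vals
}

#' Heat map of one flight segment
#'
#' Sums [bridge_occupancy()] over all consecutive fix pairs of the
#' segment, then normalises so the hottest pixel equals 1. Normalisation
#' stops any single long track from dominating the aggregate map: a
#' hotspot needs multiple segments over the same pixel.
#'
#' @param seg a [flight_segment()].
#' @param spec a [grid_spec()].
#' @param params a [bridge_params()].
#' @param method passed to [bridge_occupancy()].
#' @return An object of class `heat_grid`: list with `spec`, `values`
#'   (max-normalised matrix) and `raw_mass` (total pre-normalisation
#'   mass).
#' @export
segment_heatmap <- function(seg, spec, params = bridge_params(),
                            method = "exact") {
  f <- seg$fixes
  vals <- matrix(0, spec$nx, spec$ny)
  for (i in seq_len(nrow(f) - 1)) {
    vals <- vals + bridge_occupancy(f[i, ], f[i + 1, ], spec, params,
                                    method = method)
  }
  raw <- sum(vals)
  mx <- max(vals)
  if (mx > 0) vals <- vals / mx
  structure(list(spec = spec, values = vals, raw_mass = raw),
            class = "heat_grid")
}

#' Aggregate normalised segment heat maps
#'
#' Sums the per-segment normalised grids pixelwise, giving a count-like
#' estimate of how often each pixel was overflown. Per-pixel opacity is
#' derived from percentiles of the summed values over occupied (nonzero)
#' pixels: fully transparent below the 1st percentile, fully opaque above
#' the 5th, linear in between. Restricting the percentile computation to
#' occupied pixels keeps the vast never-visited background from
#' saturating the opacity ramp.
#'
#' @param grids list of `heat_grid` objects sharing one [grid_spec()].
#' @param lower_pctl,upper_pctl opacity percentiles (defaults 1 and 5).
#' @return A `heat_grid` with summed `values` and an `alpha` matrix in
#'   `[0, 1]`.
#' @export
aggregate_heatmaps <- function(grids, lower_pctl = 1, upper_pctl = 5) {
  stopifnot(length(grids) >= 1)
  spec <- grids[[1]]$spec
  for (g in grids) {
    if (!identical(g$spec, spec)) stop("grids must share one grid_spec")
  }
  vals <- Reduce(`+`, lapply(grids, `[[`, "values"))
  nz <- vals[vals > 0]
  if (length(nz)) {
    q <- stats::quantile(nz, c(lower_pctl, upper_pctl) / 100, names = FALSE)
    if (q[2] > q[1]) {
      alpha <- pmin(pmax((vals - q[1]) / (q[2] - q[1]), 0), 1)
    } else {
      alpha <- ifelse(vals >= q[1], 1, 0)
    }
    alpha[vals == 0] <- 0
  } else {
    alpha <- matrix(0, spec$nx, spec$ny)
  }
  structure(list(spec = spec, values = vals, alpha = alpha),
            class = "heat_grid")
}

#' @export
print.heat_grid <- function(x, ...) {
  cat(sprintf("<heat_grid> %d x %d pixels of %g m; max %.3g\n",
              x$spec$nx, x$spec$ny, x$spec$pixel_m, max(x$values)))
  invisible(x)
}

#' Write a heat grid as CSV matrix plus world file
#'
#' The CSV holds the value matrix (rows = northing, top row northmost,
#' like an image); the `.wld` world file georeferences it for GIS import.
#'
#' @param grid a `heat_grid`.
#' @param path output `.csv` path; the world file gets extension `.wld`.
#' @return `path`, invisibly.
#' @export
write_heatgrid <- function(grid, path) {
  m <- t(grid$values)[grid$spec$ny:1, , drop = FALSE]
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  wld <- sub("\\.[^.]*$", ".wld", path)
  ctr_top <- grid$spec$origin[2] + (grid$spec$ny - 0.5) * grid$spec$pixel_m
  writeLines(as.character(c(grid$spec$pixel_m, 0, 0, -grid$spec$pixel_m,
                            grid$spec$origin[1] + grid$spec$pixel_m / 2,
                            ctr_top)), wld)
  invisible(path)
}

#' Render a heat grid to PNG
#'
#' Simple raster rendering with a heat colormap and the per-pixel alpha
#' channel (requires an aggregated grid).
#'
#' @param grid a `heat_grid` with `alpha`.
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
render_heatmap_png <- function(grid, path) {
  grDevices::png(path, width = grid$spec$nx * 2, height = grid$spec$ny * 2)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({
    graphics::par(op)
    grDevices::dev.off()
  })
  v <- grid$values / max(grid$values, 1e-300)
  cols <- grDevices::hcl.colors(256, "Inferno")
  idx <- pmin(256L, 1L + floor(v * 255))
  a <- if (is.null(grid$alpha)) matrix(1, nrow(v), ncol(v)) else grid$alpha
  rgba <- grDevices::col2rgb(cols[idx])
  img <- array(0, dim = c(grid$spec$ny, grid$spec$nx, 4))
  for (k in 1:3) {
    img[, , k] <- t(matrix(rgba[k, ], nrow(v), ncol(v)))[grid$spec$ny:1, ] / 255
  }
  img[, , 4] <- t(a)[grid$spec$ny:1, ]
  graphics::plot.new()
  graphics::rasterImage(img, 0, 0, 1, 1, interpolate = FALSE)
  invisible(path)
}
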