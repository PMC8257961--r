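# Discovery of candidate drone congregation areas: collect convoluted
# fixes away from hives, cluster them, retain well-supported clusters.

#' Clustering parameters
#'
#' @param hive_exclusion_m convoluted sections whose centre of mass lies
#'   within this distance of a hive are excluded (default 50 m; a section
#'   exactly at the boundary is excluded, the rule being "greater than").
#' @param linkage_cutoff_m agglomerative clustering cutoff distance in
#'   metres (default 8).
#' @param min_segments minimum number of distinct flight segments that
#'   must contribute fixes for a cluster to count as a congregation
#'   (default 10).
#' @param linkage linkage criterion: `"single"` (default; a distance
#'   cutoff then yields the connected components of the <= cutoff
#'   adjacency graph), `"complete"` or `"average"`.
#' @param hive_mode `"active"` excludes around hives active at the time of
#'   the flight (falling back to all hives when no dates are available);
#'   `"any"` excludes around every hive regardless of dates.
#' @return An object of class `cluster_params`.
#' @export
cluster_params <- function(hive_exclusion_m = 50, linkage_cutoff_m = 8,
                           min_segments = 10, linkage = "single",
                           hive_mode = c("active", "any")) {
  stopifnot(hive_exclusion_m > 0, linkage_cutoff_m > 0, min_segments > 0)
  linkage <- match.arg(linkage, c("single", "complete", "average"))
  structure(list(hive_exclusion_m = hive_exclusion_m,
                 linkage_cutoff_m = linkage_cutoff_m,
                 min_segments = min_segments, linkage = linkage,
                 hive_mode = match.arg(hive_mode)),
            class = "cluster_params")
}

#' Collect convoluted-flight fixes away from hives
#'
#' Gathers every fix belonging to a convoluted section whose centre of
#' mass lies more than `hive_exclusion_m` from every (active) hive. The
#' hive exclusion reflects that looping flight immediately around a hive
#' is hive-related behaviour rather than congregation activity.
#'
#' @param segments list of [flight_segment()] objects.
#' @param sections combined section table from [classify_all()].
#' @param site a [site_config()] (its hives are used for exclusion).
#' @param params a [cluster_params()].
#' @return A data frame of fixes: `segment_id`, `section_id`, `fix_idx`,
#'   `x`, `y`.
#' @export
collect_convoluted_fixes <- function(segments, sections, site,
                                     params = cluster_params()) {
  conv <- sections[sections$label == "convoluted", , drop = FALSE]
  if (nrow(conv) == 0) {
    return(data.frame(segment_id = character(), section_id = character(),
                      fix_idx = integer(), x = numeric(), y = numeric()))
  }
  seg_map <- stats::setNames(segments,
                             vapply(segments, `[[`, "", "segment_id"))
  keep <- vapply(seq_len(nrow(conv)), function(i) {
    seg <- seg_map[[conv$segment_id[i]]]
    hv <- .hives_for_segment(seg, site, params$hive_mode)
    if (nrow(hv) == 0) return(TRUE)
    d <- sqrt((hv$x - conv$com_x[i])^2 + (hv$y - conv$com_y[i])^2)
    all(d > params$hive_exclusion_m)
  }, logical(1))
  conv <- conv[keep, , drop = FALSE]
  if (nrow(conv) == 0) {
    return(data.frame(segment_id = character(), section_id = character(),
                      fix_idx = integer(), x = numeric(), y = numeric()))
  }
  out <- lapply(seq_len(nrow(conv)), function(i) {
    seg <- seg_map[[conv$segment_id[i]]]
    idx <- conv$start_idx[i]:conv$end_idx[i]
    data.frame(segment_id = conv$segment_id[i],
               section_id = conv$section_id[i],
               fix_idx = idx,
               x = seg$fixes$x[idx], y = seg$fixes$y[idx],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# hives considered for exclusion around one segment
.hives_for_segment <- function(seg, site, hive_mode) {
  hv <- site$hives
  if (hive_mode == "any" || is.null(seg$start_time)) return(hv)
  t0 <- .as_time(seg$start_time)
  active <- (is.na(hv$active_start) | hv$active_start <= t0) &
    (is.na(hv$active_end) | hv$active_end >= t0)
  hv[active, , drop = FALSE]
}

#' Cluster points by agglomerative clustering with a distance cutoff
#'
#' Single-linkage clustering cut at `linkage_cutoff_m` assigns two points
#' to the same cluster exactly when they are connected by a chain of steps
#' each no longer than the cutoff (the connected components of the
#' <= cutoff adjacency graph).
#'
#' @param points data frame or matrix with columns `x`, `y`.
#' @param params a [cluster_params()].
#' @return Integer cluster assignment, one per point (empty input yields
#'   an empty vector).
#' @export
cluster_fixes <- function(points, params = cluster_params()) {
  points <- as.data.frame(points)
  n <- nrow(points)
  if (n == 0) return(integer(0))
  if (n == 1) return(1L)
  hc <- stats::hclust(stats::dist(points[, c("x", "y")]),
                      method = params$linkage)
  unname(stats::cutree(hc, h = params$linkage_cutoff_m))
}

#' Select congregations from a clustering
#'
#' A clustering routine must assign every fix to some cluster, and most
#' clusters are small scraps of single flights. Only clusters supported by
#' at least `min_segments` distinct flight segments are retained as
#' candidate congregation areas, labelled `A`, `B`, ... in decreasing
#' order of contributing segments. Each keeps its centre of mass (the mean
#' coordinates of its member fixes, robust to a few perimeter points) and
#' the convex hull of its member fixes (an illustrative boundary only).
#'
#' @param fixes fix table from [collect_convoluted_fixes()].
#' @param assignment integer vector from [cluster_fixes()] on those fixes.
#' @param params a [cluster_params()].
#' @return A list of congregation objects, each a list with `area_id`,
#'   `center` (length-2 numeric), `hull` (matrix of vertex coordinates),
#'   `members` (row indices into `fixes`), `n_segments`, `n_fixes`.
#' @export
select_congregations <- function(fixes, assignment,
                                 params = cluster_params()) {
  stopifnot(nrow(fixes) == length(assignment))
  if (nrow(fixes) == 0) return(list())
  support <- tapply(fixes$segment_id, assignment,
                    function(s) length(unique(s)))
  keep <- names(support)[support >= params$min_segments]
  if (length(keep) == 0) return(list())
  keep <- keep[order(support[keep], decreasing = TRUE)]
  out <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    members <- which(assignment == as.integer(keep[i]))
    pts <- cbind(fixes$x[members], fixes$y[members])
    hull <- pts[grDevices::chull(pts), , drop = FALSE]
    out[[i]] <- list(
      area_id = LETTERS[i],
      center = c(x = mean(pts[, 1]), y = mean(pts[, 2])),
      hull = hull,
      members = members,
      n_segments = length(unique(fixes$segment_id[members])),
      n_fixes = length(members)
    )
  }
  out
}

#' Discover drone congregation areas
#'
#' End-to-end lek discovery: collect convoluted fixes away from hives,
#' cluster them, and retain well-supported clusters.
#'
#' @inheritParams collect_convoluted_fixes
#' @return A list of congregations (see [select_congregations()]).
#' @export
find_congregations <- function(segments, sections, site,
                               params = cluster_params()) {
  fixes <- collect_convoluted_fixes(segments, sections, site, params)
  if (nrow(fixes) == 0) return(list())
  assignment <- cluster_fixes(fixes, params)
  select_congregations(fixes, assignment, params)
}

#' Congregation table
#'
#' @param areas list of congregations from [select_congregations()].
#' @return Data frame: `area_id`, `center_x`, `center_y`, `n_segments`,
#'   `n_fixes`.
#' @export
congregations_table <- function(areas) {
  if (length(areas) == 0) {
    return(data.frame(area_id = character(), center_x = numeric(),
                      center_y = numeric(), n_segments = integer(),
                      n_fixes = integer()))
  }
  do.call(rbind, lapply(areas, function(a) {
    data.frame(area_id = a$area_id, center_x = a$center["x"],
               center_y = a$center["y"], n_segments = a$n_segments,
               n_fixes = a$n_fixes, row.names = NULL,
               stringsAsFactors = FALSE)
  }))
}

#' Export congregation hulls as GeoJSON polygons
#'
#' @param areas list of congregations.
#' @param site a [site_config()] with geographic calibration.
#' @param path output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_congregations_geojson <- function(areas, site, path) {
  tr <- calibrate_geo_transform(site)
  features <- lapply(areas, function(a) {
    hull <- rbind(a$hull, a$hull[1, , drop = FALSE])  # closed ring
    ll <- local_to_geographic(hull[, 1], hull[, 2], tr)
    list(type = "Feature",
         properties = list(area_id = a$area_id,
                           n_segments = a$n_segments),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(
                           lapply(seq_len(nrow(ll)),
                                  function(i) c(ll$lon[i], ll$lat[i]))))))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
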