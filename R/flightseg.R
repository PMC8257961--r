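# Classification of flight segments into straight and convoluted sections
# by the moving-window resultant-vector-length algorithm.

#' Classifier parameters
#'
#' Defaults reproduce the standard analysis settings: a moving 21 s window
#' (seven radar rotations at the nominal 3 s sampling), a resultant vector
#' length threshold of 0.7, gap severing for transitions longer than 12 s
#' over which the bee moved more than 40 m, and a minimum convoluted run of
#' 7 temporally consecutive fixes.
#'
#' @param window_s moving window length in seconds (> 0).
#' @param r_threshold resultant-vector-length threshold in `[0, 1]`; a fix
#'   covered by any window with R above this is a straight candidate.
#' @param max_gap_s,max_gap_m a transition with `gap > max_gap_s` **and**
#'   `step > max_gap_m` cannot be interior to a convoluted section. Set
#'   either to `Inf` to disable severing.
#' @param min_run minimum number of temporally consecutive fixes in a
#'   convoluted section (>= 2).
#' @return An object of class `classifier_params`.
#' @export
classifier_params <- function(window_s = 21, r_threshold = 0.7,
                              max_gap_s = 12, max_gap_m = 40,
                              min_run = 7) {
  stopifnot(window_s > 0, r_threshold >= 0, r_threshold <= 1, min_run >= 2)
  structure(list(window_s = window_s, r_threshold = r_threshold,
                 max_gap_s = max_gap_s, max_gap_m = max_gap_m,
                 min_run = min_run),
            class = "classifier_params")
}

#' Bearings of the transitions between consecutive fixes
#'
#' Each consecutive fix pair yields a transition with a bearing measured
#' clockwise from north (`atan2(dx, dy)`), a midpoint time, the time gap
#' and the step length. Zero-displacement transitions have an undefined
#' (`NA`) bearing and are excluded from window statistics.
#'
#' @param seg a [flight_segment()] (>= 2 fixes).
#' @return A data frame with one row per transition: `t_mid`, `bearing`
#'   (radians, `NA` if undefined), `gap_s`, `step_m`.
#' @export
transition_bearings <- function(seg) {
  f <- seg$fixes
  n <- nrow(f)
  if (n < 2) stop("segment must have at least 2 fixes")
  dx <- diff(f$x)
  dy <- diff(f$y)
  step <- sqrt(dx^2 + dy^2)
  bearing <- atan2(dx, dy)
  bearing[step == 0] <- NA_real_
  data.frame(t_mid = (f$t[-n] + f$t[-1]) / 2,
             bearing = bearing,
             gap_s = diff(f$t),
             step_m = step)
}

#' Resultant vector length of bearings in a window
#'
#' The resultant vector length R of a set of bearings is the modulus of
#' their mean unit vector: 1 for perfectly aligned bearings, 0 for balanced
#' dispersion. The window is centred at `t_anchor` and collects transitions
#' whose midpoint lies within `window_s / 2` of it.
#'
#' @param bearings data frame from [transition_bearings()].
#' @param t_anchor centre of the window (seconds).
#' @param params a [classifier_params()].
#' @return R in `[0, 1]`, or `NA` when the window holds fewer than 2
#'   defined bearings (such a window cannot certify straightness).
#' @export
window_resultant <- function(bearings, t_anchor, params = classifier_params()) {
  half <- params$window_s / 2
  in_win <- bearings$t_mid >= t_anchor - half & bearings$t_mid <= t_anchor + half
  th <- bearings$bearing[in_win]
  th <- th[!is.na(th)]
  if (length(th) < 2) return(NA_real_)
  sqrt(sum(sin(th))^2 + sum(cos(th))^2) / length(th)
}

#' Classify a flight segment into straight and convoluted sections
#'
#' Implements the moving-window resultant-vector-length algorithm:
#' \enumerate{
#'   \item For every fix, a 21 s window is centred on the fix time and the
#'     resultant vector length R of the transition bearings falling in the
#'     window is computed. A fix covered by any window with
#'     `R > r_threshold` is a straight candidate; all other fixes are
#'     convoluted candidates. The test is scale free: it assumes nothing
#'     about convoluted flight beyond inconsistent direction.
#'   \item Transitions with a gap longer than `max_gap_s` over which the
#'     bee moved more than `max_gap_m` sever convoluted runs, preventing
#'     geographically and temporally separate flight from merging into one
#'     convoluted section across a detection dropout.
#'   \item Maximal convoluted-candidate runs with at least `min_run` fixes
#'     become convoluted sections; shorter runs are relabelled straight.
#'   \item The remaining fixes form straight sections (severing gaps also
#'     delimit straight sections so that a section never spans a long
#'     dropout).
#' }
#'
#' @param seg a [flight_segment()].
#' @param params a [classifier_params()].
#' @return A data frame of sections, one row each: `segment_id`,
#'   `section_id`, `label` (`"straight"`/`"convoluted"`), `start_idx`,
#'   `end_idx` (fix index range, inclusive), `n_fixes`, `t_start`, `t_end`,
#'   `duration_s`, `com_x`, `com_y` (centre of mass), `mean_speed_ms`.
#' @export
classify_sections <- function(seg, params = classifier_params()) {
  f <- seg$fixes
  n <- nrow(f)
  tb <- transition_bearings(seg)

  if (f$t[n] - f$t[1] < params$window_s) {
    warning("segment ", seg$segment_id,
            " shorter than one window; labelled straight")
    straight <- rep(TRUE, n)
  } else {
    # windows centred at every fix time; a window with R > threshold
    # certifies every fix incident to a transition inside it as straight
    straight <- rep(FALSE, n)
    half <- params$window_s / 2
    for (k in seq_len(n)) {
      in_win <- tb$t_mid >= f$t[k] - half & tb$t_mid <= f$t[k] + half
      th <- tb$bearing[in_win]
      th <- th[!is.na(th)]
      if (length(th) < 2) next
      R <- sqrt(sum(sin(th))^2 + sum(cos(th))^2) / length(th)
      if (R > params$r_threshold) {
        idx <- which(in_win)
        straight[unique(c(idx, idx + 1L))] <- TRUE
      }
    }
  }

  sever <- tb$gap_s > params$max_gap_s & tb$step_m > params$max_gap_m

  # maximal convoluted-candidate runs, severed at flagged transitions
  conv <- !straight
  run_id <- integer(n)
  current <- 0L
  for (i in seq_len(n)) {
    if (!conv[i]) {
      run_id[i] <- 0L
      next
    }
    new_run <- i == 1L || !conv[i - 1L] || sever[i - 1L]
    if (new_run) current <- current + 1L
    run_id[i] <- current
  }
  for (r in setdiff(unique(run_id), 0L)) {
    if (sum(run_id == r) < params$min_run) conv[run_id == r] <- FALSE
  }

  # partition fixes into sections: label changes and severing gaps both
  # start a new section
  brk <- logical(n)
  brk[1] <- TRUE
  for (i in 2:n) {
    brk[i] <- conv[i] != conv[i - 1L] || sever[i - 1L]
  }
  sec_id <- cumsum(brk)

  out <- lapply(unique(sec_id), function(s) {
    idx <- which(sec_id == s)
    fi <- f[idx, , drop = FALSE]
    dt <- diff(fi$t)
    step <- sqrt(diff(fi$x)^2 + diff(fi$y)^2)
    data.frame(
      segment_id = seg$segment_id,
      section_id = paste0(seg$segment_id, "_s", s),
      label = if (conv[idx[1]]) "convoluted" else "straight",
      start_idx = idx[1], end_idx = idx[length(idx)],
      n_fixes = length(idx),
      t_start = fi$t[1], t_end = fi$t[nrow(fi)],
      duration_s = fi$t[nrow(fi)] - fi$t[1],
      com_x = mean(fi$x), com_y = mean(fi$y),
      mean_speed_ms = if (length(idx) > 1) mean(step / dt) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Classify many segments
#'
#' @param segments list of [flight_segment()] objects.
#' @param params a [classifier_params()].
#' @return Combined section table (see [classify_sections()]).
#' @export
classify_all <- function(segments, params = classifier_params()) {
  do.call(rbind, lapply(segments, classify_sections, params = params))
}

#' Per-fix labels from a section table
#'
#' @param sections section table for one segment.
#' @param n_fixes number of fixes in the segment.
#' @return Character vector of `"straight"`/`"convoluted"`, one per fix.
#' @export
section_labels <- function(sections, n_fixes) {
  lab <- character(n_fixes)
  for (i in seq_len(nrow(sections))) {
    lab[sections$start_idx[i]:sections$end_idx[i]] <- sections$label[i]
  }
  lab
}

#' Tabulate sections with dataset-level aggregates
#'
#' @param sections combined section table from [classify_all()].
#' @return A list with `sections` (the table) and `aggregates`:
#'   `n_convoluted_sections`, `n_flights_with_convoluted` (flights with at
#'   least one convoluted section), `n_flights_multi_convoluted` (at least
#'   two), `mean_convoluted_duration_s`, and
#'   `mean_fraction_time_convoluted` (mean, over flights containing any
#'   convoluted flight, of the fraction of flight duration spent in
#'   convoluted sections).
#' @export
sections_table <- function(sections) {
  if (is.null(sections) || nrow(sections) == 0) {
    return(list(sections = data.frame(),
                aggregates = list(n_convoluted_sections = 0L,
                                  n_flights_with_convoluted = 0L,
                                  n_flights_multi_convoluted = 0L,
                                  mean_convoluted_duration_s = NA_real_,
                                  mean_fraction_time_convoluted = NA_real_)))
  }
  conv <- sections[sections$label == "convoluted", , drop = FALSE]
  per_flight <- table(conv$segment_id)
  frac <- vapply(names(per_flight), function(sid) {
    s <- sections[sections$segment_id == sid, , drop = FALSE]
    tot <- sum(s$duration_s)
    if (tot <= 0) return(NA_real_)
    sum(s$duration_s[s$label == "convoluted"]) / tot
  }, numeric(1))
  list(
    sections = sections,
    aggregates = list(
      n_convoluted_sections = nrow(conv),
      n_flights_with_convoluted = length(per_flight),
      n_flights_multi_convoluted = sum(per_flight >= 2),
      mean_convoluted_duration_s = if (nrow(conv)) mean(conv$duration_s) else NA_real_,
      mean_fraction_time_convoluted = if (length(frac)) mean(frac, na.rm = TRUE) else NA_real_
    )
  )
}
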