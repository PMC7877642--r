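#' Detection configuration
#'
#' Tunable parameters of the contraction detector. Defaults are anchored to
#' the smallest events reported for this preparation type (7.7% relative
#' amplitude, 1.7 s duration) and to the classification thresholds: standing
#' contractions propagate at most 1.0 mm, ripples have a path-linearity
#' R-squared of at least 0.8.
#'
#' @param min_amplitude_frac minimal relative constriction
#'   (baseline - diameter)/baseline for a pixel to enter the event mask.
#' @param min_duration_s events spanning less time are discarded.
#' @param baseline_window_s length of the rolling window used for the
#'   baseline (resting width) estimate.
#' @param baseline_prob quantile used as the rolling upper envelope.
#' @param standing_distance_mm propagation distance at or under which an
#'   event is a standing contraction.
#' @param ripple_r2 R-squared boundary between ripples (>=) and slow
#'   propulsive contractions (<).
#' @param gap_merge_frames components separated by at most this many frames
#'   at the same positions are merged.
#' @return a list of class `detection_config`.
#' @export
detection_config <- function(min_amplitude_frac = 0.07, min_duration_s = 1.7,
                             baseline_window_s = 120, baseline_prob = 0.95,
                             standing_distance_mm = 1.0, ripple_r2 = 0.8,
                             gap_merge_frames = 1L) {
  if (!(min_amplitude_frac > 0 && min_amplitude_frac < 1))
    stop("min_amplitude_frac must be in (0, 1)", call. = FALSE)
  if (any(c(min_duration_s, baseline_window_s, standing_distance_mm,
            ripple_r2) <= 0))
    stop("detection thresholds must be positive", call. = FALSE)
  if (gap_merge_frames < 0) stop("gap_merge_frames must be >= 0", call. = FALSE)
  structure(list(min_amplitude_frac = min_amplitude_frac,
                 min_duration_s = min_duration_s,
                 baseline_window_s = baseline_window_s,
                 baseline_prob = baseline_prob,
                 standing_distance_mm = standing_distance_mm,
                 ripple_r2 = ripple_r2,
                 gap_merge_frames = as.integer(gap_merge_frames)),
            class = "detection_config")
}

#' Rolling baseline (resting width) estimate
#'
#' Per position, the rolling upper envelope (95th percentile by default) of
#' the diameter series over a centred window. The envelope rides above the
#' transient constrictions and tracks slow drift such as bolus distension,
#' so that amplitudes can be expressed relative to the local resting width.
#'
#' @inheritParams frame_times
#' @param cfg a [detection_config()].
#' @return numeric matrix, same shape as `dm$values` (mm).
#' @export
estimate_baseline <- function(dm, cfg = detection_config()) {
  k <- round(cfg$baseline_window_s / dm$frame_interval_s)
  if (k < 3)
    stop("baseline window must cover at least 3 frames", call. = FALSE)
  k <- min(k, ncol(dm$values))
  .roll_quantile_rows(dm$values, as.integer(k), cfg$baseline_prob)
}

#' Detect raw contraction events
#'
#' Thresholds the relative constriction field at `min_amplitude_frac`,
#' labels 8-connected components (merging components separated by at most
#' `gap_merge_frames` at the same positions), discards components shorter
#' than `min_duration_s`, and extracts for each surviving component its
#' per-frame constriction path (the position of minimal diameter within the
#' component; ties resolved to the smallest position index).
#'
#' @inheritParams estimate_baseline
#' @param baseline optional precomputed [estimate_baseline()] matrix.
#' @return A list of raw events; each has `frames` (column indices),
#'   `onset_s`, `end_s`, `duration_s`, `path_mm` / `path_t_s` (per-frame
#'   constriction position and time), `amplitude_frac` (event-wise maximal
#'   relative constriction) and `n_pixels`. An empty list when nothing
#'   crosses the threshold.
#' @export
detect_events <- function(dm, cfg = detection_config(), baseline = NULL) {
  if (is.null(baseline)) baseline <- estimate_baseline(dm, cfg)
  rel <- (baseline - dm$values) / baseline
  mask <- rel >= cfg$min_amplitude_frac
  if (!any(mask)) return(list())
  lab <- .label_events(mask, cfg$gap_merge_frames)
  n_ev <- max(lab)
  pos <- positions_mm(dm)
  tms <- frame_times(dm)
  dt <- dm$frame_interval_s
  min_frames <- ceiling(cfg$min_duration_s / dt - 1e-9)

  events <- vector("list", n_ev)
  keep <- logical(n_ev)
  idx <- which(lab > 0)
  ev_of <- lab[idx]
  row_i <- (idx - 1L) %% nrow(lab) + 1L
  col_j <- (idx - 1L) %/% nrow(lab) + 1L
  ord <- order(ev_of, col_j, row_i)
  idx <- idx[ord]; ev_of <- ev_of[ord]; row_i <- row_i[ord]; col_j <- col_j[ord]
  split_at <- c(0L, cumsum(tabulate(ev_of, n_ev)))

  for (e in seq_len(n_ev)) {
    sel <- (split_at[e] + 1L):split_at[e + 1L]
    rows <- row_i[sel]; cols <- col_j[sel]
    frames <- unique(cols)                      # already sorted
    if (length(frames) < min_frames) next
    vals <- dm$values[cbind(rows, cols)]
    # per-frame argmin of diameter; ties -> smallest position index
    o <- order(cols, vals, rows)
    first_of_frame <- !duplicated(cols[o])
    path_rows <- rows[o][first_of_frame]
    path_frames <- cols[o][first_of_frame]
    relv <- rel[cbind(rows, cols)]
    events[[e]] <- list(frames = frames,
                        onset_s = tms[frames[1]],
                        end_s = tms[frames[length(frames)]] + dt,
                        duration_s = length(frames) * dt,
                        path_t_s = tms[path_frames],
                        path_mm = pos[path_rows],
                        amplitude_frac = max(relv),
                        n_pixels = length(sel))
    keep[e] <- TRUE
  }
  events[keep]
}

#' Fit the propagation line of a raw event
#'
#' Ordinary least squares of the constriction-path position (mm, response)
#' on time (s): the absolute slope is the propagation velocity and the
#' coefficient of determination measures path linearity. A perfectly linear
#' path has an R-squared of 1; a path with zero positional variance is
#' returned as slope 0, R-squared `NA` (degenerate, reclassified standing
#' downstream).
#'
#' @param path_t_s,path_mm per-frame path time (s) and position (mm).
#' @return list with `slope_mm_s` and `r_squared`.
#' @export
fit_propagation <- function(path_t_s, path_mm) {
  n <- length(path_t_s)
  if (n < 2 || length(unique(path_t_s)) < 2)
    return(list(slope_mm_s = 0, r_squared = NA_real_))
  fit <- stats::lm.fit(cbind(1, path_t_s), path_mm)
  ss_tot <- sum((path_mm - mean(path_mm))^2)
  if (ss_tot == 0) return(list(slope_mm_s = 0, r_squared = NA_real_))
  r2 <- 1 - sum(fit$residuals^2) / ss_tot
  list(slope_mm_s = unname(fit$coefficients[2]), r_squared = r2)
}

#' Classify a measured event
#'
#' Distance at or under `standing_distance_mm` gives a standing contraction
#' (no direction); otherwise the path-linearity R-squared separates ripples
#' (>= `ripple_r2`) from slow propulsive contractions (<). Direction is the
#' sign of the slope: positive (oral to anal) is anterograde, negative
#' retrograde; an exactly zero slope with a propagating path has no defined
#' direction and is recorded as `"none"`.
#'
#' @param distance_mm propagation distance (max - min of the path).
#' @param fit result of [fit_propagation()].
#' @param cfg a [detection_config()].
#' @return list with `kind` and `direction`.
#' @export
classify_event <- function(distance_mm, fit, cfg = detection_config()) {
  if (distance_mm <= cfg$standing_distance_mm || is.na(fit$r_squared))
    return(list(kind = "standing", direction = "none"))
  kind <- if (fit$r_squared >= cfg$ripple_r2) "ripple" else "slow_propulsive"
  direction <- if (fit$slope_mm_s > 0) "anterograde"
               else if (fit$slope_mm_s < 0) "retrograde" else "none"
  list(kind = kind, direction = direction)
}

.empty_events <- function() {
  empty <- data.frame(event_id = integer(), onset_s = numeric(),
                      end_s = numeric(), duration_s = numeric(),
                      kind = character(), amplitude_pct = numeric(),
                      distance_mm = numeric(), distance_pct = numeric(),
                      slope_mm_s = numeric(), velocity_mm_s = numeric(),
                      r_squared = numeric(), direction = character(),
                      segment = integer(), window = character(),
                      period = character(), preparation_id = character(),
                      treatment = character(), stringsAsFactors = FALSE)
  empty$path <- list()
  empty
}

#' Detect, measure and classify contractions in a diameter matrix
#'
#' Full event-level analysis of one (window of a) diameter matrix: baseline
#' estimation, event detection, propagation fit, classification and
#' per-event measurements.
#'
#' @inheritParams estimate_baseline
#' @param part optional [partition_segments()] result; events are assigned
#'   to the segment containing their path midpoint.
#' @param window optional label attached to all events (analysis window).
#' @param period optional period label ("I"/"II") attached to all events.
#' @return A data frame with one row per event: `event_id`, `onset_s`,
#'   `end_s`, `duration_s`, `kind`, `amplitude_pct`, `distance_mm`,
#'   `distance_pct`, `slope_mm_s`, `velocity_mm_s`, `r_squared`, `direction`,
#'   `segment`, `window`, `period`, `preparation_id`, `treatment`, and a
#'   `path` list column of per-frame `(t_s, pos_mm)` tables.
#' @export
detect_contractions <- function(dm, cfg = detection_config(), part = NULL,
                                baseline = NULL, window = NA_character_,
                                period = NA_character_) {
  raw <- detect_events(dm, cfg, baseline = baseline)
  if (!length(raw)) return(.empty_events())
  rows <- lapply(seq_along(raw), function(i) {
    ev <- raw[[i]]
    distance_mm <- diff(range(ev$path_mm))
    is_propulsive <- distance_mm > cfg$standing_distance_mm
    fit <- if (is_propulsive) fit_propagation(ev$path_t_s, ev$path_mm)
           else list(slope_mm_s = NA_real_, r_squared = NA_real_)
    cls <- if (is_propulsive) classify_event(distance_mm, fit, cfg)
           else list(kind = "standing", direction = "none")
    midpoint <- (min(ev$path_mm) + max(ev$path_mm)) / 2
    data.frame(event_id = i, onset_s = ev$onset_s, end_s = ev$end_s,
               duration_s = ev$duration_s, kind = cls$kind,
               amplitude_pct = 100 * ev$amplitude_frac,
               distance_mm = distance_mm,
               distance_pct = 100 * distance_mm / dm$intestine_length_mm,
               slope_mm_s = if (cls$kind == "standing") NA_real_
                            else fit$slope_mm_s,
               velocity_mm_s = if (cls$kind == "standing") NA_real_
                               else abs(fit$slope_mm_s),
               r_squared = if (cls$kind == "standing") NA_real_
                           else fit$r_squared,
               direction = cls$direction,
               segment = if (is.null(part)) NA_integer_
                         else segment_of(part, midpoint),
               window = window, period = period,
               preparation_id = dm$preparation_id, treatment = dm$treatment,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$path <- lapply(raw, function(ev)
    data.frame(t_s = ev$path_t_s, pos_mm = ev$path_mm))
  rownames(out) <- NULL
  out
}
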