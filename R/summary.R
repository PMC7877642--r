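#' Contraction frequency in cpm per mm
#'
#' The study's frequency unit: contractions per minute and per mm of gut
#' length, computed from the total number of contractions within the
#' analysed sub-period windows of one segment.
#'
#' @param n_events number of contractions counted (or an event data frame,
#'   in which case its row count is used).
#' @param windows a [select_subperiods()] result or a data frame with
#'   `start_s`/`end_s` columns; its summed duration is the analysed time.
#' @param segment_length_mm length of the segment the events were counted in.
#' @return frequency in contractions min^-1 mm^-1.
#' @export
compute_frequency <- function(n_events, windows, segment_length_mm) {
  if (is.data.frame(n_events)) n_events <- nrow(n_events)
  minutes <- sum((windows$end_s - windows$start_s) / 60)
  if (!length(minutes) || minutes <= 0)
    stop("analysed time must be positive", call. = FALSE)
  if (!(segment_length_mm > 0))
    stop("segment length must be positive", call. = FALSE)
  n_events / (minutes * segment_length_mm)
}

.kinds <- c("standing", "ripple", "slow_propulsive")

#' Summarize motility parameters per segment, period and contraction type
#'
#' Aggregates detected events over one or more preparations into the study's
#' motility parameters: per (treatment, segment, period, kind) cell the
#' event count, frequency (cpm per mm; group mean and sd over
#' per-preparation values), pooled median / min / max of amplitude, duration,
#' distance and velocity, and the anterograde proportion among directed
#' propulsive events (group mean and sd over per-preparation proportions).
#' Empty cells have zero counts and missing (NA) medians.
#'
#' @param events event data frame from [detect_contractions()] (rows from
#'   several preparations may be concatenated); must carry `segment`,
#'   `period`, `kind`, `direction` and `preparation_id`.
#' @param preparations data frame describing the analysed preparations, one
#'   row each: `preparation_id`, `treatment`, `minutes_I`, `minutes_II`
#'   (analysed minutes per period) and `seg1_mm` .. `seg4_mm` (segment
#'   lengths).
#' @return An object of class `motility_summary`: a data frame with one row
#'   per (treatment, segment, period, kind) cell.
#' @export
summarize_motility <- function(events, preparations) {
  req <- c("preparation_id", "treatment", "minutes_I", "minutes_II",
           paste0("seg", 1:4, "_mm"))
  if (!all(req %in% names(preparations)))
    stop("preparations must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  cells <- expand.grid(treatment = unique(preparations$treatment),
                       segment = 1:4, period = c("I", "II"),
                       kind = .kinds, stringsAsFactors = FALSE)
  cells <- cells[order(cells$treatment, cells$segment, cells$period,
                       cells$kind), ]
  out <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    preps <- preparations[preparations$treatment == cell$treatment, ]
    ev <- events[!is.na(events$segment) &
                 events$segment == cell$segment &
                 events$period == cell$period &
                 events$kind == cell$kind &
                 events$preparation_id %in% preps$preparation_id, ,
                 drop = FALSE]
    seg_len <- preps[[paste0("seg", cell$segment, "_mm")]]
    minutes <- preps[[paste0("minutes_", cell$period)]]
    per_prep_freq <- vapply(seq_len(nrow(preps)), function(p) {
      if (minutes[p] <= 0) return(NA_real_)
      n <- sum(ev$preparation_id == preps$preparation_id[p])
      n / (minutes[p] * seg_len[p])
    }, 0.0)
    n_dir <- table(factor(ev$direction,
                          levels = c("anterograde", "retrograde", "none")))
    per_prep_prop <- vapply(seq_len(nrow(preps)), function(p) {
      d <- ev$direction[ev$preparation_id == preps$preparation_id[p]]
      n_a <- sum(d == "anterograde"); n_r <- sum(d == "retrograde")
      if (n_a + n_r == 0) NA_real_ else n_a / (n_a + n_r)
    }, 0.0)
    med <- function(x) if (length(x) && any(!is.na(x)))
      stats::median(x, na.rm = TRUE) else NA_real_
    lim <- function(x, f) if (length(x) && any(!is.na(x)))
      f(x, na.rm = TRUE) else NA_real_
    data.frame(cell,
               n_events = nrow(ev),
               n_anterograde = as.integer(n_dir[["anterograde"]]),
               n_retrograde = as.integer(n_dir[["retrograde"]]),
               n_undirected = as.integer(n_dir[["none"]]),
               frequency_cpm_mm = mean(per_prep_freq, na.rm = TRUE),
               frequency_sd = stats::sd(per_prep_freq[!is.na(per_prep_freq)]),
               anterograde_prop = mean(per_prep_prop, na.rm = TRUE),
               anterograde_prop_sd = stats::sd(per_prep_prop[!is.na(per_prep_prop)]),
               amplitude_median = med(ev$amplitude_pct),
               amplitude_min = lim(ev$amplitude_pct, min),
               amplitude_max = lim(ev$amplitude_pct, max),
               duration_median = med(ev$duration_s),
               duration_min = lim(ev$duration_s, min),
               duration_max = lim(ev$duration_s, max),
               distance_pct_median = med(ev$distance_pct),
               velocity_median = med(ev$velocity_mm_s),
               velocity_min = lim(ev$velocity_mm_s, min),
               velocity_max = lim(ev$velocity_mm_s, max),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$frequency_cpm_mm[is.nan(out$frequency_cpm_mm)] <- NA_real_
  out$anterograde_prop[is.nan(out$anterograde_prop)] <- NA_real_
  rownames(out) <- NULL
  class(out) <- c("motility_summary", "data.frame")
  out
}

#' @export
`[.motility_summary` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' @export
print.motility_summary <- function(x, ...) {
  cat(sprintf("<motility_summary> %d cells, %d events total\n",
              nrow(x), sum(x$n_events)))
  shown <- x[x$n_events > 0,
             c("treatment", "segment", "period", "kind", "n_events",
               "frequency_cpm_mm", "amplitude_median", "duration_median",
               "velocity_median", "anterograde_prop")]
  print.data.frame(shown, digits = 3, row.names = FALSE)
  invisible(x)
}
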