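# Shared pipeline core. `provider_bet()` must return the full-span matrix at
# the emptying-time analysis rate; `provider_window(a, b)` a matrix covering
# [a, b) at the motility analysis rate. Both come either from slicing a
# recorded matrix or from rendering a synthetic scenario window on demand.
.analyze_core <- function(provider_bet, provider_window, fractions, cfg,
                          horizon_s) {
  dm_bet <- provider_bet()
  part <- partition_segments(dm_bet, fractions)
  aw1 <- average_width_segment1(dm_bet, part)
  alpha <- bew_threshold(aw1)
  bet <- compute_bet(aw1, alpha, t0_offset_s = dm_bet$t0_offset_s,
                     frame_interval_s = dm_bet$frame_interval_s)
  sp <- select_subperiods(min(bet$bet_s, horizon_s), horizon_s)
  ev_list <- lapply(seq_len(nrow(sp)), function(i) {
    if (sp$end_s[i] - sp$start_s[i] < 10) return(NULL)
    dm_w <- provider_window(sp$start_s[i], sp$end_s[i])
    detect_contractions(dm_w, cfg, part, window = sp$label[i],
                        period = sp$period[i])
  })
  ev_list <- ev_list[!vapply(ev_list, function(x) is.null(x) || !nrow(x), TRUE)]
  events <- if (length(ev_list)) do.call(rbind, ev_list) else .empty_events()
  if (nrow(events)) events$event_id <- seq_len(nrow(events))
  mins <- analyzed_minutes(sp)
  prep_row <- data.frame(
    preparation_id = dm_bet$preparation_id, treatment = dm_bet$treatment,
    intestine_length_mm = dm_bet$intestine_length_mm,
    bet_h = bet$bet_h, alpha_mm = bet$alpha,
    minutes_I = mins[["I"]], minutes_II = mins[["II"]],
    seg1_mm = part$segment_length_mm[1], seg2_mm = part$segment_length_mm[2],
    seg3_mm = part$segment_length_mm[3], seg4_mm = part$segment_length_mm[4],
    stringsAsFactors = FALSE)
  structure(list(bet = bet, subperiods = sp, partition = part,
                 events = events, preparation = prep_row),
            class = "motility_analysis")
}

#' Analyse the motility of one diameter matrix
#'
#' The main entry point for recorded data: computes the bulbous emptying
#' time from the matrix subsampled to `bet_fps` (0.35 fps, the validated
#' rate), selects the six 30-min analysis windows around it, detects and
#' classifies contraction events within each window at `detect_fps`
#' (3.5/3 fps), and assigns events to segments and periods.
#'
#' @inheritParams frame_times
#' @param fractions segment length fractions, see [partition_segments()].
#' @param cfg a [detection_config()].
#' @param bet_fps frame rate (fps) for the emptying-time analysis; the
#'   matrix is brought down to it by integer-stride subsampling.
#' @param detect_fps frame rate for event detection.
#' @return An object of class `motility_analysis` with components `bet`
#'   (a [compute_bet()] result), `subperiods`, `partition`, `events` (the
#'   [detect_contractions()] table over all windows) and `preparation` (a
#'   one-row per-preparation summary usable with [summarize_motility()]).
#' @seealso [summary.motility_analysis()], [plot.motility_analysis()]
#' @export
analyze_motility <- function(dm, fractions = c(0.39, 0.23, 0.23, 0.15),
                             cfg = detection_config(), bet_fps = 0.35,
                             detect_fps = 3.5 / 3) {
  native_fps <- 1 / dm$frame_interval_s
  stride_bet <- max(1L, round(native_fps / bet_fps))
  stride_det <- max(1L, round(native_fps / detect_fps))
  dm_det <- subsample_frames(dm, stride_det)
  horizon <- dm$t0_offset_s + ncol(dm$values) * dm$frame_interval_s
  tms <- frame_times(dm_det)
  provider_window <- function(a, b) {
    keep <- which(tms >= a & tms < b)
    if (length(keep) < 2) keep <- seq_len(2)
    out <- dm_det
    out$values <- dm_det$values[, keep, drop = FALSE]
    out$t0_offset_s <- tms[keep[1]]
    out
  }
  .analyze_core(function() subsample_frames(dm, stride_bet),
                provider_window, fractions, cfg, horizon)
}

#' Analyse one preparation of a synthetic scenario
#'
#' Runs the identical pipeline as [analyze_motility()], but renders the
#' scenario at each stage's analysis rate instead of subsampling one huge
#' full-rate matrix: the emptying-time stage sees the full 14-h span at
#' 0.35 fps, the detection stage sees only the selected windows at 3.5/3
#' fps.
#'
#' @param scen a [generate_scenario()] result.
#' @param prep preparation index.
#' @inheritParams analyze_motility
#' @return a `motility_analysis`, see [analyze_motility()].
#' @export
analyze_preparation <- function(scen, prep = 1,
                                fractions = c(0.39, 0.23, 0.23, 0.15),
                                cfg = detection_config()) {
  .analyze_core(
    function() render_diameter_matrix(scen, prep,
                                      scen$params$frame_rate_bet,
                                      0, scen$horizon_s),
    function(a, b) render_diameter_matrix(scen, prep,
                                          scen$params$frame_rate_detect,
                                          a, b),
    fractions, cfg, scen$horizon_s)
}

#' Analyse every preparation of a scenario
#'
#' @inheritParams analyze_preparation
#' @return An object of class `motility_cohort`: `analyses` (list of
#'   [analyze_preparation()] results), pooled `events`, `preparations`
#'   (per-preparation table incl. BET) and `summary` (a
#'   [summarize_motility()] table).
#' @export
analyze_scenario <- function(scen, fractions = c(0.39, 0.23, 0.23, 0.15),
                             cfg = detection_config()) {
  analyses <- lapply(seq_along(scen$preparations), function(p)
    analyze_preparation(scen, p, fractions, cfg))
  events <- do.call(rbind, lapply(analyses, `[[`, "events"))
  preparations <- do.call(rbind, lapply(analyses, `[[`, "preparation"))
  structure(list(analyses = analyses, events = events,
                 preparations = preparations,
                 summary = summarize_motility(events, preparations)),
            class = "motility_cohort")
}

#' @export
print.motility_analysis <- function(x, ...) {
  cat(sprintf("<motility_analysis> %s (%s)\n", x$preparation$preparation_id,
              x$preparation$treatment))
  cat(sprintf("  BET %.3f h (alpha %.3f mm)%s\n", x$bet$bet_h, x$bet$alpha,
              if (x$bet$degenerate_flag) " [degenerate]" else ""))
  cat(sprintf("  analysed %.0f min (period I) + %.0f min (period II) in %d windows\n",
              x$preparation$minutes_I, x$preparation$minutes_II,
              nrow(x$subperiods)))
  tab <- table(factor(x$events$kind, levels = .kinds))
  cat(sprintf("  events: %d standing, %d ripple, %d slow propulsive\n",
              tab[["standing"]], tab[["ripple"]], tab[["slow_propulsive"]]))
  invisible(x)
}

#' Summarize a motility analysis into the per-cell parameter table
#'
#' @param object a `motility_analysis` (one preparation) or
#'   `motility_cohort`.
#' @param ... ignored.
#' @return a [summarize_motility()] table.
#' @export
summary.motility_analysis <- function(object, ...) {
  summarize_motility(object$events, object$preparation)
}

#' @export
summary.motility_cohort <- function(object, ...) object$summary

#' @export
print.motility_cohort <- function(x, ...) {
  cat(sprintf("<motility_cohort> %d preparations, %d events\n",
              nrow(x$preparations), nrow(x$events)))
  cat(sprintf("  group BET %.2f +/- %.2f h\n", mean(x$preparations$bet_h),
              stats::sd(x$preparations$bet_h)))
  invisible(x)
}

#' Plot a motility analysis
#'
#' Draws the AW1 series with the emptying threshold and time, or the ST map
#' of a rendered window with detected constriction paths overlaid.
#'
#' @param x a `motility_analysis`.
#' @param which `"aw1"` (default) or `"events"`.
#' @param dm for `which = "events"`, the window matrix to draw under the
#'   detected paths.
#' @param ... ignored.
#' @export
plot.motility_analysis <- function(x, which = c("aw1", "events"), dm = NULL,
                                   ...) {
  which <- match.arg(which)
  if (which == "aw1") {
    t_h <- (x$bet$bet_s - (x$bet$bet_frame - 1) * x$bet$frame_interval_s +
              (seq_along(x$bet$aw1) - 1) * x$bet$frame_interval_s) / 3600
    plot(t_h, x$bet$aw1, type = "l", xlab = "time (h)",
         ylab = "average Segment-1 width (mm)",
         main = x$preparation$preparation_id)
    graphics::abline(h = x$bet$alpha, col = "grey40", lty = 2)
    graphics::abline(v = x$bet$bet_h, col = "red")
    graphics::mtext(sprintf("BET = %.2f h", x$bet$bet_h), col = "red",
                    side = 3, adj = 1, cex = 0.8)
  } else {
    if (is.null(dm)) stop("supply the window matrix via dm =", call. = FALSE)
    plot(dm, events = x$events)
  }
  invisible(x)
}
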