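#' Select the analysis sub-periods around the emptying time
#'
#' Motility is analysed in standardized 30-min windows: before the bulbous
#' emptying time (period I) windows t1 (first 30 min), t2 (30 min centred
#' halfway between 0 h and BET) and t3 (last 30 min before BET); after it
#' (period II) windows t4 (first 30 min after BET), t5 (30 min centred on the
#' middle of period II) and t6 (the last 30 min of the recording). When BET
#' is at or below `short_cutoff_s` (default 1.5 h), period I is instead the
#' single window covering all frames from 0 h to BET.
#'
#' Windows are clipped to stay disjoint and inside `[0, horizon]`: the first
#' and last window of each period are anchored, the middle window is
#' truncated to the gap between them, and empty windows are dropped (short
#' windows are kept rather than discarded).
#'
#' @param bet_s emptying time on the analysis clock (s), in `[0, horizon_s]`.
#' @param horizon_s end of the recording on the analysis clock (default 14 h).
#' @param window_s standard window length (default 30 min).
#' @param short_cutoff_s BET cutoff under which period I collapses to a
#'   single window (default 1.5 h).
#' @return An object of class `subperiod_set`: a data frame with columns
#'   `label` (`t1`..`t6` or `full_period_I`), `start_s`, `end_s`, `period`
#'   (`"I"`/`"II"`), plus attributes `bet_s` and `horizon_s`.
#' @export
select_subperiods <- function(bet_s, horizon_s = 14 * 3600, window_s = 1800,
                              short_cutoff_s = 1.5 * 3600) {
  if (is.na(bet_s) || bet_s < 0 || bet_s > horizon_s)
    stop("bet_s must lie in [0, horizon_s]", call. = FALSE)

  clip <- function(a, b, lo, hi) c(max(a, lo), min(b, hi))
  win <- list()
  add <- function(label, a, b, period) {
    if (b - a > 1e-9)
      win[[length(win) + 1L]] <<- data.frame(label = label, start_s = a,
                                             end_s = b, period = period,
                                             stringsAsFactors = FALSE)
  }

  if (bet_s > short_cutoff_s) {
    t1 <- clip(0, window_s, 0, bet_s)
    t3 <- clip(max(bet_s - window_s, t1[2]), bet_s, 0, bet_s)
    mid <- bet_s / 2
    t2 <- clip(mid - window_s / 2, mid + window_s / 2, t1[2], t3[1])
    add("t1", t1[1], t1[2], "I")
    add("t2", t2[1], t2[2], "I")
    add("t3", t3[1], t3[2], "I")
  } else if (bet_s > 0) {
    add("full_period_I", 0, bet_s, "I")
  }                                       # bet_s == 0: period I is empty

  t4 <- clip(bet_s, bet_s + window_s, bet_s, horizon_s)
  t6 <- clip(max(horizon_s - window_s, t4[2]), horizon_s, bet_s, horizon_s)
  mid2 <- (bet_s + horizon_s) / 2
  t5 <- clip(mid2 - window_s / 2, mid2 + window_s / 2, t4[2], t6[1])
  add("t4", t4[1], t4[2], "II")
  add("t5", t5[1], t5[2], "II")
  add("t6", t6[1], t6[2], "II")

  out <- do.call(rbind, win)
  rownames(out) <- NULL
  structure(out, bet_s = bet_s, horizon_s = horizon_s,
            class = c("subperiod_set", "data.frame"))
}

#' @export
print.subperiod_set <- function(x, ...) {
  cat(sprintf("<subperiod_set> BET = %.3f h, horizon = %.1f h\n",
              attr(x, "bet_s") / 3600, attr(x, "horizon_s") / 3600))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-14s period %-2s [%7.3f, %7.3f] h\n", x$label[i],
                x$period[i], x$start_s[i] / 3600, x$end_s[i] / 3600))
  invisible(x)
}

#' Total analysed minutes per period of a subperiod set
#' @param sp a [select_subperiods()] result.
#' @return named numeric vector, minutes analysed in periods I and II.
#' @export
analyzed_minutes <- function(sp) {
  mins <- c(I = 0, II = 0)
  if (nrow(sp)) {
    agg <- tapply((sp$end_s - sp$start_s) / 60, sp$period, sum)
    mins[names(agg)] <- agg
  }
  mins
}
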