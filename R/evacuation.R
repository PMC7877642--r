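#' Average width of Segment 1 (AW1)
#'
#' Per-frame arithmetic mean of the diameters over the positions of
#' Segment 1 (the bulbous, anterior 39% by default). This is the series on
#' which the emptying-time statistic is defined.
#'
#' @inheritParams frame_times
#' @param part a [partition_segments()] result for the same matrix.
#' @return numeric vector (mm), one value per frame.
#' @export
average_width_segment1 <- function(dm, part) {
  rows <- which(part$segment_of == 1L)
  if (!length(rows)) stop("Segment 1 contains no positions", call. = FALSE)
  colMeans(dm$values[rows, , drop = FALSE])
}

#' Bulbous emptying width threshold (alpha)
#'
#' The 5th percentile of the AW1 series, computed with linear-interpolation
#' quantiles (type 7, the default convention of common statistical
#' environments). Widths at or below alpha mark an empty bulbous.
#'
#' @param aw1 AW1 series (mm), length >= 2.
#' @param prob quantile level (default 0.05).
#' @param type quantile algorithm, passed to [stats::quantile()].
#' @return the threshold alpha in mm.
#' @export
bew_threshold <- function(aw1, prob = 0.05, type = 7) {
  if (length(aw1) < 2 || anyNA(aw1))
    stop("aw1 must be a complete series of length >= 2", call. = FALSE)
  unname(stats::quantile(aw1, probs = prob, type = type))
}

#' Bulbous emptying time (BET)
#'
#' BET is the analysis-clock time of the first frame whose AW1 is less than
#' or equal to alpha (ties count as empty). Existence is guaranteed because
#' the minimum of a series never exceeds its 5th percentile. When the very
#' first analysed frame is already at or below alpha the result is flagged
#' degenerate.
#'
#' @inheritParams bew_threshold
#' @param alpha threshold from [bew_threshold()] on the same series.
#' @param t0_offset_s analysis-clock time of the first frame (s).
#' @param frame_interval_s seconds per frame of the series.
#' @return An object of class `bet_result` with fields `aw1`, `alpha`,
#'   `bet_s`, `bet_h`, `bet_frame` and `degenerate_flag`.
#' @export
compute_bet <- function(aw1, alpha, t0_offset_s = 0, frame_interval_s = 1) {
  idx <- which(aw1 <= alpha)[1]
  if (is.na(idx))
    stop("no frame at or below alpha; alpha is not from this series",
         call. = FALSE)
  bet_s <- t0_offset_s + (idx - 1) * frame_interval_s
  structure(list(aw1 = aw1, alpha = alpha, bet_s = bet_s,
                 bet_h = bet_s / 3600, bet_frame = idx,
                 frame_interval_s = frame_interval_s,
                 degenerate_flag = idx == 1L),
            class = "bet_result")
}

#' @export
print.bet_result <- function(x, ...) {
  cat(sprintf("<bet_result> BET = %.3f h (alpha = %.3f mm, frame %d%s)\n",
              x$bet_h, x$alpha, x$bet_frame,
              if (x$degenerate_flag) ", degenerate: empty at first frame" else ""))
  invisible(x)
}

#' Emptying time of the bulbous from a diameter matrix
#'
#' Convenience wrapper: partitions the intestine, optionally subsamples the
#' matrix to the validated emptying-time analysis rate (0.35 fps), computes
#' AW1, alpha and BET.
#'
#' @inheritParams frame_times
#' @param fractions segment length fractions, see [partition_segments()].
#' @param target_fps frame rate the matrix is brought down to before the
#'   threshold rule is applied (default 0.35 fps; `NULL` keeps the native
#'   rate).
#' @param prob quantile level for the threshold (default 0.05).
#' @return a `bet_result`, see [compute_bet()].
#' @export
bulbous_emptying_time <- function(dm, fractions = c(0.39, 0.23, 0.23, 0.15),
                                  target_fps = 0.35, prob = 0.05) {
  if (!is.null(target_fps)) {
    stride <- max(1L, round(1 / (target_fps * dm$frame_interval_s)))
    dm <- subsample_frames(dm, stride)
  }
  part <- partition_segments(dm, fractions)
  aw1 <- average_width_segment1(dm, part)
  alpha <- bew_threshold(aw1, prob = prob)
  compute_bet(aw1, alpha, t0_offset_s = dm$t0_offset_s,
              frame_interval_s = dm$frame_interval_s)
}
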