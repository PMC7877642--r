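#' Match detected contractions to ground-truth events
#'
#' One-to-one greedy matching by time-position proximity: a detected event
#' matches a ground-truth event when their onsets differ by at most `tol_s`
#' and their path midpoints by at most `tol_mm`; among candidates the
#' closest onset wins. Intended for well-separated synthetic scenarios,
#' where the assignment is unambiguous.
#'
#' @param detected event table from [detect_contractions()].
#' @param truth ground-truth table (one preparation) from
#'   [ground_truth_events()].
#' @param tol_s,tol_mm matching tolerances.
#' @return `truth` with columns `det_id` (matched row of `detected`, NA for
#'   misses) and `det_kind`.
#' @export
match_events <- function(detected, truth, tol_s = 3, tol_mm = 3) {
  mid <- function(paths) vapply(paths, function(p)
    (min(p$pos_mm) + max(p$pos_mm)) / 2, 0.0)
  truth$det_id <- NA_integer_
  truth$det_kind <- NA_character_
  if (!nrow(detected) || !nrow(truth)) return(truth)
  d_mid <- mid(detected$path)
  g_mid <- mid(truth$path)
  used <- logical(nrow(detected))
  ord <- order(truth$onset_s)
  for (g in ord) {
    cand <- which(!used &
                    abs(detected$onset_s - truth$onset_s[g]) <= tol_s &
                    abs(d_mid - g_mid[g]) <= tol_mm)
    if (!length(cand)) next
    best <- cand[which.min(abs(detected$onset_s[cand] - truth$onset_s[g]))]
    used[best] <- TRUE
    truth$det_id[g] <- best
    truth$det_kind[g] <- detected$kind[best]
  }
  truth
}

#' Detection and classification scores against ground truth
#'
#' @inheritParams match_events
#' @return list with `recall`, `precision`, `kind_accuracy` (among matched
#'   events) and the matched table.
#' @export
detection_scores <- function(detected, truth, tol_s = 3, tol_mm = 3) {
  m <- match_events(detected, truth, tol_s, tol_mm)
  hit <- !is.na(m$det_id)
  list(recall = mean(hit),
       precision = if (nrow(detected)) sum(hit) / nrow(detected) else NA_real_,
       kind_accuracy = if (any(hit)) mean(m$kind[hit] == m$det_kind[hit])
                       else NA_real_,
       matched = m)
}
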