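#' Single-kind calibration scenario ("event farm")
#'
#' A scenario tailored for parameter-recovery experiments: one preparation
#' of fixed length carrying only one contraction kind, at a uniform rate
#' over all segments, with the horizon sized so that the expected event
#' count reaches `n_events`. Rates are kept modest so the well-separated
#' placement stays far from saturation.
#'
#' @param kind `"standing"`, `"ripple"` or `"slow_propulsive"`.
#' @param seed integer seed.
#' @param n_events target expected number of events.
#' @param length_mm intestine length (default 70 mm).
#' @param noise_sd_mm measurement noise; default from [default_params()].
#' @param treatment treatment whose shape distributions are used.
#' @return a [generate_scenario()] result.
#' @export
event_farm <- function(kind = c("standing", "ripple", "slow_propulsive"),
                       seed = 1, n_events = 2200, length_mm = 70,
                       noise_sd_mm = NULL, treatment = "cellulose") {
  kind <- match.arg(kind)
  p <- default_params(treatment)
  rate <- c(standing = 0.35, ripple = 0.12, slow_propulsive = 0.09)[[kind]]
  p$rates_cpm_mm[] <- 0
  p$rates_cpm_mm[, kind] <- rate
  p$period2_factor <- 1          # uniform rate; the bolus never matters here
  p$bolus_gain_mm <- 0
  if (!is.null(noise_sd_mm)) p$noise_sd_mm <- noise_sd_mm
  p$horizon_s <- ceiling(n_events / (rate * length_mm) * 60 / 600) * 600
  generate_scenario(p, 1, seed = seed, lengths_mm = length_mm)
}

#' Detect contractions over the whole horizon of a scenario preparation
#'
#' Renders the preparation at the motility analysis rate in long chunks and
#' pools the detected events; used for calibration-recovery experiments
#' where the sub-period machinery is not involved.
#'
#' @param scen a [generate_scenario()] result.
#' @param prep preparation index.
#' @param cfg a [detection_config()].
#' @param chunk_s chunk length in seconds.
#' @return a [detect_contractions()] event table.
#' @export
detect_scenario_events <- function(scen, prep = 1, cfg = detection_config(),
                                   chunk_s = 7200) {
  part <- NULL
  out <- list()
  starts <- seq(0, scen$horizon_s - 1, by = chunk_s)
  for (a in starts) {
    dmw <- render_diameter_matrix(scen, prep, scen$params$frame_rate_detect,
                                  a, min(a + chunk_s, scen$horizon_s))
    if (is.null(part)) part <- partition_segments(dmw)
    out[[length(out) + 1L]] <- detect_contractions(dmw, cfg, part)
  }
  out <- do.call(rbind, out)
  if (nrow(out)) out$event_id <- seq_len(nrow(out))
  out
}
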