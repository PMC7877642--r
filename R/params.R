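#' Calibrate a truncated lognormal to a min / median / max triple
#'
#' The motility parameter distributions (amplitude, duration, velocity,
#' distance) are right-skewed and summarized in the source data by their
#' minimum, median and maximum. This calibration represents each of them as
#' a lognormal truncated to `[min, max]`: the log-scale spread is chosen so
#' that the stated extremes sit at the quantiles expected for the extreme
#' order statistics of a sample of size `n` (z = qnorm(1 - 1/(n + 1))), and
#' the log-scale location is solved numerically so that the median of the
#' *truncated* distribution equals the target exactly.
#'
#' @param min,median,max the target triple (min < median < max, all > 0).
#' @param n sample size the extremes are assumed to come from.
#' @param lower optional truncation bound overriding `min` for sampling
#'   (>= min); the median is recalibrated against it.
#' @return An object of class `trunc_lognormal` with fields `meanlog`,
#'   `sdlog`, `lower`, `upper` and a sampler accessible via [rtrunclnorm()].
#' @export
calibrate_lognormal <- function(min, median, max, n = 1e5, lower = NULL) {
  stopifnot(min > 0, median > min, max > median)
  z <- stats::qnorm(1 - 1 / (n + 1))
  sdlog <- (log(max) - log(min)) / (2 * z)
  lo <- if (is.null(lower)) min else base::max(lower, min)
  if (lo >= median)
    stop("truncation lower bound must stay below the target median",
         call. = FALSE)
  # median of the truncation equals the target iff the parent mass on
  # (lo, median) equals the mass on (median, max); solved on the pnorm scale,
  # which stays well-behaved where quantile-based formulations saturate
  f <- function(m) {
    2 * stats::pnorm((log(median) - m) / sdlog) -
      stats::pnorm((log(lo) - m) / sdlog) -
      stats::pnorm((log(max) - m) / sdlog)
  }
  grid <- seq(log(lo) - 8 * sdlog, log(max) + 8 * sdlog, length.out = 4001)
  fg <- vapply(grid, f, 0.0)
  i <- which(fg[-1] * fg[-length(fg)] <= 0 &
               (abs(fg[-1]) + abs(fg[-length(fg)]) > 0))[1]
  if (is.na(i))
    stop("no feasible lognormal location for this triple", call. = FALSE)
  meanlog <- stats::uniroot(f, grid[c(i, i + 1)], tol = 1e-13)$root
  structure(list(meanlog = meanlog, sdlog = sdlog, lower = lo, upper = max,
                 target = c(min = min, median = median, max = max)),
            class = "trunc_lognormal")
}

#' Sample from a calibrated truncated lognormal
#' @param n number of draws.
#' @param d a [calibrate_lognormal()] object.
#' @return numeric vector of draws in `[d$lower, d$upper]`.
#' @export
rtrunclnorm <- function(n, d) {
  fa <- stats::plnorm(d$lower, d$meanlog, d$sdlog)
  fb <- stats::plnorm(d$upper, d$meanlog, d$sdlog)
  stats::qlnorm(stats::runif(n, fa, fb), d$meanlog, d$sdlog)
}

#' @export
print.trunc_lognormal <- function(x, ...) {
  cat(sprintf("<trunc_lognormal> median %.4g on [%.4g, %.4g] (meanlog %.4g, sdlog %.4g)\n",
              x$target["median"], x$lower, x$upper, x$meanlog, x$sdlog))
  invisible(x)
}

# Reported event counts behind the min/median/max triples, per kind; the
# extremes of samples this large sit at roughly +/- 3.8-4.7 log-sd.
.kind_n <- c(standing = 606120, ripple = 11978, slow_propulsive = 99010)

.rate_matrix <- function(seg1, other = c(0.5, 0.4, 0.3) * seg1[1] / 1.5) {
  # rows = segments 1..4, cols = standing, slow_propulsive, ripple (period I)
  rbind(seg1,
        c(other[1], 0.10, 0.04),
        c(other[2], 0.08, 0.03),
        c(other[3], 0.06, 0.02))
}

#' Default treatment parameters for the synthetic generator
#'
#' Calibrated generator configuration for one bolus treatment. Event-shape
#' distributions (amplitude, duration, velocity, distance) are common to all
#' treatments and calibrated so their medians equal the reported pooled
#' medians: amplitude 47.4 / 55.3 / 56.9 % and duration 1.8 / 7.2 / 15.3 s
#' for standing / ripple / slow propulsive contractions, velocity 0.22
#' (ripple) and 0.04 (slow propulsive) mm/s, ripple distance 2.2% of
#' intestine length. Treatment-specific pieces are the Segment-1 period-I
#' event rates (cellulose 1.5 / 0.26 / 0.08 cpm per mm for standing / slow /
#' ripple), the evacuation-time distribution (lipid 3.4 +/- 1.0 h, protein
#' 3.9 +/- 1.5 h, cellulose 1.1 +/- 0.7 h, truncated at 0; plastic bead
#' bimodal), and the anterograde probabilities (cellulose Segment 1 period
#' I: 0.626 for slow propulsive, 0.684 for ripples). Period II rates default
#' to half the period I rates; segment 2-4 rates decline toward the hindgut.
#'
#' @param treatment one of `"lipid"`, `"protein"`, `"cellulose"`,
#'   `"plastic_bead"`.
#' @param period2_factor multiplier taking period-I rates to period II.
#' @return An object of class `motility_params`.
#' @export
default_params <- function(treatment = c("cellulose", "lipid", "protein",
                                         "plastic_bead"),
                           period2_factor = 0.5) {
  treatment <- match.arg(treatment)
  amp <- list(
    standing = calibrate_lognormal(0.077, 0.474, 0.779, .kind_n["standing"]),
    ripple = calibrate_lognormal(0.127, 0.553, 0.790, .kind_n["ripple"]),
    slow_propulsive = calibrate_lognormal(0.124, 0.569, 0.813,
                                          .kind_n["slow_propulsive"]))
  # slow-propulsive durations are floored at 4 detection frames so that the
  # linearity fit always has a residual degree of freedom (see vignette)
  dur <- list(
    standing = calibrate_lognormal(1.7, 1.8, 23.4, .kind_n["standing"]),
    slow_propulsive = calibrate_lognormal(1.72, 15.3, 506.6,
                                          .kind_n["slow_propulsive"],
                                          lower = 4 * 3 / 3.5))
  vel <- list(
    ripple = calibrate_lognormal(0.04, 0.22, 0.67, .kind_n["ripple"]),
    slow_propulsive = calibrate_lognormal(0.001, 0.04, 0.70,
                                          .kind_n["slow_propulsive"]))
  # ripple propagation distance as a fraction of intestine length; the lower
  # truncation in mm (>= 1.3 mm) is applied per preparation at draw time
  dist <- list(ripple = calibrate_lognormal(0.012, 0.022, 0.166,
                                            .kind_n["ripple"]))
  rates <- switch(treatment,
    cellulose = .rate_matrix(c(1.5, 0.26, 0.08)),
    lipid = .rate_matrix(c(0.9, 0.12, 0.08)),
    protein = .rate_matrix(c(0.64, 0.09, 0.03)),
    plastic_bead = .rate_matrix(c(0.9, 0.12, 0.05)))
  dimnames(rates) <- list(paste0("seg", 1:4),
                          c("standing", "slow_propulsive", "ripple"))
  evac <- switch(treatment,
    lipid = list(kind = "normal", mean_h = 3.4, sd_h = 1.0),
    protein = list(kind = "normal", mean_h = 3.9, sd_h = 1.5),
    cellulose = list(kind = "normal", mean_h = 1.1, sd_h = 0.7),
    plastic_bead = list(kind = "bimodal", mean_h = c(0.8, 4.5),
                        sd_h = c(0.3, 1.0), weight = c(0.5, 0.5)))
  antero <- matrix(0.6, nrow = 4, ncol = 2,
                   dimnames = list(paste0("seg", 1:4),
                                   c("slow_propulsive", "ripple")))
  if (treatment == "cellulose") antero[1, ] <- c(0.626, 0.684)
  structure(list(treatment = treatment,
                 rates_cpm_mm = rates,            # period I
                 period2_factor = period2_factor,
                 amplitude = amp, duration = dur, velocity = vel,
                 distance = dist,
                 anterograde_prob = antero,
                 evacuation = evac,
                 noise_sd_mm = 0.02,
                 bolus_gain_mm = 2.5,
                 rest_bulbous_mm = 6.0,
                 rest_hindgut_mm = 3.0,
                 sigma_space_mm = 1.0,
                 render_trunc_frac = 0.03,
                 ripple_jitter_sd_mm = 0.05,
                 slow_jitter_floor_mm = 0.8,
                 minority_reservation = c(slow_propulsive = 0.12,
                                          ripple = 0.03),
                 ripple_distance_floor_mm = 1.3,
                 bolus_decay_s = 2 / 0.35,
                 horizon_s = 14 * 3600,
                 frame_rate_detect = 3.5 / 3,
                 frame_rate_bet = 0.35,
                 position_spacing_mm = 0.25),
            class = "motility_params")
}

#' @export
print.motility_params <- function(x, ...) {
  cat(sprintf("<motility_params> treatment %s\n", x$treatment))
  cat("  period-I rates (cpm per mm):\n")
  print(round(x$rates_cpm_mm, 3))
  ev <- x$evacuation
  cat(sprintf("  evacuation: %s, mean %s h, sd %s h; period-II factor %.2f\n",
              ev$kind, paste(ev$mean_h, collapse = "/"),
              paste(ev$sd_h, collapse = "/"), x$period2_factor))
  invisible(x)
}
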