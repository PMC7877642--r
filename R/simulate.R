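#' Resting diameter profile of a synthetic preparation
#'
#' Closed-form resting geometry: a wide bulbous (anterior 39%) tapering
#' smoothly across Segment 2 to the narrower posterior gut,
#' `rest(x) = hindgut + (bulbous - hindgut) * logistic((0.45 - x/L) / 0.025)`.
#'
#' @param params a [default_params()] object.
#' @param length_mm intestine length.
#' @param x_mm positions (mm from the oral end).
#' @return resting diameters (mm).
#' @export
resting_profile <- function(params, length_mm, x_mm) {
  u <- x_mm / length_mm
  params$rest_hindgut_mm + (params$rest_bulbous_mm - params$rest_hindgut_mm) *
    stats::plogis((0.45 - u) / 0.025)
}

.bolus_shape <- function(params, length_mm, x_mm) {
  stats::plogis((0.45 - x_mm / length_mm) / 0.025)
}

.draw_evacuation <- function(ev, n) {
  draw1 <- function() {
    repeat {
      if (ev$kind == "bimodal") {
        c_i <- sample.int(length(ev$mean_h), 1, prob = ev$weight)
        x <- stats::rnorm(1, ev$mean_h[c_i], ev$sd_h[c_i])
      } else x <- stats::rnorm(1, ev$mean_h, ev$sd_h)
      if (x >= 0) return(x)
    }
  }
  vapply(seq_len(n), function(i) draw1(), 0.0) * 3600
}

# orthogonalize a smooth jitter curve against (1, t), rescale to an exact sd
.shape_jitter <- function(t, sd_target) {
  n <- length(t)
  if (n < 3 || sd_target <= 0) return(numeric(n))
  u <- (t - t[1]) / max(t[n] - t[1], 1e-9)
  f <- stats::runif(1, 1, 2.5)
  ph <- stats::runif(1, 0, 2 * pi)
  j <- sin(2 * pi * f * u + ph) + 0.3 * sin(4 * pi * f * u + 2.1 * ph)
  r <- stats::lm.fit(cbind(1, t), j)$residuals
  s <- sqrt(mean(r^2))
  if (s < 1e-9) {
    r <- rep_len(c(1, -1), n)
    r <- r - mean(r)
    s <- sqrt(mean(r^2))
  }
  r * (sd_target / s)
}

.kind_order <- c("standing", "slow_propulsive", "ripple")

#' Generate a synthetic motility scenario with ground truth
#'
#' Simulates `n_preparations` isolated intestines under one treatment: a
#' resting profile with a wider bulbous, a bolus distending Segment 1 until
#' a drawn evacuation time (then decaying within two coarse frames),
#' contraction events of the three archetypes drawn as Poisson counts per
#' segment, kind and digestive period, with right-skewed amplitude /
#' duration / velocity distributions calibrated to the reported pooled
#' medians, and anterograde/retrograde directions drawn per segment. Events
#' render as moving Gaussian constrictions (spatial sd ~1 mm): standing
#' contractions have a fixed centre, ripples follow near-linear paths, slow
#' propulsive contractions follow a slow drift with strong smooth wander so
#' that their path linearity stays below the ripple threshold.
#'
#' Events are placed by random sequential insertion with an exclusion rule
#' (supports separated by at least one position sample or two detection
#' frames), so every ground-truth event is resolvable by the
#' connected-component detector; kinds are inserted in decreasing
#' expected-count order and events that no longer fit are dropped and
#' reported in `placement` (at the dense Segment-1 rates the longer, slower
#' kinds saturate below their nominal rate; see the vignette).
#'
#' @param params a [default_params()] configuration.
#' @param n_preparations number of preparations to simulate.
#' @param seed integer seed; the scenario is a pure function of
#'   `(params, n_preparations, seed)`.
#' @param lengths_mm optional vector of intestine lengths (mm); by default
#'   drawn uniformly in 50-90 mm.
#' @param max_attempts placement attempts per event before it is dropped.
#' @return An object of class `motility_scenario`: `params`, `seed`,
#'   `horizon_s` and `preparations`, a list holding per preparation the
#'   drawn `length_mm`, `evacuation_s`, the ground-truth `events` data frame
#'   (kind, onset, duration, amplitude, velocity, direction, distance,
#'   segment, period, path knots) and placement statistics.
#' @export
generate_scenario <- function(params, n_preparations = 1, seed = 1,
                              lengths_mm = NULL, max_attempts = 150L) {
  stopifnot(inherits(params, "motility_params"))
  if (any(params$rates_cpm_mm < 0)) stop("rates must be >= 0", call. = FALSE)
  set.seed(as.integer(seed) %% 2147483587L)
  dt <- 1 / params$frame_rate_detect
  horizon <- params$horizon_s
  n_t <- as.integer(floor(horizon / dt))
  spacing <- params$position_spacing_mm
  fractions <- c(0.39, 0.23, 0.23, 0.15)

  if (is.null(lengths_mm))
    lengths_mm <- stats::runif(n_preparations, 50, 90)
  lengths_mm <- round(lengths_mm / spacing) * spacing
  evac_all <- .draw_evacuation(params$evacuation, n_preparations)

  preps <- lapply(seq_len(n_preparations), function(p) {
    L <- lengths_mm[p]
    n_x <- as.integer(round(L / spacing))
    evac <- min(evac_all[p], horizon)
    seg_bounds <- c(0, cumsum(fractions)) * L
    dist_cal <- calibrate_lognormal(
      0.012, 0.022, 0.166, .kind_n["ripple"],
      lower = min(params$ripple_distance_floor_mm / L, 0.02))

    # --- draw counts and event parameters, vectorized per kind ---
    kind <- character(0); seg <- integer(0); per <- character(0)
    for (k in .kind_order) for (s in 1:4) for (pp in c("I", "II")) {
      rate <- params$rates_cpm_mm[s, k] *
        (if (pp == "II") params$period2_factor else 1)
      span_min <- (if (pp == "I") evac else horizon - evac) / 60
      n_ev <- stats::rpois(1, rate * span_min *
                             (seg_bounds[s + 1] - seg_bounds[s]))
      if (n_ev > 0) {
        kind <- c(kind, rep(k, n_ev))
        seg <- c(seg, rep(s, n_ev))
        per <- c(per, rep(pp, n_ev))
      }
    }
    n_ev <- length(kind)
    prep_id <- sprintf("%s_%02d", params$treatment, p)
    if (n_ev == 0)
      return(list(preparation_id = prep_id, length_mm = L,
                  evacuation_s = evac, events = NULL,
                  placement = c(target = 0L, placed = 0L)))

    amp <- numeric(n_ev); dur <- numeric(n_ev); vel <- rep(NA_real_, n_ev)
    is_st <- kind == "standing"; is_ri <- kind == "ripple"
    is_sl <- kind == "slow_propulsive"
    amp[is_st] <- rtrunclnorm(sum(is_st), params$amplitude$standing)
    amp[is_ri] <- rtrunclnorm(sum(is_ri), params$amplitude$ripple)
    amp[is_sl] <- rtrunclnorm(sum(is_sl), params$amplitude$slow_propulsive)
    dur[is_st] <- rtrunclnorm(sum(is_st), params$duration$standing)
    dur[is_sl] <- rtrunclnorm(sum(is_sl), params$duration$slow_propulsive)
    vel[is_ri] <- rtrunclnorm(sum(is_ri), params$velocity$ripple)
    vel[is_sl] <- rtrunclnorm(sum(is_sl), params$velocity$slow_propulsive)
    # ripple travel is sampled only at frame times, which forfeits up to two
    # frames' worth of drift; the floor guarantees the *sampled* path range
    # stays above the standing-contraction distance threshold
    dist_ri <- pmax(rtrunclnorm(sum(is_ri), dist_cal) * L,
                    params$ripple_distance_floor_mm + 2 * vel[is_ri] * dt)
    dur[is_ri] <- dist_ri / vel[is_ri]
    dirn <- integer(n_ev)
    prop <- !is_st
    p_ant <- ifelse(is_ri, params$anterograde_prob[cbind(seg, 2)],
                    params$anterograde_prob[cbind(seg, 1)])
    dirn[prop] <- ifelse(stats::runif(sum(prop)) < p_ant[prop], 1L, -1L)

    r_a <- params$sigma_space_mm *
      sqrt(2 * log(amp / params$render_trunc_frac))
    phi <- stats::runif(n_ev)
    nf <- pmax(1L, as.integer(floor(dur / dt + phi)))

    paths <- vector("list", n_ev)
    for (e in seq_len(n_ev)) {
      if (is_st[e]) { paths[[e]] <- numeric(nf[e]); next }
      t_rel <- (seq_len(nf[e]) - phi[e]) * dt
      drift <- dirn[e] * vel[e] * (t_rel - mean(t_rel))
      jit <- if (is_ri[e]) .shape_jitter(t_rel, params$ripple_jitter_sd_mm)
      else {
        sd_t <- sqrt(mean((t_rel - mean(t_rel))^2))
        .shape_jitter(t_rel, max(params$slow_jitter_floor_mm,
                                 0.8 * vel[e] * sd_t))
      }
      paths[[e]] <- drift + jit
    }
    rng_lo <- vapply(paths, min, 0.0)
    rng_hi <- vapply(paths, max, 0.0)

    # --- placement: box origins on the (position cell x detection frame) grid
    w <- pmax(1L, as.integer(ceiling((rng_hi - rng_lo + 2 * r_a) / spacing)))
    x_lo <- pmax(0L, as.integer(ceiling((seg_bounds[seg] - r_a) / spacing)))
    x_hi <- pmin(n_x - w, as.integer(floor(
      (seg_bounds[seg + 1] - (rng_hi - rng_lo) - r_a) / spacing)))
    per_lo <- ifelse(per == "I", 0, evac)
    per_hi <- ifelse(per == "I", evac, horizon)
    t_lo <- pmax(1L, as.integer(ceiling(per_lo / dt)))
    t_hi <- pmin(n_t - nf, as.integer(floor(per_hi / dt)))
    # insertion priority: a capped share of each segment-period cell is
    # offered to the minority kinds first (so dense cells keep measurable
    # numbers of propulsive events), then the dominant standing class, then
    # the minority remainder; see the vignette on placement saturation
    prio <- ifelse(kind == "standing", 2L, 3L)
    box_area <- (w + 2) * (nf + 4)
    for (s in 1:4) for (pp in c("I", "II")) {
      cell_area <- (seg_bounds[s + 1] - seg_bounds[s]) / spacing *
        (if (pp == "I") evac else horizon - evac) / dt
      for (k in c("slow_propulsive", "ripple")) {
        sel <- which(seg == s & per == pp & kind == k)
        if (!length(sel)) next
        resv <- params$minority_reservation[[k]] * cell_area
        reserved <- sel[cumsum(box_area[sel]) <= resv]
        prio[reserved] <- 1L
      }
    }
    ord <- order(prio, match(kind, .kind_order))
    placed <- matrix(NA_integer_, n_ev, 2)
    placed[ord, ] <- .place_boxes(w[ord], nf[ord], x_lo[ord], x_hi[ord],
                                  t_lo[ord], t_hi[ord], n_x, n_t, 1L, 2L,
                                  as.integer(max_attempts))
    ok <- which(!is.na(placed[, 1]))

    # --- assemble ground truth for the placed events ---
    onset <- (placed[ok, 2] - 1 + phi[ok]) * dt
    base_mm <- placed[ok, 1] * spacing + r_a[ok] - rng_lo[ok]
    knots <- lapply(seq_along(ok), function(i) {
      e <- ok[i]
      data.frame(t_s = (placed[e, 2] + seq_len(nf[e]) - 1) * dt,
                 pos_mm = base_mm[i] + paths[[e]])
    })
    mid <- vapply(knots, function(k) (min(k$pos_mm) + max(k$pos_mm)) / 2, 0.0)
    events <- data.frame(
      event_id = seq_along(ok), kind = kind[ok],
      segment = as.integer(findInterval(mid, seg_bounds,
                                        rightmost.closed = TRUE)),
      period = ifelse(onset < evac, "I", "II"),
      onset_s = onset, duration_s = dur[ok],
      amplitude_pct = 100 * amp[ok],
      distance_mm = rng_hi[ok] - rng_lo[ok],
      distance_pct = 100 * (rng_hi[ok] - rng_lo[ok]) / L,
      velocity_mm_s = vel[ok],
      direction = c("retrograde", "none", "anterograde")[dirn[ok] + 2L],
      stringsAsFactors = FALSE)
    events$path <- knots
    list(preparation_id = prep_id, length_mm = L, evacuation_s = evac,
         events = events,
         placement = c(target = n_ev, placed = length(ok)))
  })
  structure(list(params = params, seed = as.integer(seed),
                 horizon_s = horizon, preparations = preps),
            class = "motility_scenario")
}

#' @export
print.motility_scenario <- function(x, ...) {
  n <- length(x$preparations)
  cat(sprintf("<motility_scenario> %s, %d preparation(s), seed %d\n",
              x$params$treatment, n, x$seed))
  for (p in x$preparations) {
    ne <- if (is.null(p$events)) 0L else nrow(p$events)
    cat(sprintf("  %s: L = %.1f mm, evacuation %.2f h, %d events (%d/%d placed)\n",
                p$preparation_id, p$length_mm, p$evacuation_s / 3600, ne,
                p$placement["placed"], p$placement["target"]))
  }
  invisible(x)
}

#' Simulate scenarios from a parameter object
#'
#' S3 [stats::simulate()] method: `simulate(default_params("cellulose"),
#' nsim = 6, seed = 1)` is equivalent to
#' `generate_scenario(params, n_preparations = nsim, seed = seed)`.
#'
#' @param object a [default_params()] object.
#' @param nsim number of preparations.
#' @param seed integer seed.
#' @param ... passed to [generate_scenario()].
#' @return a `motility_scenario`.
#' @export
simulate.motility_params <- function(object, nsim = 1, seed = 1, ...) {
  generate_scenario(object, n_preparations = nsim, seed = seed, ...)
}

#' Render the diameter matrix of one synthetic preparation
#'
#' Rasterizes the scenario's ground truth (resting profile, bolus, events)
#' on a time window at a requested frame rate and adds measurement noise.
#' The frame grid is the global grid of the requested rate, so windows cut
#' from the same preparation align; the noise stream is a deterministic
#' function of (scenario seed, preparation, rate, window), so repeated
#' renders of the same window are identical.
#'
#' @param scen a [generate_scenario()] result.
#' @param prep preparation index.
#' @param frame_rate frames per second of the rendered matrix.
#' @param t_start,t_end window on the analysis clock (s).
#' @param noise add measurement noise (default TRUE).
#' @return a [diameter_matrix()].
#' @export
render_diameter_matrix <- function(scen, prep = 1,
                                   frame_rate = scen$params$frame_rate_bet,
                                   t_start = 0, t_end = scen$horizon_s,
                                   noise = TRUE) {
  params <- scen$params
  pr <- scen$preparations[[prep]]
  dt <- 1 / frame_rate
  k0 <- ceiling(t_start / dt - 1e-9)
  k1 <- floor((t_end - 1e-9) / dt)
  if (k1 - k0 + 1 < 2) stop("window too short to render", call. = FALSE)
  times <- (k0:k1) * dt
  spacing <- params$position_spacing_mm
  n_x <- round(pr$length_mm / spacing)
  x <- (seq_len(n_x) - 0.5) * spacing

  rest <- resting_profile(params, pr$length_mm, x)
  shape <- .bolus_shape(params, pr$length_mm, x)
  decay <- pmin(1, pmax(0, 1 - (times - pr$evacuation_s) / params$bolus_decay_s))
  m <- matrix(rest, n_x, length(times)) +
    params$bolus_gain_mm * outer(shape, decay)

  ev <- pr$events
  if (!is.null(ev) && nrow(ev)) {
    sel <- ev$onset_s < t_end & (ev$onset_s + ev$duration_s) > t_start
    if (any(sel)) {
      ev <- ev[sel, , drop = FALSE]
      kt <- unlist(lapply(ev$path, `[[`, "t_s"))
      kx <- unlist(lapply(ev$path, `[[`, "pos_mm"))
      off <- cumsum(c(0L, vapply(ev$path, nrow, 0L)))[seq_len(nrow(ev))]
      .render_dips(m, times, spacing, ev$onset_s, ev$duration_s,
                   ev$amplitude_pct / 100, kt, kx, as.integer(off),
                   params$sigma_space_mm, params$render_trunc_frac)
    }
  }
  if (noise && params$noise_sd_mm > 0) {
    keep <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    sub_seed <- (scen$seed * 48271 + prep * 9973 + floor(t_start) * 31 +
                   round(frame_rate * 1000)) %% 2147483587
    set.seed(sub_seed)
    m <- m + stats::rnorm(length(m), 0, params$noise_sd_mm)
    m[m < 0] <- 0
    if (!is.null(keep)) assign(".Random.seed", keep, envir = globalenv())
  }
  diameter_matrix(m, position_spacing_mm = spacing, frame_interval_s = dt,
                  t0_offset_s = times[1], intestine_length_mm = pr$length_mm,
                  preparation_id = pr$preparation_id,
                  treatment = params$treatment)
}

.gt_cols <- c("preparation_id", "event_id", "kind", "segment", "period",
              "onset_s", "duration_s", "amplitude_pct", "distance_mm",
              "distance_pct", "velocity_mm_s", "direction")

#' Write / read the ground-truth event annotation of a scenario
#'
#' One TSV row per ground-truth event, mirroring the detected-event schema
#' plus the true kind and velocity; joinable to detections by time-position
#' proximity. The round trip is exact.
#'
#' @param scen a [generate_scenario()] result.
#' @param path TSV path.
#' @return `write_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` the annotation data frame.
#' @export
write_ground_truth <- function(scen, path) {
  gt <- ground_truth_events(scen)
  if (is.null(gt)) {
    gt <- as.data.frame(setNames(rep(list(character(0)), length(.gt_cols)),
                                 .gt_cols))
  } else {
    gt <- gt[, .gt_cols]
    num <- vapply(gt, is.numeric, TRUE) &
      !vapply(gt, is.integer, TRUE)
    gt[num] <- lapply(gt[num], function(x) format(x, digits = 17, trim = TRUE))
  }
  write.table(gt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = setNames(
               c("character", "integer", "character", "integer", "character",
                 rep("numeric", 6), "character"),
               .gt_cols))
}

#' Ground-truth events of a scenario as one data frame
#' @param scen a [generate_scenario()] result.
#' @return data frame of all ground-truth events with `preparation_id`
#'   (NULL when the scenario has none).
#' @export
ground_truth_events <- function(scen) {
  rows <- lapply(scen$preparations, function(pr) {
    if (is.null(pr$events) || !nrow(pr$events)) return(NULL)
    ev <- pr$events
    ev$preparation_id <- pr$preparation_id
    ev
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}
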