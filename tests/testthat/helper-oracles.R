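# Independent oracles and hand-built fixtures used across the suite.

# type-7 quantile by the direct interpolation formula: h = (n-1)p + 1 on the
# sorted sample, linear between order statistics
quantile7_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# least squares of y on (1, t) via explicit normal equations
ols_oracle <- function(t, y) {
  n <- length(t)
  sx <- sum(t); sy <- sum(y); sxx <- sum(t^2); sxy <- sum(t * y)
  den <- n * sxx - sx^2
  slope <- (n * sxy - sx * sy) / den
  intercept <- (sy - slope * sx) / n
  res <- y - intercept - slope * t
  ss_tot <- sum((y - sy / n)^2)
  list(slope = slope, r_squared = 1 - sum(res^2) / ss_tot)
}

# flat-baseline matrix with hand-rendered Gaussian constrictions moving
# along straight paths; independent of the package's rasterizer
make_dip_matrix <- function(n_pos = 120, n_frames = 200, spacing = 0.25,
                            dt = 3 / 3.5, base = 5,
                            dips = list(), sigma = 1) {
  m <- matrix(base, n_pos, n_frames)
  pos <- (seq_len(n_pos) - 0.5) * spacing
  tms <- (seq_len(n_frames) - 1) * dt
  for (d in dips) {
    for (j in which(tms >= d$t0 & tms < d$t0 + d$dur)) {
      centre <- d$x0 + d$v * (tms[j] - d$t0)
      prof <- d$depth * exp(-(pos - centre)^2 / (2 * sigma^2))
      m[, j] <- m[, j] * (1 - prof)
    }
  }
  diameter_matrix(m, position_spacing_mm = spacing, frame_interval_s = dt,
                  intestine_length_mm = n_pos * spacing)
}

# independent 8-connected labelling with temporal gap closing, via igraph
label_oracle <- function(mask, gap) {
  nr <- nrow(mask); nc <- ncol(mask)
  closed <- mask
  for (i in seq_len(nr)) {
    on <- which(mask[i, ])
    if (length(on) > 1) {
      gaps <- diff(on)
      for (k in which(gaps > 1 & gaps <= gap + 1))
        closed[i, (on[k] + 1):(on[k + 1] - 1)] <- TRUE
    }
  }
  idx <- which(closed)
  if (!length(idx)) return(matrix(0L, nr, nc))
  r <- (idx - 1) %% nr + 1
  cc <- (idx - 1) %/% nr + 1
  id <- seq_along(idx)
  edges <- NULL
  key <- function(rr, ccc) match((ccc - 1) * nr + rr, idx)
  for (k in id) {
    for (dr in -1:1) for (dc in 0:1) {
      if (dc == 0 && dr <= 0) next
      rr <- r[k] + dr; ccc <- cc[k] + dc
      if (rr < 1 || rr > nr || ccc > nc) next
      k2 <- key(rr, ccc)
      if (!is.na(k2)) edges <- c(edges, k, k2)
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  out <- matrix(0L, nr, nc)
  out[idx] <- comp
  out
}

# partition of labelled pixels into component sets, invariant to label order
component_sets <- function(lab) {
  idx <- which(lab > 0)
  unname(lapply(split(idx, lab[idx]), sort))
}

same_partition <- function(a, b) {
  setequal(lapply(component_sets(a), paste, collapse = ","),
           lapply(component_sets(b), paste, collapse = ","))
}
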