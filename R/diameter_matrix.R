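#' Calibrated diameter matrix (spatiotemporal map)
#'
#' The universal input of the pipeline: gut diameter (mm) on a dense
#' position x time grid. Rows are positions along the intestine, index 1 at
#' the oral end (row i sits at (i - 0.5) * `position_spacing_mm`); columns are
#' video frames. The analysis clock starts at `t0_offset_s` (0 s corresponds
#' to the start of the analysis period, i.e. after the post-dissection
#' recovery period), so frame j is at time `t0_offset_s + (j - 1) *
#' frame_interval_s`.
#'
#' @param values numeric matrix of diameters (mm), positions x frames.
#' @param position_spacing_mm mm between adjacent position samples.
#' @param frame_interval_s seconds between frames (> 0).
#' @param t0_offset_s analysis-clock time of the first frame (s).
#' @param intestine_length_mm total preparation length; defaults to
#'   `nrow(values) * position_spacing_mm` and must agree with it within 1%.
#' @param preparation_id character label for the preparation.
#' @param treatment one of `"lipid"`, `"protein"`, `"cellulose"`,
#'   `"plastic_bead"`, `"empty"`.
#' @return An object of class `diameter_matrix`.
#' @export
diameter_matrix <- function(values, position_spacing_mm, frame_interval_s,
                            t0_offset_s = 0,
                            intestine_length_mm = nrow(values) * position_spacing_mm,
                            preparation_id = "prep", treatment = "empty") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dm <- structure(
    list(values = values,
         position_spacing_mm = as.numeric(position_spacing_mm),
         frame_interval_s = as.numeric(frame_interval_s),
         t0_offset_s = as.numeric(t0_offset_s),
         intestine_length_mm = as.numeric(intestine_length_mm),
         preparation_id = as.character(preparation_id),
         treatment = match.arg(treatment, c("lipid", "protein", "cellulose",
                                            "plastic_bead", "empty"))),
    class = "diameter_matrix")
  validate_diameter_matrix(dm)
}

validate_diameter_matrix <- function(dm) {
  v <- dm$values
  if (!is.matrix(v) || nrow(v) < 1 || ncol(v) < 2)
    stop("diameter matrix needs >= 1 position and >= 2 frames", call. = FALSE)
  if (anyNA(v) || any(!is.finite(v)))
    stop("diameters must be finite", call. = FALSE)
  if (any(v < 0))
    stop("negative diameters are not valid widths", call. = FALSE)
  if (!(dm$frame_interval_s > 0))
    stop("frame_interval_s must be > 0", call. = FALSE)
  if (!(dm$position_spacing_mm > 0))
    stop("position_spacing_mm must be > 0", call. = FALSE)
  span <- nrow(v) * dm$position_spacing_mm
  if (abs(span - dm$intestine_length_mm) > 0.01 * dm$intestine_length_mm)
    stop(sprintf("grid span %.3f mm disagrees with intestine_length_mm %.3f mm",
                 span, dm$intestine_length_mm), call. = FALSE)
  dm
}

#' @export
print.diameter_matrix <- function(x, ...) {
  cat(sprintf("<diameter_matrix> %s (%s)\n", x$preparation_id, x$treatment))
  cat(sprintf("  %d positions x %d frames | spacing %.3g mm | %.4g s/frame (%.3g fps)\n",
              nrow(x$values), ncol(x$values), x$position_spacing_mm,
              x$frame_interval_s, 1 / x$frame_interval_s))
  cat(sprintf("  length %.1f mm | span %.2f h from t0 = %.3g h\n",
              x$intestine_length_mm,
              ncol(x$values) * x$frame_interval_s / 3600,
              x$t0_offset_s / 3600))
  invisible(x)
}

#' Frame times of a diameter matrix
#' @param dm a [diameter_matrix()].
#' @return numeric vector of analysis-clock times (s), one per frame.
#' @export
frame_times <- function(dm) {
  dm$t0_offset_s + (seq_len(ncol(dm$values)) - 1) * dm$frame_interval_s
}

#' Position coordinates (mm, oral end = 0) of the rows of a diameter matrix
#' @inheritParams frame_times
#' @return numeric vector of cell-centre positions in mm.
#' @export
positions_mm <- function(dm) {
  (seq_len(nrow(dm$values)) - 0.5) * dm$position_spacing_mm
}

.meta_keys <- c("position_spacing_mm", "frame_interval_s", "t0_offset_s",
                "intestine_length_mm", "preparation_id", "treatment")

#' Read / write a diameter matrix
#'
#' The on-disk format is a plain TSV (one row per position, one column per
#' frame, '.' decimal separator) plus a flat key-value sidecar at
#' `<path>.meta` holding the calibration metadata. `write_diameter_matrix()`
#' and `read_diameter_matrix()` are exact inverses: metadata round-trips
#' bit-stably, grid values to better than 1e-9 mm.
#'
#' @param path path of the matrix TSV; the sidecar lives at `<path>.meta`.
#' @return `read_diameter_matrix()` returns a validated [diameter_matrix()];
#'   `write_diameter_matrix()` returns `path` invisibly.
#' @export
read_diameter_matrix <- function(path) {
  meta_path <- paste0(path, ".meta")
  if (!file.exists(path)) stop("matrix file not found: ", path, call. = FALSE)
  if (!file.exists(meta_path))
    stop("metadata sidecar not found: ", meta_path, call. = FALSE)
  lines <- readLines(meta_path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(kv) != 2))
    stop("malformed metadata sidecar (expected key<TAB>value lines)", call. = FALSE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  missing <- setdiff(.meta_keys, keys)
  if (length(missing))
    stop("metadata sidecar missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(keys))
    stop("metadata sidecar has duplicated (contradictory) keys", call. = FALSE)
  meta <- as.list(setNames(vals, keys))
  num <- function(k) {
    x <- suppressWarnings(as.numeric(meta[[k]]))
    if (is.na(x)) stop("non-numeric metadata value for ", k, call. = FALSE)
    x
  }
  values <- as.matrix(read.table(path, sep = "\t", header = FALSE,
                                 colClasses = "numeric"))
  dimnames(values) <- NULL
  diameter_matrix(values,
                  position_spacing_mm = num("position_spacing_mm"),
                  frame_interval_s = num("frame_interval_s"),
                  t0_offset_s = num("t0_offset_s"),
                  intestine_length_mm = num("intestine_length_mm"),
                  preparation_id = meta$preparation_id,
                  treatment = meta$treatment)
}

#' @param dm a [diameter_matrix()] to write.
#' @rdname read_diameter_matrix
#' @export
write_diameter_matrix <- function(dm, path) {
  validate_diameter_matrix(dm)
  write.table(format(dm$values, digits = 17, scientific = TRUE, trim = TRUE),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  meta <- c(position_spacing_mm = format(dm$position_spacing_mm, digits = 17),
            frame_interval_s = format(dm$frame_interval_s, digits = 17),
            t0_offset_s = format(dm$t0_offset_s, digits = 17),
            intestine_length_mm = format(dm$intestine_length_mm, digits = 17),
            preparation_id = dm$preparation_id,
            treatment = dm$treatment)
  writeLines(paste(names(meta), meta, sep = "\t"), paste0(path, ".meta"))
  invisible(path)
}

#' Keep every `stride`-th frame of a diameter matrix
#'
#' Frames 1, 1 + stride, 1 + 2*stride, ... are kept; the frame interval is
#' multiplied by `stride` and the analysis-clock origin is unchanged. Used to
#' bring a full-rate recording (3.5 fps) down to the validated analysis rates
#' (0.35 fps for emptying time, 3.5/3 fps for motility patterns).
#'
#' @inheritParams frame_times
#' @param stride positive integer subsampling factor.
#' @return a [diameter_matrix()].
#' @export
subsample_frames <- function(dm, stride) {
  if (length(stride) != 1 || is.na(stride) || stride < 1 ||
      stride != round(stride))
    stop("stride must be a positive integer", call. = FALSE)
  stride <- as.integer(stride)
  if (stride == 1L) return(dm)
  keep <- seq(1L, ncol(dm$values), by = stride)
  if (length(keep) < 2)
    stop("subsampling would leave fewer than 2 frames", call. = FALSE)
  dm$values <- dm$values[, keep, drop = FALSE]
  dm$frame_interval_s <- dm$frame_interval_s * stride
  validate_diameter_matrix(dm)
}

#' Partition an intestine into segments by length fractions
#'
#' Segment boundaries are placed at cumulative fractions of the intestine
#' length; positions are assigned by half-open intervals `[start, end)` so
#' every position belongs to exactly one segment. The default fractions are
#' the ballan wrasse averages: Segment 1 (bulbous) 39%, Segments 2 and 3 23%
#' each, Segment 4 (hindgut) 15%.
#'
#' @inheritParams frame_times
#' @param fractions four positive length fractions summing to 1 (tolerance
#'   1e-6).
#' @return An object of class `segment_partition` with `fractions`,
#'   `boundaries_mm` (five monotone cut positions from the oral end),
#'   `boundaries_idx` (half-open row-index intervals) and `segment_of`
#'   (segment index per position row).
#' @export
partition_segments <- function(dm, fractions = c(0.39, 0.23, 0.23, 0.15)) {
  if (length(fractions) != 4 || anyNA(fractions) || any(fractions <= 0))
    stop("fractions must be four positive numbers", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-6)
    stop("fractions must sum to 1", call. = FALSE)
  L <- dm$intestine_length_mm
  boundaries_mm <- c(0, cumsum(fractions)) * L
  boundaries_mm[5] <- L
  pos <- positions_mm(dm)
  seg <- findInterval(pos, boundaries_mm, rightmost.closed = FALSE,
                      left.open = FALSE)
  seg[seg > 4] <- 4L            # guard for positions at the anal cut point
  n <- nrow(dm$values)
  idx_start <- vapply(1:4, function(s) {
    w <- which(seg == s)
    if (length(w)) w[1] else NA_integer_
  }, 1L)
  idx_end <- vapply(1:4, function(s) {
    w <- which(seg == s)
    if (length(w)) w[length(w)] + 1L else NA_integer_
  }, 1L)
  if (any(is.na(idx_start)))
    stop("a segment contains no position sample; grid too coarse", call. = FALSE)
  structure(list(fractions = fractions,
                 boundaries_mm = boundaries_mm,
                 boundaries_idx = cbind(start = idx_start, end = idx_end),
                 segment_of = as.integer(seg),
                 segment_length_mm = diff(boundaries_mm),
                 intestine_length_mm = L),
            class = "segment_partition")
}

#' @export
print.segment_partition <- function(x, ...) {
  cat("<segment_partition>\n")
  for (s in 1:4)
    cat(sprintf("  Segment %d: [%6.2f, %6.2f) mm  (%.0f%%)\n", s,
                x$boundaries_mm[s], x$boundaries_mm[s + 1],
                100 * x$fractions[s]))
  invisible(x)
}

#' Segment index of arbitrary positions
#' @param part a [partition_segments()] result.
#' @param pos_mm positions (mm from the oral end).
#' @return integer segment indices (1-4).
#' @export
segment_of <- function(part, pos_mm) {
  seg <- findInterval(pos_mm, part$boundaries_mm)
  seg[seg < 1] <- 1L
  seg[seg > 4] <- 4L
  as.integer(seg)
}
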