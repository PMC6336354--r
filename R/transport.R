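#' @title Axonal transport, spatial distribution, ROI and spindle-tilt
#'   quantification
#' @description Kymograph-style track decomposition into directed runs and
#'   pauses, transport summaries, axon-length-normalized spatial
#'   distributions, background-subtracted ROI intensities, spindle tilt
#'   angles, and an exact 2x2 contingency test.
#' @name transport_analytics
NULL

#' Decompose a particle track into runs and pauses
#'
#' Positions are 1-D coordinates along the axon axis (increasing away from
#' the cell body). Per-frame velocities come from a centered moving
#' average of frame-to-frame displacements; frames are classed anterograde
#' (v > v_min), retrograde (v < -v_min) or pause, consecutive same-state
#' frames merged into segments (a within-track stretch framed by a pause
#' or a reversal). Pauses shorter than \code{min_pause_frames} flanked by
#' runs in the same direction are absorbed; a brief pause at a reversal is
#' kept. Segment statistics use the raw (unsmoothed) positions.
#'
#' @param positions positions in micrometers (>= 2).
#' @param dt frame interval in seconds.
#' @param v_min motion threshold in um/s (default 0.1).
#' @param smooth_window odd moving-average window in frames (default 3).
#' @param min_pause_frames minimum pause length in frames (default 2).
#' @return data.frame of class \code{"track_segments"}: \code{direction}
#'   (\code{"anterograde"}, \code{"retrograde"}, \code{"pause"}),
#'   \code{start_frame}, \code{end_frame}, \code{duration} (s),
#'   \code{run_length} (um, absolute), \code{velocity} (um/s, signed);
#'   attribute \code{truncated_window} when the track is shorter than the
#'   smoothing window.
#' @export
segment_track <- function(positions, dt, v_min = 0.1, smooth_window = 3L,
                          min_pause_frames = 2L) {
  stopifnot(length(positions) >= 2L, dt > 0, v_min > 0,
            smooth_window %% 2L == 1L)
  disp <- diff(positions)
  n <- length(disp)
  truncated <- n < smooth_window
  half <- (smooth_window - 1L) %/% 2L
  v <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(disp[lo:hi]) / dt
  }, numeric(1))
  state <- ifelse(v > v_min, 1L, ifelse(v < -v_min, -1L, 0L))
  runs <- rle(state)
  # absorb short pauses flanked by same-direction runs
  repeat {
    k <- which(runs$values == 0L & runs$lengths < min_pause_frames)
    k <- k[k > 1L & k < length(runs$values)]
    k <- k[runs$values[k - 1L] == runs$values[k + 1L] & runs$values[k - 1L] != 0L]
    if (!length(k)) break
    runs$values[k[1]] <- runs$values[k[1] - 1L]
    runs <- rle(inverse.rle(runs))
  }
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  segs <- lapply(seq_along(runs$values), function(j) {
    f0 <- starts[j]; f1 <- ends[j]          # displacement-interval indices
    x0 <- positions[f0]; x1 <- positions[f1 + 1L]
    dur <- (f1 - f0 + 1L) * dt
    data.frame(
      direction = c("retrograde", "pause", "anterograde")[runs$values[j] + 2L],
      start_frame = f0, end_frame = f1 + 1L,
      duration = dur, run_length = abs(x1 - x0),
      velocity = (x1 - x0) / dur)
  })
  out <- do.call(rbind, segs)
  attr(out, "truncated_window") <- truncated
  class(out) <- c("track_segments", "data.frame")
  out
}

#' Summarize transport over a set of tracks
#'
#' Particle direction is assigned from the net displacement between the
#' first and last position of the track: net movement smaller in magnitude
#' than \code{d_min} is stationary, otherwise the sign decides (positive =
#' anterograde, toward the tip). Segment-level velocity and run-length
#' statistics are pooled over all tracks; per-track time fractions in each
#' state and pause statistics are averaged over tracks.
#'
#' @param tracks list of numeric position vectors (um), or a data.frame
#'   with columns \code{track_id}, \code{frame}, \code{position_um}.
#' @param dt frame interval (s).
#' @param d_min net-displacement threshold (um, default 0.3).
#' @param ... segmentation parameters passed to [segment_track()].
#' @return list of class \code{"transport_summary"}:
#'   \code{particle_fractions} (anterograde/retrograde/stationary, sums to
#'   1), \code{time_fractions} (mean per-track fraction of time in each
#'   state, sums to 1), \code{segments} (pooled segment table with
#'   track ids), \code{pause_duration_mean} (s),
#'   \code{pause_frequency} (pauses per second of track time),
#'   \code{n_tracks}.
#' @export
summarize_transport <- function(tracks, dt, d_min = 0.3, ...) {
  if (is.data.frame(tracks)) {
    stopifnot(all(c("track_id", "frame", "position_um") %in% names(tracks)))
    tracks <- lapply(split(tracks, tracks$track_id), function(d)
      d$position_um[order(d$frame)])
  }
  stopifnot(length(tracks) >= 1L)
  net <- vapply(tracks, function(p) p[length(p)] - p[1], numeric(1))
  dir <- ifelse(abs(net) < d_min, "stationary",
                ifelse(net > 0, "anterograde", "retrograde"))
  pf <- c(anterograde = mean(dir == "anterograde"),
          retrograde = mean(dir == "retrograde"),
          stationary = mean(dir == "stationary"))
  seg_list <- lapply(seq_along(tracks), function(i) {
    s <- segment_track(tracks[[i]], dt, ...)
    s$track_id <- i
    s
  })
  tf_mat <- t(vapply(seg_list, function(s) {
    tot <- sum(s$duration)
    c(anterograde = sum(s$duration[s$direction == "anterograde"]) / tot,
      retrograde = sum(s$duration[s$direction == "retrograde"]) / tot,
      pause = sum(s$duration[s$direction == "pause"]) / tot)
  }, numeric(3)))
  segments <- do.call(rbind, seg_list)
  pauses <- segments[segments$direction == "pause", ]
  total_time <- sum(segments$duration)
  structure(list(
    particle_fractions = pf,
    time_fractions = colMeans(tf_mat),
    segments = segments,
    pause_duration_mean = if (nrow(pauses)) mean(pauses$duration) else 0,
    pause_frequency = nrow(pauses) / total_time,
    n_tracks = length(tracks)), class = "transport_summary")
}

#' Axon-length-normalized spatial statistics
#'
#' Relative positions in percent of axon length (0% = cell body, 100% =
#' tip), linear density per 100 um, and equal-width binned counts of the
#' relative distribution.
#'
#' @param positions particle positions (um from the cell body).
#' @param axon_length total axon length (um).
#' @param n_bins number of equal-width bins over \[0, 100\]% (default 10).
#' @return list: \code{relative_pct}, \code{density_per_100um},
#'   \code{bins} (data.frame bin_start_pct/bin_end_pct/count),
#'   \code{axon_length}.
#' @export
axon_spatial_stats <- function(positions, axon_length, n_bins = 10L) {
  stopifnot(axon_length > 0, n_bins >= 1L)
  if (any(positions < 0 | positions > axon_length))
    stop("position(s) outside [0, axon_length]")
  rel <- positions / axon_length * 100
  br <- seq(0, 100, length.out = n_bins + 1L)
  counts <- as.integer(table(cut(rel, br, include.lowest = TRUE)))
  list(relative_pct = rel,
       density_per_100um = length(positions) / axon_length * 100,
       bins = data.frame(bin_start_pct = utils::head(br, -1L),
                         bin_end_pct = br[-1L], count = counts),
       axon_length = axon_length)
}

# binary box dilation of a logical matrix by px pixels (Chebyshev ball)
.dilate_mask <- function(mask, px) {
  out <- mask
  for (k in seq_len(px)) {
    nr <- nrow(out); nc <- ncol(out)
    r <- out
    r[-1, ] <- r[-1, ] | out[-nr, ]
    r[-nr, ] <- r[-nr, ] | out[-1, ]
    cdil <- r
    cdil[, -1] <- cdil[, -1] | r[, -nc]
    cdil[, -nc] <- cdil[, -nc] | r[, -1]
    out <- cdil
  }
  out
}

#' Background-subtracted integrated ROI intensity
#'
#' Expands the inner region by \code{dilation_px} pixels; the intensity
#' difference between the expanded and inner regions, normalized to the
#' ring area, defines the per-pixel background, and the final integrated
#' signal is the inner intensity minus background scaled to the inner
#' area.
#'
#' @param image numeric matrix of intensities.
#' @param inner_mask logical matrix, same dimensions, the inner region.
#' @param dilation_px pixels of expansion (default 2).
#' @return list of class \code{"roi_quant"}: \code{area_in},
#'   \code{area_out}, \code{I_in}, \code{I_out},
#'   \code{background_per_px}, \code{final} (counts).
#' @export
roi_integrated_intensity <- function(image, inner_mask, dilation_px = 2L) {
  stopifnot(is.matrix(image), identical(dim(image), dim(inner_mask)))
  if (!any(inner_mask)) stop("inner mask is empty")
  outer_mask <- .dilate_mask(inner_mask, dilation_px)
  a_in <- sum(inner_mask); a_out <- sum(outer_mask)
  if (a_out <= a_in)
    stop("dilation produced no ring (outer area equals inner area)")
  i_in <- sum(image[inner_mask]); i_out <- sum(image[outer_mask])
  bg <- (i_out - i_in) / (a_out - a_in)
  structure(list(area_in = a_in, area_out = a_out, I_in = i_in,
                 I_out = i_out, background_per_px = bg,
                 final = i_in - bg * a_in), class = "roi_quant")
}

#' Spindle tilt angle between centrosome and anterior-posterior axes
#'
#' Axis angle between the centrosome-centrosome vector and the embryo
#' long (A-P) axis, folded into \[0, 90\] degrees.
#'
#' @param centrosome_1,centrosome_2 (x, y) coordinates (um).
#' @param pole_a,pole_p the two outermost points along the embryo long
#'   axis.
#' @return angle alpha in degrees.
#' @export
spindle_tilt_angle <- function(centrosome_1, centrosome_2, pole_a, pole_p) {
  u <- c(centrosome_2[1] - centrosome_1[1], centrosome_2[2] - centrosome_1[2])
  v <- c(pole_p[1] - pole_a[1], pole_p[2] - pole_a[2])
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("coincident points define no axis")
  ct <- abs(sum(u * v)) / (nu * nv)
  acos(pmin(pmax(ct, -1), 1)) * 180 / pi
}

#' Bin tilt angles for a rose diagram
#'
#' @param angles angles in degrees, each in \[0, 90\].
#' @param bin_width bin width in degrees (default 15).
#' @return data.frame: \code{bin_start}, \code{bin_end}, \code{count}.
#' @export
rose_bins <- function(angles, bin_width = 15) {
  stopifnot(all(angles >= 0 & angles <= 90))
  br <- seq(0, 90, by = bin_width)
  if (utils::tail(br, 1) < 90) br <- c(br, 90)
  counts <- as.integer(table(cut(angles, br, include.lowest = TRUE)))
  data.frame(bin_start = utils::head(br, -1L), bin_end = br[-1L],
             count = counts)
}

#' Exact test on a 2x2 contingency table
#'
#' Hypergeometric enumeration over all tables with the observed margins.
#' The two-sided p-value sums the point probabilities of all tables no
#' more probable than the observed one (minimum-likelihood rule), using a
#' 1e-7 relative tolerance on the comparison to absorb floating-point
#' ties; the one-sided p-value is the upper-tail sum for cell \code{a}.
#' Point probabilities are evaluated in log space.
#'
#' @param a,b,c,d nonnegative integer counts: rows are conditions, columns
#'   outcomes (\code{a} and \code{b} form the first row).
#' @param sided \code{"two"} (default) or \code{"one"}.
#' @return the p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d, sided = c("two", "one")) {
  sided <- match.arg(sided)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b > 0, c + d > 0)
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0L, k - n); hi <- min(k, m)
  xs <- lo:hi
  logp <- stats::dhyper(xs, m, n, k, log = TRUE)
  log_obs <- stats::dhyper(a, m, n, k, log = TRUE)
  if (sided == "one") {
    sum(exp(logp[xs >= a]))
  } else {
    min(sum(exp(logp[logp <= log_obs + log1p(1e-7)])), 1)
  }
}
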