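# Synthetic beating videos and block-wise frequency / phase mapping.
#
# The generator emulates time-lapse recordings of spontaneously beating
# cardiomyocyte cultures: a periodic intensity pulsation at a set beating
# rate with a spatially linear phase lag plus additive noise. The analysis
# follows the temporal peak-detection approach: block-mean intensity
# traces, prominence-filtered local maxima, local frequency from the
# median inter-peak interval, and temporal phase shift of each block's
# beats against a reference trace.

#' Specification of a synthetic beating video
#'
#' @param frames number of frames.
#' @param fps frame rate (Hz); must exceed twice the beating frequency.
#' @param frame_size frame side length (pixels).
#' @param base_frequency beating rate (beats per minute).
#' @param phase_gradient phase lag per pixel along the x axis (degrees of
#'   the beat cycle per pixel).
#' @param pulse_shape `"sinusoid"` or `"gaussian_pulse"` (a narrow pulse
#'   train, closer to real contraction transients).
#' @param noise_level additive Gaussian noise relative to the pulsation
#'   amplitude.
#' @param phase_offset constant phase added everywhere (degrees); useful
#'   to emulate a global temporal shift.
#' @param seed RNG seed.
#' @return an object of class `beating_video_spec`.
#' @export
beating_video_spec <- function(frames = 300, fps = 30, frame_size = 64,
                               base_frequency = 60, phase_gradient = 0,
                               pulse_shape = c("sinusoid", "gaussian_pulse"),
                               noise_level = 0, phase_offset = 0, seed = 1) {
  pulse_shape <- match.arg(pulse_shape)
  f_hz <- base_frequency / 60
  if (fps <= 2 * f_hz)
    stopf("sampling-inadequate spec: fps (%g) must exceed twice the beating frequency (%g Hz)",
          fps, f_hz)
  if (frames < 3 || frame_size < 1) stopf("degenerate video dimensions")
  structure(as.list(environment()), class = "beating_video_spec")
}

#' Generate a synthetic beating video
#'
#' Produces an intensity stack (x, y, t) whose traces oscillate at the
#' base frequency with a linear spatial phase lag along x, plus noise.
#' Deterministic for a fixed spec and seed.
#'
#' @param spec a [beating_video_spec()].
#' @return 3D array (x, y, frame) with attributes `fps` and `spec`.
#' @export
generate_beating_video <- function(spec) {
  stopifnot(inherits(spec, "beating_video_spec"))
  s <- spec
  f_hz <- s$base_frequency / 60
  tt <- (seq_len(s$frames) - 1) / s$fps
  phase_px <- ((seq_len(s$frame_size) - 1) * s$phase_gradient +
                 s$phase_offset) * pi / 180
  with_seed(s$seed, {
    stack <- array(0, dim = c(s$frame_size, s$frame_size, s$frames))
    for (ix in seq_len(s$frame_size)) {
      ph <- 2 * pi * f_hz * tt - phase_px[ix]
      trace <- if (s$pulse_shape == "sinusoid") {
        0.5 + 0.4 * sin(ph)
      } else {
        cyc <- (ph / (2 * pi)) %% 1
        0.1 + 0.8 * exp(-((cyc - 0.5) / 0.08)^2)
      }
      stack[ix, , ] <- matrix(trace, s$frame_size, s$frames, byrow = TRUE)
    }
    if (s$noise_level > 0)
      stack <- stack + array(stats::rnorm(length(stack), 0,
                                          s$noise_level * 0.4),
                             dim = dim(stack))
    attr(stack, "fps") <- s$fps
    attr(stack, "spec") <- s
    stack
  })
}

#' Temporal peak detection on an intensity trace
#'
#' Local maxima filtered by topographic prominence and a minimum
#' inter-peak spacing (higher peaks win). A constant trace yields no
#' peaks. Deterministic.
#'
#' @param trace numeric intensity time series (length >= 3).
#' @param min_prominence minimum peak prominence; default 0.2 times the
#'   trace amplitude (max - min).
#' @param min_interval minimum peak spacing in seconds (with `fps`) or in
#'   samples (`fps = NULL`); default 0.25 s.
#' @param fps sampling rate (Hz); if given, returned `times` are seconds.
#' @return list with integer `index` and, with `fps`, numeric `times`.
#' @export
detect_peaks <- function(trace, min_prominence = NULL, min_interval = 0.25,
                         fps = NULL) {
  x <- as.numeric(trace)
  n <- length(x)
  if (n < 3) stopf("trace must have length >= 3")
  amp <- max(x) - min(x)
  if (amp == 0)
    return(list(index = integer(0),
                times = if (!is.null(fps)) numeric(0)))
  if (is.null(min_prominence)) min_prominence <- 0.2 * amp
  min_gap <- if (is.null(fps)) max(1, round(min_interval))
             else max(1, round(min_interval * fps))

  # strict local maxima; plateaus contribute their first sample
  up <- c(FALSE, diff(x) > 0)
  down <- c(diff(x) < 0, FALSE)
  flat <- c(diff(x) == 0, FALSE)
  # propagate "rising" state through plateaus
  state <- up
  for (i in 2:n) if (flat[i - 1] && i > 1) state[i] <- state[i - 1]
  cand <- which(state & down)

  if (!length(cand)) return(list(index = integer(0),
                                 times = if (!is.null(fps)) numeric(0)))
  prom <- vapply(cand, function(i) {
    h <- x[i]
    l <- i - 1; lmin <- h
    while (l >= 1 && x[l] <= h) { lmin <- min(lmin, x[l]); l <- l - 1 }
    if (l < 1) lmin <- min(x[1:i])
    r <- i + 1; rmin <- h
    while (r <= n && x[r] <= h) { rmin <- min(rmin, x[r]); r <- r + 1 }
    if (r > n) rmin <- min(x[i:n])
    h - max(lmin, rmin)
  }, 0)
  keep <- cand[prom >= min_prominence]
  if (length(keep) > 1) {
    ord <- keep[order(-x[keep], keep)]
    sel <- integer(0)
    for (i in ord) if (!length(sel) || min(abs(sel - i)) >= min_gap)
      sel <- c(sel, i)
    keep <- sort(sel)
  }
  list(index = keep, times = if (!is.null(fps)) (keep - 1) / fps)
}

# sub-frame peak-time refinement: parabolic fit through the peak sample
# and its neighbours, removing most of the frame-quantisation jitter
refine_peak_times <- function(trace, idx, fps) {
  t0 <- (idx - 1) / fps
  ok <- idx > 1 & idx < length(trace)
  if (any(ok)) {
    i <- idx[ok]
    denom <- trace[i - 1] - 2 * trace[i] + trace[i + 1]
    shift <- ifelse(abs(denom) > 1e-12,
                    0.5 * (trace[i - 1] - trace[i + 1]) / denom, 0)
    t0[ok] <- t0[ok] + pmax(pmin(shift, 0.5), -0.5) / fps
  }
  t0
}

block_traces <- function(stack, block_size) {
  d <- dim(stack)
  nbx <- d[1] %/% block_size; nby <- d[2] %/% block_size
  if (nbx < 1 || nby < 1) stopf("block_size larger than the frame")
  traces <- array(0, dim = c(nbx, nby, d[3]))
  for (bx in seq_len(nbx)) for (by in seq_len(nby)) {
    xs <- ((bx - 1) * block_size + 1):(bx * block_size)
    ys <- ((by - 1) * block_size + 1):(by * block_size)
    traces[bx, by, ] <- apply(stack[xs, ys, , drop = FALSE], 3, mean)
  }
  traces
}

# beating validity: enough peaks, tight interval spread, and genuine
# periodicity (autocorrelation at the candidate beat period); the last
# criterion rejects noise-only traces whose spurious peaks are spaced
# quasi-regularly by the minimum-interval rule alone
valid_block <- function(trace, pk_times, fps, n_min = 2, acf_min = 0.25) {
  n <- length(pk_times)
  if (n < n_min) return(FALSE)
  if (n >= 4) {
    iv <- diff(pk_times)
    if (stats::IQR(iv) > 0.5 * stats::median(iv)) return(FALSE)
    lag <- round(stats::median(iv) * fps)
    if (lag >= 1 && lag < length(trace) - 2) {
      x <- trace - mean(trace)
      m <- length(x) - lag
      r <- sum(x[1:m] * x[(lag + 1):(m + lag)]) /
        (sqrt(sum(x[1:m]^2)) * sqrt(sum(x[(lag + 1):(m + lag)]^2)) + 1e-30)
      if (r < acf_min) return(FALSE)
    }
  }
  TRUE
}

#' Block-wise beating frequency and phase maps
#'
#' `frequency_map()` splits the stack into square blocks, detects beats on
#' each block-mean trace and reports the local frequency as the reciprocal
#' median inter-peak interval; blocks without at least two regular beats
#' are masked invalid. `phase_map()` additionally reports each valid
#' block's temporal phase shift — the circular mean offset of its beat
#' times from the nearest beats of a reference trace, expressed in degrees
#' of the beat cycle.
#'
#' @param stack 3D intensity array (x, y, frame), e.g. from
#'   [generate_beating_video()].
#' @param block_size block side length (pixels), default 16.
#' @param fps frame rate (Hz); defaults to the stack's `fps` attribute.
#' @param min_prominence,min_interval peak-detection controls, see
#'   [detect_peaks()].
#' @param reference `"global_mean"` (phase relative to the whole-field
#'   mean trace) or `"block"` (relative to the block at `ref_block`, which
#'   then has phase 0 by definition).
#' @param ref_block reference block indices (length 2) for
#'   `reference = "block"`.
#' @return an object of class `beating_maps` with `frequency` (Hz),
#'   `phase` (degrees, `NA` on invalid blocks), `valid`, `block_size` and
#'   block centre coordinates.
#' @export
frequency_map <- function(stack, block_size = 16, fps = NULL,
                          min_prominence = NULL, min_interval = 0.25) {
  fps <- fps %||% attr(stack, "fps")
  if (is.null(fps)) stopf("fps must be given (or carried by the stack)")
  tr <- block_traces(stack, block_size)
  nb <- dim(tr)[1:2]
  freq <- matrix(NA_real_, nb[1], nb[2])
  valid <- matrix(FALSE, nb[1], nb[2])
  for (bx in seq_len(nb[1])) for (by in seq_len(nb[2])) {
    pk <- detect_peaks(tr[bx, by, ], min_prominence, min_interval, fps)
    if (valid_block(tr[bx, by, ], pk$times, fps)) {
      valid[bx, by] <- TRUE
      freq[bx, by] <- 1 / stats::median(diff(pk$times))
    }
  }
  if (!any(valid)) warning("no valid blocks: no regular beating detected")
  structure(list(frequency = freq, phase = NULL, valid = valid,
                 block_size = block_size, fps = fps,
                 block_x = (seq_len(nb[1]) - 0.5) * block_size,
                 block_y = (seq_len(nb[2]) - 0.5) * block_size),
            class = "beating_maps")
}

#' @rdname frequency_map
#' @export
phase_map <- function(stack, block_size = 16, fps = NULL,
                      min_prominence = NULL, min_interval = 0.25,
                      reference = c("global_mean", "block"),
                      ref_block = c(1, 1)) {
  reference <- match.arg(reference)
  fps <- fps %||% attr(stack, "fps")
  if (is.null(fps)) stopf("fps must be given (or carried by the stack)")
  maps <- frequency_map(stack, block_size, fps, min_prominence,
                        min_interval)
  tr <- block_traces(stack, block_size)
  ref_trace <- if (reference == "global_mean") apply(stack, 3, mean)
               else tr[ref_block[1], ref_block[2], ]
  ref_pk <- detect_peaks(ref_trace, min_prominence, min_interval, fps)
  if (length(ref_pk$times) < 2)
    stopf("reference trace has no regular beats")
  ref_times <- refine_peak_times(ref_trace, ref_pk$index, fps)
  period <- stats::median(diff(ref_times))
  nb <- dim(tr)[1:2]
  phase <- matrix(NA_real_, nb[1], nb[2])
  for (bx in seq_len(nb[1])) for (by in seq_len(nb[2])) {
    if (!maps$valid[bx, by]) next
    pk <- detect_peaks(tr[bx, by, ], min_prominence, min_interval, fps)
    pk_times <- refine_peak_times(tr[bx, by, ], pk$index, fps)
    off <- vapply(pk_times, function(tm)
      tm - ref_times[which.min(abs(ref_times - tm))], 0)
    ph <- off / period * 360
    # circular mean of per-beat offsets
    phase[bx, by] <- atan2(mean(sin(ph * pi / 180)),
                           mean(cos(ph * pi / 180))) * 180 / pi
  }
  maps$phase <- phase
  maps
}

#' @export
print.beating_maps <- function(x, ...) {
  nv <- sum(x$valid)
  cat("Block-wise beating maps (", nrow(x$valid), "x", ncol(x$valid),
      " blocks, ", nv, " valid)\n", sep = "")
  if (nv) {
    cat(sprintf("  median frequency: %.3g Hz (%.3g bpm)\n",
                stats::median(x$frequency[x$valid]),
                60 * stats::median(x$frequency[x$valid])))
    if (!is.null(x$phase))
      cat(sprintf("  phase range: [%.1f, %.1f] deg\n",
                  min(x$phase, na.rm = TRUE), max(x$phase, na.rm = TRUE)))
  }
  invisible(x)
}

#' Heatmap plot of beating maps
#' @param x a `beating_maps` object.
#' @param which `"frequency"` or `"phase"`.
#' @param ... passed to [graphics::image()].
#' @export
plot.beating_maps <- function(x, which = c("frequency", "phase"), ...) {
  which <- match.arg(which)
  m <- if (which == "frequency") x$frequency else x$phase
  if (is.null(m)) stopf("no %s map present", which)
  graphics::image(x$block_x, x$block_y, m, xlab = "x (px)", ylab = "y (px)",
                  main = paste("local", which), ...)
  invisible(x)
}

#' Multi-page TIFF video I/O
#'
#' @param stack 3D intensity array (x, y, frame), values in [0, 1].
#' @param file output path (.tif/.tiff).
#' @param fps frame rate stored alongside on read via argument.
#' @return `read_video_tiff` returns the stack array.
#' @export
write_video_tiff <- function(stack, file) {
  EBImage::writeImage(EBImage::Image(stack), file, bits.per.sample = 16L)
  invisible(file)
}

#' @rdname write_video_tiff
#' @export
read_video_tiff <- function(file, fps = NULL) {
  x <- EBImage::imageData(EBImage::readImage(file))
  if (!is.null(fps)) attr(x, "fps") <- fps
  x
}
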