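#' Repetition segmentation and the working-phase ROM statistic
#'
#' A session trace is segmented into repetitions at the local minima between
#' successive excursion peaks; each repetition is length-normalized, its
#' working phase (the near-maximal plateau) is isolated by amplitude
#' normalization, and the ROM is the mean raw angle over the working phase
#' minus the rest baseline. A plain max-minus-min range is deliberately only
#' a secondary diagnostic: with guided hold-phase exercises it is dominated
#' by transient overshoot rather than the maintained excursion.
#'
#' @name segmentation
NULL

# local maxima with topographic prominence; flat peaks report the middle
# index of the tied run
find_peaks <- function(x, min_prominence) {
  n <- length(x)
  if (n < 3) return(integer(0))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(r$values)
  peaks <- integer(0)
  for (j in seq_len(k)) {
    left <- if (j > 1) r$values[j - 1] else -Inf
    right <- if (j < k) r$values[j + 1] else -Inf
    if (r$values[j] > left && r$values[j] > right &&
        (j > 1 || k == 1) && (j < k || k == 1)) {
      peaks <- c(peaks, floor((starts[j] + ends[j]) / 2))
    }
  }
  if (!length(peaks)) return(integer(0))
  prom <- vapply(peaks, function(p) peak_prominence(x, p), numeric(1))
  peaks <- peaks[prom >= min_prominence]
  if (length(peaks) < 2) return(peaks)
  # merge peaks not separated by a valley at least min_prominence deep
  # (exact plateau ties would otherwise register several peaks per hold)
  kept <- peaks[1]
  for (p in peaks[-1]) {
    last <- kept[length(kept)]
    valley <- min(x[last:p])
    if (valley <= min(x[last], x[p]) - min_prominence) {
      kept <- c(kept, p)
    } else if (x[p] > x[last]) {
      kept[length(kept)] <- p
    }
  }
  kept
}

# prominence: height above the higher of the two key saddles (lowest point
# between the peak and the nearest higher terrain on each side)
peak_prominence <- function(x, p) {
  n <- length(x)
  left_min <- x[p]
  i <- p
  while (i > 1) {
    i <- i - 1
    if (x[i] > x[p]) break
    left_min <- min(left_min, x[i])
  }
  if (i == 1 && x[1] <= x[p]) left_min <- min(left_min, x[1])
  right_min <- x[p]
  i <- p
  while (i < n) {
    i <- i + 1
    if (x[i] > x[p]) break
    right_min <- min(right_min, x[i])
  }
  if (i == n && x[n] <= x[p]) right_min <- min(right_min, x[n])
  x[p] - max(left_min, right_min)
}

# middle index of the (possibly tied) minimum of x[lo:hi]
argmin_mid <- function(x, lo, hi) {
  seg <- x[lo:hi]
  idx <- which(seg <= min(seg) + 1e-12)
  lo + idx[ceiling(length(idx) / 2)] - 1L
}

#' Detect repetitions in an aligned trace
#'
#' Finds the excursion peaks with topographic prominence at least
#' `prominence_frac` of the trace's global excursion, places repetition
#' boundaries at the local minima between successive peaks (and before the
#' first / after the last), and returns each repetition resampled to
#' `n_points` samples. Traces whose dominant excursion is negative (e.g.
#' bending to the opposite side) are segmented on the negated signal.
#'
#' @param trace an [angle_trace] (aligned, offset-corrected)
#' @param expected_n expected number of repetitions; a mismatch triggers a
#'   warning with diagnostics, never silent truncation
#' @param prominence_frac minimum peak prominence as a fraction of the
#'   global excursion (default 0.25)
#' @param n_points resample length per repetition (default 101, the
#'   gait-cycle convention)
#' @param smooth_fc cutoff of the zero-phase FIR low-pass applied before
#'   detection, Hz (default 4: well above the repetition band, low enough
#'   to keep sample-to-sample sensor noise from faking prominence peaks);
#'   `NULL` disables smoothing. Cycles are cut from the smoothed trace.
#' @return an object of class `repetition_set`: `boundaries` (sample
#'   indices, one more than the number of repetitions), `cycles` (list of
#'   resampled repetition series, raw units), `cycles_raw` (unresampled),
#'   `n_points`, `negated` (whether the trace was sign-flipped for
#'   detection)
#' @export
detect_repetitions <- function(trace, expected_n = NULL,
                               prominence_frac = 0.25, n_points = 101,
                               smooth_fc = 4) {
  stopifnot(inherits(trace, "angle_trace"))
  x <- trace$values
  if (!is.null(smooth_fc) && smooth_fc < trace$rate / 2) {
    taps <- min(61L, 2L * floor((length(x) - 1) / 2) + 1L)
    if (taps >= 5L) {
      x <- fir_apply(x, fir_sinc_lowpass(smooth_fc, trace$rate, taps))
    }
  }
  exc <- max(x) - min(x)
  if (exc <= 1e-9) stop("segmentation failure: trace has no excursion")
  # rest baseline = start of the trace (pre-task rest); a dominant negative
  # excursion (e.g. bending to the other side) is segmented on -x
  k0 <- max(2L, min(length(x), round(trace$rate)))
  baseline <- stats::median(x[1:k0])
  negated <- (baseline - min(x)) > (max(x) - baseline)
  if (negated) x <- -x
  peaks <- find_peaks(x, min_prominence = prominence_frac * exc)
  if (length(peaks) < 1) {
    stop("segmentation failure: no repetition peaks above the prominence threshold")
  }
  bounds <- integer(length(peaks) + 1)
  bounds[1] <- argmin_mid(x, 1L, peaks[1])
  if (length(peaks) > 1) {
    for (i in seq_len(length(peaks) - 1)) {
      bounds[i + 1] <- argmin_mid(x, peaks[i], peaks[i + 1])
    }
  }
  bounds[length(bounds)] <- argmin_mid(x, peaks[length(peaks)], length(x))
  if (any(diff(bounds) < 2)) {
    stop("segmentation failure: degenerate repetition boundaries")
  }
  n_rep <- length(peaks)
  if (!is.null(expected_n) && n_rep != expected_n) {
    warning(sprintf(
      "detected %d repetitions but expected %d (peaks at samples: %s)",
      n_rep, expected_n, paste(peaks, collapse = ", ")
    ))
  }
  sign_fac <- if (negated) -1 else 1
  cycles_raw <- lapply(seq_len(n_rep), function(i) {
    sign_fac * x[bounds[i]:bounds[i + 1]]
  })
  cycles <- lapply(cycles_raw, resample_cycle, n_points = n_points)
  structure(
    list(boundaries = bounds, cycles = cycles, cycles_raw = cycles_raw,
         n_points = as.integer(n_points), negated = negated,
         rate = trace$rate, task_name = trace$task_name,
         system = trace$system),
    class = "repetition_set"
  )
}

#' @export
print.repetition_set <- function(x, ...) {
  cat(sprintf(
    "<repetition_set> %s/%s: %d repetitions, %d points each%s\n",
    x$system, x$task_name, length(x$cycles), x$n_points,
    if (x$negated) " (negative excursion)" else ""
  ))
  invisible(x)
}

#' Resample a repetition cycle to a fixed length
#'
#' Linear-interpolation resampling onto `n_points` equally spaced points
#' over the cycle's support; the first and last samples are preserved
#' exactly, and affine segments are reproduced exactly.
#'
#' @param cycle numeric angle series of one repetition (length >= 4)
#' @param n_points target length (default 101)
#' @return numeric vector of length `n_points`
#' @export
resample_cycle <- function(cycle, n_points = 101) {
  cycle <- as.numeric(cycle)
  if (length(cycle) < 4) stop("cycle too short to resample (need >= 4 samples)")
  stats::approx(seq(0, 1, length.out = length(cycle)), cycle,
                xout = seq(0, 1, length.out = n_points))$y
}

#' Isolate the working phase of a repetition
#'
#' Amplitude-normalizes the cycle to `[0, 1]` and returns the longest
#' contiguous run of samples with normalized value at least `tau`: the
#' plateau on which the subject holds the near-maximal excursion.
#'
#' @param cycle numeric angle series of one repetition
#' @param tau plateau threshold on the normalized amplitude (default 0.9);
#'   `tau = 1` degenerates to the argmax sample(s)
#' @return integer vector `c(start, end)` of window sample indices
#' @export
working_phase <- function(cycle, tau = 0.9) {
  cycle <- as.numeric(cycle)
  rng <- range(cycle)
  if (diff(rng) <= 1e-12) stop("flat cycle: working phase undefined")
  stopifnot(tau > 0, tau <= 1)
  z <- (cycle - rng[1]) / diff(rng)
  ok <- z >= tau - 1e-12
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  c(starts[best], ends[best])
}

#' Working-phase ROM of one repetition
#'
#' The primary statistic is the mean of the raw (un-normalized) angle over
#' the working phase minus the rest baseline: it measures how well the
#' subject maintains the maximal excursion during the hold. Alternatives:
#' `"final_position"` (raw angle at the last working-phase sample minus the
#' baseline) and the `"max_min"` range, kept as a secondary diagnostic only.
#' Cycles with a dominant negative excursion are flipped so the returned
#' ROM is positive.
#'
#' @param cycle numeric angle series of one repetition (raw degrees)
#' @param rest_value rest baseline angle, degrees (default 0)
#' @param tau plateau threshold (see [working_phase()])
#' @param mode `"working_mean"` (default), `"final_position"`, or `"max_min"`
#' @return ROM in degrees
#' @export
compute_rom <- function(cycle, rest_value = 0, tau = 0.9,
                        mode = c("working_mean", "final_position", "max_min")) {
  mode <- match.arg(mode)
  cycle <- as.numeric(cycle)
  if (mode == "max_min") return(max(cycle) - min(cycle))
  up <- max(cycle) - rest_value
  down <- rest_value - min(cycle)
  if (down > up) {
    cycle <- -cycle
    rest_value <- -rest_value
  }
  win <- working_phase(cycle, tau = tau)
  if (mode == "working_mean") {
    mean(cycle[win[1]:win[2]]) - rest_value
  } else {
    cycle[win[2]] - rest_value
  }
}

#' Per-repetition ROM estimates for one task/system
#'
#' @param per_rep_rom numeric vector of per-repetition ROMs, degrees
#' @param task_name,system labels
#' @param pooled whether left/right sides have been pooled
#' @return an object of class `rom_estimate` with `per_rep_rom`,
#'   `mean_rom`, `sd_rom`, `n`
#' @export
rom_estimate <- function(per_rep_rom, task_name = NA_character_,
                         system = c("IMU", "MoCap"), pooled = FALSE) {
  system <- match.arg(system)
  per_rep_rom <- as.numeric(per_rep_rom)
  if (!length(per_rep_rom)) stop("need at least one repetition ROM")
  structure(
    list(per_rep_rom = per_rep_rom, mean_rom = mean(per_rep_rom),
         sd_rom = stats::sd(per_rep_rom), n = length(per_rep_rom),
         task_name = task_name, system = system, pooled = pooled),
    class = "rom_estimate"
  )
}

#' @export
print.rom_estimate <- function(x, ...) {
  cat(sprintf(
    "<rom_estimate> %s/%s: %.2f (%.2f) deg over %d reps%s\n",
    x$system, x$task_name, x$mean_rom,
    if (is.na(x$sd_rom)) 0 else x$sd_rom, x$n,
    if (x$pooled) " [sides pooled]" else ""
  ))
  invisible(x)
}

#' ROM estimate from an aligned trace
#'
#' Segments the trace and computes the working-phase ROM of every
#' repetition against a shared rest baseline.
#'
#' @param trace aligned, offset-corrected [angle_trace]
#' @param expected_n expected repetition count
#' @param rest_value rest baseline, degrees; default: mean of the first
#'   second of the trace (the pre-task rest window, shared with the offset
#'   estimation stage)
#' @param tau plateau threshold
#' @param n_points resample length
#' @return a [rom_estimate()]
#' @export
trace_to_rom <- function(trace, expected_n = NULL, rest_value = NULL,
                         tau = 0.9, n_points = 101) {
  if (is.null(rest_value)) {
    k <- max(2L, min(length(trace$values), round(trace$rate)))
    rest_value <- mean(trace$values[1:k])
  }
  reps <- detect_repetitions(trace, expected_n = expected_n,
                             n_points = n_points)
  roms <- vapply(reps$cycles, compute_rom, numeric(1),
                 rest_value = rest_value, tau = tau)
  rom_estimate(roms, task_name = trace$task_name, system = trace$system)
}

#' Pool the two sides of a bilateral task
#'
#' Concatenates per-repetition ROMs of the left and right executions of a
#' bilateral task, after (optionally) checking that the sides do not differ
#' significantly. Pooling follows the study convention: with 10 repetitions
#' per side the pooled estimate has 20 repetitions. When `pretest = TRUE`
#' (default) a paired two-sample t-test on the per-repetition ROMs is run
#' and pooling proceeds only if `p > alpha`; the test is a declared choice
#' (the convention names no specific test).
#'
#' @param left,right [rom_estimate()]s of the same task and system
#' @param pretest run the side-difference pre-test (default TRUE)
#' @param alpha pre-test significance level (default 0.05)
#' @return a pooled [rom_estimate()]; if the pre-test is significant the
#'   pooled estimate is still returned but with a warning
#' @export
pool_sides <- function(left, right, pretest = TRUE, alpha = 0.05) {
  stopifnot(inherits(left, "rom_estimate"), inherits(right, "rom_estimate"))
  if (!length(left$per_rep_rom) || !length(right$per_rep_rom)) {
    stop("cannot pool an empty side")
  }
  if (!identical(left$task_name, right$task_name) ||
      !identical(left$system, right$system)) {
    stop("sides must share task and system")
  }
  if (pretest && left$n == right$n && left$n >= 2) {
    p <- stats::t.test(left$per_rep_rom, right$per_rep_rom,
                       paired = TRUE)$p.value
    if (is.finite(p) && p <= alpha) {
      warning(sprintf(
        "side difference pre-test significant (p = %.3g); pooled estimate may mix distinct patterns",
        p
      ))
    }
  }
  rom_estimate(c(left$per_rep_rom, right$per_rep_rom),
               task_name = left$task_name, system = left$system,
               pooled = TRUE)
}
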