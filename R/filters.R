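#' Digital Butterworth low-pass design (bilinear transform)
#'
#' Designs an order-`n` low-pass Butterworth filter for sampling rate `fs`
#' and cutoff `fc` by the standard route: analog prototype poles on the unit
#' circle, frequency pre-warping, bilinear transform. The digital cutoff is
#' exact: the gain at `fc` is 1/sqrt(2) by construction, and the DC gain
#' is 1.
#'
#' @param fc cutoff frequency, Hz (must satisfy `0 < fc < fs/2`)
#' @param fs sampling rate, Hz
#' @param order filter order (default 3, the pipeline's standard)
#' @return list with numerator `b` and denominator `a` coefficients
#'   (`a[1] = 1`)
#' @export
butter_lowpass <- function(fc, fs, order = 3) {
  if (fc <= 0 || fc >= fs / 2) {
    stop("cutoff must lie strictly between 0 and the Nyquist frequency")
  }
  stopifnot(order >= 1)
  k <- seq_len(order)
  # analog prototype poles (unit cutoff), then pre-warped cutoff
  p_proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  wc <- 2 * fs * tan(pi * fc / fs)
  p <- p_proto * wc
  # bilinear transform of the poles
  zp <- (2 * fs + p) / (2 * fs - p)
  a <- Re(poly_from_roots(zp))
  # `order` zeros at z = -1; scale for unit DC gain
  b_unscaled <- choose(order, 0:order)
  b <- b_unscaled * sum(a) / sum(b_unscaled)
  list(b = b, a = a)
}

# monic polynomial coefficients from roots (complex-safe)
poly_from_roots <- function(r) {
  coefs <- 1
  for (ri in r) coefs <- c(coefs, 0) - c(0, coefs * ri)
  coefs
}

# causal IIR filtering, direct form, zero initial conditions
iir_filter <- function(x, b, a) {
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[nb:(nb - 1 + length(x))]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

#' Causal low-pass Butterworth filtering
#'
#' Single-pass (causal) application of an order-`order` Butterworth low-pass
#' filter, the pipeline's standard pre-processing for the stomp-artifact
#' acceleration channels. The filter is causal by design (a zero-phase
#' forward-backward pass would double the effective order); its group delay
#' cancels in the lag estimate because both artifact channels receive the
#' same filter.
#'
#' @param x numeric signal
#' @param fs sampling rate, Hz
#' @param fc cutoff frequency, Hz (default 5)
#' @param order filter order (default 3)
#' @return filtered signal, same length as `x`
#' @export
lowpass_butterworth <- function(x, fs, fc = 5, order = 3) {
  ba <- butter_lowpass(fc, fs, order)
  iir_filter(as.numeric(x), ba$b, ba$a)
}

# windowed-sinc (Blackman) linear-phase FIR low-pass, unit DC gain
fir_sinc_lowpass <- function(fc, fs, taps = 301) {
  if (taps %% 2 == 0) taps <- taps + 1
  m <- (taps - 1) / 2
  n <- -m:m
  h <- 2 * fc / fs * sinc_fun(2 * fc / fs * n)
  w <- 0.42 + 0.5 * cos(pi * n / m) + 0.08 * cos(2 * pi * n / m)
  h <- h * w
  h / sum(h)
}

sinc_fun <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# zero-phase FIR filtering with reflection padding at the edges
fir_apply <- function(x, h) {
  m <- (length(h) - 1) / 2
  n <- length(x)
  pad_l <- x[pmin(n, pmax(1, (m + 1):2))]
  pad_r <- x[pmin(n, pmax(1, (n - 1):(n - m)))]
  xp <- c(pad_l, x, pad_r)
  y <- stats::filter(xp, h, method = "convolution", sides = 2)
  as.numeric(y)[(m + 1):(m + n)]
}

#' Down-sample a 100 Hz reference trace to the IMU rate
#'
#' Anti-alias filters the trace with a zero-phase windowed-sinc FIR low-pass
#' below the new Nyquist frequency, then interpolates onto the 30 Hz sample
#' grid. Output length is `floor(n * 30 / 100)` and the output clock starts
#' at the input's `t0`, so a 100 Hz grid and a native 30 Hz grid stay
#' aligned sample-for-sample.
#'
#' @param trace an [angle_trace] at 100 Hz (or any rate above `new_rate`)
#' @param new_rate target rate, Hz (default 30)
#' @param fc anti-alias cutoff, Hz (default `0.8 * new_rate / 2` = 12 Hz for
#'   the standard 100 to 30 Hz case)
#' @param taps FIR length (default 301 at 100 Hz, about 3 s)
#' @return an [angle_trace] at `new_rate`
#' @export
downsample_to_imu_rate <- function(trace, new_rate = 30, fc = NULL,
                                   taps = 301) {
  stopifnot(inherits(trace, "angle_trace"))
  if (trace$rate <= new_rate) {
    stop(sprintf("trace rate (%g Hz) must exceed the target rate (%g Hz)",
                 trace$rate, new_rate))
  }
  if (is.null(fc)) fc <- 0.8 * new_rate / 2
  x <- trace$values
  n <- length(x)
  taps <- min(taps, 2 * floor((n - 1) / 2) + 1)
  xf <- fir_apply(x, fir_sinc_lowpass(fc, trace$rate, taps))
  m <- floor(n * new_rate / trace$rate)
  t_out <- (seq_len(m) - 1) / new_rate
  t_in <- (seq_len(n) - 1) / trace$rate
  vals <- stats::approx(t_in, xf, xout = t_out, rule = 2)$y
  angle_trace(vals, rate = new_rate, t0 = trace$t0, system = trace$system,
              task_name = trace$task_name)
}

#' Down-sample a raw numeric channel (same scheme as the angle traces)
#' @param x numeric signal
#' @param from_rate,new_rate rates in Hz
#' @inheritParams downsample_to_imu_rate
#' @return numeric vector of length `floor(length(x) * new_rate / from_rate)`
#' @export
downsample_signal <- function(x, from_rate, new_rate = 30, fc = NULL,
                              taps = 301) {
  tr <- angle_trace(x, rate = from_rate)
  downsample_to_imu_rate(tr, new_rate = new_rate, fc = fc, taps = taps)$values
}
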