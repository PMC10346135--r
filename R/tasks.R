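#' Motor-task vocabulary
#'
#' The seven trunk and lower-limb motor tasks of the device's validation
#' protocol. Bilateral tasks are performed once per side (10 repetitions
#' each) and their per-repetition ROMs are pooled downstream.
#'
#' @return character vector of the seven task names
#' @export
task_names <- function() {
  c("semi-squat", "hip_abduction", "hip_flexion", "hip_extension",
    "knee_extension", "trunk_flexion", "trunk_bending")
}

BILATERAL_TASKS <- c("hip_abduction", "hip_flexion", "hip_extension",
                     "knee_extension", "trunk_bending")

#' Published per-task validation summary
#'
#' The per-task summary table from the device's published validation study:
#' mean (SD) ROM per system, absolute inter-system difference, accuracy,
#' RMSE, MCID (= 1 SEM) with its exceedance flag, and the Pearson / Lin
#' concordance correlations with their significance flags. These printed
#' summary values are the study's "stated world": they seed the default
#' task templates and the cohort simulator, and the agreement worked
#' examples recompute the accuracy column from the two mean columns.
#'
#' @return a data.frame with one row per task (see column names)
#' @export
#' @examples
#' published_rom_summary()[, c("task", "imu_mean", "mocap_mean", "accuracy_pct")]
published_rom_summary <- function() {
  path <- system.file("extdata", "published_rom_summary.csv",
                      package = "kinagree", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published misplacement sensitivity summary
#'
#' Mean (SD) ROM for the IMU in its correct, medially displaced, and
#' laterally displaced positions for the two hip tasks of the misplacement
#' protocol, with the RMSE of each displaced arm against the correct one.
#'
#' @return a data.frame with one row per task
#' @export
published_misplacement_summary <- function() {
  path <- system.file("extdata", "published_misplacement_summary.csv",
                      package = "kinagree", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Build a motor-task template
#'
#' A template describes one task session as `n_repetitions` rest-ramp-hold-
#' return cycles reaching `target_rom` degrees at the plateau. The default
#' target for each task is the reference-system mean ROM from the published
#' validation summary, so a simulated cohort reproduces the study's stated
#' conditions by default.
#'
#' Timing defaults (rest 2 s between repetitions, 0.5 s smoothstep ramps,
#' 6 s hold) are chosen so that the working-phase-mean ROM statistic
#' recovers the plateau value to within 0.1 degrees on noise-free data for
#' every task in the vocabulary.
#'
#' @param task_name one of [task_names()]
#' @param target_rom plateau amplitude, degrees (> 0); default from the
#'   published summary's reference-system column
#' @param n_repetitions number of repetition cycles (default 10)
#' @param rest_duration inter-repetition rest, seconds
#' @param ramp_duration rise/return ramp duration, seconds
#' @param hold_duration plateau hold duration, seconds
#' @param lead_in rest before the first repetition, seconds (the stomp
#'   synchronization artifact sits inside this window)
#' @return an object of class `task_template`
#' @export
#' @examples
#' make_template("semi-squat")
make_template <- function(task_name, target_rom = NULL, n_repetitions = 10,
                          rest_duration = 2, ramp_duration = 0.5,
                          hold_duration = 6, lead_in = 3) {
  if (!is.character(task_name) || length(task_name) != 1L ||
      !(task_name %in% task_names())) {
    stop(sprintf(
      "unknown task '%s'; valid tasks are: %s",
      as.character(task_name)[1], paste(task_names(), collapse = ", ")
    ))
  }
  if (is.null(target_rom)) {
    ref <- published_rom_summary()
    target_rom <- ref$mocap_mean[match(task_name, ref$task)]
  }
  stopifnot(is.numeric(target_rom), target_rom > 0,
            n_repetitions >= 1, rest_duration > 0,
            ramp_duration > 0, hold_duration > 0, lead_in > 0)
  structure(
    list(task_name = task_name, target_rom = target_rom,
         n_repetitions = as.integer(n_repetitions),
         rest_duration = rest_duration, ramp_duration = ramp_duration,
         hold_duration = hold_duration, lead_in = lead_in,
         bilateral = task_name %in% BILATERAL_TASKS),
    class = "task_template"
  )
}

#' @export
print.task_template <- function(x, ...) {
  cat(sprintf(
    "<task_template> %s: %d reps to %.2f deg (%sbilateral)\n  lead-in %.1f s; cycle = ramp %.1f s + hold %.1f s + ramp %.1f s + rest %.1f s\n",
    x$task_name, x$n_repetitions, x$target_rom,
    if (x$bilateral) "" else "not ", x$lead_in,
    x$ramp_duration, x$hold_duration, x$ramp_duration, x$rest_duration
  ))
  invisible(x)
}

#' Duration of one repetition cycle, seconds
#' @param template a [make_template()] object
#' @return scalar seconds
#' @export
cycle_duration <- function(template) {
  with(template, 2 * ramp_duration + hold_duration + rest_duration)
}

#' Total session duration, seconds
#' @param template a [make_template()] object
#' @return scalar seconds
#' @export
session_duration <- function(template) {
  template$lead_in + template$n_repetitions * cycle_duration(template)
}

# C1 smoothstep ramp: 0 -> 1 over u in [0, 1]
smoothstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  u * u * (3 - 2 * u)
}

#' Noise-free session angle profile
#'
#' Piecewise-smooth ground-truth segment angle: 0 degrees at rest, a
#' smoothstep ramp to `target_rom`, a flat hold, a smoothstep return, for
#' exactly `n_repetitions` cycles after the lead-in rest. Vectorized over
#' `t`.
#'
#' @param template a [make_template()] object
#' @param t time(s) in seconds, each within `[0, session_duration(template)]`
#' @return angle(s) in degrees
#' @export
#' @examples
#' tpl <- make_template("hip_flexion")
#' ground_truth_angle(tpl, tpl$lead_in + tpl$ramp_duration +
#'   tpl$hold_duration / 2) # plateau midpoint -> target
ground_truth_angle <- function(template, t) {
  session_profile(template, t,
                  rep(template$target_rom, template$n_repetitions))
}

# profile with one plateau amplitude per repetition (real subjects vary
# repetition to repetition; both systems observe the same true motion)
session_profile <- function(template, t, rep_targets) {
  stopifnot(length(rep_targets) == template$n_repetitions)
  total <- session_duration(template)
  if (any(t < -1e-9) || any(t > total + 1e-9)) {
    stop(sprintf("t outside session span [0, %.2f] s", total))
  }
  u <- t - template$lead_in
  cyc <- cycle_duration(template)
  phase <- u %% cyc
  idx <- pmin(template$n_repetitions, pmax(1L, floor(u / cyc) + 1L))
  # samples before the lead-in end sit at rest
  phase[u < 0] <- -1
  r <- template$ramp_duration
  h <- template$hold_duration
  a <- numeric(length(t))
  up <- phase >= 0 & phase < r
  hold <- phase >= r & phase < r + h
  down <- phase >= r + h & phase < 2 * r + h
  a[up] <- smoothstep(phase[up] / r)
  a[hold] <- 1
  a[down] <- 1 - smoothstep((phase[down] - r - h) / r)
  a * rep_targets[idx]
}
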