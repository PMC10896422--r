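#' Synthetic healthy reference kinematic curves
#'
#' A smooth synthetic stand-in for a normative healthy-adult curve set:
#' nine lower-limb kinematic variables (degrees) over 0-100% of the gait
#' cycle, built from sinusoid shapes with physiologically plausible
#' ranges (e.g. knee flexion with its stance and swing peaks, ankle
#' dorsi/plantarflexion with push-off, a mildly external foot
#' progression). It is synthetic: use a real normative dataset for
#' clinical work.
#'
#' @return 101 x 9 numeric matrix; columns are the kinematic variables.
#' @examples
#' ref <- referenceCurves()
#' colnames(ref)
#' @export
referenceCurves <- function() {
  p <- seq(0, 1, length.out = 101)   # fraction of gait cycle
  tp <- 2 * pi * p
  m <- cbind(
    pelvic_tilt = 10 + 1.5 * sin(2 * tp),
    pelvic_obliquity = 4 * sin(tp + 0.3),
    pelvic_rotation = 5 * sin(tp),
    hip_flexion = 15 + 20 * cos(tp + 0.35),
    hip_abduction = 3 * sin(tp + 1.1) - 1,
    hip_rotation = 4 * sin(tp + 2.0),
    knee_flexion = 22 - 18 * cos(tp - 0.5) + 22 * exp(-((p - 0.72) / 0.09)^2),
    ankle_dorsiflexion = 5 * sin(2 * tp + 0.6) -
      14 * exp(-((p - 0.58) / 0.06)^2),
    foot_progression = -7 + 2 * sin(tp + 0.8)
  )
  rownames(m) <- NULL
  m
}

#' Gait simulation configuration
#'
#' Generative model for synthetic walking trials. Spatial-temporal
#' defaults describe a healthy young adult at self-selected speed
#' (stride time 1.1 s, stride length 1.30 m, so 1.18 m/s and 109
#' steps/min; stance 62% of the cycle, which fixes total double support
#' at 2 x 62 - 100 = 24% in symmetric gait; step width 0.10 m).
#' Condition effects mirror the cognitive-motor interference pattern the
#' analysis is designed to detect: a 0.10 m stride-length reduction and a
#' 5 degree external-rotation foot-progression offset under both Go/NoGo
#' levels, and a 3 degree foot-progression offset under N-Back level 2
#' only.
#'
#' @param stride_time stride (cycle) time, s.
#' @param stride_length stride length, m.
#' @param step_width mediolateral heel separation, m.
#' @param stance_fraction stance phase fraction of the cycle.
#' @param reference 101 x 9 reference curve matrix ([referenceCurves()]).
#' @param condition_effects data.frame: `condition`, `stride_delta` (m),
#'   `foot_progression_delta` (deg, negative = external rotation).
#' @param curve_noise_sd additive noise on the kinematic curves, deg.
#' @param cycle_noise_sd cycle-to-cycle stride-length noise, m.
#' @param n_cycles gait cycles per trial.
#' @param frame_rate camera frame rate, Hz.
#' @param subject_stride_sd between-subject stride-length SD, m.
#' @param subject_fp_sd between-subject foot-progression offset SD, deg.
#' @param stride_asymmetry extra left-minus-right stride length, m
#'   (0 = symmetric).
#' @return list of class `gait_sim_config`.
#' @export
gaitSimConfig <- function(stride_time = 1.1, stride_length = 1.30,
                          step_width = 0.10, stance_fraction = 0.62,
                          reference = referenceCurves(),
                          condition_effects = defaultGaitEffects(),
                          curve_noise_sd = 1.0, cycle_noise_sd = 0.02,
                          n_cycles = 8, frame_rate = 100,
                          subject_stride_sd = 0.07, subject_fp_sd = 1.5,
                          stride_asymmetry = 0) {
  stopifnot(stride_time > 0, stride_length > 0,
            stance_fraction > 0.5, stance_fraction < 1,
            nrow(reference) == 101, ncol(reference) == 9,
            n_cycles >= 2, frame_rate > 0)
  structure(list(stride_time = stride_time, stride_length = stride_length,
                 step_width = step_width, stance_fraction = stance_fraction,
                 double_support_fraction = 2 * stance_fraction - 1,
                 reference = reference,
                 condition_effects = condition_effects,
                 curve_noise_sd = curve_noise_sd,
                 cycle_noise_sd = cycle_noise_sd, n_cycles = n_cycles,
                 frame_rate = frame_rate,
                 subject_stride_sd = subject_stride_sd,
                 subject_fp_sd = subject_fp_sd,
                 stride_asymmetry = stride_asymmetry),
            class = "gait_sim_config")
}

#' @rdname gaitSimConfig
#' @export
defaultGaitEffects <- function() {
  data.frame(
    condition = c("baseline", "go_nogo_1", "go_nogo_2", "n_back_1",
                  "n_back_2"),
    stride_delta = c(0, -0.10, -0.10, 0, 0),
    foot_progression_delta = c(0, -5, -5, 0, -3)
  )
}

#' @rdname gaitSimConfig
#' @export
nullGaitEffects <- function() {
  d <- defaultGaitEffects()
  d$stride_delta[] <- 0
  d$foot_progression_delta[] <- 0
  d
}

# piecewise heel progression: planted during stance, half-cosine advance
# during swing; landing positions are exact multiples of the stride length
.heel_progression <- function(t, hs, to, land_x) {
  x <- numeric(length(t))
  x[t <= hs[1]] <- land_x[1]
  for (i in seq_along(hs)) {
    this_to <- to[i]
    in_stance <- t >= hs[i] & t <= this_to
    x[in_stance] <- land_x[i]
    if (i < length(hs)) {
      in_swing <- t > this_to & t < hs[i + 1]
      ph <- (t[in_swing] - this_to) / (hs[i + 1] - this_to)
      x[in_swing] <- land_x[i] +
        (land_x[i + 1] - land_x[i]) * (1 - cos(pi * ph)) / 2
    } else {
      x[t > this_to] <- land_x[i]
    }
  }
  x
}

.heel_lift <- function(t, hs, to) {
  z <- numeric(length(t))
  for (i in seq_along(hs)) {
    if (i < length(hs)) {
      in_swing <- t > to[i] & t < hs[i + 1]
      ph <- (t[in_swing] - to[i]) / (hs[i + 1] - to[i])
      z[in_swing] <- 0.06 * sin(pi * ph)
    }
  }
  z
}

#' Simulate one walking trial
#'
#' Generates heel and second-metatarsal-head marker trajectories for both
#' sides walking along a straight progression axis, gait events
#' consistent with the configured stance fraction, and time-normalized
#' kinematic curves equal to the reference plus the condition's
#' foot-progression offset plus noise. With all noise at zero every gait
#' metric computed by the metrics module recovers its configured value.
#'
#' @param config a [gaitSimConfig()].
#' @param condition condition label (must appear in
#'   `config$condition_effects`).
#' @param seed integer seed.
#' @param stride_offset,fp_offset additive per-subject offsets on stride
#'   length (m) and foot progression (deg), applied on top of the
#'   condition effect (used by [simulateStudy()]).
#' @return a [GaitTrial-class].
#' @examples
#' trial <- simulateGaitTrial(gaitSimConfig(), "baseline", seed = 1)
#' trial
#' @export
simulateGaitTrial <- function(config, condition, seed, stride_offset = 0,
                              fp_offset = 0) {
  stopifnot(inherits(config, "gait_sim_config"))
  eff <- config$condition_effects
  i <- match(condition, eff$condition)
  if (is.na(i)) stop("unknown condition: ", condition)
  set.seed(as.integer(seed))
  Tc <- config$stride_time
  L_left <- config$stride_length + eff$stride_delta[i] + stride_offset +
    config$stride_asymmetry
  L_right <- config$stride_length + eff$stride_delta[i] + stride_offset
  nc <- config$n_cycles
  w <- config$step_width
  stance <- config$stance_fraction

  t0 <- Tc                            # first left heel strike
  hs_l <- t0 + (0:nc) * Tc
  to_l <- hs_l + stance * Tc
  hs_r <- t0 + ((0:(nc + 1)) - 0.5) * Tc
  to_r <- hs_r + stance * Tc
  t_end <- max(to_l[length(to_l)], to_r[length(to_r)]) + 0.2
  frames <- seq(0, t_end, by = 1 / config$frame_rate)

  cyc_noise_l <- rnorm(nc, 0, config$cycle_noise_sd)
  cyc_noise_r <- rnorm(nc + 1, 0, config$cycle_noise_sd)
  land_l <- c(0, cumsum(L_left + cyc_noise_l))
  land_r <- -L_right / 2 + c(0, cumsum(L_right + cyc_noise_r))

  mk <- function(x, y, z) cbind(x = x, y = y, z = z)
  heel_L <- mk(.heel_progression(frames, hs_l, to_l, land_l),
               rep(w / 2, length(frames)), .heel_lift(frames, hs_l, to_l))
  heel_R <- mk(.heel_progression(frames, hs_r, to_r, land_r),
               rep(-w / 2, length(frames)), .heel_lift(frames, hs_r, to_r))
  mtH_L <- heel_L; mtH_L[, "x"] <- mtH_L[, "x"] + 0.18
  mtH_R <- heel_R; mtH_R[, "x"] <- mtH_R[, "x"] + 0.18

  fp_delta <- eff$foot_progression_delta[i] + fp_offset
  make_curves <- function() {
    cv <- config$reference
    cv[, "foot_progression"] <- cv[, "foot_progression"] + fp_delta
    if (config$curve_noise_sd > 0) {
      cv <- cv + matrix(rnorm(length(cv), 0, config$curve_noise_sd),
                        nrow(cv))
    }
    cv
  }
  new("GaitTrial",
      markers = list(heel_L = heel_L, heel_R = heel_R,
                     mtH_L = mtH_L, mtH_R = mtH_R),
      frameRate = config$frame_rate,
      events = list(left = list(heel_strike = hs_l, toe_off = to_l),
                    right = list(heel_strike = hs_r, toe_off = to_r)),
      curves = list(left = make_curves(), right = make_curves()),
      condition = condition)
}
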