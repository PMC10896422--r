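#' Kinematic variable names of the gait profile
#'
#' The nine lower-limb range-of-motion variables scored by the Gait
#' Variable Scores, in the column order used throughout the package.
#'
#' @return character vector of length 9.
#' @export
gaitVariables <- function() {
  c("pelvic_tilt", "pelvic_obliquity", "pelvic_rotation", "hip_flexion",
    "hip_abduction", "hip_rotation", "knee_flexion", "ankle_dorsiflexion",
    "foot_progression")
}

# interpolate a frames x 3 marker trajectory at arbitrary times
.marker_at <- function(marker, frame_rate, times) {
  ft <- (seq_len(nrow(marker)) - 1) / frame_rate
  vapply(c("x", "y", "z"), function(cc) {
    approx(ft, marker[, cc], xout = times, rule = 2)$y
  }, numeric(length(times)))
}

# unit progression axis in the horizontal plane: principal direction of
# heel displacement, sign-aligned with the net displacement
.progression_axis <- function(heel) {
  xy <- heel[, c("x", "y"), drop = FALSE]
  pc <- prcomp(xy, center = TRUE, scale. = FALSE)
  ax <- pc$rotation[, 1]
  net <- colMeans(tail(xy, 5)) - colMeans(head(xy, 5))
  if (sum(ax * net) < 0) ax <- -ax
  ax
}

#' Spatial-temporal gait parameters
#'
#' The seven spatial-temporal parameters of one side, from marker
#' trajectories and gait events: cadence (steps/min, `120/stride_time`),
#' gait speed (m/s), stance / swing / double-support percentages of the
#' cycle, stride length (m) and step width (m). Stride length is the mean
#' heel displacement along the progression axis (the principal horizontal
#' direction of heel travel) between consecutive ipsilateral heel
#' strikes; step width is the mean heel separation perpendicular to that
#' axis at contralateral heel strikes.
#'
#' @param trial a [GaitTrial-class], or a list with elements `markers`,
#'   `frameRate`, `events` of the same shape.
#' @param side `"left"` or `"right"`.
#' @return one-row data.frame: `cadence`, `gait_speed`, `stance_pct`,
#'   `swing_pct`, `double_support_pct`, `stride_length`, `step_width`
#'   (plus `stride_time` for convenience).
#' @examples
#' cfg <- gaitSimConfig(curve_noise_sd = 0, cycle_noise_sd = 0)
#' spatiotemporalParams(simulateGaitTrial(cfg, "baseline", 1), "left")
#' @export
spatiotemporalParams <- function(trial, side = c("left", "right")) {
  side <- match.arg(side)
  markers <- if (is(trial, "GaitTrial")) trial@markers else trial$markers
  events <- if (is(trial, "GaitTrial")) trial@events else trial$events
  frate <- if (is(trial, "GaitTrial")) trial@frameRate else trial$frameRate
  contra <- if (side == "left") "right" else "left"
  hs <- events[[side]]$heel_strike
  to <- events[[side]]$toe_off
  if (length(hs) < 2) stop("need at least 2 ipsilateral heel strikes")
  t_span <- (nrow(markers[[1]]) - 1) / frate
  if (max(hs, events[[contra]]$heel_strike) > t_span + 1e-9) {
    stop("events extend beyond the marker recording")
  }
  heel <- markers[[paste0("heel_", toupper(substr(side, 1, 1)))]]
  heel_c <- markers[[paste0("heel_", toupper(substr(contra, 1, 1)))]]
  ax <- .progression_axis(heel)
  perp <- c(-ax[2], ax[1])

  stride_time <- mean(diff(hs))
  pos_hs <- .marker_at(heel, frate, hs)[, c("x", "y")] %*% ax
  stride_length <- mean(diff(pos_hs))

  # stance: first ipsilateral toe-off after each heel strike
  stance_t <- vapply(hs[-length(hs)], function(h) {
    nxt <- to[to > h + 1e-9]
    if (length(nxt) == 0) NA_real_ else nxt[1] - h
  }, 0)
  stance_pct <- mean(100 * stance_t / diff(hs), na.rm = TRUE)

  # double support: initial DS (to the contralateral toe-off of the
  # stance already in progress) + terminal DS (contralateral heel strike
  # to ipsilateral toe-off), per cycle; cycles without the full event
  # pattern (e.g. at the trial boundary) yield NA and are skipped
  hs_c <- events[[contra]]$heel_strike
  to_c <- events[[contra]]$toe_off
  ds_pct <- vapply(seq_len(length(hs) - 1), function(i) {
    ds1 <- to_c[to_c > hs[i] + 1e-9]
    hsc <- hs_c[hs_c > hs[i] + 1e-9]
    toi <- to[to > hs[i] + 1e-9]
    if (!length(ds1) || !length(hsc) || !length(toi)) return(NA_real_)
    # the contra toe-off must precede the next contra heel strike and
    # the ipsi toe-off must fall after it, or the pattern is incomplete
    if (ds1[1] > hsc[1] || toi[1] < hsc[1] ||
        hsc[1] > hs[i + 1]) return(NA_real_)
    100 * ((ds1[1] - hs[i]) + (toi[1] - hsc[1])) / (hs[i + 1] - hs[i])
  }, 0)

  # step width at contralateral heel strikes inside the analyzed span
  hsc_in <- hs_c[hs_c > min(hs) & hs_c < max(hs)]
  widths <- abs((.marker_at(heel, frate, hsc_in)[, c("x", "y")] -
                   .marker_at(heel_c, frate, hsc_in)[, c("x", "y")]) %*% perp)

  data.frame(cadence = 120 / stride_time,
             gait_speed = stride_length / stride_time,
             stance_pct = stance_pct, swing_pct = 100 - stance_pct,
             double_support_pct = mean(ds_pct, na.rm = TRUE),
             stride_length = stride_length, step_width = mean(widths),
             stride_time = stride_time)
}

#' Time-normalize a curve onto the gait cycle
#'
#' Linear interpolation of a time series onto 0, 1, ..., 100% of one gait
#' cycle (101 points).
#'
#' @param time sample times, s.
#' @param values sampled values.
#' @param cycle numeric length-2: the cycle's start and end times
#'   (consecutive ipsilateral heel strikes).
#' @return numeric vector of length 101.
#' @examples
#' t <- seq(0, 2, by = 0.01)
#' y <- timeNormalize(t, 3 * t, cycle = c(0.5, 1.5))
#' range(y)
#' @export
timeNormalize <- function(time, values, cycle) {
  stopifnot(length(cycle) == 2)
  if (diff(cycle) <= 0) stop("degenerate cycle (non-positive duration)")
  if (cycle[1] < min(time) - 1e-9 || cycle[2] > max(time) + 1e-9) {
    stop("cycle outside the recorded span")
  }
  approx(time, values, xout = seq(cycle[1], cycle[2], length.out = 101))$y
}

#' Gait Variable Score
#'
#' Root-mean-square difference between a subject's time-normalized
#' kinematic curve and the reference curve, in degrees. Zero for a curve
#' identical to the reference; a constant offset of c degrees scores
#' exactly |c|.
#'
#' @param subject_curve,reference_curve numeric vectors of length 101.
#' @return GVS in degrees (non-negative scalar).
#' @examples
#' ref <- referenceCurves()[, "foot_progression"]
#' gvs(ref + 5, ref)
#' @export
gvs <- function(subject_curve, reference_curve) {
  if (length(subject_curve) != 101 || length(reference_curve) != 101) {
    stop("curves must have 101 points")
  }
  sqrt(mean((subject_curve - reference_curve)^2))
}

#' Gait Profile Score
#'
#' Aggregates the nine Gait Variable Scores into one deviation index.
#' The default is the standard root-mean-square aggregation; `"sum"`
#' gives the plain sum of the GVS values.
#'
#' @param gvs_values numeric vector of 9 non-negative GVS values (deg).
#' @param method `"rms"` (default) or `"sum"`.
#' @return GPS in degrees.
#' @examples
#' gps(rep(4, 9))
#' gps(c(3, rep(0, 8)))
#' @export
gps <- function(gvs_values, method = c("rms", "sum")) {
  method <- match.arg(method)
  if (length(gvs_values) != 9) stop("exactly 9 GVS values expected")
  if (any(gvs_values < 0)) stop("GVS values must be non-negative")
  if (method == "rms") sqrt(mean(gvs_values^2)) else sum(gvs_values)
}

#' GVS and GPS for one trial side
#'
#' @param trial a [GaitTrial-class].
#' @param reference 101 x 9 reference curve matrix.
#' @param side `"left"` or `"right"`.
#' @param method GPS aggregation, see [gps()].
#' @return one-row data.frame: nine `gvs_<variable>` columns and `gps`.
#' @export
trialGaitProfile <- function(trial, reference = referenceCurves(),
                             side = c("left", "right"),
                             method = c("rms", "sum")) {
  side <- match.arg(side)
  cv <- trial@curves[[side]]
  g <- vapply(gaitVariables(), function(v) gvs(cv[, v], reference[, v]), 0)
  out <- as.data.frame(as.list(setNames(g, paste0("gvs_", names(g)))))
  out$gps <- gps(g, method = method)
  out
}

#' Paired left-right comparison of gait parameters
#'
#' Aligns per-trial (or per-subject) parameter tables for the two sides
#' and tests each parameter with a Wilcoxon signed-rank test. When no
#' parameter differs significantly, restricting further analysis to one
#' side is licensed (as the analysis pipeline does).
#'
#' @param left,right data.frames with identical columns, one row per
#'   trial or subject, same row order.
#' @param alpha significance level for the license flag.
#' @return list: `differences` (left minus right), `tests` (data.frame
#'   `parameter`, `statistic`, `p_value`), `left_only_ok` (logical).
#' @export
compareSides <- function(left, right, alpha = 0.05) {
  if (nrow(left) != nrow(right)) stop("unequal trial counts per side")
  if (nrow(left) < 2) stop("need more than one trial for a comparison")
  params <- intersect(names(left), names(right))
  params <- params[vapply(left[params], is.numeric, TRUE)]
  diffs <- left[params] - right[params]
  # differences at floating-point noise level are not evidence of
  # asymmetry: a consistent 1e-14 residue would otherwise be "significant"
  for (p in params) {
    scale <- max(abs(left[[p]]), abs(right[[p]]), 1e-12)
    diffs[[p]][abs(diffs[[p]]) < 1e-9 * scale] <- 0
  }
  tests <- do.call(rbind, lapply(params, function(p) {
    d <- diffs[[p]]
    if (all(d == 0)) {
      data.frame(parameter = p, statistic = NA_real_, p_value = 1)
    } else {
      w <- wilcoxonSignedRank(left[[p]], right[[p]])
      data.frame(parameter = p, statistic = w$statistic, p_value = w$p_value)
    }
  }))
  list(differences = diffs, tests = tests,
       left_only_ok = all(tests$p_value > alpha))
}

#' Coordinate-based gait event detection
#'
#' Optional helper for marker data without event annotations: heel
#' strikes are detected where the heel's forward velocity (along the
#' progression axis) falls to zero after a swing, toe-offs where it
#' rises again. Annotated events, when available, take precedence in the
#' pipeline.
#'
#' @param trial a [GaitTrial-class] or compatible list.
#' @param side `"left"` or `"right"`.
#' @param vel_threshold stance velocity threshold, m/s.
#' @return list with `heel_strike` and `toe_off` times (s).
#' @export
detectGaitEvents <- function(trial, side = c("left", "right"),
                             vel_threshold = 0.1) {
  side <- match.arg(side)
  markers <- if (is(trial, "GaitTrial")) trial@markers else trial$markers
  frate <- if (is(trial, "GaitTrial")) trial@frameRate else trial$frameRate
  heel <- markers[[paste0("heel_", toupper(substr(side, 1, 1)))]]
  ax <- .progression_axis(heel)
  pos <- heel[, c("x", "y")] %*% ax
  vel <- c(0, diff(pos)) * frate
  moving <- vel > vel_threshold
  trans <- diff(as.integer(moving))
  t <- (seq_len(nrow(heel)) - 1) / frate
  list(heel_strike = t[which(trans == -1) + 1],
       toe_off = t[which(trans == 1) + 1])
}
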