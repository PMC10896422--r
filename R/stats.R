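#' Spearman correlation of a feature with the three difficulty levels
#'
#' Rank correlation of a length-3 series against levels (1, 2, 3). With
#' three points the coefficient is +1 or -1 exactly when the series is
#' strictly monotone; this is the screening statistic.
#'
#' @param values numeric length-3 (level 1 = no task, 2 and 3 = the two
#'   difficulty levels).
#' @return Spearman's rho in `[-1, 1]`; `NA` when the values are all
#'   equal (no ordering).
#' @examples
#' spearmanLevelRho(c(1, 2, 3))
#' spearmanLevelRho(c(1, 3, 2))
#' @export
spearmanLevelRho <- function(values) {
  if (length(values) != 3) stop("exactly 3 level values expected")
  if (!all(is.finite(values))) stop("non-finite values")
  if (sd(values) == 0) return(NA_real_)
  suppressWarnings(cor(values, 1:3, method = "spearman"))
}

#' Friedman test for a subjects-by-levels matrix
#'
#' Friedman rank test with average-rank tie handling and the chi-square
#' approximation on k - 1 degrees of freedom (delegating to
#' [stats::friedman.test()]). A matrix in which every subject's values
#' are identical across levels carries no ordering evidence and returns
#' chi-square 0 with p = 1.
#'
#' @param m numeric matrix, subjects x conditions (>= 3 subjects,
#'   >= 2 conditions).
#' @return list with `chi2` and `p_value`.
#' @examples
#' m <- matrix(rep(c(1, 2, 3), each = 13), 13) + rnorm(39, 0, 0.1)
#' friedmanTest(m)
#' @export
friedmanTest <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 3 || ncol(m) < 2) stop("need >= 3 subjects and >= 2 levels")
  if (!all(is.finite(m))) stop("non-finite values")
  if (all(apply(m, 1, function(r) length(unique(r)) == 1))) {
    return(list(chi2 = 0, p_value = 1))
  }
  ft <- friedman.test(m)
  list(chi2 = unname(ft$statistic), p_value = ft$p.value)
}

#' Kendall's W from a Friedman chi-square
#'
#' The concordance effect size of the Friedman test,
#' `W = chi2 / (n * (k - 1))`, clipped to `[0, 1]`. With n = 13 subjects
#' and k = 3 levels this reproduces the conventional effect sizes
#' reported with chi-square statistics (e.g. chi2 = 21.40 gives
#' W = 0.82).
#'
#' @param chi2 Friedman chi-square statistic (>= 0).
#' @param n_subjects number of subjects (rows).
#' @param k_conditions number of conditions (columns).
#' @return Kendall's W in `[0, 1]`.
#' @examples
#' kendallsW(21.40, 13, 3)
#' @export
kendallsW <- function(chi2, n_subjects, k_conditions) {
  if (n_subjects < 2 || k_conditions < 2) {
    stop("need at least 2 subjects and 2 conditions")
  }
  if (chi2 < 0) stop("chi2 must be non-negative")
  min(max(chi2 / (n_subjects * (k_conditions - 1)), 0), 1)
}

#' Effect-size class of a Kendall's W
#'
#' Cohen-style benchmarks used in the screening report: `high` for
#' W >= 0.8, `slightly_high` for 0.5 < W < 0.8 (open interval: W = 0.5
#' itself is `other`), `other` below.
#'
#' @param w Kendall's W.
#' @return one of `"high"`, `"slightly_high"`, `"other"`.
#' @export
effectSizeClass <- function(w) {
  vapply(w, function(wi) {
    if (is.na(wi)) NA_character_
    else if (wi >= 0.8) "high"
    else if (wi > 0.5 && wi < 0.8) "slightly_high"
    else "other"
  }, "")
}

# subjects x 3 matrix of one feature's values across the levels of a
# task context (baseline, task level 1, task level 2)
.level_matrix <- function(ft, feature, setting, task) {
  cd <- as.data.frame(colData(ft))
  m <- assay(ft, "power")
  conds <- c("baseline", paste0(task, "_1"), paste0(task, "_2"))
  subjects <- sort(unique(cd$subject))
  out <- matrix(NA_real_, length(subjects), 3,
                dimnames = list(subjects, conds))
  for (j in seq_along(conds)) {
    sel <- cd$setting == setting & cd$condition == conds[j]
    if (!any(sel)) stop("missing condition ", conds[j], " in setting ",
                        setting)
    out[match(cd$subject[sel], subjects), j] <- m[feature, which(sel)]
  }
  out
}

#' Monotonicity screening of the feature table
#'
#' The two-stage screening procedure of one analysis context (a setting
#' crossed with a task): for every feature, Spearman's rho between the
#' across-subject mean values and the three difficulty levels is
#' computed; features with rho exactly +1 or -1 (a strictly monotone
#' mean trend) pass the screen and are subjected to a Friedman test
#' across levels, with Kendall's W as effect size. All features appear
#' in the output whether or not they pass.
#'
#' @param ft a [FeatureTable-class].
#' @param setting `"sitting"` or `"walking"`.
#' @param task `"go_nogo"` or `"n_back"`.
#' @param alpha significance level for the `significant` flag.
#' @return data.frame with one row per feature: `feature`, `channel`,
#'   `band`, `power_type`, `setting`, `task`, `rho`, `passes_screen`,
#'   `chi2`, `p_value`, `kendalls_w`, `effect_class`, `significant`.
#' @export
screenFeatures <- function(ft, setting, task = c("go_nogo", "n_back"),
                           alpha = 0.05) {
  stopifnot(is(ft, "FeatureTable"))
  task <- match.arg(task)
  feats <- rownames(ft)
  rd <- as.data.frame(rowData(ft))
  res <- do.call(rbind, lapply(seq_along(feats), function(i) {
    lm <- .level_matrix(ft, feats[i], setting, task)
    if (anyNA(lm)) stop("missing level values for feature ", feats[i])
    rho <- spearmanLevelRho(colMeans(lm))
    passes <- !is.na(rho) && abs(abs(rho) - 1) < 1e-9
    if (passes) {
      fr <- friedmanTest(lm)
      w <- kendallsW(fr$chi2, nrow(lm), ncol(lm))
      data.frame(feature = feats[i], rho = rho, passes_screen = TRUE,
                 chi2 = fr$chi2, p_value = fr$p_value, kendalls_w = w,
                 effect_class = effectSizeClass(w))
    } else {
      data.frame(feature = feats[i], rho = if (is.na(rho)) NA_real_ else rho,
                 passes_screen = FALSE, chi2 = NA_real_, p_value = NA_real_,
                 kendalls_w = NA_real_, effect_class = NA_character_)
    }
  }))
  res <- cbind(res[, "feature", drop = FALSE], rd,
               setting = setting, task = task,
               res[, setdiff(names(res), "feature")])
  res$significant <- res$passes_screen & !is.na(res$p_value) &
    res$p_value < alpha
  rownames(res) <- NULL
  res
}

#' Per-subject Spearman correlations for one feature
#'
#' The subject-level companion of the screening: Spearman's rho between
#' each subject's three level values and the levels, with counts of
#' subjects at exactly +1 and -1. A subject with tied values cannot be
#' strictly monotone and is flagged (rho reported as computed, or `NA`
#' when constant), never dropped.
#'
#' @param ft a [FeatureTable-class].
#' @param feature feature id (`<channel>_<band>_<absolute|relative>`).
#' @inheritParams screenFeatures
#' @return list: `rho` (named per-subject vector), `n_positive`,
#'   `n_negative` (counts of rho = +1 / -1 subjects).
#' @export
perSubjectSpearman <- function(ft, feature, setting,
                               task = c("go_nogo", "n_back")) {
  task <- match.arg(task)
  lm <- .level_matrix(ft, feature, setting, task)
  if (anyNA(lm)) stop("missing level values for some subject")
  rho <- apply(lm, 1, spearmanLevelRho)
  list(rho = rho,
       n_positive = sum(!is.na(rho) & abs(rho - 1) < 1e-9),
       n_negative = sum(!is.na(rho) & abs(rho + 1) < 1e-9))
}

#' Wilcoxon signed-rank test (paired)
#'
#' Two-sided paired test via [stats::wilcox.test()]: the exact
#' small-sample distribution when there are at most 25 non-zero
#' differences and no ties or zeros, the normal approximation otherwise.
#'
#' @param x,y paired samples (or `y = NULL` to test differences in `x`).
#' @return list with `statistic` (V) and `p_value`.
#' @examples
#' wilcoxonSignedRank(c(1.1, 2.3, 0.9, 4.2, 3.3, 2.8), rep(2, 6))
#' @export
wilcoxonSignedRank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  if (length(d) < 2) stop("need at least 2 pairs")
  if (all(d == 0)) stop("all differences zero; test degenerate")
  clean <- !any(d == 0) && !any(duplicated(abs(d)))
  wt <- suppressWarnings(
    wilcox.test(d, exact = clean && length(d) <= 25, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Wilcoxon-Mann-Whitney test (unpaired)
#'
#' Two-sided rank-sum test via [stats::wilcox.test()]: exact for small
#' tie-free samples, normal approximation with tie correction otherwise.
#'
#' @param a,b the two samples.
#' @return list with `statistic` (U for sample `a`) and `p_value`.
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
#' @export
mannWhitneyU <- function(a, b) {
  if (length(a) < 3 || length(b) < 3) stop("both samples need >= 3 values")
  if (length(unique(c(a, b))) == 1) {
    # fully tied pooled sample: no ordering evidence at all
    return(list(statistic = length(a) * length(b) / 2, p_value = 1))
  }
  clean <- !any(duplicated(c(a, b)))
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = clean && length(a) + length(b) <= 50,
                correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}
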