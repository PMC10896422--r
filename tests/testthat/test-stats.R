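test_that("the level correlation takes its closed-form values", {
  expect_equal(spearmanLevelRho(c(1, 2, 3)), 1)
  expect_equal(spearmanLevelRho(c(3, 2, 1)), -1)
  expect_equal(spearmanLevelRho(c(1, 3, 2)), 0.5)
  expect_true(is.na(spearmanLevelRho(c(2, 2, 2))))
  expect_error(spearmanLevelRho(c(1, NA, 3)), "finite")
  expect_error(spearmanLevelRho(c(1, 2)), "3")
})

test_that("the Friedman wrapper matches closed forms and the rank oracle", {
  # identical values across levels: no ordering evidence
  flat <- matrix(5, 13, 3)
  expect_equal(friedmanTest(flat), list(chi2 = 0, p_value = 1))
  # perfect concordance: chi2 = n (k - 1)
  inc <- matrix(rep(c(1, 2, 3), each = 13), 13) +
    matrix(rnorm(39, 0, 1e-3), 13)
  inc <- t(apply(inc, 1, sort))
  expect_equal(friedmanTest(inc)$chi2, 26)
  # small matrices against the enumeration oracle
  for (s in 1:10) {
    set.seed(s)
    n <- sample(3:7, 1)
    m <- matrix(tie_free(n * 3, s), n, 3)
    expect_equal(friedmanTest(m)$chi2, oracle_friedman_chi2(m),
                 tolerance = 1e-9)
  }
  expect_error(friedmanTest(matrix(1:4, 2, 2)), ">= 3 subjects")
})

test_that("Kendall's W reproduces the study's printed effect sizes", {
  expect_equal(round(kendallsW(21.40, 13, 3), 2), 0.82)
  expect_equal(round(kendallsW(24.20, 13, 3), 2), 0.93)
  expect_equal(round(kendallsW(14.00, 13, 3), 2), 0.54)
  expect_equal(kendallsW(0, 13, 3), 0)
  expect_equal(kendallsW(26, 13, 3), 1)
  expect_error(kendallsW(5, 1, 3), "at least 2")
  expect_error(kendallsW(-1, 13, 3), "non-negative")
})

test_that("W from the Friedman statistic equals the concordance \
definition", {
  for (s in 1:10) {
    set.seed(100 + s)
    n <- sample(4:9, 1); k <- sample(3:5, 1)
    m <- matrix(tie_free(n * k, 100 + s), n, k)
    fr <- friedmanTest(m)
    expect_equal(kendallsW(fr$chi2, n, k), oracle_kendalls_w(m),
                 tolerance = 1e-9)
  }
})

test_that("effect-size classes honor their boundaries exactly", {
  expect_equal(effectSizeClass(c(0.82, 0.8, 0.79, 0.51, 0.5, 0.2)),
               c("high", "high", "slightly_high", "slightly_high",
                 "other", "other"))
})

test_that("the signed-rank wrapper agrees with exhaustive enumeration", {
  for (s in 1:12) {
    n <- 5 + (s %% 3)
    d <- tie_free(n, 200 + s)
    ours <- wilcoxonSignedRank(d)
    oracle <- oracle_signed_rank(d)
    expect_equal(ours$statistic, oracle$statistic)
    expect_equal(ours$p_value, oracle$p_value, tolerance = 1e-12)
  }
  expect_error(wilcoxonSignedRank(rep(0, 6)), "degenerate")
  # n = 6 toy pairs from the docs example
  x <- c(1.1, 2.3, 0.9, 4.2, 3.3, 2.8)
  expect_equal(wilcoxonSignedRank(x, rep(2, 6))$p_value,
               oracle_signed_rank(x - 2)$p_value)
})

test_that("the signed-rank test holds its nominal size", {
  set.seed(31)
  alpha_hat <- mean(vapply(1:2000, function(i) {
    wilcoxonSignedRank(rnorm(12))$p_value < 0.05
  }, TRUE))
  expect_gt(alpha_hat, 0.02)
  expect_lt(alpha_hat, 0.07)
})

test_that("the rank-sum wrapper agrees with exhaustive enumeration", {
  res <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)   # 2/20 arrangements as extreme
  expect_equal(oracle_mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  for (s in 1:12) {
    na <- sample(3:7, 1); nb <- sample(3:7, 1)
    a <- tie_free(na, 300 + s); b <- tie_free(nb, 400 + s) + 0.3
    ours <- mannWhitneyU(a, b)
    oracle <- oracle_mann_whitney(a, b)
    expect_equal(ours$statistic, oracle$statistic)
    expect_equal(ours$p_value, oracle$p_value, tolerance = 1e-12)
  }
  # identical samples carry no evidence
  expect_equal(mannWhitneyU(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(mannWhitneyU(numeric(0), 1:3), ">= 3")
})

test_that("screening is invariant under strictly increasing transforms", {
  set.seed(55)
  m <- matrix(exp(rnorm(13 * 3)), 13, 3) +
    matrix(rep(c(0, 0.5, 1), each = 13), 13)
  for (f in list(function(x) x^3, function(x) exp(x),
                 function(x) 10 * x + 2)) {
    # per-subject rank correlations are purely rank-based
    expect_equal(apply(f(m), 1, spearmanLevelRho),
                 apply(m, 1, spearmanLevelRho))
    fr <- friedmanTest(f(m))
    expect_equal(fr$chi2, friedmanTest(m)$chi2, tolerance = 1e-9)
    expect_equal(kendallsW(fr$chi2, 13, 3),
                 kendallsW(friedmanTest(m)$chi2, 13, 3), tolerance = 1e-9)
  }
})

test_that("per-subject correlations count monotone subjects correctly", {
  rows <- lapply(sprintf("S%02d", 1:13), function(sid) {
    vals <- matrix(c(1, 2, 3) + runif(1), 112, 3, byrow = TRUE)
    rownames(vals) <- NULL
    vals
  })
  # build a feature table where every subject increases strictly
  feats <- character(0)
  grid <- expand.grid(channel = eegChannels(), band = eegBands()$band,
                      type = c("absolute", "relative"))
  fid <- paste(grid$channel, grid$band, grid$type, sep = "_")
  conds <- c("baseline", "go_nogo_1", "go_nogo_2")
  cols <- list(); info <- list()
  for (i in 1:13) {
    for (j in 1:3) {
      key <- paste(i, j)
      cols[[key]] <- setNames(rows[[i]][, j], fid)
      info[[key]] <- data.frame(subject = sprintf("S%02d", i),
                                setting = "sitting", condition = conds[j],
                                level = j)
    }
  }
  ft <- buildFeatureTable(cols, do.call(rbind, info))
  ps <- perSubjectSpearman(ft, fid[1], "sitting", "go_nogo")
  expect_equal(unname(ps$rho), rep(1, 13))
  expect_equal(ps$n_positive, 13)
  expect_equal(ps$n_negative, 0)
  # a tie breaks strict monotonicity for that subject
  expect_true(abs(spearmanLevelRho(c(1, 1, 2))) < 1)
})

test_that("under exchangeable noise about a third of subjects look \
monotone", {
  # exact: of the 6 equally likely orderings of 3 tie-free values,
  # exactly one is increasing (rho = +1) and one decreasing (rho = -1)
  perms <- matrix(c(1, 2, 3, 1, 3, 2, 2, 1, 3, 2, 3, 1, 3, 1, 2, 3, 2, 1),
                  ncol = 3, byrow = TRUE)
  vals <- c(1.7, 2.4, 9.1)
  rhos <- apply(perms, 1, function(p) spearmanLevelRho(vals[p]))
  expect_equal(sum(abs(rhos - 1) < 1e-9), 1)
  expect_equal(sum(abs(rhos + 1) < 1e-9), 1)
  expect_true(all(abs(rhos) <= 1))
  # and in simulation the monotone fraction sits near 1/3
  set.seed(77)
  n <- 13 * 40
  k <- sum(vapply(seq_len(n), function(i) {
    r <- spearmanLevelRho(rnorm(3))
    !is.na(r) && abs(abs(r) - 1) < 1e-9
  }, TRUE))
  expect_gte(k, qbinom(5e-5, n, 1 / 3))
  expect_lte(k, qbinom(1 - 5e-5, n, 1 / 3))
})
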