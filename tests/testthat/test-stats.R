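test_that("RM-ANOVA matches an explicit sums-of-squares oracle and aov", {
  m <- matrix(c(5, 7, 9,
                4, 6, 10,
                6, 8, 8,
                5, 9, 11), nrow = 4, byrow = TRUE)
  res <- rm_anova(m)
  # hand computation
  grand <- mean(m)
  ss_state <- 4 * sum((colMeans(m) - grand)^2)
  ss_subj <- 3 * sum((rowMeans(m) - grand)^2)
  ss_err <- sum((m - grand)^2) - ss_state - ss_subj
  f_oracle <- (ss_state / 2) / (ss_err / 6)
  expect_equal(res$F, f_oracle, tolerance = 1e-10)
  expect_equal(res$partial_eta_sq, ss_state / (ss_state + ss_err),
               tolerance = 1e-10)
  expect_equal(res$df1, 2); expect_equal(res$df2, 6)
  # independent route through aov()
  long <- data.frame(value = as.vector(m),
                     state = factor(rep(1:3, each = 4)),
                     subject = factor(rep(1:4, 3)))
  fit <- summary(aov(value ~ state + Error(subject), data = long))
  f_aov <- fit[["Error: Within"]][[1]]["state", "F value"]
  p_aov <- fit[["Error: Within"]][[1]]["state", "Pr(>F)"]
  expect_equal(res$F, f_aov, tolerance = 1e-10)
  expect_equal(res$p, p_aov, tolerance = 1e-10)
})

test_that("RM-ANOVA degrees of freedom follow (k-1, (k-1)(n-1))", {
  set.seed(1)
  m <- matrix(rnorm(53 * 3), 53, 3)
  res <- rm_anova(m)
  expect_equal(c(res$df1, res$df2), c(2, 104))
})

test_that("degenerate RM-ANOVA inputs are flagged", {
  m <- matrix(rep(c(1, 2, 3), each = 5), 5, 3)
  m_same <- matrix(5, 4, 3)
  expect_warning(res <- rm_anova(m_same), "F undefined")
  expect_true(is.na(res$F))
  expect_error(rm_anova(m), "zero error variance")
  m_na <- matrix(rnorm(15), 5, 3); m_na[2, 1] <- NA
  expect_message(res2 <- rm_anova(m_na), "dropped listwise")
  expect_equal(res2$n, 4)
})

test_that("RM-ANOVA with two states satisfies F = t squared", {
  set.seed(2)
  for (r in 1:10) {
    a <- rnorm(12); b <- rnorm(12, 0.3)
    f <- rm_anova(cbind(a, b))
    t2 <- paired_t(a, b)$t^2
    expect_equal(f$F, t2, tolerance = 1e-8)
  }
})

test_that("paired t and Cohen's d follow the difference-score definitions", {
  b <- c(10, 20, 30)
  a <- b + c(1, 2, 3)           # diffs 1, 2, 3: mean 2, sd 1
  res <- paired_t(a, b)
  expect_equal(res$cohens_d, 2)
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(res$df, 2)
  expect_warning(res0 <- paired_t(b, b), "zero-variance")
  expect_true(is.na(res0$t))
  expect_equal(res0$cohens_d, 0)
})

test_that("paired t type-I error is calibrated under the null", {
  set.seed(3)
  n_rep <- 800
  p <- replicate(n_rep, {
    x <- matrix(rnorm(2 * 15), ncol = 2)
    paired_t(x[, 1], x[, 2])$p
  })
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.03); expect_lt(rate, 0.07)
})

test_that("BH step-up matches its thresholds and is monotone", {
  res <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(res$reject))
  expect_true(fdr_bh(0.049, q = 0.05)$reject)
  expect_false(fdr_bh(0.051, q = 0.05)$reject)
  set.seed(4)
  p <- runif(50)
  adj <- fdr_bh(p)$p_adj
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(fdr_bh(numeric(0)), "empty")
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("empirical FDR of BH stays at or below the nominal level", {
  set.seed(5)
  fdp <- replicate(400, {
    p <- runif(100)
    rej <- fdr_bh(p, 0.05)$reject
    sum(rej) / max(1, sum(rej))   # all nulls: any rejection is false
  })
  expect_lte(mean(fdp), 0.05 + 2 * sd(fdp) / sqrt(400))
})

test_that("partial correlation equals plain r under orthogonal covariates", {
  set.seed(6)
  n <- 40
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  cov_orth <- residuals(lm(rnorm(n) ~ x + y))
  plain <- brain_behavior_corr(x, y)
  partial <- brain_behavior_corr(x, y, covariates = cov_orth)
  expect_equal(partial$r, plain$r, tolerance = 1e-10)
  expect_equal(brain_behavior_corr(x, x)$r, 1)
  expect_error(brain_behavior_corr(x, y, covariates = cbind(x, 2 * x)),
               "rank-deficient")
})

test_that("FD regression attenuates a motion-driven spurious correlation", {
  set.seed(7)
  plain_r <- partial_r <- numeric(60)
  for (i in 1:60) {
    d <- simulate_confounded_pair(40, slope_measure = 15,
                                  slope_behavior = 15, noise_sd = 0.3,
                                  seed = 1000 + i)
    plain_r[i] <- brain_behavior_corr(d$measure, d$behavior)$r
    partial_r[i] <- brain_behavior_corr(d$measure, d$behavior,
                                        covariates = d$fd)$r
  }
  expect_gt(mean(plain_r), 0.4)
  expect_lt(abs(mean(partial_r)), 0.1)
})
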