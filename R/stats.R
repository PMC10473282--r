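#' One-way repeated-measures ANOVA
#'
#' Within-subject decomposition of a complete subjects x states table:
#' `F = MS_state / MS_error` with `df1 = k - 1`, `df2 = (k - 1)(n - 1)`, and
#' partial eta squared `SS_state / (SS_state + SS_error)`. No sphericity
#' correction is applied by default; Greenhouse-Geisser is available behind
#' `gg = TRUE`.
#'
#' @param values numeric matrix, rows = subjects, columns = states; or a
#'   long data.frame with columns `subject`, `state`, `value`. Rows with
#'   missing values are dropped listwise (logged).
#' @param gg apply the Greenhouse-Geisser epsilon correction to the df and
#'   p value.
#' @return data.frame with `F`, `df1`, `df2`, `p`, `partial_eta_sq`, `n`,
#'   `k` (and `gg_epsilon` when `gg = TRUE`).
#' @export
rm_anova <- function(values, gg = FALSE) {
  m <- as_wide_states(values)
  keep <- complete.cases(m)
  if (any(!keep)) {
    message(sum(!keep), " subject(s) dropped listwise (missing values)")
    m <- m[keep, , drop = FALSE]
  }
  n <- nrow(m); k <- ncol(m)
  if (k < 2) stop("need at least 2 states")
  if (n < 3) stop("need at least 3 complete subjects")
  grand <- mean(m)
  ss_state <- n * sum((colMeans(m) - grand)^2)
  ss_subject <- k * sum((rowMeans(m) - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_error <- ss_total - ss_state - ss_subject
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  ms_error <- ss_error / df2
  if (ms_error <= .Machine$double.eps * max(1, ss_total)) {
    if (ss_state <= .Machine$double.eps * max(1, ss_total)) {
      warning("state and error sums of squares are both zero: F undefined")
      return(data.frame(F = NA_real_, df1 = df1, df2 = df2, p = NA_real_,
                        partial_eta_sq = NA_real_, n = n, k = k))
    }
    stop("zero error variance")
  }
  f <- (ss_state / df1) / ms_error
  eps <- 1
  if (gg) {
    # Greenhouse-Geisser epsilon from the double-centred covariance matrix
    cc <- cov(m)
    cc <- cc - outer(rowMeans(cc), rep(1, k)) -
      outer(rep(1, k), colMeans(cc)) + mean(cc)
    eps <- sum(diag(cc))^2 / ((k - 1) * sum(cc^2))
    eps <- min(max(eps, 1 / (k - 1)), 1)
  }
  p <- stats::pf(f, df1 * eps, df2 * eps, lower.tail = FALSE)
  out <- data.frame(F = f, df1 = df1, df2 = df2, p = p,
                    partial_eta_sq = ss_state / (ss_state + ss_error),
                    n = n, k = k)
  if (gg) out$gg_epsilon <- eps
  out
}

as_wide_states <- function(values) {
  if (is.matrix(values)) return(values)
  if (is.data.frame(values) && all(c("subject", "state", "value") %in%
                                   names(values))) {
    states <- unique(values$state)
    subjects <- unique(values$subject)
    m <- matrix(NA_real_, length(subjects), length(states),
                dimnames = list(subjects, states))
    m[cbind(match(values$subject, subjects), match(values$state, states))] <-
      values$value
    return(m)
  }
  as.matrix(values)
}

#' Paired t test with Cohen's d
#'
#' Two-sided paired t on the differences `a - b`; `d = mean(diff)/sd(diff)`.
#' With zero-variance differences the t statistic is undefined and flagged
#' (`d = 0` by convention, with a warning).
#'
#' @param a,b paired numeric vectors of equal length >= 3 (NA pairs dropped).
#' @return data.frame with `t`, `df`, `p`, `cohens_d`, `mean_diff`, `n`.
#' @export
paired_t <- function(a, b) {
  keep <- !(is.na(a) | is.na(b))
  a <- a[keep]; b <- b[keep]
  if (length(a) != length(b) || length(a) < 3)
    stop("need paired vectors of equal length >= 3")
  d <- a - b
  if (sd(d) == 0) {
    warning("zero-variance differences: t undefined, d set to 0")
    return(data.frame(t = NA_real_, df = length(d) - 1, p = NA_real_,
                      cohens_d = 0, mean_diff = mean(d), n = length(d)))
  }
  tt <- t.test(a, b, paired = TRUE)
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, cohens_d = mean(d) / sd(d),
             mean_diff = mean(d), n = length(d))
}

#' Benjamini-Hochberg FDR correction within a family
#'
#' Step-up BH procedure at level `q` applied to one declared family of
#' p values.
#'
#' @param pvalues numeric vector of p values in `[0, 1]`.
#' @param q FDR level.
#' @return list with `reject` (logical mask) and `p_adj` (BH-adjusted
#'   p values).
#' @export
fdr_bh <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0) stop("empty p-value family")
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p values must be in [0, 1]")
  p_adj <- p.adjust(pvalues, method = "BH")
  list(reject = !is.na(p_adj) & p_adj <= q, p_adj = p_adj)
}

#' Brain-behavior correlation with optional covariate residualization
#'
#' Pearson correlation between a per-subject network measure and a
#' behavioral score. When covariates (e.g. mean FD of each state and, for
#' similarity measures, their interaction) are supplied, both variables are
#' residualized on the covariates (with intercept) and the correlation of
#' the residuals is returned, with degrees of freedom reduced accordingly.
#'
#' @param measure,behavior aligned numeric vectors (one value per subject).
#' @param covariates optional numeric vector or matrix of nuisance
#'   covariates; must be full rank.
#' @return data.frame with `r`, `p`, `df`, `n`.
#' @export
brain_behavior_corr <- function(measure, behavior, covariates = NULL) {
  if (length(measure) != length(behavior))
    stop("measure and behavior must be aligned")
  n_cov <- 0L
  if (!is.null(covariates)) {
    x <- cbind(1, as.matrix(covariates))
    if (qr(x)$rank < ncol(x)) stop("rank-deficient covariate design")
    n_cov <- ncol(x) - 1L
    measure <- stats::lm.fit(x, measure)$residuals
    behavior <- stats::lm.fit(x, behavior)$residuals
  }
  n <- length(measure)
  df <- n - 2L - n_cov
  if (df < 1) stop("not enough subjects for the covariate design")
  r <- cor(measure, behavior)
  tstat <- r * sqrt(df / (1 - r^2))
  data.frame(r = r, p = 2 * pt(-abs(tstat), df), df = df, n = n)
}
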