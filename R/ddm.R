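#' Diffusion-model parameter container
#'
#' Two-choice Wiener diffusion with unit diffusion coefficient: evidence
#' starts at `z * a` and drifts at rate `v` toward absorbing bounds at 0 and
#' `a`; the response time is the first-passage time plus the nondecision
#' time `ter` (stimulus encoding and motor execution). Drift rate and
#' boundary separation index the high-order decision process; nondecision
#' time indexes the sensorimotor/low-order process.
#'
#' @param v drift rate (evidence units per second).
#' @param a boundary separation (> 0).
#' @param ter nondecision time in seconds (>= 0).
#' @param z starting-point fraction in (0, 1); 0.5 is unbiased.
#' @return list of class `ddm_params`.
#' @export
ddm_params <- function(v, a, ter, z = 0.5) {
  stopifnot(a > 0, ter >= 0, z > 0, z < 1)
  structure(list(v = v, a = a, ter = ter, z = z), class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf("DDM parameters: v = %.4g, a = %.4g, Ter = %.4g s, z = %.3g\n",
              x$v, x$a, x$ter, x$z))
  invisible(x)
}

#' Simulate two-choice trials from the diffusion model
#'
#' Euler-Maruyama simulation of the Wiener process with unit diffusion from
#' `z * a` to the absorbing bounds; a trial is correct when the upper bound
#' is hit. A Brownian-bridge correction detects within-step boundary
#' crossings (probability `exp(-2 d0 d1 / dt)` for endpoint distances d0,
#' d1 to a boundary), removing the first-passage bias of the plain Euler
#' scheme. Trials that fail to absorb within `max_time` are resampled (the
#' count is recorded in the `n_resampled` attribute).
#'
#' @param params a [ddm_params()].
#' @param n_trials number of trials (>= 1).
#' @param dt_sim Euler time step in seconds (<= 0.005).
#' @param seed integer seed.
#' @param max_time give-up time per trial in seconds.
#' @return data.frame with columns `rt` (s) and `correct` (0/1); attributes
#'   `params` and `n_resampled`.
#' @export
simulate_trials <- function(params, n_trials, dt_sim = 0.001, seed = 1,
                            max_time = 10) {
  stopifnot(inherits(params, "ddm_params"), n_trials >= 1, dt_sim > 0,
            dt_sim <= 0.005)
  set.seed(as_seed(seed))
  rt <- numeric(n_trials)
  correct <- integer(n_trials)
  pending <- seq_len(n_trials)
  n_resampled <- 0L
  sq <- sqrt(dt_sim)
  max_steps <- ceiling(max_time / dt_sim)
  while (length(pending) > 0) {
    n <- length(pending)
    x <- rep(params$z * params$a, n)
    done <- logical(n)
    step_done <- integer(n)
    hit_upper <- logical(n)
    active <- seq_len(n)
    for (step in seq_len(max_steps)) {
      x_old <- x[active]
      x_new <- x_old + params$v * dt_sim + sq * rnorm(length(active))
      up <- x_new >= params$a
      down <- x_new <= 0
      # Brownian-bridge probability of an unobserved within-step crossing
      inside <- !up & !down
      if (any(inside)) {
        d_up0 <- params$a - x_old[inside]; d_up1 <- params$a - x_new[inside]
        p_up <- exp(-2 * d_up0 * d_up1 / dt_sim)
        p_dn <- exp(-2 * x_old[inside] * x_new[inside] / dt_sim)
        u <- runif(sum(inside))
        bridge_up <- u < p_up
        bridge_dn <- !bridge_up & (u < p_up + p_dn)
        up[inside] <- bridge_up
        down[inside] <- bridge_dn
      }
      hit <- up | down
      x[active] <- x_new
      if (any(hit)) {
        idx <- active[hit]
        done[idx] <- TRUE
        step_done[idx] <- step
        hit_upper[idx] <- up[hit]
        active <- active[!hit]
      }
      if (length(active) == 0) break
    }
    finished <- pending[done]
    rt[finished] <- step_done[done] * dt_sim + params$ter
    correct[finished] <- as.integer(hit_upper[done])
    n_resampled <- n_resampled + sum(!done)
    pending <- pending[!done]
  }
  if (n_resampled > 0)
    message(n_resampled, " trial(s) failed to absorb within ", max_time,
            " s and were resampled")
  structure(data.frame(rt = rt, correct = correct),
            params = params, n_resampled = n_resampled)
}

#' Closed-form upper-bound absorption probability
#'
#' For drift `v`, separation `a`, start fraction `z`, unit diffusion:
#' `P(upper) = (1 - exp(-2 v z a)) / (1 - exp(-2 v a))`, which reduces to
#' `1 / (1 + exp(-v a))` at `z = 0.5` (the EZ forward equation) and to `z`
#' at `v = 0`.
#'
#' @inheritParams simulate_trials
#' @return probability of a correct (upper-bound) response.
#' @export
ddm_accuracy <- function(params) {
  v <- params$v; a <- params$a; z <- params$z
  if (abs(v) < 1e-12) return(z)
  (1 - exp(-2 * v * z * a)) / (1 - exp(-2 * v * a))
}

#' EZ-diffusion parameter estimation
#'
#' Closed-form inversion of (accuracy, mean and variance of correct-trial
#' RTs) into drift rate, boundary separation, and nondecision time, assuming
#' an unbiased starting point and unit diffusion. Accuracies of exactly 0,
#' 0.5 or 1 are edge-corrected by 1/(2n) so the logit stays finite.
#'
#' @param trials data.frame with columns `rt` (s) and `correct` (0/1);
#'   at least 40 trials.
#' @param s diffusion coefficient of the generating process (1 for
#'   [simulate_trials()]).
#' @return A [ddm_params()] with the recovered `v`, `a`, `ter`.
#' @export
fit_ez <- function(trials, s = 1) {
  stopifnot(all(c("rt", "correct") %in% names(trials)))
  n <- nrow(trials)
  if (n < 40) stop("need at least 40 trials")
  p <- mean(trials$correct)
  if (p == 1) p <- 1 - 1 / (2 * n)
  else if (p == 0) p <- 1 / (2 * n)
  else if (p == 0.5) p <- 0.5 + 1 / (2 * n)
  rts <- trials$rt[trials$correct == 1]
  if (length(rts) < 2) stop("too few correct trials for RT moments")
  mrt <- mean(rts)
  vrt <- var(rts)
  if (vrt <= 0) stop("degenerate RT variance")
  l <- qlogis(p)
  x <- l * (l * p^2 - l * p + p - 0.5) / vrt
  v <- sign(p - 0.5) * s * x^(1 / 4)
  a <- s^2 * l / v
  y <- -v * a / s^2
  mdt <- (a / (2 * v)) * (1 - exp(y)) / (1 + exp(y))
  ter <- mrt - mdt
  ddm_params(v = v, a = a, ter = max(0, ter))
}

#' Fit EZ-diffusion per subject and state
#'
#' @param trials data.frame with columns `subject`, `state`, `rt`, `correct`.
#' @return data.frame with one row per subject-state: `subject`, `state`,
#'   `v`, `a`, `ter`, `accuracy`, `n_trials`.
#' @export
fit_ez_table <- function(trials) {
  stopifnot(all(c("subject", "state", "rt", "correct") %in% names(trials)))
  groups <- split(trials, list(trials$subject, trials$state), drop = TRUE)
  rows <- lapply(groups, function(g) {
    fit <- fit_ez(g)
    data.frame(subject = g$subject[1], state = g$state[1],
               v = fit$v, a = fit$a, ter = fit$ter,
               accuracy = mean(g$correct), n_trials = nrow(g))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$subject, out$state), ]
}
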