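#' Scenario configuration for the synthetic cohort generator
#'
#' A scenario fixes the generating model of the synthetic cohort: a
#' multivariate normal with exchangeable-within-block covariance. Nodes are
#' split into `n_modules` a-priori modules; within-module correlation is
#' `rho_in` and between-module correlation in state s is
#' `rho_base + integration[s]`, so the planted state effect is a change in
#' between-module coupling (functional integration). Observation noise of
#' standard deviation `sigma` is added on top of the latent signal and
#' per-subject heterogeneity jitters both correlation levels.
#'
#' With 14 modules the a-priori labels follow the standard functional
#' parcellation nomenclature (SOMH, SOMM, AU, VIS, CO, DM, MEM, VA, FP, SAL,
#' DA, SUB, CER, UNC); CER and UNC are excluded from modular analyses by
#' default. Other module counts get generic labels `M01`, `M02`, ...
#'
#' @param n_modules number of a-priori modules (default 6, matching the
#'   60-node test geometry; 14 gives the full brain-module labelling).
#' @param rho_in within-module correlation of the latent signal.
#' @param rho_base baseline between-module correlation.
#' @param integration named numeric vector of per-state increments added to
#'   `rho_base`; names are the state labels in presentation order. The
#'   default plants integration increasing with cognitive load
#'   (rest < 1-back < 2-back).
#' @param sigma observation noise SD (attenuates observed correlations by a
#'   factor 1/(1 + sigma^2)).
#' @param jitter_sd SD of the per-subject jitter on `rho_in` and the
#'   between-module level.
#' @param switch_frac fraction of nodes eligible to switch module membership
#'   in [generate_switching_cohort()].
#' @param ddm_truth named list of per-task-state diffusion parameters
#'   (each a list with `v`, `a`, `ter`) used by [generate_behavior()].
#' @return A list of class `nr_scenario`.
#' @export
nr_scenario <- function(n_modules = 6,
                        rho_in = 0.45,
                        rho_base = 0.05,
                        integration = c(rest = 0, `1-back` = 0.075, `2-back` = 0.15),
                        sigma = 0.3,
                        jitter_sd = 0.02,
                        switch_frac = 0.5,
                        ddm_truth = list(
                          `1-back` = list(v = 2.0, a = 1.10, ter = 0.30),
                          `2-back` = list(v = 1.4, a = 1.25, ter = 0.33))) {
  stopifnot(n_modules >= 2, rho_in >= 0, rho_in < 1,
            rho_base >= 0, all(integration >= 0), sigma >= 0, jitter_sd >= 0,
            switch_frac >= 0, switch_frac <= 1)
  if (is.null(names(integration)) || any(names(integration) == ""))
    stop("'integration' must be a named vector (names are state labels)")
  if (any(rho_base + integration >= rho_in))
    stop("between-module correlation must stay below rho_in (infeasible rho combination)")
  structure(list(n_modules = n_modules, rho_in = rho_in, rho_base = rho_base,
                 integration = integration, sigma = sigma,
                 jitter_sd = jitter_sd, switch_frac = switch_frac,
                 ddm_truth = ddm_truth),
            class = "nr_scenario")
}

module_labels <- function(n_modules) {
  if (n_modules == 14)
    c("SOMH", "SOMM", "AU", "VIS", "CO", "DM", "MEM", "VA", "FP", "SAL",
      "DA", "SUB", "CER", "UNC")
  else sprintf("M%02d", seq_len(n_modules))
}

# Assign n_nodes to modules as evenly as possible, in label order.
assign_modules <- function(n_nodes, n_modules) {
  labs <- module_labels(n_modules)
  sizes <- rep(n_nodes %/% n_modules, n_modules)
  extra <- n_nodes %% n_modules
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  setNames(rep(labs, times = sizes), sprintf("n%03d", seq_len(n_nodes)))
}

# Exchangeable block correlation matrix from a membership vector.
block_cov <- function(membership, rho_in, rho_out) {
  same <- outer(membership, membership, "==")
  s <- ifelse(same, rho_in, rho_out)
  diag(s) <- 1
  s
}

# Enforce positive definiteness by flooring eigenvalues at `floor` and
# renormalizing to unit diagonal. Repairs are logged, never silent.
ensure_pd <- function(s, floor = 1e-8, quiet = FALSE) {
  e <- eigen(s, symmetric = TRUE)
  if (min(e$values) >= floor) return(s)
  if (min(e$values) < -0.05)
    stop("covariance not positive-definite: infeasible rho combination ",
         "(min eigenvalue ", signif(min(e$values), 3), ")")
  v <- pmax(e$values, floor)
  s2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(s2))
  s2 <- s2 / outer(d, d)
  if (!quiet) message("PD repair applied (eigenvalue floor ", floor, ")")
  attr(s2, "pd_repaired") <- TRUE
  s2
}

# Draw a T x N matrix from N(0, Sigma) rows, plus observation noise.
rmvn_ts <- function(n_t, sigma_mat, sigma_noise) {
  r <- chol(sigma_mat)
  n <- ncol(sigma_mat)
  x <- matrix(rnorm(n_t * n), n_t, n) %*% r
  if (sigma_noise > 0) x <- x + sigma_noise * matrix(rnorm(n_t * n), n_t, n)
  x
}

subject_rhos <- function(scenario, n_subjects) {
  j <- rnorm(n_subjects, 0, scenario$jitter_sd)
  rho_in <- pmin(pmax(scenario$rho_in + j, 0), 0.95)
  j2 <- rnorm(n_subjects, 0, scenario$jitter_sd)
  list(rho_in = rho_in, out_shift = j2)
}

#' Generate a synthetic cohort of node time series
#'
#' Draws, for each subject and cognitive state, a `n_timepoints` x `n_nodes`
#' multivariate-normal time-series matrix whose population correlation is
#' `rho_in` within modules and `rho_base + integration[state]` between
#' modules (before observation-noise attenuation). Ground truth (module
#' labels, planted integration levels, per-subject rhos) is recorded on the
#' returned object.
#'
#' @param n_subjects,n_nodes,n_timepoints cohort dimensions.
#' @param dt sampling interval in seconds.
#' @param scenario an [nr_scenario()].
#' @param seed integer seed; the generator is a pure function of
#'   (arguments, seed).
#' @return An object of class `cohort_ts`: a list with `data` (nested list
#'   `data[[subject]][[state]]` of T x N matrices), `dt`, `state_names`,
#'   `node_ids`, and `truth`.
#' @examples
#' co <- generate_cohort(2, 20, 120, dt = 2, scenario = nr_scenario(4), seed = 1)
#' dim(co$data[[1]][["rest"]])
#' @export
generate_cohort <- function(n_subjects, n_nodes = 60, n_timepoints = 150,
                            dt = 2, scenario = nr_scenario(), seed = 1) {
  stopifnot(inherits(scenario, "nr_scenario"), n_subjects >= 1, dt > 0)
  if (n_nodes < 2 * scenario$n_modules)
    stop("n_nodes must be at least 2 x n_modules")
  if (n_timepoints < 100)
    stop("n_timepoints must be >= 100")
  set.seed(as_seed(seed))
  states <- names(scenario$integration)
  membership <- assign_modules(n_nodes, scenario$n_modules)
  sr <- subject_rhos(scenario, n_subjects)
  subjects <- sprintf("sub%02d", seq_len(n_subjects))

  data <- vector("list", n_subjects)
  names(data) <- subjects
  for (i in seq_len(n_subjects)) {
    per_state <- vector("list", length(states))
    names(per_state) <- states
    for (s in seq_along(states)) {
      rho_out <- max(0, min(scenario$rho_base + scenario$integration[[s]] +
                              sr$out_shift[i], sr$rho_in[i] - 0.01))
      sig <- ensure_pd(block_cov(membership, sr$rho_in[i], rho_out))
      per_state[[s]] <- rmvn_ts(n_timepoints, sig, scenario$sigma)
      colnames(per_state[[s]]) <- names(membership)
    }
    data[[i]] <- per_state
  }

  truth <- list(module_of_node = membership,
                integration_level = scenario$integration,
                rho_in = scenario$rho_in, rho_base = scenario$rho_base,
                sigma = scenario$sigma,
                subject_rho_in = setNames(sr$rho_in, subjects),
                subject_out_shift = setNames(sr$out_shift, subjects),
                ddm_truth = scenario$ddm_truth)
  structure(list(data = data, dt = dt, state_names = states,
                 node_ids = names(membership), truth = truth,
                 seed = as_seed(seed)),
            class = "cohort_ts")
}

#' @export
print.cohort_ts <- function(x, ...) {
  d <- dim(x$data[[1]][[1]])
  cat("Synthetic cohort:", length(x$data), "subjects x",
      length(x$state_names), "states;", d[1], "time points x", d[2],
      "nodes; dt =", x$dt, "s\n")
  cat("States:", paste(x$state_names, collapse = ", "), "\n")
  invisible(x)
}

#' Generate a cohort with window-scale module switching
#'
#' Like [generate_cohort()], but the generating covariance changes across
#' consecutive time segments of length `window_grid` seconds: within each
#' segment, each switching-eligible node (a fixed `switch_frac` of nodes)
#' independently adopts a uniformly chosen other module with probability
#' `switch_rate`. This plants dynamic modular reorganization whose magnitude
#' grows with `switch_rate`, for testing dMSI variability measures.
#'
#' @inheritParams generate_cohort
#' @param switch_rate per-segment probability that an eligible node swaps
#'   module membership in the generating covariance.
#' @param window_grid segment length in seconds; must give segments of at
#'   least 3 samples.
#' @param record_cov if `TRUE`, the actual covariance matrix used for each
#'   subject/state/segment is stored under `truth$segment_cov` (memory-heavy;
#'   intended for verification).
#' @return A `cohort_ts` whose `truth$segments` records, per subject and
#'   state, the segment sample boundaries and the N x n_segments membership
#'   matrix actually used.
#' @export
generate_switching_cohort <- function(n_subjects, n_nodes = 60,
                                      n_timepoints = 150, dt = 2,
                                      scenario = nr_scenario(),
                                      switch_rate = 0.5, window_grid = 20,
                                      seed = 1, record_cov = FALSE) {
  stopifnot(switch_rate >= 0, switch_rate <= 1, window_grid > 0)
  if (n_nodes < 2 * scenario$n_modules)
    stop("n_nodes must be at least 2 x n_modules")
  seg_len <- round(window_grid / dt)
  n_seg <- n_timepoints %/% seg_len
  bounds <- c(seq(0, (n_seg - 1) * seg_len, by = seg_len), n_timepoints)
  seg_sizes <- diff(bounds)
  if (any(seg_sizes < 3))
    stop("segment shorter than 3 samples; increase window_grid or n_timepoints")
  set.seed(as_seed(seed))
  states <- names(scenario$integration)
  membership <- assign_modules(n_nodes, scenario$n_modules)
  labs <- unique(membership)
  eligible <- sort(sample.int(n_nodes, round(scenario$switch_frac * n_nodes)))
  sr <- subject_rhos(scenario, n_subjects)
  subjects <- sprintf("sub%02d", seq_len(n_subjects))

  data <- vector("list", n_subjects)
  names(data) <- subjects
  segments <- vector("list", n_subjects)
  names(segments) <- subjects
  seg_cov <- if (record_cov) segments else NULL
  for (i in seq_len(n_subjects)) {
    per_state <- setNames(vector("list", length(states)), states)
    per_state_seg <- per_state
    per_state_cov <- per_state
    for (s in seq_along(states)) {
      rho_out <- max(0, min(scenario$rho_base + scenario$integration[[s]] +
                              sr$out_shift[i], sr$rho_in[i] - 0.01))
      mem_mat <- matrix(NA_character_, n_nodes, length(seg_sizes),
                        dimnames = list(names(membership), NULL))
      x <- matrix(NA_real_, n_timepoints, n_nodes)
      covs <- if (record_cov) vector("list", length(seg_sizes)) else NULL
      for (g in seq_along(seg_sizes)) {
        mem <- membership
        switching <- eligible[runif(length(eligible)) < switch_rate]
        for (v in switching)
          mem[v] <- sample(setdiff(labs, membership[v]), 1)
        mem_mat[, g] <- mem
        sig <- ensure_pd(block_cov(mem, sr$rho_in[i], rho_out), quiet = TRUE)
        rows <- (bounds[g] + 1):bounds[g + 1]
        x[rows, ] <- rmvn_ts(length(rows), sig, scenario$sigma)
        if (record_cov) covs[[g]] <- sig
      }
      colnames(x) <- names(membership)
      per_state[[s]] <- x
      per_state_seg[[s]] <- list(bounds = bounds, membership = mem_mat)
      if (record_cov) per_state_cov[[s]] <- covs
    }
    data[[i]] <- per_state
    segments[[i]] <- per_state_seg
    if (record_cov) seg_cov[[i]] <- per_state_cov
  }

  truth <- list(module_of_node = membership,
                integration_level = scenario$integration,
                rho_in = scenario$rho_in, rho_base = scenario$rho_base,
                sigma = scenario$sigma, switch_rate = switch_rate,
                eligible_nodes = names(membership)[eligible],
                subject_rho_in = setNames(sr$rho_in, subjects),
                subject_out_shift = setNames(sr$out_shift, subjects),
                segments = segments, segment_cov = seg_cov,
                ddm_truth = scenario$ddm_truth)
  structure(list(data = data, dt = dt, state_names = states,
                 node_ids = names(membership), truth = truth,
                 seed = as_seed(seed)),
            class = "cohort_ts")
}

#' Generate mean framewise-displacement covariates
#'
#' Strictly positive per-subject, per-state head-motion summaries drawn from
#' a truncated normal (resampled until positive).
#'
#' @param n_subjects,n_states table dimensions.
#' @param mean,sd mean FD in mm and its SD across subject-states.
#' @param state_names optional state labels (default `state1..`).
#' @param seed integer seed.
#' @return data.frame with columns `subject`, `state`, `fd`.
#' @export
generate_fd <- function(n_subjects, n_states, mean = 0.12, sd = 0.03,
                        state_names = NULL, seed = 1) {
  stopifnot(mean > 0, sd >= 0)
  set.seed(as_seed(seed))
  n <- n_subjects * n_states
  fd <- rnorm(n, mean, sd)
  while (any(fd <= 0)) fd[fd <= 0] <- rnorm(sum(fd <= 0), mean, sd)
  states <- state_names %||% sprintf("state%d", seq_len(n_states))
  data.frame(subject = rep(sprintf("sub%02d", seq_len(n_subjects)),
                           each = n_states),
             state = rep(states, n_subjects),
             fd = fd)
}

#' Simulate an FD-confounded brain-behavior pair
#'
#' Harness for the head-motion validation path: generates per-subject FD and
#' a brain measure and behavior score that are both driven by FD but share no
#' direct association. Regressing FD out of both variables should attenuate
#' their spurious correlation toward zero.
#'
#' @param n_subjects number of subjects.
#' @param slope_measure,slope_behavior FD effect (per mm) on each variable.
#' @param noise_sd independent noise SD of each variable.
#' @param fd_mean,fd_sd FD distribution parameters (mm).
#' @param seed integer seed.
#' @return data.frame with columns `subject`, `fd`, `measure`, `behavior`.
#' @export
simulate_confounded_pair <- function(n_subjects, slope_measure = 10,
                                     slope_behavior = 10, noise_sd = 1,
                                     fd_mean = 0.12, fd_sd = 0.03, seed = 1) {
  fd <- generate_fd(n_subjects, 1, fd_mean, fd_sd, seed = seed)$fd
  set.seed(as_seed(seed + 1))
  data.frame(subject = sprintf("sub%02d", seq_len(n_subjects)),
             fd = fd,
             measure = slope_measure * fd + rnorm(n_subjects, 0, noise_sd),
             behavior = slope_behavior * fd + rnorm(n_subjects, 0, noise_sd))
}

#' Simulate trial-level behavior for a cohort
#'
#' Draws two-choice trials from the Wiener diffusion process for each subject
#' and task state, using the scenario's per-state diffusion parameters plus
#' subject-level jitter.
#'
#' @param n_subjects number of subjects.
#' @param ddm_truth named list of per-state parameters, each a list with
#'   `v`, `a`, `ter` (see [nr_scenario()]).
#' @param n_trials trials per subject-state.
#' @param subject_sd SD of the per-subject jitter applied to `v` (and, scaled
#'   by 1/4, to `a` and `ter`).
#' @param dt_sim Euler step of the trial simulator, seconds.
#' @param seed integer seed.
#' @return data.frame with columns `subject`, `state`, `rt`, `correct`.
#' @export
generate_behavior <- function(n_subjects,
                              ddm_truth = nr_scenario()$ddm_truth,
                              n_trials = 200, subject_sd = 0.15,
                              dt_sim = 0.001, seed = 1) {
  seeds <- child_seeds(seed, n_subjects * length(ddm_truth) + 1)
  set.seed(seeds[1])
  jit <- rnorm(n_subjects, 0, subject_sd)
  out <- list()
  k <- 1L
  for (i in seq_len(n_subjects)) {
    for (s in names(ddm_truth)) {
      p <- ddm_truth[[s]]
      pars <- ddm_params(v = max(0.2, p$v + jit[i]),
                         a = max(0.5, p$a + jit[i] / 4),
                         ter = max(0.05, p$ter + jit[i] / 40))
      tr <- simulate_trials(pars, n_trials, dt_sim = dt_sim,
                            seed = seeds[1 + k])
      out[[k]] <- data.frame(subject = sprintf("sub%02d", i), state = s,
                             rt = tr$rt, correct = tr$correct)
      k <- k + 1L
    }
  }
  do.call(rbind, out)
}
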