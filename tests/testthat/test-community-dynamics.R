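# Build a windowed_fc directly from a list of weight matrices.
wfc <- function(mats, window_length = 40, step = 20) {
  windows <- lapply(mats, function(m) {
    dimnames(m) <- list(sprintf("n%03d", seq_len(nrow(m))),
                        sprintf("n%03d", seq_len(nrow(m))))
    structure(m, class = c("fc_matrix", "matrix"))
  })
  structure(list(windows = windows, window_length = window_length,
                 step = step,
                 start_times = (seq_along(mats) - 1) * step, dt = 2,
                 state_label = NULL),
            class = "windowed_fc")
}

toy_ensemble <- function() {
  # r = 1, w = 2: nodes 1-2 always together; node 3 joins them in window 2
  p1 <- matrix(c(1L, 1L, 2L,
                 1L, 1L, 1L), ncol = 2,
               dimnames = list(c("a", "b", "c"), NULL))
  structure(list(partitions = list(p1), r = 1L, w = 2L,
                 node_ids = c("a", "b", "c"), gamma = 1, omega = 1,
                 q = NA_real_, seed = 1L),
            class = "partition_ensemble")
}

test_that("allegiance entries are exact co-assignment fractions", {
  ens <- toy_ensemble()
  p <- allegiance(ens)
  expect_equal(p["a", "b"], 1)      # always co-assigned
  expect_equal(p["a", "c"], 0.5)    # co-assigned in one of two windows
  expect_equal(diag(p), setNames(rep(1, 3), c("a", "b", "c")))
  expect_true(isSymmetric(unclass(p)))
})

test_that("allegiance values are rationals with denominator r*w and match a recount", {
  set.seed(21)
  w_list <- lapply(1:4, function(i) planted_fc(12, 1, 0.1) +
                     abs(matrix(rnorm(144, 0, 0.05), 12, 12)))
  wf <- wfc(lapply(w_list, function(m) { m <- (m + t(m)) / 2; diag(m) <- 0; m }))
  ens <- multilayer_communities(wf, omega = 1, repetitions = 5, seed = 8)
  p <- allegiance(ens)
  denom <- ens$r * ens$w
  expect_equal(p * denom, round(p * denom), tolerance = 1e-12)
  # direct recount over the stored ensemble
  recount <- matrix(0, 12, 12)
  for (part in ens$partitions)
    for (s in seq_len(ens$w))
      recount <- recount + outer(part[, s], part[, s], "==")
  recount <- recount / denom
  diag(recount) <- 1
  pm <- unclass(p); attributes(pm) <- attributes(pm)["dim"]
  expect_equal(pm, unname(recount), tolerance = 1e-12)
})

test_that("allegiance is invariant under community-label permutation within layers", {
  ens <- toy_ensemble()
  p0 <- allegiance(ens)
  ens2 <- ens
  ens2$partitions[[1]][, 1] <- c(7L, 4L, 9L)[ens$partitions[[1]][, 1]]
  expect_equal(unclass(allegiance(ens2)), unclass(p0))
})

test_that("omega = 0 reduces exactly to per-window Louvain under shared seeds", {
  set.seed(22)
  co <- generate_cohort(1, 60, 150, dt = 2,
                        scenario = nr_scenario(6, sigma = 0.2), seed = 12)
  wf <- sliding_windows(co$data[[1]][[1]], dt = 2, length = 40, step = 20)
  reps <- 5
  ens <- multilayer_communities(wf, omega = 0, repetitions = reps, seed = 30)
  seeds <- netreconfig:::per_layer_seeds(30, reps, length(wf$windows))
  for (r in seq_len(reps))
    for (s in seq_along(wf$windows)) {
      ref <- louvain_q(netreconfig:::trunc_neg(wf$windows[[s]]),
                       gamma = 1, seed = seeds[r, s])$partition
      expect_identical(unname(ens$partitions[[r]][, s]), unname(ref))
    }
})

test_that("strong coupling locks communities across identical layers", {
  base <- planted_fc(10, 1, 0.05)
  wf <- wfc(list(base, base, base))
  ens <- multilayer_communities(wf, omega = 50, repetitions = 3, seed = 2)
  for (p in ens$partitions) {
    expect_true(all(p[, 1] == p[, 2]))
    expect_true(all(p[, 2] == p[, 3]))
    expect_equal(ari(p[, 1], rep(1:2, each = 5)), 1)
  }
})

test_that("per-layer multilayer detection recovers planted modules", {
  sc <- nr_scenario(6, rho_in = 0.5, rho_base = 0.05,
                    integration = c(rest = 0), sigma = 0, jitter_sd = 0)
  co <- generate_cohort(1, 60, 600, dt = 2, scenario = sc, seed = 23)
  truth <- co$truth$module_of_node
  # windows long enough to be informative on their own (80 samples)
  wf <- sliding_windows(co$data[[1]][[1]], dt = 2, length = 160, step = 80)
  ens <- multilayer_communities(wf, gamma = 1, omega = 1, repetitions = 3,
                                seed = 6)
  aris <- sapply(ens$partitions, function(p)
    sapply(seq_len(ncol(p)), function(s) ari(p[, s], truth)))
  expect_gte(min(aris), 0.9)
  # short noisy windows (20 samples) under-resolve alone, but stronger
  # interlayer coupling pools evidence across layers and restores recovery
  wf20 <- sliding_windows(co$data[[1]][[1]], dt = 2, length = 40, step = 20)
  ens20 <- multilayer_communities(wf20, gamma = 1, omega = 5,
                                  repetitions = 3, seed = 6)
  aris20 <- sapply(ens20$partitions, function(p)
    sapply(seq_len(ncol(p)), function(s) ari(p[, s], truth)))
  expect_gte(min(aris20), 0.9)
})

test_that("multilayer Q is consistent with the supra-modularity scoring", {
  set.seed(25)
  mats <- lapply(1:3, function(i) {
    m <- abs(matrix(rnorm(64), 8, 8)); m <- (m + t(m)) / 2; diag(m) <- 0; m
  })
  wf <- wfc(mats)
  ens <- multilayer_communities(wf, omega = 0.5, repetitions = 4, seed = 9)
  b <- netreconfig:::supra_modularity_matrix(
    lapply(mats, netreconfig:::trunc_neg), 1, 0.5)
  for (r in seq_len(ens$r)) {
    flat <- as.integer(ens$partitions[[r]])
    expect_equal(ens$q[r], sum(b[outer(flat, flat, "==")]),
                 tolerance = 1e-10)
    # greedy ascent never ends below the singleton start
    expect_gte(ens$q[r], sum(diag(b)) - 1e-12)
  }
})

test_that("consensus returns identical input partitions in one iteration", {
  part <- rep(1:3, each = 4)
  res <- consensus_partition(list(part, part, part), seed = 1)
  expect_true(res$converged)
  expect_equal(res$n_iter, 1L)
  expect_equal(ari(res$partition, part), 1)
})

test_that("consensus of noisy restarts recovers an unambiguous clique split", {
  n <- 8
  w <- matrix(0, n, n)
  w[1:4, 1:4] <- 1; w[5:8, 5:8] <- 1; diag(w) <- 0
  w[4, 5] <- w[5, 4] <- 0.2
  restarts <- lapply(netreconfig:::child_seeds(40, 20), function(s)
    louvain_q(w, seed = s)$partition)
  res <- consensus_partition(restarts, tau = 0.5, seed = 3)
  expect_true(res$converged)
  expect_equal(ari(res$partition, rep(1:2, each = 4)), 1)
})

test_that("consensus is at least as accurate as the mean individual restart", {
  sc <- nr_scenario(6, rho_in = 0.4, rho_base = 0.1,
                    integration = c(rest = 0), sigma = 0.6, jitter_sd = 0)
  co <- generate_cohort(1, 60, 110, dt = 2, scenario = sc, seed = 29)
  fc <- compute_sfc(co$data[[1]][[1]])
  truth <- co$truth$module_of_node
  restarts <- lapply(netreconfig:::child_seeds(41, 25), function(s)
    louvain_q(fc, seed = s)$partition)
  mean_ari <- mean(sapply(restarts, ari, b = truth))
  res <- consensus_partition(restarts, tau = 0.5, seed = 4)
  expect_gte(ari(res$partition, truth), mean_ari - 1e-12)
})
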