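# Adjacency with planted intra/inter edge counts for a 3-module layout.
counts_graph <- function() {
  # module A: nodes 1-8, B: 9-16, C: 17-24
  n <- 24
  adj <- matrix(0L, n, n)
  add <- function(i, j) { adj[i, j] <<- 1L; adj[j, i] <<- 1L }
  # 20 intra-A edges
  pairs_a <- combn(1:8, 2)[, 1:20]
  for (k in seq_len(ncol(pairs_a))) add(pairs_a[1, k], pairs_a[2, k])
  # 10 distinct A-B edges
  for (k in 1:8) add(k, 8 + k)
  add(1, 10); add(2, 11)
  # make B and C internally connected a bit
  for (i in 9:15) add(i, i + 1)
  for (i in 17:23) add(i, i + 1)
  adj
}

mem3 <- setNames(rep(c("A", "B", "C"), each = 8), NULL)

test_that("MSI matches the intra/inter edge-count formula", {
  adj <- counts_graph()
  g <- bg(adj)
  v <- msi(g, mem3, "A")
  expect_equal(attr(v, "e_intra"), 20)
  expect_equal(attr(v, "e_inter"), 10)
  expect_equal(as.numeric(v), (20 - 10) / 20)  # 0.5
  # module with no external edges has maximal segregation
  v_c <- msi(g, mem3, "C")
  expect_equal(as.numeric(v_c), 1)
  # strongly integrated module: E_intra = 5, E_inter = 15
  adj2 <- matrix(0L, 22, 22)
  for (i in 1:5) { adj2[i, i + 1] <- adj2[i + 1, i] <- 1L }        # 5 intra
  for (i in 1:15) {
    a <- (i - 1) %% 6 + 1; b <- 6 + i
    adj2[a, b] <- adj2[b, a] <- 1L                                  # 15 inter
  }
  memD <- rep(c("D", "E"), c(6, 16))
  vD <- msi(bg(adj2), memD, "D")
  expect_equal(attr(vD, "e_intra"), 5)
  expect_equal(attr(vD, "e_inter"), 15)
  expect_equal(as.numeric(vD), -2)
})

test_that("E_inter summed over modules double-counts each between-module edge", {
  set.seed(14)
  g <- random_connected_graph(24, 0.25)
  prof <- msi_profile(g, mem3, analyzed_modules = c("A", "B", "C"))
  n_between <- sum(g$adjacency[outer(mem3, mem3, "!=")]) / 2
  expect_equal(sum(prof$e_inter), 2 * n_between)
})

test_that("MSI moves strictly with single edge additions", {
  adj <- counts_graph()
  base <- as.numeric(msi(bg(adj), mem3, "A"))
  # add one inter edge A-C (1 <-> 24): MSI decreases
  adj_inter <- adj; adj_inter[1, 24] <- adj_inter[24, 1] <- 1L
  expect_lt(as.numeric(msi(bg(adj_inter), mem3, "A")), base)
  # add one intra edge inside A: MSI increases
  free <- which(adj[1:8, 1:8] == 0 & upper.tri(adj[1:8, 1:8]), arr.ind = TRUE)
  adj_intra <- adj
  adj_intra[free[1, 1], free[1, 2]] <- adj_intra[free[1, 2], free[1, 1]] <- 1L
  expect_gt(as.numeric(msi(bg(adj_intra), mem3, "A")), base)
})

test_that("msi_profile is invariant to node relabeling and module-complete graphs score 1", {
  set.seed(15)
  g <- random_connected_graph(24, 0.3)
  prof <- msi_profile(g, mem3, analyzed_modules = c("A", "B", "C"))
  perm <- sample(24)
  gp <- bg(g$adjacency[perm, perm])
  prof_p <- msi_profile(gp, mem3[perm], analyzed_modules = c("A", "B", "C"))
  expect_equal(prof, prof_p)
  # disjoint union of complete modules
  blocks <- matrix(0L, 12, 12)
  for (b in 0:2) blocks[b * 4 + 1:4, b * 4 + 1:4] <- 1L
  diag(blocks) <- 0L
  memB <- rep(c("X", "Y", "Z"), each = 4)
  profB <- msi_profile(bg(blocks), memB, analyzed_modules = c("X", "Y", "Z"))
  expect_true(all(profB$msi == 1))
})

test_that("excluded modules still count toward E_inter of analyzed modules", {
  adj <- matrix(0L, 9, 9)
  adj[1, 2] <- adj[2, 1] <- 1L       # intra M
  adj[1, 7] <- adj[7, 1] <- 1L       # M <-> CER
  adj[2, 3] <- adj[3, 2] <- 1L       # intra M (second edge)
  mem <- rep(c("M", "CER", "UNC"), each = 3)
  prof <- msi_profile(bg(adj), mem)
  expect_equal(prof$module, "M")
  expect_equal(prof$e_inter, 1)
  expect_equal(prof$msi, (2 - 1) / 2)
})

test_that("undefined MSI follows the configured missing policy", {
  adj <- matrix(0L, 6, 6)
  adj[1, 4] <- adj[4, 1] <- adj[2, 5] <- adj[5, 2] <- 1L
  adj[4, 5] <- adj[5, 4] <- adj[5, 6] <- adj[6, 5] <- 1L
  mem <- rep(c("P", "Q"), each = 3)
  expect_message(v <- msi(bg(adj), mem, "P"), "NA")
  expect_true(is.na(v))
  expect_error(msi(bg(adj), mem, "P", on_empty = "error"), "undefined")
})

test_that("dMSI summaries follow the series definitions", {
  s_const <- dmsi_series(rep(0.3, 14))
  expect_equal(s_const$sd, 0)
  expect_equal(s_const$speed, 0)
  s <- dmsi_series(c(0.2, 0.4, 0.1))
  expect_equal(s$speed, (0.2 + 0.3) / 2)
  expect_equal(s$sd, sd(c(0.2, 0.4, 0.1)))
})

test_that("identical windows reproduce the static MSI with zero variability", {
  set.seed(16)
  ts_block <- matrix(rnorm(40 * 24), ncol = 24)
  ts <- rbind(ts_block, ts_block, ts_block)
  wf <- sliding_windows(ts, dt = 1, length = 40, step = 40)
  dm <- dmsi(wf, mem3, "A", density = 0.2)
  g_static <- binarize(compute_sfc(ts_block), 0.2)
  expect_equal(dm$values, rep(as.numeric(msi(g_static, mem3, "A")),
                              length(dm$values)))
  expect_equal(dm$sd, 0)
  expect_equal(dm$speed, 0)
})

test_that("dmsi_profile matches per-module dmsi", {
  set.seed(17)
  ts <- matrix(rnorm(120 * 24), ncol = 24)
  wf <- sliding_windows(ts, dt = 1, length = 30, step = 15)
  prof <- dmsi_profile(wf, mem3, modules = c("A", "B"), density = 0.25)
  for (mod in c("A", "B")) {
    dm <- dmsi(wf, mem3, mod, density = 0.25)
    row <- prof[prof$module == mod, ]
    expect_equal(row$sd, dm$sd)
    expect_equal(row$speed, dm$speed)
  }
})
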