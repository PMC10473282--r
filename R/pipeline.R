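#' Pipeline run configuration
#'
#' Collects every tunable of the cohort -> FC -> topology -> dynamics ->
#' behavior -> statistics pipeline in one object. All randomness downstream
#' is derived from `seed`, so a run is a pure function of (inputs, config).
#'
#' @param seed master integer seed.
#' @param band band-pass edges in Hz (`NULL` to skip filtering).
#' @param window,step sliding-window length and step in seconds.
#' @param density edge density for binarization.
#' @param gamma Louvain resolution parameter.
#' @param omega interlayer coupling of the multilayer detection.
#' @param q_repetitions Louvain restarts for maximal-Q searches.
#' @param ml_repetitions repetitions of the multilayer detection.
#' @param n_null null networks for small-worldness (0 skips sigma).
#' @param fdr_q FDR level for the declared families.
#' @param analyzed_modules module labels scored by MSI/dMSI (`NULL`: all
#'   except `CER`/`UNC`).
#' @param focus_module module whose dynamic reconfiguration is correlated
#'   with behavior (`NULL`: first analyzed module).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, band = c(0.008, 0.25), window = 40,
                       step = 20, density = 0.2, gamma = 1, omega = 1,
                       q_repetitions = 100, ml_repetitions = 100,
                       n_null = 100, fdr_q = 0.05, analyzed_modules = NULL,
                       focus_module = NULL) {
  stopifnot(window > step, step > 0, density > 0, density < 1)
  structure(list(seed = as_seed(seed), band = band, window = window,
                 step = step, density = density, gamma = gamma,
                 omega = omega, q_repetitions = q_repetitions,
                 ml_repetitions = ml_repetitions, n_null = n_null,
                 fdr_q = fdr_q, analyzed_modules = analyzed_modules,
                 focus_module = focus_module),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

state_pairs <- function(states) {
  cmb <- combn(states, 2)
  lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
}

#' Run the full reconfiguration pipeline on a cohort
#'
#' Orchestrates band-pass filtering, static and windowed FC, between-state
#' edge-weight similarity (subject and group level), group-level modular
#' structure, global topology, MSI profiles, dMSI trajectories, multilayer
#' allegiance analysis, EZ-diffusion fits, and the repeated-measures
#' statistics with FDR within declared families.
#'
#' @param cohort a `cohort_ts` (or path to a cohort `manifest.json`).
#' @param config a [run_config()].
#' @param behavior optional trial table (`subject`, `state`, `rt`,
#'   `correct`); defaults to `cohort$behavior` if present.
#' @param fd optional FD table (`subject`, `state`, `fd`); defaults to
#'   `cohort$fd`.
#' @param out_dir optional directory; when given, all tidy tables are
#'   written as TSV plus a JSON run manifest.
#' @return list of tidy data.frames (`similarity`, `topology`,
#'   `group_partitions`, `msi`, `dmsi`, `allegiance_similarity`, `ddm`,
#'   `stats`, `manifest`).
#' @export
run_pipeline <- function(cohort, config = run_config(), behavior = NULL,
                         fd = NULL, out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "cohort_ts"), inherits(config, "run_config"))
  behavior <- behavior %||% cohort$behavior
  fd <- fd %||% cohort$fd
  states <- cohort$state_names
  subjects <- names(cohort$data)
  assignment <- cohort$truth$module_of_node
  analyzed <- config$analyzed_modules %||%
    setdiff(unique(assignment), c("CER", "UNC"))
  focus <- config$focus_module %||% analyzed[1]
  n_ss <- length(subjects) * length(states)
  seeds <- child_seeds(config$seed, 4)
  sigma_seeds <- matrix(child_seeds(seeds[1], n_ss), length(subjects))
  q_seeds <- matrix(child_seeds(seeds[2], n_ss), length(subjects))
  ml_seeds <- matrix(child_seeds(seeds[3], n_ss), length(subjects))

  # --- FC construction -----------------------------------------------------
  sfc <- list(); winfc <- list()
  stage("fc", for (si in seq_along(subjects)) {
    sub <- subjects[si]
    sfc[[sub]] <- list(); winfc[[sub]] <- list()
    for (st in states) {
      ts <- cohort$data[[sub]][[st]]
      if (!is.null(config$band))
        ts <- bandpass(ts, config$band[1], config$band[2], cohort$dt)
      sfc[[sub]][[st]] <- compute_sfc(ts, state_label = st)
      winfc[[sub]][[st]] <- sliding_windows(ts, cohort$dt, config$window,
                                            config$step, state_label = st)
    }
  })

  # --- edge-weight similarity ---------------------------------------------
  pairs <- state_pairs(states)
  similarity <- stage("similarity", {
    rows <- list()
    for (sub in subjects)
      for (pr in pairs)
        rows[[length(rows) + 1]] <- data.frame(
          level = "subject", subject = sub,
          pair = paste(pr, collapse = " vs "),
          r = fc_similarity(sfc[[sub]][[pr[1]]], sfc[[sub]][[pr[2]]]))
    group_fc <- lapply(states, function(st) {
      acc <- Reduce(`+`, lapply(subjects, function(sub)
        unclass(sfc[[sub]][[st]])))
      acc / length(subjects)
    })
    names(group_fc) <- states
    for (pr in pairs)
      rows[[length(rows) + 1]] <- data.frame(
        level = "group", subject = NA_character_,
        pair = paste(pr, collapse = " vs "),
        r = fc_similarity(group_fc[[pr[1]]], group_fc[[pr[2]]]))
    attr(rows, "group_fc") <- group_fc
    rows
  })
  group_fc <- attr(similarity, "group_fc")
  similarity <- do.call(rbind, similarity)

  # --- group-level modular structure --------------------------------------
  group_partitions <- stage("group modularity", {
    gp_seeds <- child_seeds(seeds[4], length(states))
    rows <- lapply(seq_along(states), function(i) {
      res <- max_modularity(group_fc[[states[i]]], config$gamma,
                            config$q_repetitions, seed = gp_seeds[i])
      data.frame(state = states[i], node_id = names(res$partition),
                 community = unname(res$partition), q = res$q)
    })
    do.call(rbind, rows)
  })

  # --- global topology -----------------------------------------------------
  topology <- stage("topology", {
    rows <- list()
    for (si in seq_along(subjects))
      for (sj in seq_along(states)) {
        sub <- subjects[si]; st <- states[sj]
        g <- binarize(sfc[[sub]][[st]], config$density)
        vals <- c(clustering = clustering_coefficient(g),
                  efficiency = global_efficiency(g),
                  betweenness = mean_betweenness(g),
                  modularity = max_modularity(sfc[[sub]][[st]], config$gamma,
                                              config$q_repetitions,
                                              seed = q_seeds[si, sj])$q)
        if (config$n_null > 0)
          vals <- c(vals, sigma = as.numeric(
            small_worldness(g, config$n_null, seed = sigma_seeds[si, sj])))
        rows[[length(rows) + 1]] <- data.frame(
          subject = sub, state = st, metric = names(vals),
          value = unname(vals))
      }
    do.call(rbind, rows)
  })

  # --- MSI profiles --------------------------------------------------------
  msi_tab <- stage("msi", {
    rows <- list()
    for (sub in subjects)
      for (st in states) {
        g <- binarize(sfc[[sub]][[st]], config$density)
        prof <- msi_profile(g, assignment, analyzed_modules = analyzed)
        prof$subject <- sub; prof$state <- st
        rows[[length(rows) + 1]] <- prof
      }
    do.call(rbind, rows)
  })

  # --- dMSI trajectories ---------------------------------------------------
  dmsi_tab <- stage("dmsi", {
    rows <- list()
    for (sub in subjects)
      for (st in states) {
        prof <- dmsi_profile(winfc[[sub]][[st]], assignment,
                             modules = analyzed, density = config$density)
        prof <- cbind(subject = sub, state = st, prof)
        rows[[length(rows) + 1]] <- prof
      }
    do.call(rbind, rows)
  })

  # --- multilayer allegiance ----------------------------------------------
  allegiance_sim <- stage("dynamics", {
    alle <- list()
    for (si in seq_along(subjects)) {
      sub <- subjects[si]
      alle[[sub]] <- list()
      for (sj in seq_along(states)) {
        ens <- multilayer_communities(winfc[[sub]][[states[sj]]],
                                      gamma = config$gamma,
                                      omega = config$omega,
                                      repetitions = config$ml_repetitions,
                                      seed = ml_seeds[si, sj])
        alle[[sub]][[states[sj]]] <- allegiance(ens)
      }
    }
    rows <- list()
    for (sub in subjects)
      for (pr in pairs)
        rows[[length(rows) + 1]] <- data.frame(
          subject = sub, pair = paste(pr, collapse = " vs "),
          r = allegiance_similarity(alle[[sub]][[pr[1]]],
                                    alle[[sub]][[pr[2]]]))
    do.call(rbind, rows)
  })

  # --- behavior ------------------------------------------------------------
  ddm_tab <- if (!is.null(behavior))
    stage("ddm", fit_ez_table(behavior)) else NULL

  # --- statistics ----------------------------------------------------------
  stats_out <- stage("stats", pipeline_stats(
    similarity, topology, msi_tab, dmsi_tab, allegiance_sim, ddm_tab, fd,
    states, analyzed, focus, config$fdr_q))

  manifest <- list(config = unclass(config), states = states,
                   subjects = subjects, n_nodes = length(cohort$node_ids),
                   analyzed_modules = analyzed, focus_module = focus,
                   package_version = as.character(utils::packageVersion("netreconfig")))

  out <- list(similarity = similarity, topology = topology,
              group_partitions = group_partitions, msi = msi_tab,
              dmsi = dmsi_tab, allegiance_similarity = allegiance_sim,
              ddm = ddm_tab, stats = stats_out, manifest = manifest)
  if (!is.null(out_dir)) write_results(out, out_dir)
  out
}

# Wide subject x state matrix from a long table.
wide_measure <- function(df, value_col, subjects, states) {
  m <- matrix(NA_real_, length(subjects), length(states),
              dimnames = list(subjects, states))
  m[cbind(match(df$subject, subjects), match(df$state, states))] <-
    df[[value_col]]
  m
}

pipeline_stats <- function(similarity, topology, msi_tab, dmsi_tab,
                           allegiance_sim, ddm_tab, fd, states, analyzed,
                           focus, fdr_q) {
  subjects <- unique(topology$subject)
  anova_rows <- list()
  add_anova <- function(family, measure, m) {
    res <- rm_anova(m)
    anova_rows[[length(anova_rows) + 1]] <<- data.frame(
      family = family, measure = measure, res)
  }

  for (met in unique(topology$metric)) {
    d <- topology[topology$metric == met, ]
    add_anova("global_topology", met, wide_measure(d, "value", subjects, states))
  }
  msi_mean <- aggregate(msi ~ subject + state, msi_tab, mean, na.rm = TRUE)
  add_anova("msi", "mean_msi", wide_measure(msi_mean, "msi", subjects, states))
  for (mod in analyzed) {
    d <- msi_tab[msi_tab$module == mod, ]
    add_anova("msi", paste0("msi_", mod), wide_measure(d, "msi", subjects, states))
  }
  for (mod in analyzed) {
    d <- dmsi_tab[dmsi_tab$module == mod, ]
    add_anova("dmsi_sd", paste0("dmsi_sd_", mod),
              wide_measure(d, "sd", subjects, states))
    add_anova("dmsi_speed", paste0("dmsi_speed_", mod),
              wide_measure(d, "speed", subjects, states))
  }
  anova_tab <- do.call(rbind, anova_rows)
  anova_tab$p_adj <- NA_real_
  anova_tab$fdr_significant <- NA
  for (fam in unique(anova_tab$family)) {
    idx <- anova_tab$family == fam
    corr <- fdr_bh(anova_tab$p[idx], fdr_q)
    anova_tab$p_adj[idx] <- corr$p_adj
    anova_tab$fdr_significant[idx] <- corr$reject
  }

  # post hoc paired t for FDR-significant main effects
  posthoc <- list()
  sig <- anova_tab[!is.na(anova_tab$fdr_significant) &
                     anova_tab$fdr_significant, ]
  source_tab <- function(measure) {
    if (measure == "mean_msi") return(list(msi_mean, "msi"))
    if (grepl("^msi_", measure))
      return(list(msi_tab[msi_tab$module == sub("^msi_", "", measure), ], "msi"))
    if (grepl("^dmsi_sd_", measure))
      return(list(dmsi_tab[dmsi_tab$module == sub("^dmsi_sd_", "", measure), ], "sd"))
    if (grepl("^dmsi_speed_", measure))
      return(list(dmsi_tab[dmsi_tab$module == sub("^dmsi_speed_", "", measure), ], "speed"))
    list(topology[topology$metric == measure, ], "value")
  }
  for (i in seq_len(nrow(sig))) {
    st <- source_tab(sig$measure[i])
    m <- wide_measure(st[[1]], st[[2]], subjects, states)
    for (pr in state_pairs(states)) {
      tt <- paired_t(m[, pr[1]], m[, pr[2]])
      posthoc[[length(posthoc) + 1]] <- data.frame(
        measure = sig$measure[i], pair = paste(pr, collapse = " vs "), tt)
    }
  }
  posthoc <- if (length(posthoc)) do.call(rbind, posthoc) else NULL

  # behavioral contrasts between task states
  behavior_t <- NULL
  brain_behavior <- NULL
  if (!is.null(ddm_tab) && length(unique(ddm_tab$state)) >= 2) {
    task_states <- unique(ddm_tab$state)
    bt <- list()
    for (param in c("v", "a", "ter")) {
      m <- wide_measure(ddm_tab, param, subjects, task_states)
      for (pr in state_pairs(task_states)) {
        tt <- paired_t(m[, pr[1]], m[, pr[2]])
        bt[[length(bt) + 1]] <- data.frame(
          parameter = param, pair = paste(pr, collapse = " vs "), tt)
      }
    }
    behavior_t <- do.call(rbind, bt)

    # exploratory (uncorrected) brain-behavior correlations: similarity of
    # rest vs the hardest state, and focus-module dynamics, against the DDM
    # parameters of that state; FD regressed out when supplied.
    last <- states[length(states)]
    pair_lab <- paste(states[1], "vs", last)
    sim_sub <- similarity[similarity$level == "subject" &
                            similarity$pair == pair_lab, ]
    sim_v <- sim_sub$r[match(subjects, sim_sub$subject)]
    dm_focus <- dmsi_tab[dmsi_tab$module == focus & dmsi_tab$state == last, ]
    measures <- list(sfc_similarity = sim_v,
                     dmsi_sd_focus = dm_focus$sd[match(subjects,
                                                       dm_focus$subject)])
    covariates <- NULL
    if (!is.null(fd)) {
      fd1 <- fd$fd[fd$state == states[1]][match(subjects,
                                                fd$subject[fd$state == states[1]])]
      fd2 <- fd$fd[fd$state == last][match(subjects,
                                           fd$subject[fd$state == last])]
      covariates <- cbind(fd1, fd2, fd1 * fd2)
    }
    bb <- list()
    for (mn in names(measures))
      for (param in c("v", "a", "ter")) {
        beh <- ddm_tab[ddm_tab$state == last, ]
        bv <- beh[[param]][match(subjects, beh$subject)]
        ok <- !(is.na(measures[[mn]]) | is.na(bv))
        n_cov <- if (is.null(covariates)) 0L else ncol(covariates)
        if (sum(ok) >= n_cov + 4) {
          res <- brain_behavior_corr(measures[[mn]][ok], bv[ok],
                                     covariates = if (!is.null(covariates))
                                       covariates[ok, , drop = FALSE] else NULL)
          bb[[length(bb) + 1]] <- data.frame(
            measure = mn, parameter = param, state = last,
            fd_regressed = !is.null(covariates), exploratory = TRUE, res)
        }
      }
    brain_behavior <- if (length(bb)) do.call(rbind, bb) else NULL
  }

  list(anova = anova_tab, posthoc = posthoc, behavior_t = behavior_t,
       brain_behavior = brain_behavior)
}

write_results <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    if (!is.null(df))
      write.table(df, file.path(out_dir, paste0(name, ".tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }
  wt(out$similarity, "similarity")
  wt(out$topology, "topology")
  wt(out$group_partitions, "group_partitions")
  wt(out$msi, "msi")
  wt(out$dmsi, "dmsi")
  wt(out$allegiance_similarity, "allegiance_similarity")
  wt(out$ddm, "ddm")
  wt(out$stats$anova, "stats_anova")
  wt(out$stats$posthoc, "stats_posthoc")
  wt(out$stats$behavior_t, "stats_behavior_t")
  wt(out$stats$brain_behavior, "stats_brain_behavior")
  jsonlite::write_json(out$manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Sensitivity sweep over density, window, and step settings
#'
#' Re-evaluates the planted state contrast (first vs last state) on the mean
#' MSI and on the dMSI SD of the first analyzed module for every grid cell,
#' with and without regressing mean FD out of the measures. Infeasible cells
#' (window too long for the series, or step >= window) are skipped and
#' flagged.
#'
#' @param cohort a `cohort_ts`.
#' @param config base [run_config()].
#' @param densities,windows,steps numeric grids (seconds for
#'   `windows`/`steps`).
#' @param fd optional FD table; enables the FD-regression arm.
#' @return data.frame with one row per (density, window, step,
#'   fd_regression) cell: paired-t statistics, direction of the mean-MSI
#'   contrast, and a `skipped` flag.
#' @export
run_sensitivity <- function(cohort, config = run_config(),
                            densities = c(0.15, 0.20, 0.25),
                            windows = c(30, 40, 50), steps = c(10, 20, 30),
                            fd = NULL) {
  stopifnot(inherits(cohort, "cohort_ts"))
  subjects <- names(cohort$data)
  states <- cohort$state_names
  first <- states[1]; last <- states[length(states)]
  assignment <- cohort$truth$module_of_node
  analyzed <- config$analyzed_modules %||%
    setdiff(unique(assignment), c("CER", "UNC"))
  fd_arms <- if (is.null(fd)) FALSE else c(FALSE, TRUE)

  # remove the FD slope but keep the state mean, so paired contrasts
  # between states are not erased by per-state demeaning
  resid_fd <- function(v, st) {
    if (is.null(fd)) return(v)
    f <- fd$fd[fd$state == st][match(subjects, fd$subject[fd$state == st])]
    fc <- f - mean(f)
    beta <- sum(fc * (v - mean(v))) / sum(fc^2)
    v - beta * fc
  }

  rows <- list()
  for (dens in densities) for (win in windows) for (stp in steps) {
    n_t <- nrow(cohort$data[[1]][[1]])
    feasible <- stp < win &&
      floor((n_t * cohort$dt - win) / stp) + 1 >= 3
    if (!feasible) {
      message("skipping infeasible cell: density=", dens, " window=", win,
              " step=", stp)
      for (arm in fd_arms)
        rows[[length(rows) + 1]] <- data.frame(
          density = dens, window = win, step = stp, fd_regression = arm,
          n_windows = NA, msi_t = NA, msi_p = NA,
          msi_direction = NA_character_, dmsi_sd_t = NA, dmsi_sd_p = NA,
          skipped = TRUE)
      next
    }
    msi_m <- matrix(NA_real_, length(subjects), 2,
                    dimnames = list(subjects, c(first, last)))
    sd_m <- msi_m
    n_win <- NA
    for (sub in subjects) for (st in c(first, last)) {
      ts <- cohort$data[[sub]][[st]]
      if (!is.null(config$band))
        ts <- bandpass(ts, config$band[1], config$band[2], cohort$dt)
      g <- binarize(compute_sfc(ts), dens)
      prof <- msi_profile(g, assignment, analyzed_modules = analyzed)
      msi_m[sub, st] <- mean(prof$msi, na.rm = TRUE)
      wf <- sliding_windows(ts, cohort$dt, win, stp)
      n_win <- length(wf$windows)
      sd_m[sub, st] <- dmsi(wf, assignment, analyzed[1], density = dens)$sd
    }
    for (arm in fd_arms) {
      a1 <- msi_m[, first]; a2 <- msi_m[, last]
      s1 <- sd_m[, first]; s2 <- sd_m[, last]
      if (arm) {
        a1 <- resid_fd(a1, first); a2 <- resid_fd(a2, last)
        s1 <- resid_fd(s1, first); s2 <- resid_fd(s2, last)
      }
      t_msi <- paired_t(a2, a1)
      t_sd <- paired_t(s2, s1)
      rows[[length(rows) + 1]] <- data.frame(
        density = dens, window = win, step = stp, fd_regression = arm,
        n_windows = n_win, msi_t = t_msi$t, msi_p = t_msi$p,
        msi_direction = if (t_msi$mean_diff < 0) "integration" else
          "segregation",
        dmsi_sd_t = t_sd$t, dmsi_sd_p = t_sd$p, skipped = FALSE)
    }
  }
  do.call(rbind, rows)
}
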