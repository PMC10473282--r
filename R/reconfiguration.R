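#' Modular segregation index of one module
#'
#' `MSI = (E_intra - E_inter) / E_intra`, where `E_intra` counts edges with
#' both endpoints in the module and `E_inter` counts edges with exactly one
#' endpoint in the module. Values near 1 mean the module is almost
#' disconnected from the rest of the network; negative values mean it has
#' more between- than within-module edges, i.e. stronger functional
#' integration.
#'
#' @param g a `binary_graph`.
#' @param assignment named character vector, node id -> module label, or a
#'   plain vector in node order.
#' @param module module label to score.
#' @param on_empty what to do when `E_intra = 0` (MSI undefined): `"na"`
#'   returns `NA` with a message, `"error"` stops.
#' @return MSI value (or `NA`), with attributes `e_intra` and `e_inter`.
#' @export
msi <- function(g, assignment, module, on_empty = c("na", "error")) {
  on_empty <- match.arg(on_empty)
  adj <- g$adjacency
  mem <- align_assignment(assignment, rownames(adj), nrow(adj))
  if (!module %in% mem) stop("module '", module, "' not in assignment")
  inside <- mem == module
  e_intra <- sum(adj[inside, inside, drop = FALSE]) / 2
  e_inter <- sum(adj[inside, !inside, drop = FALSE])
  if (e_intra == 0) {
    if (on_empty == "error") stop("E_intra = 0 for module '", module,
                                  "': MSI undefined")
    message("E_intra = 0 for module '", module, "': MSI set to NA")
    return(structure(NA_real_, e_intra = 0, e_inter = e_inter))
  }
  structure((e_intra - e_inter) / e_intra, e_intra = e_intra,
            e_inter = e_inter)
}

align_assignment <- function(assignment, ids, n) {
  if (length(assignment) != n)
    stop("assignment length does not match node count")
  if (!is.null(names(assignment)) && !is.null(ids)) {
    if (!all(ids %in% names(assignment)))
      stop("assignment is missing node ids")
    assignment <- assignment[ids]
  }
  as.character(assignment)
}

#' MSI profile over the analyzed modules
#'
#' Computes [msi()] for every analyzed module of a graph. Modules excluded
#' from analysis (by default the cerebellar `CER` and uncertain `UNC`
#' labels) still contribute their nodes to the `E_inter` counts of analyzed
#' modules.
#'
#' @inheritParams msi
#' @param analyzed_modules character vector of module labels to score;
#'   default: all labels except `CER` and `UNC`.
#' @return data.frame with columns `module`, `msi`, `e_intra`, `e_inter`.
#' @export
msi_profile <- function(g, assignment,
                        analyzed_modules = NULL,
                        on_empty = c("na", "error")) {
  on_empty <- match.arg(on_empty)
  mem <- align_assignment(assignment, rownames(g$adjacency),
                          nrow(g$adjacency))
  labs <- unique(mem)
  analyzed <- analyzed_modules %||% setdiff(labs, c("CER", "UNC"))
  if (length(analyzed) == 0) stop("empty analyzed module set")
  if (!all(analyzed %in% labs))
    stop("analyzed modules not in assignment: ",
         paste(setdiff(analyzed, labs), collapse = ", "))
  rows <- lapply(analyzed, function(mod) {
    v <- msi(g, mem, mod, on_empty = on_empty)
    data.frame(module = mod, msi = as.numeric(v),
               e_intra = attr(v, "e_intra"), e_inter = attr(v, "e_inter"))
  })
  do.call(rbind, rows)
}

#' Dynamic MSI trajectory of a module over sliding windows
#'
#' Binarizes each window of a [sliding_windows()] result at a common density
#' (MST-backed, as for static graphs), applies [msi()] per window, and
#' summarizes the trajectory by its sample standard deviation (fluctuation
#' extent) and speed (mean absolute first difference).
#'
#' @param windows a `windowed_fc`.
#' @param assignment node -> module labels.
#' @param module module label.
#' @param density edge density for per-window binarization.
#' @param on_empty policy for windows with `E_intra = 0` (propagated as
#'   missing values, dropped from the summaries).
#' @return A `dmsi_series`: list with `values` (per-window MSI), `sd`,
#'   `speed`, `n_missing`, `start_times`.
#' @export
dmsi <- function(windows, assignment, module, density = 0.2,
                 on_empty = c("na", "error")) {
  on_empty <- match.arg(on_empty)
  stopifnot(inherits(windows, "windowed_fc"))
  if (length(windows$windows) < 3)
    message("fewer than 3 windows: dMSI speed is a single difference")
  values <- vapply(windows$windows, function(fc) {
    as.numeric(msi(binarize(fc, density), assignment, module,
                   on_empty = on_empty))
  }, numeric(1))
  dmsi_series(values, start_times = windows$start_times)
}

#' dMSI summaries for several modules at once
#'
#' Binarizes each window once and scores every module of `modules` on the
#' shared binarized windows; equivalent to calling [dmsi()] per module but
#' without redundant thresholding.
#'
#' @inheritParams dmsi
#' @param modules character vector of module labels (default: all labels
#'   except `CER`/`UNC`).
#' @return data.frame with columns `module`, `sd`, `speed`, `n_missing`.
#' @export
dmsi_profile <- function(windows, assignment, modules = NULL, density = 0.2,
                         on_empty = c("na", "error")) {
  on_empty <- match.arg(on_empty)
  stopifnot(inherits(windows, "windowed_fc"))
  mem <- align_assignment(assignment, rownames(windows$windows[[1]]),
                          nrow(windows$windows[[1]]))
  modules <- modules %||% setdiff(unique(mem), c("CER", "UNC"))
  graphs <- lapply(windows$windows, binarize, density = density)
  rows <- lapply(modules, function(mod) {
    values <- vapply(graphs, function(g)
      as.numeric(msi(g, mem, mod, on_empty = on_empty)), numeric(1))
    s <- dmsi_series(values, start_times = windows$start_times)
    data.frame(module = mod, sd = s$sd, speed = s$speed,
               n_missing = s$n_missing)
  })
  do.call(rbind, rows)
}

#' Summarize a per-window MSI series
#'
#' @param values numeric vector of per-window MSI values (may contain NA).
#' @param start_times optional window onsets (s).
#' @return A `dmsi_series` list with `values`, `sd` (sample SD), `speed`
#'   (mean |first difference|), `n_missing`.
#' @export
dmsi_series <- function(values, start_times = NULL) {
  ok <- !is.na(values)
  v <- values[ok]
  structure(list(values = values,
                 sd = if (sum(ok) >= 2) sd(v) else NA_real_,
                 speed = if (sum(ok) >= 2) mean(abs(diff(v))) else NA_real_,
                 n_missing = sum(!ok),
                 start_times = start_times),
            class = "dmsi_series")
}

#' @export
print.dmsi_series <- function(x, ...) {
  cat("dMSI series over", length(x$values), "windows: SD =",
      signif(x$sd, 4), ", speed =", signif(x$speed, 4),
      if (x$n_missing > 0) paste0(" (", x$n_missing, " missing)") else "",
      "\n")
  invisible(x)
}
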