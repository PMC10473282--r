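# Delimited-text round-tripping of cohorts and results. One TSV per
# subject-state (rows = time points, columns = nodes), a modules table, an
# optional FD table, truth.json, and a manifest JSON collecting the paths.

#' Write a cohort to a directory of TSV files
#'
#' @param cohort a `cohort_ts`.
#' @param dir output directory (created if needed).
#' @param fd optional FD covariate table (`subject`, `state`, `fd`).
#' @param behavior optional trial table (`subject`, `state`, `rt`,
#'   `correct`).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, fd = NULL, behavior = NULL) {
  stopifnot(inherits(cohort, "cohort_ts"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ts_files <- list()
  for (sub in names(cohort$data))
    for (st in cohort$state_names) {
      f <- file.path(dir, paste0("ts_", sub, "_", gsub("[^A-Za-z0-9]", "",
                                                       st), ".tsv"))
      write.table(cohort$data[[sub]][[st]], f, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      ts_files[[paste(sub, st, sep = "|")]] <- basename(f)
    }
  mod <- data.frame(node_id = cohort$node_ids,
                    module_label = unname(cohort$truth$module_of_node))
  write.table(mod, file.path(dir, "modules.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(fd))
    write.table(fd, file.path(dir, "fd.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(behavior))
    write.table(behavior, file.path(dir, "behavior.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$segments <- NULL      # nested per-subject bookkeeping stays in R
  truth$segment_cov <- NULL
  truth$module_of_node <- as.list(truth$module_of_node)  # keep node names
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(dt = cohort$dt, state_names = cohort$state_names,
                   subjects = names(cohort$data),
                   node_ids = cohort$node_ids, seed = cohort$seed,
                   ts_files = ts_files, modules = "modules.tsv",
                   fd = if (!is.null(fd)) "fd.tsv" else NULL,
                   behavior = if (!is.null(behavior)) "behavior.tsv" else NULL,
                   truth = "truth.json")
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(mf)
}

#' Read a cohort back from its manifest
#'
#' @param manifest path to a `manifest.json` written by [write_cohort()].
#' @return A `cohort_ts` (with `truth` as stored in `truth.json`), plus
#'   `fd` and `behavior` elements when present.
#' @export
read_cohort <- function(manifest) {
  dir <- dirname(manifest)
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  data <- list()
  for (sub in m$subjects) {
    data[[sub]] <- list()
    for (st in m$state_names) {
      f <- file.path(dir, m$ts_files[[paste(sub, st, sep = "|")]])
      x <- as.matrix(read.table(f, header = TRUE, sep = "\t",
                                check.names = FALSE))
      data[[sub]][[st]] <- x
    }
  }
  truth <- jsonlite::read_json(file.path(dir, m$truth),
                               simplifyVector = TRUE)
  truth$module_of_node <- unlist(truth$module_of_node)
  out <- structure(list(data = data, dt = m$dt, state_names = m$state_names,
                        node_ids = m$node_ids, truth = truth,
                        seed = m$seed),
                   class = "cohort_ts")
  if (!is.null(m$fd))
    out$fd <- read.table(file.path(dir, m$fd), header = TRUE, sep = "\t")
  if (!is.null(m$behavior))
    out$behavior <- read.table(file.path(dir, m$behavior), header = TRUE,
                               sep = "\t")
  out
}
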