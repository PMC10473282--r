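#' Zero-phase band-pass filter for node time series
#'
#' Applies a second-order Butterworth band-pass (forward-backward, so zero
#' phase) to each column after removing its mean. Edge effects are reduced by
#' reflective padding. When `high` equals the Nyquist frequency the upper
#' edge is a no-op and a high-pass design is used instead (the common case
#' for a 0.008-0.25 Hz band at a 2-s sampling interval).
#'
#' @param ts numeric matrix, rows = time points, columns = nodes.
#' @param low,high band edges in Hz; `0 <= low < high <= 1/(2 dt)`.
#' @param dt sampling interval in seconds.
#' @return Filtered matrix of the same shape, columns mean-centred.
#' @export
bandpass <- function(ts, low = 0.008, high = 0.25, dt = 1) {
  ts <- as.matrix(ts)
  nyq <- 1 / (2 * dt)
  if (low < 0 || low >= high) stop("need 0 <= low < high")
  if (high > nyq + 1e-12) stop("high edge ", high, " Hz above Nyquist ", nyq, " Hz")
  n_t <- nrow(ts)
  if (n_t < 12) stop("time series too short for the filter order")
  if (anyNA(ts)) stop("NA values in input")
  flt <- if (high >= nyq * 0.999) {
    if (low <= 0) return(scale(ts, scale = FALSE)[, , drop = FALSE])
    signal::butter(2, low / nyq, type = "high")
  } else if (low <= 0) {
    signal::butter(2, high / nyq, type = "low")
  } else {
    signal::butter(2, c(low, high) / nyq, type = "pass")
  }
  np <- min(n_t - 1, 100)
  out <- apply(ts, 2, function(x) {
    x <- x - mean(x)
    xp <- c(rev(x[2:(np + 1)]), x, rev(x[(n_t - np):(n_t - 1)]))
    y <- signal::filtfilt(flt, xp)[(np + 1):(np + n_t)]
    y - mean(y)
  })
  dimnames(out) <- dimnames(ts)
  out
}

#' Static functional connectivity matrix (Fisher z)
#'
#' Pairwise Pearson correlation between node time series, Fisher
#' z-transformed. Correlations are clipped at |r| = 1 - 1e-7 before atanh so
#' identical columns give a large finite z (about 8.4) rather than Inf.
#'
#' @param ts numeric matrix, rows = time points, columns = nodes.
#' @param state_label optional label stored on the result.
#' @return An `fc_matrix`: symmetric N x N matrix of Fisher-z weights with a
#'   zero diagonal; node ids in `dimnames`.
#' @export
compute_sfc <- function(ts, state_label = NULL) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) stop("need at least 3 time points")
  if (anyNA(ts)) stop("NA values in input")
  sds <- apply(ts, 2, sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(which(sds == 0), collapse = ", "),
         " (correlation undefined)")
  r <- cor(ts)
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- 0
  ids <- colnames(ts) %||% sprintf("n%03d", seq_len(ncol(ts)))
  dimnames(z) <- list(ids, ids)
  structure(z, class = c("fc_matrix", "matrix"), state_label = state_label)
}

#' Sliding-window dynamic functional connectivity
#'
#' Cuts the series into rectangular windows anchored at onset, advancing by
#' `step` seconds, and computes [compute_sfc()] within each. The window count
#' is `floor((T dt - length)/step) + 1`.
#'
#' @param ts numeric matrix, rows = time points, columns = nodes.
#' @param dt sampling interval (s).
#' @param length,step window length and step in seconds; both must be
#'   multiples of `dt`, with `length >= 3 dt`.
#' @param state_label optional label stored on each window.
#' @return A `windowed_fc`: list with `windows` (list of `fc_matrix`),
#'   `window_length`, `step`, `start_times` (s), `dt`.
#' @export
sliding_windows <- function(ts, dt, length = 40, step = 20,
                            state_label = NULL) {
  ts <- as.matrix(ts)
  n_t <- nrow(ts)
  if (length < 3 * dt) stop("window length must be >= 3 samples")
  tol <- 1e-9
  if (abs(length / dt - round(length / dt)) > tol)
    stop("window length must be a multiple of dt")
  if (abs(step / dt - round(step / dt)) > tol)
    stop("step must be a multiple of dt")
  n_win <- floor((n_t * dt - length) / step) + 1
  if (n_win < 2)
    stop("fewer than 2 windows possible (series ", n_t * dt,
         " s, window ", length, " s, step ", step, " s)")
  len_s <- round(length / dt)
  step_s <- round(step / dt)
  windows <- lapply(seq_len(n_win), function(i) {
    rows <- ((i - 1) * step_s + 1):((i - 1) * step_s + len_s)
    compute_sfc(ts[rows, , drop = FALSE], state_label = state_label)
  })
  structure(list(windows = windows, window_length = length, step = step,
                 start_times = (seq_len(n_win) - 1) * step, dt = dt,
                 state_label = state_label),
            class = "windowed_fc")
}

#' @export
print.windowed_fc <- function(x, ...) {
  cat("Windowed FC:", length(x$windows), "windows of", x$window_length,
      "s (step", x$step, "s),", nrow(x$windows[[1]]), "nodes\n")
  invisible(x)
}

#' Edge-weight similarity between two FC matrices
#'
#' Pearson correlation of the strictly-upper-triangle vectorizations
#' (diagonal excluded) of two FC matrices over the same node set.
#'
#' @param a,b `fc_matrix` objects (or plain symmetric matrices) of equal
#'   dimension.
#' @return Pearson correlation coefficient.
#' @export
fc_similarity <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("matrices must share the node set")
  va <- upper_vec(a); vb <- upper_vec(b)
  if (sd(va) == 0 || sd(vb) == 0) stop("zero-variance edge vector")
  cor(va, vb)
}
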