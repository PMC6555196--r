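#' Tidy simulation results
#'
#' `tidy()` returns the stored time series in long form (one row per
#' segment per time point, columns `time`, `segment`, `cell`, `section`,
#' `vm`, and, when stored, `vout` and `i_m`); `glance()` returns a one-row
#' summary of the run.
#'
#' @param x a `ephapsis_result`.
#' @param segments optional subset of segment ids.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.ephapsis_result <- function(x, segments = NULL, ...) {
  segments <- segments %||% seq_len(nrow(x$vm))
  nt <- length(x$times)
  out <- tibble::tibble(
    time = rep(x$times, each = length(segments)),
    segment = rep(segments, nt),
    cell = rep(x$segments$cell[segments], nt),
    section = rep(x$segments$section[segments], nt),
    vm = as.vector(x$vm[segments, , drop = FALSE])
  )
  if (!is.null(x$vout)) out$vout <- as.vector(x$vout[segments, , drop = FALSE])
  if (!is.null(x$i_m)) out$i_m <- as.vector(x$i_m[segments, , drop = FALSE])
  out
}

#' @rdname tidy.ephapsis_result
#' @export
glance.ephapsis_result <- function(x, ...) {
  tibble::tibble(
    n_segments = nrow(x$vm),
    n_cells = length(unique(x$segments$cell_index)),
    n_times = length(x$times),
    t_start = x$times[1], t_end = max(x$times),
    mode = x$mode, sigma = x$sigma,
    vm_min = min(x$vm), vm_max = max(x$vm),
    vout_max_abs = if (is.null(x$vout)) NA_real_ else max(abs(x$vout))
  )
}

#' Tidy phase-locking summaries
#'
#' `tidy()` returns the per-pair peak table; `glance()` the aggregate
#' mean +- SD peak cross-correlation and the peak-lag mode.
#'
#' @param x a `ephapsis_locking`.
#' @param ... unused.
#' @export
tidy.ephapsis_locking <- function(x, ...) x$pairs

#' @rdname tidy.ephapsis_locking
#' @export
glance.ephapsis_locking <- function(x, ...) {
  tibble::tibble(
    condition = format(x$condition),
    n_pairs = nrow(x$pairs),
    peak_mean = mean(x$pairs$peak_value),
    peak_sd = sd(x$pairs$peak_value),
    period_ms = x$period
  )
}
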