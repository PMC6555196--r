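#' Spike detection on membrane-potential traces
#'
#' A spike time is the linearly interpolated upward crossing of `threshold`;
#' crossings within `refractory` ms of the previous accepted spike are
#' ignored. `detect_spikes()` works on a simulation result and returns a
#' tidy spike table; `spike_times()` is the vector version for a single
#' trace; `spike_peak_times()` locates action-potential *peaks* with
#' parabolic interpolation around local maxima above `threshold`, giving
#' sub-sample timing used for spike-timing accuracy measurements.
#'
#' @param res a `ephapsis_result`.
#' @param segments segment ids to analyze (default: every segment).
#' @param times,v time grid (ms) and trace (mV).
#' @param threshold detection threshold, mV.
#' @param refractory refractory window, ms.
#' @return `detect_spikes()`: tibble with columns `segment`, `time`.
#'   `spike_times()`/`spike_peak_times()`: numeric vector of times, ms.
#' @export
detect_spikes <- function(res, segments = NULL, threshold = 0, refractory = 2) {
  segments <- segments %||% seq_len(nrow(res$vm))
  purrr::map_dfr(segments, function(s) {
    tibble::tibble(segment = s,
                   time = spike_times(res$times, res$vm[s, ],
                                      threshold, refractory))
  })
}

#' @rdname detect_spikes
#' @export
spike_times <- function(times, v, threshold = 0, refractory = 2) {
  if (is.unsorted(times, strictly = TRUE)) {
    abort_validation("time grid must be strictly increasing")
  }
  above <- v >= threshold
  k <- which(!above[-length(v)] & above[-1])  # upward crossings in (k, k+1]
  if (!length(k)) return(numeric(0))
  tc <- times[k] + (threshold - v[k]) / (v[k + 1] - v[k]) * (times[k + 1] - times[k])
  out <- tc[1]
  for (t in tc[-1]) if (t - out[length(out)] >= refractory) out <- c(out, t)
  out
}

#' @rdname detect_spikes
#' @export
spike_peak_times <- function(times, v, threshold = 0, refractory = 2) {
  cross <- spike_times(times, v, threshold, refractory)
  if (!length(cross)) return(numeric(0))
  dt <- times[2] - times[1]
  vapply(cross, function(tc) {
    # search for the local maximum within one refractory window of the crossing
    i0 <- max(findInterval(tc, times), 2)
    i1 <- min(i0 + ceiling(refractory / dt), length(v) - 1)
    seg <- v[i0:i1]
    ip <- i0 + which.max(seg) - 1
    if (ip <= 1 || ip >= length(v)) return(times[ip])
    a <- v[ip - 1]; b <- v[ip]; c <- v[ip + 1]
    denom <- a - 2 * b + c
    delta <- if (abs(denom) < 1e-300) 0 else 0.5 * (a - c) / denom
    times[ip] + delta * dt
  }, 1)
}

#' Bin spike times into counts
#'
#' Half-open bins `[t0 + k w, t0 + (k+1) w)` over the window `(t0, t1)`.
#'
#' @param spikes numeric spike times, ms.
#' @param window `c(t0, t1)`, ms.
#' @param bin_width bin width, ms (> 0).
#' @return A tibble with `bin_start` and `count`; the count vector is also
#'   attached as attribute `"counts"`.
#' @export
bin_spikes <- function(spikes, window, bin_width = 1) {
  if (bin_width <= 0) abort_validation("bin_width must be > 0")
  if (window[2] <= window[1]) abort_validation("window must have t1 > t0")
  edges <- seq(window[1], window[2], by = bin_width)
  if (tail(edges, 1) < window[2]) edges <- c(edges, tail(edges, 1) + bin_width)
  s <- spikes[spikes >= window[1] & spikes < tail(edges, 1)]
  counts <- as.integer(tabulate(findInterval(s, edges), nbins = length(edges) - 1))
  out <- tibble::tibble(bin_start = edges[-length(edges)], count = counts)
  attr(out, "counts") <- counts
  out
}

#' Spike-train cross-correlation
#'
#' For each lag `k` in `[-max_lag_bins, +max_lag_bins]`, the Pearson
#' correlation between `a[t]` and `b[t + k]` over the overlapping bins: a
#' positive peak lag means `b` fires *after* `a`. The Pearson normalization
#' makes values comparable across pairs and conditions and bounds them in
#' `[-1, 1]`. By exactness of the estimator,
#' `cross_correlation(a, b)` at lag `k` equals `cross_correlation(b, a)` at
#' `-k`.
#'
#' @param a,b equal-length integer count vectors (see [bin_spikes()]).
#' @param max_lag_bins maximum lag in bins (< length of the vectors).
#' @param bin_width bin width, ms (for labelling the lag axis).
#' @return A `ephapsis_xcorr` tibble with columns `lag_ms` and `value`.
#' @export
cross_correlation <- function(a, b, max_lag_bins, bin_width = 1) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) abort_validation("count vectors must have equal length")
  if (max_lag_bins >= length(a)) {
    abort_validation("max_lag_bins must be smaller than the vector length")
  }
  if (var(a) == 0 || var(b) == 0) {
    rlang::abort("cross-correlation undefined: a count vector has zero variance",
                 class = "ephapsis_degenerate_error")
  }
  n <- length(a)
  lags <- -max_lag_bins:max_lag_bins
  vals <- vapply(lags, function(k) {
    if (k >= 0) {
      x <- a[seq_len(n - k)]; y <- b[seq_len(n - k) + k]
    } else {
      x <- a[seq_len(n + k) - k]; y <- b[seq_len(n + k)]
    }
    if (var(x) == 0 || var(y) == 0) return(NA_real_)
    cor(x, y)
  }, 1)
  structure(tibble::tibble(lag_ms = lags * bin_width, value = vals),
            class = c("ephapsis_xcorr", class(tibble::tibble())),
            bin_width = bin_width, normalization = "pearson")
}

# largest local maximum of a cross-correlation at strictly positive lag;
# window-edge bins have no outer neighbour and cannot qualify as local maxima
xcorr_peak <- function(xc, positive_only = FALSE) {
  v <- xc$value
  lag <- xc$lag_ms
  keep <- if (positive_only) lag > 0 else rep(TRUE, length(lag))
  idx <- which(keep & !is.na(v))
  if (positive_only) {
    loc <- idx[vapply(idx, function(i) {
      i > 1 && i < length(v) && v[i] >= v[i - 1] && v[i] >= v[i + 1]
    }, TRUE)]
    if (length(loc)) idx <- loc
  }
  best <- idx[which.max(v[idx])]
  list(lag = lag[best], value = v[best])
}

#' Phase-locking summary of a multi-cell simulation set
#'
#' Reproduces the axon-bundle analysis: for every unordered cell pair in
#' every result, spikes in the analysis window (by default the last 1000 ms
#' of the run) are detected at each cell's reference segment, binned at
#' `bin_width` ms, and cross-correlated over +-1 mean oscillator period
#' (the period is estimated from the pooled inter-spike intervals). The
#' peak value and peak lag are recorded per pair, and the mean +- SD
#' cross-correlation function across pairs and results is returned;
#' because pairs are unordered, each pair's function enters the mean in
#' both lag orientations, making the mean symmetric in expectation. Cells
#' with no spikes in the window are excluded from pairing (with a message).
#'
#' @param results a list of `ephapsis_result`s (e.g. one per seeded set of
#'   initial conditions), each holding at least 2 cells.
#' @param condition label attached to the output (e.g. the conductivity).
#' @param window analysis window `c(t0, t1)`, ms; default: last 1000 ms.
#' @param bin_width bin width, ms.
#' @param threshold,refractory spike-detection parameters.
#' @param ref_segment function mapping (result, cell index) to the segment
#'   id whose trace is analyzed; defaults to each cell's middle segment.
#' @return A `ephapsis_locking` object: list with `pairs` (tibble: result,
#'   cell_i, cell_j, peak_value, peak_lag_ms), `mean_cc` (tibble: lag_ms,
#'   mean, sd, condition), `period` (ms) and `condition`.
#' @export
bundle_locking_summary <- function(results, condition = NA, window = NULL,
                                   bin_width = 1, threshold = 0,
                                   refractory = 2, ref_segment = NULL) {
  if (inherits(results, "ephapsis_result")) results <- list(results)
  ref_segment <- ref_segment %||% function(res, ci) {
    ids <- res$segments$id[res$segments$cell_index == ci]
    ids[ceiling(length(ids) / 2)]
  }
  all_trains <- list()
  for (r in seq_along(results)) {
    res <- results[[r]]
    cells <- sort(unique(res$segments$cell_index))
    if (length(cells) < 2) abort_validation("each result must hold >= 2 cells")
    win <- window %||% c(max(res$times) - 1000, max(res$times))
    for (ci in cells) {
      seg <- ref_segment(res, ci)
      st <- spike_times(res$times, res$vm[seg, ], threshold, refractory)
      all_trains[[length(all_trains) + 1L]] <- list(
        result = r, cell = ci, window = win,
        spikes = st[st >= win[1] & st < win[2]]
      )
    }
  }
  isis <- unlist(lapply(all_trains, function(tr) diff(tr$spikes)))
  if (!length(isis)) abort_validation("no spikes found in the analysis window")
  period <- mean(isis)
  max_lag <- max(1L, round(period / bin_width))

  pair_rows <- list()
  cc_stack <- list()
  for (r in seq_along(results)) {
    trains <- Filter(function(tr) tr$result == r, all_trains)
    silent <- vapply(trains, function(tr) length(tr$spikes) == 0, TRUE)
    if (any(silent)) {
      message("result ", r, ": excluding silent cell(s) ",
              paste(vapply(trains[silent], function(tr) tr$cell, 1), collapse = ", "))
      trains <- trains[!silent]
    }
    if (length(trains) < 2) next
    for (i in seq_len(length(trains) - 1)) {
      for (j in (i + 1):length(trains)) {
        ca <- attr(bin_spikes(trains[[i]]$spikes, trains[[i]]$window, bin_width),
                   "counts")
        cb <- attr(bin_spikes(trains[[j]]$spikes, trains[[j]]$window, bin_width),
                   "counts")
        xc <- tryCatch(cross_correlation(ca, cb, max_lag, bin_width),
                       ephapsis_degenerate_error = function(e) NULL)
        if (is.null(xc)) next
        pk <- xcorr_peak(xc)
        pair_rows[[length(pair_rows) + 1L]] <- tibble::tibble(
          result = r, cell_i = trains[[i]]$cell, cell_j = trains[[j]]$cell,
          peak_value = pk$value, peak_lag_ms = pk$lag
        )
        # pairs are unordered, so each enters the mean in both orientations
        cc_stack[[length(cc_stack) + 1L]] <- xc$value
        cc_stack[[length(cc_stack) + 1L]] <- rev(xc$value)
      }
    }
  }
  if (!length(pair_rows)) abort_validation("no analyzable cell pairs")
  ccm <- do.call(rbind, cc_stack)
  lags <- (-max_lag:max_lag) * bin_width
  structure(list(
    pairs = dplyr::bind_rows(pair_rows),
    mean_cc = tibble::tibble(
      lag_ms = lags,
      mean = colMeans(ccm, na.rm = TRUE),
      sd = apply(ccm, 2, sd, na.rm = TRUE),
      condition = condition
    ),
    period = period, bin_width = bin_width, condition = condition
  ), class = "ephapsis_locking")
}

#' @export
print.ephapsis_locking <- function(x, ...) {
  cat("<ephapsis_locking> ", nrow(x$pairs), " pair measurements, period ",
      signif(x$period, 4), " ms, condition: ", format(x$condition), "\n", sep = "")
  invisible(x)
}

#' Unordered cell pairs of a result
#'
#' @param res a `ephapsis_result`.
#' @return A tibble with columns `cell_i`, `cell_j`, one row per unordered
#'   pair (7 cells yield 21 pairs).
#' @export
cell_pairs <- function(res) {
  cells <- sort(unique(res$segments$cell_index))
  if (length(cells) < 2) return(tibble::tibble(cell_i = integer(0), cell_j = integer(0)))
  cmb <- utils::combn(cells, 2)
  tibble::tibble(cell_i = cmb[1, ], cell_j = cmb[2, ])
}
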