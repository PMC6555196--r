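#' Tune DC drives to target oscillation periods
#'
#' Axon-bundle experiments need each axon set into a repetitive-firing
#' regime with a slightly different baseline frequency. This helper finds,
#' for each requested period, the DC amplitude injected into an isolated
#' axon's first segment that yields that mean inter-spike interval, using a
#' coarse amplitude scan followed by secant refinement (the f-I relation is
#' monotone in this range).
#'
#' @param target_periods desired mean inter-spike intervals, ms.
#' @param axon_params fixture parameters of the axon (see
#'   [fixture_network()]).
#' @param t_sim tuning simulation length, ms (ISIs measured after the first
#'   `t_discard` ms).
#' @param t_discard initial transient discarded, ms.
#' @param tol acceptable period error, ms.
#' @param rel_tol integrator relative tolerance used during tuning.
#' @return Named numeric vector of DC amplitudes, nA.
#' @export
tune_bundle_drive <- function(target_periods,
                              axon_params = list(nseg = 21L),
                              t_sim = 300, t_discard = 100, tol = 0.05,
                              rel_tol = 1e-6) {
  measure <- local({
    cache <- new.env(parent = emptyenv())
    function(amp) {
      key <- sprintf("%.12g", amp)
      if (!is.null(cache[[key]])) return(cache[[key]])
      p <- isolated_axon_period(amp, axon_params, t_sim, t_discard, rel_tol)
      cache[[key]] <- p
      p
    }
  })
  scan_amp <- c(0.1, 0.2, 0.4, 0.8, 1.5)
  scan_per <- vapply(scan_amp, measure, 1)
  vapply(target_periods, function(tp) {
    ok <- is.finite(scan_per)
    if (!any(ok) || tp < min(scan_per[ok]) * 0.5) {
      abort_validation(paste0("cannot reach target period ", tp, " ms"))
    }
    # initial secant bracket from the scan (period decreases with amplitude)
    x1 <- scan_amp[ok][which.min(abs(scan_per[ok] - tp))]
    f1 <- measure(x1) - tp
    x2 <- x1 * if (f1 > 0) 1.25 else 0.8
    f2 <- measure(x2) - tp
    for (it in 1:12) {
      if (abs(f2) < tol) break
      if (!is.finite(f2) || f1 == f2) {
        x2 <- x2 * 1.3
        f2 <- measure(x2) - tp
        next
      }
      x3 <- x2 - f2 * (x2 - x1) / (f2 - f1)
      x3 <- max(x3, 0.02)
      x1 <- x2; f1 <- f2
      x2 <- x3; f2 <- measure(x2) - tp
    }
    x2
  }, 1, USE.NAMES = FALSE)
}

# mean ISI (ms) of an isolated axon fixture at DC amplitude `amp`
isolated_axon_period <- function(amp, axon_params, t_sim = 300,
                                 t_discard = 100, rel_tol = 1e-6) {
  net <- fixture_network("axon", axon_params)
  sys <- assemble(net, models = list(hh = hh_model()),
                  stimuli = list(dc_stimulus(1, amp)),
                  options = solver_options(mode = "open_loop",
                                           rel_tol = rel_tol, abs_tol = 1e-8,
                                           store_gating = FALSE))
  res <- solve_open_loop(sys, c(0, t_sim))
  mid <- ceiling(nrow(res$vm) / 2)
  st <- spike_times(res$times, res$vm[mid, ])
  st <- st[st >= t_discard]
  if (length(st) < 3) return(Inf)
  mean(diff(st))
}

#' Axon-bundle phase-locking experiment
#'
#' Runs the closed-loop (or ephaptic-off) hexagonal 7-axon bundle: each
#' axon receives a DC drive tuned so that its isolated mean oscillation
#' period spreads +-`spread` around `target_period`; each axon starts from
#' a random point on its own isolated limit cycle (the axon is settled in
#' isolation for `settle` ms and its state is sampled at a uniformly random
#' phase of the final period, seeded per run); the bundle is then simulated
#' for `t_total` ms.
#'
#' @param sigma extracellular conductivity, S/m.
#' @param seeds integer seeds, one simulation per seed (the same tuned
#'   drives are reused across seeds and conductivities).
#' @param ephaptic `TRUE` for closed loop, `FALSE` for the ephaptic-off
#'   (open-loop) control.
#' @param t_total simulated time, ms.
#' @param settle isolated settling time for initial conditions, ms.
#' @param target_period mean isolated oscillation period, ms.
#' @param spread relative spread of per-axon periods (+-, fractional).
#' @param bundle_params fixture parameters of the bundle (see
#'   [fixture_network()]).
#' @param amplitudes optional pre-tuned DC amplitudes (nA, length 7); when
#'   `NULL` they are tuned with [tune_bundle_drive()].
#' @param dense_output_dt stored output spacing, ms.
#' @param slim drop field/current matrices from the returned results to
#'   save memory (spike analysis only needs the potentials).
#' @param rel_tol,abs_tol integrator tolerances.
#' @return List with `results` (one `ephapsis_result` per seed),
#'   `amplitudes`, `periods`, `sigma`, `seeds`, `ephaptic`.
#' @export
run_bundle_experiment <- function(sigma, seeds, ephaptic = TRUE,
                                  t_total = 2000, settle = 500,
                                  target_period = 12.5, spread = 0.08,
                                  bundle_params = list(pitch = 5, nseg = 21L),
                                  amplitudes = NULL,
                                  dense_output_dt = 0.1, slim = TRUE,
                                  rel_tol = 1e-6, abs_tol = 1e-8) {
  n_axons <- 7L
  periods <- target_period * (1 + spread * seq(-1, 1, length.out = n_axons))
  axon_params <- bundle_params
  axon_params$pitch <- NULL
  if (is.null(amplitudes)) {
    amplitudes <- tune_bundle_drive(periods, axon_params = axon_params)
  }

  # settle each axon in isolation once; shared across seeds
  settled <- lapply(amplitudes, function(amp) {
    net1 <- fixture_network("axon", axon_params)
    sys1 <- assemble(net1, models = list(hh = hh_model()),
                     stimuli = list(dc_stimulus(1, amp)),
                     options = solver_options(mode = "open_loop",
                                              rel_tol = rel_tol,
                                              abs_tol = abs_tol,
                                              dense_output_dt = 0.025))
    res1 <- solve_open_loop(sys1, c(0, settle))
    mid <- ceiling(nrow(res1$vm) / 2)
    pk <- spike_peak_times(res1$times, res1$vm[mid, ])
    if (length(pk) < 3) {
      abort_validation("settled axon is not oscillating; cannot sample a limit cycle")
    }
    list(res = res1, t_a = pk[length(pk) - 1], t_b = pk[length(pk)])
  })

  net <- fixture_network("hex_bundle", bundle_params)
  opts <- solver_options(mode = if (ephaptic) "closed_loop" else "open_loop",
                         rel_tol = rel_tol, abs_tol = abs_tol,
                         dense_output_dt = dense_output_dt,
                         store_gating = FALSE)
  stimuli <- lapply(seq_len(n_axons), function(c_idx) {
    first_seg <- min(net$segments$id[net$segments$cell_index == c_idx])
    dc_stimulus(first_seg, amplitudes[c_idx])
  })
  sys <- assemble(net, models = list(hh = hh_model()), stimuli = stimuli,
                  med = medium(if (is.finite(sigma)) sigma else 1),
                  options = opts)

  results <- lapply(seeds, function(sd) {
    set.seed(sd)
    u <- runif(n_axons)
    y0 <- compose_bundle_state(sys, settled, u)
    opts_run <- opts
    opts_run$seed <- sd
    res <- if (ephaptic) {
      solve_closed_loop(sys, c(0, t_total), options = opts_run, y0 = y0)
    } else {
      solve_open_loop(sys, c(0, t_total), options = opts_run, y0 = y0)
    }
    if (slim) {
      res$i_m <- NULL
      res$vout <- NULL
      res$gating <- NULL
      res$y_final <- NULL
    }
    res
  })
  list(results = results, amplitudes = amplitudes, periods = periods,
       sigma = sigma, seeds = seeds, ephaptic = ephaptic)
}

# initial bundle state from per-axon settled trajectories and phases u
compose_bundle_state <- function(sys, settled, u) {
  n <- sys$n
  y0 <- numeric(sys$nstate)
  gr <- sys$groups[[1]]  # single hh group covering every segment
  ng <- length(gr$idx)
  for (c_idx in seq_along(settled)) {
    s <- settled[[c_idx]]
    t_target <- s$t_a + u[c_idx] * (s$t_b - s$t_a)
    k <- which.min(abs(s$res$times - t_target))
    seg_ids <- sys$segments$id[sys$segments$cell_index == c_idx]
    y0[seg_ids] <- s$res$vm[, k]
    for (v in seq_along(gr$model$state_names)) {
      nm <- gr$model$state_names[v]
      block <- gr$state_idx[(v - 1) * ng + seq_len(ng)]
      y0[block[match(seg_ids, gr$idx)]] <- s$res$gating[["hh"]][[nm]][, k]
    }
  }
  y0
}

#' Conductivity sweep of the bundle experiment
#'
#' Runs [run_bundle_experiment()] at each conductivity (plus the
#' ephaptic-off control when requested) and summarizes phase locking per
#' condition with [bundle_locking_summary()].
#'
#' @param sigmas conductivities, S/m.
#' @inheritParams run_bundle_experiment
#' @param include_off also run the ephaptic-off control.
#' @param window,bin_width analysis parameters (see
#'   [bundle_locking_summary()]); window defaults to the last 1000 ms.
#' @return List with `summaries` (one `ephapsis_locking` per condition),
#'   `table` (tibble: sigma, result, cell_i, cell_j, peak_value,
#'   peak_lag_ms) and `amplitudes`.
#' @export
bundle_sweep <- function(sigmas, seeds, t_total = 2000, include_off = TRUE,
                         window = NULL, bin_width = 1, ...) {
  amplitudes <- NULL
  summaries <- list()
  rows <- list()
  conditions <- c(as.character(sigmas), if (include_off) "off")
  for (cond in conditions) {
    if (cond == "off") {
      ex <- run_bundle_experiment(sigma = Inf, seeds = seeds, ephaptic = FALSE,
                                  t_total = t_total, amplitudes = amplitudes, ...)
    } else {
      ex <- run_bundle_experiment(sigma = as.numeric(cond), seeds = seeds,
                                  ephaptic = TRUE, t_total = t_total,
                                  amplitudes = amplitudes, ...)
    }
    amplitudes <- ex$amplitudes
    sm <- bundle_locking_summary(ex$results, condition = cond,
                                 window = window, bin_width = bin_width)
    summaries[[cond]] <- sm
    rows[[cond]] <- dplyr::mutate(sm$pairs, sigma = cond, .before = 1)
  }
  list(summaries = summaries, table = dplyr::bind_rows(rows),
       amplitudes = amplitudes)
}
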