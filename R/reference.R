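#' Independent fixed-step reference integration
#'
#' Integrates an open-loop system with a fixed-step backward-Euler scheme
#' and Newton iteration (implemented in compiled code, sharing no
#' time-stepping machinery with the adaptive solver). It uses the same
#' spatial discretization and is the in-repo accuracy oracle against which
#' the adaptive solution is validated: membrane-potential RMS differences
#' and matched spike-time differences between the two solvers bound the
#' numerical error of either.
#'
#' Supported systems: Hodgkin-Huxley and passive segments, DC and
#' sinusoidal intracellular stimuli, no synapses, no extracellular stimuli.
#'
#' @param sys a `ephapsis_system`.
#' @param t_span `c(t0, t1)`, ms.
#' @param dt_fixed step size, ms (e.g. `1e-3` for 1 us).
#' @param store_dt output storage interval, ms; defaults to the system's
#'   `dense_output_dt` and must be a multiple of `dt_fixed`.
#' @param y0 initial state (defaults to [initial_conditions()]).
#' @return A `ephapsis_result` (open loop).
#' @export
reference_solve <- function(sys, t_span, dt_fixed = 1e-3, store_dt = NULL,
                            y0 = NULL) {
  if (dt_fixed <= 0) abort_validation("dt_fixed must be > 0")
  if (length(sys$synapses)) {
    abort_validation("reference_solve() does not support synapses")
  }
  if (length(sys$ext_stim)) {
    abort_validation("reference_solve() does not support extracellular stimuli")
  }
  store_dt <- store_dt %||% sys$options$dense_output_dt
  store_every <- round(store_dt / dt_fixed)
  if (abs(store_every * dt_fixed - store_dt) > 1e-12) {
    abort_validation("store_dt must be an integer multiple of dt_fixed")
  }

  n <- sys$n
  code <- integer(n)
  par <- matrix(0, n, 6)
  gs <- .u("gdens_to_uS")
  for (g in seq_along(sys$groups)) {
    gr <- sys$groups[[g]]
    p <- gr$model$params
    if (gr$model$name == "hh") {
      code[gr$idx] <- 1L
      par[gr$idx, 1] <- p$gna * sys$area[gr$idx] * gs
      par[gr$idx, 2] <- p$gk * sys$area[gr$idx] * gs
      par[gr$idx, 3] <- p$gl * sys$area[gr$idx] * gs
      par[gr$idx, 4] <- p$ena
      par[gr$idx, 5] <- p$ek
      par[gr$idx, 6] <- p$el
    } else if (gr$model$name == "passive") {
      code[gr$idx] <- 0L
      par[gr$idx, 3] <- p$g_leak * sys$area[gr$idx] * gs
      par[gr$idx, 6] <- p$e_leak
    } else {
      abort_validation(paste0("reference_solve() supports only the shipped ",
                              "hh/passive models (got '", gr$model$name, "')"))
    }
  }
  stim <- matrix(0, n, 4)
  for (st in sys$int_stim) {
    if (st$waveform == "dc") {
      stim[st$target, 1] <- stim[st$target, 1] + st$amplitude
    } else if (st$waveform == "sinusoid") {
      if (stim[st$target, 2] != 0) {
        abort_validation("at most one sinusoidal stimulus per segment")
      }
      stim[st$target, 2] <- st$amplitude
      stim[st$target, 3] <- st$frequency
      stim[st$target, 4] <- st$phase
    } else {
      abort_validation("reference_solve() supports only dc/sinusoid stimuli")
    }
  }

  # map the R state layout [vm | group blocks] to [V | m | h | n over HH segs]
  y0 <- y0 %||% initial_conditions(sys)
  hh_segs <- which(code == 1L)
  nh <- length(hh_segs)
  map <- seq_len(n)  # vm block maps one-to-one
  if (nh > 0) {
    map <- c(map, rep(NA_integer_, 3 * nh))
    for (g in seq_along(sys$groups)) {
      gr <- sys$groups[[g]]
      if (gr$model$name != "hh") next
      ng <- length(gr$idx)
      for (k in 1:3) {
        rpos <- gr$state_idx[(k - 1) * ng + seq_len(ng)]
        cpos <- n + (k - 1) * nh + match(gr$idx, hh_segs)
        map[cpos] <- rpos
      }
    }
  }
  y0_c <- y0[map]

  out <- be_reference_solve(sys$a_mat, sys$cvec, code, par, stim, y0_c,
                            t_span[1], t_span[2], dt_fixed,
                            as.integer(store_every))
  # back-map to the R layout and reuse the standard result assembly
  yR <- matrix(0, nrow(out$y), sys$nstate)
  yR[, map] <- out$y
  sys$rhs_mode <- "open_loop"
  res <- build_result(sys, as.vector(out$times), yR, sys$options)
  res$solver <- "backward_euler_reference"
  res$dt_fixed <- dt_fixed
  res
}
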