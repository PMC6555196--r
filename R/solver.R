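#' Solver options
#'
#' @param rel_tol,abs_tol integrator tolerances (abs_tol in mV for membrane
#'   potentials). Defaults are tight because spike-timing comparisons at the
#'   tens-of-microseconds level require them.
#' @param max_step maximum internal step, ms (`NULL` for unrestricted).
#' @param mode `"closed_loop"` (extracellular potentials feed back into the
#'   membrane dynamics) or `"open_loop"` (fields computed post hoc only).
#' @param formulation `"eliminated_ode"` solves the algebraic constraint
#'   exactly inside every derivative evaluation; `"mass_matrix_dae"` keeps
#'   the extracellular potentials as algebraic variables of a singular
#'   mass-matrix DAE. The two agree to integrator tolerance.
#' @param seed integer seed recorded with results and used by randomized
#'   initial conditions.
#' @param dense_output_dt spacing of the stored output grid, ms.
#' @param store_gating keep gating time series in the result.
#' @param maxsteps maximum internal integrator steps per output interval.
#' @return A `ephapsis_options` list.
#' @export
solver_options <- function(rel_tol = 1e-6, abs_tol = 1e-8, max_step = NULL,
                           mode = c("closed_loop", "open_loop"),
                           formulation = c("eliminated_ode", "mass_matrix_dae"),
                           seed = NULL, dense_output_dt = 0.025,
                           store_gating = TRUE, maxsteps = 100000) {
  if (rel_tol <= 0 || abs_tol <= 0) abort_validation("tolerances must be > 0")
  if (dense_output_dt <= 0) abort_validation("dense_output_dt must be > 0")
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol, max_step = max_step,
                 mode = match.arg(mode), formulation = match.arg(formulation),
                 seed = seed, dense_output_dt = dense_output_dt,
                 store_gating = store_gating, maxsteps = maxsteps),
            class = "ephapsis_options")
}

#' Assemble a coupled system
#'
#' Binds membrane models to segments, builds the axial conductance matrix
#' from the discretized geometry, attaches stimuli and synapses, and (for
#' closed-loop systems) builds the transfer matrix and pre-factors the
#' linear self-consistency operator. With `T` the transfer matrix and `A`
#' the axial conductance matrix, the extracellular potentials satisfy
#' `(I - T A) V_out = T (A V_m + I_inj - I_gap) + V_ext` at every instant;
#' the assembled system stores `(I - T A)^{-1}` so each derivative
#' evaluation solves the constraint exactly.
#'
#' @param net a discretized `ephapsis_network`.
#' @param models named list of `ephapsis_model`s; names are matched against
#'   the sections' model tags.
#' @param stimuli list of `ephapsis_stimulus`.
#' @param synapses list of `ephapsis_synapse`.
#' @param med a `ephapsis_medium` (or conductivity, S/m).
#' @param options a [solver_options()].
#' @param sampling boundary-averaging rule, see [field_sampling()].
#' @return A `ephapsis_system`.
#' @export
assemble <- function(net, models = list(hh = hh_model()), stimuli = list(),
                     synapses = list(), med = medium(0.3),
                     options = solver_options(),
                     sampling = field_sampling()) {
  if (is.null(net$segments)) net <- discretize(net)
  segs <- net$segments
  n <- nrow(segs)
  sigma <- as_sigma(med)
  if (sigma <= 0) abort_validation("sigma must be > 0")

  missing_tag <- !(segs$model_tag %in% names(models))
  if (any(missing_tag)) {
    k <- which(missing_tag)[1]
    rlang::abort(paste0("segment ", segs$id[k], " (section '", segs$section[k],
                        "') is bound to unknown model '", segs$model_tag[k], "'"),
                 class = "ephapsis_validation_error")
  }

  a_mat <- axial_conductance_matrix(net)           # uS
  cvec <- segs$cm * segs$area * .u("cap_to_nF")    # nF
  area <- segs$area

  # model groups and state layout: [vm | group gating blocks | synapse blocks]
  tags <- unique(segs$model_tag)
  groups <- lapply(tags, function(tg) {
    idx <- which(segs$model_tag == tg)
    model <- models[[tg]]
    k <- length(model$state_names)
    list(tag = tg, idx = idx, model = model, k = k)
  })
  names(groups) <- tags
  pos <- n
  for (g in seq_along(groups)) {
    k <- groups[[g]]$k
    ng <- length(groups[[g]]$idx)
    groups[[g]]$state_idx <- if (k > 0) pos + seq_len(ng * k) else integer(0)
    pos <- pos + ng * k
  }
  kernel_syn <- which(vapply(synapses, function(s)
    s$kind %in% c("chemical", "external_spikes"), TRUE))
  syn_idx <- if (length(kernel_syn)) pos + seq_len(2 * length(kernel_syn)) else integer(0)
  nstate <- pos + 2 * length(kernel_syn)

  for (st in stimuli) {
    if (st$side == "intracellular" && (st$target < 1 || st$target > n)) {
      abort_validation(paste0("stimulus target ", st$target, " out of range"))
    }
  }
  for (sy in synapses) {
    tg <- c(if (!is.null(sy$pre) && sy$kind != "external_spikes") sy$pre, sy$post)
    if (any(tg < 1 | tg > n)) abort_validation("synapse endpoint out of range")
  }

  # boundary-averaged imposed potentials per unit waveform value
  ext_stim <- Filter(function(s) s$side == "extracellular", stimuli)
  int_stim <- Filter(function(s) s$side == "intracellular", stimuli)
  # boundary-averaged spatial pattern per unit waveform value: the imposed
  # potential at time t is pattern * stimulus_current(spec, t)
  ext_patterns <- lapply(ext_stim, function(st) {
    vapply(seq_len(n), function(i) {
      pts <- segment_samples(as.list(segs[i, ]), sampling)
      if (st$kind == "point") {
        R <- sqrt(rowSums(sweep(pts, 2, st$position)^2))
        if (any(R < 1e-9)) {
          abort_singularity("extracellular electrode coincides with a segment boundary sample")
        }
        mean(1 / (4 * pi * sigma * R))
      } else {
        mean(-as.vector(pts %*% st$field))
      }
    }, 1)
  })

  sys <- list(
    network = net, segments = segs, n = n, models = models, groups = groups,
    stimuli = stimuli, int_stim = int_stim, ext_stim = ext_stim,
    ext_patterns = ext_patterns, synapses = synapses,
    kernel_syn = kernel_syn, syn_idx = syn_idx,
    medium = medium(sigma), sampling = sampling,
    a_mat = a_mat, cvec = cvec, area = area,
    nstate = nstate, options = options,
    transfer = NULL, minv = NULL, pmat = NULL
  )
  class(sys) <- "ephapsis_system"
  if (options$mode == "closed_loop") sys <- attach_transfer(sys)
  sys
}

attach_transfer <- function(sys) {
  tm <- build_transfer_matrix(sys$network, sys$medium, sys$sampling)
  m <- diag(sys$n) - tm %*% sys$a_mat
  rc <- rcond(m)
  if (!is.finite(rc) || rc < 1e-12) {
    rlang::abort(paste0(
      "self-consistency operator (I - T A) is numerically singular ",
      "(rcond = ", format(rc), ") at sigma = ", sys$medium$sigma,
      " S/m; geometry scale ~", signif(max(abs(sys$segments$length)), 3), " um"),
      class = "ephapsis_conditioning_error")
  }
  minv <- solve(m)
  sys$transfer <- tm
  sys$minv <- minv
  sys$pmat <- minv %*% tm
  sys
}

#' @export
print.ephapsis_system <- function(x, ...) {
  cat("<ephapsis_system> ", x$n, " segments, ", x$nstate, " states, sigma = ",
      x$medium$sigma, " S/m, mode = ", x$options$mode, "\n", sep = "")
  invisible(x)
}

## ---- state layout helpers --------------------------------------------------

group_states <- function(sys, g, y) {
  gr <- sys$groups[[g]]
  if (gr$k == 0) return(matrix(0, length(gr$idx), 0))
  matrix(y[gr$state_idx], length(gr$idx), gr$k)
}

#' Initial conditions at rest
#'
#' Membrane potentials at each model's resting potential, gating variables
#' at their steady state for that potential, synaptic kernel states at zero.
#'
#' @param sys a `ephapsis_system`.
#' @param vm optional explicit membrane potentials (length `n`).
#' @return Numeric state vector.
#' @export
initial_conditions <- function(sys, vm = NULL) {
  y <- numeric(sys$nstate)
  vm0 <- numeric(sys$n)
  for (g in seq_along(sys$groups)) {
    gr <- sys$groups[[g]]
    rest <- model_rest(gr$model)
    vm0[gr$idx] <- rest
  }
  if (!is.null(vm)) vm0 <- vm
  y[seq_len(sys$n)] <- vm0
  for (g in seq_along(sys$groups)) {
    gr <- sys$groups[[g]]
    if (gr$k > 0) {
      y[gr$state_idx] <- as.vector(gr$model$initial_state(vm0[gr$idx]))
    }
  }
  y
}

## ---- instantaneous current bookkeeping ------------------------------------

# injected intracellular current vector (nA) at time t
injected_current <- function(sys, t, vm = NULL) {
  inj <- numeric(sys$n)
  for (st in sys$int_stim) {
    inj[st$target] <- inj[st$target] +
      stimulus_current(st, t, state = list(vm = vm, t = t))
  }
  inj
}

# imposed extracellular potential per segment (mV) at time t
imposed_vext <- function(sys, t) {
  v <- numeric(sys$n)
  for (k in seq_along(sys$ext_stim)) {
    v <- v + sys$ext_patterns[[k]] * stimulus_current(sys$ext_stim[[k]], t)
  }
  v
}

# gap currents leaving each segment (nA) and chemical currents (nA)
synapse_currents <- function(sys, t, vm, y) {
  gap <- numeric(sys$n)
  chem <- numeric(sys$n)
  dsyn <- numeric(2 * length(sys$kernel_syn))
  for (s in seq_along(sys$synapses)) {
    sy <- sys$synapses[[s]]
    if (sy$kind == "gap") {
      i <- sy$g_max * .u("nS_to_uS") * (vm[sy$post] - vm[sy$pre])
      gap[sy$post] <- gap[sy$post] + i
      gap[sy$pre] <- gap[sy$pre] - i
    }
  }
  for (ksi in seq_along(sys$kernel_syn)) {
    sy <- sys$synapses[[sys$kernel_syn[ksi]]]
    st <- y[sys$syn_idx[c(2 * ksi - 1, 2 * ksi)]]
    out <- synaptic_current(sy, t, v_post = vm[sy$post], syn_state = st)
    chem[sy$post] <- chem[sy$post] + out$i_syn
    dsyn[c(2 * ksi - 1, 2 * ksi)] <- out$dstate
  }
  list(gap = gap, chem = chem, dsyn = dsyn)
}

# ionic current (nA) and gating derivatives for the whole network
ionic_currents <- function(sys, t, vm, y) {
  i_ion <- numeric(sys$n)
  dg <- vector("list", length(sys$groups))
  for (g in seq_along(sys$groups)) {
    gr <- sys$groups[[g]]
    st <- group_states(sys, g, y)
    ev <- gr$model$evaluate(t, vm[gr$idx], st, gr$model$params)
    i_ion[gr$idx] <- ev$i_ion * sys$area[gr$idx] * .u("iion_to_nA")
    dg[[g]] <- ev$dstate
  }
  list(i_ion = i_ion, dg = dg)
}

## ---- right-hand sides ------------------------------------------------------

# eliminated-ODE right-hand side; mode taken from sys$rhs_mode
system_rhs <- function(t, y, sys) {
  fp <- sys$fastpack
  if (!is.null(fp)) {
    dy_c <- rhs_fast(t, y[fp$map], sys$a_mat, fp$q, sys$cvec, fp$code,
                     fp$par, fp$stim)
    dy <- numeric(length(dy_c))
    dy[fp$map] <- dy_c
    return(list(dy))
  }
  n <- sys$n
  vm <- y[seq_len(n)]
  ion <- ionic_currents(sys, t, vm, y)
  syn <- synapse_currents(sys, t, vm, y)
  inj <- injected_current(sys, t, vm)
  s0 <- as.vector(sys$a_mat %*% vm) + inj - syn$gap
  vext <- imposed_vext(sys, t)
  if (sys$rhs_mode == "closed_loop") {
    vout <- as.vector(sys$pmat %*% s0)
    if (length(sys$ext_stim)) vout <- vout + as.vector(sys$minv %*% vext)
  } else {
    vout <- vext
  }
  i_eph <- as.vector(sys$a_mat %*% vout)
  dvm <- (s0 + i_eph - ion$i_ion - syn$chem) / sys$cvec
  dy <- numeric(sys$nstate)
  dy[seq_len(n)] <- dvm
  for (g in seq_along(sys$groups)) {
    gr <- sys$groups[[g]]
    if (gr$k > 0) dy[gr$state_idx] <- as.vector(ion$dg[[g]])
  }
  if (length(sys$syn_idx)) dy[sys$syn_idx] <- syn$dsyn
  list(dy)
}

# compiled fast path: shipped hh/passive models, dc/sinusoid intracellular
# stimuli, no synapses, no imposed extracellular fields
build_fastpack <- function(sys) {
  ok <- all(vapply(sys$groups, function(g)
    g$model$name %in% c("hh", "passive"), TRUE)) &&
    length(sys$synapses) == 0 && length(sys$ext_stim) == 0 &&
    all(vapply(sys$int_stim, function(s)
      s$waveform %in% c("dc", "sinusoid"), TRUE))
  if (!ok) return(NULL)
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
    } else {
      par[gr$idx, 3] <- p$g_leak * sys$area[gr$idx] * gs
      par[gr$idx, 6] <- p$e_leak
    }
  }
  stim <- matrix(0, n, 4)
  for (st in sys$int_stim) {
    if (st$waveform == "dc") {
      stim[st$target, 1] <- stim[st$target, 1] + st$amplitude
    } else {
      if (stim[st$target, 2] != 0) return(NULL)
      stim[st$target, 2] <- st$amplitude
      stim[st$target, 3] <- st$frequency
      stim[st$target, 4] <- st$phase
    }
  }
  hh_segs <- which(code == 1L)
  nh <- length(hh_segs)
  map <- seq_len(n)
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
  q <- if (sys$rhs_mode == "closed_loop") {
    diag(n) + sys$a_mat %*% sys$pmat
  } else {
    diag(n)
  }
  list(map = map, code = code, par = par, stim = stim, q = q)
}

# sparsity pattern of the eliminated-ODE Jacobian, as (row, col) indices
# ordered by column: the Vm block (dense in closed loop, the axial pattern
# in open loop), the Vm/gating cross terms, and the synapse-state couplings
system_sparsity <- function(sys) {
  n <- sys$n
  if (sys$rhs_mode == "closed_loop") {
    vmblock <- cbind(rep(seq_len(n), n), rep(seq_len(n), each = n))
  } else {
    nz <- which(sys$a_mat != 0, arr.ind = TRUE)
    vmblock <- rbind(nz, cbind(seq_len(n), seq_len(n)))
    # gap junctions and state-dependent stimuli add cross-cell vm terms
    for (sy in sys$synapses) {
      if (sy$kind == "gap") {
        vmblock <- rbind(vmblock,
                         cbind(c(sy$pre, sy$post), c(sy$post, sy$pre)))
      }
    }
  }
  idx <- vmblock
  for (g in seq_along(sys$groups)) {
    gr <- sys$groups[[g]]
    if (gr$k == 0) next
    ng <- length(gr$idx)
    for (k in seq_len(gr$k)) {
      cols <- gr$state_idx[(k - 1) * ng + seq_len(ng)]
      idx <- rbind(idx, cbind(gr$idx, cols), cbind(cols, gr$idx),
                   cbind(cols, cols))
    }
  }
  for (ksi in seq_along(sys$kernel_syn)) {
    sy <- sys$synapses[[sys$kernel_syn[ksi]]]
    scols <- sys$syn_idx[c(2 * ksi - 1, 2 * ksi)]
    idx <- rbind(idx, cbind(sy$post, scols), cbind(scols, scols))
  }
  idx <- unique(idx)
  idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
}

# mass-matrix DAE right-hand side: y = [vm, gating, syn, vout]
system_rhs_dae <- function(t, y, sys) {
  n <- sys$n
  yd <- y[seq_len(sys$nstate)]
  vout <- y[sys$nstate + seq_len(n)]
  vm <- yd[seq_len(n)]
  ion <- ionic_currents(sys, t, vm, yd)
  syn <- synapse_currents(sys, t, vm, yd)
  inj <- injected_current(sys, t, vm)
  s0 <- as.vector(sys$a_mat %*% vm) + inj - syn$gap
  i_eph <- as.vector(sys$a_mat %*% vout)
  i_m <- s0 + i_eph
  dvm <- (i_m - ion$i_ion - syn$chem) / sys$cvec
  resid <- as.vector(sys$transfer %*% i_m) + imposed_vext(sys, t) - vout
  dy <- numeric(sys$nstate + n)
  dy[seq_len(n)] <- dvm
  for (g in seq_along(sys$groups)) {
    gr <- sys$groups[[g]]
    if (gr$k > 0) dy[gr$state_idx] <- as.vector(ion$dg[[g]])
  }
  if (length(sys$syn_idx)) dy[sys$syn_idx] <- syn$dsyn
  dy[sys$nstate + seq_len(n)] <- resid
  list(dy)
}

## ---- integration drivers ---------------------------------------------------

#' Solve the coupled system
#'
#' `solve_closed_loop()` integrates the membrane dynamics with the
#' extracellular potentials fed back self-consistently at every step (the
#' ephaptic current). `solve_open_loop()` integrates the same network with
#' the feedback removed; fields can then be computed post hoc from the
#' recorded membrane currents. With the default `eliminated_ode`
#' formulation the algebraic constraint is linear and is solved exactly
#' inside every derivative evaluation, giving an equivalent stiff ODE; the
#' `mass_matrix_dae` formulation keeps the potentials as algebraic
#' variables of a singular-mass-matrix DAE (solved with RADAU) and is kept
#' as a cross-check.
#'
#' @param sys a `ephapsis_system`.
#' @param t_span `c(t0, t1)`, ms.
#' @param options a [solver_options()]; defaults to the system's.
#' @param y0 initial state (defaults to [initial_conditions()]).
#' @param vout_post_hoc for open-loop solves: also compute the (decoupled)
#'   extracellular potentials from the recorded membrane currents.
#' @return A `ephapsis_result` with the stored time grid, `vm`, `vout` and
#'   membrane-current matrices (`n_segments x n_times`), gating time series
#'   and metadata.
#' @export
solve_closed_loop <- function(sys, t_span, options = NULL, y0 = NULL) {
  options <- options %||% sys$options
  if (is.null(sys$transfer)) sys <- attach_transfer(sys)
  sys$rhs_mode <- "closed_loop"
  integrate_system(sys, t_span, options, y0)
}

#' @rdname solve_closed_loop
#' @export
solve_open_loop <- function(sys, t_span, options = NULL, y0 = NULL,
                            vout_post_hoc = FALSE) {
  options <- options %||% sys$options
  sys$rhs_mode <- "open_loop"
  res <- integrate_system(sys, t_span, options, y0)
  if (vout_post_hoc) {
    if (is.null(sys$transfer)) sys <- attach_transfer(sys)
    res$vout <- sys$transfer %*% res$i_m + res$vout
  }
  res
}

integrate_system <- function(sys, t_span, options, y0 = NULL) {
  stopifnot(length(t_span) == 2, t_span[2] > t_span[1])
  if (!is.null(options$seed)) set.seed(options$seed)
  y0 <- y0 %||% initial_conditions(sys)
  times <- seq(t_span[1], t_span[2], by = options$dense_output_dt)
  if (tail(times, 1) < t_span[2]) times <- c(times, t_span[2])

  use_dae <- options$formulation == "mass_matrix_dae" &&
    sys$rhs_mode == "closed_loop"
  has_ext_events <- any(vapply(sys$synapses, function(s)
    s$kind == "external_spikes", TRUE))
  has_chem <- any(vapply(sys$synapses, function(s) s$kind == "chemical", TRUE))

  hmax <- options$max_step %||% (t_span[2] - t_span[1])
  if (use_dae) {
    if (has_ext_events || has_chem) {
      abort_validation("mass_matrix_dae formulation does not support event-driven synapses")
    }
    out <- solve_dae_radau(sys, times, y0, options, hmax)
  } else {
    out <- solve_ode_adaptive(sys, times, y0, options, hmax,
                              has_ext_events, has_chem)
  }
  build_result(sys, out$times, out$y, options)
}

solve_ode_adaptive <- function(sys, times, y0, options, hmax,
                               has_ext_events, has_chem) {
  sys$fastpack <- build_fastpack(sys)
  rhs <- function(t, y, p) system_rhs(t, y, sys)
  events <- NULL
  rootfun <- NULL
  if (has_ext_events || has_chem) {
    ev <- make_synapse_events(sys)
    events <- ev$events
    rootfun <- ev$rootfun
  }
  inz <- system_sparsity(sys)
  if (nrow(inz) < 2) {  # trivial single-entry Jacobian: sparse setup degenerates
    out <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                          rtol = options$rel_tol, atol = options$abs_tol,
                          hmax = hmax, maxsteps = options$maxsteps,
                          rootfunc = rootfun, events = events)
  } else {
    lrw <- 30 * sys$nstate + 8 * nrow(inz) + 20000
    out <- deSolve::lsodes(y0, times, rhs, parms = NULL,
                           rtol = options$rel_tol, atol = options$abs_tol,
                           hmax = hmax, maxsteps = options$maxsteps,
                           sparsetype = "sparseusr", inz = inz, lrw = lrw,
                           rootfunc = rootfun, events = events)
  }
  check_integration(out, times)
  list(times = out[, 1], y = out[, -1, drop = FALSE])
}

solve_dae_radau <- function(sys, times, y0, options, hmax) {
  n <- sys$n
  # consistent initial algebraic variables from the elimination
  vm0 <- y0[seq_len(n)]
  inj0 <- injected_current(sys, times[1], vm0)
  syn0 <- synapse_currents(sys, times[1], vm0, y0)
  s0 <- as.vector(sys$a_mat %*% vm0) + inj0 - syn0$gap
  vout0 <- as.vector(sys$pmat %*% s0) +
    as.vector(sys$minv %*% imposed_vext(sys, times[1]))
  yfull <- c(y0, vout0)
  mass <- diag(c(rep(1, sys$nstate), rep(0, n)))
  rhs <- function(t, y, p) system_rhs_dae(t, y, sys)
  out <- deSolve::radau(yfull, times, rhs, parms = NULL, mass = mass,
                        rtol = options$rel_tol, atol = options$abs_tol,
                        hmax = hmax, maxsteps = options$maxsteps)
  check_integration(out, times)
  list(times = out[, 1], y = out[, 1 + seq_len(sys$nstate), drop = FALSE])
}

check_integration <- function(out, times) {
  if (nrow(out) < length(times)) {
    rlang::abort(paste0("integrator stopped early at t = ",
                        signif(out[nrow(out), 1], 6), " ms"),
                 class = "ephapsis_integration_error")
  }
}

make_synapse_events <- function(sys) {
  # external preset spikes: state increments at known times;
  # endogenous chemical spikes: located by root finding on v_pre - threshold
  ext_times <- list()
  for (ksi in seq_along(sys$kernel_syn)) {
    sy <- sys$synapses[[sys$kernel_syn[ksi]]]
    if (sy$kind == "external_spikes") {
      ext_times[[length(ext_times) + 1L]] <-
        cbind(ksi = ksi, t = sy$spike_times)
    }
  }
  chem_ids <- which(vapply(sys$kernel_syn, function(s)
    sys$synapses[[s]]$kind == "chemical", TRUE))
  last_fire <- new.env(parent = emptyenv())
  for (k in chem_ids) assign(as.character(k), -Inf, envir = last_fire)

  event_fn <- function(t, y, p) {
    for (blk in ext_times) {
      hit <- abs(blk[, "t"] - t) < 1e-9
      for (ksi in blk[hit, "ksi"]) {
        y[sys$syn_idx[c(2 * ksi - 1, 2 * ksi)]] <-
          y[sys$syn_idx[c(2 * ksi - 1, 2 * ksi)]] + 1
      }
    }
    if (length(chem_ids)) {
      dy <- system_rhs(t, y, sys)[[1]]
      for (k in chem_ids) {
        sy <- sys$synapses[[sys$kernel_syn[k]]]
        vpre <- y[sy$pre]
        rising <- dy[sy$pre] > 0
        lf <- get(as.character(k), envir = last_fire)
        if (abs(vpre - sy$threshold) < 1e-3 && rising &&
            (t - lf) >= sy$refractory) {
          assign(as.character(k), t, envir = last_fire)
          y[sys$syn_idx[c(2 * k - 1, 2 * k)]] <-
            y[sys$syn_idx[c(2 * k - 1, 2 * k)]] + 1
        }
      }
    }
    y
  }
  rootfun <- NULL
  if (length(chem_ids)) {
    rootfun <- function(t, y, p) {
      vapply(chem_ids, function(k) {
        sy <- sys$synapses[[sys$kernel_syn[k]]]
        y[sy$pre] - sy$threshold
      }, 1)
    }
  }
  ev_times <- if (length(ext_times)) {
    sort(unique(unlist(lapply(ext_times, function(b) b[, "t"]))))
  } else NULL
  events <- if (!is.null(ev_times) && is.null(rootfun)) {
    list(func = event_fn, time = ev_times)
  } else if (!is.null(rootfun)) {
    list(func = event_fn, time = ev_times, root = TRUE)
  } else NULL
  list(events = events, rootfun = rootfun)
}

## ---- result assembly -------------------------------------------------------

build_result <- function(sys, times, y, options) {
  n <- sys$n
  nt <- length(times)
  dimnames(y) <- NULL
  vm <- t(y[, seq_len(n), drop = FALSE])  # n x T

  inj <- matrix(0, n, nt)
  gap <- matrix(0, n, nt)
  vext <- matrix(0, n, nt)
  needs_loop <- length(sys$int_stim) > 0 || length(sys$ext_stim) > 0 ||
    length(sys$synapses) > 0
  if (needs_loop) {
    for (k in seq_len(nt)) {
      inj[, k] <- injected_current(sys, times[k], vm[, k])
      if (length(sys$ext_stim)) vext[, k] <- imposed_vext(sys, times[k])
      if (length(sys$synapses)) {
        gap[, k] <- synapse_currents(sys, times[k], vm[, k], y[k, ])$gap
      }
    }
  }
  s0 <- sys$a_mat %*% vm + inj - gap
  if (sys$rhs_mode == "closed_loop") {
    vout <- sys$pmat %*% s0
    if (length(sys$ext_stim)) vout <- vout + sys$minv %*% vext
  } else {
    vout <- vext
  }
  i_m <- s0 + sys$a_mat %*% vout

  gating <- NULL
  if (isTRUE(options$store_gating)) {
    gating <- list()
    for (g in seq_along(sys$groups)) {
      gr <- sys$groups[[g]]
      if (gr$k > 0) {
        gating[[gr$tag]] <- lapply(stats::setNames(seq_len(gr$k),
                                                   gr$model$state_names),
          function(k) {
            ng <- length(gr$idx)
            t(y[, gr$state_idx[(k - 1) * ng + seq_len(ng)], drop = FALSE])
          })
      }
    }
  }
  structure(list(
    times = times, vm = vm, vout = as.matrix(vout), i_m = as.matrix(i_m),
    gating = gating, segments = sys$segments, mode = sys$rhs_mode,
    sigma = sys$medium$sigma, options = options, seed = options$seed,
    geometry_hash = geometry_hash(sys$network),
    y_final = y[nt, seq_len(sys$nstate)]
  ), class = "ephapsis_result")
}

#' @export
print.ephapsis_result <- function(x, ...) {
  cat("<ephapsis_result> ", nrow(x$vm), " segments x ", length(x$times),
      " times (", x$mode, ", sigma = ", x$sigma, " S/m)\n", sep = "")
  invisible(x)
}

geometry_hash <- function(net) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(net$segments, f)
  unname(tools::md5sum(f))
}

#' Membrane and ephaptic currents of an assembled system
#'
#' `membrane_currents()` returns the per-segment transmembrane source
#' currents (nA) at a given state, computed either from the axial side
#' (`A V_in + I_inj - I_gap`, Kirchhoff bookkeeping) or from the membrane
#' side (`C dV_m/dt + I_ion + I_syn`); the two agree to solver tolerance.
#' `ephaptic_currents()` returns the extra axial drive produced by
#' gradients of the extracellular potential,
#' `i_eph,i = sum_j (V_out,j - V_out,i) / R_ij`.
#'
#' @param sys a `ephapsis_system`.
#' @param t time, ms.
#' @param y full state vector.
#' @param side bookkeeping side.
#' @param vout per-segment extracellular potentials, mV.
#' @return Per-segment currents, nA.
#' @export
membrane_currents <- function(sys, t, y, side = c("axial", "membrane")) {
  side <- match.arg(side)
  if (is.null(sys$rhs_mode)) sys$rhs_mode <- sys$options$mode
  n <- sys$n
  vm <- y[seq_len(n)]
  syn <- synapse_currents(sys, t, vm, y)
  inj <- injected_current(sys, t, vm)
  s0 <- as.vector(sys$a_mat %*% vm) + inj - syn$gap
  vext <- imposed_vext(sys, t)
  vout <- if (sys$rhs_mode == "closed_loop") {
    as.vector(sys$pmat %*% s0) +
      (if (length(sys$ext_stim)) as.vector(sys$minv %*% vext) else 0)
  } else {
    vext
  }
  if (side == "axial") {
    s0 + as.vector(sys$a_mat %*% vout)
  } else {
    ion <- ionic_currents(sys, t, vm, y)
    dvm <- system_rhs(t, y, sys)[[1]][seq_len(n)]
    sys$cvec * dvm + ion$i_ion + syn$chem
  }
}

#' @rdname membrane_currents
#' @export
ephaptic_currents <- function(sys, vout) {
  if (length(vout) != sys$n) abort_validation("vout must have one entry per segment")
  as.vector(sys$a_mat %*% vout)
}

#' Self-consistency residual of a closed-loop result
#'
#' Maximum over stored times of `max_i |V_out - T I_m|_i`, which a
#' closed-loop solution must keep within a small multiple of the absolute
#' tolerance.
#'
#' @param sys the `ephapsis_system` that produced the result.
#' @param res a closed-loop `ephapsis_result`.
#' @return Residual, mV.
#' @export
consistency_residual <- function(sys, res) {
  if (is.null(sys$transfer)) sys <- attach_transfer(sys)
  max(abs(res$vout - sys$transfer %*% res$i_m))
}
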