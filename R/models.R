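#' The continuous membrane-model contract
#'
#' A membrane model supplies the ionic current density and the time
#' derivatives of its gating variables, as continuous functions of time,
#' membrane potential and state. Only continuous formulations are supported:
#' hybrid models that reset their state discontinuously (integrate-and-fire,
#' Izhikevich) cannot be solved self-consistently with the extracellular
#' potential and are rejected by design.
#'
#' `evaluate(t, v, states, params)` receives the time (ms), a vector of
#' membrane potentials (mV, one per segment bound to the model) and a matrix
#' of gating states (`n x k`, columns in `state_names` order), and returns
#' `list(i_ion = <uA/cm^2 vector>, dstate = <n x k matrix, per ms>)`.
#' `initial_state(v)` returns the steady gating state for potentials `v`.
#'
#' @param name model name.
#' @param state_names character vector of gating-variable names (may be empty).
#' @param evaluate,initial_state functions as described above.
#' @param params named list of constants.
#' @return A `ephapsis_model`.
#' @export
membrane_model <- function(name, state_names, evaluate, initial_state,
                           params = list()) {
  structure(list(name = name, state_names = state_names, evaluate = evaluate,
                 initial_state = initial_state, params = params),
            class = "ephapsis_model")
}

#' @export
print.ephapsis_model <- function(x, ...) {
  cat("<ephapsis_model> '", x$name, "' states: ",
      if (length(x$state_names)) paste(x$state_names, collapse = ", ") else "(none)",
      "\n", sep = "")
  invisible(x)
}

# x / (1 - exp(-x/y)), the singularity-safe ratio in the classic rate functions
vtrap <- function(x, y) {
  out <- x / -expm1(-x / y)
  small <- abs(x / y) < 1e-7
  out[small] <- y * (1 + x[small] / (2 * y))
  out
}

hh_rates <- function(v) {
  list(
    am = 0.1 * vtrap(v + 40, 10),
    bm = 4 * exp(-(v + 65) / 18),
    ah = 0.07 * exp(-(v + 65) / 20),
    bh = 1 / (1 + exp(-(v + 35) / 10)),
    an = 0.01 * vtrap(v + 55, 10),
    bn = 0.125 * exp(-(v + 65) / 80)
  )
}

#' Classic Hodgkin-Huxley membrane model
#'
#' The squid-axon sodium/potassium/leak formulation at 6.3 C with the
#' standard rate functions, e.g. `alpha_m = 0.1 (V+40) / (1 - exp(-(V+40)/10))`,
#' `beta_m = 4 exp(-(V+65)/18)`, and the conventional constants
#' `gNa = 120`, `gK = 36`, `gL = 0.3` mS/cm^2, `ENa = 50`, `EK = -77`,
#' `EL = -54.3` mV. Resting potential is close to -65 mV. Ionic current
#' density is returned in uA/cm^2.
#'
#' @param params named overrides of `gna`, `gk`, `gl` (mS/cm^2), `ena`,
#'   `ek`, `el` (mV).
#' @return A `ephapsis_model` with gating variables `m`, `h`, `n`.
#' @examples
#' m <- hh_model()
#' m$initial_state(-65)
#' @export
hh_model <- function(params = list()) {
  p <- modifyList(list(gna = 120, gk = 36, gl = 0.3,
                       ena = 50, ek = -77, el = -54.3), params)
  if (any(unlist(p[c("gna", "gk", "gl")]) < 0)) {
    abort_validation("conductances must be >= 0")
  }
  evaluate <- function(t, v, states, params) {
    m <- states[, 1]; h <- states[, 2]; n <- states[, 3]
    r <- hh_rates(v)
    i_ion <- unname(params$gna * m^3 * h * (v - params$ena) +
                      params$gk * n^4 * (v - params$ek) +
                      params$gl * (v - params$el))
    dstate <- cbind(r$am * (1 - m) - r$bm * m,
                    r$ah * (1 - h) - r$bh * h,
                    r$an * (1 - n) - r$bn * n)
    list(i_ion = i_ion, dstate = dstate)
  }
  initial_state <- function(v) {
    r <- hh_rates(v)
    cbind(m = r$am / (r$am + r$bm),
          h = r$ah / (r$ah + r$bh),
          n = r$an / (r$an + r$bn))
  }
  membrane_model("hh", c("m", "h", "n"), evaluate, initial_state, p)
}

#' Passive (leak-only) membrane model
#'
#' `I_ion = g_leak (V - E_leak)`, no gating variables.
#'
#' @param g_leak leak conductance density, mS/cm^2 (>= 0).
#' @param e_leak leak reversal potential, mV.
#' @return A `ephapsis_model`.
#' @export
passive_model <- function(g_leak = 0.3, e_leak = -65) {
  if (g_leak < 0) abort_validation("g_leak must be >= 0")
  p <- list(g_leak = g_leak, e_leak = e_leak)
  evaluate <- function(t, v, states, params) {
    list(i_ion = params$g_leak * (v - params$e_leak),
         dstate = matrix(0, length(v), 0))
  }
  initial_state <- function(v) matrix(0, length(v), 0)
  membrane_model("passive", character(0), evaluate, initial_state, p)
}

#' Resting potential of a membrane model
#'
#' Solves `I_ion(V, steady-state gating) = 0` on `[-90, -40]` mV.
#'
#' @param model a `ephapsis_model`.
#' @return Resting potential, mV.
#' @export
model_rest <- function(model) {
  f <- function(v) {
    st <- model$initial_state(v)
    model$evaluate(0, v, st, model$params)$i_ion
  }
  uniroot(f, c(-90, -40), tol = 1e-12)$root
}

## ---- stimuli ---------------------------------------------------------------

#' Intracellular and extracellular stimuli
#'
#' Intracellular stimuli inject current (nA) into one segment; extracellular
#' stimuli impose a potential in the medium, either from a point electrode
#' (a point current source, nA) or from parallel plates (a uniform electric
#' field, mV/um, producing the linear potential `V(x) = -E . x`). All
#' waveforms are `dc` (constant), `sinusoid`
#' (`amplitude * sin(2 pi f t / 1000 + phase)`, `f` in Hz, `t` in ms), or
#' `custom` (an arbitrary function of time and system state).
#'
#' @param target segment id (intracellular stimuli).
#' @param amplitude amplitude: nA (currents) or mV/um (plate fields).
#' @param frequency sinusoid frequency, Hz (>= 0).
#' @param phase sinusoid phase, rad.
#' @param fn for custom stimuli: `function(t, state)` returning nA; `state`
#'   is a list with elements `vm` and `t`.
#' @param position electrode location, 3-vector um.
#' @param field plate field vector `E`, mV/um.
#' @return A `ephapsis_stimulus`.
#' @export
dc_stimulus <- function(target, amplitude) {
  new_stimulus(list(side = "intracellular", waveform = "dc",
                    target = as.integer(target), amplitude = amplitude))
}

#' @rdname dc_stimulus
#' @export
sine_stimulus <- function(target, amplitude, frequency, phase = 0) {
  if (frequency < 0) abort_validation("frequency must be >= 0")
  new_stimulus(list(side = "intracellular", waveform = "sinusoid",
                    target = as.integer(target), amplitude = amplitude,
                    frequency = frequency, phase = phase))
}

#' @rdname dc_stimulus
#' @export
custom_stimulus <- function(target, fn) {
  stopifnot(is.function(fn))
  new_stimulus(list(side = "intracellular", waveform = "custom",
                    target = as.integer(target), fn = fn))
}

#' @rdname dc_stimulus
#' @export
point_electrode <- function(position, amplitude, frequency = NULL, phase = 0) {
  wf <- if (is.null(frequency)) "dc" else "sinusoid"
  new_stimulus(list(side = "extracellular", kind = "point", waveform = wf,
                    position = as.numeric(position), amplitude = amplitude,
                    frequency = frequency, phase = phase))
}

#' @rdname dc_stimulus
#' @export
plate_field <- function(field, frequency = NULL, phase = 0) {
  wf <- if (is.null(frequency)) "dc" else "sinusoid"
  new_stimulus(list(side = "extracellular", kind = "plates", waveform = wf,
                    field = as.numeric(field), amplitude = 1,
                    frequency = frequency, phase = phase))
}

new_stimulus <- function(x) structure(x, class = "ephapsis_stimulus")

#' Evaluate a stimulus waveform
#'
#' @param spec a `ephapsis_stimulus`.
#' @param t time, ms.
#' @param state optional system state (list with `vm`), passed to custom
#'   stimulus functions.
#' @return The waveform value at `t` (nA for current stimuli).
#' @export
stimulus_current <- function(spec, t, state = NULL) {
  switch(spec$waveform,
    dc = spec$amplitude,
    sinusoid = spec$amplitude * sin(2 * pi * spec$frequency * t / 1000 + spec$phase),
    custom = tryCatch(spec$fn(t, state), error = function(e) {
      rlang::abort(paste0("custom stimulus failed at t = ", t, ": ",
                          conditionMessage(e)),
                   class = "ephapsis_stimulus_error")
    }),
    abort_validation("unknown stimulus waveform")
  )
}

## ---- synapses --------------------------------------------------------------

#' Synapses: chemical, gap junction, external spike train
#'
#' Chemical and external synapses use a difference-of-exponentials
#' conductance, normalized so that a single presynaptic spike drives the
#' conductance to `g_max` at its peak
#' (`t_peak = tau_rise tau_decay / (tau_decay - tau_rise) log(tau_decay/tau_rise)`);
#' the synaptic current is `g(t) (V_post - E_syn)`. Presynaptic spikes of
#' chemical synapses are upward crossings of `threshold` with a 2 ms
#' refractory period, located by the integrator's event machinery so the
#' right-hand side stays continuous between events. Gap junctions couple two
#' segments with the ohmic current `g (V_post - V_pre)`; gap-junction
#' current flows cell-to-cell without crossing the membrane, so it is not an
#' extracellular field source.
#'
#' @param pre,post segment ids.
#' @param g_max peak conductance, nS (chemical/external) or coupling
#'   conductance (gap), >= 0.
#' @param e_syn synaptic reversal potential, mV.
#' @param tau_rise,tau_decay kernel time constants, ms (`tau_rise < tau_decay`).
#' @param threshold presynaptic spike-detection threshold, mV.
#' @param spike_times preset presynaptic spike times, ms (external synapses).
#' @return A `ephapsis_synapse`.
#' @export
chemical_synapse <- function(pre, post, g_max, e_syn = 0,
                             tau_rise = 0.5, tau_decay = 3, threshold = 0) {
  check_syn_kernel(g_max, tau_rise, tau_decay)
  new_synapse(list(kind = "chemical", pre = as.integer(pre),
                   post = as.integer(post), g_max = g_max, e_syn = e_syn,
                   tau_rise = tau_rise, tau_decay = tau_decay,
                   threshold = threshold, refractory = 2))
}

#' @rdname chemical_synapse
#' @export
gap_junction <- function(pre, post, g_max) {
  if (g_max < 0) abort_validation("g_max must be >= 0")
  new_synapse(list(kind = "gap", pre = as.integer(pre),
                   post = as.integer(post), g_max = g_max))
}

#' @rdname chemical_synapse
#' @export
external_synapse <- function(post, spike_times, g_max, e_syn = 0,
                             tau_rise = 0.5, tau_decay = 3) {
  check_syn_kernel(g_max, tau_rise, tau_decay)
  new_synapse(list(kind = "external_spikes", post = as.integer(post),
                   spike_times = sort(as.numeric(spike_times)), g_max = g_max,
                   e_syn = e_syn, tau_rise = tau_rise, tau_decay = tau_decay))
}

check_syn_kernel <- function(g_max, tau_rise, tau_decay) {
  if (g_max < 0) abort_validation("g_max must be >= 0")
  if (!(tau_rise < tau_decay)) abort_validation("tau_rise must be < tau_decay")
}

new_synapse <- function(x) structure(x, class = "ephapsis_synapse")

# peak time and unit-normalization of the difference-of-exponentials kernel
syn_kernel_norm <- function(tau_rise, tau_decay) {
  tp <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  list(t_peak = tp, norm = 1 / (exp(-tp / tau_decay) - exp(-tp / tau_rise)))
}

#' Instantaneous synaptic current
#'
#' Evaluates one synapse outside the integrator (the solver uses the same
#' arithmetic internally). For kernel synapses, `syn_state` holds the two
#' exponential states `(a, b)` with `g = g_max * norm * (b - a)`; each
#' presynaptic spike increments both by 1. Derivatives are
#' `(-a/tau_rise, -b/tau_decay)`.
#'
#' @param spec a `ephapsis_synapse`.
#' @param t time, ms.
#' @param pre_history numeric vector of presynaptic spike times (used only to
#'   reconstruct `syn_state` when it is not supplied).
#' @param v_post,v_pre membrane potentials, mV.
#' @param syn_state numeric `(a, b)` kernel state, or `NULL` to reconstruct
#'   it from `pre_history`.
#' @return `list(i_syn = nA, dstate = d(a,b)/dt, g = nS)`.
#' @export
synaptic_current <- function(spec, t, pre_history = numeric(0),
                             v_post = NULL, v_pre = NULL, syn_state = NULL) {
  if (spec$kind == "gap") {
    return(list(i_syn = spec$g_max * .u("nS_to_uS") * (v_post - v_pre),
                dstate = numeric(0), g = spec$g_max))
  }
  if (!spec$kind %in% c("chemical", "external_spikes")) {
    abort_validation("unknown synapse kind")
  }
  if (is.null(syn_state)) {
    past <- pre_history[pre_history <= t]
    a <- sum(exp(-(t - past) / spec$tau_rise))
    b <- sum(exp(-(t - past) / spec$tau_decay))
    syn_state <- c(a, b)
  }
  k <- syn_kernel_norm(spec$tau_rise, spec$tau_decay)
  g <- spec$g_max * k$norm * (syn_state[2] - syn_state[1])  # nS
  i <- g * .u("nS_to_uS") * (v_post - spec$e_syn)           # nA
  list(i_syn = i,
       dstate = c(-syn_state[1] / spec$tau_rise, -syn_state[2] / spec$tau_decay),
       g = g)
}
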