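test_that("HH model has a genuine fixed point at rest", {
  m <- hh_model()
  vrest <- model_rest(m)
  expect_equal(vrest, -65, tolerance = 0.02)  # -65 +- 1 mV, textbook value
  st <- m$initial_state(vrest)
  ev <- m$evaluate(0, vrest, st, m$params)
  expect_equal(ev$i_ion, 0, tolerance = 1e-10)
  expect_equal(as.vector(ev$dstate), c(0, 0, 0), tolerance = 1e-12)
  expect_true(all(st >= 0 & st <= 1))
})

test_that("HH evaluate matches hand-evaluated rate functions at V = 0, state 0", {
  m <- hh_model()
  ev <- m$evaluate(0, 0, matrix(0, 1, 3), m$params)
  # only the leak survives with m = h = n = 0
  expect_equal(ev$i_ion, 0.3 * (0 - (-54.3)), tolerance = 1e-12)
  # gating derivatives are alpha(0) * (1 - 0) - beta(0) * 0 = alpha(0)
  am0 <- 0.1 * 40 / (1 - exp(-4))
  ah0 <- 0.07 * exp(-65 / 20)
  an0 <- 0.01 * 55 / (1 - exp(-5.5))
  expect_equal(as.vector(ev$dstate), c(am0, ah0, an0), tolerance = 1e-10)
  expect_error(hh_model(list(gna = -1)), class = "ephapsis_validation_error")
})

test_that("shipped models are continuous over the physiological voltage range", {
  for (m in list(hh_model(), passive_model())) {
    v <- seq(-100, 60, by = 0.5)
    st <- m$initial_state(v)
    ev <- m$evaluate(0, v, st, m$params)
    for (eps in c(1e-3, 1e-5)) {
      ev2 <- m$evaluate(0, v + eps, st, m$params)
      expect_lt(max(abs(ev2$i_ion - ev$i_ion)), 200 * eps + 1e-12)
      if (ncol(st) > 0) {
        expect_lt(max(abs(ev2$dstate - ev$dstate)), 100 * eps + 1e-12)
      }
    }
  }
})

test_that("a driven HH compartment fires repetitively with textbook spike shape", {
  net <- one_compartment()
  sys <- assemble(net, stimuli = list(dc_stimulus(1, 0.1)),
                  options = solver_options(mode = "open_loop"))
  res <- solve_open_loop(sys, c(0, 100))
  st <- spike_times(res$times, res$vm[1, ])
  expect_gte(length(st), 2)
  expect_gt(max(res$vm), 20)
})

test_that("passive dynamics relax exponentially with tau = Cm/g", {
  net <- one_compartment("pas")
  sys <- assemble(net, models = list(pas = passive_model(0.3, -65)),
                  stimuli = list(dc_stimulus(1, 0.05)),
                  options = solver_options(mode = "open_loop"))
  res <- solve_open_loop(sys, c(0, 30))
  area <- segment_table(net)$area
  g_uS <- 0.3 * area * 1e-5
  tau <- 1 / 0.3  # Cm / g_leak in ms
  vinf <- -65 + 0.05 / g_uS
  expected <- vinf + (-65 - vinf) * exp(-res$times / tau)
  # fitted relaxation within 1% of the closed-form RC solution
  expect_lt(max(abs(res$vm[1, ] - expected)) / abs(vinf + 65), 0.01)

  m <- passive_model(0.5, -70)
  expect_equal(m$evaluate(0, -70, matrix(0, 1, 0), m$params)$i_ion, 0)
  expect_error(passive_model(-0.1), class = "ephapsis_validation_error")
})

test_that("g_leak = 0 with no stimulus leaves the potential constant", {
  net <- one_compartment("pas")
  sys <- assemble(net, models = list(pas = passive_model(0, -65)),
                  options = solver_options(mode = "open_loop"))
  res <- solve_open_loop(sys, c(0, 10), y0 = initial_conditions(sys, vm = -51))
  expect_equal(range(res$vm), c(-51, -51), tolerance = 1e-9)
})

test_that("stimulus waveforms evaluate per contract", {
  expect_equal(stimulus_current(dc_stimulus(1, 0.1), 123.4), 0.1)
  s <- sine_stimulus(1, 2, frequency = 10, phase = 0)
  expect_equal(stimulus_current(s, 0), 0)
  expect_equal(stimulus_current(s, 25), 2 * sin(2 * pi * 10 * 0.025))
  expect_error(sine_stimulus(1, 1, frequency = -5),
               class = "ephapsis_validation_error")
  cs <- custom_stimulus(1, function(t, state) -state$vm[1])
  expect_equal(stimulus_current(cs, 0, state = list(vm = c(-60))), 60)
  bad <- custom_stimulus(1, function(t, state) stop("boom"))
  expect_error(stimulus_current(bad, 1), class = "ephapsis_stimulus_error")
})

test_that("synaptic kernels and gap junctions follow their closed forms", {
  # gap junction: zero at equal potentials, antisymmetric otherwise
  g <- gap_junction(1, 2, g_max = 5)
  expect_equal(synaptic_current(g, 0, v_post = -60, v_pre = -60)$i_syn, 0)
  i_ab <- synaptic_current(g, 0, v_post = -50, v_pre = -70)$i_syn
  i_ba <- synaptic_current(g, 0, v_post = -70, v_pre = -50)$i_syn
  expect_equal(i_ab, -i_ba)

  # difference-of-exponentials conductance peaks at the closed-form time
  syn <- external_synapse(1, spike_times = 0, g_max = 2,
                          tau_rise = 0.5, tau_decay = 3)
  tp_closed <- 0.5 * 3 / (3 - 0.5) * log(3 / 0.5)
  tt <- seq(0.01, 10, by = 0.001)
  gg <- vapply(tt, function(t)
    synaptic_current(syn, t, pre_history = 0, v_post = 0)$g, 1)
  expect_equal(tt[which.max(gg)], tp_closed, tolerance = 2e-3)
  expect_equal(max(gg), 2, tolerance = 1e-6)  # normalized to g_max

  expect_error(chemical_synapse(1, 2, g_max = 1, tau_rise = 3, tau_decay = 1),
               class = "ephapsis_validation_error")
  expect_error(chemical_synapse(1, 2, g_max = -1),
               class = "ephapsis_validation_error")
})

test_that("an external suprathreshold synapse fires the postsynaptic cell", {
  net <- one_compartment()
  sys <- assemble(net, synapses = list(
    external_synapse(1, spike_times = 5, g_max = 100, e_syn = 0)),
    options = solver_options(mode = "open_loop"))
  res <- solve_open_loop(sys, c(0, 30))
  st <- spike_times(res$times, res$vm[1, ])
  expect_length(st, 1)
  expect_gt(st, 5)
  expect_lt(st, 10)
})
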