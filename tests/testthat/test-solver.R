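test_that("assembly lays out states and axial structure from the topology", {
  net <- fixture_network("ball_and_stick", list(nseg = 5))
  sys <- assemble(net, options = solver_options(mode = "open_loop"))
  expect_equal(sys$n, 6)                    # soma + 5 axon segments
  expect_equal(sys$nstate, 6 * 4)           # vm + m, h, n
  offdiag <- sum(sys$a_mat[upper.tri(sys$a_mat)] != 0)
  expect_equal(offdiag, 5)                  # 5 coupled pairs
  # Kirchhoff: symmetric with zero row sums
  expect_equal(sys$a_mat, t(sys$a_mat))
  expect_equal(rowSums(sys$a_mat), rep(0, 6), tolerance = 1e-15)

  # one-compartment passive system: a single state
  net1 <- one_compartment("pas")
  sys1 <- assemble(net1, models = list(pas = passive_model()),
                   options = solver_options(mode = "open_loop"))
  expect_equal(sys1$nstate, 1)

  expect_error(assemble(net, models = list(other = hh_model())),
               class = "ephapsis_validation_error")
  expect_error(assemble(net, models = list(hh = hh_model()),
                        stimuli = list(dc_stimulus(99, 1))),
               class = "ephapsis_validation_error")
})

test_that("membrane current bookkeeping is consistent and conservative", {
  # equilibrium: unstimulated passive cell at E_leak has zero currents
  net <- short_axon(nseg = 4, model = "pas")
  sys <- assemble(net, models = list(pas = passive_model(0.3, -65)),
                  options = solver_options(mode = "open_loop"))
  sys$rhs_mode <- "open_loop"
  y0 <- initial_conditions(sys, vm = rep(-65, 4))
  expect_equal(membrane_currents(sys, 0, y0), rep(0, 4), tolerance = 1e-12)

  # with injection: per-cell sum of membrane currents equals injected current
  net2 <- fixture_network("ball_and_stick", list(nseg = 7))
  sys2 <- assemble(net2, stimuli = list(dc_stimulus(1, 0.7)),
                   options = solver_options(mode = "open_loop"))
  res <- solve_open_loop(sys2, c(0, 10))
  expect_lt(max(abs(colSums(res$i_m) - 0.7)), 1e-7)

  # both bookkeeping sides agree along a trajectory
  sys2$rhs_mode <- "open_loop"
  k <- 150
  y <- c(res$vm[, k], unlist(lapply(c("m", "h", "n"), function(v)
    res$gating$hh[[v]][, k])))
  ax <- membrane_currents(sys2, res$times[k], y, side = "axial")
  mem <- membrane_currents(sys2, res$times[k], y, side = "membrane")
  expect_equal(ax, mem, tolerance = 1e-9)

  # two-compartment passive cell under DC: steady state matches the circuit
  net3 <- short_axon(nseg = 2, length = 100, model = "pas")
  g_leak <- 0.3
  sys3 <- assemble(net3, models = list(pas = passive_model(g_leak, -65)),
                   stimuli = list(dc_stimulus(1, 0.2)),
                   options = solver_options(mode = "open_loop"))
  res3 <- solve_open_loop(sys3, c(0, 60))
  st <- segment_table(net3)
  gm <- g_leak * st$area * 1e-5          # uS
  ga <- 1 / net3$axial$r_mohm            # uS
  # nodal circuit solution: (G) v = i with v relative to E_leak
  G <- rbind(c(gm[1] + ga, -ga), c(-ga, gm[2] + ga))
  v_ss <- solve(G, c(0.2, 0)) - 65
  expect_equal(res3$vm[, ncol(res3$vm)], v_ss, tolerance = 5e-3 * max(abs(v_ss + 65)))
  im_ss <- res3$i_m[, ncol(res3$i_m)]
  im_circuit <- gm * (v_ss + 65)
  expect_equal(im_ss, im_circuit, tolerance = 5e-3 * max(abs(im_circuit)))
})

test_that("ephaptic currents are the axial differences of V_out", {
  net <- short_axon(nseg = 3, length = 100)
  sys <- assemble(net, options = solver_options(mode = "open_loop"))
  r <- net$axial$r_mohm[1]
  sys$a_mat <- sys$a_mat * (r / 10)  # rescale links to exactly 10 MOhm
  expect_equal(ephaptic_currents(sys, c(1, 0, 0)), c(-0.1, 0.1, 0),
               tolerance = 1e-12)
  # uniform V_out drives nothing
  expect_equal(ephaptic_currents(sys, rep(3.7, 3)), rep(0, 3), tolerance = 1e-12)
  # telescoping: interior contributions cancel along an unbranched cable
  vout <- c(0.4, -1.2, 0.9)
  expect_equal(sum(ephaptic_currents(sys, vout)), 0, tolerance = 1e-12)
})

test_that("a zero-channel, zero-stimulus network stays exactly at rest", {
  net <- fixture_network("pair", list(nseg = 5))
  sys <- assemble(net, models = list(hh = passive_model(0, -65)),
                  med = medium(0.05), options = solver_options())
  y0 <- initial_conditions(sys, vm = rep(-65, sys$n))
  res <- solve_closed_loop(sys, c(0, 5), y0 = y0)
  expect_equal(range(res$vm), c(-65, -65), tolerance = 1e-9)
  expect_equal(range(res$vout), c(0, 0), tolerance = 1e-9)
})

test_that("closed-loop solutions are self-consistent and converge to open loop", {
  net <- fixture_network("pair", list(nseg = 11, length = 300))
  stim <- list(dc_stimulus(1, 0.5))
  opts <- solver_options(store_gating = FALSE)
  res_open <- solve_open_loop(
    assemble(net, stimuli = stim, options = solver_options(mode = "open_loop",
                                                           store_gating = FALSE)),
    c(0, 20))
  dmax <- vapply(c(0.05, 0.5, 5, 50), function(sg) {
    sys <- assemble(net, stimuli = stim, med = medium(sg), options = opts)
    res <- solve_closed_loop(sys, c(0, 20))
    expect_lt(consistency_residual(sys, res), 10 * opts$abs_tol)
    max(abs(res$vm - res_open$vm))
  }, 1)
  # non-increasing down to the integrator's spike-jitter floor (~0.01 mV)
  expect_true(all(diff(dmax) < 0 | dmax[-1] < 0.01))
  expect_lt(dmax[4], 0.05 * dmax[1])

  # the undriven neighbour feels the driven axon's spikes
  sys_lo <- assemble(net, stimuli = stim, med = medium(0.05), options = opts)
  res_lo <- solve_closed_loop(sys_lo, c(0, 20))
  und <- segment_table(net)$cell_index == 2
  expect_gt(max(abs(res_lo$vm[und, ] + 65)), 0.01)  # deflections, but
  expect_lt(max(res_lo$vm[und, ]), 0)               # subthreshold
})

test_that("eliminated-ODE and mass-matrix DAE formulations agree", {
  net <- fixture_network("pair", list(nseg = 7, length = 200))
  stim <- list(dc_stimulus(1, 0.4))
  tol <- 1e-6
  sys <- assemble(net, stimuli = stim, med = medium(0.1),
                  options = solver_options(rel_tol = tol, abs_tol = 1e-8,
                                           store_gating = FALSE))
  res_ode <- solve_closed_loop(sys, c(0, 8))
  opts_dae <- solver_options(rel_tol = tol, abs_tol = 1e-8,
                             formulation = "mass_matrix_dae",
                             store_gating = FALSE)
  res_dae <- solve_closed_loop(sys, c(0, 8), options = opts_dae)
  # agreement within 10x integrator tolerance (spike upstrokes dominate)
  expect_lt(max(abs(res_ode$vm - res_dae$vm)) / max(abs(res_ode$vm)), 10 * tol * 100)
  expect_lt(sqrt(mean((res_ode$vm - res_dae$vm)^2)), 0.05)
})

test_that("the reference integrator converges to the adaptive solution", {
  net <- fixture_network("axon", list(nseg = 11, length = 300))
  sys <- assemble(net, stimuli = list(dc_stimulus(1, 0.3)),
                  options = solver_options(mode = "open_loop"))
  res <- solve_open_loop(sys, c(0, 12))
  errs <- vapply(c(5e-3, 2.5e-3, 1.25e-3), function(dt) {
    ref <- reference_solve(sys, c(0, 12), dt_fixed = dt, store_dt = 0.025)
    max(abs(ref$vm - res$vm))
  }, 1)
  expect_true(all(diff(errs) < 0))   # monotone convergence
  expect_gt(errs[1] / errs[3], 2.5)  # at least first-order behaviour

  # determinism: identical inputs give bit-identical output
  r1 <- reference_solve(sys, c(0, 5), dt_fixed = 2.5e-3)
  r2 <- reference_solve(sys, c(0, 5), dt_fixed = 2.5e-3)
  expect_identical(r1$vm, r2$vm)

  # a linear passive system tracks the exact exponential to O(dt)
  net_p <- one_compartment("pas")
  sys_p <- assemble(net_p, models = list(pas = passive_model(0.3, -65)),
                    stimuli = list(dc_stimulus(1, 0.05)),
                    options = solver_options(mode = "open_loop"))
  dt <- 1e-3
  ref_p <- reference_solve(sys_p, c(0, 10), dt_fixed = dt)
  g_uS <- 0.3 * segment_table(net_p)$area * 1e-5
  tau <- 1 / 0.3
  vinf <- -65 + 0.05 / g_uS
  exact <- vinf + (-65 - vinf) * exp(-ref_p$times / tau)
  expect_lt(max(abs(ref_p$vm[1, ] - exact)), 5 * dt * max(abs(exact + 65)) / tau)
})

test_that("intracellular DC maps dynamics onto the expected propagation order", {
  net <- fixture_network("axon", list(nseg = 21))
  sys <- assemble(net, stimuli = list(dc_stimulus(1, 0.5)),
                  options = solver_options(mode = "open_loop",
                                           store_gating = FALSE))
  res <- solve_open_loop(sys, c(0, 15))
  first_spike <- vapply(c(1, 11, 21), function(s)
    spike_times(res$times, res$vm[s, ])[1], 1)
  expect_true(all(diff(first_spike) > 0))  # orderly conduction
})

test_that("an imposed uniform field polarizes a passive cable antisymmetrically", {
  net <- short_axon(nseg = 11, length = 500, model = "pas")
  sys <- assemble(net, models = list(pas = passive_model(0.3, -65)),
                  stimuli = list(plate_field(c(0.001, 0, 0))),  # mV/um along x
                  options = solver_options(mode = "open_loop"))
  res <- solve_open_loop(sys, c(0, 50))
  dv <- res$vm[, ncol(res$vm)] + 65
  expect_lt(dv[1], -0.001)   # anodal end hyperpolarizes
  expect_gt(dv[11], 0.001)   # cathodal end depolarizes
  expect_equal(dv[6], 0, tolerance = 1e-6)        # midpoint by symmetry
  expect_equal(dv[1], -dv[11], tolerance = 1e-6)  # antisymmetric profile
})

test_that("gap junctions couple cells like the equivalent resistive circuit", {
  r <- sqrt(1000 / (4 * pi))
  mk <- function(nm) add_section(cell(nm), sphere_section("s", radius = r,
                                                          model = "pas"))
  net <- discretize(place(place(network(), mk("a")), mk("b"),
                          offset = c(0, 50, 0)))
  sys <- assemble(net, models = list(pas = passive_model(0.3, -65)),
                  stimuli = list(dc_stimulus(1, 0.05)),
                  synapses = list(gap_junction(1, 2, g_max = 2)),
                  options = solver_options(mode = "open_loop"))
  res <- solve_open_loop(sys, c(0, 80))
  gm <- 0.3 * 1000 * 1e-5
  gj <- 2e-3
  G <- rbind(c(gm + gj, -gj), c(-gj, gm + gj))
  vss <- solve(G, c(0.05, 0)) - 65
  expect_equal(res$vm[, ncol(res$vm)], vss, tolerance = 1e-4)
})

test_that("endogenous chemical synapses relay spikes with a short delay", {
  r <- sqrt(1000 / (4 * pi))
  mk <- function(nm) add_section(cell(nm), sphere_section("s", radius = r))
  net <- discretize(place(place(network(), mk("a")), mk("b"),
                          offset = c(0, 50, 0)))
  sys <- assemble(net, models = list(hh = hh_model()),
                  stimuli = list(dc_stimulus(1, 0.1)),
                  synapses = list(chemical_synapse(1, 2, g_max = 50, e_syn = 0)),
                  options = solver_options(mode = "open_loop"))
  res <- solve_open_loop(sys, c(0, 40))
  s1 <- spike_times(res$times, res$vm[1, ])
  s2 <- spike_times(res$times, res$vm[2, ])
  expect_gte(length(s1), 2)
  expect_equal(length(s2), length(s1))
  lag <- s2 - s1
  expect_true(all(lag > 0 & lag < 2))  # postsynaptic follows within 2 ms
})
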