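test_that("point-source potential matches its closed form and clamp", {
  med <- medium(0.3)
  # 1 nA at 10 um in 0.3 S/m: 1/(4 pi 0.3 10) mV
  expect_equal(point_source_potential(1, 10, 1, med), 1 / (4 * pi * 0.3 * 10),
               tolerance = 1e-12)
  # 1/R scaling outside the sphere
  expect_equal(point_source_potential(1, 40, 1, med),
               point_source_potential(1, 20, 1, med) / 2)
  # interior clamp at the surface value
  expect_equal(point_source_potential(1, 0, 5, med),
               point_source_potential(1, 5, 5, med))
  expect_error(medium(0), class = "ephapsis_validation_error")
})

test_that("line-source potential equals dense quadrature of point sources", {
  sigma <- 0.3
  L <- 10
  # evaluation beside the midpoint at r = 5: l = 5, h = -5
  v_closed <- line_source_potential(1, r = 5, l = 5, h = -5, medium(sigma))
  n_sub <- 1e5
  zs <- (seq_len(n_sub) - 0.5) / n_sub * L
  v_quad <- sum(1 / (4 * pi * sigma * sqrt(5^2 + (5 - zs)^2))) / n_sub
  expect_equal(v_closed, v_quad, tolerance = 1e-6)

  # also off the end (l and h of the same sign) and behind the start
  for (l in c(14, -3)) {
    v_c <- line_source_potential(1, r = 2, l = l, h = l - L, medium(sigma))
    v_q <- sum(1 / (4 * pi * sigma * sqrt(2^2 + (l - zs)^2))) / n_sub
    expect_equal(v_c, v_q, tolerance = 1e-6)
  }

  expect_equal(line_source_potential(0, 5, 5, -5, medium(sigma)), 0)
  # mirror symmetry about the midpoint
  expect_equal(line_source_potential(1, 3, 7, -3, medium(sigma)),
               line_source_potential(1, 3, 3, -7, medium(sigma)))
  expect_error(line_source_potential(1, 0, 5, -5, medium(sigma)),
               class = "ephapsis_singularity_error")
})

test_that("line source converges to a point source in the far field", {
  med <- medium(0.3)
  L <- 10
  for (d in c(20 * L, 100 * L)) {
    v_line <- line_source_potential(1, r = d, l = L / 2, h = -L / 2, med)
    v_point <- 1 / (4 * pi * 0.3 * d)
    expect_lt(abs(v_line - v_point) / v_point, 0.005)
  }
  # and to zero at extreme distance (1e4 x geometry scale)
  v_near <- line_source_potential(1, r = 2, l = L / 2, h = -L / 2, med)
  v_far <- line_source_potential(1, r = 1e4 * L, l = L / 2, h = -L / 2, med)
  expect_lt(abs(v_far), 1e-3 * abs(v_near))
})

test_that("boundary-averaged self-coefficient matches the surface quadrature oracle", {
  net <- short_axon(nseg = 1, length = 10, radius = 1)
  seg <- as.list(segment_table(net)[1, ])
  # at matched sample density the two independent kernel evaluations agree
  got_dense <- boundary_averaged_coefficient(seg, seg, medium(0.3),
                                             field_sampling(100, 100))
  oracle <- surface_average_oracle(seg, seg, 0.3)
  expect_equal(got_dense, oracle, tolerance = 1e-9)
  # the default 5 x 8 rule stays within 1% of the dense surface average
  got_default <- boundary_averaged_coefficient(seg, seg, medium(0.3),
                                               field_sampling(5, 8))
  expect_lt(abs(got_default - oracle) / oracle, 0.01)

  # far-field coefficient approaches the point-source value
  net2 <- fixture_network("pair", list(pitch = 400, nseg = 1, length = 10))
  st <- segment_table(net2)
  cf <- boundary_averaged_coefficient(as.list(st[1, ]), as.list(st[2, ]),
                                      medium(0.3))
  expect_lt(abs(cf - 1 / (4 * pi * 0.3 * 400)) / (1 / (4 * pi * 0.3 * 400)),
            0.01)
})

test_that("transfer matrices superpose, scale as 1/sigma, and are motion-invariant", {
  net <- short_axon(nseg = 3, length = 30, radius = 1)
  t1 <- build_transfer_matrix(net, medium(1))
  t10 <- build_transfer_matrix(net, medium(10))
  expect_equal(t1, 10 * t10, tolerance = 1e-14, ignore_attr = TRUE)
  expect_true(all(is.finite(diag(t1))))

  # superposition: matrix times a current pattern = sum of single-source fields
  iv <- c(1, -2, 1)
  single <- sapply(1:3, function(j) {
    ii <- numeric(3); ii[j] <- iv[j]
    t1 %*% ii
  })
  expect_equal(as.vector(t1 %*% iv), rowSums(single), tolerance = 1e-15)

  # rigid motion of the whole network leaves every coefficient unchanged
  ax <- cell("a") |>
    add_section(cylinder_section("axon", radius = 1, length = 30, nseg = 3))
  th <- 1.1
  rot <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  net_m <- discretize(place(network(), ax, offset = c(7, -4, 2), rotation = rot))
  t_m <- build_transfer_matrix(net_m, medium(1))
  expect_equal(t_m, t1, tolerance = 1e-10, ignore_attr = TRUE)

  # n = 1 network: the matrix is the self-coefficient
  net1 <- short_axon(nseg = 1, length = 10)
  st1 <- segment_table(net1)
  tm1 <- build_transfer_matrix(net1, medium(0.3))
  expect_equal(as.vector(tm1),
               boundary_averaged_coefficient(as.list(st1[1, ]),
                                             as.list(st1[1, ]), medium(0.3)))
})

test_that("well-separated coefficients are reciprocal within 2 percent", {
  net <- fixture_network("pair", list(pitch = 300, nseg = 2, length = 20))
  tm <- build_transfer_matrix(net, medium(0.3))
  expect_equal(tm[1, 3], tm[3, 1], tolerance = 0.02 * tm[1, 3])
})

test_that("probe evaluation reproduces kernels and decays with distance", {
  # a single sphere: probes reproduce the point-source form exactly
  net <- one_compartment()
  st <- segment_table(net)
  p <- probe_points(st$x[1] + 25, st$y[1], st$z[1])
  cf <- probe_coefficients(net, p, medium(0.3))
  expect_equal(as.vector(cf), 1 / (4 * pi * 0.3 * 25), tolerance = 1e-12)

  out <- evaluate_probes(net, matrix(2, 1, 3), p, medium(0.3), times = 1:3)
  expect_equal(out$v_mV, rep(2 / (4 * pi * 0.3 * 25), 3), tolerance = 1e-12)
  # zero currents give zero potentials
  out0 <- evaluate_probes(net, matrix(0, 1, 5), p, medium(0.3))
  expect_equal(out0$v_mV, rep(0, 5))

  # probe on a cylinder axis is a reported singularity
  neta <- short_axon(nseg = 2, length = 100)
  bad <- probe_points(50, 0, 0)
  expect_error(probe_coefficients(neta, bad, medium(0.3)),
               class = "ephapsis_singularity_error")
})

test_that("extracellular stimulation fields follow their closed forms", {
  med <- medium(0.3)
  el <- point_electrode(c(0, 0, 0), amplitude = 1)
  expect_equal(as.vector(extracellular_stimulus_field(el, cbind(20, 0, 0), med)),
               1 / (4 * pi * 0.3 * 20), tolerance = 1e-12)
  el0 <- point_electrode(c(0, 0, 0), amplitude = 0)
  expect_equal(as.vector(extracellular_stimulus_field(el0, cbind(20, 0, 0), med)), 0)
  expect_error(extracellular_stimulus_field(el, cbind(0, 0, 0), med),
               class = "ephapsis_singularity_error")

  pl <- plate_field(c(0, 0, 2))
  v <- extracellular_stimulus_field(pl, rbind(c(0, 0, 0), c(0, 0, 7)), med)
  expect_equal(v[2] - v[1], -2 * 7, tolerance = 1e-12)
})
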