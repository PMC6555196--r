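test_that("cells are built from sections with validated names and dimensions", {
  cl <- cell("c") |> add_section(sphere_section("soma", radius = 10))
  expect_length(cl$sections, 1)

  bs <- cl |>
    add_section(cylinder_section("axon", radius = 1, length = 1000,
                                 proximal = c(10, 0, 0), nseg = 41)) |>
    connect("axon", 0, "soma", 1)
  expect_length(bs$sections, 2)
  expect_length(bs$connections, 1)

  expect_error(add_section(bs, sphere_section("soma", radius = 5)),
               class = "ephapsis_naming_error")
  expect_error(sphere_section("s", radius = -1),
               class = "ephapsis_validation_error")
  expect_error(cylinder_section("a", radius = 1, length = 0),
               class = "ephapsis_validation_error")
  expect_error(connect(bs, "axon", 0, "nope", 1),
               class = "ephapsis_validation_error")
  # a second parent for the same end
  bs2 <- add_section(bs, cylinder_section("b", radius = 1, length = 10,
                                          proximal = c(10, 0, 0)))
  expect_error(connect(bs2, "axon", 0, "b", 1),
               class = "ephapsis_validation_error")
  # cycles are rejected
  expect_error(connect(bs2 |> connect("b", 0, "soma", 1), "b", 1, "axon", 1),
               class = "ephapsis_validation_error")
})

test_that("discretization produces the half-segment series resistances", {
  net <- short_axon(nseg = 2, length = 100, radius = 1)
  # R = Ra * l / (pi r^2): 100 Ohm cm * 50 um / (pi um^2) = 15.9155 MOhm
  expect_equal(net$axial$r_mohm, 100 * 50 / pi * 1e-2, tolerance = 1e-12)

  net1 <- short_axon(nseg = 1)
  expect_equal(nrow(net1$axial), 0)

  # total membrane area is nseg-invariant
  for (ns in c(1, 7, 40)) {
    expect_equal(sum(segment_table(short_axon(nseg = ns))$area),
                 2 * pi * 1 * 100, tolerance = 1e-9)
  }
  # series resistance along an unbranched cable is nseg-invariant
  total_r <- function(ns) sum(short_axon(nseg = ns)$axial$r_mohm)
  r8 <- total_r(8); r16 <- total_r(16)
  # interior resistance spans (nseg-1)/nseg of the cable
  expect_equal(r8 * 8 / 7, r16 * 16 / 15, tolerance = 1e-12)
})

test_that("sphere couples through the cylinder half-segment resistance only", {
  cl <- cell("bs") |>
    add_section(sphere_section("soma", radius = 10)) |>
    add_section(cylinder_section("axon", radius = 1, length = 100,
                                 proximal = c(10, 0, 0), nseg = 2)) |>
    connect("axon", 0, "soma", 1)
  net <- discretize(place(network(), cl))
  link <- net$axial[net$axial$i == 1, ]
  expect_equal(link$r_mohm, 100 * 25 / pi * 1e-2, tolerance = 1e-12)
})

test_that("a Y-branch gives the parent-end segment three axial neighbours", {
  cl <- cell("y") |>
    add_section(cylinder_section("trunk", radius = 1, length = 100, nseg = 4)) |>
    add_section(cylinder_section("d1", radius = 1, length = 50,
                                 proximal = c(100, 0, 0),
                                 orientation = c(1, 1, 0) / sqrt(2), nseg = 2)) |>
    add_section(cylinder_section("d2", radius = 1, length = 50,
                                 proximal = c(100, 0, 0),
                                 orientation = c(1, -1, 0) / sqrt(2), nseg = 2)) |>
    connect("d1", 0, "trunk", 1) |>
    connect("d2", 0, "trunk", 1)
  net <- discretize(place(network(), cl))
  deg <- tabulate(c(net$axial$i, net$axial$j), nbins = nrow(net$segments))
  expect_equal(deg[4], 3)  # distal trunk segment: one internal + two daughters
})

test_that("place() applies rigid transforms and preserves distances", {
  ax <- cell("a") |>
    add_section(cylinder_section("axon", radius = 1, length = 100, nseg = 5))
  net <- place(network(), ax) |> place(ax, offset = c(0, 0, 100)) |> discretize()
  st <- segment_table(net)
  expect_equal(st$z[st$cell_index == 2] - st$z[st$cell_index == 1],
               rep(100, 5))

  expect_error(place(network(), ax, rotation = matrix(1, 3, 3)),
               class = "ephapsis_validation_error")

  # mirror placement: x negated, areas unchanged, pairwise distances kept
  mir <- place(network(), ax, rotation = diag(c(-1, 1, 1))) |> discretize()
  stm <- segment_table(mir)
  st0 <- segment_table(discretize(place(network(), ax)))
  expect_equal(stm$x, -st0$x)
  expect_equal(stm$area, st0$area)
  d0 <- dist(st0[, c("x", "y", "z")])
  dm <- dist(stm[, c("x", "y", "z")])
  expect_equal(as.vector(dm), as.vector(d0), tolerance = 1e-12)

  # arbitrary rotation preserves pairwise distances
  th <- 0.7
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  str <- segment_table(discretize(place(network(), ax, offset = c(3, -2, 9),
                                        rotation = rot)))
  expect_equal(as.vector(dist(str[, c("x", "y", "z")])), as.vector(d0),
               tolerance = 1e-9)
})

test_that("fixture networks have the documented geometry", {
  hex <- fixture_network("hex_bundle", list(pitch = 5))
  st <- segment_table(hex)
  centers <- dplyr::summarise(dplyr::group_by(st, cell_index),
                              y = mean(y), z = mean(z))
  expect_equal(nrow(centers), 7)
  d_to_center <- sqrt((centers$y - centers$y[1])^2 + (centers$z - centers$z[1])^2)
  expect_equal(d_to_center[-1], rep(5, 6), tolerance = 1e-9)
  # outer axons are pairwise adjacent at the pitch distance
  outer_d <- as.matrix(dist(centers[-1, c("y", "z")]))
  nearest <- apply(outer_d + diag(Inf, 6), 1, min)
  expect_equal(unname(nearest), rep(5, 6), tolerance = 1e-9)

  ax <- fixture_network("axon")
  expect_equal(nrow(segment_table(ax)), 41)
  expect_error(fixture_network("nope"))
})

test_that("networks keep cells axially separate with consecutive ids", {
  net <- fixture_network("pair")
  st <- segment_table(net)
  expect_equal(st$id, seq_len(nrow(st)))
  cross <- st$cell_index[net$axial$i] != st$cell_index[net$axial$j]
  expect_false(any(cross))
})
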