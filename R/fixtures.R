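#' Canonical validation geometries
#'
#' Deterministic networks used throughout the documentation, tests and the
#' validation suite:
#'
#' * `"axon"` - one straight cylinder (default 1000 um long, 2 um diameter,
#'   41 segments) running along +x.
#' * `"ball_and_stick"` - sphere soma (10 um radius) with the axon attached.
#' * `"bipolar"` - soma with two symmetric axons along +x and -x.
#' * `"branched"` - soma, a 500 um parent axon, and two 500 um daughters
#'   leaving the parent's distal end at +-30 degrees.
#' * `"pair"` - two parallel axons separated laterally by `pitch` um.
#' * `"hex_bundle"` - seven parallel axons: one on the bundle axis and six
#'   at the vertices of a hexagon of circumradius `pitch` (so every outer
#'   axon is exactly `pitch` um from the centre axon and from its two
#'   neighbours). Bundle axons default to 21 segments each to keep the
#'   closed-loop system at desk scale.
#'
#' @param kind fixture name.
#' @param params optional overrides: `length`, `diameter`, `nseg`,
#'   `soma_radius`, `pitch`, `model`.
#' @return A discretized `ephapsis_network`.
#' @examples
#' net <- fixture_network("hex_bundle")
#' nrow(segment_table(net))
#' @export
fixture_network <- function(kind = c("axon", "ball_and_stick", "bipolar",
                                     "branched", "pair", "hex_bundle"),
                            params = list()) {
  kind <- match.arg(kind)
  p <- modifyList(list(length = 1000, diameter = 2, nseg = 41L,
                       soma_radius = 10, pitch = 5, model = "hh"), params)
  r <- p$diameter / 2
  ax <- function(name, proximal = c(0, 0, 0), orientation = c(1, 0, 0),
                 length = p$length, nseg = p$nseg) {
    cylinder_section(name, radius = r, length = length, proximal = proximal,
                     orientation = orientation, nseg = as.integer(nseg),
                     model = p$model)
  }
  soma <- function() sphere_section("soma", radius = p$soma_radius, model = p$model)

  net <- network()
  if (kind == "axon") {
    cl <- cell("axon") |> add_section(ax("axon"))
    net <- place(net, cl)
  } else if (kind == "ball_and_stick") {
    cl <- cell("ball_and_stick") |>
      add_section(soma()) |>
      add_section(ax("axon", proximal = c(p$soma_radius, 0, 0))) |>
      connect("axon", 0, "soma", 1)
    net <- place(net, cl)
  } else if (kind == "bipolar") {
    cl <- cell("bipolar") |>
      add_section(soma()) |>
      add_section(ax("axon1", proximal = c(p$soma_radius, 0, 0),
                     orientation = c(1, 0, 0))) |>
      add_section(ax("axon2", proximal = c(-p$soma_radius, 0, 0),
                     orientation = c(-1, 0, 0))) |>
      connect("axon1", 0, "soma", 1) |>
      connect("axon2", 0, "soma", 0)
    net <- place(net, cl)
  } else if (kind == "branched") {
    half <- p$length / 2
    nhalf <- max(1L, as.integer(ceiling(p$nseg / 2)))
    tip <- c(p$soma_radius + half, 0, 0)
    d1 <- c(cos(pi / 6), sin(pi / 6), 0)
    d2 <- c(cos(pi / 6), -sin(pi / 6), 0)
    cl <- cell("branched") |>
      add_section(soma()) |>
      add_section(ax("trunk", proximal = c(p$soma_radius, 0, 0),
                     length = half, nseg = nhalf)) |>
      add_section(ax("branch1", proximal = tip, orientation = d1,
                     length = half, nseg = nhalf)) |>
      add_section(ax("branch2", proximal = tip, orientation = d2,
                     length = half, nseg = nhalf)) |>
      connect("trunk", 0, "soma", 1) |>
      connect("branch1", 0, "trunk", 1) |>
      connect("branch2", 0, "trunk", 1)
    net <- place(net, cl)
  } else if (kind == "pair") {
    cl <- cell("axon") |> add_section(ax("axon"))
    net <- place(net, cl) |> place(cl, offset = c(0, p$pitch, 0))
  } else if (kind == "hex_bundle") {
    nseg_b <- if ("nseg" %in% names(params)) as.integer(params$nseg) else 21L
    cl <- cell("axon") |>
      add_section(ax("axon", nseg = nseg_b))
    net <- place(net, cl)  # central axon on the x axis
    for (k in 0:5) {
      th <- k * pi / 3
      net <- place(net, cl, offset = c(0, p$pitch * cos(th), p$pitch * sin(th)))
    }
  }
  discretize(net)
}
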