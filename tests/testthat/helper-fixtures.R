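# shared builders for small test systems

# single isopotential compartment with ~1000 um^2 membrane
one_compartment <- function(model_tag = "hh") {
  r <- sqrt(1000 / (4 * pi))
  discretize(place(network(), add_section(
    cell("c"), sphere_section("s", radius = r, model = model_tag))))
}

# short cylinder cell with a given segment count
short_axon <- function(nseg = 5, length = 100, radius = 1, model = "hh") {
  discretize(place(network(), add_section(
    cell("c"),
    cylinder_section("axon", radius = radius, length = length,
                     nseg = nseg, model = model))))
}

# dense surface quadrature of a source segment's kernel over a target
# cylinder's lateral surface: the independent oracle for boundary averaging
surface_average_oracle <- function(source, target, sigma, n_axial = 100,
                                   n_azimuthal = 100) {
  a <- c(target$x0, target$y0, target$z0)
  b <- c(target$x1, target$y1, target$z1)
  u <- (b - a) / sqrt(sum((b - a)^2))
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  fr <- (seq_len(n_axial) - 0.5) / n_axial
  th <- 2 * pi * (seq_len(n_azimuthal) - 0.5) / n_azimuthal
  g <- expand.grid(fr = fr, th = th)
  pts <- matrix(a, nrow(g), 3, byrow = TRUE) + outer(g$fr, b - a) +
    target$radius * (cos(g$th) %o% e1 + sin(g$th) %o% e2)
  # evaluate the source's line-source kernel by direct formula
  sa <- c(source$x0, source$y0, source$z0)
  sb <- c(source$x1, source$y1, source$z1)
  d <- sb - sa
  L <- sqrt(sum(d^2))
  s <- d / L
  rel <- sweep(pts, 2, sa)
  l <- as.vector(rel %*% s)
  h <- l - L
  rp <- sqrt(pmax(rowSums(rel^2) - l^2, 0))
  f <- function(x, r) ifelse(x > 0, r^2 / (sqrt(x^2 + r^2) + x), sqrt(x^2 + r^2) - x)
  mean(log(f(h, rp) / f(l, rp)) / (4 * pi * sigma * L))
}
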