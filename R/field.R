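#' Extracellular medium
#'
#' The extracellular space is an infinite, homogeneous, isotropic ohmic
#' medium characterized by a single conductivity. Potentials from neural
#' sources are exterior solutions of the quasi-electrostatic Poisson
#' equation and scale exactly as 1/sigma.
#'
#' @param sigma conductivity, S/m (> 0). Typical CNS values are on the order
#'   of 0.05-0.5 S/m.
#' @export
medium <- function(sigma) {
  if (!is.numeric(sigma) || sigma <= 0) abort_validation("sigma must be > 0")
  structure(list(sigma = sigma), class = "ephapsis_medium")
}

as_sigma <- function(x) {
  if (inherits(x, "ephapsis_medium")) x$sigma else as.numeric(x)
}

#' Sampling rule for boundary averaging
#'
#' Extracellular potentials are attached to a segment by averaging the field
#' over its boundary: `n_axial x n_azimuthal` points on a cylinder's lateral
#' surface, and a ring of `n_azimuthal` points on a great circle for a
#' sphere. Samples sit at the segment's own radius, which keeps the
#' self-coefficient finite.
#'
#' @param n_axial,n_azimuthal sample counts (>= 1).
#' @export
field_sampling <- function(n_axial = 5, n_azimuthal = 8) {
  if (n_axial < 1 || n_azimuthal < 1) {
    abort_validation("sampling must have at least one point")
  }
  list(n_axial = as.integer(n_axial), n_azimuthal = as.integer(n_azimuthal))
}

abort_singularity <- function(msg) {
  rlang::abort(msg, class = "ephapsis_singularity_error")
}

#' Line-source potential of a cylindrical segment
#'
#' Potential of a uniform line of current of length `L` in an infinite ohmic
#' medium (the line-source approximation):
#' `V = I / (4 pi sigma L) * ln| (sqrt(h^2+r^2) - h) / (sqrt(l^2+r^2) - l) |`,
#' where `r` is the perpendicular distance from the axis, `l` the signed
#' axial distance from the beginning of the cylinder, and `h = l - L` the
#' signed axial distance from its end. The form equals the exact integral of
#' point sources distributed uniformly along the axis. Units: nA, um, S/m,
#' mV.
#'
#' @param i current, nA.
#' @param r perpendicular distance from the axis, um.
#' @param l axial distance from the cylinder beginning, um (signed).
#' @param h axial distance from the cylinder end, um (signed); `L = l - h`.
#' @param med a `ephapsis_medium` or conductivity in S/m.
#' @return Potential in mV.
#' @export
line_source_potential <- function(i, r, l, h, med) {
  sigma <- as_sigma(med)
  L <- l - h
  if (any(L <= 0)) abort_validation("l - h must be positive (the cylinder length)")
  if (any(r < 1e-12 & l >= 0 & h <= 0)) {
    abort_singularity("evaluation point lies on the line source")
  }
  i / (4 * pi * sigma * L) * log(stable_sqdiff(h, r) / stable_sqdiff(l, r))
}

# sqrt(x^2 + r^2) - x without cancellation for large positive x
stable_sqdiff <- function(x, r) {
  s <- sqrt(x^2 + r^2)
  ifelse(x > 0, r^2 / (s + x), s - x)
}

#' Point-source potential of a spherical segment
#'
#' Exterior solution for a spherical current source,
#' `V = I / (4 pi sigma max(R, r_sphere))`: outside the sphere the potential
#' decays as 1/R; evaluation points at or below the sphere surface take the
#' surface value (the exterior solution is constant on the surface, and the
#' clamp keeps self-coefficients finite).
#'
#' @param i current, nA.
#' @param R distance from the sphere centre, um (>= 0).
#' @param r_sphere sphere radius, um.
#' @inheritParams line_source_potential
#' @return Potential in mV.
#' @export
point_source_potential <- function(i, R, r_sphere, med) {
  sigma <- as_sigma(med)
  if (any(R < 0)) abort_validation("R must be >= 0")
  i / (4 * pi * sigma * pmax(R, r_sphere))
}

## ---- vectorized kernels over point sets ------------------------------------

# coefficient (mV/nA) of a line source from a to b at points (m x 3).
# clamp_r: for boundary averaging, points closer to the axis than the
# source cylinder's radius (possible for touching collinear segments) are
# evaluated at the lateral surface, the cylinder analogue of the sphere
# surface clamp; probe evaluation passes no clamp and reports a singularity.
line_coef_points <- function(points, a, b, sigma, context = "evaluation point",
                             clamp_r = NULL) {
  d <- b - a
  L <- sqrt(sum(d^2))
  s <- d / L
  rel <- sweep(points, 2, a)
  l <- as.vector(rel %*% s)
  h <- l - L
  perp2 <- pmax(rowSums(rel^2) - l^2, 0)
  r <- sqrt(perp2)
  if (!is.null(clamp_r)) r <- pmax(r, clamp_r)
  on_axis <- r < 1e-9 & l >= -1e-9 & h <= 1e-9
  if (any(on_axis)) {
    abort_singularity(paste0(context, " ", which(on_axis)[1],
                             " lies on a line-source axis"))
  }
  log(stable_sqdiff(h, r) / stable_sqdiff(l, r)) / (4 * pi * sigma * L)
}

# coefficient (mV/nA) of a spherical source at points (m x 3)
point_coef_points <- function(points, center, r_sphere, sigma) {
  R <- sqrt(rowSums(sweep(points, 2, center)^2))
  1 / (4 * pi * sigma * pmax(R, r_sphere))
}

# two unit vectors orthogonal to u
orthobasis <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  rbind(e1, e2)
}

# boundary sample points of one segment (row of the segment table)
segment_samples <- function(seg, sampling) {
  r <- seg$radius
  if (seg$kind == "sphere") {
    th <- 2 * pi * (seq_len(sampling$n_azimuthal) - 1) / sampling$n_azimuthal
    cbind(seg$x + r * cos(th), seg$y + r * sin(th), rep(seg$z, length(th)))
  } else {
    a <- c(seg$x0, seg$y0, seg$z0)
    b <- c(seg$x1, seg$y1, seg$z1)
    u <- (b - a) / sqrt(sum((b - a)^2))
    eb <- orthobasis(u)
    fr <- (seq_len(sampling$n_axial) - 0.5) / sampling$n_axial
    th <- 2 * pi * (seq_len(sampling$n_azimuthal) - 1) / sampling$n_azimuthal
    grid <- expand.grid(fr = fr, th = th)
    axial <- matrix(a, nrow(grid), 3, byrow = TRUE) +
      outer(grid$fr, b - a)
    axial + r * (cos(grid$th) %o% eb[1, ] + sin(grid$th) %o% eb[2, ])
  }
}

# kernel of source segment j evaluated at arbitrary points
source_coef_points <- function(points, seg, sigma, context = "evaluation point",
                               clamp = FALSE) {
  if (seg$kind == "sphere") {
    point_coef_points(points, c(seg$x, seg$y, seg$z), seg$radius, sigma)
  } else {
    line_coef_points(points, c(seg$x0, seg$y0, seg$z0),
                     c(seg$x1, seg$y1, seg$z1), sigma, context,
                     clamp_r = if (clamp) seg$radius else NULL)
  }
}

#' Boundary-averaged coupling coefficient between two segments
#'
#' Mean of the source segment's potential kernel (line source for cylinders,
#' point source for spheres) over sample points on the target segment's
#' boundary, in mV/nA.
#'
#' @param source,target rows of a segment table (see [segment_table()]).
#' @param med a `ephapsis_medium` or conductivity, S/m.
#' @param sampling a [field_sampling()].
#' @return Coefficient, mV/nA.
#' @export
boundary_averaged_coefficient <- function(source, target, med,
                                          sampling = field_sampling()) {
  sigma <- as_sigma(med)
  pts <- segment_samples(as.list(target), sampling)
  mean(source_coef_points(pts, as.list(source), sigma, "boundary sample",
                          clamp = TRUE))
}

#' Transfer matrix: segment currents to boundary-averaged potentials
#'
#' Dense `n x n` matrix whose entry `(i, j)` is the boundary-averaged
#' potential at segment `i` per unit membrane current from segment `j`
#' (mV/nA). Because the underlying Poisson equation is linear, superposition
#' holds: the potentials of any current pattern are `T %*% I_m`. Entries
#' scale exactly as 1/sigma.
#'
#' @param net a discretized `ephapsis_network`.
#' @inheritParams boundary_averaged_coefficient
#' @return A matrix with attributes `sigma_used` and `sampling`.
#' @export
build_transfer_matrix <- function(net, med, sampling = field_sampling()) {
  sigma <- as_sigma(med)
  segs <- segment_table(net)
  n <- nrow(segs)
  seg_list <- split(segs, seq_len(n))
  pts_list <- lapply(seg_list, function(s) segment_samples(as.list(s), sampling))
  npts <- vapply(pts_list, nrow, 1L)
  all_pts <- do.call(rbind, pts_list)
  grp <- rep(seq_len(n), npts)
  tm <- matrix(0, n, n)
  for (j in seq_len(n)) {
    k <- source_coef_points(all_pts, as.list(seg_list[[j]]), sigma,
                            "boundary sample", clamp = TRUE)
    tm[, j] <- as.vector(tapply(k, grp, mean))
  }
  attr(tm, "sigma_used") <- sigma
  attr(tm, "sampling") <- sampling
  tm
}

## ---- probes ----------------------------------------------------------------

#' Probe grids
#'
#' `probe_points()` builds a probe grid from explicit coordinates;
#' `probe_line()` places `n` probes evenly along a line segment.
#'
#' @param x,y,z coordinates, um.
#' @param labels probe identifiers.
#' @param from,to line endpoints, 3-vectors in um.
#' @param n number of probes.
#' @return A tibble with columns `x`, `y`, `z`, `label`.
#' @export
probe_points <- function(x, y, z, labels = NULL) {
  p <- tibble::tibble(x = x, y = y, z = z,
                      label = labels %||% paste0("p", seq_along(x)))
  if (anyDuplicated(p[c("x", "y", "z")])) {
    abort_validation("probe points must be distinct")
  }
  p
}

#' @rdname probe_points
#' @export
probe_line <- function(from, to, n, labels = NULL) {
  fr <- seq(0, 1, length.out = n)
  probe_points(from[1] + fr * (to[1] - from[1]),
               from[2] + fr * (to[2] - from[2]),
               from[3] + fr * (to[3] - from[3]), labels)
}

#' Probe coefficients and post-hoc LFPs
#'
#' `probe_coefficients()` returns the `m x n` matrix mapping per-segment
#' membrane currents (nA) to potentials (mV) at `m` probe points, using the
#' closed-form line/point-source kernels. `quadrature_probe_coefficients()`
#' computes the same matrix by dense numerical quadrature - each cylinder is
#' replaced by `n_sub` equal point sources along its axis - and serves as an
#' independent cross-check of the closed forms. `evaluate_probes()` applies
#' the coefficients to a recorded current time series: a purely post-hoc
#' (open-loop) field computation usable on any simulation result.
#'
#' @param net a discretized `ephapsis_network`.
#' @param probes a probe tibble (see [probe_points()]).
#' @param med a `ephapsis_medium` or conductivity, S/m.
#' @param n_sub number of point-source subdivisions per cylinder.
#' @param currents `n_segments x n_times` membrane currents, nA.
#' @param times optional time grid, ms.
#' @return Coefficients: an `m x n` matrix. `evaluate_probes()`: a tibble
#'   with columns `time`, `probe`, `v_mV` (matrix in attribute `"matrix"`).
#' @export
probe_coefficients <- function(net, probes, med) {
  sigma <- as_sigma(med)
  segs <- segment_table(net)
  pts <- as.matrix(probes[, c("x", "y", "z")])
  coef <- matrix(0, nrow(pts), nrow(segs))
  for (j in seq_len(nrow(segs))) {
    coef[, j] <- source_coef_points(pts, as.list(segs[j, ]), sigma, "probe")
  }
  dimnames(coef) <- list(probes$label, NULL)
  coef
}

#' @rdname probe_coefficients
#' @export
quadrature_probe_coefficients <- function(net, probes, med, n_sub = 10000) {
  sigma <- as_sigma(med)
  segs <- segment_table(net)
  pts <- as.matrix(probes[, c("x", "y", "z")])
  coef <- matrix(0, nrow(pts), nrow(segs))
  for (j in seq_len(nrow(segs))) {
    s <- as.list(segs[j, ])
    if (s$kind == "sphere") {
      coef[, j] <- point_coef_points(pts, c(s$x, s$y, s$z), s$radius, sigma)
    } else {
      a <- c(s$x0, s$y0, s$z0)
      b <- c(s$x1, s$y1, s$z1)
      fr <- (seq_len(n_sub) - 0.5) / n_sub
      # sum over sub-sources in chunks to bound memory
      acc <- numeric(nrow(pts))
      chunk <- 2000L
      for (start in seq(1L, n_sub, by = chunk)) {
        id <- start:min(start + chunk - 1L, n_sub)
        sub <- matrix(a, length(id), 3, byrow = TRUE) + outer(fr[id], b - a)
        dx <- outer(pts[, 1], sub[, 1], "-")
        dy <- outer(pts[, 2], sub[, 2], "-")
        dz <- outer(pts[, 3], sub[, 3], "-")
        acc <- acc + rowSums(1 / sqrt(dx^2 + dy^2 + dz^2))
      }
      coef[, j] <- acc / (4 * pi * sigma * n_sub)
    }
  }
  dimnames(coef) <- list(probes$label, NULL)
  coef
}

#' @rdname probe_coefficients
#' @export
evaluate_probes <- function(net, currents, probes, med, times = NULL) {
  currents <- as.matrix(currents)
  if (nrow(currents) != nrow(segment_table(net))) {
    abort_validation("currents must have one row per segment")
  }
  coef <- probe_coefficients(net, probes, med)
  v <- coef %*% currents
  tt <- times %||% seq_len(ncol(v))
  out <- tibble::tibble(
    time = rep(tt, each = nrow(v)),
    probe = rep(probes$label, ncol(v)),
    v_mV = as.vector(v)
  )
  attr(out, "matrix") <- v
  out
}

#' Potential imposed by an extracellular stimulus
#'
#' Point electrodes add a point-source potential `I/(4 pi sigma R)` at each
#' evaluation point; parallel plates add the linear potential
#' `V(x) = -E . x`. Both superpose with the neural sources into the
#' extracellular potential.
#'
#' @param spec an extracellular `ephapsis_stimulus` (see [point_electrode()]).
#' @param points `m x 3` matrix of evaluation points, um.
#' @param med a `ephapsis_medium` or conductivity, S/m.
#' @param t time, ms (for sinusoidal waveforms).
#' @return Potentials, mV.
#' @export
extracellular_stimulus_field <- function(spec, points, med, t = 0) {
  sigma <- as_sigma(med)
  points <- rbind(points)
  amp <- stimulus_current(spec, t)
  if (spec$kind == "point") {
    R <- sqrt(rowSums(sweep(points, 2, spec$position)^2))
    if (any(R < 1e-9)) {
      abort_singularity("evaluation at the electrode location")
    }
    amp / (4 * pi * sigma * R)
  } else if (spec$kind == "plates") {
    -as.vector(points %*% spec$field) * amp
  } else {
    abort_validation("unknown extracellular stimulus kind")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
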