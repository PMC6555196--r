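#' Geometric sections: spheres and cylinders
#'
#' Cells are assembled from *sections*, the geometric primitives of
#' compartmental modelling: spheres for somata and cylinders for axons and
#' dendrites. A cylinder is described by its proximal point (end 0), a unit
#' orientation vector and a length; end 1 is the distal point. Each section
#' carries its own passive membrane properties and the tag of the membrane
#' model bound to it at assembly time.
#'
#' @param name section identifier, unique within a cell.
#' @param radius radius in um (> 0).
#' @param center sphere centre, 3-vector in um.
#' @param length cylinder length in um (> 0).
#' @param proximal cylinder proximal point (end 0), 3-vector in um.
#' @param orientation unit 3-vector from proximal to distal end.
#' @param nseg number of segments the cylinder is split into (>= 1); spheres
#'   always have a single segment.
#' @param cm specific membrane capacitance, uF/cm^2.
#' @param ra axial resistivity, Ohm cm.
#' @param model tag of the membrane model attached to this section.
#' @return A `ephapsis_section` object.
#' @examples
#' sphere_section("soma", radius = 10)
#' cylinder_section("axon", radius = 1, length = 1000, nseg = 41)
#' @export
sphere_section <- function(name, radius, center = c(0, 0, 0),
                           cm = 1, ra = 100, model = "hh") {
  check_positive(radius, "radius")
  sec <- list(
    name = as.character(name), kind = "sphere", radius = radius,
    length = NA_real_, proximal = as.numeric(center),
    orientation = c(NA_real_, NA_real_, NA_real_),
    nseg = 1L, cm = cm, ra = ra, model_tag = model
  )
  structure(sec, class = "ephapsis_section")
}

#' @rdname sphere_section
#' @export
cylinder_section <- function(name, radius, length, proximal = c(0, 0, 0),
                             orientation = c(1, 0, 0), nseg = 1L,
                             cm = 1, ra = 100, model = "hh") {
  check_positive(radius, "radius")
  check_positive(length, "length")
  if (nseg < 1 || nseg != round(nseg)) {
    abort_validation("nseg must be a positive integer")
  }
  nrm <- sqrt(sum(orientation^2))
  if (abs(nrm - 1) > 1e-9) {
    if (nrm == 0) abort_validation("orientation must be a nonzero vector")
    orientation <- orientation / nrm
  }
  sec <- list(
    name = as.character(name), kind = "cylinder", radius = radius,
    length = length, proximal = as.numeric(proximal),
    orientation = as.numeric(orientation),
    nseg = as.integer(nseg), cm = cm, ra = ra, model_tag = model
  )
  structure(sec, class = "ephapsis_section")
}

check_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort_validation(paste0(what, " must be a positive number"))
  }
}

abort_validation <- function(msg) {
  rlang::abort(msg, class = "ephapsis_validation_error")
}
abort_naming <- function(msg) {
  rlang::abort(msg, class = "ephapsis_naming_error")
}
abort_format <- function(msg) {
  rlang::abort(msg, class = "ephapsis_format_error")
}

#' Build a cell from sections
#'
#' A cell is an ordered collection of sections plus the electrical
#' connections between their ends. `connect()` attaches `end_a` of section
#' `sec_a` onto `end_b` of section `sec_b` (child onto parent); the touching
#' end segments are coupled axially after discretization. Ends are `0`
#' (proximal) and `1` (distal); a sphere's single node serves as both ends.
#'
#' @param name cell identifier.
#' @param cl a `ephapsis_cell`.
#' @param section a `ephapsis_section`.
#' @param sec_a,sec_b section names.
#' @param end_a,end_b ends, `0` or `1`.
#' @return The modified cell.
#' @examples
#' bs <- cell("ball_and_stick") |>
#'   add_section(sphere_section("soma", radius = 10)) |>
#'   add_section(cylinder_section("axon", radius = 1, length = 1000,
#'                                proximal = c(10, 0, 0), nseg = 41)) |>
#'   connect("axon", 0, "soma", 1)
#' @export
cell <- function(name) {
  structure(list(name = as.character(name), sections = list(),
                 connections = list()),
            class = "ephapsis_cell")
}

#' @rdname cell
#' @export
add_section <- function(cl, section) {
  stopifnot(inherits(cl, "ephapsis_cell"))
  if (!inherits(section, "ephapsis_section")) {
    abort_validation("add_section() requires a ephapsis_section")
  }
  if (section$name %in% names(cl$sections)) {
    abort_naming(paste0("duplicate section name: '", section$name, "'"))
  }
  cl$sections[[section$name]] <- section
  cl
}

#' @rdname cell
#' @export
connect <- function(cl, sec_a, end_a, sec_b, end_b) {
  stopifnot(inherits(cl, "ephapsis_cell"))
  for (s in c(sec_a, sec_b)) {
    if (!s %in% names(cl$sections)) {
      abort_validation(paste0("unknown section: '", s, "'"))
    }
  }
  if (!end_a %in% c(0, 1) || !end_b %in% c(0, 1)) {
    abort_validation("ends must be 0 (proximal) or 1 (distal)")
  }
  child_key <- paste0(sec_a, "|", end_a)
  used <- vapply(cl$connections, function(cn) paste0(cn$sec_a, "|", cn$end_a), "")
  if (child_key %in% used) {
    abort_validation(paste0("end ", end_a, " of section '", sec_a,
                            "' is already attached to a parent"))
  }
  # cycle check: section graph must remain a forest
  comp <- section_components(cl)
  if (comp[sec_a] == comp[sec_b]) {
    abort_validation(paste0("connecting '", sec_a, "' to '", sec_b,
                            "' would create a cycle"))
  }
  cl$connections[[length(cl$connections) + 1L]] <-
    list(sec_a = sec_a, end_a = as.integer(end_a),
         sec_b = sec_b, end_b = as.integer(end_b))
  cl
}

# connected components of the section graph (union-find)
section_components <- function(cl) {
  nm <- names(cl$sections)
  parent <- stats::setNames(seq_along(nm), nm)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (cn in cl$connections) {
    ra <- find(match(cn$sec_a, nm)); rb <- find(match(cn$sec_b, nm))
    if (ra != rb) parent[ra] <- rb
  }
  stats::setNames(vapply(seq_along(nm), function(i) unname(find(i)), 1L), nm)
}

#' Networks: placed copies of cells
#'
#' A network is the whole simulated system, whether it holds one compartment
#' or many cells. `place()` adds a deep copy of a cell with a rigid
#' transformation (rotation then offset) applied to all of its coordinates.
#'
#' @param net a `ephapsis_network`.
#' @param cl a `ephapsis_cell`.
#' @param offset 3-vector, um.
#' @param rotation 3x3 orthonormal matrix (mirror placements allowed).
#' @return The modified network.
#' @examples
#' ax <- cell("axon") |>
#'   add_section(cylinder_section("axon", radius = 1, length = 1000, nseg = 41))
#' net <- network() |>
#'   place(ax) |>
#'   place(ax, offset = c(0, 0, 100))
#' @export
network <- function() {
  structure(list(placements = list(), segments = NULL, axial = NULL),
            class = "ephapsis_network")
}

#' @rdname network
#' @export
place <- function(net, cl, offset = c(0, 0, 0), rotation = diag(3)) {
  stopifnot(inherits(net, "ephapsis_network"), inherits(cl, "ephapsis_cell"))
  rotation <- as.matrix(rotation)
  if (!isTRUE(all.equal(crossprod(rotation), diag(3), tolerance = 1e-8))) {
    abort_validation("rotation must be orthonormal")
  }
  moved <- cl
  for (nm in names(moved$sections)) {
    s <- moved$sections[[nm]]
    s$proximal <- as.numeric(rotation %*% s$proximal + offset)
    if (s$kind == "cylinder") {
      s$orientation <- as.numeric(rotation %*% s$orientation)
    }
    moved$sections[[nm]] <- s
  }
  net$placements[[length(net$placements) + 1L]] <-
    list(cell = moved, offset = as.numeric(offset), rotation = rotation)
  net$segments <- NULL  # invalidate any previous discretization
  net$axial <- NULL
  net
}

#' Discretize a network into segments
#'
#' Splits every cylinder section into `nseg` equal-length segments and turns
#' each sphere into a single isopotential segment. Axial resistances follow
#' the standard half-segment series rule `R = Ra * l / (pi r^2)` where `l`
#' sums the two half-segment lengths on either side of the interface; a
#' sphere is treated as isopotential, so a sphere-to-cylinder interface
#' carries only the cylinder's half-segment resistance.
#'
#' @param net a `ephapsis_network`.
#' @return The network with `$segments` (a tibble, one row per segment with
#'   ids `1..n`) and `$axial` (a tibble of symmetric axial resistances in
#'   MOhm, listed once with `i < j`).
#' @export
discretize <- function(net) {
  stopifnot(inherits(net, "ephapsis_network"))
  if (length(net$placements) == 0) {
    abort_validation("network has no cells")
  }
  seg_rows <- list()
  ax_rows <- list()
  next_id <- 1L
  for (ci in seq_along(net$placements)) {
    cl <- net$placements[[ci]]$cell
    if (length(cl$sections) > 1) {
      comp <- section_components(cl)
      if (length(unique(comp)) > 1) {
        abort_validation(paste0("cell '", cl$name, "' has disconnected sections"))
      }
    }
    # per-section first/last segment ids and half resistances
    sec_first <- sec_last <- integer(0)
    sec_half <- numeric(0)
    for (nm in names(cl$sections)) {
      s <- cl$sections[[nm]]
      if (s$kind == "sphere") {
        id <- next_id
        seg_rows[[length(seg_rows) + 1L]] <- tibble::tibble(
          id = id, cell_index = ci, cell = cl$name, section = nm,
          seg_index = 1L, kind = "sphere", radius = s$radius,
          x = s$proximal[1], y = s$proximal[2], z = s$proximal[3],
          x0 = s$proximal[1], y0 = s$proximal[2], z0 = s$proximal[3],
          x1 = s$proximal[1], y1 = s$proximal[2], z1 = s$proximal[3],
          length = 0, area = 4 * pi * s$radius^2,
          cm = s$cm, ra = s$ra, model_tag = s$model_tag
        )
        sec_first[nm] <- sec_last[nm] <- id
        sec_half[nm] <- 0  # isopotential sphere: no internal access resistance
        next_id <- next_id + 1L
      } else {
        lseg <- s$length / s$nseg
        ks <- seq_len(s$nseg)
        starts <- outer((ks - 1) * lseg, s$orientation) +
          matrix(s$proximal, s$nseg, 3, byrow = TRUE)
        ends <- starts + matrix(s$orientation * lseg, s$nseg, 3, byrow = TRUE)
        ctr <- (starts + ends) / 2
        ids <- next_id + ks - 1L
        seg_rows[[length(seg_rows) + 1L]] <- tibble::tibble(
          id = ids, cell_index = ci, cell = cl$name, section = nm,
          seg_index = ks, kind = "cylinder", radius = s$radius,
          x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
          x0 = starts[, 1], y0 = starts[, 2], z0 = starts[, 3],
          x1 = ends[, 1], y1 = ends[, 2], z1 = ends[, 3],
          length = lseg, area = 2 * pi * s$radius * lseg,
          cm = s$cm, ra = s$ra, model_tag = s$model_tag
        )
        rhalf <- s$ra * (lseg / 2) / (pi * s$radius^2) * .u("raxial_to_MOhm")
        if (s$nseg > 1) {
          ax_rows[[length(ax_rows) + 1L]] <- tibble::tibble(
            i = ids[-s$nseg], j = ids[-1], r_mohm = 2 * rhalf
          )
        }
        sec_first[nm] <- ids[1]
        sec_last[nm] <- ids[s$nseg]
        sec_half[nm] <- rhalf
        next_id <- next_id + s$nseg
      }
    }
    end_seg <- function(nm, end) if (end == 0) sec_first[[nm]] else sec_last[[nm]]
    for (cn in cl$connections) {
      ia <- end_seg(cn$sec_a, cn$end_a)
      ib <- end_seg(cn$sec_b, cn$end_b)
      r <- sec_half[[cn$sec_a]] + sec_half[[cn$sec_b]]
      if (r <= 0) {
        # two spheres joined directly: give them a nominal small resistance
        # rather than a short circuit
        abort_validation("cannot connect two spheres directly")
      }
      ax_rows[[length(ax_rows) + 1L]] <- tibble::tibble(
        i = min(ia, ib), j = max(ia, ib), r_mohm = r
      )
    }
  }
  net$segments <- dplyr::bind_rows(seg_rows)
  net$axial <- if (length(ax_rows)) dplyr::bind_rows(ax_rows) else
    tibble::tibble(i = integer(0), j = integer(0), r_mohm = numeric(0))
  net
}

#' @export
print.ephapsis_network <- function(x, ...) {
  cat("<ephapsis_network> ", length(x$placements), " cell(s)", sep = "")
  if (!is.null(x$segments)) {
    cat(", ", nrow(x$segments), " segments (discretized)", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
print.ephapsis_cell <- function(x, ...) {
  cat("<ephapsis_cell> '", x$name, "': ", length(x$sections), " section(s), ",
      length(x$connections), " connection(s)\n", sep = "")
  invisible(x)
}

# number of segments of a discretized network
n_segments <- function(net) {
  if (is.null(net$segments)) abort_validation("network is not discretized")
  nrow(net$segments)
}

#' Segment table of a discretized network
#'
#' @param net a discretized `ephapsis_network`.
#' @return A tibble with one row per segment (id, cell, section, geometry,
#'   membrane area and passive properties).
#' @export
segment_table <- function(net) {
  if (is.null(net$segments)) net <- discretize(net)
  net$segments
}

# ids of the segments belonging to one placed cell
cell_segment_ids <- function(net, cell_index) {
  net$segments$id[net$segments$cell_index == cell_index]
}

# dense axial conductance matrix in uS (off-diagonal 1/R, zero row sums)
axial_conductance_matrix <- function(net) {
  n <- n_segments(net)
  a <- matrix(0, n, n)
  if (nrow(net$axial)) {
    g <- 1 / net$axial$r_mohm  # uS; mV * uS = nA... (mV/MOhm = nA)
    idx <- cbind(net$axial$i, net$axial$j)
    a[idx] <- a[idx] + g
    a[idx[, 2:1, drop = FALSE]] <- a[idx[, 2:1, drop = FALSE]] + g
  }
  diag(a) <- -rowSums(a)
  a
}
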