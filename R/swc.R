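#' Read and write SWC morphologies
#'
#' Parses the standard 7-column SWC dialect (`id type x y z radius parent`,
#' `#` comments, whitespace separation) into a cell. Soma records (type 1)
#' are collapsed into a single equivalent sphere of equal total surface area
#' centred at the area-weighted centroid of the soma points; every other
#' record becomes one cylinder section running from its parent's coordinate
#' to its own, preserving the tree topology. Records must be topologically
#' sorted (a parent appears before its children) and only the first record
#' may be a root (`parent = -1`).
#'
#' @param x path to an SWC file, or a character vector of SWC lines.
#' @param cell_name name given to the resulting cell.
#' @param model membrane model tag given to all sections.
#' @param nseg number of segments per cylinder section.
#' @return A `ephapsis_cell`.
#' @export
read_swc <- function(x, cell_name = "swc_cell", model = "hh", nseg = 1L) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readLines(x)
  } else {
    unlist(strsplit(x, "\n"))
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) abort_format("SWC input has no records")
  fields <- strsplit(lines, "[[:space:]]+")
  bad <- which(vapply(fields, length, 1L) != 7)
  if (length(bad)) {
    abort_format(paste0("SWC line ", bad[1], " does not have 7 columns"))
  }
  m <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  )
  if (anyNA(m)) abort_format("SWC contains a non-numeric field")
  colnames(m) <- c("id", "type", "x", "y", "z", "radius", "parent")
  rec <- tibble::as_tibble(m)
  if (any(rec$parent == -1 & seq_len(nrow(rec)) != 1)) {
    abort_format("SWC has a root record (parent = -1) that is not the first record")
  }
  if (rec$parent[1] != -1) abort_format("first SWC record must be a root (parent = -1)")
  idx_of <- match(rec$parent, rec$id)
  late <- which(rec$parent != -1 & (is.na(idx_of) | idx_of >= seq_len(nrow(rec))))
  if (length(late)) {
    abort_format(paste0("SWC record ", rec$id[late[1]],
                        " references an absent or later parent"))
  }
  if (rec$type[1] != 1) {
    abort_format("root SWC record must be a soma point (type 1)")
  }

  soma <- rec[rec$type == 1, ]
  w <- soma$radius^2
  soma_center <- c(sum(soma$x * w), sum(soma$y * w), sum(soma$z * w)) / sum(w)
  soma_radius <- sqrt(sum(soma$radius^2))  # equal total surface area
  cl <- cell(cell_name) |>
    add_section(sphere_section("soma", radius = soma_radius,
                               center = soma_center, model = model))

  # section name per record id; soma points all map to "soma"
  sec_of <- stats::setNames(rep(NA_character_, nrow(rec)), rec$id)
  sec_of[as.character(soma$id)] <- "soma"

  for (k in seq_len(nrow(rec))) {
    r <- rec[k, ]
    if (r$type == 1) next
    pk <- idx_of[k]
    p <- rec[pk, ]
    from <- c(p$x, p$y, p$z)
    to <- c(r$x, r$y, r$z)
    v <- to - from
    len <- sqrt(sum(v^2))
    if (len <= 0) abort_format(paste0("SWC record ", r$id, " has zero length"))
    nm <- paste0("n", format(r$id, scientific = FALSE, trim = TRUE))
    cl <- add_section(cl, cylinder_section(
      nm, radius = r$radius, length = len, proximal = from,
      orientation = v / len, nseg = nseg, model = model
    ))
    parent_sec <- sec_of[[as.character(p$id)]]
    parent_end <- if (parent_sec == "soma") 1L else 1L
    cl <- connect(cl, nm, 0L, parent_sec, parent_end)
    sec_of[[as.character(r$id)]] <- nm
  }
  cl
}

#' @rdname read_swc
#' @param cl a cell previously produced by `read_swc()` (one sphere soma plus
#'   cylinder sections whose proximal points coincide with their parents'
#'   distal points).
#' @param path optional output file; when `NULL` the SWC lines are returned.
#' @export
write_swc <- function(cl, path = NULL) {
  stopifnot(inherits(cl, "ephapsis_cell"))
  if (!"soma" %in% names(cl$sections) || cl$sections$soma$kind != "sphere") {
    abort_validation("write_swc() requires a cell with a sphere section named 'soma'")
  }
  nm <- names(cl$sections)
  ids <- stats::setNames(seq_along(nm), nm)
  parent_of <- stats::setNames(rep(NA_character_, length(nm)), nm)
  for (cn in cl$connections) parent_of[cn$sec_a] <- cn$sec_b
  fmt <- function(v) format(v, digits = 12, scientific = FALSE, trim = TRUE)
  out <- character(length(nm))
  for (k in seq_along(nm)) {
    s <- cl$sections[[nm[k]]]
    if (s$kind == "sphere") {
      out[k] <- paste(k, 1, fmt(s$proximal[1]), fmt(s$proximal[2]),
                      fmt(s$proximal[3]), fmt(s$radius), -1)
    } else {
      distal <- s$proximal + s$orientation * s$length
      pid <- if (is.na(parent_of[nm[k]])) -1 else ids[[parent_of[nm[k]]]]
      out[k] <- paste(k, 3, fmt(distal[1]), fmt(distal[2]), fmt(distal[3]),
                      fmt(s$radius), pid)
    }
  }
  out <- c("# SWC written by ephapsis", out)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(path)
}
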