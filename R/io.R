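#' Persist and reload simulation results
#'
#' Results are written as a directory of full-precision CSV files (one per
#' array: `times`, `vm`, `vout`, `im`, plus `segments` and a `meta.json`
#' with the schema version, solver options, seed and geometry hash). The
#' CSV writer emits shortest round-trip representations, so a write/read
#' cycle reproduces every double bitwise.
#'
#' @param res a `ephapsis_result`.
#' @param path directory to create/fill.
#' @return `write_result()`: the path, invisibly. `read_result()`: a
#'   `ephapsis_result`.
#' @export
write_result <- function(res, path) {
  stopifnot(inherits(res, "ephapsis_result"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  # %.17g guarantees the shortest exact round trip for doubles
  wr <- function(m, f) {
    txt <- matrix(sprintf("%.17g", t(m)), nrow = ncol(m))
    writeLines(apply(txt, 1, paste, collapse = ","), file.path(path, f))
  }
  writeLines(sprintf("%.17g", res$times), file.path(path, "times.csv"))
  wr(res$vm, "vm.csv")
  if (!is.null(res$vout)) wr(res$vout, "vout.csv")
  if (!is.null(res$i_m)) wr(res$i_m, "im.csv")
  data.table::fwrite(res$segments, file.path(path, "segments.csv"))
  meta <- list(
    schema_version = "1.0",
    n_segments = nrow(res$vm), n_times = length(res$times),
    mode = res$mode, sigma = res$sigma, seed = res$seed,
    geometry_hash = res$geometry_hash,
    options = unclass(res$options),
    has_vout = !is.null(res$vout), has_im = !is.null(res$i_m)
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) abort_format("not a result directory: missing meta.json")
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(meta$schema_version, "1.0")) {
    abort_format(paste0("result schema version '", meta$schema_version,
                        "' not supported (reader version 1.0)"))
  }
  rd <- function(f, nr, nc) {
    m <- t(as.matrix(data.table::fread(file.path(path, f), header = FALSE)))
    if (nrow(m) != nr || ncol(m) != nc) {
      abort_format(paste0(f, " is truncated or malformed: expected ", nr, " x ",
                          nc, ", got ", nrow(m), " x ", ncol(m)))
    }
    dimnames(m) <- NULL
    m
  }
  times <- data.table::fread(file.path(path, "times.csv"), header = FALSE)[[1]]
  if (length(times) != meta$n_times) abort_format("times.csv is truncated")
  vm <- rd("vm.csv", meta$n_segments, meta$n_times)
  vout <- if (isTRUE(meta$has_vout)) rd("vout.csv", meta$n_segments, meta$n_times)
  i_m <- if (isTRUE(meta$has_im)) rd("im.csv", meta$n_segments, meta$n_times)
  segs <- tibble::as_tibble(data.table::fread(file.path(path, "segments.csv")))
  structure(list(
    times = times, vm = vm, vout = vout, i_m = i_m, gating = NULL,
    segments = segs, mode = meta$mode, sigma = meta$sigma,
    options = meta$options, seed = meta$seed,
    geometry_hash = meta$geometry_hash
  ), class = "ephapsis_result")
}
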