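#' Experiment configuration files
#'
#' Experiments can be described in a small YAML dialect in which every
#' physical quantity carries its unit in the key name (unit mistakes are
#' the dominant failure mode in this domain). Top-level blocks:
#'
#' ```yaml
#' name: axon_demo
#' seed: 1
#' geometry:
#'   fixture: axon            # or swc: path/to/cell.swc
#'   params: {nseg: 41, length_um: 1000, diameter_um: 2}
#' dynamics:
#'   model: hh                # hh | passive
#'   params: {}               # model parameter overrides
#' stimuli:
#'   - {type: dc, target: 1, amplitude_nA: 0.5}
#'   - {type: sine, target: 1, amplitude_nA: 0.1, frequency_Hz: 10, phase_rad: 0}
#' medium:
#'   sigma_S_per_m: 0.3       # or sweep_S_per_m: [0.05, 0.5]
#' solver:
#'   mode: closed_loop        # closed_loop | open_loop
#'   formulation: eliminated_ode
#'   rel_tol: 1.0e-6
#'   abs_tol_mV: 1.0e-8
#'   dense_output_dt_ms: 0.025
#'   t_total_ms: 30
#' analysis:
#'   enabled: false
#'   window_ms: [1000, 2000]
#'   bin_width_ms: 1
#'   threshold_mV: 0
#'   refractory_ms: 2
#' output:
#'   dir: results
#' ```
#'
#' `parse_config()` validates the keys (unknown keys are an error listing
#' them), fills every default explicitly, and returns a
#' `ephapsis_config`; `serialize_config()` writes it back to YAML such
#' that `parse_config(serialize_config(cfg))` is the identity.
#'
#' @param x a file path or YAML text.
#' @param cfg a `ephapsis_config`.
#' @return `parse_config()`: a `ephapsis_config` list.
#'   `serialize_config()`: YAML text.
#' @export
parse_config <- function(x) {
  raw <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    yaml::read_yaml(x)
  } else {
    yaml::yaml.load(paste(x, collapse = "\n"))
  }
  defaults <- config_defaults()
  check_keys(raw, names(defaults), "top level")
  cfg <- modifyList(defaults, raw)

  check_keys(cfg$geometry, c("fixture", "swc", "params"), "geometry")
  check_keys(cfg$dynamics, c("model", "params"), "dynamics")
  check_keys(cfg$medium, c("sigma_S_per_m", "sweep_S_per_m"), "medium")
  check_keys(cfg$solver, c("mode", "formulation", "rel_tol", "abs_tol_mV",
                           "dense_output_dt_ms", "t_total_ms"), "solver")
  check_keys(cfg$analysis, c("enabled", "window_ms", "bin_width_ms",
                             "threshold_mV", "refractory_ms"), "analysis")
  check_keys(cfg$output, c("dir"), "output")
  for (i in seq_along(cfg$stimuli)) {
    check_keys(cfg$stimuli[[i]],
               c("type", "target", "amplitude_nA", "frequency_Hz", "phase_rad"),
               paste0("stimuli[", i, "]"))
  }
  if (is.null(cfg$geometry$fixture) && is.null(cfg$geometry$swc)) {
    abort_validation("geometry must name a fixture or an swc file")
  }
  if (!cfg$dynamics$model %in% c("hh", "passive")) {
    abort_validation(paste0("unknown model '", cfg$dynamics$model, "'"))
  }
  sweep <- cfg$medium$sweep_S_per_m
  if (!is.null(sweep) && !length(sweep)) {
    abort_validation("sweep_S_per_m must be a non-empty list")
  }
  structure(cfg, class = "ephapsis_config")
}

config_defaults <- function() {
  list(
    name = "experiment",
    seed = 1L,
    geometry = list(fixture = "axon", swc = NULL, params = list()),
    dynamics = list(model = "hh", params = list()),
    stimuli = list(list(type = "dc", target = 1L, amplitude_nA = 0.5)),
    medium = list(sigma_S_per_m = 0.3, sweep_S_per_m = NULL),
    solver = list(mode = "open_loop", formulation = "eliminated_ode",
                  rel_tol = 1e-6, abs_tol_mV = 1e-8,
                  dense_output_dt_ms = 0.025, t_total_ms = 30),
    analysis = list(enabled = FALSE, window_ms = NULL, bin_width_ms = 1,
                    threshold_mV = 0, refractory_ms = 2),
    output = list(dir = "results")
  )
}

check_keys <- function(block, known, where) {
  if (is.null(block)) return(invisible())
  unknown <- setdiff(names(block), known)
  if (length(unknown)) {
    abort_validation(paste0("unknown key(s) in ", where, ": ",
                            paste(unknown, collapse = ", ")))
  }
  invisible()
}

#' @rdname parse_config
#' @export
serialize_config <- function(cfg) {
  # NULL-valued defaults are omitted on output and restored on parsing
  drop_nulls <- function(x) {
    if (!is.list(x)) return(x)
    x <- x[!vapply(x, is.null, TRUE)]
    lapply(x, drop_nulls)
  }
  yaml::as.yaml(drop_nulls(unclass(cfg)))
}

config_fixture_params <- function(p) {
  out <- list()
  if (!is.null(p$nseg)) out$nseg <- as.integer(p$nseg)
  if (!is.null(p$length_um)) out$length <- p$length_um
  if (!is.null(p$diameter_um)) out$diameter <- p$diameter_um
  if (!is.null(p$soma_radius_um)) out$soma_radius <- p$soma_radius_um
  if (!is.null(p$pitch_um)) out$pitch <- p$pitch_um
  out
}

config_stimuli <- function(cfg) {
  lapply(cfg$stimuli, function(s) {
    if (s$type == "dc") {
      dc_stimulus(s$target, s$amplitude_nA)
    } else if (s$type == "sine") {
      sine_stimulus(s$target, s$amplitude_nA, s$frequency_Hz, s$phase_rad %||% 0)
    } else {
      abort_validation(paste0("unknown stimulus type '", s$type, "'"))
    }
  })
}

#' Run a configured experiment
#'
#' Builds the network, assembles and solves the system once per
#' conductivity (a single sigma or a sweep), optionally runs the
#' phase-locking analysis, and persists everything under the configured
#' output directory together with a run manifest (config copy, seed,
#' package version, wall time). Identical config + seed reproduce every
#' numeric output bitwise.
#'
#' @param cfg a `ephapsis_config` (or a path/text accepted by
#'   [parse_config()]).
#' @param out_dir overrides the configured output directory.
#' @return Invisibly, a character vector of artifact paths.
#' @export
run_experiment <- function(cfg, out_dir = NULL) {
  if (!inherits(cfg, "ephapsis_config")) cfg <- parse_config(cfg)
  t_start <- Sys.time()
  out_dir <- out_dir %||% cfg$output$dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  net <- if (!is.null(cfg$geometry$swc)) {
    cl <- read_swc(cfg$geometry$swc, model = cfg$dynamics$model)
    discretize(place(network(), cl))
  } else {
    fp <- config_fixture_params(cfg$geometry$params)
    fp$model <- cfg$dynamics$model
    fixture_network(cfg$geometry$fixture, fp)
  }
  model <- if (cfg$dynamics$model == "hh") {
    hh_model(cfg$dynamics$params)
  } else {
    do.call(passive_model, cfg$dynamics$params)
  }
  models <- stats::setNames(list(model), cfg$dynamics$model)
  opts <- solver_options(
    rel_tol = cfg$solver$rel_tol, abs_tol = cfg$solver$abs_tol_mV,
    mode = cfg$solver$mode, formulation = cfg$solver$formulation,
    seed = cfg$seed, dense_output_dt = cfg$solver$dense_output_dt_ms
  )
  sigmas <- cfg$medium$sweep_S_per_m %||% cfg$medium$sigma_S_per_m
  results <- list()
  for (sg in sigmas) {
    sys <- assemble(net, models = models, stimuli = config_stimuli(cfg),
                    med = medium(sg), options = opts)
    res <- if (cfg$solver$mode == "closed_loop") {
      solve_closed_loop(sys, c(0, cfg$solver$t_total_ms))
    } else {
      solve_open_loop(sys, c(0, cfg$solver$t_total_ms))
    }
    tag <- paste0("sigma_", format(sg, scientific = TRUE))
    p <- file.path(out_dir, paste0(cfg$name, "_", tag))
    write_result(res, p)
    paths <- c(paths, p)
    results[[tag]] <- res
  }

  if (isTRUE(cfg$analysis$enabled) &&
      length(unique(net$segments$cell_index)) >= 2) {
    rows <- list()
    for (tag in names(results)) {
      sm <- bundle_locking_summary(results[[tag]], condition = tag,
                                   window = cfg$analysis$window_ms,
                                   bin_width = cfg$analysis$bin_width_ms,
                                   threshold = cfg$analysis$threshold_mV,
                                   refractory = cfg$analysis$refractory_ms)
      rows[[tag]] <- dplyr::mutate(sm$pairs, condition = tag, .before = 1)
    }
    lp <- file.path(out_dir, paste0(cfg$name, "_locking.csv"))
    data.table::fwrite(dplyr::bind_rows(rows), lp)
    paths <- c(paths, lp)
  }

  manifest <- list(
    config = unclass(cfg), seed = cfg$seed,
    package_version = as.character(utils::packageVersion("ephapsis")),
    wall_time_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    artifacts = paths
  )
  mp <- file.path(out_dir, paste0(cfg$name, "_manifest.json"))
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(paths, mp))
}
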