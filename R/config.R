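# YAML run configuration with a strict schema: unknown keys are rejected,
# defaults are materialized on load, and a loaded config resolves to a
# scan_spec. CLI flags override config keys (documented in the CLI script).

config_defaults <- function() {
  list(model = "full",
       variants = NULL,          # defaults to `model` when unset
       objective = "parp_cleavage",
       regulator = "XIAP",
       values = 0,
       n_live = 16000,
       termination_tol = 1e-4,
       seed = 1L,
       max_evaluations = 1e6,
       proposal = "single_ellipsoid",
       overrides = NULL,
       t_end = 20000,
       n_points = 201,
       output_dir = ".")
}

objective_selectors <- function() {
  c("parp_cleavage", "flux_caspase", "flux_mitochondrial", "flux_total")
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, rejects unknown keys, materializes defaults
#' (production sampler settings: 16,000 live points, termination tolerance
#' 1e-4) and validates the objective selector and model names.
#'
#' @param path YAML file. A `values` key may either be a numeric vector or
#'   a `{from, to, by}` map describing a regulator grid.
#' @return A `run_config` list.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defaults <- config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, raw, keep.null = TRUE)
  if (is.list(cfg$values) && all(c("from", "to", "by") %in%
                                 names(cfg$values))) {
    cfg$values <- seq(cfg$values$from, cfg$values$to, by = cfg$values$by)
  }
  cfg$values <- as.numeric(unlist(cfg$values))
  if (!cfg$objective %in% objective_selectors()) {
    stop("unknown objective '", cfg$objective, "'; choose one of: ",
         paste(objective_selectors(), collapse = ", "), call. = FALSE)
  }
  known_models <- c(names(subnetwork_variants()),
                    unname(subnetwork_variants()))
  for (m in c(cfg$model, cfg$variants)) {
    if (!m %in% known_models) {
      stop("unknown model '", m, "'; catalogue: ",
           paste(unname(subnetwork_variants()), collapse = ", "),
           call. = FALSE)
    }
  }
  if (is.null(cfg$variants)) cfg$variants <- cfg$model
  cfg$n_live <- as.integer(cfg$n_live)
  cfg$seed <- as.integer(cfg$seed)
  if (!is.null(cfg$overrides)) cfg$overrides <- unlist(cfg$overrides)
  structure(cfg, class = "run_config")
}

#' Write a configuration back to YAML
#'
#' `load_config(dump_config(cfg, path))` reproduces `cfg` exactly.
#' @param config A `run_config`.
#' @param path Output YAML file.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  out <- unclass(config)
  out$overrides <- if (!is.null(out$overrides)) as.list(out$overrides)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Resolve a configuration to a scan specification
#'
#' @param config A `run_config` from [load_config()].
#' @return A [scan_spec()].
#' @export
as_scan_spec <- function(config) {
  scan_spec(
    variants = config$variants,
    regulator = config$regulator,
    values = config$values,
    objective = config$objective,
    config = ns_config(n_live = config$n_live,
                       termination_tol = config$termination_tol,
                       seed = config$seed,
                       max_evaluations = config$max_evaluations,
                       proposal = config$proposal),
    overrides = config$overrides,
    sim = sim_settings(t_end = config$t_end, n_points = config$n_points))
}
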