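section_defaults <- function(fn, drop = character()) {
  fm <- formals(fn)
  fm <- fm[setdiff(names(fm), c(drop, "..."))]
  lapply(fm, function(x) if (is.call(x) || is.name(x)) NULL else x)
}

config_skeleton <- function() {
  list(
    seed = 1L,
    outdir = ".",
    glt1 = section_defaults(glt1_params),
    ions = section_defaults(ion_state),
    membrane = section_defaults(membrane_params),
    morphology = section_defaults(morphology_config),
    stimulus = section_defaults(stimulus_field),
    reversal = list(v_policy = "resting", V_fixed = -85),
    analysis = list(tail_window = c(50, 400), baseline_rule = "extrapolate",
                    tail_method = "least_squares",
                    tau_bounds = c(0.1, 1e4)),
    synth = section_defaults(synth_config)
  )
}

check_keys <- function(supplied, allowed, where) {
  bad <- setdiff(names(supplied), allowed)
  if (length(bad)) {
    stop("load_config: unknown key", if (length(bad) > 1) "s" else "", " ",
         paste0('"', bad, '"', collapse = ", "),
         " in section `", where, "`", call. = FALSE)
  }
}

#' Load a run configuration from a YAML file
#'
#' Defaults are the published model parameters; the file overrides them.
#' Unknown keys are rejected by name. An empty (or missing-section) file
#' yields the full default configuration.
#'
#' Sections: `glt1`, `ions`, `membrane`, `morphology`, `stimulus`,
#' `reversal` (`v_policy`, `V_fixed`), `analysis` (`tail_window`,
#' `baseline_rule`, `tail_method`, `tau_bounds`), `synth`, plus top-level
#' `seed` and `outdir`. Keys mirror the corresponding constructor arguments
#' (e.g. `k12`..`k61`, `p16`, `density` under `glt1`).
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#'
#' @return A list of class `"run_config"` with constructed parameter objects
#'   (`glt1`, `ions`, `membrane`, `morphology`, `stimulus`), the raw merged
#'   values (`$raw`), `seed`, `outdir`, `reversal`, `analysis` and the
#'   `synth` section (as arguments for [synth_config()]).
#' @examples
#' cfg <- load_config(NULL)
#' cfg$glt1
#' @export
load_config <- function(path = NULL) {
  skel <- config_skeleton()
  user <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("load_config: no such file: ", path, call. = FALSE)
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  }
  if (!is.list(user)) stop("load_config: config must be a YAML mapping", call. = FALSE)
  check_keys(user, names(skel), "(top level)")
  merged <- skel
  for (sec in names(user)) {
    if (is.list(skel[[sec]]) && !is.null(names(skel[[sec]]))) {
      check_keys(user[[sec]], names(skel[[sec]]), sec)
      for (k in names(user[[sec]])) merged[[sec]][[k]] <- user[[sec]][[k]]
    } else {
      merged[[sec]] <- user[[sec]]
    }
  }
  strip_null <- function(x) x[!vapply(x, is.null, logical(1))]
  build <- function(fn, args) do.call(fn, strip_null(args))
  cfg <- list(
    seed = as.integer(merged$seed),
    outdir = merged$outdir,
    glt1 = build(glt1_params, merged$glt1),
    ions = build(ion_state, merged$ions),
    membrane = build(membrane_params, merged$membrane),
    morphology = build(morphology_config, merged$morphology),
    stimulus = build(stimulus_field, merged$stimulus),
    reversal = merged$reversal,
    analysis = merged$analysis,
    synth = strip_null(merged$synth),
    raw = merged
  )
  class(cfg) <- "run_config"
  cfg
}

#' Write the fully resolved configuration next to run outputs
#'
#' @param config A `"run_config"` from [load_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_resolved_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  raw <- config$raw
  raw$package_version <- as.character(utils::packageVersion("gluptake"))
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> seed", x$seed, "outdir", x$outdir, "\n")
  cat("  sections: glt1, ions, membrane, morphology, stimulus, reversal, analysis, synth\n")
  invisible(x)
}
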