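#' Read and validate a run configuration
#'
#' Run configurations are YAML with one section per pipeline stage plus
#' shared `system`, `cvs`, `seed`, `outdir` and `stages` keys.  Unknown
#' top-level keys are rejected with an explicit message; every stochastic
#' stage requires a seed (a global `seed` suffices).
#'
#' @param path Path to a YAML config file.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
  attr(cfg, "path") <- path
  class(cfg) <- "run_config"
  cfg
}

.known_stages <- c("synth", "zts", "string", "metad", "fes", "cluster",
                   "network", "classify", "density", "rmsf", "drive")
.stochastic_stages <- c("synth", "string", "metad", "rmsf")

#' @rdname read_run_config
#' @param cfg A configuration list (already parsed).
#' @export
validate_run_config <- function(cfg) {
  allowed <- c("seed", "outdir", "stages", "system", "cvs", .known_stages)
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$stages)) stop("missing required config key: stages")
  bad <- setdiff(cfg$stages, .known_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  needs_seed <- intersect(cfg$stages, .stochastic_stages)
  for (st in needs_seed) {
    if (is.null(cfg$seed) && is.null(cfg[[st]]$seed))
      stop(sprintf("stochastic stage '%s' requires a seed (key: seed)", st))
  }
  invisible(TRUE)
}

# Build a toy_system from a config section (stage-level overrides global).
.config_system <- function(cfg, stage = NULL) {
  sc <- cfg[[stage]]$system %||% cfg$system
  if (is.null(sc)) stop("missing required config key: system")
  if (is.null(sc$kind)) stop("missing required config key: system.kind")
  args <- sc
  args$kind <- NULL
  known <- c("temperature", "friction", "timestep", "mass", "seed")
  fixed <- args[intersect(names(args), known)]
  pot <- args[setdiff(names(args), known)]
  # unnamed nested numeric lists are reference matrices given row-wise
  pot <- lapply(pot, function(v)
    if (is.list(v) && is.null(names(v)) &&
        all(vapply(v, is.numeric, TRUE)))
      do.call(rbind, v) else v)
  do.call(toy_system, c(list(kind = sc$kind), pot, fixed))
}

.config_cvs <- function(cfg, stage = NULL) {
  cvs <- cfg[[stage]]$cvs %||% cfg$cvs
  if (is.null(cvs)) stop("missing required config key: cvs")
  lapply(cvs, function(cv) {
    switch(cv$kind,
      "cartesian" = cv_cartesian(cv$particle, cv$dim %||% 1),
      "distance" = cv_distance(cv$i, cv$j),
      "com-distance" = cv_com_distance(unlist(cv$group1),
                                       unlist(cv$group2)),
      "contact-map" = cv_contact_map(read_contact_map(cv$file),
                                     reference = cv$reference %||% "inactive",
                                     variant = cv$variant %||% "literal"),
      stop("unknown CV kind: ", cv$kind))
  })
}

#' Write a run manifest
#'
#' The manifest records everything needed to re-execute a run
#' bit-identically: package version, config file checksum, effective seeds,
#' input checksums and per-stage output paths.  It is written atomically
#' (temp file + rename).
#'
#' @param path Output JSON path.
#' @param config The [read_run_config()] used.
#' @param outputs Named list of produced file paths, by stage.
#' @param seeds Named list of effective seeds.
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(path, config, outputs, seeds = list()) {
  cfg_path <- attr(config, "path")
  existing <- unlist(outputs)[file.exists(unlist(outputs))]
  manifest <- list(
    package = "pathdyn",
    version = as.character(utils::packageVersion("pathdyn")),
    config = cfg_path,
    config_md5 = if (!is.null(cfg_path)) unname(tools::md5sum(cfg_path))
                 else NA_character_,
    seeds = seeds,
    outputs = outputs,
    output_md5 = as.list(tools::md5sum(existing)))
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, path)
  invisible(manifest)
}

#' Re-execute a run from its manifest
#'
#' Reads a manifest written by [write_run_manifest()], verifies that the
#' recorded config file still has the recorded checksum, and re-runs the
#' pipeline from it; with the recorded seeds this reproduces the original
#' outputs bit-identically.
#'
#' @param manifest_path Path to a `manifest.json`.
#' @param outdir Output directory for the re-run (default: alongside the
#'   manifest).
#' @return Named list of output paths by stage, invisibly.
#' @export
rerun_from_manifest <- function(manifest_path, outdir = NULL) {
  man <- jsonlite::read_json(manifest_path)
  if (is.null(man$config) || !file.exists(man$config))
    stop("manifest does not point to an existing config file")
  if (!is.null(man$config_md5) &&
      !identical(unname(tools::md5sum(man$config)), man$config_md5))
    stop("config file has changed since the manifest was written")
  run_pipeline(read_run_config(man$config),
               outdir = outdir %||% dirname(manifest_path))
}
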