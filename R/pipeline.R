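## Orchestration: structured run configuration (YAML), validation, and the
## end-to-end report command that runs every applicable stage on a
## trajectory and writes CSV/JSON products plus a provenance manifest.

#' Load a run configuration
#'
#' Reads a YAML run configuration, filling unset keys from the versioned
#' default file shipped with the package
#' (`system.file("extdata", "default_config.yaml", package = "k2pflex")`),
#' so every analysis parameter in any output is traceable to the config or
#' a documented default.
#'
#' @param path YAML file path, or NULL for the shipped defaults.
#' @return a `run_config` list.
#' @export
run_config <- function(path = NULL) {
  def <- yaml::read_yaml(system.file("extdata", "default_config.yaml",
                                     package = "k2pflex"))
  cfg <- if (is.null(path)) def else utils::modifyList(def, yaml::read_yaml(path))
  structure(cfg, class = "run_config")
}

#' Validate a run configuration
#'
#' Checks selections, site intervals and numeric parameters before any
#' computation.
#'
#' @param config a [run_config()] list.
#' @return character vector of problems (empty = valid).
#' @export
validate_config <- function(config) {
  probs <- character()
  num <- function(key, lo = 0) {
    v <- config[[key]]
    if (!is.null(v) && (!is.numeric(v) || v <= lo))
      probs <<- c(probs, sprintf("%s must be a number > %g (got %s)",
                                 key, lo, format(v)))
  }
  num("raster"); num("slice_thickness"); num("bin_width_nm")
  num("margin", -1e-9); num("contact_threshold")
  num("stride_ps"); num("smooth_ps"); num("dwell_ps")
  num("dewetting_threshold"); num("dewetting_min_duration")
  s <- config$filter_sites
  if (!is.null(s)) {
    zmin <- unlist(lapply(s, `[[`, "zmin"))
    zmax <- unlist(lapply(s, `[[`, "zmax"))
    nm <- names(s)
    if (any(zmin >= zmax))
      probs <- c(probs, paste("filter site with zmin >= zmax:",
                              paste(nm[zmin >= zmax], collapse = ", ")))
    o <- order(-zmax)
    for (k in seq_len(length(nm) - 1)) {
      hi <- o[k]; lo <- o[k + 1]
      if (zmax[lo] > zmin[hi])
        probs <- c(probs, sprintf("overlapping filter sites %s and %s",
                                  nm[hi], nm[lo]))
    }
  }
  for (key in c("tm_ranges", "gating")) {
    if (is.null(config[[key]]))
      probs <- c(probs, paste("missing config section:", key))
  }
  probs
}

.write_stage_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis report
#'
#' Executes every stage applicable to the inputs named in the config --
#' RMSD against the down/up references, gating distances, event detection,
#' state classification, landscape table, and (when a bilayer/box is
#' present) area per lipid -- and writes the CSV/JSON products plus a
#' provenance manifest (package version, config hash, per-file checksums)
#' to `out_dir`.  Deterministic given inputs and seed; any stage error
#' aborts the run, names the stage, and removes partial outputs.
#'
#' @param config a [run_config()]; must name `topology` and `trajectory`
#'   files, plus `down_ref`/`up_ref` PDB paths for the reference stages.
#' @param out_dir output directory (created; must not exist or be empty).
#' @return invisibly, the manifest list.
#' @export
run_report <- function(config, out_dir) {
  probs <- validate_config(config)
  if (length(probs) > 0)
    stop("invalid config:\n  ", paste(probs, collapse = "\n  "))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0)
    stop("output directory exists and is not empty: ", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  stage <- "setup"
  on_fail <- function(e) {
    unlink(file.path(out_dir, basename(written)))
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }
  manifest <- tryCatch({
    stage <- "read inputs"
    for (f in c(config$topology, config$trajectory))
      if (!file.exists(f)) stop("missing input file: ", f)
    traj <- read_trajectory(config$topology, config$trajectory)
    pairs <- gating_pairs(atom = config$gating$atom %||% "CA")
    stage <- "gating distances"
    gd <- gating_distances(traj, pairs)
    written <- c(written, .write_stage_csv(as.data.frame(gd),
                                           file.path(out_dir, "gating.csv")))
    refs_avail <- !is.null(config$down_ref) && !is.null(config$up_ref)
    if (refs_avail) {
      stage <- "read references"
      for (f in c(config$down_ref, config$up_ref))
        if (!file.exists(f)) stop("missing input file: ", f)
      down <- read_structure(config$down_ref)
      up <- read_structure(config$up_ref)
      stage <- "rmsd"
      spec <- selection_spec(atom_names = "CA",
                             resid_ranges = config$tm_ranges)
      rmsd <- data.frame(time = traj$times,
                         rmsd_down = rmsd_series(traj, down, spec)$rmsd,
                         rmsd_up = rmsd_series(traj, up, spec)$rmsd)
      written <- c(written, .write_stage_csv(rmsd,
                                             file.path(out_dir, "rmsd.csv")))
      stage <- "classification"
      cls <- classify_states(traj, down, up, spec,
                             margin = config$margin %||% 0.5)
      written <- c(written, .write_stage_csv(cls,
                                             file.path(out_dir, "states.csv")))
      stage <- "landscape"
      ls <- landscape_table(traj, list(down = down, up = up), pairs,
                            stride_ps = config$stride_ps %||% 1000)
      written <- c(written, .write_stage_csv(ls,
                                             file.path(out_dir, "landscape.csv")))
      stage <- "event detection"
      dv <- gating_distances(down, pairs)
      uv <- gating_distances(up, pairs)
      mget3 <- function(g) list(fenestration = mean(g$fenestration),
                                zipper = mean(g$zipper),
                                expansion = mean(g$expansion))
      ev <- detect_event_sequence(gd, mget3(dv), mget3(uv),
                                  smooth_ps = config$smooth_ps %||% 5000,
                                  dwell_ps = config$dwell_ps %||% 10000)
      evp <- file.path(out_dir, "events.json")
      jsonlite::write_json(ev, evp, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null")
      written <- c(written, evp)
    }
    if (!is.null(config$n_lipids_per_leaflet) && !is.null(traj$box)) {
      stage <- "area per lipid"
      apl <- area_per_lipid(traj, config$n_lipids_per_leaflet)
      written <- c(written, .write_stage_csv(apl,
                                             file.path(out_dir, "apl.csv")))
    }
    stage <- "manifest"
    cfg_file <- tempfile(fileext = ".yaml")
    yaml::write_yaml(unclass(config), cfg_file)
    man <- list(
      package = "k2pflex",
      version = as.character(utils::packageVersion("k2pflex")),
      config_md5 = unname(tools::md5sum(cfg_file)),
      seed = config$seed %||% NA,
      files = as.list(tools::md5sum(sort(written))))
    names(man$files) <- basename(names(man$files))
    unlink(cfg_file)
    jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    man
  }, error = on_fail)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
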