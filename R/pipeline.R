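#' Run the full simulate -> insertion -> profile pipeline
#'
#' Orchestrates one reproducible end-to-end run: synthetic constant-pH /
#' pH-replica-exchange simulation ([run_simulation()]), insertion-depth
#' computation against the local phosphate reference
#' ([compute_insertion()]), and profile construction ([build_profiles()]).
#' All stage outputs are written as TSV/JSON under `out_dir` (via a
#' temporary file plus rename, so partially written tables are never left
#' behind), and a run manifest recording the configuration, seeds, file
#' paths and per-stage record counts is written last.  Identical
#' `(config, seed)` pairs produce identical outputs.
#'
#' @param config a [sim_config()], or a path to a YAML config file.
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed; overrides `config$seed` and fans out to
#'   the simulation and bootstrap stages.
#' @param bin_width depth bin width (A) for the profiles.
#' @param bootstraps Bayesian bootstraps per ok bin.
#' @param radius,min_atoms local phosphate reference parameters.
#' @param write_trajectory also persist the raw frame table (large).
#' @return the run manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, bin_width = 1.0,
                         bootstraps = 1000L, radius = 6, min_atoms = 10L,
                         write_trajectory = TRUE) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  stage <- "simulate"
  manifest <- list(package_version = as.character(utils::packageVersion("memtitrate")),
                   seed = config$seed, config = unclass(config),
                   stages = list())
  on_fail <- function(e) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    atomic_json(manifest, file.path(out_dir, "manifest.json"))
    stop(e)
  }
  tryCatch({
    bundle <- run_simulation(config)
    n_frames <- nrow(bundle$frames)
    if (write_trajectory) {
      paths$frames <- file.path(out_dir, "frames.tsv")
      atomic_write(function(p) write_frames(bundle, p,
                     membrane_path = file.path(out_dir, "frames_membrane.tsv")),
                   paths$frames)
      paths$membrane <- file.path(out_dir, "frames_membrane.tsv")
    } else {
      paths$membrane <- file.path(out_dir, "membrane.tsv")
      atomic_write(function(p) write_membrane(bundle$snapshots, p),
                   paths$membrane)
    }
    manifest$stages$simulate <- list(n_frames = n_frames,
                                     n_replicates = config$n_replicates,
                                     n_replicas = length(config$pH_ladder))

    stage <- "insertion"
    records <- compute_insertion(bundle, radius = radius,
                                 min_atoms = min_atoms)
    paths$records <- file.path(out_dir, "records.tsv")
    atomic_write(function(p) utils::write.table(records, p, sep = "\t",
                                                row.names = FALSE,
                                                quote = FALSE),
                 paths$records)
    manifest$stages$insertion <- list(n_records = nrow(records),
                                      n_dropped = n_frames - nrow(records),
                                      n_fallback = sum(records$fallback_used))

    stage <- "profile"
    profiles <- build_profiles(records, config = config,
                               bin_width = bin_width,
                               bootstraps = bootstraps)
    prof_dir <- file.path(out_dir, "profiles")
    write_profiles(profiles, prof_dir)
    paths$profiles <- prof_dir
    manifest$stages$profile <- list(
      n_analysed = profiles$params$n_analysed_records,
      n_burned = nrow(records) - profiles$params$n_analysed_records,
      n_outside_range = profiles$params$n_outside_range,
      n_bins = nrow(profiles$pka_profile),
      n_ok = sum(profiles$pka_profile$status == "ok"))
  }, error = on_fail)

  manifest$paths <- lapply(paths, normalizePath)
  stopifnot(all(vapply(manifest$paths, file.exists, TRUE)))
  atomic_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

atomic_write <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

atomic_json <- function(x, path) {
  atomic_write(function(p) jsonlite::write_json(x, p, auto_unbox = TRUE,
                                                digits = NA, pretty = TRUE,
                                                force = TRUE),
               path)
}
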