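#' Read and write event logs
#'
#' Event logs are TSV files with columns `actor`, `behaviour`, `t_start_s`,
#' `t_end_s`, `attributes` (a JSON string, possibly empty). Reading
#' validates each row: `t_end >= t_start` is required and, in strict mode,
#' behaviour labels must come from the controlled vocabulary.
#'
#' @param path File path.
#' @param strict Reject unknown behaviour labels (default) or pass them
#'   through.
#' @return `read_events()`: the event tibble. `write_events()`: `path`,
#'   invisibly.
#' @export
read_events <- function(path, strict = TRUE) {
  ev <- readr::read_tsv(path, col_types = readr::cols(
    actor = readr::col_character(),
    behaviour = readr::col_character(),
    t_start_s = readr::col_double(),
    t_end_s = readr::col_double(),
    attributes = readr::col_character()
  ), na = character(), quote = "")
  bad <- which(ev$t_end_s < ev$t_start_s)
  if (length(bad))
    abort(sprintf("malformed event rows (t_end < t_start) at line(s): %s",
                  paste(bad + 1L, collapse = ", ")))
  if (strict) {
    unk <- setdiff(unique(ev$behaviour), behaviour_vocabulary())
    if (length(unk))
      abort(sprintf("unknown behaviour label(s): %s",
                    paste(unk, collapse = ", ")))
  }
  ev
}

#' @rdname read_events
#' @param events Event tibble.
#' @export
write_events <- function(events, path) {
  stopifnot(all(c("actor", "behaviour", "t_start_s", "t_end_s") %in%
                  names(events)))
  if (!"attributes" %in% names(events)) events$attributes <- ""
  events$attributes <- as.character(events$attributes)
  # JSON attribute strings contain quotes; no field ever contains a tab, so
  # write without quote escaping and read with quoting disabled
  readr::write_tsv(events, path, escape = "none")
  invisible(path)
}

#' Read and write spike tables
#'
#' Spike tables are TSV files with columns `unit_id`, `t_s`. Reading sorts
#' each unit's spikes and drops exact duplicate timestamps with a warning
#' reporting the count; negative times are an error.
#'
#' @param path File path.
#' @return `read_spikes()`: tibble `unit_id`, `t_s`, sorted within unit.
#' @export
read_spikes <- function(path) {
  sp <- readr::read_tsv(path, col_types = readr::cols(
    unit_id = readr::col_character(), t_s = readr::col_double()))
  if (any(sp$t_s < 0)) abort("negative spike times")
  sp <- dplyr::arrange(sp, .data$unit_id, .data$t_s)
  dup <- duplicated(sp)
  if (any(dup)) {
    warn(sprintf("%d duplicate spike timestamps dropped", sum(dup)))
    sp <- sp[!dup, ]
  }
  sp
}

#' @rdname read_spikes
#' @param spikes Spike tibble (`unit_id`, `t_s`).
#' @export
write_spikes <- function(spikes, path) {
  stopifnot(all(c("unit_id", "t_s") %in% names(spikes)))
  readr::write_tsv(spikes[c("unit_id", "t_s")], path)
  invisible(path)
}

#' Write a simulated dataset bundle
#'
#' Writes the full synthetic dataset (trajectories, events, spikes, pulses,
#' photometry, retrieval trials, ground truth) as plain TSV/JSON files plus
#' a `manifest.json` recording the seed, a config echo and per-file MD5
#' checksums; [read_bundle()] verifies the checksums on load.
#'
#' @param dir Output directory (created if needed).
#' @param session A `cage_session`.
#' @param population Output of [simulate_spike_population()] (optional).
#' @param tagging Output of [simulate_tagging_session()] (optional).
#' @param photometry Output of [simulate_photometry()] (optional).
#' @param cohort Output of [simulate_learning_cohort()] (optional).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(dir, session, population = NULL, tagging = NULL,
                         photometry = NULL, cohort = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    readr::write_tsv(df, p)
    files <<- c(files, name)
  }
  wr(session$trajectories, "trajectories.tsv")
  write_events(session$events, file.path(dir, "events.tsv"))
  files <- c(files, "events.tsv")
  if (!is.null(population)) {
    write_spikes(population$spikes, file.path(dir, "spikes.tsv"))
    files <- c(files, "spikes.tsv")
  }
  if (!is.null(tagging)) {
    wr(tagging$pulses, "pulses.tsv")
    write_spikes(tagging$spikes, file.path(dir, "tagging_spikes.tsv"))
    files <- c(files, "tagging_spikes.tsv")
  }
  if (!is.null(photometry)) wr(tibble::as_tibble(photometry$trace),
                               "photometry.tsv")
  if (!is.null(cohort)) wr(cohort, "retrieval.tsv")

  truth <- list(
    chases = session$truth$chases,
    units = if (!is.null(population)) population$units else NULL,
    transients = if (!is.null(photometry)) photometry$truth else NULL
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, null = "null")
  files <- c(files, "truth.json")

  cfg <- session$config
  cfg$cohorts <- as.list(cfg$cohorts)
  manifest <- list(
    dataset_id = sprintf("nestwatch-%d", cfg$seed),
    schema_version = "1.0",
    seed = cfg$seed,
    nest = list(center = session$nest$center,
                radius_cm = session$nest$radius_cm),
    t_total_s = session$t_total_s,
    config = cfg[setdiff(names(cfg), "cohorts")],
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(dir, files))), files))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset bundle
#'
#' @param dir Bundle directory written by [write_bundle()].
#' @return List with `manifest`, `trajectories`, `events`, `nest`, and any
#'   of `spikes`, `pulses`, `tagging_spikes`, `photometry`, `retrieval`,
#'   `truth` present in the bundle.
#' @export
read_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  for (f in names(manifest$files)) {
    p <- file.path(dir, f)
    if (!file.exists(p)) abort(sprintf("bundle file missing: %s", f))
    if (!identical(unname(tools::md5sum(p)), manifest$files[[f]]))
      abort(sprintf("checksum mismatch for %s", f))
  }
  rd <- function(name, ...) {
    p <- file.path(dir, name)
    if (file.exists(p)) readr::read_tsv(p, show_col_types = FALSE) else NULL
  }
  out <- list(
    manifest = manifest,
    trajectories = rd("trajectories.tsv"),
    events = read_events(file.path(dir, "events.tsv")),
    nest = nest_region(manifest$nest$center[1], manifest$nest$center[2],
                       manifest$nest$radius_cm),
    spikes = if (file.exists(file.path(dir, "spikes.tsv")))
      read_spikes(file.path(dir, "spikes.tsv")) else NULL,
    pulses = rd("pulses.tsv"),
    tagging_spikes = if (file.exists(file.path(dir, "tagging_spikes.tsv")))
      read_spikes(file.path(dir, "tagging_spikes.tsv")) else NULL,
    photometry = rd("photometry.tsv"),
    retrieval = rd("retrieval.tsv")
  )
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj))
    out$truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
  out
}
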