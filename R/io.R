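#' Write run outputs to a directory
#'
#' Persists a completed run as plain files: the event log and occupancy /
#' queue-length series as CSV (UTF-8, comma-separated, header row), the
#' full analysis report as JSON, and a run manifest recording the seed,
#' config hash and package version.
#'
#' @param result A `hospital_sim`.
#' @param dir Output directory (created if missing).
#' @param format `"csv"`, `"json"` or `"both"`.
#' @param config_path Optional path of the config file the run used, hashed
#'   into the manifest.
#' @return Invisible character vector of the files written.
#' @export
write_result <- function(result, dir, format = c("both", "csv", "json"),
                         config_path = NULL) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  if (format %in% c("csv", "both")) {
    f <- file.path(dir, "events.csv")
    readr::write_csv(result$events, f)
    files <- c(files, f)
    f <- file.path(dir, "occupancy.csv")
    readr::write_csv(result$occupancy, f)
    files <- c(files, f)
    f <- file.path(dir, "queue_lengths.csv")
    readr::write_csv(result$queue_lengths, f)
    files <- c(files, f)
    f <- file.path(dir, "network_edges.csv")
    readr::write_csv(build_flow_network(result)$edges, f)
    files <- c(files, f)
  }
  if (format %in% c("json", "both")) {
    f <- file.path(dir, "report.json")
    write_report(analyze(result), f)
    files <- c(files, f)
  }
  manifest <- list(
    package = "wardflow",
    version = as.character(packageVersion("wardflow")),
    seed = result$seed,
    steps_run = result$steps_run,
    config_path = config_path,
    config_hash = config_hash(result$config),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = basename(files)
  )
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(c(files, mf))
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  write_config(config, tf)
  unname(tools::md5sum(tf))
}

#' Serialise a `flow_analysis` report to JSON
#' @param report A `flow_analysis` from [analyze()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  doc <- list(
    basic = as.list(report$basic),
    waiting = list(
      pct_within_target = report$waiting$pct_within_target,
      n_measured = report$waiting$n_measured,
      n_censored = report$waiting$n_censored,
      waits = report$waiting$waits
    ),
    occupancy = report$occupancy,
    network = list(
      nodes = report$network$nodes,
      edges = report$network$edges,
      statistics = report$network_stats
    ),
    journeys = list(
      journeys = report$journeys$journeys,
      path_lengths = report$journeys$path_lengths,
      n_censored = report$journeys$n_censored
    ),
    target = report$target,
    steps_run = report$steps_run
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, dataframe = "columns",
                       digits = NA, null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read an event log written by [write_result()]
#'
#' Applies a strict schema check: the five documented columns in order,
#' integer steps and ids, known event kinds.
#'
#' @param path Path to `events.csv`.
#' @return The events tibble.
#' @export
read_events <- function(path) {
  ev <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    step = readr::col_integer(),
    patient_id = readr::col_integer(),
    kind = readr::col_character(),
    from = readr::col_character(),
    to = readr::col_character()
  ), progress = FALSE))
  expected <- c("step", "patient_id", "kind", "from", "to")
  if (!identical(names(ev), expected)) {
    stop("event log schema mismatch: expected columns ",
         paste(expected, collapse = ", "), "; found ",
         paste(names(ev), collapse = ", "), call. = FALSE)
  }
  probs <- readr::problems(ev)
  if (nrow(probs) > 0) {
    stop(sprintf("event log schema mismatch at row %d, column %d: %s",
                 probs$row[1], probs$col[1], probs$expected[1]), call. = FALSE)
  }
  bad_kind <- which(!ev$kind %in% EVENT_KINDS)
  if (length(bad_kind) > 0) {
    stop(sprintf("event log schema mismatch: unknown event kind '%s' at row %d",
                 ev$kind[bad_kind[1]], bad_kind[1]), call. = FALSE)
  }
  ev
}

#' Reconstruct an analysable result from a saved event log
#'
#' Rebuilds occupancy by replaying bed movements (admissions, transfers,
#' diversions, returns, discharges) step by step, so a report generated
#' from a saved log equals the one produced at run time.
#'
#' @param events Events tibble (see [read_events()]).
#' @param config The `hospital_config` the run used.
#' @param steps_run Number of steps the run executed; defaults to the last
#'   event step.
#' @return A `hospital_sim` (without per-patient requirement list-columns).
#' @export
result_from_events <- function(events, config, steps_run = NULL) {
  stop_if_invalid(config)
  if (is.null(steps_run)) {
    steps_run <- if (nrow(events) > 0) max(events$step) else 0L
  }
  steps_run <- as.integer(steps_run)
  wards <- config$wards$id
  occ <- matrix(0L, nrow = max(steps_run, 1L), ncol = length(wards),
                dimnames = list(NULL, wards))
  level <- setNames(integer(length(wards)), wards)
  ev <- events[order(events$step), ]
  moves <- ev[ev$kind %in% c("ADMIT", "TRANSFER", "DIVERT", "RETURN",
                             "DISCHARGE"), ]
  split_steps <- split(seq_len(nrow(moves)), moves$step)
  for (s in seq_len(steps_run)) {
    rows <- split_steps[[as.character(s)]]
    if (!is.null(rows)) {
      for (r in rows) {
        k <- moves$kind[r]
        if (k != "ADMIT") level[moves$from[r]] <- level[moves$from[r]] - 1L
        if (k != "DISCHARGE") level[moves$to[r]] <- level[moves$to[r]] + 1L
      }
    }
    occ[s, ] <- level
  }
  occupancy <- if (steps_run == 0) {
    tibble::tibble(step = integer(), ward = character(), occupancy = integer())
  } else {
    tibble::tibble(
      step = rep(seq_len(steps_run), times = length(wards)),
      ward = rep(wards, each = steps_run),
      occupancy = as.integer(occ[seq_len(steps_run), ])
    )
  }
  arr <- ev[ev$kind == "ARRIVAL", ]
  dis <- ev[ev$kind == "DISCHARGE", ]
  patients <- tibble::tibble(
    id = arr$patient_id,
    arrival_step = arr$step,
    discharge_step = dis$step[match(arr$patient_id, dis$patient_id)]
  )
  structure(
    list(
      config = config,
      seed = NA_integer_,
      events = tibble::as_tibble(ev),
      occupancy = occupancy,
      queue_lengths = tibble::tibble(step = integer(), ward = character(),
                                     queue_length = integer()),
      patients = patients,
      steps_run = steps_run,
      totals = c(arrived = nrow(arr),
                 admitted = sum(ev$kind == "ADMIT" &
                                  ev$to == entry_ward(config)),
                 discharged = nrow(dis))
    ),
    class = "hospital_sim"
  )
}
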