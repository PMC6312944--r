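#' Draw the number of arrivals for one step
#'
#' Arrival pressure on the emergency department is controlled by an
#' inclusive integer range: each step's arrival count is uniform on
#' `[arrivals_min, arrivals_max]`.
#'
#' @param settings A [sim_settings()] list (or any list with `arrivals_min`
#'   and `arrivals_max`).
#' @return A single integer arrival count. Uses the current R random stream.
#' @export
sample_arrivals <- function(settings) {
  lo <- as.integer(settings$arrivals_min)
  hi <- as.integer(settings$arrivals_max)
  stopifnot(lo <= hi)
  if (lo == hi) return(lo)
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

#' Generate a required ward pathway by random walk
#'
#' Walks the ward-transition probability graph from the entry ward,
#' drawing each successor from the current ward's outgoing probability row,
#' until the absorbing `DISCHARGE` node is drawn. `DISCHARGE` itself is not
#' part of the returned pathway. Walks that visit `max_len` wards without
#' absorbing are truncated (the patient is discharged after the last ward),
#' which guarantees termination on cyclic graphs.
#'
#' @param graph Named list of named outgoing-probability vectors.
#' @param entry Entry ward id.
#' @param max_len Maximum pathway length.
#' @return Character vector of ward ids, starting at `entry`.
#' @export
#' @examples
#' g <- list(ed = c(w1 = 0.3, DISCHARGE = 0.7), w1 = c(DISCHARGE = 1))
#' set.seed(1)
#' generate_pathway(g, "ed")
generate_pathway <- function(graph, entry, max_len = 20) {
  stopifnot(entry %in% names(graph), max_len >= 1)
  path <- character(max_len)
  cur <- entry
  n <- 0L
  repeat {
    n <- n + 1L
    path[n] <- cur
    if (n >= max_len) break
    row <- graph[[cur]]
    nxt <- if (length(row) == 1L) {
      names(row)
    } else {
      names(row)[sample.int(length(row), 1L, prob = row)]
    }
    if (identical(nxt, DISCHARGE_NODE)) break
    cur <- nxt
  }
  path[seq_len(n)]
}

#' Generate one virtual patient
#'
#' Builds a patient record: a random-walk pathway plus, for every ward on
#' it, a Poisson length-of-stay requirement (clamped to at least 1 step —
#' a patient always occupies a bed for at least one step) and a Poisson
#' resource-need requirement. The patient starts in the entry ward's queue.
#'
#' @param config A validated `hospital_config`.
#' @param arrival_step Step index at which the patient arrives.
#' @param id Unique integer id (assigned in arrival order by the engine).
#' @return A list of class `wardflow_patient` with fields `id`,
#'   `arrival_step`, `pathway`, `los_required`, `need_required`,
#'   `path_position` (1 = first required ward), `location`
#'   (`"ENTRY_QUEUE"` at creation), `diverted` and `queue_entry_step`.
#' @export
generate_patient <- function(config, arrival_step, id) {
  entry <- config$wards$id[config$wards$is_entry][1]
  path <- generate_pathway(config$graph, entry,
                           config$settings$max_pathway_length)
  idx <- match(path, config$wards$id)
  los <- pmax(1, rpois(length(path), config$wards$los_lambda[idx]))
  need <- as.numeric(rpois(length(path), config$wards$need_lambda[idx]))
  structure(
    list(
      id = as.integer(id),
      arrival_step = as.integer(arrival_step),
      pathway = path,
      los_required = as.numeric(los),
      need_required = need,
      path_position = 1L,
      location = "ENTRY_QUEUE",
      diverted = FALSE,
      queue_entry_step = as.integer(arrival_step)
    ),
    class = "wardflow_patient"
  )
}

#' Sample a cohort of patients without running the simulator
#'
#' Convenience wrapper used for calibration checks and by the
#' `sample-patients` CLI subcommand: draws `n` patients as if they all
#' arrived at step 0.
#'
#' @param config A validated `hospital_config`.
#' @param n Number of patients.
#' @param seed Random seed.
#' @return A tibble with one row per patient: `id`, `arrival_step`,
#'   `pathway`, `los_required` and `need_required` (the last three are
#'   list-columns).
#' @export
sample_patients <- function(config, n, seed = config$settings$seed) {
  stop_if_invalid(config)
  with_sim_seed(seed, {
    pats <- lapply(seq_len(n), function(i) generate_patient(config, 0L, i))
    tibble::tibble(
      id = vapply(pats, `[[`, integer(1), "id"),
      arrival_step = vapply(pats, `[[`, integer(1), "arrival_step"),
      pathway = lapply(pats, `[[`, "pathway"),
      los_required = lapply(pats, `[[`, "los_required"),
      need_required = lapply(pats, `[[`, "need_required")
    )
  })
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
with_sim_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
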