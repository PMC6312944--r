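#' Hospital configuration objects
#'
#' A `hospital_config` bundles everything needed to run the simulator:
#' the ward table, the ward-transition probability graph, and the run
#' settings. Configurations are plain-text JSON on disk and validated
#' R objects in memory.
#'
#' @section Ward table:
#' One row per ward with columns `id` (lowercase snake_case key), `name`,
#' `capacity` (beds), `resources` (treatment-resource units available per
#' step), `los_lambda` (Poisson mean length of stay, in steps),
#' `need_lambda` (Poisson mean total resource need), `queue_policy`
#' (`"chronological"`, `"high_need_first"` or `"low_need_first"`),
#' `resource_policy` (`"even"`, `"high_need"` or `"low_need"`),
#' `allow_overflow` (may this ward board patients diverted from elsewhere?)
#' and `is_entry` (exactly one ward, the emergency department, is the entry
#' point).
#'
#' @section Transition graph:
#' A named list mapping each ward id to a named numeric vector of outgoing
#' transfer probabilities over wards and the reserved absorbing node
#' `"DISCHARGE"`. Each row must sum to 1 and every ward must be able to
#' reach `DISCHARGE`.
#'
#' @param wards A data frame (one row per ward) with the columns above;
#'   missing policy columns are filled with defaults
#'   (`chronological`/`even`, no overflow).
#' @param graph Named list of named numeric probability vectors.
#' @param settings Named list of run settings; see [sim_settings()].
#' @return A validated object of class `hospital_config`.
#' @seealso [default_config()], [load_config()], [validate_config()]
#' @export
#' @examples
#' cfg <- hospital_config(
#'   wards = data.frame(id = "ed", name = "ED", capacity = 5,
#'                      resources = 10, los_lambda = 2, need_lambda = 2,
#'                      is_entry = TRUE),
#'   graph = list(ed = c(DISCHARGE = 1)),
#'   settings = sim_settings(max_steps = 24)
#' )
#' validate_config(cfg)
hospital_config <- function(wards, graph, settings = sim_settings()) {
  wards <- tibble::as_tibble(wards)
  defaults <- list(
    name = NULL, queue_policy = "chronological", resource_policy = "even",
    allow_overflow = FALSE, is_entry = FALSE
  )
  if (!"name" %in% names(wards) && "id" %in% names(wards)) {
    wards$name <- wards$id
  }
  for (col in setdiff(names(defaults), "name")) {
    if (!col %in% names(wards)) wards[[col]] <- defaults[[col]]
  }
  for (col in c("capacity", "resources", "los_lambda", "need_lambda")) {
    if (col %in% names(wards)) wards[[col]] <- as.numeric(wards[[col]])
  }
  graph <- lapply(graph, function(row) {
    v <- unlist(row)
    storage.mode(v) <- "double"
    v
  })
  settings <- do.call(sim_settings, settings)
  structure(
    list(wards = wards, graph = graph, settings = settings),
    class = "hospital_config"
  )
}

#' Simulation run settings
#'
#' Bounds and global parameters of a run. Steps correspond to hours by
#' default, so the default `waiting_time_target = 4` encodes the UK 4-hour
#' A&E target.
#'
#' @param max_steps Maximum number of time steps to simulate.
#' @param max_patients Stop generating arrivals once this many patients have
#'   arrived; `Inf` disables the bound. At least one of the two bounds must
#'   be active.
#' @param arrivals_min,arrivals_max Per-step arrival count is drawn uniformly
#'   from this inclusive integer range.
#' @param waiting_time_target Target, in steps, for time from arrival to
#'   first exit from the entry ward.
#' @param seed Default random seed for [run_simulation()].
#' @param resource_unit_cost,bed_unit_cost Cost per resource unit (per bed)
#'   per step, used for the operating-cost summary.
#' @param max_pathway_length Cap on random-walk pathway length; walks that
#'   visit this many wards without absorbing are truncated.
#' @return A named list of class `sim_settings`.
#' @export
sim_settings <- function(max_steps = 720, max_patients = Inf,
                         arrivals_min = 0, arrivals_max = 4,
                         waiting_time_target = 4, seed = 42,
                         resource_unit_cost = 1, bed_unit_cost = 2,
                         max_pathway_length = 20) {
  if (is.null(max_patients)) max_patients <- Inf
  structure(
    list(
      max_steps = as.numeric(max_steps),
      max_patients = as.numeric(max_patients),
      arrivals_min = as.numeric(arrivals_min),
      arrivals_max = as.numeric(arrivals_max),
      waiting_time_target = as.numeric(waiting_time_target),
      seed = as.numeric(seed),
      resource_unit_cost = as.numeric(resource_unit_cost),
      bed_unit_cost = as.numeric(bed_unit_cost),
      max_pathway_length = as.numeric(max_pathway_length)
    ),
    class = "sim_settings"
  )
}

ward_id_pattern <- "^[a-z][a-z0-9_]*$"

#' Validate a hospital configuration
#'
#' Checks every structural invariant of a configuration and returns the
#' violations found, rather than raising. An empty result means the
#' configuration is valid.
#'
#' @param config A `hospital_config`.
#' @return A tibble with columns `path` (JSON path of the offending field),
#'   `rule` (short rule key) and `message`; zero rows when valid.
#' @export
validate_config <- function(config) {
  v <- list()
  bad <- function(path, rule, message) {
    v[[length(v) + 1L]] <<- tibble::tibble(
      path = path, rule = rule, message = message
    )
  }
  w <- config$wards
  if (!is.data.frame(w) || nrow(w) == 0) {
    bad("$.wards", "nonempty", "at least one ward is required")
    return(dplyr::bind_rows(v))
  }

  if (anyDuplicated(w$id)) {
    bad("$.wards", "unique_ids",
        paste0("duplicated ward id(s): ",
               paste(unique(w$id[duplicated(w$id)]), collapse = ", ")))
  }
  for (i in seq_len(nrow(w))) {
    id <- w$id[i]
    p <- function(f) sprintf("$.wards[%d].%s", i - 1L, f)
    if (!grepl(ward_id_pattern, id) || id %in% c(DISCHARGE_NODE, EXTERNAL_NODE)) {
      bad(p("id"), "id_format",
          sprintf("ward id '%s' must be lowercase snake_case and not reserved", id))
    }
    if (is.na(w$capacity[i]) || w$capacity[i] < 0 ||
        w$capacity[i] != floor(w$capacity[i])) {
      bad(p("capacity"), "capacity_nonneg_int",
          sprintf("ward '%s': capacity must be a non-negative integer", id))
    }
    if (is.na(w$resources[i]) || w$resources[i] < 0) {
      bad(p("resources"), "resources_nonneg",
          sprintf("ward '%s': resources must be >= 0", id))
    }
    if (is.na(w$los_lambda[i]) || w$los_lambda[i] < 0) {
      bad(p("los_lambda"), "los_lambda_nonneg",
          sprintf("ward '%s': los_lambda must be >= 0", id))
    }
    if (is.na(w$need_lambda[i]) || w$need_lambda[i] < 0) {
      bad(p("need_lambda"), "need_lambda_nonneg",
          sprintf("ward '%s': need_lambda must be >= 0", id))
    }
    if (!w$queue_policy[i] %in% list_policies("queue")) {
      bad(p("queue_policy"), "known_policy",
          sprintf("ward '%s': unknown queue policy '%s'", id, w$queue_policy[i]))
    }
    if (!w$resource_policy[i] %in% list_policies("resource")) {
      bad(p("resource_policy"), "known_policy",
          sprintf("ward '%s': unknown resource policy '%s'", id,
                  w$resource_policy[i]))
    }
  }
  n_entry <- sum(w$is_entry)
  if (n_entry != 1) {
    bad("$.wards[*].is_entry", "one_entry_ward",
        sprintf("exactly one entry ward required, found %d", n_entry))
  }

  g <- config$graph
  ids <- w$id
  if (DISCHARGE_NODE %in% names(g)) {
    bad(paste0("$.graph.", DISCHARGE_NODE), "discharge_absorbing",
        "DISCHARGE is absorbing and must have no outgoing edges")
  }
  gids <- setdiff(names(g), DISCHARGE_NODE)
  if (!setequal(gids, ids)) {
    for (u in setdiff(gids, ids)) {
      bad(paste0("$.graph.", u), "unknown_ward_id",
          sprintf("graph row for unknown ward id '%s'", u))
    }
    for (u in setdiff(ids, gids)) {
      bad(paste0("$.graph.", u), "missing_row",
          sprintf("ward '%s' has no outgoing probability row", u))
    }
  }
  for (u in intersect(gids, ids)) {
    row <- g[[u]]
    path <- paste0("$.graph.", u)
    targets <- names(row)
    if (is.null(targets) || any(!nzchar(targets))) {
      bad(path, "named_targets", sprintf("ward '%s': edges must name targets", u))
      next
    }
    unknown <- setdiff(targets, c(ids, DISCHARGE_NODE))
    if (length(unknown)) {
      bad(path, "unknown_ward_id",
          sprintf("ward '%s': edge to unknown node(s) %s", u,
                  paste(unknown, collapse = ", ")))
    }
    if (u %in% targets) {
      bad(path, "no_self_loop", sprintf("ward '%s': self-loop not allowed", u))
    }
    if (any(row < 0 | row > 1)) {
      bad(path, "prob_range",
          sprintf("ward '%s': probabilities must lie in [0, 1]", u))
    }
    if (abs(sum(row) - 1) > 1e-9) {
      bad(path, "prob_sum",
          sprintf("ward '%s': outgoing probabilities sum to %.6f, not 1", u,
                  sum(row)))
    }
  }
  # every ward must reach DISCHARGE through positive-probability edges
  if (setequal(gids, ids)) {
    reach <- DISCHARGE_NODE
    repeat {
      nxt <- ids[vapply(ids, function(u) {
        row <- g[[u]]
        any(row[names(row) %in% reach] > 0)
      }, logical(1))]
      grown <- union(reach, nxt)
      if (setequal(grown, reach)) break
      reach <- grown
    }
    for (u in setdiff(ids, reach)) {
      bad(paste0("$.graph.", u), "discharge_reachable",
          sprintf("ward '%s' cannot reach DISCHARGE", u))
    }
  }

  s <- config$settings
  active_steps <- is.finite(s$max_steps) && s$max_steps >= 1
  active_pat <- is.finite(s$max_patients) && s$max_patients >= 1
  if (!active_steps && !active_pat) {
    bad("$.settings", "bound_active",
        "at least one of max_steps >= 1 or max_patients >= 1 is required")
  }
  if (s$max_steps < 0) {
    bad("$.settings.max_steps", "nonneg", "max_steps must be >= 0")
  }
  if (s$arrivals_min < 0 || s$arrivals_min != floor(s$arrivals_min)) {
    bad("$.settings.arrivals_min", "nonneg_int",
        "arrivals_min must be a non-negative integer")
  }
  if (s$arrivals_max < s$arrivals_min) {
    bad("$.settings.arrivals_max", "range",
        "arrivals_max must be >= arrivals_min")
  }
  if (s$waiting_time_target < 1) {
    bad("$.settings.waiting_time_target", "min_one",
        "waiting_time_target must be >= 1")
  }
  if (s$max_pathway_length < 1) {
    bad("$.settings.max_pathway_length", "min_one",
        "max_pathway_length must be >= 1")
  }
  if (s$resource_unit_cost < 0 || s$bed_unit_cost < 0) {
    bad("$.settings", "cost_nonneg", "unit costs must be >= 0")
  }

  if (length(v) == 0) {
    tibble::tibble(path = character(), rule = character(), message = character())
  } else {
    dplyr::bind_rows(v)
  }
}

stop_if_invalid <- function(config) {
  viol <- validate_config(config)
  if (nrow(viol) > 0) {
    stop("invalid hospital configuration:\n",
         paste0("  - [", viol$path, "] ", viol$message, collapse = "\n"),
         call. = FALSE)
  }
  invisible(config)
}

#' Load a hospital configuration from JSON
#'
#' Reads a configuration from a JSON file or string, fills defaults for
#' omitted optional fields (policies default to chronological/even, overflow
#' off) and validates it.
#'
#' @param source Path to a JSON file, or a JSON string.
#' @return A validated `hospital_config`.
#' @export
load_config <- function(source) {
  doc <- tryCatch(
    jsonlite::fromJSON(source, simplifyVector = FALSE),
    error = function(e) stop("malformed config: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (!is.list(doc) || is.null(doc$wards) || is.null(doc$graph)) {
    stop("malformed config: top-level 'wards' and 'graph' are required",
         call. = FALSE)
  }
  wards <- dplyr::bind_rows(lapply(doc$wards, function(wd) {
    tibble::tibble(
      id = wd$id %||% NA_character_,
      name = wd$name %||% wd$id %||% NA_character_,
      capacity = as.numeric(wd$capacity %||% 0),
      resources = as.numeric(wd$resources %||% 0),
      los_lambda = as.numeric(wd$los_lambda %||% 1),
      need_lambda = as.numeric(wd$need_lambda %||% 0),
      queue_policy = wd$queue_policy %||% "chronological",
      resource_policy = wd$resource_policy %||% "even",
      allow_overflow = isTRUE(wd$allow_overflow),
      is_entry = isTRUE(wd$is_entry)
    )
  }))
  settings <- doc$settings %||% list()
  if (!is.null(settings$max_patients) && is.na(suppressWarnings(
    as.numeric(settings$max_patients)))) {
    settings$max_patients <- Inf
  }
  known <- names(formals(sim_settings))
  cfg <- hospital_config(wards, doc$graph, settings[intersect(names(settings), known)])
  stop_if_invalid(cfg)
  cfg
}

#' Serialise a hospital configuration to JSON
#'
#' @param config A `hospital_config`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `path` invisibly when writing, otherwise a JSON string.
#' @export
write_config <- function(config, path = NULL) {
  w <- config$wards
  wards <- lapply(seq_len(nrow(w)), function(i) {
    list(
      id = w$id[i], name = w$name[i],
      capacity = w$capacity[i], resources = w$resources[i],
      los_lambda = w$los_lambda[i], need_lambda = w$need_lambda[i],
      queue_policy = w$queue_policy[i], resource_policy = w$resource_policy[i],
      allow_overflow = w$allow_overflow[i], is_entry = w$is_entry[i]
    )
  })
  s <- unclass(config$settings)
  if (!is.finite(s$max_patients)) s$max_patients <- NULL
  doc <- list(wards = wards, graph = lapply(config$graph, as.list),
              settings = s)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' The shipped default hospital
#'
#' An emergency department (the entry ward) plus seven specialist wards —
#' acute assessment, surgery, cardiology, orthopaedics, general medicine,
#' geriatrics and paediatrics — with a total capacity of exactly 220 beds.
#' Arrivals are uniform on 0–4 patients per step (mean 2/hour), the
#' waiting-time target is 4 steps (the UK 4-hour A&E standard at hourly
#' steps) and runs last 720 steps (one simulated month).
#'
#' The transition probabilities and per-ward Poisson means are calibrated
#' inventions: they are chosen to produce a realistic mix of short
#' emergency-only visits and longer multi-ward journeys, with per-ward bed
#' demand (arrival rate into the ward times mean length of stay) sitting
#' below capacity so the default hospital runs near, but not over, its
#' limits. The surgical wards accept overflow boarding.
#'
#' @return A validated `hospital_config`.
#' @export
#' @examples
#' cfg <- default_config()
#' sum(cfg$wards$capacity)  # 220
default_config <- function() {
  wards <- tibble::tibble(
    id = c("ed", "acute_assessment", "surgery", "cardiology", "orthopaedics",
           "general_medicine", "geriatrics", "paediatrics"),
    name = c("Emergency Department", "Acute Assessment Unit", "Surgery",
             "Cardiology", "Orthopaedics", "General Medicine", "Geriatrics",
             "Paediatrics"),
    capacity = c(20, 60, 40, 25, 25, 30, 15, 5),
    resources = c(50, 30, 20, 15, 15, 20, 18, 6),
    los_lambda = c(2, 24, 48, 48, 72, 48, 96, 24),
    need_lambda = c(2, 24, 48, 48, 72, 48, 96, 24),
    queue_policy = "chronological",
    resource_policy = "even",
    allow_overflow = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
    is_entry = c(TRUE, rep(FALSE, 7))
  )
  graph <- list(
    ed = c(acute_assessment = 0.35, surgery = 0.07, cardiology = 0.05,
           orthopaedics = 0.05, general_medicine = 0.08, geriatrics = 0.03,
           paediatrics = 0.04, DISCHARGE = 0.33),
    acute_assessment = c(general_medicine = 0.12, surgery = 0.05,
                         cardiology = 0.05, geriatrics = 0.05,
                         orthopaedics = 0.03, DISCHARGE = 0.70),
    surgery = c(orthopaedics = 0.05, general_medicine = 0.10, DISCHARGE = 0.85),
    cardiology = c(general_medicine = 0.10, DISCHARGE = 0.90),
    orthopaedics = c(general_medicine = 0.08, DISCHARGE = 0.92),
    general_medicine = c(geriatrics = 0.12, DISCHARGE = 0.88),
    geriatrics = c(DISCHARGE = 1),
    paediatrics = c(DISCHARGE = 1)
  )
  hospital_config(wards, graph, sim_settings())
}

#' @export
print.hospital_config <- function(x, ...) {
  s <- x$settings
  cat(sprintf("<hospital_config> %d wards, %d beds\n", nrow(x$wards),
              sum(x$wards$capacity)))
  cat(sprintf("  entry ward: %s\n", x$wards$id[x$wards$is_entry]))
  cat(sprintf("  bounds: max_steps=%s max_patients=%s arrivals=[%d,%d]/step\n",
              format(s$max_steps), format(s$max_patients),
              s$arrivals_min, s$arrivals_max))
  cat(sprintf("  waiting-time target: %d steps\n", as.integer(s$waiting_time_target)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
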