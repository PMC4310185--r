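#' Entity schema and event tables
#'
#' Raw hospital data enter the package as two tidy tables.
#'
#' **Events** — one row per timestamped entity instance:
#' `patient_id` (chr), `code` (chr), `class` (chr; e.g. "diagnosis",
#' "admission", "emergency", "medication"), `kind` ("point" or "continuing"),
#' `start_date` (Date), `end_date` (Date, `NA` for point events or open
#' stays), plus optional attribute columns such as `emergency` (0/1 on
#' admission rows).
#'
#' **Schema** — one row per entity type: `code`, `class`, `kind`,
#' `parent_code` (`NA` at a root). Parent links must form a forest within
#' each class; parent-level event series aggregate their descendants via
#' [expand_hierarchy()].
#'
#' @name entity-schema
NULL

#' Read an events CSV
#'
#' @param path CSV with columns `patient_id, code, class, kind, start_date,
#'   end_date` and optional attribute columns (e.g. `emergency`).
#' @return A tibble of events with parsed dates.
#' @export
read_events <- function(path) {
  ev <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          patient_id = readr::col_character(),
                          code = readr::col_character(),
                          class = readr::col_character(),
                          kind = readr::col_character(),
                          start_date = readr::col_date(),
                          end_date = readr::col_date(),
                          .default = readr::col_guess()
                        ))
  validate_events(ev)
}

#' Read a schema CSV
#'
#' @param path CSV with columns `code, class, kind, parent_code`.
#' @return A validated schema tibble.
#' @export
read_schema <- function(path) {
  sc <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  validate_schema(sc)
}

#' Validate an events table
#'
#' Checks required columns, event kinds, and that `end_date`, when present,
#' is not before `start_date`.
#'
#' @param events Events tibble (see [entity-schema]).
#' @return The events tibble, invisibly validated.
#' @export
validate_events <- function(events) {
  need <- c("patient_id", "code", "class", "kind", "start_date")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop("events table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"end_date" %in% names(events)) events$end_date <- as.Date(NA)
  bad_kind <- setdiff(unique(events$kind), c("point", "continuing"))
  if (length(bad_kind))
    stop("unknown event kind: ", paste(bad_kind, collapse = ", "), call. = FALSE)
  bad <- !is.na(events$end_date) & events$end_date < events$start_date
  if (any(bad))
    stop(sum(bad), " event(s) have end_date before start_date", call. = FALSE)
  tibble::as_tibble(events)
}

#' Validate an entity schema
#'
#' Codes must be unique within each entity class and parent links must form
#' a forest (no cycles, parents defined in the same class).
#'
#' @param schema Schema tibble with columns `code, class, kind, parent_code`.
#' @return The schema tibble.
#' @export
validate_schema <- function(schema) {
  need <- c("code", "class", "kind")
  miss <- setdiff(need, names(schema))
  if (length(miss))
    stop("schema missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (!"parent_code" %in% names(schema)) schema$parent_code <- NA_character_
  dup <- duplicated(schema[c("class", "code")])
  if (any(dup))
    stop("duplicate schema codes within a class: ",
         paste(unique(schema$code[dup]), collapse = ", "), call. = FALSE)
  # cycle check: follow parent links from every node, bounded by tree size
  for (cl in unique(schema$class)) {
    sub <- schema[schema$class == cl, ]
    parent <- stats::setNames(sub$parent_code, sub$code)
    for (start in sub$code) {
      seen <- character(0)
      node <- start
      while (!is.na(node)) {
        if (node %in% seen)
          stop("schema parent links contain a cycle at code ", node,
               call. = FALSE)
        seen <- c(seen, node)
        node <- if (node %in% names(parent)) parent[[node]] else NA_character_
      }
    }
  }
  tibble::as_tibble(schema)
}

# ancestors of each code (excluding itself), as a named list per class
schema_ancestors <- function(schema) {
  out <- list()
  for (cl in unique(schema$class)) {
    sub <- schema[schema$class == cl, ]
    parent <- stats::setNames(sub$parent_code, sub$code)
    anc <- lapply(sub$code, function(code) {
      path <- character(0)
      node <- parent[[code]]
      while (!is.na(node) && !is.null(node)) {
        path <- c(path, node)
        node <- if (node %in% names(parent)) parent[[node]] else NA_character_
      }
      path
    })
    out[[cl]] <- stats::setNames(anc, sub$code)
  }
  out
}

#' Duplicate events onto ancestor codes
#'
#' Each event is emitted once for its own code and once for every ancestor in
#' the schema tree, so that parent-level event series aggregate child events
#' (e.g. surgery codes and their higher-level categories).
#'
#' @param events Events tibble.
#' @param schema Validated schema tibble.
#' @return Events tibble with ancestor duplicates appended; attribute columns
#'   are carried along unchanged.
#' @export
expand_hierarchy <- function(events, schema) {
  schema <- validate_schema(schema)
  anc <- schema_ancestors(schema)
  key_anc <- function(class, code) {
    a <- anc[[class]]
    if (is.null(a) || is.null(a[[code]])) character(0) else a[[code]]
  }
  uniq <- dplyr::distinct(events, .data$class, .data$code)
  uniq$ancestors <- purrr::map2(uniq$class, uniq$code, key_anc)
  uniq <- uniq[lengths(uniq$ancestors) > 0L, ]
  if (nrow(uniq) == 0L) return(events)
  extra <- purrr::pmap_dfr(uniq, function(class, code, ancestors) {
    rows <- events[events$class == class & events$code == code, ]
    purrr::map_dfr(ancestors, function(a) {
      r <- rows
      r$code <- a
      r
    })
  })
  dplyr::bind_rows(events, extra)
}

#' Discretize events onto a timeline
#'
#' Point events contribute one count at the unit containing `start_date`.
#' Continuing events contribute one count to every unit intersecting
#' `[start_date, end_date]` (a missing `end_date` is treated as a single
#' unit at the start). Overlapping stays of the same entity sum, so counts
#' can exceed one per unit. Events starting after the end of the timeline
#' are dropped with a warning.
#'
#' @param events Events tibble.
#' @param tl An [timeline()] object.
#' @return Long tibble of per-unit counts: `patient_id, class, code, t, n`.
#' @export
discretize_events <- function(events, tl) {
  events <- validate_events(events)
  if (nrow(events) == 0L)
    return(tibble::tibble(patient_id = character(), class = character(),
                          code = character(), t = integer(), n = integer()))
  t_start <- date_to_index(events$start_date, tl)
  over <- t_start > tl$n_units
  if (any(over)) {
    warning(sum(over), " event(s) past the end of the timeline were dropped",
            call. = FALSE)
    events <- events[!over, , drop = FALSE]
    t_start <- t_start[!over]
  }
  if (nrow(events) == 0L)
    return(tibble::tibble(patient_id = character(), class = character(),
                          code = character(), t = integer(), n = integer()))
  t_end <- t_start
  cont <- events$kind == "continuing" & !is.na(events$end_date)
  if (any(cont)) {
    te <- date_to_index(events$end_date[cont], tl)
    t_end[cont] <- pmin(te, tl$n_units)
  }
  span <- t_end - t_start + 1L
  long <- tibble::tibble(
    patient_id = rep(events$patient_id, span),
    class = rep(events$class, span),
    code = rep(events$code, span),
    t = unlist(purrr::map2(t_start, t_end, seq.int), use.names = FALSE)
  )
  dplyr::count(long, .data$patient_id, .data$class, .data$code, .data$t,
               name = "n")
}

#' Build the count series of one entity for one patient
#'
#' Returns the discrete-time series E(t), t = 1..T, counting occurrences of
#' `entity_code` per unit for a single patient's records.
#'
#' @param events Events tibble, already filtered to one patient.
#' @param entity_code Entity code to count.
#' @param tl An [timeline()] object.
#' @param schema Optional schema tibble; if supplied, an unknown
#'   `entity_code` is an error.
#' @return An `event_series` object: integer counts of length `tl$n_units`
#'   with `patient_id` and `entity_code` attributes.
#' @export
build_event_series <- function(events, entity_code, tl, schema = NULL) {
  if (!is.null(schema) && !entity_code %in% schema$code)
    stop("entity code not in schema: ", entity_code, call. = FALSE)
  if (length(unique(events$patient_id)) > 1L)
    stop("`events` must be filtered to a single patient", call. = FALSE)
  sub <- events[events$code == entity_code, , drop = FALSE]
  counts <- integer(tl$n_units)
  if (nrow(sub) > 0L) {
    long <- discretize_events(sub, tl)
    counts[long$t] <- counts[long$t] + long$n
  }
  structure(counts,
            patient_id = if (nrow(events)) events$patient_id[[1]] else NA_character_,
            entity_code = entity_code,
            class = c("event_series", "integer"))
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %s / %s, T = %d, total = %d\n",
              attr(x, "patient_id"), attr(x, "entity_code"),
              length(x), sum(x)))
  invisible(x)
}
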