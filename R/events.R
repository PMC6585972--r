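#' Record an experimental event
#'
#' Events are timestamped occurrences from the event hierarchy (moves, sowing,
#' harvest, treatment, measurement, sampling, troubles) tied to one or more
#' experimental objects via `concerns`. Recording an event also asserts the
#' `concerns` triples in the knowledge graph, so events participate in
#' semantic retrieval. Recording twice under the same URI replaces the stored
#' event (a query never returns duplicates).
#'
#' Move events (`event_class = "MoveTo"`) must carry `from_location` and
#' `to_location` properties (and may carry `from_position` / `to_position`);
#' the source must differ from the destination in location or position.
#'
#' @param store a [pheno_store()].
#' @param event_class a class within the `Event` subtree.
#' @param timestamp event instant (ISO-8601 string or `POSIXct`).
#' @param concerns non-empty character vector of object URIs, all of which must
#'   exist in the knowledge graph.
#' @param uri event URI; auto-generated label-style URI when `NULL` (e.g.
#'   `event:moveTo328`).
#' @param agent optional agent URI.
#' @param description optional free text.
#' @param properties named list of extra literal properties (e.g.
#'   `from_location`, `to_location`, `from_position`, `to_position`).
#' @return the stored event as a one-row tibble, invisibly.
#' @export
record_event <- function(store, event_class, timestamp, concerns, uri = NULL,
                         agent = NA_character_, description = NA_character_,
                         properties = list()) {
  assert_store(store)
  assert_class_known(store, event_class)
  if (!is_a(store, event_class, "Event")) {
    stop("'", event_class, "' is not within the Event subtree", call. = FALSE)
  }
  concerns <- as.character(concerns)
  if (!length(concerns) || any(!nzchar(concerns)) || anyNA(concerns)) {
    stop("`concerns` must be a non-empty set of object URIs", call. = FALSE)
  }
  missing <- concerns[!object_exists(store, concerns)]
  if (length(missing)) {
    stop("event concerns unknown object(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  ts <- parse_instant(timestamp)
  stopifnot(length(ts) == 1)
  if (event_class == "MoveTo" || is_a(store, event_class, "MoveTo")) {
    fl <- properties$from_location
    tl <- properties$to_location
    if (is.null(fl) || is.null(tl)) {
      stop("a MoveTo event requires `from_location` and `to_location` properties",
        call. = FALSE
      )
    }
    same_loc <- identical(fl, tl)
    same_pos <- identical(properties$from_position, properties$to_position)
    if (same_loc && same_pos) {
      stop("a MoveTo event must change location or position", call. = FALSE)
    }
  }
  if (is.null(uri)) {
    n <- (store$counters[["event"]] %||% 0) + 1
    store$counters[["event"]] <- n
    uri <- paste0("event:", tolower(substr(event_class, 1, 1)),
      substr(event_class, 2, nchar(event_class)), n)
  }
  row <- tibble::tibble(
    uri = uri, event_class = event_class, timestamp = ts,
    concerns = list(unique(concerns)),
    agent = agent %||% NA_character_,
    description = description %||% NA_character_,
    properties = list(properties)
  )
  store$events <- dplyr::bind_rows(store$events[store$events$uri != uri, ], row)
  assert_class(store, uri, event_class)
  add_triples(store, tibble::tibble(
    subject = uri, predicate = "concerns", object = unique(concerns)
  ))
  invisible(row)
}

#' Annotate objects or data points
#'
#' Web-style annotations: an agent attaches a textual body to one or more
#' targets with a motivation (`commenting`, `describing` or `flagging`). A
#' target is an object URI, or a data-point reference — a list with fields
#' `object`, `variable` and `timestamp`. Annotations are linked to their
#' target objects in the knowledge graph via `concerns`.
#'
#' @param store a [pheno_store()].
#' @param agent agent URI.
#' @param body non-empty annotation text.
#' @param targets character vector of object URIs and/or a list mixing URIs and
#'   data-point references.
#' @param motivation one of `"commenting"`, `"describing"`, `"flagging"`.
#' @param created creation instant (defaults to the current time).
#' @param uri annotation URI; auto-generated when `NULL`.
#' @return the stored annotation as a one-row tibble, invisibly.
#' @export
annotate <- function(store, agent, body, targets,
                     motivation = c("commenting", "describing", "flagging"),
                     created = Sys.time(), uri = NULL) {
  assert_store(store)
  motivation <- match.arg(motivation)
  if (!is.character(body) || length(body) != 1 || is.na(body) || !nzchar(body)) {
    stop("annotation `body` must be non-empty text", call. = FALSE)
  }
  if (is.character(targets)) targets <- as.list(targets)
  if (!length(targets)) stop("annotation `targets` must be non-empty", call. = FALSE)
  target_objects <- vapply(targets, function(t) {
    if (is.character(t)) t else t$object %||% NA_character_
  }, character(1))
  if (anyNA(target_objects) || any(!nzchar(target_objects))) {
    stop("each target must be an object URI or carry an `object` field", call. = FALSE)
  }
  missing <- target_objects[!object_exists(store, target_objects)]
  if (length(missing)) {
    stop("annotation targets unknown object(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (is.null(uri)) {
    n <- (store$counters[["annotation"]] %||% 0) + 1
    store$counters[["annotation"]] <- n
    uri <- paste0("annotation:Annotation", n)
  }
  row <- tibble::tibble(
    uri = uri, agent = agent, created = parse_instant(created),
    motivation = motivation, body = body, targets = list(targets)
  )
  store$annotations <- dplyr::bind_rows(store$annotations[store$annotations$uri != uri, ], row)
  assert_class(store, uri, "Annotation")
  add_triples(store, tibble::tibble(
    subject = uri, predicate = "concerns", object = unique(target_objects)
  ))
  invisible(row)
}

#' Events concerning an object
#'
#' Lists events whose `concerns` include the object — or, with
#' `inherit = TRUE`, any of its part-of ancestors, so e.g. a lodging incident
#' recorded on a plot is visible from every leaf of that plot. The class
#' filter is subsumption-aware (`"Trouble"` matches breakdowns, dysfunctions
#' and incidents); the time window is half-open `[from, to)`. Results are
#' ordered by timestamp, then URI.
#'
#' @param store a [pheno_store()].
#' @param object object URI.
#' @param class_filter optional event class; subclasses match too.
#' @param window optional length-2 vector (start, end) of instants.
#' @param inherit also return events on part-of ancestors (default `FALSE`).
#' @return a tibble of events (possibly empty), one row per event.
#' @export
events_for <- function(store, object, class_filter = NULL, window = NULL,
                       inherit = FALSE) {
  assert_store(store)
  targets <- object
  if (inherit) {
    targets <- unique(c(targets, kg_related(store, object, "isPartOf")))
  }
  ev <- store$events
  hit <- vapply(ev$concerns, function(cc) any(cc %in% targets), logical(1))
  ev <- ev[hit, ]
  if (!is.null(class_filter)) {
    assert_class_known(store, class_filter)
    keep <- vapply(ev$event_class, function(cl) is_a(store, cl, class_filter), logical(1))
    ev <- ev[keep, ]
  }
  if (!is.null(window)) {
    w <- parse_instant(window)
    ev <- ev[ev$timestamp >= w[1] & ev$timestamp < w[2], ]
  }
  dplyr::arrange(ev, .data$timestamp, .data$uri)
}

event_property <- function(ev_row, name) {
  p <- ev_row$properties[[1]]
  p[[name]] %||% NA_character_
}

#' Residence intervals of an object
#'
#' Reconstructs where an object was over an observation window from its
#' initial placement (a `locatedIn` triple, or a `Sowing` event carrying a
#' `location`/`to_location` property at or before the window start) and its
#' `MoveTo` events. Intervals are half-open `[start, end)`: a measurement at
#' the instant of a move belongs to the new location. They are contiguous,
#' ordered, and cover the window up to the earliest `Harvest` event if one
#' occurs inside it.
#'
#' Two moves of the same object at the identical instant are an ambiguity
#' error; a move whose `from_location` contradicts the current location is a
#' consistency error naming both locations.
#'
#' @param store a [pheno_store()].
#' @param object object URI.
#' @param from,to observation window bounds (instants).
#' @return a tibble with columns `location`, `start`, `end` and `basis` (list
#'   of the event URIs delimiting the interval).
#' @export
residence_intervals <- function(store, object, from, to) {
  assert_store(store)
  from <- parse_instant(from)
  to <- parse_instant(to)
  if (!(from < to)) stop("`from` must precede `to`", call. = FALSE)

  # initial placements: locatedIn triples (valid from the beginning of time)
  # and Sowing events with a location property
  t <- store$triples
  placed <- t$object[t$subject == object & t$predicate == "locatedIn" &
    is.na(t$literal_kind)]
  placements <- tibble::tibble(
    time = rep(as.POSIXct(-Inf, origin = "1970-01-01", tz = "UTC"), length(placed)),
    location = placed, uri = rep(NA_character_, length(placed))
  )
  ev <- store$events
  mine <- ev[vapply(ev$concerns, function(cc) object %in% cc, logical(1)), ]
  if (nrow(mine)) {
    sow <- mine[vapply(mine$event_class, function(cl) is_a(store, cl, "Sowing"), logical(1)), ]
    for (i in seq_len(nrow(sow))) {
      loc <- sow$properties[[i]]$location %||% sow$properties[[i]]$to_location
      if (!is.null(loc)) {
        placements <- dplyr::bind_rows(placements, tibble::tibble(
          time = sow$timestamp[i], location = loc, uri = sow$uri[i]
        ))
      }
    }
  }
  placements <- placements[placements$time <= from, ]
  if (!nrow(placements)) {
    stop("no placement for '", object, "' at or before the window start ",
      "(need a locatedIn triple or a located Sowing event)",
      call. = FALSE
    )
  }
  placements <- dplyr::arrange(placements, .data$time)
  current <- placements$location[nrow(placements)]
  basis <- placements$uri[nrow(placements)]

  moves <- mine[vapply(mine$event_class, function(cl) is_a(store, cl, "MoveTo"), logical(1)), ]
  moves <- dplyr::arrange(moves, .data$timestamp, .data$uri)
  if (nrow(moves) > 1 && any(duplicated(moves$timestamp))) {
    dup <- moves$timestamp[duplicated(moves$timestamp)][1]
    stop("ambiguous schedule: two MoveTo events for '", object, "' at ",
      format_instant(dup),
      call. = FALSE
    )
  }
  harvests <- mine[vapply(mine$event_class, function(cl) is_a(store, cl, "Harvest"), logical(1)), ]
  end_limit <- to
  if (nrow(harvests)) {
    h <- min(harvests$timestamp)
    if (h < end_limit) end_limit <- h
  }
  if (end_limit <= from) {
    return(tibble::tibble(
      location = character(), start = empty_instant(), end = empty_instant(),
      basis = list()
    ))
  }

  out_loc <- character()
  out_start <- empty_instant()
  out_end <- empty_instant()
  out_basis <- list()
  cursor <- from
  for (i in seq_len(nrow(moves))) {
    ts <- moves$timestamp[i]
    fl <- event_property(moves[i, ], "from_location")
    tl <- event_property(moves[i, ], "to_location")
    if (!is.na(fl) && fl != current) {
      stop(
        "inconsistent move '", moves$uri[i], "': from_location '", fl,
        "' but '", object, "' is currently in '", current, "'",
        call. = FALSE
      )
    }
    if (ts <= from) { # replayed before the window opens
      current <- tl
      basis <- moves$uri[i]
      next
    }
    if (ts >= end_limit) break
    out_loc <- c(out_loc, current)
    out_start <- c(out_start, cursor)
    out_end <- c(out_end, ts)
    out_basis <- c(out_basis, list(stats::na.omit(c(basis, moves$uri[i]))))
    cursor <- ts
    current <- tl
    basis <- moves$uri[i]
  }
  out_loc <- c(out_loc, current)
  out_start <- c(out_start, cursor)
  out_end <- c(out_end, end_limit)
  closing <- if (nrow(harvests) && end_limit < to) harvests$uri[which.min(harvests$timestamp)] else NULL
  out_basis <- c(out_basis, list(stats::na.omit(c(basis, closing))))
  tibble::tibble(
    location = out_loc, start = out_start, end = out_end,
    basis = lapply(out_basis, as.character)
  )
}

#' Interval durations in days
#'
#' @param intervals a tibble from [residence_intervals()].
#' @return numeric vector of durations, `(end - start)` in units of 86 400 s.
#' @export
interval_days <- function(intervals) {
  as.numeric(difftime(intervals$end, intervals$start, units = "secs")) / 86400
}
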