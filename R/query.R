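#' Add observations
#'
#' Observations are per-object measurements of a defined variable: a numeric
#' `value` or a text `value_text`, a timestamp, and optional provenance (source
#' image, method, agent).
#'
#' @param store a [pheno_store()].
#' @param data a data frame with columns `object`, `variable`, `timestamp` and
#'   `value` (numeric) and/or `value_text`; optional `image`, `method`,
#'   `agent`.
#' @return the store, invisibly.
#' @export
add_observations <- function(store, data) {
  assert_store(store)
  data <- tibble::as_tibble(data)
  stopifnot(all(c("object", "variable", "timestamp") %in% names(data)))
  if (!("value" %in% names(data))) data$value <- NA_real_
  if (!("value_text" %in% names(data))) data$value_text <- NA_character_
  for (col in c("image", "method", "agent")) {
    if (!(col %in% names(data))) data[[col]] <- NA_character_
  }
  if (any(is.na(data$value) & is.na(data$value_text))) {
    stop("each observation needs `value` or `value_text`", call. = FALSE)
  }
  data$timestamp <- parse_instant(data$timestamp)
  data$value <- as.numeric(data$value)
  store$observations <- dplyr::bind_rows(
    store$observations,
    data[, names(empty_observations())]
  )
  invisible(store)
}

#' Query constraint constructors
#'
#' Building blocks for [query_spec()]:
#'
#' * `has_event(class, window, inherit)` — the object (or, with inheritance,
#'   a part-of ancestor) has an event of the class (subsumption-aware) in the
#'   window.
#' * `has_relation(path, target)` — `target` is reachable from the object
#'   along the predicate path (see [kg_related()]; `^` inverts a step).
#' * `where_value(variable, comparator, threshold, aggregator, window)` — the
#'   aggregated value of the variable passes the comparator. Aggregators:
#'   `any` (some in-window point passes — the reading behind "sensors that
#'   display temperatures higher than 40"), `latest`, `max`, `min`, `mean`.
#'
#' @param class event class name.
#' @param window optional length-2 vector of instants.
#' @param inherit inherit events from part-of ancestors (default `TRUE`).
#' @param path character vector of predicate steps.
#' @param target resource URI to reach.
#' @param variable variable URI.
#' @param comparator one of `"<"`, `"<="`, `">"`, `">="`, `"="`.
#' @param threshold numeric (or character for `"="` on text values).
#' @param aggregator one of `"any"`, `"latest"`, `"max"`, `"min"`, `"mean"`.
#' @return a constraint object for [query_spec()].
#' @name query-constraints
NULL

#' @rdname query-constraints
#' @export
has_event <- function(class, window = NULL, inherit = TRUE) {
  structure(list(class = class, window = window, inherit = inherit),
    class = "pheno_constraint_event"
  )
}

#' @rdname query-constraints
#' @export
has_relation <- function(path, target) {
  structure(list(path = path, target = target),
    class = "pheno_constraint_relation"
  )
}

#' @rdname query-constraints
#' @export
where_value <- function(variable, comparator, threshold, aggregator = "any",
                        window = NULL) {
  comparator <- match.arg(comparator, c("<", "<=", ">", ">=", "="))
  aggregator <- match.arg(aggregator, c("any", "latest", "max", "min", "mean"))
  structure(
    list(
      variable = variable, comparator = comparator, threshold = threshold,
      aggregator = aggregator, window = window
    ),
    class = "pheno_constraint_value"
  )
}

#' Hybrid query specification
#'
#' Combines a target class with semantic constraints (events, graph relations)
#' and quantitative constraints over observations. Each constraint list has
#' its own combinator (`"AND"` = intersection, `"OR"` = union); the two lists
#' are then intersected. This covers queries such as "plants with leaf area
#' higher than 0.6 m2 and/or plant height higher than 1500 mm" or "images of
#' plots having suffered lodging".
#'
#' @param target_class class of the objects to return (subsumption-aware).
#' @param semantic list of [has_event()] / [has_relation()] constraints.
#' @param data list of [where_value()] constraints.
#' @param semantic_combinator,data_combinator `"AND"` or `"OR"`.
#' @return a `query_spec` object for [select_objects()].
#' @export
query_spec <- function(target_class, semantic = list(), data = list(),
                       semantic_combinator = "AND", data_combinator = "AND") {
  semantic_combinator <- match.arg(semantic_combinator, c("AND", "OR"))
  data_combinator <- match.arg(data_combinator, c("AND", "OR"))
  structure(
    list(
      target_class = target_class, semantic = semantic, data = data,
      semantic_combinator = semantic_combinator, data_combinator = data_combinator
    ),
    class = "query_spec"
  )
}

comparator_fun <- function(comparator) {
  switch(comparator,
    "<" = `<`, "<=" = `<=`, ">" = `>`, ">=" = `>=`, "=" = `==`
  )
}

combine_sets <- function(sets, combinator, universe) {
  if (!length(sets)) {
    return(universe)
  }
  out <- sets[[1]]
  for (s in sets[-1]) {
    out <- if (combinator == "AND") intersect(out, s) else union(out, s)
  }
  out
}

eval_constraint <- function(constraint, store, candidates) {
  UseMethod("eval_constraint")
}

#' @export
eval_constraint.pheno_constraint_event <- function(constraint, store, candidates) {
  assert_class_known(store, constraint$class)
  keep <- vapply(candidates, function(obj) {
    nrow(events_for(store, obj,
      class_filter = constraint$class,
      window = constraint$window, inherit = constraint$inherit
    )) > 0
  }, logical(1))
  candidates[keep]
}

#' @export
eval_constraint.pheno_constraint_relation <- function(constraint, store, candidates) {
  keep <- vapply(candidates, function(obj) {
    constraint$target %in% kg_related(store, obj, constraint$path)
  }, logical(1))
  candidates[keep]
}

#' @export
eval_constraint.pheno_constraint_value <- function(constraint, store, candidates) {
  obs <- store$observations
  if (!(constraint$variable %in% obs$variable) &&
    !(constraint$variable %in% store$variables$uri)) {
    stop("unknown variable '", constraint$variable, "'", call. = FALSE)
  }
  obs <- obs[obs$variable == constraint$variable & obs$object %in% candidates, ]
  if (!is.null(constraint$window)) {
    w <- parse_instant(constraint$window)
    obs <- obs[obs$timestamp >= w[1] & obs$timestamp < w[2], ]
  }
  numeric_needed <- constraint$comparator != "=" || is.numeric(constraint$threshold)
  if (numeric_needed && nrow(obs) && all(is.na(obs$value)) && any(!is.na(obs$value_text))) {
    stop(
      "numeric comparator on text-valued variable '", constraint$variable, "'",
      call. = FALSE
    )
  }
  cmp <- comparator_fun(constraint$comparator)
  vals <- if (numeric_needed) obs$value else obs$value_text
  keep_obs <- obs[!is.na(vals), ]
  vals <- vals[!is.na(vals)]
  passing <- vapply(unique(keep_obs$object), function(obj) {
    sel <- keep_obs$object == obj
    v <- vals[sel]
    agg <- switch(constraint$aggregator,
      any = return(any(cmp(v, constraint$threshold))),
      latest = v[which.max(keep_obs$timestamp[sel])],
      max = max(v),
      min = min(v),
      mean = mean(v)
    )
    cmp(agg, constraint$threshold)
  }, logical(1))
  intersect(candidates, unique(keep_obs$object)[passing])
}

#' Select objects matching a hybrid query
#'
#' @param store a [pheno_store()].
#' @param spec a [query_spec()].
#' @return sorted character vector of object URIs (deterministic ordering).
#' @examples
#' \dontrun{
#' select_objects(store, query_spec(
#'   "Plant",
#'   data = list(
#'     where_value("var:leaf_area", ">", 0.6, aggregator = "max"),
#'     where_value("var:plant_height", ">", 1500, aggregator = "max")
#'   ),
#'   data_combinator = "OR"
#' ))
#' }
#' @export
select_objects <- function(store, spec) {
  assert_store(store)
  stopifnot(inherits(spec, "query_spec"))
  candidates <- instances_of(store, spec$target_class, include_subclasses = TRUE)
  if (!length(candidates)) {
    return(character())
  }
  sem_sets <- lapply(spec$semantic, eval_constraint, store = store, candidates = candidates)
  dat_sets <- lapply(spec$data, eval_constraint, store = store, candidates = candidates)
  sem <- combine_sets(sem_sets, spec$semantic_combinator, candidates)
  dat <- combine_sets(dat_sets, spec$data_combinator, candidates)
  sort(intersect(sem, dat))
}

#' Read a query specification from JSON
#'
#' A small JSON dialect mirroring [query_spec()]:
#'
#' ```json
#' {"target_class": "Plant",
#'  "data_combinator": "OR",
#'  "data": [{"variable": "var:leaf_area", "comparator": ">",
#'            "threshold": 0.6, "aggregator": "max"}],
#'  "semantic": [{"has_event": {"class": "Incident", "inherit": true}},
#'               {"has_relation": {"path": ["isPartOf"], "target": "plot1"}}]}
#' ```
#'
#' @param json JSON text or a file path.
#' @return a [query_spec()].
#' @export
query_from_json <- function(json) {
  raw <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE)
  semantic <- lapply(raw$semantic %||% list(), function(x) {
    if (!is.null(x$has_event)) {
      e <- x$has_event
      has_event(e$class, window = unlist(e$window), inherit = e$inherit %||% TRUE)
    } else if (!is.null(x$has_relation)) {
      r <- x$has_relation
      has_relation(unlist(r$path), r$target)
    } else {
      stop("semantic constraint must be `has_event` or `has_relation`", call. = FALSE)
    }
  })
  data <- lapply(raw$data %||% list(), function(x) {
    where_value(x$variable, x$comparator, x$threshold,
      aggregator = x$aggregator %||% "any", window = unlist(x$window)
    )
  })
  query_spec(
    raw$target_class,
    semantic = semantic, data = data,
    semantic_combinator = raw$semantic_combinator %||% "AND",
    data_combinator = raw$data_combinator %||% "AND"
  )
}

#' Sensors exceeding a threshold
#'
#' Which sensors recorded at least one in-window point strictly above the
#' threshold — e.g. "show all sensors that display temperatures higher than
#' 40".
#'
#' @param store a [pheno_store()].
#' @param variable variable URI.
#' @param threshold numeric threshold (strict).
#' @param window optional length-2 vector of instants (half-open).
#' @return sorted character vector of sensor URIs.
#' @export
sensors_exceeding <- function(store, variable, threshold, window = NULL) {
  assert_store(store)
  s <- store$series[store$series$variable == variable, ]
  if (!is.null(window)) {
    w <- parse_instant(window)
    s <- s[s$timestamp >= w[1] & s$timestamp < w[2], ]
  }
  sort(unique(s$sensor[s$value > threshold]))
}
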