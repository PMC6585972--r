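#' Export observations as interoperable JSON
#'
#' Serializes observations in a breeding-API-flavoured dialect: one record per
#' observation with fields `observationUnitDbId` (the object URI),
#' `germplasmName` (the object's declared variety, when one exists),
#' `observationVariableDbId`, `value` (number, or string for text values) and
#' `observationTimeStamp` (ISO-8601). The dialect is versioned locally
#' (`phenotrack-obs/1`); no network service is involved.
#'
#' @param store a [pheno_store()].
#' @param objects optional character vector restricting the export.
#' @param variables optional character vector restricting the export.
#' @param path optional output file; when `NULL` the JSON text is returned.
#' @return JSON text (invisibly when written to `path`).
#' @export
export_observations <- function(store, objects = NULL, variables = NULL,
                                path = NULL) {
  assert_store(store)
  obs <- store$observations
  if (!is.null(objects)) obs <- obs[obs$object %in% objects, ]
  if (!is.null(variables)) obs <- obs[obs$variable %in% variables, ]
  obs <- dplyr::arrange(obs, .data$object, .data$variable, .data$timestamp)
  t <- store$triples
  gt <- t[t$predicate == "hasVariety" & is.na(t$literal_kind), ]
  records <- lapply(seq_len(nrow(obs)), function(i) {
    val <- if (is.na(obs$value[i])) obs$value_text[i] else obs$value[i]
    germ <- gt$object[match(obs$object[i], gt$subject)]
    rec <- list(
      observationUnitDbId = obs$object[i],
      observationVariableDbId = obs$variable[i],
      value = val,
      observationTimeStamp = format_instant(obs$timestamp[i])
    )
    if (!is.na(germ)) rec$germplasmName <- germ
    rec
  })
  json <- jsonlite::toJSON(
    list(format = "phenotrack-obs/1", data = records),
    auto_unbox = TRUE, digits = NA, pretty = FALSE
  )
  if (!is.null(path)) {
    writeLines(json, path, useBytes = TRUE)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' Import observations from JSON
#'
#' Reads the dialect written by [export_observations()]. Schema violations
#' (missing fields, unparseable timestamps) raise an error naming the
#' offending record index. Export followed by import is the identity on the
#' observation set.
#'
#' @param store a [pheno_store()] to add the observations to.
#' @param json JSON text or a file path.
#' @return the store, invisibly.
#' @export
import_observations <- function(store, json) {
  assert_store(store)
  raw <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE)
  records <- raw$data %||% raw
  required <- c(
    "observationUnitDbId", "observationVariableDbId", "value",
    "observationTimeStamp"
  )
  rows <- lapply(seq_along(records), function(i) {
    rec <- records[[i]]
    missing <- setdiff(required, names(rec))
    if (length(missing)) {
      stop("record ", i, ": missing field '", missing[1], "'", call. = FALSE)
    }
    ts <- tryCatch(parse_instant(rec$observationTimeStamp), error = function(e) {
      stop("record ", i, ": ", conditionMessage(e), call. = FALSE)
    })
    numeric_val <- is.numeric(rec$value)
    tibble::tibble(
      object = rec$observationUnitDbId,
      variable = rec$observationVariableDbId,
      timestamp = ts,
      value = if (numeric_val) as.numeric(rec$value) else NA_real_,
      value_text = if (numeric_val) NA_character_ else as.character(rec$value)
    )
  })
  if (length(rows)) add_observations(store, dplyr::bind_rows(rows))
  invisible(store)
}

# serialize an event properties list as key=value pairs joined with |
props_to_text <- function(props) {
  vapply(props, function(p) {
    if (!length(p)) {
      return("")
    }
    paste(names(p), vapply(p, as.character, character(1)), sep = "=", collapse = "|")
  }, character(1))
}

props_from_text <- function(txt) {
  lapply(txt, function(x) {
    if (is.na(x) || !nzchar(x)) {
      return(list())
    }
    parts <- strsplit(x, "|", fixed = TRUE)[[1]]
    kv <- strsplit(parts, "=", fixed = TRUE)
    stats::setNames(
      lapply(kv, function(p) paste(p[-1], collapse = "=")),
      vapply(kv, `[[`, character(1), 1)
    )
  })
}

#' Export store entities as CSV
#'
#' Tabular dumps with deterministic row order. Supported kinds and columns:
#'
#' * `observations`: `object`, `variable`, `timestamp`, `value`, `value_text`,
#'   `image`, `method`, `agent`
#' * `events`: `uri`, `class`, `timestamp`, `concerns` (`|`-separated),
#'   `agent`, `description`, `properties` (`key=value` pairs, `|`-separated)
#' * `triples`: `subject`, `predicate`, `object`, `literal_kind` (class
#'   assertions appear with predicate `a` and the bare class name)
#' * `series`: `timestamp`, `sensor_uri`, `variable_uri`, `value`, `unit`
#' * `variables`: `variable_uri`, `trait_label`, `method_label`, `unit_label`,
#'   `mappings` (`relation=id` pairs over the three component terms)
#'
#' @param store a [pheno_store()].
#' @param kind one of the entity kinds above.
#' @param path optional output file.
#' @return the exported tibble (invisibly when written to `path`).
#' @export
export_csv <- function(store, kind, path = NULL) {
  assert_store(store)
  if (!is.character(kind) || length(kind) != 1 ||
    !(kind %in% c("observations", "events", "triples", "series", "variables"))) {
    stop("unknown export kind '", paste(kind, collapse = ","), "'", call. = FALSE)
  }
  out <- switch(kind,
    observations = {
      o <- dplyr::arrange(
        store$observations,
        .data$object, .data$variable, .data$timestamp
      )
      o$timestamp <- format_instant(o$timestamp)
      o
    },
    events = {
      e <- dplyr::arrange(store$events, .data$timestamp, .data$uri)
      tibble::tibble(
        uri = e$uri, class = e$event_class,
        timestamp = format_instant(e$timestamp),
        concerns = vapply(e$concerns, paste, character(1), collapse = "|"),
        agent = e$agent, description = e$description,
        properties = props_to_text(e$properties)
      )
    },
    triples = {
      rows <- dplyr::arrange(
        store$triples,
        .data$subject, .data$predicate, .data$object
      )
      cls <- dplyr::arrange(store$classes, .data$resource, .data$class)
      dplyr::bind_rows(
        rows,
        tibble::tibble(
          subject = cls$resource, predicate = "a", object = cls$class,
          literal_kind = NA_character_
        )
      )
    },
    series = {
      s <- dplyr::arrange(store$series, .data$sensor, .data$variable, .data$timestamp)
      tibble::tibble(
        timestamp = format_instant(s$timestamp), sensor_uri = s$sensor,
        variable_uri = s$variable, value = s$value, unit = s$unit
      )
    },
    variables = {
      v <- dplyr::arrange(store$variables, .data$uri)
      lab <- function(uri) store$terms$label[match(uri, store$terms$uri)]
      maps <- vapply(seq_len(nrow(v)), function(i) {
        m <- dplyr::bind_rows(
          term_mappings(store, v$trait[i]),
          term_mappings(store, v$method[i]),
          term_mappings(store, v$unit[i])
        )
        paste(m$relation, m$external_id, sep = "=", collapse = "|")
      }, character(1))
      tibble::tibble(
        variable_uri = v$uri, trait_label = lab(v$trait),
        method_label = lab(v$method), unit_label = lab(v$unit),
        mappings = maps
      )
    }
  )
  if (!is.null(path)) {
    readr::write_csv(out, path, na = "")
    return(invisible(out))
  }
  out
}

#' Import store entities from CSV
#'
#' Reads the schemas written by [export_csv()] for `triples`, `events`,
#' `observations` and `series`. Triple and event imports are the inverse of
#' the export, so export-then-import reproduces the graph and event set.
#'
#' @param store a [pheno_store()].
#' @param kind `"triples"`, `"events"`, `"observations"` or `"series"`.
#' @param path input CSV file.
#' @return the store, invisibly.
#' @export
import_csv <- function(store, kind, path) {
  assert_store(store)
  kind <- match.arg(kind, c("triples", "events", "observations", "series"))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE, na = "")
  switch(kind,
    triples = {
      df$literal_kind <- as.character(df$literal_kind %||% NA_character_)
      is_class <- df$predicate == "a"
      if (any(is_class)) {
        assert_class(store, df$subject[is_class], df$object[is_class])
      }
      if (any(!is_class)) {
        add_triples(store, tibble::tibble(
          subject = as.character(df$subject[!is_class]),
          predicate = as.character(df$predicate[!is_class]),
          object = as.character(df$object[!is_class]),
          literal_kind = df$literal_kind[!is_class]
        ))
      }
    },
    events = {
      props <- props_from_text(as.character(df$properties))
      for (i in seq_len(nrow(df))) {
        record_event(store,
          event_class = df$class[i], timestamp = df$timestamp[i],
          concerns = strsplit(df$concerns[i], "|", fixed = TRUE)[[1]],
          uri = df$uri[i], agent = as.character(df$agent[i]),
          description = as.character(df$description[i]),
          properties = props[[i]]
        )
      }
    },
    observations = {
      if (nrow(df)) add_observations(store, df)
    },
    series = {
      df <- dplyr::arrange(df, .data$sensor_uri, .data$variable_uri, .data$timestamp)
      for (grp in split(df, paste(df$sensor_uri, df$variable_uri))) {
        add_sensor_series(
          store, grp$sensor_uri[1], grp$variable_uri[1],
          tibble::tibble(timestamp = grp$timestamp, value = grp$value),
          unit = grp$unit[1]
        )
      }
    }
  )
  invisible(store)
}

#' Save / load a store as plain-text files
#'
#' Persists a store into a directory: the knowledge graph as N-Triples, the
#' tabular records as CSV, and the configuration as YAML. This is the
#' persistence layer used by the command-line interface.
#'
#' @param store a [pheno_store()].
#' @param dir directory path (created if needed).
#' @return `save_store()` returns `dir` invisibly; `load_store()` returns the
#'   reconstructed store.
#' @export
save_store <- function(store, dir) {
  assert_store(store)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_store_config(store$config, file.path(dir, "config.yaml"))
  write_triples(store, file.path(dir, "triples.nt"), format = "ntriples")
  export_csv(store, "events", file.path(dir, "events.csv"))
  export_csv(store, "observations", file.path(dir, "observations.csv"))
  export_csv(store, "series", file.path(dir, "series.csv"))
  export_csv(store, "variables", file.path(dir, "variables.csv"))
  a <- store$assignments
  readr::write_csv(tibble::tibble(
    location = a$location, variable = a$variable, sensor = a$sensor,
    start = format_instant(a$start),
    end = ifelse(is.na(a$end), "", format_instant(a$end))
  ), file.path(dir, "assignments.csv"), na = "")
  t <- dplyr::arrange(store$terms, .data$uri)
  readr::write_csv(t, file.path(dir, "terms.csv"), na = "")
  v <- dplyr::arrange(store$variables, .data$uri)
  readr::write_csv(v, file.path(dir, "variable_terms.csv"), na = "")
  invisible(dir)
}

#' @rdname save_store
#' @export
load_store <- function(dir) {
  cfg <- read_store_config(file.path(dir, "config.yaml"))
  store <- pheno_store(cfg)
  suppressWarnings(
    read_triples(store, file.path(dir, "triples.nt"), format = "ntriples")
  )
  terms <- readr::read_csv(file.path(dir, "terms.csv"),
    show_col_types = FALSE, progress = FALSE
  )
  for (i in seq_len(nrow(terms))) {
    define_term(store, terms$uri[i], terms$label[i], terms$kind[i])
  }
  vt <- readr::read_csv(file.path(dir, "variable_terms.csv"),
    show_col_types = FALSE, progress = FALSE
  )
  for (i in seq_len(nrow(vt))) {
    define_variable(store, vt$uri[i], vt$trait[i], vt$method[i], vt$unit[i])
  }
  ev_path <- file.path(dir, "events.csv")
  if (file.size(ev_path) > 0) import_csv(store, "events", ev_path)
  import_csv(store, "series", file.path(dir, "series.csv"))
  a <- readr::read_csv(file.path(dir, "assignments.csv"),
    show_col_types = FALSE, progress = FALSE, na = ""
  )
  for (i in seq_len(nrow(a))) {
    assign_sensor(store, a$location[i], a$variable[i], a$sensor[i],
      start = a$start[i],
      end = if (is.na(a$end[i]) || !nzchar(a$end[i])) NA else a$end[i]
    )
  }
  import_csv(store, "observations", file.path(dir, "observations.csv"))
  store
}
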