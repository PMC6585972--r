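#' Built-in predicate registry
#'
#' Predicates carry a transitivity flag; exactly the predicates flagged
#' transitive participate in closure inference. `isPartOf` is the workhorse
#' transitive relation (sample is part of leaf is part of plant is part of
#' plot). Unknown predicates used in [add_triple()] are auto-registered as
#' non-transitive with a warning, keeping the graph open to
#' installation-specific vocabulary.
#'
#' @return a tibble with columns `predicate`, `transitive`, `description`.
#' @export
builtin_predicates <- function() {
  tibble::tribble(
    ~predicate, ~transitive, ~description,
    "isPartOf", TRUE, "mereological containment (sample/leaf/plant/plot)",
    "participatesIn", FALSE, "object takes part in an experiment",
    "hasVariety", FALSE, "plant material to its genotype",
    "concerns", FALSE, "event or annotation to the objects it is about",
    "hasSensor", FALSE, "location or device chain to a sensor",
    "locatedIn", FALSE, "initial placement of an object in an installation",
    "measures", FALSE, "sensor to the variable it measures",
    "derivesFrom", FALSE, "physical provenance (plant from seed lot)",
    "hasTrait", FALSE, "variable to its trait term",
    "hasMethod", FALSE, "variable to its method term",
    "hasUnit", FALSE, "variable to its unit term",
    "label", FALSE, "human-readable label literal",
    "exactMatch", FALSE, "SKOS exact mapping to an external term",
    "closeMatch", FALSE, "SKOS close mapping to an external term",
    "broader", FALSE, "SKOS broader external term",
    "narrower", FALSE, "SKOS narrower external term"
  )
}

#' Register a predicate
#'
#' @param store a [pheno_store()].
#' @param predicate predicate name.
#' @param transitive should chains of this predicate be closed under
#'   [kg_closure()]?
#' @param description free-text note.
#' @return the store, invisibly.
#' @export
register_predicate <- function(store, predicate, transitive = FALSE, description = "") {
  assert_store(store)
  stopifnot(is.character(predicate), length(predicate) == 1, nzchar(predicate))
  p <- store$predicates
  if (predicate %in% p$predicate) {
    store$predicates$transitive[p$predicate == predicate] <- transitive
  } else {
    store$predicates <- dplyr::bind_rows(
      p,
      tibble::tibble(predicate = predicate, transitive = transitive, description = description)
    )
  }
  invalidate_cache(store)
  invisible(store)
}

predicate_transitive <- function(store, predicate) {
  p <- store$predicates
  isTRUE(p$transitive[match(predicate, p$predicate)])
}

literal_kinds <- function() c("string", "number", "timestamp")

#' Add or remove a triple
#'
#' A triple is an atomic statement `subject predicate object`, e.g.
#' `plant736 participatesIn ExperimentA`. Objects are resources unless a
#' `literal_kind` (`"string"`, `"number"` or `"timestamp"`) is given. Adding is
#' idempotent (set semantics); removing an absent triple is a no-op that
#' returns `FALSE`.
#'
#' @param store a [pheno_store()].
#' @param subject,predicate,object triple components (non-empty strings).
#' @param literal_kind `NA` for a resource object, otherwise the declared
#'   literal kind.
#' @return `add_triple()` returns the store invisibly; `remove_triple()`
#'   returns `TRUE` if the triple was present.
#' @export
add_triple <- function(store, subject, predicate, object, literal_kind = NA_character_) {
  assert_store(store)
  add_triples(store, tibble::tibble(
    subject = subject, predicate = predicate,
    object = as.character(object), literal_kind = literal_kind
  ))
}

# vectorised internal entry point used by the generator
add_triples <- function(store, df) {
  df <- tibble::as_tibble(df)
  if (!("literal_kind" %in% names(df))) df$literal_kind <- NA_character_
  bad <- is.na(df$subject) | !nzchar(df$subject) |
    is.na(df$predicate) | !nzchar(df$predicate) |
    is.na(df$object) | !nzchar(df$object)
  if (any(bad)) {
    stop("malformed triple: subject, predicate and object must be non-empty",
      call. = FALSE
    )
  }
  bad_kind <- !is.na(df$literal_kind) & !(df$literal_kind %in% literal_kinds())
  if (any(bad_kind)) {
    stop("unknown literal kind '", df$literal_kind[bad_kind][1], "'", call. = FALSE)
  }
  new_preds <- setdiff(unique(df$predicate), store$predicates$predicate)
  if (length(new_preds)) {
    warning("auto-registering non-transitive predicate(s): ",
      paste(new_preds, collapse = ", "),
      call. = FALSE
    )
    for (p in new_preds) {
      suppressWarnings(register_predicate(store, p, transitive = FALSE))
    }
  }
  store$triples <- dplyr::distinct(
    dplyr::bind_rows(store$triples, df),
    .data$subject, .data$predicate, .data$object,
    .keep_all = TRUE
  )
  invalidate_cache(store)
  invisible(store)
}

#' @rdname add_triple
#' @export
remove_triple <- function(store, subject, predicate, object) {
  assert_store(store)
  t <- store$triples
  hit <- t$subject == subject & t$predicate == predicate & t$object == object
  if (!any(hit)) {
    return(FALSE)
  }
  store$triples <- t[!hit, ]
  invalidate_cache(store)
  TRUE
}

#' Assert the class of a resource
#'
#' @param store a [pheno_store()].
#' @param resource resource URI.
#' @param class a registered class name.
#' @return the store, invisibly.
#' @export
assert_class <- function(store, resource, class) {
  assert_store(store)
  assert_class_known(store, unique(class))
  df <- tibble::tibble(resource = resource, class = class)
  bad <- is.na(df$resource) | !nzchar(df$resource)
  if (any(bad)) stop("empty resource in class assertion", call. = FALSE)
  store$classes <- dplyr::distinct(dplyr::bind_rows(store$classes, df))
  invalidate_cache(store)
  invisible(store)
}

resource_class <- function(store, resource) {
  store$classes$class[match(resource, store$classes$resource)]
}

#' Instances of a class
#'
#' All resources asserted to `class` — and, when `include_subclasses` is set,
#' to any of its descendants (subsumption-aware retrieval).
#'
#' @param store a [pheno_store()].
#' @param class a registered class name.
#' @param include_subclasses include instances of subclasses (default `TRUE`).
#' @return sorted character vector of resource URIs.
#' @export
instances_of <- function(store, class, include_subclasses = TRUE) {
  assert_store(store)
  assert_class_known(store, class)
  cls <- if (include_subclasses) class_descendants(store, class) else class
  sort(unique(store$classes$resource[store$classes$class %in% cls]))
}

# resource-object edges of one predicate
predicate_edges <- function(store, predicate) {
  t <- store$triples
  t[t$predicate == predicate & is.na(t$literal_kind), c("subject", "object")]
}

#' Transitive closure of a predicate
#'
#' Returns exactly the inferred triples `(a, p, c)` such that `c` is reachable
#' from `a` via two or more `p`-edges and `(a, p, c)` is not itself asserted.
#' Asserted triples are left untouched. Closures are computed on demand and
#' cached; any mutation of the graph invalidates the cache.
#'
#' @param store a [pheno_store()].
#' @param predicate a predicate flagged transitive (see
#'   [register_predicate()]).
#' @return a tibble of inferred triples (`subject`, `predicate`, `object`).
#' @examples
#' st <- pheno_store()
#' add_triple(st, "leaf884", "isPartOf", "plant736")
#' add_triple(st, "plant736", "isPartOf", "plot12")
#' kg_closure(st, "isPartOf") # infers leaf884 isPartOf plot12
#' @export
kg_closure <- function(store, predicate) {
  assert_store(store)
  if (!(predicate %in% store$predicates$predicate)) {
    stop("unknown predicate '", predicate, "'", call. = FALSE)
  }
  if (!predicate_transitive(store, predicate)) {
    stop("predicate '", predicate, "' is not flagged transitive", call. = FALSE)
  }
  key <- paste0("closure\r", predicate)
  cached <- store$cache[[key]]
  if (!is.null(cached)) {
    return(cached)
  }
  edges <- predicate_edges(store, predicate)
  out <- tibble::tibble(
    subject = character(), predicate = character(), object = character()
  )
  if (nrow(edges)) {
    succ <- split(edges$object, edges$subject)
    reach_from <- function(a) {
      seen <- new.env(parent = emptyenv())
      frontier <- succ[[a]] %||% character()
      for (x in frontier) seen[[x]] <- TRUE
      while (length(frontier)) {
        nxt <- unique(unlist(succ[frontier], use.names = FALSE))
        nxt <- nxt[vapply(nxt, function(x) is.null(seen[[x]]), logical(1))]
        for (x in nxt) seen[[x]] <- TRUE
        frontier <- nxt
      }
      ls(seen)
    }
    subjects <- unique(edges$subject)
    pairs <- lapply(subjects, function(a) {
      r <- reach_from(a)
      if (length(r)) tibble::tibble(subject = a, object = r) else NULL
    })
    all_pairs <- dplyr::bind_rows(pairs)
    if (nrow(all_pairs)) {
      asserted <- paste(edges$subject, edges$object, sep = "\r")
      inferred <- all_pairs[!(paste(all_pairs$subject, all_pairs$object, sep = "\r")
      %in% asserted), ]
      out <- tibble::tibble(
        subject = inferred$subject, predicate = predicate, object = inferred$object
      )
    }
  }
  out <- dplyr::arrange(out, .data$subject, .data$object)
  store$cache[[key]] <- out
  out
}

#' Resources reachable along a predicate path
#'
#' Follows an ordered list of predicates from a start resource. Transitive
#' predicates traverse their closure (one step of `isPartOf` reaches all
#' part-of ancestors); a step may be inverted by prefixing it with `^`
#' (e.g. `"^concerns"` walks from an object to the events concerning it).
#' An unknown start resource yields an empty set.
#'
#' @param store a [pheno_store()].
#' @param start resource URI.
#' @param predicate_path character vector of predicate names, in order.
#' @return sorted character vector of reachable resources.
#' @examples
#' st <- pheno_store()
#' add_triple(st, "sample331", "isPartOf", "plant736")
#' add_triple(st, "plant736", "participatesIn", "ExperimentA")
#' kg_related(st, "sample331", c("isPartOf", "participatesIn"))
#' @export
kg_related <- function(store, start, predicate_path) {
  assert_store(store)
  stopifnot(length(predicate_path) >= 1)
  frontier <- unique(start)
  for (step in predicate_path) {
    inverse <- startsWith(step, "^")
    pred <- sub("^\\^", "", step)
    edges <- predicate_edges(store, pred)
    if (pred %in% store$predicates$predicate && predicate_transitive(store, pred)) {
      closure <- kg_closure(store, pred)
      edges <- dplyr::bind_rows(edges, closure[, c("subject", "object")])
    }
    frontier <- if (inverse) {
      unique(edges$subject[edges$object %in% frontier])
    } else {
      unique(edges$object[edges$subject %in% frontier])
    }
    if (!length(frontier)) {
      return(character())
    }
  }
  sort(frontier)
}
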