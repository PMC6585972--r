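#' Built-in class hierarchies
#'
#' Two application hierarchies ship with every store. The experimental-object
#' hierarchy (namespace `OEPO`) covers scientific objects (plant, plot, leaf,
#' sample, pot, seed lot), devices (sensor, camera, imaging cabin, cart),
#' infrastructures (national, local, installation), germplasm (species,
#' variety) plus images, experiments and agents. The experimental-event
#' hierarchy (namespace `OEEv`) covers moves, sowing, harvest, treatment,
#' measurement, sampling and troubles, the latter subdivided into breakdown,
#' dysfunction and incident. Each hierarchy is a forest: every class has at
#' most one parent and cycles are rejected.
#'
#' @return a tibble with columns `class`, `parent`, `namespace`.
#' @export
builtin_hierarchy <- function() {
  h <- tibble::tribble(
    ~class, ~parent, ~namespace,
    # events
    "Event", NA, "OEEv",
    "MoveTo", "Event", "OEEv",
    "Sowing", "Event", "OEEv",
    "Harvest", "Event", "OEEv",
    "Treatment", "Event", "OEEv",
    "Measurement", "Event", "OEEv",
    "Sampling", "Event", "OEEv",
    "Trouble", "Event", "OEEv",
    "Breakdown", "Trouble", "OEEv",
    "Dysfunction", "Trouble", "OEEv",
    "Incident", "Trouble", "OEEv",
    # experimental objects
    "ScientificObject", NA, "OEPO",
    "Plant", "ScientificObject", "OEPO",
    "Plot", "ScientificObject", "OEPO",
    "Leaf", "ScientificObject", "OEPO",
    "Sample", "ScientificObject", "OEPO",
    "Pot", "ScientificObject", "OEPO",
    "SeedLot", "ScientificObject", "OEPO",
    "Device", NA, "OEPO",
    "Sensor", "Device", "OEPO",
    "Camera", "Device", "OEPO",
    "ImagingCabin", "Device", "OEPO",
    "Cart", "Device", "OEPO",
    "Infrastructure", NA, "OEPO",
    "NationalInfrastructure", "Infrastructure", "OEPO",
    "LocalInfrastructure", "Infrastructure", "OEPO",
    "Installation", "Infrastructure", "OEPO",
    "Germplasm", NA, "OEPO",
    "Species", "Germplasm", "OEPO",
    "Variety", "Germplasm", "OEPO",
    "Image", NA, "OEPO",
    "Experiment", NA, "OEPO",
    "Agent", NA, "OEPO",
    "Annotation", NA, "OEPO",
    # trait-method-unit vocabulary
    "Variable", NA, "OEPO",
    "Trait", NA, "OEPO",
    "Method", NA, "OEPO",
    "Unit", NA, "OEPO"
  )
  validate_hierarchy(h)
  h
}

validate_hierarchy <- function(h) {
  if (anyDuplicated(h$class)) stop("duplicate class in hierarchy", call. = FALSE)
  known <- h$class
  bad <- !is.na(h$parent) & !(h$parent %in% known)
  if (any(bad)) stop("unknown parent class: ", h$parent[bad][1], call. = FALSE)
  # forest check: walking up from any class must terminate
  parent_of <- stats::setNames(h$parent, h$class)
  for (cl in h$class) {
    seen <- character()
    cur <- cl
    while (!is.na(cur)) {
      if (cur %in% seen) stop("cycle in class hierarchy at '", cur, "'", call. = FALSE)
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
    }
  }
  invisible(h)
}

#' Extend a class hierarchy
#'
#' Registers a user-defined class under an existing parent (or as a new root).
#' Installations differ in the objects and events they need; the built-in
#' hierarchies are deliberately extensible.
#'
#' @param store a [pheno_store()].
#' @param class new class name.
#' @param parent parent class name or `NA` for a root.
#' @param namespace `"OEPO"` or `"OEEv"` (defaults to the parent's namespace).
#' @return the store, invisibly.
#' @export
add_class <- function(store, class, parent = NA, namespace = NULL) {
  assert_store(store)
  stopifnot(is.character(class), length(class) == 1, nzchar(class))
  h <- store$hierarchy
  if (class %in% h$class) stop("class '", class, "' already registered", call. = FALSE)
  if (!is.na(parent) && !(parent %in% h$class)) {
    stop("unknown parent class '", parent, "'", call. = FALSE)
  }
  if (is.null(namespace)) {
    namespace <- if (is.na(parent)) "OEPO" else h$namespace[h$class == parent]
  }
  store$hierarchy <- dplyr::bind_rows(
    h,
    tibble::tibble(class = class, parent = as.character(parent), namespace = namespace)
  )
  invalidate_cache(store)
  invisible(store)
}

class_exists <- function(store, class) class %in% store$hierarchy$class

assert_class_known <- function(store, class) {
  missing <- setdiff(class, store$hierarchy$class)
  if (length(missing)) {
    stop("unknown class: '", missing[1], "'", call. = FALSE)
  }
  invisible(class)
}

class_ancestors <- function(store, class) {
  parent_of <- stats::setNames(store$hierarchy$parent, store$hierarchy$class)
  out <- character()
  cur <- class
  while (!is.na(cur)) {
    out <- c(out, cur)
    cur <- parent_of[[cur]]
  }
  out
}

class_descendants <- function(store, class) {
  h <- store$hierarchy
  out <- class
  frontier <- class
  while (length(frontier)) {
    kids <- h$class[!is.na(h$parent) & h$parent %in% frontier]
    kids <- setdiff(kids, out)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Subsumption test
#'
#' `is_a(store, class, ancestor)` is `TRUE` when `ancestor` is reachable from
#' `class` by zero or more parent steps in the class hierarchy — reflexive and
#' transitive. A query for `Trouble` therefore matches `Breakdown`,
#' `Dysfunction` and `Incident` instances.
#'
#' @param store a [pheno_store()].
#' @param class,ancestor class names; both must be registered.
#' @return logical scalar.
#' @examples
#' st <- pheno_store()
#' is_a(st, "Breakdown", "Trouble") # TRUE
#' is_a(st, "Plant", "Trouble")     # FALSE
#' @export
is_a <- function(store, class, ancestor) {
  assert_store(store)
  assert_class_known(store, c(class, ancestor))
  ancestor %in% class_ancestors(store, class)
}
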