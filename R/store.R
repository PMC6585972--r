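#' Create an empty phenotyping store
#'
#' The store is the central container of phenotrack: a knowledge graph
#' (triples, class assertions, class hierarchies, predicate registry) together
#' with the tabular records of an experiment (events, annotations, sensor
#' series, sensor-location assignments, observations, variables and terms) and
#' the URI-minting registry. It has reference semantics (it is an environment),
#' so functions such as [add_triple()] or [record_event()] modify it in place
#' and return it invisibly, which keeps pipelines readable:
#'
#' ```r
#' store <- pheno_store()
#' store |> add_triple("a", "isPartOf", "b") |> add_triple("b", "isPartOf", "c")
#' ```
#'
#' @param config a configuration list from [store_config()].
#' @return a `pheno_store` object.
#' @export
pheno_store <- function(config = store_config()) {
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$counters <- new.env(parent = emptyenv())
  st$minted <- new.env(parent = emptyenv())
  st$triples <- empty_triples()
  st$classes <- tibble::tibble(resource = character(), class = character())
  st$hierarchy <- builtin_hierarchy()
  st$predicates <- builtin_predicates()
  st$events <- empty_events()
  st$annotations <- empty_annotations()
  st$assignments <- tibble::tibble(
    location = character(), variable = character(), sensor = character(),
    start = empty_instant(), end = empty_instant()
  )
  st$series <- tibble::tibble(
    sensor = character(), variable = character(), unit = character(),
    timestamp = empty_instant(), value = double()
  )
  st$observations <- empty_observations()
  st$terms <- tibble::tibble(uri = character(), label = character(), kind = character())
  st$variables <- tibble::tibble(
    uri = character(), trait = character(), method = character(), unit = character()
  )
  st$cache <- new.env(parent = emptyenv())
  class(st) <- c("pheno_store", "environment")
  st
}

#' Store configuration
#'
#' Declares the infrastructure base URIs available for URI minting, the prefix
#' abbreviations accepted on input (and used to compact Turtle output), the
#' zero-padding width of minted serial numbers, the registered object type
#' codes, and the time zone used for civil-day aggregation.
#'
#' @param bases named character vector of infrastructure base URIs; names are
#'   the prefix abbreviations (e.g. `c(m3p = "http://www.phenome-fppn.fr/m3p")`).
#' @param prefixes additional prefix abbreviations (vocabulary namespaces are
#'   always available).
#' @param padding zero-padding width for minted serials (default 6); parsing
#'   accepts any width.
#' @param type_codes named character vector mapping type codes to class names.
#' @param tz time zone for civil-day aggregation (default `"UTC"`).
#' @return a list of class `pheno_config`.
#' @export
store_config <- function(bases = default_bases(),
                         prefixes = character(),
                         padding = 6L,
                         type_codes = default_type_codes(),
                         tz = "UTC") {
  stopifnot(is.character(bases), !is.null(names(bases)), all(nzchar(names(bases))))
  padding <- as.integer(padding)
  if (is.na(padding) || padding < 1L) stop("`padding` must be a positive integer", call. = FALSE)
  if (anyDuplicated(names(type_codes))) stop("type codes must be unique", call. = FALSE)
  cfg <- list(
    bases = sub("/+$", "", bases),
    prefixes = c(sub("/+$", "", bases), prefixes, vocab_namespaces()),
    padding = padding,
    type_codes = type_codes,
    tz = tz
  )
  class(cfg) <- "pheno_config"
  cfg
}

#' @export
print.pheno_config <- function(x, ...) {
  cat("<pheno_config>\n")
  cat("  bases:", paste(names(x$bases), x$bases, sep = " = ", collapse = ", "), "\n")
  cat("  padding:", x$padding, "  tz:", x$tz, "\n")
  cat("  type codes:", paste(names(x$type_codes), x$type_codes, sep = "->", collapse = ", "), "\n")
  invisible(x)
}

default_bases <- function() {
  c(
    m3p = "http://www.phenome-fppn.fr/m3p",
    diaphen = "http://www.phenome-fppn.fr/diaphen"
  )
}

#' Built-in object type codes
#'
#' The letter codes embedded in structured URIs and the object classes they
#' denote: `c` plant, `o` plot, `l` leaf, `pc` pot, `ct` cart, `ac` device,
#' `ic` image.
#'
#' @return named character vector (code -> class name).
#' @export
default_type_codes <- function() {
  c(
    c = "Plant", o = "Plot", l = "Leaf", pc = "Pot",
    ct = "Cart", ac = "Device", ic = "Image"
  )
}

#' Read / write a store configuration file
#'
#' Plain YAML key-value file declaring bases, prefixes, padding width and type
#' codes.
#'
#' @param path file path.
#' @param config a [store_config()] object (for writing).
#' @return [read_store_config()] returns a `pheno_config`;
#'   [write_store_config()] returns `path` invisibly.
#' @export
read_store_config <- function(path) {
  raw <- yaml::read_yaml(path)
  store_config(
    bases = unlist(raw$bases %||% default_bases()),
    prefixes = unlist(raw$prefixes %||% character()),
    padding = raw$padding %||% 6L,
    type_codes = unlist(raw$type_codes %||% default_type_codes()),
    tz = raw$tz %||% "UTC"
  )
}

#' @rdname read_store_config
#' @export
write_store_config <- function(config, path) {
  yaml::write_yaml(
    list(
      bases = as.list(config$bases),
      padding = config$padding,
      type_codes = as.list(config$type_codes),
      tz = config$tz
    ),
    path
  )
  invisible(path)
}

#' @export
print.pheno_store <- function(x, ...) {
  cat("<pheno_store>\n")
  cat("  triples:      ", nrow(x$triples), "\n")
  cat("  classed:      ", nrow(x$classes), "resources\n")
  cat("  events:       ", nrow(x$events), "\n")
  cat("  annotations:  ", nrow(x$annotations), "\n")
  cat("  series points:", nrow(x$series), "\n")
  cat("  observations: ", nrow(x$observations), "\n")
  cat("  variables:    ", nrow(x$variables), "\n")
  invisible(x)
}

# ---- internal shared helpers -------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_instant <- function() as.POSIXct(character(), tz = "UTC")

empty_triples <- function() {
  tibble::tibble(
    subject = character(), predicate = character(),
    object = character(), literal_kind = character()
  )
}

empty_events <- function() {
  tibble::tibble(
    uri = character(), event_class = character(), timestamp = empty_instant(),
    concerns = list(), agent = character(), description = character(),
    properties = list()
  )
}

empty_annotations <- function() {
  tibble::tibble(
    uri = character(), agent = character(), created = empty_instant(),
    motivation = character(), body = character(), targets = list()
  )
}

empty_observations <- function() {
  tibble::tibble(
    object = character(), variable = character(), timestamp = empty_instant(),
    value = double(), value_text = character(),
    image = character(), method = character(), agent = character()
  )
}

assert_store <- function(store) {
  if (!inherits(store, "pheno_store")) {
    stop("expected a `pheno_store` (see `pheno_store()`)", call. = FALSE)
  }
  invisible(store)
}

invalidate_cache <- function(store) {
  rm(list = ls(store$cache, all.names = TRUE), envir = store$cache)
  invisible(store)
}

#' Parse timestamps
#'
#' Accepts `POSIXct`, `Date`, or ISO-8601 strings (date-only strings are taken
#' as midnight UTC). All instants in the store are kept in UTC.
#'
#' @param x vector to parse.
#' @return `POSIXct` in UTC.
#' @keywords internal
parse_instant <- function(x) {
  if (inherits(x, "POSIXct")) return(lubridate::with_tz(x, "UTC"))
  if (inherits(x, "Date")) return(as.POSIXct(x, tz = "UTC"))
  out <- suppressWarnings(lubridate::as_datetime(x, tz = "UTC"))
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    stop("unparseable timestamp(s): ", paste(utils::head(x[bad], 3), collapse = ", "),
      call. = FALSE
    )
  }
  out
}

format_instant <- function(x) {
  format(lubridate::with_tz(x, "UTC"), "%Y-%m-%dT%H:%M:%SZ")
}

# Is a URI known to the store (classed, minted, or mentioned in a triple)?
object_exists <- function(store, uri) {
  vapply(uri, function(u) {
    if (is.na(u) || !nzchar(u)) return(FALSE)
    if (!is.null(store$minted[[u]])) return(TRUE)
    if (u %in% store$classes$resource) return(TRUE)
    if (u %in% store$triples$subject) return(TRUE)
    res_obj <- store$triples$object[is.na(store$triples$literal_kind)]
    u %in% res_obj
  }, logical(1), USE.NAMES = FALSE)
}

# Deterministic 31-bit string hash (for deriving per-resource RNG streams).
hash31 <- function(x) {
  vapply(x, function(s) {
    h <- 17
    for (b in utf8ToInt(enc2utf8(s))) h <- (h * 31 + b) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

derive_seed <- function(seed, key) {
  as.integer((as.numeric(seed) * 1000003 + hash31(key)) %% 2147483647)
}
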