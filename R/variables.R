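#' Define a trait, method or unit term
#'
#' Observed variables are triplets of terms: the trait (what is measured), the
#' method (how) and the unit. Terms are local URIs with a label and may carry
#' SKOS-style mappings to reference-ontology identifiers (see
#' [add_mapping()]); methods may stay local-only with no mapping at all.
#'
#' @param store a [pheno_store()].
#' @param uri local term URI.
#' @param label non-empty human-readable label.
#' @param kind `"trait"`, `"method"` or `"unit"`.
#' @return the store, invisibly.
#' @export
define_term <- function(store, uri, label, kind = c("trait", "method", "unit")) {
  assert_store(store)
  kind <- match.arg(kind)
  if (!is.character(label) || length(label) != 1 || is.na(label) || !nzchar(label)) {
    stop("term `label` must be non-empty", call. = FALSE)
  }
  store$terms <- dplyr::distinct(dplyr::bind_rows(
    store$terms[store$terms$uri != uri, ],
    tibble::tibble(uri = uri, label = label, kind = kind)
  ))
  cls <- c(trait = "Trait", method = "Method", unit = "Unit")[[kind]]
  assert_class(store, uri, cls)
  add_triple(store, uri, "label", label, literal_kind = "string")
  invisible(store)
}

term_kind <- function(store, uri) {
  store$terms$kind[match(uri, store$terms$uri)]
}

#' Define a variable as a trait-method-unit triplet
#'
#' Two variables may share a trait while differing in method or unit — e.g.
#' leaf area measured on a 3-D plant reconstruction in the glasshouse vs
#' inferred from the gap fraction in the field are distinct variables. The
#' component terms must already be defined with the matching kinds.
#'
#' @param store a [pheno_store()].
#' @param uri local variable URI.
#' @param trait,method,unit term URIs of the respective kinds.
#' @return the store, invisibly.
#' @export
define_variable <- function(store, uri, trait, method, unit) {
  assert_store(store)
  comp <- c(trait = trait, method = method, unit = unit)
  for (slot in names(comp)) {
    k <- term_kind(store, comp[[slot]])
    if (is.na(k)) stop("unknown term '", comp[[slot]], "'", call. = FALSE)
    if (k != slot) {
      stop(
        "term '", comp[[slot]], "' has kind '", k, "' but is used as the ",
        slot, " of '", uri, "'",
        call. = FALSE
      )
    }
  }
  store$variables <- dplyr::bind_rows(
    store$variables[store$variables$uri != uri, ],
    tibble::tibble(uri = uri, trait = trait, method = method, unit = unit)
  )
  assert_class(store, uri, "Variable")
  add_triples(store, tibble::tibble(
    subject = uri,
    predicate = c("hasTrait", "hasMethod", "hasUnit"),
    object = c(trait, method, unit)
  ))
  invisible(store)
}

#' Map a local term to an external ontology identifier
#'
#' Records a SKOS-style mapping (`exactMatch`, `closeMatch`, `broader` or
#' `narrower`) between a local term and an opaque external identifier such as
#' `"CO_322:0000880"` (a Crop Ontology trait) or `"UO_0000242"` (a Unit
#' Ontology unit). Mappings are stored as triples in the knowledge graph, so
#' they survive serialization round-trips; duplicates collapse. External
#' identifiers are not resolved against live ontology services.
#'
#' @param store a [pheno_store()].
#' @param term local term URI (must be defined).
#' @param relation one of the four SKOS mapping relations.
#' @param external_id opaque external identifier.
#' @return the store, invisibly.
#' @export
add_mapping <- function(store, term, relation, external_id) {
  assert_store(store)
  if (!(relation %in% SKOS_RELATIONS)) {
    stop(
      "unknown mapping relation '", relation, "' (use one of: ",
      paste(SKOS_RELATIONS, collapse = ", "), ")",
      call. = FALSE
    )
  }
  if (is.na(term_kind(store, term))) {
    stop("unknown term '", term, "'", call. = FALSE)
  }
  add_triple(store, term, relation, external_id, literal_kind = "string")
  invisible(store)
}

#' Mappings of a term
#'
#' @param store a [pheno_store()].
#' @param term local term URI.
#' @return a tibble with columns `relation` and `external_id`.
#' @export
term_mappings <- function(store, term) {
  t <- store$triples
  hit <- t$subject == term & t$predicate %in% SKOS_RELATIONS
  tibble::tibble(relation = t$predicate[hit], external_id = t$object[hit])
}

#' Find local terms by external identifier
#'
#' Inverse lookup: which local terms carry a mapping (in the requested
#' relation set) to a given external ontology identifier. This is how a
#' standardized query (e.g. by Crop Ontology accession) reaches
#' installation-local vocabulary.
#'
#' @param store a [pheno_store()].
#' @param external_id external identifier string.
#' @param relations subset of the four SKOS relations to honour (default:
#'   `exactMatch` and `closeMatch`).
#' @return sorted character vector of local term URIs (possibly empty).
#' @export
find_by_external <- function(store, external_id,
                             relations = c("exactMatch", "closeMatch")) {
  assert_store(store)
  bad <- setdiff(relations, SKOS_RELATIONS)
  if (length(bad)) stop("unknown mapping relation '", bad[1], "'", call. = FALSE)
  t <- store$triples
  hit <- t$predicate %in% relations & t$object == external_id
  sort(unique(t$subject[hit]))
}
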