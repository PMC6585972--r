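#' Vocabulary namespaces
#'
#' Namespaces used when serializing the knowledge graph: the experimental
#' object and event vocabularies, SKOS mapping relations, RDF/RDFS plumbing and
#' XML-Schema datatypes.
#'
#' @return named character vector of namespace URIs.
#' @export
vocab_namespaces <- function() {
  c(
    oepo = "http://www.phenome-fppn.fr/vocabulary/2018/oepo#",
    oeev = "http://www.phenome-fppn.fr/vocabulary/2018/oeev#",
    skos = "http://www.w3.org/2004/02/skos/core#",
    rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs = "http://www.w3.org/2000/01/rdf-schema#",
    xsd = "http://www.w3.org/2001/XMLSchema#"
  )
}

RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
SKOS_RELATIONS <- c("exactMatch", "closeMatch", "broader", "narrower")

# predicate short name -> serialization URI
predicate_uri <- function(predicate) {
  ns <- vocab_namespaces()
  ifelse(predicate %in% SKOS_RELATIONS, paste0(ns[["skos"]], predicate),
    ifelse(predicate == "label", paste0(ns[["rdfs"]], "label"),
      ifelse(grepl("://", predicate, fixed = TRUE), predicate,
        paste0(ns[["oepo"]], predicate)
      )
    )
  )
}

# serialization URI -> predicate short name (unknown vocab stays verbatim)
predicate_local <- function(uri) {
  ns <- vocab_namespaces()
  out <- uri
  for (n in c("oepo", "skos")) {
    pfx <- ns[[n]]
    hit <- startsWith(out, pfx)
    out[hit] <- substring(out[hit], nchar(pfx) + 1)
  }
  out[out == paste0(ns[["rdfs"]], "label")] <- "label"
  out
}

class_uri <- function(store, class) {
  ns <- vocab_namespaces()
  nsname <- store$hierarchy$namespace[match(class, store$hierarchy$class)]
  paste0(ifelse(nsname == "OEEv", ns[["oeev"]], ns[["oepo"]]), class)
}

datatype_uri <- function(kind) {
  ns <- vocab_namespaces()[["xsd"]]
  c(number = paste0(ns, "double"), timestamp = paste0(ns, "dateTime"))[kind]
}

kind_from_datatype <- function(dt) {
  ns <- vocab_namespaces()[["xsd"]]
  if (is.na(dt) || !nzchar(dt)) return("string")
  if (dt == paste0(ns, "double") || dt == paste0(ns, "decimal") ||
    dt == paste0(ns, "integer")) {
    return("number")
  }
  if (dt == paste0(ns, "dateTime") || dt == paste0(ns, "date")) {
    return("timestamp")
  }
  "string"
}

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_literal <- function(x) {
  x <- gsub("\\t", "\t", x, fixed = TRUE)
  x <- gsub("\\r", "\r", x, fixed = TRUE)
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

# the full serializable triple table: asserted triples + class assertions
serializable_triples <- function(store) {
  rows <- store$triples
  rows$predicate <- predicate_uri(rows$predicate)
  if (nrow(store$classes)) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      subject = store$classes$resource,
      predicate = RDF_TYPE,
      object = class_uri(store, store$classes$class),
      literal_kind = NA_character_
    ))
  }
  dplyr::arrange(rows, .data$subject, .data$predicate, .data$object)
}

render_object <- function(object, literal_kind) {
  ifelse(is.na(literal_kind),
    paste0("<", object, ">"),
    ifelse(literal_kind == "string",
      paste0("\"", escape_literal(object), "\""),
      paste0("\"", escape_literal(object), "\"^^<", datatype_uri(literal_kind), ">")
    )
  )
}

#' Write the knowledge graph to a file
#'
#' Serializes asserted triples plus class assertions (`rdf:type`) as N-Triples
#' or as a Turtle subset (`@prefix` declarations, `a` for class assertions, one
#' statement per line). Output row order is deterministic, so equal graphs give
#' byte-identical files.
#'
#' @param store a [pheno_store()].
#' @param path output file path.
#' @param format `"ntriples"` or `"turtle"`.
#' @return `path`, invisibly.
#' @seealso [read_triples()]
#' @export
write_triples <- function(store, path, format = c("ntriples", "turtle")) {
  assert_store(store)
  format <- match.arg(format)
  rows <- serializable_triples(store)
  if (format == "ntriples") {
    lines <- paste0(
      "<", rows$subject, "> <", rows$predicate, "> ",
      render_object(rows$object, rows$literal_kind), " ."
    )
  } else {
    prefixes <- store$config$prefixes
    prefixes <- prefixes[!duplicated(names(prefixes))]
    compact <- function(uri) {
      out <- paste0("<", uri, ">")
      for (i in order(-nchar(prefixes))) {
        pfx <- prefixes[[i]]
        sep <- if (grepl("[#/]$", pfx)) "" else "/"
        full <- paste0(pfx, sep)
        hit <- startsWith(uri, full) & !grepl("[ \"<>]", substring(uri, nchar(full) + 1))
        out[hit] <- paste0(names(prefixes)[i], ":", substring(uri[hit], nchar(full) + 1))
      }
      out
    }
    header <- paste0(
      "@prefix ", names(prefixes), ": <",
      ifelse(grepl("[#/]$", prefixes), prefixes, paste0(prefixes, "/")), "> ."
    )
    pred_txt <- ifelse(rows$predicate == RDF_TYPE, "a", compact(rows$predicate))
    obj_txt <- ifelse(is.na(rows$literal_kind),
      compact(rows$object),
      render_object(rows$object, rows$literal_kind)
    )
    lines <- c(header, "", paste0(compact(rows$subject), " ", pred_txt, " ", obj_txt, " ."))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read triples into a store
#'
#' Parses N-Triples or the Turtle subset written by [write_triples()]
#' (`@prefix` declarations, `a` for class assertions, one statement per line;
#' blank lines and `#` comments are skipped). Prefixed names are expanded;
#' `rdf:type` statements whose object resolves to a class known to the store's
#' hierarchy become class assertions; vocabulary predicates are mapped back to
#' their short names. Syntax errors report the offending line number.
#'
#' `write_triples()` then `read_triples()` into a fresh store is the identity
#' on the triple set and class assertions.
#'
#' @param store a [pheno_store()] to add the triples to.
#' @param path input file path (or a character vector of lines via `text`).
#' @param format `"ntriples"` or `"turtle"`.
#' @param text optional character vector of lines, used instead of `path`.
#' @return the store, invisibly.
#' @export
read_triples <- function(store, path = NULL, format = c("ntriples", "turtle"),
                         text = NULL) {
  assert_store(store)
  format <- match.arg(format)
  lines <- text %||% readLines(path, warn = FALSE)
  prefixes <- store$config$prefixes
  syntax_error <- function(i, why) {
    stop("syntax error at line ", i, ": ", why, call. = FALSE)
  }
  parse_term <- function(tok, i, prefixes) {
    if (startsWith(tok, "<")) {
      if (!endsWith(tok, ">")) syntax_error(i, "unterminated IRI")
      return(list(value = substr(tok, 2, nchar(tok) - 1), kind = NA_character_))
    }
    if (startsWith(tok, "\"")) {
      m <- regmatches(
        tok,
        regexec('^"((?:[^"\\\\]|\\\\.)*)"(?:\\^\\^(<[^>]+>|[A-Za-z][A-Za-z0-9_.-]*:[^ ]+))?$', tok)
      )[[1]]
      if (length(m) != 3) syntax_error(i, "malformed literal")
      dt <- m[3]
      if (nzchar(dt)) {
        dt <- if (startsWith(dt, "<")) substr(dt, 2, nchar(dt) - 1) else expand_prefixed(dt, prefixes)
      } else {
        dt <- NA_character_
      }
      return(list(value = unescape_literal(m[2]), kind = kind_from_datatype(dt)))
    }
    # prefixed name
    list(value = expand_prefixed(tok, prefixes), kind = NA_character_)
  }
  subjects <- character()
  preds <- character()
  objects <- character()
  kinds <- character()
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (format == "turtle" && grepl("^@prefix", line)) {
      m <- regmatches(line, regexec("^@prefix\\s+([A-Za-z][A-Za-z0-9_.-]*):\\s*<([^>]*)>\\s*\\.$", line))[[1]]
      if (length(m) != 3) syntax_error(i, "malformed @prefix")
      prefixes[m[2]] <- m[3]
      next
    }
    if (!grepl("\\.$", line)) syntax_error(i, "unterminated statement (missing '.')")
    body <- trimws(sub("\\.$", "", line))
    # subject and predicate never contain spaces in this subset
    m <- regmatches(body, regexec("^(\\S+)\\s+(\\S+)\\s+(.+)$", body))[[1]]
    if (length(m) != 4) syntax_error(i, "expected 'subject predicate object .'")
    s <- parse_term(m[2], i, prefixes)
    if (!is.na(s$kind)) syntax_error(i, "literal subject")
    p_tok <- m[3]
    if (format == "turtle" && p_tok == "a") {
      p_uri <- RDF_TYPE
    } else {
      p <- parse_term(p_tok, i, prefixes)
      if (!is.na(p$kind)) syntax_error(i, "literal predicate")
      p_uri <- p$value
    }
    o <- parse_term(m[4], i, prefixes)
    subjects <- c(subjects, s$value)
    preds <- c(preds, p_uri)
    objects <- c(objects, o$value)
    kinds <- c(kinds, o$kind)
  }
  if (!length(subjects)) {
    return(invisible(store))
  }
  df <- tibble::tibble(
    subject = subjects, predicate = preds, object = objects, literal_kind = kinds
  )
  is_type <- df$predicate == RDF_TYPE
  if (any(is_type)) {
    cls_local <- basename_uri(df$object[is_type])
    known <- cls_local %in% store$hierarchy$class
    if (any(known)) {
      assert_class(store, df$subject[is_type][known], cls_local[known])
    }
    # unknown classes stay as plain rdf:type triples
    keep_type <- which(is_type)[!known]
    df <- df[c(which(!is_type), keep_type), ]
  }
  if (nrow(df)) {
    df$predicate <- predicate_local(df$predicate)
    add_triples(store, df)
  }
  invisible(store)
}

basename_uri <- function(uri) sub("^.*[#/]", "", uri)
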