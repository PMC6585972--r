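#' Structured resource URIs
#'
#' Every physical object in an experiment (plant, plot, leaf, pot, cart,
#' device, image, ...) is identified by a structured URI of the form
#'
#' ```
#' <base>/<path.../><year>/<type code><yy><serial>
#' ```
#'
#' where `base` is the infrastructure prefix (national + local, e.g.
#' `http://www.phenome-fppn.fr/m3p`), `path` is zero or more installation
#' segments (e.g. `arch`), `year` is the 4-digit campaign year, the type code
#' is a short lowercase letter code (see [default_type_codes()]), `yy` repeats
#' the last two digits of the year and `serial` is a zero-padded positive
#' integer. Example: `http://www.phenome-fppn.fr/m3p/arch/2017/c17000118` is
#' plant 118 of the 2017 campaign in the `arch` installation.
#'
#' `resource_uri()` builds one from components; [mint_uri()] draws the next
#' serial from a store's counters; [parse_uri()] decomposes a string.
#'
#' @param base absolute base URI (no trailing slash needed).
#' @param path character vector of installation segments (may be empty).
#' @param year 4-digit integer campaign year.
#' @param type_code lowercase letter code.
#' @param serial positive integer.
#' @param padding zero-padding width for the serial (widened automatically if
#'   the serial needs more digits).
#' @return a `resource_uri` object: a list with fields `base`, `path`, `year`,
#'   `type_code`, `serial` and `canonical` (the full string form).
#' @export
resource_uri <- function(base, path = character(), year, type_code, serial,
                         padding = 6L) {
  base <- sub("/+$", "", base)
  year <- as.integer(year)
  serial <- as.numeric(serial)
  if (is.na(year) || year < 1000L || year > 9999L) {
    stop("`year` must be a 4-digit integer", call. = FALSE)
  }
  if (is.na(serial) || serial < 1) stop("`serial` must be >= 1", call. = FALSE)
  width <- max(as.integer(padding), nchar(format(serial, scientific = FALSE)))
  local <- sprintf("%s%02d%0*.0f", type_code, year %% 100L, width, serial)
  canonical <- paste(c(base, path, year, local), collapse = "/")
  structure(
    list(
      base = base, path = as.character(path), year = year,
      type_code = type_code, serial = serial, canonical = canonical
    ),
    class = "resource_uri"
  )
}

#' @export
format.resource_uri <- function(x, ...) x$canonical

#' @export
print.resource_uri <- function(x, ...) {
  cat("<", x$canonical, ">\n", sep = "")
  cat(
    "  base:", x$base,
    " path:", if (length(x$path)) paste(x$path, collapse = "/") else "(none)",
    " year:", x$year, " type:", x$type_code, " serial:", format(x$serial), "\n"
  )
  invisible(x)
}

#' @export
as.character.resource_uri <- function(x, ...) x$canonical

#' @export
`==.resource_uri` <- function(e1, e2) {
  identical(e1$base, e2$base) && identical(e1$path, e2$path) &&
    identical(e1$year, e2$year) && identical(e1$type_code, e2$type_code) &&
    e1$serial == e2$serial
}

#' Register an object type code
#'
#' @param store a [pheno_store()].
#' @param code short lowercase letter code (unique).
#' @param class the object class the code denotes.
#' @return the store, invisibly.
#' @export
register_type_code <- function(store, code, class) {
  assert_store(store)
  if (!grepl("^[a-z]+$", code)) stop("type code must be lowercase letters", call. = FALSE)
  if (code %in% names(store$config$type_codes)) {
    stop("type code '", code, "' already registered", call. = FALSE)
  }
  store$config$type_codes[[code]] <- class
  invisible(store)
}

counter_key <- function(base, year, type_code) paste(base, year, type_code, sep = "\r")

#' Mint the next URI for an object type
#'
#' Draws the next serial from the per-(base, year, type code) counter, records
#' the URI as existing, and returns it. Counters are monotonic: a minted serial
#' is never reissued, so minted URIs are pairwise distinct. If the next serial
#' no longer fits in the configured padding width the width is widened with a
#' warning.
#'
#' @param store a [pheno_store()].
#' @param type_code a registered type code (see [default_type_codes()]).
#' @param year 4-digit campaign year.
#' @param base a configured base abbreviation (e.g. `"m3p"`) or an absolute
#'   base URI.
#' @param path installation path segments (e.g. `"arch"`).
#' @return a [resource_uri()].
#' @examples
#' st <- pheno_store()
#' u <- mint_uri(st, "c", 2017, base = "m3p", path = "arch")
#' @export
mint_uri <- function(store, type_code, year, base, path = character()) {
  assert_store(store)
  codes <- store$config$type_codes
  if (!(type_code %in% names(codes))) {
    stop("unknown type code '", type_code, "' (registered: ",
      paste(names(codes), collapse = ", "), ")",
      call. = FALSE
    )
  }
  year <- as.integer(year)
  if (is.na(year) || year < 1000L || year > 9999L) {
    stop("`year` must be a 4-digit integer", call. = FALSE)
  }
  base_uri <- expand_base(store$config, base)
  key <- counter_key(base_uri, year, type_code)
  serial <- (store$counters[[key]] %||% 0) + 1
  store$counters[[key]] <- serial
  padding <- store$config$padding
  if (nchar(format(serial, scientific = FALSE)) > padding) {
    warning("serial ", serial, " exceeds padding width ", padding, "; widening",
      call. = FALSE
    )
  }
  u <- resource_uri(base_uri, path, year, type_code, serial, padding = padding)
  store$minted[[u$canonical]] <- TRUE
  assert_class(store, u$canonical, codes[[type_code]])
  u
}

expand_base <- function(config, base) {
  if (base %in% names(config$bases)) {
    config$bases[[base]]
  } else if (grepl("://", base, fixed = TRUE)) {
    sub("/+$", "", base)
  } else {
    stop("unknown base abbreviation '", base, "'", call. = FALSE)
  }
}

#' Expand a prefixed name to an absolute URI
#'
#' `m3p:arch/2017/c17000118` becomes
#' `http://www.phenome-fppn.fr/m3p/arch/2017/c17000118` given the default
#' prefix table. Absolute URIs pass through unchanged.
#'
#' @param text character vector.
#' @param prefixes named character vector of prefix expansions.
#' @return character vector of absolute URIs.
#' @export
expand_prefixed <- function(text, prefixes) {
  vapply(text, function(x) {
    if (grepl("://", x, fixed = TRUE)) return(x)
    m <- regmatches(x, regexec("^([A-Za-z][A-Za-z0-9_.-]*):(.*)$", x))[[1]]
    if (length(m) == 3) {
      pfx <- m[2]
      if (!(pfx %in% names(prefixes))) {
        stop("unknown prefix '", pfx, ":'", call. = FALSE)
      }
      expansion <- prefixes[[pfx]]
      sep <- if (grepl("[#/]$", expansion)) "" else "/"
      return(paste0(expansion, sep, m[3]))
    }
    x
  }, character(1), USE.NAMES = FALSE)
}

#' Parse a structured URI
#'
#' Decomposes the canonical string form into its components. Prefixed forms
#' (e.g. `m3p:arch/2017/c17000118`) are expanded first via the configured
#' prefix table. The local identifier's leading letter run is the type code,
#' the next two digits must repeat the year directory modulo 100, and the
#' remaining digits are the serial; any zero-padding width is accepted.
#'
#' @param text a single URI string.
#' @param config a [store_config()] (or a [pheno_store()], whose config is
#'   used) supplying base URIs and prefix expansions.
#' @return a [resource_uri()].
#' @examples
#' parse_uri("http://www.phenome-fppn.fr/m3p/arch/2017/c17000118")
#' @export
parse_uri <- function(text, config = store_config()) {
  if (inherits(config, "pheno_store")) config <- config$config
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(text)) stop("empty URI", call. = FALSE)
  text <- expand_prefixed(text, config$prefixes)
  if (!grepl("://", text, fixed = TRUE)) {
    stop("not an absolute URI: '", text, "'", call. = FALSE)
  }
  segs <- strsplit(text, "/", fixed = TRUE)[[1]]
  segs <- segs[nzchar(segs) | seq_along(segs) <= 2] # keep "http:" "" structure out
  # segs: "http:" "" host seg1 seg2 ...
  if (length(segs) < 5) stop("missing year segment in '", text, "'", call. = FALSE)
  local <- segs[length(segs)]
  year_seg <- segs[length(segs) - 1]
  if (!grepl("^[0-9]{4}$", year_seg)) {
    stop("missing year segment before local identifier in '", text, "'", call. = FALSE)
  }
  year <- as.integer(year_seg)
  m <- regmatches(local, regexec("^([A-Za-z]+)([0-9]*)$", local))[[1]]
  if (length(m) != 3 || !nzchar(m[2])) {
    stop("malformed local identifier '", local, "'", call. = FALSE)
  }
  type_code <- m[2]
  digits <- m[3]
  if (nchar(digits) < 3) {
    stop("empty serial in local identifier '", local, "'", call. = FALSE)
  }
  yy <- as.integer(substr(digits, 1, 2))
  if (yy != year %% 100L) {
    stop(
      "year digits '", substr(digits, 1, 2), "' in '", local,
      "' do not match year segment ", year, call. = FALSE
    )
  }
  serial_txt <- substr(digits, 3, nchar(digits))
  serial <- as.numeric(serial_txt)
  if (serial < 1) stop("serial must be >= 1 in '", local, "'", call. = FALSE)
  # split base vs path: longest configured base that prefixes the URI wins;
  # otherwise scheme://host/first-segment (national + local infrastructure).
  pre <- segs[seq_len(length(segs) - 2)]
  host_prefix <- paste0(pre[1], "//", pre[3])
  rest <- if (length(pre) > 3) pre[4:length(pre)] else character()
  base <- NULL
  bases <- config$bases[order(-nchar(config$bases))]
  for (b in bases) {
    if (startsWith(paste0(text, "/"), paste0(b, "/"))) {
      base <- b
      break
    }
  }
  if (is.null(base)) {
    base <- if (length(rest)) paste(c(host_prefix, rest[1]), collapse = "/") else host_prefix
  }
  n_base_segs <- length(strsplit(sub("^[a-z]+://", "", base), "/")[[1]]) - 1L
  path <- if (length(rest) > n_base_segs) rest[(n_base_segs + 1):length(rest)] else character()
  u <- resource_uri(base, path, year, type_code, serial,
    padding = nchar(serial_txt)
  )
  u$canonical <- text
  u
}
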