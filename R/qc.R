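#' Summarize a trait kinetic into a scalar
#'
#' Reduces a per-object time course (e.g. a leaf-area growth curve from image
#' analysis) to a single comparable number: the final value, or the area under
#' the curve by the trapezoid rule with time measured in days.
#'
#' @param points a data frame with columns `timestamp` and `value` (at least
#'   one row).
#' @param statistic `"final_value"` or `"auc"`.
#' @return a numeric scalar.
#' @examples
#' pts <- data.frame(
#'   timestamp = c("2017-04-13", "2017-04-15"),
#'   value = c(0, 4)
#' )
#' summarize_kinetics(pts, "auc") # triangle: 4
#' @export
summarize_kinetics <- function(points, statistic = c("final_value", "auc")) {
  statistic <- match.arg(statistic)
  points <- tibble::as_tibble(points)
  if (!nrow(points)) stop("empty series", call. = FALSE)
  ts <- parse_instant(points$timestamp)
  ord <- order(ts)
  ts <- ts[ord]
  v <- as.numeric(points$value)[ord]
  if (statistic == "final_value") {
    return(v[length(v)])
  }
  if (length(v) == 1) {
    return(0)
  }
  days <- as.numeric(difftime(ts, ts[1], units = "secs")) / 86400
  sum(diff(days) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}

#' Replicate groups of a variable
#'
#' Groups the objects carrying observations of `variable` by their genotype
#' (the `hasVariety` relation) and computes the per-member summary statistic,
#' ready for [flag_outliers()].
#'
#' @param store a [pheno_store()].
#' @param variable variable URI.
#' @param statistic passed to [summarize_kinetics()].
#' @param window optional length-2 vector of instants restricting the curves.
#' @return a tibble with columns `genotype`, `member`, `value`.
#' @export
replicate_groups <- function(store, variable, statistic = "auc", window = NULL) {
  assert_store(store)
  t <- store$triples
  gt <- t[t$predicate == "hasVariety" & is.na(t$literal_kind), c("subject", "object")]
  obs <- store$observations[store$observations$variable == variable, ]
  if (!is.null(window)) {
    w <- parse_instant(window)
    obs <- obs[obs$timestamp >= w[1] & obs$timestamp < w[2], ]
  }
  members <- intersect(unique(obs$object), gt$subject)
  if (!length(members)) {
    return(tibble::tibble(genotype = character(), member = character(), value = double()))
  }
  out <- lapply(members, function(m) {
    pts <- obs[obs$object == m, c("timestamp", "value")]
    tibble::tibble(
      genotype = gt$object[match(m, gt$subject)],
      member = m,
      value = summarize_kinetics(pts, statistic)
    )
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$genotype, .data$member)
}

#' Flag anomalous replicates
#'
#' Robust screen for a deviant replicate among plants of the same genotype —
#' e.g. a seed contamination that makes one of four replicates grow far more
#' slowly. Each member's modified z-score is
#' `0.6745 * |x - median| / MAD` (MAD = median absolute deviation from the
#' median); members whose score exceeds the threshold (default 3.5, the usual
#' modified-z convention) are flagged. When the MAD is zero the score falls
#' back to the mean absolute deviation form
#' `|x - median| / (1.253314 * meanAD)`; when that is also zero all members
#' are identical and nothing is flagged. Groups with fewer than three members
#' yield an empty flag set with a warning. The detector is scale-invariant and
#' its name is recorded in the report so alternatives can be compared.
#'
#' @param summaries per-member summary values: a named numeric vector, or a
#'   data frame with columns `member` and `value` (e.g. one genotype's rows
#'   from [replicate_groups()]).
#' @param threshold flagging threshold on the modified z-score.
#' @param genotype optional genotype URI recorded in the report.
#' @return an `outlier_report`: list with fields `genotype`, `method`,
#'   `threshold`, and `scores` (tibble `member`, `value`, `score`, `flagged`).
#' @examples
#' flag_outliers(c(a = 100, b = 102, c = 98, d = 50)) # flags d (score ~16.5)
#' @export
flag_outliers <- function(summaries, threshold = 3.5, genotype = NA_character_) {
  if (is.data.frame(summaries)) {
    member <- summaries$member
    value <- summaries$value
    if ("genotype" %in% names(summaries) && is.na(genotype)) {
      genotype <- summaries$genotype[1]
    }
  } else {
    value <- as.numeric(summaries)
    member <- names(summaries) %||% paste0("member", seq_along(value))
  }
  if (any(!is.finite(value))) stop("summary values must be finite", call. = FALSE)
  n <- length(value)
  if (n < 3) {
    warning("fewer than 3 replicates; nothing flagged", call. = FALSE)
    scores <- rep(NA_real_, n)
  } else {
    med <- stats::median(value)
    dev <- abs(value - med)
    mad0 <- stats::median(dev)
    if (mad0 > 0) {
      scores <- 0.6745 * dev / mad0
    } else {
      mean_ad <- mean(dev)
      scores <- if (mean_ad > 0) dev / (1.253314 * mean_ad) else rep(0, n)
    }
  }
  flagged <- !is.na(scores) & scores > threshold
  structure(
    list(
      genotype = genotype,
      method = "modified_zscore",
      threshold = threshold,
      scores = tibble::tibble(
        member = member, value = value, score = scores, flagged = flagged
      )
    ),
    class = "outlier_report"
  )
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(
    "Outlier report (", x$method, ", threshold ", x$threshold, ") - ",
    sum(x$scores$flagged), " of ", nrow(x$scores), " flagged\n",
    sep = ""
  )
  print(x$scores)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname flag_outliers
#' @param x an `outlier_report`.
#' @param ... unused.
#' @export
tidy.outlier_report <- function(x, ...) x$scores

#' @rdname flag_outliers
#' @export
glance.outlier_report <- function(x, ...) {
  tibble::tibble(
    genotype = x$genotype, method = x$method, threshold = x$threshold,
    n = nrow(x$scores), n_flagged = sum(x$scores$flagged),
    max_score = if (nrow(x$scores)) suppressWarnings(max(x$scores$score)) else NA_real_
  )
}

#' Screen all replicate groups of an experiment
#'
#' Runs [flag_outliers()] on every genotype's replicate group for a variable.
#'
#' @param store a [pheno_store()].
#' @param variable variable URI.
#' @param statistic passed to [summarize_kinetics()].
#' @param threshold passed to [flag_outliers()].
#' @param window optional time window.
#' @return a list of `outlier_report`s, named by genotype.
#' @export
qc_outliers <- function(store, variable, statistic = "auc", threshold = 3.5,
                        window = NULL) {
  groups <- replicate_groups(store, variable, statistic, window)
  out <- lapply(split(groups, groups$genotype), function(g) {
    suppressWarnings(flag_outliers(g, threshold = threshold))
  })
  out[order(names(out))]
}

#' Trace the origin of an object through the graph
#'
#' Walks configured provenance paths backwards from an object — typically to
#' find the seed lot a suspicious plant derives from, or its declared variety.
#'
#' @param store a [pheno_store()].
#' @param object object URI.
#' @param predicate_paths list of predicate paths (each a character vector);
#'   defaults to `derivesFrom` and `hasVariety`.
#' @return a named list mapping each path (names joined with `/`) to the
#'   reachable resources (possibly empty).
#' @export
trace_origin <- function(store, object,
                         predicate_paths = list("derivesFrom", "hasVariety")) {
  assert_store(store)
  out <- lapply(predicate_paths, function(p) kg_related(store, object, p))
  names(out) <- vapply(predicate_paths, paste, character(1), collapse = "/")
  out
}

#' Auto-annotate flagged replicates
#'
#' Creates one flagging annotation per flagged member of an outlier report,
#' naming the method, score and threshold in the body. Each call creates fresh
#' annotations with new URIs — re-running on the same report is not
#' idempotent, by design (each screening run is its own provenance record).
#'
#' @param store a [pheno_store()].
#' @param report an `outlier_report` from [flag_outliers()].
#' @param agent agent URI recorded as the annotator.
#' @return a tibble of the created annotations (zero rows when nothing is
#'   flagged).
#' @export
auto_annotate <- function(store, report, agent) {
  assert_store(store)
  stopifnot(inherits(report, "outlier_report"))
  flagged <- report$scores[report$scores$flagged, ]
  rows <- lapply(seq_len(nrow(flagged)), function(i) {
    annotate(
      store,
      agent = agent,
      body = sprintf(
        "Flagged by %s: score %.2f exceeds threshold %.2f",
        report$method, flagged$score[i], report$threshold
      ),
      targets = flagged$member[i],
      motivation = "flagging"
    )
  })
  dplyr::bind_rows(rows)
}
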