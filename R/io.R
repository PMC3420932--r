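#' Read a confidence-weighted edge list
#'
#' Parses a TSV of `tail<TAB>head<TAB>confidence` rows into a
#' [pathway_network()].  Lines starting with `#` and blank lines are
#' ignored.  Two dialects are supported: `"simple"` carries a real
#' confidence in \[0, 1\]; `"string-score"` carries an integer score in
#' 0-1000 that is divided by 1000 on import.  Confidences become traversal
#' costs via [confidence_to_cost()].
#'
#' Policy: duplicate rows for the same ordered pair keep the maximum
#' confidence (best evidence wins, deterministically); self-loop rows are
#' dropped with a warning; with `directed = FALSE` each row produces both
#' orientations at equal cost.
#'
#' @param path Path to the edge-list file.
#' @param dialect `"simple"` or `"string-score"`.
#' @param directed Logical; if `FALSE` the file is symmetrized.
#' @return A `pathway_network`.
#' @export
read_network <- function(path, dialect = c("simple", "string-score"),
                         directed = TRUE) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0L) {
    stop(sprintf("no edge rows in '%s'", path), call. = FALSE)
  }
  parts <- strsplit(lines[rows], "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed row at line %d of '%s' (need 3 tab-separated fields)",
                 rows[bad[1L]], path), call. = FALSE)
  }
  from <- vapply(parts, `[[`, character(1), 1L)
  to <- vapply(parts, `[[`, character(1), 2L)
  raw <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3L)))
  if (anyNA(raw)) {
    stop(sprintf("non-numeric confidence at line %d of '%s'",
                 rows[which(is.na(raw))[1L]], path), call. = FALSE)
  }
  conf <- if (dialect == "string-score") raw / 1000 else raw
  out_of_range <- which(conf < 0 | conf > 1)
  if (length(out_of_range) > 0L) {
    stop(sprintf("confidence out of range at line %d of '%s'",
                 rows[out_of_range[1L]], path), call. = FALSE)
  }
  self <- from == to
  if (any(self)) {
    warning(sprintf("dropping %d self-loop row(s) in '%s'", sum(self), path),
            call. = FALSE)
    from <- from[!self]; to <- to[!self]; conf <- conf[!self]
  }
  if (!directed) {
    from2 <- c(from, to)
    to <- c(to, from)
    from <- from2
    conf <- c(conf, conf)
  }
  # duplicate ordered pairs: keep maximum confidence
  key <- edge_key(from, to)
  o <- order(key, -conf)
  keep1 <- !duplicated(key[o])
  sel <- o[keep1]
  pathway_network(data.frame(from = from[sel], to = to[sel],
                             cost = confidence_to_cost(conf[sel]),
                             stringsAsFactors = FALSE))
}

#' Write a network back to the edge-list format
#'
#' @param net A `pathway_network`.
#' @param path Output path.
#' @param dialect `"simple"` (confidence printed with full precision) or
#'   `"string-score"` (integer score `round(1000 * confidence)`).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, dialect = c("simple", "string-score")) {
  dialect <- match.arg(dialect)
  conf <- 1 - net$edges$cost
  third <- if (dialect == "string-score") {
    sprintf("%d", as.integer(round(conf * 1000)))
  } else {
    sprintf("%.17g", conf)
  }
  writeLines(c("# tail\thead\tconfidence",
               paste(net$edges$from, net$edges$to, third, sep = "\t")),
             path)
  invisible(path)
}

read_node_list <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines[!grepl("^(#|$)", lines)]
}

#' Read source and target node lists
#'
#' One identifier per line; `#` comment lines ignored.  Membership in a
#' network is checked separately with [validate_endpoints()].
#'
#' @param sources_path,targets_path Paths to the node-list files.
#' @return A `pathway_endpoints`.
#' @export
read_endpoints <- function(sources_path, targets_path) {
  pathway_endpoints(read_node_list(sources_path),
                    read_node_list(targets_path))
}

#' Write endpoint node lists
#' @param ends A `pathway_endpoints`.
#' @param sources_path,targets_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_endpoints <- function(ends, sources_path, targets_path) {
  writeLines(ends$sources, sources_path)
  writeLines(ends$targets, targets_path)
  invisible(c(sources_path, targets_path))
}

#' Read a reference edge set
#'
#' Rows of `node_a<TAB>node_b[<TAB>confidence]`; `#` comments ignored.
#' Unordered pairs are deduplicated keeping the maximum confidence;
#' self-pair rows are dropped with a warning.
#'
#' @param path Path to the pair file.
#' @param label Label stored on the returned set.
#' @return A `reference_edge_set`.
#' @export
read_reference_set <- function(path, label = basename(path)) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) {
    warning(sprintf("'%s' contains no pair rows; empty reference set", path),
            call. = FALSE)
    return(reference_edge_set(NULL, label = label))
  }
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) {
    stop(sprintf("malformed row at line %d of '%s'",
                 which(keep)[which(lengths(parts) < 2L)[1L]], path),
         call. = FALSE)
  }
  conf <- vapply(parts, function(p) {
    if (length(p) >= 3L) as.numeric(p[[3L]]) else NA_real_
  }, numeric(1))
  reference_edge_set(data.frame(a = vapply(parts, `[[`, character(1), 1L),
                                b = vapply(parts, `[[`, character(1), 2L),
                                confidence = conf,
                                stringsAsFactors = FALSE),
                     label = label)
}

#' Write a ranked prediction list as TSV
#'
#' Emits the run metadata as `#`-prefixed header lines followed by the
#' columns `rank tail head edge_cost objective_before objective_after delta
#' tie_count`.
#'
#' @param pred A `prediction_list` as returned by [greedy_predict()] and
#'   the baseline predictors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, path) {
  meta <- attributes(pred)
  spec <- meta$spec
  hdr <- c(sprintf("# method: %s", meta$method %||% "unknown"),
           sprintf("# objective: %s", spec$variant %||% "none"),
           sprintf("# hops: %s", if (isTRUE(spec$hop_restricted))
             spec$hops else "unrestricted"),
           sprintf("# penalty: %s", format(meta$penalty %||% NA)),
           sprintf("# seed: %s", format(meta$seed %||% NA)),
           sprintf("# candidate_source: %s",
                   meta$candidate_source %||% "all-missing"),
           sprintf("# stop_reason: %s", meta$stop_reason %||% "budget"),
           paste("# rank", "tail", "head", "edge_cost", "objective_before",
                 "objective_after", "delta", "tie_count", sep = "\t"))
  body <- sprintf("%d\t%s\t%s\t%.17g\t%.17g\t%.17g\t%.17g\t%d",
                  pred$rank, pred$from, pred$to, pred$cost,
                  pred$objective_before, pred$objective_after,
                  pred$delta, pred$tie_count)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a prediction TSV written by [write_predictions()]
#' @param path Path to the prediction file.
#' @return A data frame with the prediction columns.
#' @export
read_predictions <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0L) {
    return(data.frame(rank = integer(), from = character(),
                      to = character(), cost = numeric(),
                      objective_before = numeric(),
                      objective_after = numeric(), delta = numeric(),
                      tie_count = integer(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  data.frame(rank = as.integer(vapply(parts, `[[`, character(1), 1L)),
             from = vapply(parts, `[[`, character(1), 2L),
             to = vapply(parts, `[[`, character(1), 3L),
             cost = as.numeric(vapply(parts, `[[`, character(1), 4L)),
             objective_before = as.numeric(vapply(parts, `[[`, character(1), 5L)),
             objective_after = as.numeric(vapply(parts, `[[`, character(1), 6L)),
             delta = as.numeric(vapply(parts, `[[`, character(1), 7L)),
             tie_count = as.integer(vapply(parts, `[[`, character(1), 8L)),
             stringsAsFactors = FALSE)
}
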