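#' Parse timestamped contact records
#'
#' Reads SocioPatterns-style proximity records, one contact per line.  Each
#' record states that a pair of individuals was in face-to-face range during
#' the preceding sampling window (20 s in the SocioPatterns deployments).
#' Node identifiers are kept as opaque strings so badge IDs with leading
#' zeros survive round-trips; timestamps must be non-negative integers in
#' seconds.
#'
#' @param lines character vector of input lines.  Lines starting with `#`
#'   and blank lines are skipped.
#' @param dialect column order: `"tij"` (timestamp, id1, id2 — the order used
#'   in SocioPatterns files) or `"ijt"` (id1, id2, timestamp).  There is no
#'   auto-detection; the caller must know the file layout.
#' @return a data.frame with columns `u`, `v` (character, canonically ordered
#'   so `u <= v`) and `t` (integer seconds), sorted by time then pair, with
#'   duplicate (pair, t) records collapsed.
#' @export
parse_contact_events <- function(lines, dialect = c("tij", "ijt")) {
  dialect <- match.arg(dialect)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.frame(u = character(), v = character(), t = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- idx[which(nf < 3L)[1L]]
    stop("malformed contact record at line ", bad,
         ": expected at least 3 whitespace-separated fields", call. = FALSE)
  }
  f1 <- vapply(fields, `[[`, "", 1L)
  f2 <- vapply(fields, `[[`, "", 2L)
  f3 <- vapply(fields, `[[`, "", 3L)
  if (dialect == "tij") {
    tchr <- f1; a <- f2; b <- f3
  } else {
    a <- f1; b <- f2; tchr <- f3
  }
  tnum <- suppressWarnings(as.numeric(tchr))
  bad <- which(is.na(tnum) | tnum != floor(tnum) | tnum < 0)
  if (length(bad)) {
    stop("malformed timestamp at line ", idx[bad[1L]],
         ": expected a non-negative integer, got '", tchr[bad[1L]], "'",
         call. = FALSE)
  }
  if (any(a == b)) {
    stop("self-contact at line ", idx[which(a == b)[1L]],
         ": the two node identifiers are equal", call. = FALSE)
  }
  u <- ifelse(a <= b, a, b)
  v <- ifelse(a <= b, b, a)
  ev <- data.frame(u = u, v = v, t = as.integer(tnum),
                   stringsAsFactors = FALSE)
  ev <- ev[!duplicated(ev[c("u", "v", "t")]), , drop = FALSE]
  ev <- ev[order(ev$t, ev$u, ev$v), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Read contact records from a file
#'
#' File-path wrapper around [parse_contact_events()].  Gzip-compressed files
#' are decompressed transparently.
#'
#' @param path path to a plain or gzipped text file.
#' @inheritParams parse_contact_events
#' @return see [parse_contact_events()].
#' @export
read_contact_events <- function(path, dialect = c("tij", "ijt")) {
  con <- file(path, "rt")  # file() decompresses gzip transparently
  on.exit(close(con))
  parse_contact_events(readLines(con), dialect = dialect)
}

#' Merge contact pings into interaction sessions
#'
#' A session is a maximal run of consecutive records for one pair whose
#' inter-record gap never exceeds `max_gap`.  Each record marks contact
#' during the preceding sampling window of length `interval`, so a session
#' over timestamps t_1 < ... < t_n starts at `t_1 - interval` and ends at
#' `t_n`: an isolated record contributes one full window (`interval`
#' seconds), never zero.
#'
#' @param times strictly increasing integer timestamps (seconds) of the
#'   records for one pair.
#' @param interval sampling window length Delta in seconds (default 20).
#' @param max_gap largest inter-record gap still bridged within one session,
#'   in seconds; must be at least `interval` (default: equal to `interval`).
#' @return a data.frame with columns `st`, `et`, `duration` (seconds), one
#'   row per session, in time order.
#' @export
sessionize <- function(times, interval = 20, max_gap = interval) {
  stopifnot(interval > 0, max_gap >= interval)
  if (length(times) == 0L) {
    return(data.frame(st = numeric(), et = numeric(), duration = numeric()))
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("timestamps must be strictly increasing within a pair", call. = FALSE)
  }
  breaks <- which(diff(times) > max_gap)
  first <- c(1L, breaks + 1L)
  last <- c(breaks, length(times))
  st <- times[first] - interval
  et <- times[last]
  data.frame(st = st, et = et, duration = et - st)
}

#' Total contact duration of one pair
#'
#' The pair's edge weight is the summed length of stay over all of its
#' interaction sessions, in seconds.
#'
#' @param sessions a data.frame as returned by [sessionize()].
#' @return total duration in seconds (0 for an empty session table, in which
#'   case no edge should be emitted).
#' @export
pair_weight <- function(sessions) {
  if (nrow(sessions) == 0L) return(0)
  sum(sessions$et - sessions$st)
}

#' Build the static weighted contact graph
#'
#' Sessionizes the record stream per pair and aggregates total contact
#' duration into one undirected edge weight per pair.  Pairs with no
#' sessions are absent; all stored weights are positive.
#'
#' @param events a data.frame of contact events from
#'   [parse_contact_events()].
#' @inheritParams sessionize
#' @return an undirected [igraph][igraph::graph_from_data_frame] graph with a
#'   `weight` edge attribute in seconds.
#' @export
build_weighted_graph <- function(events, interval = 20, max_gap = interval) {
  if (nrow(events) == 0L) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  key <- paste(events$u, events$v, sep = "\r")
  weights <- vapply(split(events$t, key), function(ts) {
    pair_weight(sessionize(sort(unique(ts)), interval = interval,
                           max_gap = max_gap))
  }, numeric(1))
  pairs <- do.call(rbind, strsplit(names(weights), "\r", fixed = TRUE))
  el <- data.frame(from = pairs[, 1L], to = pairs[, 2L],
                   weight = unname(weights), stringsAsFactors = FALSE)
  el <- el[el$weight > 0, , drop = FALSE]
  igraph::graph_from_data_frame(el, directed = FALSE)
}

#' Load a pre-weighted undirected edge list
#'
#' For datasets that ship edge weights directly (e.g. ordinal contact-duration
#' levels) in `source target weight` lines.  Duplicate pair lines are
#' rejected: the aggregation rule would be ambiguous.
#'
#' @param path path to a whitespace-separated text file; `#` comment lines
#'   are skipped.
#' @return an undirected weighted igraph graph.
#' @export
load_weighted_edgelist <- function(path) {
  con <- file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) return(igraph::make_empty_graph(0, directed = FALSE))
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 3L)) {
    stop("edge-list line ", idx[which(nf != 3L)[1L]],
         ": expected exactly 3 fields", call. = FALSE)
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  w <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(w) | w <= 0)
  if (length(bad)) {
    stop("edge-list line ", idx[bad[1L]],
         ": weight must be a positive number", call. = FALSE)
  }
  if (any(a == b)) {
    stop("edge-list line ", idx[which(a == b)[1L]], ": self-loop", call. = FALSE)
  }
  u <- ifelse(a <= b, a, b)
  v <- ifelse(a <= b, b, a)
  if (anyDuplicated(paste(u, v))) {
    stop("duplicate pair in edge list: aggregation would be ambiguous",
         call. = FALSE)
  }
  igraph::graph_from_data_frame(
    data.frame(from = u, to = v, weight = w, stringsAsFactors = FALSE),
    directed = FALSE)
}

#' Write a weighted edge list
#'
#' Tab-separated `u v weight` lines, loss-free partner of
#' [load_weighted_edgelist()].
#'
#' @param graph an undirected weighted igraph graph.
#' @param path output file path.
#' @export
write_weighted_edgelist <- function(graph, path) {
  el <- igraph::as_data_frame(graph, what = "edges")
  writeLines(sprintf("%s\t%s\t%.10g", el$from, el$to, el$weight), path)
  invisible(path)
}

#' Ordinal contact-duration level
#'
#' Maps a contact duration in seconds onto the four-level ordinal scale used
#' by pre-thresholded contact datasets: 1 below 5 min, 2 from 5 to 15 min,
#' 3 from 15 min to 1 h, 4 at 1 h and above.  Category boundaries are
#' left-closed on the upper category (exactly 300 s is level 2).
#'
#' @param duration numeric vector of durations in seconds, non-negative.
#' @return integer vector of levels in 1..4.
#' @export
ordinal_weight <- function(duration) {
  if (any(duration < 0)) stop("duration must be non-negative", call. = FALSE)
  findInterval(duration, c(0, 300, 900, 3600))
}
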