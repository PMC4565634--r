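# Markers used in lineage tables. A thread that dies shows DUMP in the column
# where it hit the dump sink and DEAD in every later column; a thread born
# after T1 shows empty cells before its birth column.
MARK_DUMP  <- "DUMP"
MARK_DEAD  <- "DEAD"
MARK_EMPTY <- ""

#' Read snapshot memberships from a delimited file
#'
#' Expects one record per (node, time, cluster) membership. The column order
#' in the file is configurable through `columns`; the file may or may not have
#' a header line (auto-detected when `header = NA` by checking whether the
#' time column of the first line is numeric).
#'
#' @param path File path.
#' @param sep Field delimiter (default tab).
#' @param columns Character vector naming the file's columns in order; must be
#'   a permutation of `c("node", "time", "cluster")`.
#' @param header `TRUE`, `FALSE`, or `NA` to auto-detect.
#' @return A [dynamic_partition()].
#' @export
read_memberships <- function(path, sep = "\t",
                             columns = c("node", "time", "cluster"),
                             header = NA) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.info(path)$size == 0 ||
      length(readLines(path, n = 1L, warn = FALSE)) == 0L)
    stop("empty membership file: ", path)
  if (!setequal(columns, c("node", "time", "cluster")) ||
      length(columns) != 3L)
    stop("'columns' must be a permutation of node, time, cluster")
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character", comment.char = "",
                           quote = "", blank.lines.skip = TRUE)
  if (ncol(raw) < 3L) stop("need 3 columns, found ", ncol(raw))
  raw <- raw[, seq_len(3L)]
  names(raw) <- columns
  if (is.na(header)) {
    header <- is.na(suppressWarnings(as.numeric(raw$time[1L])))
  }
  if (isTRUE(header)) raw <- raw[-1L, , drop = FALSE]
  if (nrow(raw) == 0L) stop("empty membership file: ", path)
  partition_from_long(raw$node, raw$time, raw$cluster)
}

#' Write snapshot memberships
#'
#' @param dp A [dynamic_partition()].
#' @param path Output file path.
#' @param sep Field delimiter.
#' @param header Write a header line?
#' @export
write_memberships <- function(dp, path, sep = "\t", header = TRUE) {
  df <- partition_table(dp)
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

#' Read per-snapshot edge lists
#'
#' One file per snapshot with 2 or 3 columns: source, target and an optional
#' positive integer multiplicity (default 1). Repeated (source, target) lines
#' accumulate. Self-loops are retained but reported via the `self_loops`
#' attribute.
#'
#' @param paths Character vector of file paths, one per snapshot, in time
#'   order.
#' @param sep Field delimiter.
#' @param dp Optional [dynamic_partition()]; endpoints absent from the
#'   matching snapshot are reported with a warning (not an error).
#' @return An object of class `edge_series`: a list with one data.frame
#'   (`src`, `dst`, `count`) per snapshot.
#' @export
read_edge_snapshots <- function(paths, sep = "", dp = NULL) {
  series <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    if (!file.exists(p)) stop("edge file not found: ", p)
    if (file.info(p)$size == 0) {
      series[[i]] <- empty_edges()
      next
    }
    raw <- utils::read.table(p, sep = sep, header = FALSE,
                             colClasses = "character", comment.char = "",
                             quote = "")
    if (!ncol(raw) %in% c(2L, 3L))
      stop("edge file must have 2 or 3 columns: ", p)
    count <- if (ncol(raw) == 3L) {
      m <- suppressWarnings(as.integer(raw[[3L]]))
      if (anyNA(m) || any(m < 1L))
        stop("multiplicities must be positive integers: ", p)
      m
    } else rep(1L, nrow(raw))
    df <- stats::aggregate(count ~ src + dst,
                           data = data.frame(src = raw[[1L]], dst = raw[[2L]],
                                             count = count,
                                             stringsAsFactors = FALSE),
                           FUN = sum)
    df <- df[order(df$src, df$dst), , drop = FALSE]
    rownames(df) <- NULL
    loops <- df$src == df$dst
    attr(df, "self_loops") <- df[loops, c("src", "dst"), drop = FALSE]
    series[[i]] <- df
  }
  if (!is.null(dp)) {
    stopifnot(inherits(dp, "dynamic_partition"))
    if (length(paths) != dp$T)
      stop("expected ", dp$T, " edge files, got ", length(paths))
    for (i in seq_along(series)) {
      known <- unlist(dp$snapshots[[i]]$clusters, use.names = FALSE)
      ends <- unique(c(series[[i]]$src, series[[i]]$dst))
      unknown <- setdiff(ends, known)
      if (length(unknown))
        warning("snapshot ", i, ": ", length(unknown),
                " edge endpoint(s) absent from the partition: ",
                paste(utils::head(unknown, 5L), collapse = ", "))
    }
  }
  structure(series, class = "edge_series")
}

empty_edges <- function() {
  df <- data.frame(src = character(), dst = character(),
                   count = integer(), stringsAsFactors = FALSE)
  attr(df, "self_loops") <- df[, c("src", "dst")]
  df
}

#' Write per-snapshot edge lists
#'
#' @param es An `edge_series`.
#' @param paths Output file paths, one per snapshot.
#' @param sep Field delimiter.
#' @export
write_edge_snapshots <- function(es, paths, sep = " ") {
  stopifnot(length(es) == length(paths))
  for (i in seq_along(es))
    utils::write.table(as.data.frame(es[[i]]), paths[[i]], sep = sep,
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(paths)
}

#' Write a lineage query database
#'
#' Emits a T-column delimited table, one row per thread, with columns labelled
#' `T1..TT`. A dying thread shows `DUMP` at the death column and `DEAD` after;
#' cells before a birth are empty. [read_lineage_table()] reproduces the
#' database exactly.
#'
#' @param db A `query_database` from [build_query_database()].
#' @param path Output file path.
#' @param sep Field delimiter.
#' @export
write_lineage_table <- function(db, path, sep = "\t") {
  stopifnot(inherits(db, "query_database"))
  if (nrow(db) == 0L) stop("empty query database")
  out <- as.data.frame(unclass(db), stringsAsFactors = FALSE)
  out$origin <- NULL
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a lineage query database
#'
#' Reads a table written by [write_lineage_table()] (or a published lineage
#' table in the same layout) and reconstructs the `query_database`, including
#' thread origins: rows alive at T1 take their T1 label as origin; rows born
#' later get `NewC<k>` identifiers numbered from (number of T1 origins + 1)
#' in (birth time, first label) order.
#'
#' @param path File path.
#' @param sep Field delimiter.
#' @param header Does the file carry a `T1..TT` header line? Default `TRUE`.
#' @return A `query_database`.
#' @export
read_lineage_table <- function(path, sep = "\t", header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = sep, header = header,
                           colClasses = "character", comment.char = "",
                           quote = "", na.strings = NULL,
                           blank.lines.skip = FALSE)
  raw[is.na(raw)] <- MARK_EMPTY
  names(raw) <- paste0("T", seq_len(ncol(raw)))
  new_query_database(raw)
}

# assigns origins and class; shared by the join builder and the reader
new_query_database <- function(df) {
  Tn <- ncol(df)
  stopifnot(Tn >= 1L)
  origin <- character(nrow(df))
  alive <- df$T1 != MARK_EMPTY
  origin[alive] <- df$T1[alive]
  n0 <- length(unique(df$T1[alive]))
  if (any(!alive)) {
    idx <- which(!alive)
    birth_time <- vapply(idx, function(i) {
      r <- unlist(df[i, ], use.names = FALSE)
      match(TRUE, r != MARK_EMPTY)
    }, integer(1L))
    first_label <- vapply(seq_along(idx), function(k)
      df[[birth_time[k]]][idx[k]], character(1L))
    key <- unique(data.frame(bt = birth_time, fl = first_label,
                             stringsAsFactors = FALSE))
    key <- key[order(key$bt, key$fl), , drop = FALSE]
    key$id <- paste0("NewC", n0 + seq_len(nrow(key)))
    origin[idx] <- key$id[match(paste(birth_time, first_label),
                                paste(key$bt, key$fl))]
  }
  df$origin <- origin
  df <- df[do.call(order, c(df[c(paste0("T", seq_len(Tn)), "origin")],
                            list(method = "radix"))), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("query_database", "data.frame"), T = Tn)
}

#' Write an event log
#'
#' One record per classified evolution event with type, interval, participant
#' labels and participant node counts, in deterministic (time, type, labels)
#' order.
#'
#' @param events Event data.frame from [classify_events()] / [track_all()].
#' @param path Output file path.
#' @param sep Field delimiter.
#' @export
write_events <- function(events, path, sep = "\t") {
  ev <- sort_events(as.data.frame(events))
  utils::write.table(ev, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an event log written by [write_events()]
#'
#' @param path File path.
#' @param sep Field delimiter.
#' @return Event data.frame.
#' @export
read_events <- function(path, sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", comment.char = "",
                          quote = "", na.strings = "NA")
  df$time <- as.integer(df$time)
  df$size_source <- as.integer(df$size_source)
  df$size_target <- as.integer(df$size_target)
  df$sources[is.na(df$sources)] <- ""
  df$targets[is.na(df$targets)] <- ""
  sort_events(df)
}

sort_events <- function(ev) {
  ev <- ev[order(ev$time, ev$type, ev$sources, ev$targets,
                 method = "radix"), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}
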