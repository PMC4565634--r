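#' Pair table of one tracked interval
#'
#' The (source, sink) rows of a pruned bipartite map: one row per retained
#' edge plus one row per dump / birth attachment, in deterministic
#' (source, target) order.
#'
#' @param map A pruned `bipartite_map` with pseudo attachments.
#' @return An object of class `pair_table`: a data.frame with columns
#'   `source`, `target` and attribute `t` (the interval index).
#' @export
make_pair_table <- function(map) {
  stopifnot(inherits(map, "bipartite_map"), !is.null(map$retained),
            !is.null(map$pseudo))
  kept <- map$edges[map$retained, c("source", "target"), drop = FALSE]
  ps <- map$pseudo[, c("source", "target"), drop = FALSE]
  rows <- unique(rbind(kept, ps))
  rows <- rows[order(rows$source, rows$target), , drop = FALSE]
  rownames(rows) <- NULL
  structure(rows, class = c("pair_table", "data.frame"), t = map$t)
}

# constructor used when replaying a lineage table or in tests
pair_table <- function(source, target, t) {
  rows <- unique(data.frame(source = as.character(source),
                            target = as.character(target),
                            stringsAsFactors = FALSE))
  rows <- rows[order(rows$source, rows$target), , drop = FALSE]
  rownames(rows) <- NULL
  structure(rows, class = c("pair_table", "data.frame"), t = as.integer(t))
}

#' One outer-join step of the lineage database construction
#'
#' Full outer join of the current database (columns `T1..Tk`) with the pair
#' table of the interval `k -> k+1`, on last database column == pair-table
#' source. Matching rows produce the cross product (m database rows times n
#' pair rows yield m*n rows). Threads already dead extend with `DEAD`; a
#' pair row whose source is a birth identifier (`C0`, `C-1`, ...) starts a
#' new thread padded with empty cells before the birth column; a live thread
#' matching nothing dies (`DUMP`). Edges into the dump sink are normalised to
#' the `DUMP` marker.
#'
#' @param db A `query_database` with `k` columns.
#' @param p A `pair_table` for interval `k -> k+1`.
#' @return The extended database (unsorted; [build_query_database()] sorts).
#' @export
outer_join_step <- function(db, p) {
  stopifnot(inherits(db, "query_database"), inherits(p, "pair_table"))
  k <- attr(db, "T")
  if (!is.null(attr(p, "t")) && !is.na(attr(p, "t")) && attr(p, "t") != k)
    stop("pair table is for interval ", attr(p, "t"),
         " but database has ", k, " columns")
  cols <- paste0("T", seq_len(k))
  last <- db[[cols[k]]]
  out <- vector("list", nrow(db) + nrow(p))
  n_out <- 0L
  push <- function(prefix, value) {
    n_out <<- n_out + 1L
    out[[n_out]] <<- c(prefix, value)
  }
  for (i in seq_len(nrow(db))) {
    prefix <- as.character(unlist(db[i, cols], use.names = FALSE))
    li <- last[i]
    if (li %in% c(MARK_DEAD, MARK_DUMP)) {
      push(prefix, MARK_DEAD)
    } else {
      tg <- p$target[p$source == li]
      if (length(tg) == 0L) {
        push(prefix, MARK_DUMP)
      } else {
        for (v in tg)
          push(prefix, if (v == DUMP_LABEL) MARK_DUMP else v)
      }
    }
  }
  births <- p[is_birth_label(p$source), , drop = FALSE]
  for (i in seq_len(nrow(births)))
    push(rep(MARK_EMPTY, k), births$target[i])
  out <- out[seq_len(n_out)]
  mat <- do.call(rbind, out)
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- paste0("T", seq_len(k + 1L))
  rownames(df) <- NULL
  new_query_database(df)
}

#' Build the lineage query database from pair tables
#'
#' Left-fold of [outer_join_step()] over the interval pair tables in time
#' order, starting from the first table. The result has one column per
#' time-stamp and one row per lineage thread, in deterministic lexicographic
#' row order. Thread origins are the T1 labels, or `NewC<k>` identifiers for
#' threads born later (numbered from the T1 community count + 1, in birth
#' order).
#'
#' @param pair_tables List of `pair_table`s for intervals `1..T-1`.
#' @return A `query_database` (a data.frame with columns `T1..TT` plus
#'   `origin`).
#' @export
build_query_database <- function(pair_tables) {
  if (length(pair_tables) == 0L) stop("no pair tables")
  p1 <- pair_tables[[1L]]
  stopifnot(inherits(p1, "pair_table"))
  born <- is_birth_label(p1$source)
  first <- data.frame(
    T1 = ifelse(born, MARK_EMPTY, p1$source),
    T2 = ifelse(p1$target == DUMP_LABEL, MARK_DUMP, p1$target),
    stringsAsFactors = FALSE)
  db <- new_query_database(first)
  for (p in pair_tables[-1L]) db <- outer_join_step(db, p)
  db
}

#' Extract adjacent-column pair tables back out of a database
#'
#' Inverse bridge used for replaying a published lineage table and for the
#' idempotence property: projecting every two adjacent columns (dropping
#' dead/empty padding) recovers the interval pair tables, with `DUMP`
#' re-expanded to the dump sink and pre-birth rows re-expanded to birth
#' identifiers (`C0`, `C-1`, ... per interval, in target-label order).
#'
#' @param db A `query_database`.
#' @return List of `pair_table`s for intervals `1..T-1`.
#' @export
database_pair_tables <- function(db) {
  stopifnot(inherits(db, "query_database"))
  Tn <- attr(db, "T")
  lapply(seq_len(Tn - 1L), function(t) {
    a <- db[[paste0("T", t)]]
    b <- db[[paste0("T", t + 1L)]]
    live <- !(a %in% c(MARK_EMPTY, MARK_DEAD, MARK_DUMP))
    src <- a[live]
    tgt <- b[live]
    tgt[tgt == MARK_DUMP] <- DUMP_LABEL
    # births observed at t+1: empty at t, real label at t+1
    newborn <- sort(unique(b[a == MARK_EMPTY &
                             !(b %in% c(MARK_EMPTY, MARK_DEAD, MARK_DUMP))]))
    if (length(newborn)) {
      src <- c(src, paste0("C", -(seq_along(newborn) - 1L)))
      tgt <- c(tgt, newborn)
    }
    pair_table(src, tgt, t)
  })
}

#' Extract drawable threads from a lineage database
#'
#' Rows sharing an origin are merged into a branch tree (a prefix tree over
#' the label sequences): a branch is created at each split and branches never
#' re-collapse, even when they later carry the same community label. Each
#' tree node records (time, label); node sizes are attached later from the
#' partition when available.
#'
#' @param db A `query_database`.
#' @return An object of class `thread_set`: a list with `nodes` (data.frame
#'   `id`, `origin`, `time`, `label`, `parent`) and `origins` (character
#'   vector in first-appearance order: T1 label order, then birth order).
#' @export
extract_threads <- function(db) {
  stopifnot(inherits(db, "query_database"))
  Tn <- attr(db, "T")
  cols <- paste0("T", seq_len(Tn))
  origins_t1 <- sort(unique(db$origin[db$T1 != MARK_EMPTY]))
  newc <- unique(db$origin[db$T1 == MARK_EMPTY])
  newc <- newc[order(as.integer(sub("^NewC", "", newc)))]
  origins <- c(origins_t1, newc)

  nodes <- list()
  n_nodes <- 0L
  add_node <- function(origin, time, label, parent) {
    n_nodes <<- n_nodes + 1L
    nodes[[n_nodes]] <<- data.frame(id = n_nodes, origin = origin,
                                    time = time, label = label,
                                    parent = parent,
                                    stringsAsFactors = FALSE)
    n_nodes
  }
  # recursive prefix-tree build over the rows of one origin
  grow <- function(origin, rows, t, parent) {
    if (t > Tn) return(invisible())
    vals <- db[[cols[t]]][rows]
    live <- !(vals %in% c(MARK_EMPTY, MARK_DEAD, MARK_DUMP))
    for (lab in sort(unique(vals[live]))) {
      sub <- rows[vals == lab]
      id <- add_node(origin, t, lab, parent)
      grow(origin, sub, t + 1L, id)
    }
    invisible()
  }
  for (o in origins) {
    rows <- which(db$origin == o)
    start <- min(vapply(rows, function(i) {
      r <- unlist(db[i, cols], use.names = FALSE)
      match(TRUE, r != MARK_EMPTY)
    }, integer(1L)))
    grow(o, rows, start, NA_integer_)
  }
  nodes <- if (n_nodes) do.call(rbind, nodes[seq_len(n_nodes)]) else
    data.frame(id = integer(), origin = character(), time = integer(),
               label = character(), parent = integer(),
               stringsAsFactors = FALSE)
  structure(list(nodes = nodes, origins = origins, T = Tn),
            class = "thread_set")
}

#' @export
print.thread_set <- function(x, ...) {
  cat("Thread set:", length(x$origins), "origins over", x$T,
      "time-stamps;", nrow(x$nodes), "branch nodes\n")
  invisible(x)
}

#' Attach community sizes to a thread set
#'
#' @param threads A `thread_set`.
#' @param dp The [dynamic_partition()] the lineage came from.
#' @return The thread set with a `size` column on `nodes`.
#' @export
thread_sizes <- function(threads, dp) {
  stopifnot(inherits(threads, "thread_set"))
  dp <- as.dynamic_partition(dp)
  nd <- threads$nodes
  nd$size <- NA_integer_
  for (i in seq_len(nrow(nd))) {
    cl <- dp$snapshots[[nd$time[i]]]$clusters[[nd$label[i]]]
    if (!is.null(cl)) nd$size[i] <- length(cl)
  }
  threads$nodes <- nd
  threads
}
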