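#' Snapshot partition
#'
#' A partition of the nodes observed at one time-stamp into disjoint,
#' non-empty communities.
#'
#' @param time_index Integer time-stamp (1-based).
#' @param clusters Named list of character vectors; names are cluster labels,
#'   elements are node identifiers. Labels are opaque strings and only
#'   comparable within one snapshot.
#' @return An object of class `snapshot_partition`.
#' @export
snapshot_partition <- function(time_index, clusters) {
  time_index <- as.integer(time_index)
  if (length(time_index) != 1L || is.na(time_index))
    stop("'time_index' must be a single integer")
  if (!is.list(clusters) || is.null(names(clusters)) ||
      any(!nzchar(names(clusters))))
    stop("'clusters' must be a named list of node-id vectors")
  # canonical member order so equal partitions compare identical
  clusters <- lapply(clusters, function(x)
    sort(unique(as.character(x)), method = "radix"))
  if (any(lengths(clusters) == 0L))
    stop("empty cluster(s): ", paste(names(clusters)[lengths(clusters) == 0L],
                                     collapse = ", "))
  all_nodes <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(all_nodes)) {
    dup <- unique(all_nodes[duplicated(all_nodes)])
    stop("node(s) assigned to more than one cluster at time ", time_index,
         ": ", paste(utils::head(dup, 5L), collapse = ", "))
  }
  structure(list(time_index = time_index,
                 clusters = clusters[order(names(clusters),
                                           method = "radix")],
                 n = length(clusters)),
            class = "snapshot_partition")
}

#' Dynamic partition across snapshots
#'
#' An ordered sequence of snapshot partitions over consecutive time-stamps
#' `1..T`. Nodes may appear and disappear between snapshots; no imputation is
#' performed.
#'
#' @param snapshots List of [snapshot_partition()] objects.
#' @return An object of class `dynamic_partition` with fields `snapshots`,
#'   `node_universe` and `T` (number of time-stamps).
#' @export
dynamic_partition <- function(snapshots) {
  if (!is.list(snapshots) || length(snapshots) == 0L)
    stop("'snapshots' must be a non-empty list of snapshot_partition objects")
  ok <- vapply(snapshots, inherits, logical(1L), "snapshot_partition")
  if (!all(ok)) stop("all elements must be snapshot_partition objects")
  times <- vapply(snapshots, `[[`, integer(1L), "time_index")
  snapshots <- snapshots[order(times)]
  times <- sort(times)
  if (!identical(times, seq_along(times)))
    stop("time indices must be the consecutive integers 1..T; got: ",
         paste(times, collapse = ", "),
         ". Re-index the input time-stamps.")
  universe <- sort(unique(unlist(lapply(snapshots, function(s)
    unlist(s$clusters, use.names = FALSE)), use.names = FALSE)))
  structure(list(snapshots = snapshots, node_universe = universe,
                 T = length(snapshots)),
            class = "dynamic_partition")
}

#' @export
print.snapshot_partition <- function(x, ...) {
  cat("Snapshot partition, t =", x$time_index, "\n")
  cat("  ", x$n, "clusters,", length(unlist(x$clusters, use.names = FALSE)),
      "nodes\n")
  sizes <- lengths(x$clusters)
  cat("  sizes:", paste(sprintf("%s=%d", names(sizes), sizes),
                        collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.dynamic_partition <- function(x, ...) {
  cat("Dynamic partition over", x$T, "time-stamps\n")
  cat("  node universe:", length(x$node_universe), "nodes\n")
  for (s in x$snapshots)
    cat(sprintf("  t=%d: %d clusters, %d nodes\n", s$time_index, s$n,
                length(unlist(s$clusters, use.names = FALSE))))
  invisible(x)
}

#' Coerce a node/time/cluster table to a dynamic partition
#'
#' @param x A data.frame with columns `node`, `time`, `cluster` (any order).
#' @param ... Unused.
#' @return A [dynamic_partition()].
#' @export
as.dynamic_partition <- function(x, ...) {
  if (inherits(x, "dynamic_partition")) return(x)
  if (!is.data.frame(x)) stop("cannot coerce ", class(x)[1L],
                              " to dynamic_partition")
  need <- c("node", "time", "cluster")
  if (!all(need %in% names(x)))
    stop("data.frame needs columns: ", paste(need, collapse = ", "))
  partition_from_long(x$node, x$time, x$cluster)
}

# shared builder for as.dynamic_partition and read_memberships
partition_from_long <- function(node, time, cluster) {
  node <- as.character(node)
  cluster <- as.character(cluster)
  time_num <- suppressWarnings(as.numeric(time))
  if (anyNA(time_num) || any(time_num != round(time_num)))
    stop("time values must be integer-coercible")
  time <- as.integer(time_num)
  df <- unique(data.frame(node = node, time = time, cluster = cluster,
                          stringsAsFactors = FALSE))
  if (nrow(df) == 0L) stop("no membership records")
  key <- paste(df$node, df$time, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- df$node[duplicated(key)]
    stop("conflicting cluster memberships for node(s): ",
         paste(unique(utils::head(bad, 5L)), collapse = ", "))
  }
  snaps <- lapply(sort(unique(df$time)), function(t) {
    sub <- df[df$time == t, , drop = FALSE]
    snapshot_partition(t, split(sub$node, sub$cluster))
  })
  dynamic_partition(snaps)
}

#' Flatten a dynamic partition to a long table
#'
#' Inverse of [as.dynamic_partition()]: one row per (node, time, cluster)
#' membership, sorted by time, cluster, node.
#'
#' @param dp A [dynamic_partition()].
#' @return A data.frame with columns `node`, `time`, `cluster`.
#' @export
partition_table <- function(dp) {
  stopifnot(inherits(dp, "dynamic_partition"))
  rows <- lapply(dp$snapshots, function(s) {
    data.frame(node = unlist(s$clusters, use.names = FALSE),
               time = s$time_index,
               cluster = rep(names(s$clusters), lengths(s$clusters)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$time, out$cluster, out$node, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# node-count lookup: named integer vector of cluster sizes at time t
cluster_sizes <- function(dp, t) {
  lengths(dp$snapshots[[t]]$clusters)
}
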