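# Numeric tolerance for weight-vs-threshold comparisons. Jaccard weights are
# ratios of small integers; the tolerance only guards against decimal
# round-off (e.g. a user-supplied threshold equal to a printed weight), so
# boundary edges with weight == theta are always retained.
WEIGHT_TOL <- 1e-12

# pseudo-source label pattern for newborn communities: C0, C-1, C-2, ...
BIRTH_LABEL_RE <- "^C(0|-[0-9]+)$"
DUMP_LABEL <- "Dump"

is_birth_label <- function(x) grepl(BIRTH_LABEL_RE, x)

#' Jaccard coefficient of two node sets
#'
#' `|a n b| / |a u b|`, the fraction of shared members; symmetric, in `[0,1]`.
#'
#' @param a,b Character vectors of node identifiers (at least one non-empty).
#' @return A number in `[0, 1]`.
#' @export
jaccard_weight <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  if (length(a) == 0L && length(b) == 0L)
    stop("both node sets are empty")
  length(intersect(a, b)) / length(union(a, b))
}

#' Build the weighted bipartite map between two consecutive snapshots
#'
#' Creates the directed bipartite graph from the communities at time `t` to
#' those at `t + 1`; an edge exists exactly when the Jaccard coefficient of
#' the two member sets is positive, and carries that coefficient as weight.
#'
#' @param s_t,s_t1 [snapshot_partition()] objects at consecutive time indices.
#' @return An object of class `bipartite_map` with the edge table filled in;
#'   the threshold slots are set by [compute_threshold()].
#' @export
build_bipartite_map <- function(s_t, s_t1) {
  stopifnot(inherits(s_t, "snapshot_partition"),
            inherits(s_t1, "snapshot_partition"))
  if (s_t1$time_index != s_t$time_index + 1L)
    stop("snapshots must have consecutive time indices (got ",
         s_t$time_index, " and ", s_t1$time_index, ")")
  sizes_t <- lengths(s_t$clusters)
  sizes_t1 <- lengths(s_t1$clusters)
  node2src <- rep(names(s_t$clusters), sizes_t)
  names(node2src) <- unlist(s_t$clusters, use.names = FALSE)
  node2dst <- rep(names(s_t1$clusters), sizes_t1)
  names(node2dst) <- unlist(s_t1$clusters, use.names = FALSE)
  common <- intersect(names(node2src), names(node2dst))
  if (length(common)) {
    tab <- table(source = node2src[common], target = node2dst[common])
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(df)[3L] <- "inter"
    df <- df[df$inter > 0L, , drop = FALSE]
    df$weight <- df$inter /
      (sizes_t[df$source] + sizes_t1[df$target] - df$inter)
    edges <- df[order(df$source, df$target),
                c("source", "target", "weight"), drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(source = character(), target = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(t = s_t$time_index, edges = edges,
                 sources = names(s_t$clusters),
                 targets = names(s_t1$clusters),
                 size_source = sizes_t, size_target = sizes_t1,
                 L = NULL, theta = NA_real_, theta_applied = NA_real_,
                 retained = NULL, pseudo = NULL),
            class = "bipartite_map")
}

#' Compute the adaptive significance threshold of a bipartite map
#'
#' Collects, for every community at `t` with at least one positive-weight
#' outgoing edge, its maximum outgoing weight, and for every community at
#' `t + 1` with at least one incoming edge, its maximum incoming weight (list
#' `L`); the threshold `theta` is the minimum of that list. Taking the minimum
#' of the per-community maxima keeps low-density communities connected while
#' still filtering noise edges.
#'
#' When the map has no edges at all, `theta` stays `NA` and downstream steps
#' treat every community at `t` as dying and every community at `t + 1` as
#' newborn.
#'
#' @param map A `bipartite_map`.
#' @return The map with `L` and `theta` (and `theta_applied`) set.
#' @export
compute_threshold <- function(map) {
  stopifnot(inherits(map, "bipartite_map"))
  e <- map$edges
  if (nrow(e) == 0L) {
    map$L <- numeric(0)
    map$theta <- NA_real_
    map$theta_applied <- NA_real_
    return(map)
  }
  out_max <- tapply(e$weight, e$source, max)
  in_max <- tapply(e$weight, e$target, max)
  L <- c(stats::setNames(as.numeric(out_max),
                         paste0("out:", names(out_max))),
         stats::setNames(as.numeric(in_max),
                         paste0("in:", names(in_max))))
  map$L <- L
  map$theta <- min(L)
  map$theta_applied <- map$theta
  map
}

#' Prune a bipartite map at its threshold
#'
#' Marks as retained the edges whose weight is greater than or equal to the
#' applied threshold (boundary edges are kept). With the adaptive threshold
#' every community that had a positive-weight edge keeps its maximum edge; a
#' user-overridden threshold may disconnect communities, which then fall to
#' the dump sink / birth sources in [attach_pseudo_clusters()].
#'
#' @param map A `bipartite_map` with threshold set (see [compute_threshold()]).
#' @param theta Optional override of the applied threshold.
#' @return The map with the logical `retained` column filled in.
#' @export
prune_map <- function(map, theta = NULL) {
  stopifnot(inherits(map, "bipartite_map"))
  if (!is.null(theta)) map$theta_applied <- theta
  th <- map$theta_applied
  if (nrow(map$edges) == 0L) {
    map$retained <- logical(0)
    return(map)
  }
  if (is.na(th)) stop("threshold not set; call compute_threshold() first")
  map$retained <- map$edges$weight >= th - WEIGHT_TOL
  map
}

#' Attach dump sink and birth sources to a pruned map
#'
#' Every community at `t` left with no retained outgoing edge is routed to the
#' `Dump` sink (death); every community at `t + 1` with no retained incoming
#' edge is attached to a fresh birth source. Birth sources are labelled
#' `C0`, `C-1`, `C-2`, ... in descending order of the newborn community's node
#' count (ties broken by label order). Each birth records the fraction of its
#' nodes unseen at time `t`.
#'
#' @param map A pruned `bipartite_map`.
#' @param s_t,s_t1 The snapshots the map was built from.
#' @return The map with the `pseudo` attachment table set.
#' @export
attach_pseudo_clusters <- function(map, s_t, s_t1) {
  stopifnot(inherits(map, "bipartite_map"), !is.null(map$retained))
  kept <- map$edges[map$retained, , drop = FALSE]
  dying <- setdiff(map$sources, kept$source)
  newborn <- setdiff(map$targets, kept$target)
  pseudo <- data.frame(source = character(), target = character(),
                       kind = character(), unseen_frac = numeric(),
                       stringsAsFactors = FALSE)
  if (length(dying))
    pseudo <- rbind(pseudo, data.frame(
      source = sort(dying), target = DUMP_LABEL, kind = "dump",
      unseen_frac = NA_real_, stringsAsFactors = FALSE))
  if (length(newborn)) {
    sz <- map$size_target[newborn]
    ord <- order(-sz, newborn)
    newborn <- newborn[ord]
    labels <- paste0("C", -(seq_along(newborn) - 1L))  # C0, C-1, ...
    seen_t <- unlist(s_t$clusters, use.names = FALSE)
    unseen <- vapply(newborn, function(cl) {
      nodes <- s_t1$clusters[[cl]]
      mean(!nodes %in% seen_t)
    }, numeric(1L))
    pseudo <- rbind(pseudo, data.frame(
      source = labels, target = newborn, kind = "birth",
      unseen_frac = unseen, stringsAsFactors = FALSE))
  }
  rownames(pseudo) <- NULL
  map$pseudo <- pseudo
  map
}

#' Apply the user threshold override rule
#'
#' Given the tracked threshold sequence over intervals `1..T-1` and a
#' user-supplied minimum edge weight `rho` with tolerance `nu`, computes the
#' mean tracked threshold `mu_theta`; if `|rho - mu_theta| <= nu` the value
#' `rho` replaces the threshold at every interval, otherwise the tracked
#' thresholds are kept unchanged. The tolerance prevents a `rho` far from the
#' data-driven scale from emptying the maps.
#'
#' @param thetas Numeric vector of tracked thresholds.
#' @param rho User minimum edge weight, in `[0, 1]`.
#' @param nu Non-negative tolerance (default 0.1).
#' @return A list with `applied` (the per-interval thresholds), `mu_theta`,
#'   and the logical `overridden`.
#' @export
apply_user_threshold <- function(thetas, rho, nu = 0.1) {
  if (length(thetas) == 0L) stop("'thetas' must be non-empty")
  if (length(rho) != 1L || is.na(rho) || rho < 0 || rho > 1)
    stop("'rho' must be a single value in [0, 1]")
  if (nu < 0) stop("'nu' must be >= 0")
  mu <- mean(thetas, na.rm = TRUE)
  overridden <- is.finite(mu) && abs(rho - mu) <= nu + WEIGHT_TOL
  applied <- if (overridden) rep(rho, length(thetas)) else thetas
  list(applied = applied, mu_theta = mu, overridden = overridden)
}

#' Classify evolution events on a pruned bipartite map
#'
#' Classifies, for the interval `t -> t+1` of one pruned map with pseudo
#' attachments:
#' \itemize{
#'   \item split: a community at `t` with two or more retained outgoing edges;
#'   \item merge: a community at `t+1` with two or more retained incoming
#'     edges;
#'   \item death / birth: dump / birth-source attachments;
#'   \item continuation: a pair that is a mutual unique retained
#'     correspondence (the relation holds in both time directions, which
#'     excludes merge and split participants);
#'   \item growth / shrinkage: annotation on a 1-to-1 correspondence whose
#'     size changes by at least `growth_frac` relative to the size at `t`;
#'     such a pair carries continuation plus growth or shrinkage.
#' }
#'
#' @param map A pruned `bipartite_map` with pseudo attachments.
#' @param growth_frac Relative size-change fraction (default 0.2).
#' @return A data.frame of events with columns `type`, `time`, `sources`,
#'   `targets` (participant labels joined by `+`, sorted), `size_source`,
#'   `size_target`, `unseen_frac`.
#' @export
classify_events <- function(map, growth_frac = 0.2) {
  stopifnot(inherits(map, "bipartite_map"), !is.null(map$retained),
            !is.null(map$pseudo))
  kept <- map$edges[map$retained, , drop = FALSE]
  ev <- list()
  add <- function(type, sources, targets, unseen = NA_real_) {
    ev[[length(ev) + 1L]] <<- data.frame(
      type = type, time = map$t,
      sources = paste(sort(sources), collapse = "+"),
      targets = paste(sort(targets), collapse = "+"),
      size_source = if (length(sources))
        sum(map$size_source[sources]) else NA_integer_,
      size_target = if (length(targets))
        sum(map$size_target[targets]) else NA_integer_,
      unseen_frac = unseen, stringsAsFactors = FALSE)
  }
  out_deg <- table(kept$source)
  in_deg <- table(kept$target)
  # splits: source out-degree >= 2
  for (s in names(out_deg)[out_deg >= 2L])
    add("split", s, kept$target[kept$source == s])
  # merges: target in-degree >= 2
  for (tg in names(in_deg)[in_deg >= 2L])
    add("merge", kept$source[kept$target == tg], tg)
  # deaths and births from pseudo attachments
  ps <- map$pseudo
  for (i in which(ps$kind == "dump")) add("death", ps$source[i], character(0))
  for (i in which(ps$kind == "birth"))
    add("birth", character(0), ps$target[i], unseen = ps$unseen_frac[i])
  # continuations: mutual unique correspondence
  uniq_src <- names(out_deg)[out_deg == 1L]
  for (s in uniq_src) {
    tg <- kept$target[kept$source == s]
    if (in_deg[[tg]] == 1L) {
      add("continuation", s, tg)
      n0 <- map$size_source[[s]]; n1 <- map$size_target[[tg]]
      if (n1 >= n0 * (1 + growth_frac) - WEIGHT_TOL && n1 > n0)
        add("growth", s, tg)
      else if (n1 <= n0 * (1 - growth_frac) + WEIGHT_TOL && n1 < n0)
        add("shrinkage", s, tg)
    }
  }
  if (length(ev) == 0L)
    return(data.frame(type = character(), time = integer(),
                      sources = character(), targets = character(),
                      size_source = integer(), size_target = integer(),
                      unseen_frac = numeric(), stringsAsFactors = FALSE))
  sort_events(do.call(rbind, ev))
}

#' Track communities across all snapshots
#'
#' Runs the full per-interval tracking: builds the bipartite map for every
#' consecutive snapshot pair, computes the adaptive thresholds, optionally
#' applies the user override rule (`rho`/`nu`), prunes, attaches pseudo
#' communities and classifies events.
#'
#' @param dp A [dynamic_partition()] with at least 2 snapshots.
#' @param rho Optional user minimum edge weight in `[0, 1]`.
#' @param nu Tolerance for the override rule (default 0.1).
#' @param growth_frac Relative growth/shrinkage fraction (default 0.2).
#' @return A list with `maps` (list of pruned `bipartite_map`s with pseudo
#'   attachments), `events` (all intervals, time order), `thetas` (tracked),
#'   `thetas_applied`, `mu_theta`, `overridden`.
#' @export
track_all <- function(dp, rho = NULL, nu = 0.1, growth_frac = 0.2) {
  dp <- as.dynamic_partition(dp)
  if (dp$T < 2L) stop("at least 2 time-stamps required for tracking")
  maps <- vector("list", dp$T - 1L)
  for (t in seq_len(dp$T - 1L))
    maps[[t]] <- compute_threshold(
      build_bipartite_map(dp$snapshots[[t]], dp$snapshots[[t + 1L]]))
  thetas <- vapply(maps, `[[`, numeric(1L), "theta")
  mu_theta <- mean(thetas, na.rm = TRUE)
  overridden <- FALSE
  applied <- thetas
  if (!is.null(rho)) {
    res <- apply_user_threshold(thetas, rho, nu)
    applied <- res$applied
    mu_theta <- res$mu_theta
    overridden <- res$overridden
  }
  events <- vector("list", length(maps))
  for (t in seq_along(maps)) {
    m <- maps[[t]]
    if (nrow(m$edges) > 0L) m <- prune_map(m, theta = applied[t])
    else m$retained <- logical(0)
    m <- attach_pseudo_clusters(m, dp$snapshots[[t]], dp$snapshots[[t + 1L]])
    maps[[t]] <- m
    events[[t]] <- classify_events(m, growth_frac = growth_frac)
  }
  list(maps = maps, events = do.call(rbind, events), thetas = thetas,
       thetas_applied = applied, mu_theta = mu_theta,
       overridden = overridden)
}

#' @export
print.bipartite_map <- function(x, ...) {
  cat("Bipartite tracking map, interval", x$t, "->", x$t + 1L, "\n")
  cat("  ", length(x$sources), "->", length(x$targets), "communities;",
      nrow(x$edges), "positive-weight edges\n")
  if (!is.na(x$theta))
    cat(sprintf("  theta = %.4f (applied %.4f)\n", x$theta, x$theta_applied))
  else cat("  theta undefined (no edges)\n")
  if (!is.null(x$retained))
    cat("  retained edges:", sum(x$retained), "\n")
  if (!is.null(x$pseudo) && nrow(x$pseudo))
    cat("  pseudo:", sum(x$pseudo$kind == "dump"), "death(s),",
        sum(x$pseudo$kind == "birth"), "birth(s)\n")
  invisible(x)
}

# edge table export for downstream modules / the heatmap renderer
map_edge_table <- function(map) {
  e <- map$edges
  e$retained <- if (nrow(e)) map$retained else logical(0)
  e$theta <- map$theta_applied
  e$t <- map$t
  e
}
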