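# Timeline layout: each origin owns a horizontal track (center y = track
# index, increasing downward, band half-width 0.4). Within a band the main
# branch sits at slot 0 and each branch created by a split is appended at the
# next free slot below; the child with the smallest cluster label inherits
# the parent's slot. Branches persist without re-collapsing. A cross-track
# merge terminates the absorbed line with a dashed segment to the surviving
# circle.

BAND_HALF <- 0.4
MAX_RADIUS <- 0.35
DEFAULT_RADIUS <- 0.15

slot_spacing <- function(m) {
  # spec'd delta = band width / (branches + 1), capped so the deepest slot
  # stays inside the half-band
  if (m <= 1L) return(0)
  min(2 * BAND_HALF / (m + 1L), BAND_HALF / (m - 1L))
}

#' Resolve cross-track merge events of a thread set
#'
#' Detects, interval by interval, groups of branch lines from at least two
#' distinct origins arriving at the same community, and decides which line
#' survives. Survivor priority: an explicit policy entry, else the incoming
#' line with the greatest tracking edge weight (requires `maps`), else the
#' smallest track index under `ordering`. The absorbed lines (and their
#' entire later branch structure) stop being drawn; the merged community
#' lives on the survivor's track.
#'
#' @param threads A `thread_set` (see [extract_threads()]).
#' @param ordering Character vector: permutation of the origins (used for the
#'   track-index tie-break).
#' @param survivor_policy Optional named character vector mapping
#'   `"<time>:<label>"` of a merge to the origin that must survive it.
#' @param maps Optional list of tracked `bipartite_map`s supplying edge
#'   weights for the weight rule.
#' @return A list with `merges` (data.frame: `time`, `label`,
#'   `absorbed_node`, `absorbed_origin`, `survivor_node`, `survivor_origin`)
#'   and `removed` (integer node ids not drawn).
#' @export
resolve_merges <- function(threads, ordering = NULL, survivor_policy = NULL,
                           maps = NULL) {
  stopifnot(inherits(threads, "thread_set"))
  if (is.null(ordering)) ordering <- threads$origins
  check_ordering(threads, ordering)
  nd <- threads$nodes
  track_of <- stats::setNames(seq_along(ordering), ordering)
  removed <- logical(nrow(nd) + 1L)  # indexed by node id
  merges <- list()
  descendants <- function(id) {
    acc <- id
    frontier <- id
    repeat {
      kids <- nd$id[!is.na(nd$parent) & nd$parent %in% frontier]
      if (!length(kids)) break
      acc <- c(acc, kids)
      frontier <- kids
    }
    acc
  }
  for (tt in sort(unique(nd$time[!is.na(nd$parent)]))) {
    arrive <- nd[nd$time == tt & !is.na(nd$parent) & !removed[nd$id], ,
                 drop = FALSE]
    if (nrow(arrive) == 0L) next
    for (lab in sort(unique(arrive$label))) {
      grp <- arrive[arrive$label == lab, , drop = FALSE]
      grp <- grp[!removed[grp$id], , drop = FALSE]
      if (length(unique(grp$origin)) < 2L) next
      surv_origin <- pick_survivor(grp, nd, tt, lab, track_of,
                                   survivor_policy, maps)
      surv_nodes <- grp$id[grp$origin == surv_origin]
      surv_node <- min(surv_nodes)
      for (i in which(grp$origin != surv_origin)) {
        merges[[length(merges) + 1L]] <- data.frame(
          time = tt, label = lab, absorbed_node = grp$id[i],
          absorbed_origin = grp$origin[i], survivor_node = surv_node,
          survivor_origin = surv_origin, stringsAsFactors = FALSE)
        removed[descendants(grp$id[i])] <- TRUE
      }
    }
  }
  merges <- if (length(merges)) do.call(rbind, merges) else
    data.frame(time = integer(), label = character(),
               absorbed_node = integer(), absorbed_origin = character(),
               survivor_node = integer(), survivor_origin = character(),
               stringsAsFactors = FALSE)
  list(merges = merges, removed = which(removed))
}

pick_survivor <- function(grp, nd, tt, lab, track_of, policy, maps) {
  key <- paste0(tt, ":", lab)
  if (!is.null(policy) && key %in% names(policy)) {
    cand <- policy[[key]]
    if (!cand %in% grp$origin)
      stop("survivor policy for ", key, " names origin '", cand,
           "' which does not arrive at that community")
    return(cand)
  }
  if (!is.null(maps) && tt >= 2L && tt - 1L <= length(maps)) {
    e <- maps[[tt - 1L]]$edges
    w <- vapply(seq_len(nrow(grp)), function(i) {
      src <- nd$label[nd$id == grp$parent[i]]
      hit <- e$weight[e$source == src & e$target == lab]
      if (length(hit)) max(hit) else -Inf
    }, numeric(1L))
    if (any(is.finite(w))) {
      best <- which(w >= max(w) - WEIGHT_TOL)
      cand <- grp$origin[best]
      return(cand[which.min(track_of[cand])])
    }
  }
  grp$origin[which.min(track_of[grp$origin])]
}

check_ordering <- function(threads, ordering) {
  if (!setequal(ordering, threads$origins) ||
      length(ordering) != length(threads$origins))
    stop("ordering must be a permutation of the origins; unknown: ",
         paste(setdiff(ordering, threads$origins), collapse = ", "))
  invisible(TRUE)
}

# ordering-independent part of the layout: slot offsets per origin, segment
# list in (origin, offset) coordinates, constant within-band crossing count
local_layout <- function(threads, resolution) {
  nd <- threads$nodes
  drawn <- !(nd$id %in% resolution$removed)
  nd$slot <- NA_integer_
  for (o in threads$origins) {
    sel <- which(nd$origin == o & drawn)
    if (!length(sel)) next
    next_free <- 1L
    for (i in sel[order(nd$time[sel], nd$id[sel])]) {
      p <- nd$parent[i]
      if (is.na(p)) { nd$slot[i] <- 0L; next }
      sibs <- sel[!is.na(nd$parent[sel]) & nd$parent[sel] == p]
      labs <- nd$label[sibs]
      first <- sibs[order(labs, method = "radix")][1L]
      if (i == first) nd$slot[i] <- nd$slot[nd$id == p]
      else if (is.na(nd$slot[i])) {
        nd$slot[i] <- next_free
        next_free <- next_free + 1L
      }
    }
  }
  # per-origin slot spacing
  delta <- vapply(threads$origins, function(o) {
    s <- nd$slot[nd$origin == o & drawn]
    slot_spacing(if (length(s)) max(s) + 1L else 1L)
  }, numeric(1L))
  names(delta) <- threads$origins
  nd$offset <- ifelse(drawn, nd$slot * delta[nd$origin], NA_real_)

  circ <- nd[drawn, c("id", "origin", "time", "label", "slot", "offset"),
             drop = FALSE]
  circ$size <- if ("size" %in% names(nd)) nd$size[drawn] else NA_integer_

  seg <- nd[drawn & !is.na(nd$parent) & !(nd$parent %in% resolution$removed),
            , drop = FALSE]
  off_of <- stats::setNames(nd$offset, nd$id)
  segments <- data.frame(
    interval = seg$time - 1L,
    origin0 = seg$origin, off0 = as.numeric(off_of[as.character(seg$parent)]),
    origin1 = seg$origin, off1 = seg$offset,
    c0 = seg$parent, c1 = seg$id,
    kind = ifelse(seg$offset == as.numeric(off_of[as.character(seg$parent)]),
                  "timeline", "branch"),
    stringsAsFactors = FALSE)
  mg <- resolution$merges
  if (nrow(mg)) {
    dash <- data.frame(
      interval = mg$time - 1L,
      origin0 = mg$absorbed_origin,
      off0 = as.numeric(off_of[as.character(
        nd$parent[match(mg$absorbed_node, nd$id)])]),
      origin1 = mg$survivor_origin,
      off1 = as.numeric(off_of[as.character(mg$survivor_node)]),
      c0 = nd$parent[match(mg$absorbed_node, nd$id)],
      c1 = mg$survivor_node,
      kind = "merge-dash", stringsAsFactors = FALSE)
    segments <- rbind(segments, dash)
  }
  rownames(segments) <- NULL
  list(circles = circ, segments = segments)
}

#' Assign timeline tracks and build the drawing geometry
#'
#' Turns a thread set into concrete timeline geometry under a given
#' top-to-bottom track ordering: every origin's branches are laid out in its
#' band (y = track index +/- 0.4), cross-track merges become dashed segments
#' to the surviving circle, and circle radii scale with the square root of
#' the community size (area proportional to node count), normalised so the
#' largest radius is 0.35 track units.
#'
#' @param threads A `thread_set`, optionally with sizes attached via
#'   [thread_sizes()].
#' @param ordering Track ordering (permutation of the origins); default is
#'   T1 label order with newborn origins appended.
#' @param survivor_policy,maps Passed to [resolve_merges()].
#' @param resolution Optional pre-resolved merge structure (so that
#'   alternative orderings of the same instance share one merge resolution).
#' @return An object of class `timeline_geometry` with `circles`
#'   (`id`, `origin`, `time`, `label`, `track`, `slot`, `y`, `radius`,
#'   `size`) and `segments` (`interval`, `y0`, `y1`, `kind`, `c0`, `c1`).
#' @export
assign_tracks <- function(threads, ordering = NULL, survivor_policy = NULL,
                          maps = NULL, resolution = NULL) {
  stopifnot(inherits(threads, "thread_set"))
  if (is.null(ordering)) ordering <- threads$origins
  check_ordering(threads, ordering)
  if (is.null(resolution))
    resolution <- resolve_merges(threads, ordering, survivor_policy, maps)
  loc <- local_layout(threads, resolution)
  globalize_layout(loc, ordering, threads$T)
}

globalize_layout <- function(loc, ordering, Tn) {
  pos <- stats::setNames(seq_along(ordering), ordering)
  circ <- loc$circles
  circ$track <- as.integer(pos[circ$origin])
  circ$y <- circ$track + circ$offset
  if (all(is.na(circ$size))) circ$radius <- DEFAULT_RADIUS
  else {
    r <- sqrt(circ$size)
    circ$radius <- r / max(r, na.rm = TRUE) * MAX_RADIUS
    circ$radius[is.na(circ$radius)] <- DEFAULT_RADIUS
  }
  seg <- loc$segments
  seg$y0 <- pos[seg$origin0] + seg$off0
  seg$y1 <- pos[seg$origin1] + seg$off1
  structure(list(circles = circ, segments = seg, ordering = ordering,
                 T = Tn),
            class = "timeline_geometry")
}

#' @export
print.timeline_geometry <- function(x, ...) {
  cat("Timeline geometry:", nrow(x$circles), "circles,",
      nrow(x$segments), "segments over", length(x$ordering), "tracks\n")
  cat("  ordering:", paste(x$ordering, collapse = " > "), "\n")
  cat("  cross-overs:", count_crossovers(x), "\n")
  invisible(x)
}

#' Count line cross-overs of a timeline geometry
#'
#' Number of unordered pairs of segments in the same time interval whose
#' straight lines strictly cross, i.e. whose endpoint orderings swap between
#' the two interval boundaries; pairs sharing an endpoint circle are
#' excluded. The count is invariant under any strictly increasing transform
#' of the y coordinates.
#'
#' @param geom A `timeline_geometry`.
#' @return Non-negative integer.
#' @export
count_crossovers <- function(geom) {
  stopifnot(inherits(geom, "timeline_geometry"))
  s <- geom$segments
  total <- 0L
  for (iv in unique(s$interval)) {
    g <- s[s$interval == iv, , drop = FALSE]
    m <- nrow(g)
    if (m < 2L) next
    d0 <- outer(g$y0, g$y0, "-")
    d1 <- outer(g$y1, g$y1, "-")
    cross <- d0 * d1 < 0
    shared <- outer(g$c0, g$c0, "==") | outer(g$c0, g$c1, "==") |
      outer(g$c1, g$c0, "==") | outer(g$c1, g$c1, "==")
    total <- total + sum(cross & !shared & upper.tri(cross))
  }
  as.integer(total)
}

# fast crossing count for ordering search: constant within-band part plus
# the ordering-dependent pairs that involve a merge dash
prepare_crossing_search <- function(threads, resolution) {
  loc <- local_layout(threads, resolution)
  s <- loc$segments
  dash <- s$kind == "merge-dash"
  const <- 0L
  for (iv in unique(s$interval[!dash])) {
    g <- s[!dash & s$interval == iv, , drop = FALSE]
    if (nrow(g) < 2L) next
    for (i in seq_len(nrow(g) - 1L)) for (j in (i + 1L):nrow(g)) {
      if (g$origin0[i] != g$origin0[j]) next  # disjoint bands cannot cross
      if (g$c0[i] == g$c0[j] || g$c0[i] == g$c1[j] ||
          g$c1[i] == g$c0[j] || g$c1[i] == g$c1[j]) next
      if ((g$off0[i] - g$off0[j]) * (g$off1[i] - g$off1[j]) < 0)
        const <- const + 1L
    }
  }
  list(segments = s, dash_idx = which(dash), const = const)
}

crossings_for_ordering <- function(pre, ordering) {
  s <- pre$segments
  pos <- stats::setNames(seq_along(ordering), ordering)
  y0 <- pos[s$origin0] + s$off0
  y1 <- pos[s$origin1] + s$off1
  n <- pre$const
  seen <- logical(nrow(s))
  for (i in pre$dash_idx) {
    seen[i] <- TRUE
    same <- which(s$interval == s$interval[i] & !seen)
    for (j in same) {
      if (s$c0[i] == s$c0[j] || s$c0[i] == s$c1[j] ||
          s$c1[i] == s$c0[j] || s$c1[i] == s$c1[j]) next
      if ((y0[i] - y0[j]) * (y1[i] - y1[j]) < 0) n <- n + 1L
    }
  }
  as.integer(n)
}

#' Greedily reorder tracks to reduce line cross-overs
#'
#' Builds pairwise interaction weights between origins (the number of
#' cross-track merge attachments linking them over all intervals), seeds the
#' order with the origin of largest total interaction, and repeatedly appends
#' the unplaced origin with the strongest interaction with the last placed
#' one (ties: interaction with any placed origin, then initial-order index).
#' Origins with no interaction keep their relative initial order at the end.
#' The result is guaranteed not to increase the cross-over count: if the
#' greedy order scores worse than `initial`, `initial` is returned.
#'
#' @param threads A `thread_set`.
#' @param initial Initial track ordering.
#' @param survivor_policy,maps Passed to [resolve_merges()] (resolved once,
#'   under `initial`).
#' @return A track ordering (character vector).
#' @export
greedy_reorder <- function(threads, initial = NULL, survivor_policy = NULL,
                           maps = NULL) {
  stopifnot(inherits(threads, "thread_set"))
  if (is.null(initial)) initial <- threads$origins
  check_ordering(threads, initial)
  res <- resolve_merges(threads, initial, survivor_policy, maps)
  orgs <- initial
  n <- length(orgs)
  M <- matrix(0L, n, n, dimnames = list(orgs, orgs))
  mg <- res$merges
  for (i in seq_len(nrow(mg))) {
    a <- mg$absorbed_origin[i]; b <- mg$survivor_origin[i]
    M[a, b] <- M[a, b] + 1L
    M[b, a] <- M[b, a] + 1L
  }
  tot <- rowSums(M)
  active <- orgs[tot > 0]
  if (length(active)) {
    placed <- character(0)
    seed <- active[order(-tot[active], match(active, initial))][1L]
    placed <- seed
    while (length(placed) < length(active)) {
      rest <- setdiff(active, placed)
      last <- placed[length(placed)]
      sc1 <- M[last, rest]
      sc2 <- if (length(placed) > 1L)
        colSums(M[placed, rest, drop = FALSE]) else sc1
      pick <- rest[order(-sc1, -sc2, match(rest, initial))][1L]
      placed <- c(placed, pick)
    }
    candidate <- c(placed, setdiff(initial, active))
  } else candidate <- initial
  pre <- prepare_crossing_search(threads, res)
  if (crossings_for_ordering(pre, candidate) <=
      crossings_for_ordering(pre, initial)) candidate else initial
}

#' Exhaustive track-ordering search (small instances)
#'
#' Enumerates all permutations of the origins and returns a global minimiser
#' of the cross-over count (the lexicographically smallest one under the
#' initial ordering's indexing, among the minimisers).
#'
#' @param threads A `thread_set`.
#' @param initial Initial ordering (defines the index lexicography).
#' @param survivor_policy,maps Passed to [resolve_merges()].
#' @param max_origins Refuse instances larger than this (default 8).
#' @return A list with `ordering` and `crossings`.
#' @export
brute_force_order <- function(threads, initial = NULL,
                              survivor_policy = NULL, maps = NULL,
                              max_origins = 8L) {
  stopifnot(inherits(threads, "thread_set"))
  if (is.null(initial)) initial <- threads$origins
  check_ordering(threads, initial)
  n <- length(initial)
  if (n > max_origins)
    stop(n, " origins exceed the exhaustive-search cap of ", max_origins,
         "; use the greedy ordering mode instead")
  res <- resolve_merges(threads, initial, survivor_policy, maps)
  pre <- prepare_crossing_search(threads, res)
  best <- NULL
  best_n <- Inf
  for (idx in permutations_lex(n)) {
    ord <- initial[idx]
    cn <- crossings_for_ordering(pre, ord)
    if (cn < best_n) { best_n <- cn; best <- ord }
  }
  list(ordering = best, crossings = as.integer(best_n))
}

# lexicographic permutation generator (list of index vectors)
permutations_lex <- function(n) {
  if (n == 1L) return(list(1L))
  out <- vector("list", factorial(n))
  k <- 0L
  rec <- function(prefix, rest) {
    if (!length(rest)) {
      k <<- k + 1L
      out[[k]] <<- prefix
      return(invisible())
    }
    for (r in rest) rec(c(prefix, r), setdiff(rest, r))
  }
  rec(integer(0), seq_len(n))
  out
}
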