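# Planted-event benchmark generator. A schedule plants births, deaths,
# merges, splits, expansions and shrinkages over T snapshots; the generated
# membership tables come with exact ground-truth event records so recovery
# can be tested set-exactly.

#' Planted event schedule
#'
#' @param T Number of snapshots (>= 2).
#' @param initial_sizes Integer vector of initial community sizes; the
#'   communities are labelled `C1..Cn`.
#' @param events Named list, one entry per interval `"2".."T"` (absent
#'   entries mean "no planted events"); each entry is a list with any of:
#'   `deaths` (labels), `births` (integer sizes), `merges` (list of label
#'   vectors), `splits` (list of `list(label=, frac=)`), `grows` / `shrinks`
#'   (list of `list(label=, frac=)`). A community may take part in at most
#'   one planted event per interval; fractions must lie in (0, 1).
#' @param churn Per-node probability of migrating to another community in
#'   each interval (default 0 so recovery is exact).
#' @param growth_frac The relative size-change fraction used when deriving
#'   ground-truth growth/shrinkage annotations (matches the tracker default
#'   0.2).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return An object of class `event_schedule`.
#' @export
event_schedule <- function(T, initial_sizes, events = list(), churn = 0,
                           growth_frac = 0.2, seed = 1L) {
  T <- as.integer(T)
  stopifnot(T >= 2L, all(initial_sizes >= 1L), churn >= 0, churn < 1)
  for (nm in names(events)) {
    t <- suppressWarnings(as.integer(nm))
    if (is.na(t) || t < 2L || t > T)
      stop("event entry '", nm, "' is not an interval in 2..T")
    ev <- events[[nm]]
    for (sp in c(ev$splits, ev$grows, ev$shrinks))
      if (sp$frac <= 0 || sp$frac >= 1)
        stop("fractions must lie in (0, 1)")
    for (mg in ev$merges)
      if (length(mg) < 2L) stop("a merge needs at least 2 communities")
  }
  structure(list(T = T, initial_sizes = as.integer(initial_sizes),
                 events = events, churn = churn,
                 growth_frac = growth_frac, seed = as.integer(seed)),
            class = "event_schedule")
}

#' Generate a dynamic partition from a planted schedule
#'
#' Deaths remove all of a community's nodes; births introduce previously
#' unseen node identifiers; merges pool node sets under the smallest
#' participating label; a split of fraction `f` carves `round(f * size)`
#' nodes into a child labelled `<parent>S<j>`; expansions add and shrinkages
#' remove the stated fraction of (fresh / existing) nodes; unscheduled
#' communities persist unchanged apart from optional churn.
#'
#' @param schedule An [event_schedule()].
#' @return A list with `partition` (a [dynamic_partition()]) and `truth`
#'   (ground-truth event data.frame in the layout of [classify_events()];
#'   growth/shrinkage records are included only when the realised relative
#'   change reaches the schedule's `growth_frac`).
#' @export
generate_dynamic_partition <- function(schedule) {
  stopifnot(inherits(schedule, "event_schedule"))
  set.seed(schedule$seed)
  node_counter <- 0L
  fresh_nodes <- function(n) {
    ids <- paste0("n", node_counter + seq_len(n))
    node_counter <<- node_counter + n
    ids
  }
  n0 <- length(schedule$initial_sizes)
  clusters <- lapply(schedule$initial_sizes, fresh_nodes)
  names(clusters) <- paste0("C", seq_len(n0))
  snaps <- list(snapshot_partition(1L, clusters))
  truth <- list()
  gf <- schedule$growth_frac
  add_truth <- function(type, t, sources, targets, n_src, n_tgt) {
    truth[[length(truth) + 1L]] <<- data.frame(
      type = type, time = t,
      sources = paste(sort(sources), collapse = "+"),
      targets = paste(sort(targets), collapse = "+"),
      size_source = if (length(sources)) n_src else NA_integer_,
      size_target = if (length(targets)) n_tgt else NA_integer_,
      stringsAsFactors = FALSE)
  }
  split_counter <- integer(0)
  for (t in 2:schedule$T) {
    ev <- schedule$events[[as.character(t)]]
    prev <- clusters
    touched <- character(0)
    claim <- function(labels) {
      dead <- setdiff(labels, names(prev))
      if (length(dead))
        stop("interval ", t, ": event references unknown/dead communit",
             if (length(dead) > 1L) "ies: " else "y: ",
             paste(dead, collapse = ", "))
      twice <- intersect(labels, touched)
      if (length(twice))
        stop("interval ", t, ": communit", "y ", twice[1L],
             " scheduled for more than one event")
      touched <<- c(touched, labels)
    }
    nxt <- prev
    for (d in ev$deaths) {
      claim(d)
      add_truth("death", t - 1L, d, character(0), length(prev[[d]]), NA)
      nxt[[d]] <- NULL
    }
    for (mg in ev$merges) {
      claim(mg)
      tgt <- sort(mg)[1L]
      pooled <- unlist(prev[mg], use.names = FALSE)
      nxt[setdiff(mg, tgt)] <- NULL
      nxt[[tgt]] <- pooled
      add_truth("merge", t - 1L, mg, tgt,
                sum(lengths(prev[mg])), length(pooled))
    }
    for (sp in ev$splits) {
      claim(sp$label)
      nodes <- prev[[sp$label]]
      k <- max(1L, min(length(nodes) - 1L, round(sp$frac * length(nodes))))
      moved <- sample(nodes, k)
      j <- (split_counter[sp$label] %||% 0L) + 1L
      split_counter[sp$label] <- j
      child <- paste0(sp$label, "S", j)
      nxt[[sp$label]] <- setdiff(nodes, moved)
      nxt[[child]] <- moved
      add_truth("split", t - 1L, sp$label, c(sp$label, child),
                length(nodes), length(nodes))
    }
    for (b in seq_along(ev$births)) {
      lab <- paste0("B", t, "_", b)
      nxt[[lab]] <- fresh_nodes(ev$births[[b]])
      add_truth("birth", t - 1L, character(0), lab, NA, ev$births[[b]])
    }
    for (g in ev$grows) {
      claim(g$label)
      nxt[[g$label]] <- c(prev[[g$label]],
                          fresh_nodes(round(g$frac * length(prev[[g$label]]))))
    }
    for (s in ev$shrinks) {
      claim(s$label)
      nodes <- prev[[s$label]]
      k <- min(length(nodes) - 1L, round(s$frac * length(nodes)))
      nxt[[s$label]] <- setdiff(nodes, sample(nodes, k))
    }
    # churn: small random migrations between surviving communities
    if (schedule$churn > 0 && length(nxt) >= 2L) {
      labs <- names(nxt)
      for (lab in labs) {
        k <- stats::rbinom(1L, length(nxt[[lab]]), schedule$churn)
        k <- min(k, length(nxt[[lab]]) - 1L)
        if (k < 1L) next
        mv <- sample(nxt[[lab]], k)
        dest <- sample(setdiff(labs, lab), k, replace = TRUE)
        nxt[[lab]] <- setdiff(nxt[[lab]], mv)
        for (i in seq_len(k)) nxt[[dest[i]]] <- c(nxt[[dest[i]]], mv[i])
      }
    }
    # continuations (and realised growth/shrinkage) for untouched survivors
    for (lab in names(nxt)) {
      if (!lab %in% names(prev)) next
      if (lab %in% unlist(lapply(ev$merges, identity))) next
      if (lab %in% vapply(ev$splits, `[[`, "", "label")) next
      if (lab %in% ev$deaths) next
      n_old <- length(prev[[lab]]); n_new <- length(nxt[[lab]])
      add_truth("continuation", t - 1L, lab, lab, n_old, n_new)
      if (n_new >= n_old * (1 + gf) - WEIGHT_TOL && n_new > n_old)
        add_truth("growth", t - 1L, lab, lab, n_old, n_new)
      else if (n_new <= n_old * (1 - gf) + WEIGHT_TOL && n_new < n_old)
        add_truth("shrinkage", t - 1L, lab, lab, n_old, n_new)
    }
    clusters <- nxt
    snaps[[t]] <- snapshot_partition(t, clusters)
  }
  truth <- sort_events(do.call(rbind, truth))
  list(partition = dynamic_partition(snaps), truth = truth)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

#' Sample planted-partition edge lists for a dynamic partition
#'
#' Per snapshot, each within-community node pair carries an edge with
#' probability `p_in` and each between-community pair with probability
#' `p_out` (`p_out < p_in`).
#'
#' @param dp A [dynamic_partition()].
#' @param p_in,p_out Edge probabilities with `0 <= p_out < p_in <= 1`.
#' @param seed Integer seed.
#' @return An `edge_series`.
#' @export
generate_edges <- function(dp, p_in, p_out, seed = 1L) {
  dp <- as.dynamic_partition(dp)
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1))
    stop("need 0 <= p_out < p_in <= 1")
  set.seed(seed)
  series <- lapply(dp$snapshots, function(s) {
    cl <- s$clusters
    out <- list()
    labs <- names(cl)
    for (i in seq_along(labs)) for (j in i:length(labs)) {
      a <- cl[[i]]; b <- cl[[j]]
      if (i == j) {
        n <- length(a)
        if (n < 2L) next
        pairs <- sample_pairs(n * (n - 1L) / 2L, p_in)
        if (!length(pairs)) next
        ij <- within_pair_index(pairs, n)
        out[[length(out) + 1L]] <- data.frame(src = a[ij[, 1L]],
                                              dst = a[ij[, 2L]],
                                              stringsAsFactors = FALSE)
      } else if (p_out > 0) {
        pairs <- sample_pairs(length(a) * length(b), p_out)
        if (!length(pairs)) next
        ia <- ((pairs - 1L) %% length(a)) + 1L
        ib <- ((pairs - 1L) %/% length(a)) + 1L
        out[[length(out) + 1L]] <- data.frame(src = a[ia], dst = b[ib],
                                              stringsAsFactors = FALSE)
      }
    }
    df <- if (length(out)) do.call(rbind, out) else
      data.frame(src = character(), dst = character(),
                 stringsAsFactors = FALSE)
    df$count <- rep(1L, nrow(df))
    df <- df[order(df$src, df$dst), , drop = FALSE]
    rownames(df) <- NULL
    attr(df, "self_loops") <- df[df$src == df$dst, c("src", "dst"),
                                 drop = FALSE]
    df
  })
  structure(series, class = "edge_series")
}

sample_pairs <- function(n_pairs, p) {
  k <- stats::rbinom(1L, n_pairs, p)
  if (k == 0L) integer(0) else sort(sample.int(n_pairs, k))
}

# map linear index over the n*(n-1)/2 unordered pairs to (i, j), i < j
within_pair_index <- function(idx, n) {
  j <- ceiling((1 + sqrt(1 + 8 * idx)) / 2)
  i <- idx - (j - 1) * (j - 2) / 2
  cbind(as.integer(i), as.integer(j))
}

#' Preset: birth/death benchmark schedule
#'
#' 13 communities of ~1,000 nodes over 5 snapshots; one death at t = 3 and
#' t = 4, one birth at t = 4 and t = 5.
#'
#' @param seed Integer seed.
#' @return An [event_schedule()].
#' @export
schedule_birthdeath <- function(seed = 1L) {
  sizes <- c(rep(77L, 12L), 76L)  # 1,000 nodes
  event_schedule(5L, sizes, events = list(
    "3" = list(deaths = "C2"),
    "4" = list(deaths = "C5", births = list(60L)),
    "5" = list(births = list(55L))
  ), seed = seed)
}

#' Preset: hide benchmark schedule (one death per interval)
#'
#' 7 communities over 5 snapshots; exactly one community disappears at each
#' time-stamp after the first.
#'
#' @param seed Integer seed.
#' @return An [event_schedule()].
#' @export
schedule_hide <- function(seed = 1L) {
  event_schedule(5L, rep(100L, 7L), events = list(
    "2" = list(deaths = "C1"), "3" = list(deaths = "C2"),
    "4" = list(deaths = "C3"), "5" = list(deaths = "C4")
  ), seed = seed)
}

#' Preset: merge/split benchmark schedule
#'
#' 7 communities, 1,000 nodes, 5 snapshots; one merge and two splits per
#' interval.
#'
#' @param seed Integer seed.
#' @return An [event_schedule()].
#' @export
schedule_mergesplit <- function(seed = 1L) {
  sizes <- c(rep(143L, 6L), 142L)
  event_schedule(5L, sizes, events = list(
    "2" = list(merges = list(c("C1", "C2")),
               splits = list(list(label = "C3", frac = 0.4),
                             list(label = "C4", frac = 0.35))),
    "3" = list(merges = list(c("C5", "C6")),
               splits = list(list(label = "C3", frac = 0.45),
                             list(label = "C7", frac = 0.4))),
    "4" = list(merges = list(c("C3S1", "C4S1")),
               splits = list(list(label = "C1", frac = 0.4),
                             list(label = "C5", frac = 0.35))),
    "5" = list(merges = list(c("C1S1", "C3S2")),
               splits = list(list(label = "C4", frac = 0.4),
                             list(label = "C7S1", frac = 0.45)))
  ), seed = seed)
}

#' Draw a random planted schedule
#'
#' Used for recovery testing: a random initial partition (up to
#' `max_clusters` communities over roughly `n_nodes` nodes) and a random mix
#' of planted events per interval, constrained so every community takes part
#' in at most one event per interval and event magnitudes stay above the
#' significance scale (split fractions 0.3-0.5, growth 0.3-0.5, shrinkage
#' 0.25-0.4, births of 30-80 nodes).
#'
#' @param seed Integer seed.
#' @param T Number of snapshots (default 5).
#' @param n_nodes Approximate initial node count (default 1000).
#' @param max_clusters Maximum initial community count (default 13).
#' @param churn Churn rate passed through (default 0).
#' @return An [event_schedule()].
#' @export
random_schedule <- function(seed, T = 5L, n_nodes = 1000L,
                            max_clusters = 13L, churn = 0) {
  set.seed(seed)
  n_cl <- sample(4:max_clusters, 1L)
  w <- stats::runif(n_cl, 0.5, 1.5)
  sizes <- pmax(30L, as.integer(round(w / sum(w) * n_nodes)))
  alive <- paste0("C", seq_len(n_cl))
  split_j <- integer(0)
  events <- list()
  for (t in 2:T) {
    free <- alive
    ev <- list()
    take <- function(k) {
      picked <- sample(free, k)
      free <<- setdiff(free, picked)
      picked
    }
    if (length(free) > 4L && stats::runif(1) < 0.5) {
      d <- take(1L)
      ev$deaths <- d
      alive <- setdiff(alive, d)
    }
    if (length(free) > 3L && stats::runif(1) < 0.5) {
      mg <- take(2L)
      ev$merges <- list(mg)
      alive <- c(setdiff(alive, mg), sort(mg)[1L])
    }
    n_split <- sample(0:2, 1L)
    for (k in seq_len(min(n_split, max(0L, length(free) - 1L)))) {
      sp <- take(1L)
      j <- (split_j[sp] %||% 0L) + 1L
      split_j[sp] <- j
      ev$splits <- c(ev$splits,
                     list(list(label = sp, frac = stats::runif(1, 0.3, 0.5))))
      alive <- c(alive, paste0(sp, "S", j))
    }
    if (stats::runif(1) < 0.4) {
      b <- sample(30:80, 1L)
      ev$births <- list(b)
      alive <- c(alive, paste0("B", t, "_1"))
    }
    if (length(free) > 0L && stats::runif(1) < 0.4) {
      g <- take(1L)
      ev$grows <- list(list(label = g, frac = stats::runif(1, 0.3, 0.5)))
    }
    if (length(free) > 0L && stats::runif(1) < 0.4) {
      s <- take(1L)
      ev$shrinks <- list(list(label = s, frac = stats::runif(1, 0.25, 0.4)))
    }
    events[[as.character(t)]] <- ev
  }
  event_schedule(T, sizes, events, churn = churn,
                 seed = seed + 1000003L)
}
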