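#' Trace community evolution across network snapshots
#'
#' The main entry point: takes the per-snapshot community memberships
#' produced by any evolutionary clustering method and runs the full
#' post-processing chain — Jaccard-weighted bipartite tracking maps with the
#' adaptive min-of-max significance threshold, classification of the seven
#' evolution events (birth, death, continuation, merge, split, growth,
#' shrinkage), construction of the lineage query database by chained full
#' outer joins, and timeline layout with optional cross-over-reducing track
#' reordering.
#'
#' @param x A [dynamic_partition()], a data.frame with columns
#'   `node`/`time`/`cluster`, or a membership file path.
#' @param rho Optional user minimum edge weight in `[0, 1]`; applied to
#'   every interval when within `nu` of the mean tracked threshold (see
#'   [apply_user_threshold()]).
#' @param nu Tolerance for the threshold override (default 0.1).
#' @param growth_frac Relative growth/shrinkage fraction (default 0.2).
#' @param ordering `"given"` (keep the initial T1 ordering), `"greedy"`
#'   (default; [greedy_reorder()]), or `"bruteforce"`
#'   ([brute_force_order()], instances of at most `max_origins` origins).
#' @param initial_order Optional explicit initial track ordering.
#' @param survivor_policy Optional named vector `"<time>:<label>" -> origin`
#'   fixing merge survivors (see [resolve_merges()]).
#' @param max_origins Cap for the exhaustive ordering search (default 8).
#' @param ... Ignored.
#' @return An object of class `commtrace`; see the print/summary/plot
#'   methods, and the components `maps`, `events`, `db`, `threads`,
#'   `geometry`, `crossings_initial`, `crossings_final`.
#' @examples
#' sim <- generate_dynamic_partition(schedule_mergesplit(seed = 7))
#' fit <- commtrace(sim$partition)
#' fit
#' summary(fit)
#' @export
commtrace <- function(x, rho = NULL, nu = 0.1, growth_frac = 0.2,
                      ordering = c("greedy", "given", "bruteforce"),
                      initial_order = NULL, survivor_policy = NULL,
                      max_origins = 8L, ...) {
  ordering <- match.arg(ordering)
  dp <- if (is.character(x) && length(x) == 1L) read_memberships(x)
        else as.dynamic_partition(x)
  tr <- track_all(dp, rho = rho, nu = nu, growth_frac = growth_frac)
  pts <- lapply(tr$maps, make_pair_table)
  db <- build_query_database(pts)
  threads <- thread_sizes(extract_threads(db), dp)
  init <- initial_order %||chr% threads$origins
  check_ordering(threads, init)
  resolution <- resolve_merges(threads, init, survivor_policy, tr$maps)
  geom_init <- assign_tracks(threads, init, resolution = resolution)
  final <- switch(ordering,
    given = init,
    greedy = greedy_reorder(threads, init, survivor_policy, tr$maps),
    bruteforce = brute_force_order(threads, init, survivor_policy, tr$maps,
                                   max_origins = max_origins)$ordering)
  geom_final <- assign_tracks(threads, final, resolution = resolution)
  structure(list(partition = dp, maps = tr$maps, events = tr$events,
                 thetas = tr$thetas, thetas_applied = tr$thetas_applied,
                 mu_theta = tr$mu_theta, overridden = tr$overridden,
                 rho = rho, nu = nu, growth_frac = growth_frac,
                 pair_tables = pts, db = db, threads = threads,
                 ordering_mode = ordering,
                 ordering_initial = init, ordering_final = final,
                 geometry_initial = geom_init, geometry = geom_final,
                 crossings_initial = count_crossovers(geom_init),
                 crossings_final = count_crossovers(geom_final),
                 call = match.call()),
            class = "commtrace")
}

`%||chr%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.commtrace <- function(x, ...) {
  cat("Community evolution trace\n")
  cat("  snapshots:", x$partition$T, " nodes:",
      length(x$partition$node_universe), "\n")
  th <- sprintf("%.3f", x$thetas)
  cat("  thresholds theta^t:", paste(th, collapse = ", "),
      sprintf(" (mu_theta = %.3f%s)\n", x$mu_theta,
              if (x$overridden) sprintf(", overridden by rho = %g", x$rho)
              else ""))
  tb <- table(x$events$type)
  cat("  events:", paste(sprintf("%s %d", names(tb), tb), collapse = ", "),
      "\n")
  cat("  lineage threads:", nrow(x$db), " origins:",
      length(x$threads$origins), "\n")
  cat(sprintf("  cross-overs: %d (initial order) -> %d (%s order)\n",
              x$crossings_initial, x$crossings_final, x$ordering_mode))
  invisible(x)
}

#' @export
summary.commtrace <- function(object, ...) {
  structure(list(fit = object), class = "summary.commtrace")
}

#' @export
print.summary.commtrace <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nPer-interval thresholds:\n")
  print(data.frame(interval = seq_along(f$thetas),
                   theta = round(f$thetas, 4),
                   applied = round(f$thetas_applied, 4)), row.names = FALSE)
  cat("\nEvents:\n")
  ev <- f$events
  ev$unseen_frac <- NULL
  print(ev, row.names = FALSE)
  cat("\nTrack ordering:", paste(f$ordering_final, collapse = " > "), "\n")
  invisible(x)
}

#' @param y Unused.
#' @rdname commtrace
#' @export
plot.commtrace <- function(x, y, ...) {
  render_timeline(x$geometry, file = NULL, ...)
  invisible(x)
}

#' @export
coef.commtrace <- function(object, ...) {
  stats::setNames(object$thetas_applied,
                  paste0("theta_", seq_along(object$thetas_applied)))
}

#' Residual-style noise report: edge weights below the applied threshold
#' @param object A `commtrace` fit.
#' @param ... Unused.
#' @return A data.frame of the pruned (non-significant) edges.
#' @export
residuals.commtrace <- function(object, ...) {
  pruned <- lapply(object$maps, function(m) {
    e <- map_edge_table(m)
    e[!e$retained, c("t", "source", "target", "weight"), drop = FALSE]
  })
  out <- do.call(rbind, pruned)
  rownames(out) <- NULL
  out
}
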